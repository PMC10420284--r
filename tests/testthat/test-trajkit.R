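make_simple_traj <- function(zs, masses = rep(1, length(zs)),
                             names = paste0("A", seq_along(zs)),
                             molecule = rep(1, length(zs)),
                             species = rep("probe", length(zs)),
                             n_frames = 3, box = c(6, 6, 8)) {
  n <- length(zs)
  coords <- array(0, dim = c(n, 3, n_frames))
  coords[, 1, ] <- 3; coords[, 2, ] <- 3
  coords[, 3, ] <- zs
  trajectory(coords, matrix(box, 1),
             data.frame(name = names, mass = masses, molecule = molecule,
                        species = species))
}

test_that("center-of-mass z series is mass-weighted and COM-relative", {
  tr <- make_simple_traj(1.5)
  expect_equal(com_z_series(tr, "A1", 1), rep(1.5, 3))

  tr2 <- make_simple_traj(c(1, 2))
  expect_equal(com_z_series(tr2, c("A1", "A2"), 1), rep(1.5, 3))

  # rigid translation leaves the bilayer-relative series unchanged
  tr3 <- make_simple_traj(c(1.5, 0.1, -0.1),
                          species = c("probe", "lipid", "lipid"),
                          molecule = c(1, 2, 3))
  s0 <- com_z_series(tr3, "A1", 1, bilayer_species = "lipid")
  tr3s <- tr3
  tr3s$coords[, 3, ] <- tr3s$coords[, 3, ] + 0.3
  expect_equal(com_z_series(tr3s, "A1", 1, bilayer_species = "lipid"), s0,
               tolerance = 1e-12)
  expect_error(com_z_series(tr3, "nope", 1), "empty")
})

test_that("mass density profile has correct units and conserves mass", {
  # one 100-amu atom in a 6 x 6 box, 0.1 nm bins: 46.1 kg/m^3 in its bin
  tr <- make_simple_traj(1.55, masses = 100)
  prof <- mass_density_profile(tr, "probe", bin_width = 0.1)
  nz <- prof$density[prof$density > 0]
  expect_length(nz, 1)
  expect_equal(nz, 100 * 1.66054e-27 / (36 * 0.1 * 1e-27), tolerance = 1e-4)
  expect_equal(nz, 46.1, tolerance = 1e-3)

  # integral over z times the box cross-section = species mass, any binning
  tr2 <- make_simple_traj(c(0.3, 1.7, -2.2), masses = c(10, 20, 30))
  for (bw in c(0.1, 0.2)) {
    prof2 <- mass_density_profile(tr2, "probe", bin_width = bw)
    got <- sum(prof2$density) * bw * 36 * 1e-27
    expect_equal(got, 60 * 1.66053906660e-27, tolerance = 1e-9)
  }
})

test_that("group positions average |z| per molecule first, then across", {
  tr <- make_simple_traj(c(1.5, -1.5), molecule = c(1, 2),
                         names = c("A1", "A1"))
  gp <- group_positions(tr, list(core = "A1"), molecules = 1:2)
  expect_equal(gp$mean_abs_z, 1.5)
  expect_equal(gp$ci_half_width, 0)

  tr2 <- make_simple_traj(c(1, 2), molecule = c(1, 2),
                          names = c("A1", "A1"))
  gp2 <- group_positions(tr2, list(core = "A1"), molecules = 1:2)
  expect_equal(gp2$mean_abs_z, 1.5)
})

test_that("Gaussian-placed group recovers its mean position with shrinking CI", {
  make_gauss <- function(n_mol, n_frames, seed) {
    pl <- do.call(rbind, lapply(seq_len(n_mol), function(m)
      data.frame(name = "O41", mass = 16, molecule = m, species = "solute",
                 rule = "gaussian", z = 0.89, z_sd = 0.21, x = m, y = 2)))
    gen_toy_trajectory(toy_traj_spec(c(n_mol + 2, 4, 6), n_frames, pl,
                                     seed = seed))
  }
  tr <- make_gauss(12, 400, seed = 31)
  gp <- group_positions(tr, list(O41 = "O41"), molecules = 1:12)
  expect_equal(gp$mean_abs_z, 0.89, tolerance = 0.05)
  expect_gt(gp$ci_half_width, 0)
  # CI shrinks roughly as 1/sqrt(n_molecules)
  ci <- vapply(c(4, 16), function(nm)
    group_positions(make_gauss(nm, 400, seed = 37),
                    list(O41 = "O41"), molecules = seq_len(nm))$ci_half_width,
    0)
  expect_gt(ci[1], ci[2])
})

test_that("tilt honors the outward-normal convention in both leaflets", {
  # head 1 nm directly above tail, molecule in the upper leaflet: theta = 0
  up <- make_simple_traj(c(1.0, 2.0, 0.0), names = c("T", "H", "P"),
                         molecule = c(1, 1, 9),
                         species = c("sol", "sol", "lipid"))
  t_up <- tilt_distribution(up, c("T", "H"), 1, bilayer_species = "lipid")
  expect_equal(t_up$mean_theta, 0, tolerance = 1e-9)

  # mirrored geometry in the lower leaflet: still 0 after the normal flip
  dn <- make_simple_traj(c(-1.0, -2.0, 0.0), names = c("T", "H", "P"),
                         molecule = c(1, 1, 9),
                         species = c("sol", "sol", "lipid"))
  t_dn <- tilt_distribution(dn, c("T", "H"), 1, bilayer_species = "lipid")
  expect_equal(t_dn$mean_theta, 0, tolerance = 1e-9)

  # head toward the bilayer center from the upper leaflet: theta = 180
  flip <- make_simple_traj(c(2.0, 1.0, 0.0), names = c("T", "H", "P"),
                           molecule = c(1, 1, 9),
                           species = c("sol", "sol", "lipid"))
  expect_equal(tilt_distribution(flip, c("T", "H"), 1,
                                 bilayer_species = "lipid")$mean_theta, 180,
               tolerance = 1e-9)
})

test_that("uniform spherical axis gives sin-theta density with mean 90", {
  pl <- rbind(
    data.frame(name = "T", mass = 12, molecule = 1, species = "sol",
               rule = "fixed", z = 1.5, x = 3, y = 3),
    data.frame(name = "H", mass = 14, molecule = 1, species = "sol",
               rule = "fixed", z = 1.5, x = 3, y = 3))
  ap <- data.frame(molecule = 1, tail = "T", head = "H", length = 0.5,
                   theta_deg = NA)
  tr <- gen_toy_trajectory(toy_traj_spec(c(6, 6, 8), 8000, pl,
                                         axis_pairs = ap, seed = 41))
  td <- tilt_distribution(tr, c("T", "H"), 1, bin_width_deg = 10)
  expect_equal(td$mean_theta, 90, tolerance = 0.02)
  expect_equal(sum(td$density * 10), 1, tolerance = 1e-12)
  # density proportional to sin(theta): peak near 90, low near the poles
  expect_gt(td$density[td$theta_bins == 85], 3 * td$density[td$theta_bins == 5])
})

test_that("geometric H-bond criterion separates bonded and distant pairs", {
  # donor-acceptor at 0.40 nm: outside the default 0.35 nm cutoff
  n <- 4
  coords <- array(0, dim = c(n, 3, 1))
  coords[, 1, ] <- c(1, 1.1, 1.40, 1.25)   # D, H, A_far, A_near
  coords[, 2, ] <- 1; coords[, 3, ] <- 1
  tr <- trajectory(coords, matrix(c(6, 6, 6), 1),
                   data.frame(name = c("N1", "HN1", "OF", "ON"),
                              mass = c(14, 1, 16, 16),
                              molecule = c(1, 1, 2, 3),
                              species = c("solute", "solute", "lipid",
                                          "lipid")))
  s <- hbond_frequencies(tr, data.frame(donor = "N1", hydrogen = "HN1"),
                         list(far = "OF", near = "ON"))
  expect_equal(unname(s$freq[1, "far"]), 0)
  expect_equal(unname(s$freq[1, "near"]), 1)
  # angle criterion: acceptor at 0.25 nm but 90 degrees off the N-H axis
  tr2 <- tr
  tr2$coords[4, , 1] <- c(1, 1.25, 1)
  s2 <- hbond_frequencies(tr2, data.frame(donor = "N1", hydrogen = "HN1"),
                          list(far = "OF", near = "ON"))
  expect_equal(unname(s2$freq[1, "near"]), 0)
  # missing hydrogen is an explicit error
  expect_error(
    hbond_frequencies(tr, data.frame(donor = "N1", hydrogen = "HX"),
                      list(near = "ON")),
    "missing hydrogen")
})

test_that("per-donor and class-fraction arithmetic matches hand values", {
  s <- hbond_summary(matrix(c(0.5, 0.48), nrow = 2,
                            dimnames = list(c("N1", "N3"), "carbonyl")),
                     n_donors = 2)
  expect_equal(attr(per_donor_frequency(s), "display"), 0.49)
  expect_equal(s$grand_total, 0.98)

  s2 <- hbond_summary(matrix(c(1, 1), 1, dimnames = list("N", c("phosphate",
                                                                "carbonyl"))))
  expect_equal(unname(acceptor_class_fractions(s2)), c(50, 50))
  s3 <- hbond_summary(matrix(c(0.39, 0.59, 0.02), 1,
                             dimnames = list("N", c("phosphate", "carbonyl",
                                                    "glycerol"))))
  expect_equal(unname(acceptor_class_fractions(s3)), c(39, 59, 2))
  expect_equal(sum(acceptor_class_fractions(s3)), 100)
  s4 <- hbond_summary(matrix(1, 1, 1, dimnames = list("N", "phosphate")))
  expect_equal(unname(acceptor_class_fractions(s4)), 100)
  expect_equal(per_donor_frequency(hbond_summary(matrix(0, 1, 1),
                                                 n_donors = 3)), 0,
               ignore_attr = TRUE)
  expect_error(acceptor_class_fractions(hbond_summary(matrix(0, 1, 1))),
               "zero")
})

test_that("observables are invariant under rigid translation of all frames", {
  fx <- hbond_fixture(c(phosphate = 0.4, carbonyl = 0.5), n_donors = 2,
                      n_frames = 200)
  s0 <- hbond_frequencies(fx$traj, fx$donors, fx$acceptor_classes)
  shifted <- fx$traj
  shifted$coords <- shifted$coords + 0.37
  s1 <- hbond_frequencies(shifted, fx$donors, fx$acceptor_classes)
  expect_equal(s1$freq, s0$freq)
})
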