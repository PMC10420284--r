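# Shared fixtures and independent oracles, all built in code.

RT298 <- memparti::rt_kj(298)

# --- analytic biased-Gaussian window sampler ---------------------------------
# For flat or quadratic G(z) = g0 + a0/2 * z^2 the biased stationary density
# of a window (center c, force constant k) is Gaussian with
#   mean = k*c/(k + a0),  var = RT/(k + a0).
# Sampling it directly is an oracle independent of the Brownian integrator.
gaussian_windows <- function(centers, k, n, a0 = 0, seed = 1,
                             temperature = 298) {
  RT <- memparti::rt_kj(temperature)
  withr::with_seed(seed, lapply(centers, function(c.) {
    memparti::umbrella_window(
      c., k, rnorm(n, mean = k * c. / (k + a0), sd = sqrt(RT / (k + a0))))
  }))
}

# --- brute-force WHAM oracle -------------------------------------------------
# Directly maximizes the pooled histogram log-likelihood
#   L(p) = sum_b n_b log p_b - sum_j N_j log(sum_b c_jb p_b)
# over the probability simplex of the populated bins (softmax parameterized,
# analytic gradient), independent of the self-consistent iteration.
# Returns dG = -RT log p on the populated bins, gauge-fixed to mean zero.
brute_force_wham <- function(windows, n_bins, z_range, temperature = 298) {
  RT <- memparti::rt_kj(temperature)
  edges <- seq(z_range[1], z_range[2], length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  counts <- vapply(windows, function(w) {
    s <- w$samples[w$samples >= z_range[1] & w$samples <= z_range[2]]
    idx <- findInterval(s, edges, rightmost.closed = TRUE)
    tabulate(pmin(pmax(idx, 1L), n_bins), n_bins)
  }, numeric(n_bins))
  nb <- rowSums(counts)
  pop <- which(nb > 0)
  N <- colSums(counts)
  C <- exp(-0.5 * sweep(outer(centers[pop],
                              vapply(windows, `[[`, 0, "center"), "-")^2,
                        2, vapply(windows, `[[`, 0, "force_const"), "*") / RT)
  nbp <- nb[pop]
  negll <- function(u) {
    p <- exp(u - max(u)); p <- p / sum(p)
    -(sum(nbp * log(p)) - sum(N * log(as.vector(crossprod(C, p)))))
  }
  grad <- function(u) {
    p <- exp(u - max(u)); p <- p / sum(p)
    S <- as.vector(crossprod(C, p))
    -(nbp - p * as.vector(C %*% (N / S)))
  }
  u0 <- log(nbp / sum(nbp))
  opt <- optim(u0, negll, grad, method = "BFGS",
               control = list(maxit = 10000, reltol = 1e-16))
  opt <- optim(opt$par, negll, grad, method = "BFGS",
               control = list(maxit = 10000, reltol = 1e-16))
  p <- exp(opt$par - max(opt$par)); p <- p / sum(p)
  dG <- -RT * log(p)
  list(z = centers[pop], dG = dG - mean(dG), pop = pop)
}

# --- toy-trajectory builders -------------------------------------------------

# Trajectory with one solute molecule whose N-H donors bond to lipid acceptor
# atoms of several classes at a prescribed per-pair occupancy matrix
# (n_donors x classes).  Donor d sits at x = 2*d nm so cross-pair distances
# stay far beyond the cutoff.
hbond_fixture_matrix <- function(occ, n_frames = 5000) {
  classes <- colnames(occ)
  n_donors <- nrow(occ)
  pl <- list(); hp <- list()
  for (d in seq_len(n_donors)) {
    dn <- paste0("N", d); hn <- paste0("HN", d)
    pl[[length(pl) + 1L]] <- data.frame(
      name = c(dn, hn), mass = c(14, 1), molecule = 1, species = "solute",
      rule = "fixed", z = 1.5, x = 2 * d, y = 2)
    for (ci in seq_along(classes)) {
      an <- paste0("O", d, "_", ci)
      pl[[length(pl) + 1L]] <- data.frame(
        name = an, mass = 16, molecule = 100 + d, species = "lipid",
        rule = "fixed", z = 1.5, x = 2 * d, y = 2)
      hp[[length(hp) + 1L]] <- data.frame(
        molecule = 1, donor = dn, hydrogen = hn, acceptor = an,
        occupancy = occ[d, ci])
    }
  }
  spec <- memparti::toy_traj_spec(
    box = c(2 * n_donors + 2, 4, 6), n_frames = n_frames,
    placements = do.call(rbind, pl), hbond_pairs = do.call(rbind, hp))
  donors <- data.frame(donor = paste0("N", seq_len(n_donors)),
                       hydrogen = paste0("HN", seq_len(n_donors)))
  acceptors <- lapply(seq_along(classes), function(ci)
    paste0("O", seq_len(n_donors), "_", ci))
  names(acceptors) <- classes
  list(traj = memparti::gen_toy_trajectory(spec), donors = donors,
       acceptor_classes = acceptors)
}

# class totals split evenly across donors
hbond_fixture <- function(class_totals, n_donors, n_frames = 5000) {
  classes <- names(class_totals)
  pl <- list(); hp <- list()
  for (d in seq_len(n_donors)) {
    dn <- paste0("N", d); hn <- paste0("HN", d)
    pl[[length(pl) + 1L]] <- data.frame(
      name = c(dn, hn), mass = c(14, 1), molecule = 1, species = "solute",
      rule = "fixed", z = 1.5, x = 2 * d, y = 2)
    for (ci in seq_along(classes)) {
      an <- paste0("O", d, "_", ci)
      pl[[length(pl) + 1L]] <- data.frame(
        name = an, mass = 16, molecule = 100 + d, species = "lipid",
        rule = "fixed", z = 1.5, x = 2 * d, y = 2)
      hp[[length(hp) + 1L]] <- data.frame(
        molecule = 1, donor = dn, hydrogen = hn, acceptor = an,
        occupancy = class_totals[[ci]] / n_donors)
    }
  }
  spec <- memparti::toy_traj_spec(
    box = c(2 * n_donors + 2, 4, 6), n_frames = n_frames,
    placements = do.call(rbind, pl), hbond_pairs = do.call(rbind, hp))
  traj <- memparti::gen_toy_trajectory(spec)
  donors <- data.frame(donor = paste0("N", seq_len(n_donors)),
                       hydrogen = paste0("HN", seq_len(n_donors)))
  acceptors <- lapply(seq_along(classes), function(ci)
    paste0("O", seq_len(n_donors), "_", ci))
  names(acceptors) <- classes
  list(traj = traj, donors = donors, acceptor_classes = acceptors)
}

# n_mol solute molecules with a two-atom long axis at fixed tilt theta_deg,
# all in the upper leaflet, plus a couple of lipid atoms to define the
# bilayer COM near z = 0.
tilt_fixture <- function(theta_deg, n_mol = 4, n_frames = 50, seed = 1) {
  pl <- list(list(name = "P", mass = 31, molecule = 999, species = "lipid",
                  rule = "fixed", z = 0.02, x = 0.5, y = 0.5),
             list(name = "P2", mass = 31, molecule = 998, species = "lipid",
                  rule = "fixed", z = -0.02, x = 0.7, y = 0.5))
  ap <- list()
  for (m in seq_len(n_mol)) {
    pl[[length(pl) + 1L]] <- list(name = "C1", mass = 12, molecule = m,
                                  species = "solute", rule = "fixed",
                                  z = 1.2, x = 1.5 * m, y = 2)
    pl[[length(pl) + 1L]] <- list(name = "N2", mass = 14, molecule = m,
                                  species = "solute", rule = "fixed",
                                  z = 1.2, x = 1.5 * m, y = 2)
    ap[[m]] <- data.frame(molecule = m, tail = "C1", head = "N2",
                          length = 1.0, theta_deg = theta_deg)
  }
  spec <- memparti::toy_traj_spec(
    box = c(1.5 * n_mol + 2, 4, 8), n_frames = n_frames,
    placements = do.call(rbind, lapply(pl, as.data.frame)),
    axis_pairs = do.call(rbind, ap), seed = seed)
  memparti::gen_toy_trajectory(spec)
}
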