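test_that("noise-free intensity and anisotropy fits recover truth to 6 s.f.", {
  grid <- default_lipid_grid()
  for (Kp in c(1.8e3, 5.8e2)) {
    tr <- fluor_truth(Kp = Kp, noise_cv = 0)
    fi <- fit_intensity(gen_fluor_titration(tr, grid, "intensity"))
    expect_equal(fi$Kp, Kp, tolerance = 1e-6)
    expect_equal(fi$endpoint_low, tr$Iw, tolerance = 1e-6)
    expect_equal(fi$endpoint_high, tr$Im, tolerance = 1e-6)
    fa <- fit_anisotropy(
      gen_fluor_titration(tr, grid, "anisotropy", band = "470-490"),
      alphaM = 8)
    expect_equal(fa$Kp, Kp, tolerance = 1e-6)
    expect_false(fa$unidentifiable)
  }
})

test_that("three-point exact series pins the closed-form anchor signals", {
  # Kp*Vbar*L in {0, 1, 1e6}: signals 1, 6, ~11
  Kp <- 1000; Vbar <- 0.8
  tr <- fluor_truth(Kp = Kp, Iw = 1, Im = 11, Vbar = Vbar, noise_cv = 0)
  s <- gen_fluor_titration(tr, c(0, 1, 2, 1e6) / (Kp * Vbar), "intensity")
  expect_equal(s$signal[1:2], c(1, 6))
  expect_equal(s$signal[4], 11, tolerance = 1e-5)
  f <- fit_intensity(s, Vbar = Vbar)
  expect_equal(f$Kp, Kp, tolerance = 1e-6)
})

test_that("flat and endpoint-degenerate series are flagged unidentifiable", {
  tr <- fluor_truth(Iw = 5, Im = 5, noise_cv = 0)
  s <- gen_fluor_titration(tr, default_lipid_grid(), "intensity")
  f <- fit_intensity(s)
  expect_true(f$unidentifiable)

  tr2 <- fluor_truth(rw = 0.1, rm = 0.1, noise_cv = 0,
                     alphaM_by_band = c(b = 1))
  f2 <- fit_anisotropy(
    gen_fluor_titration(tr2, default_lipid_grid(), "anisotropy", band = "b"),
    alphaM = 1)
  expect_true(f2$unidentifiable)
})

test_that("fitted Kp is invariant to intensity rescaling and point order", {
  tr <- fluor_truth(Kp = 2.4e3, noise_cv = 0.02, seed = 21)
  s <- gen_fluor_titration(tr, default_lipid_grid(), "intensity")
  f1 <- fit_intensity(s)
  s_scaled <- titration_series(s$lipid, 37.5 * s$signal, "intensity")
  expect_equal(fit_intensity(s_scaled)$Kp, f1$Kp, tolerance = 1e-6)
  o <- c(5, 1, 9, 3, 13, 7, 2, 11, 4, 12, 6, 10, 8)
  s_perm <- titration_series(s$lipid[o], s$signal[o], "intensity")
  expect_equal(fit_intensity(s_perm)$Kp, f1$Kp, tolerance = 1e-9)
})

test_that("forward curves are monotone whenever the endpoints differ", {
  grid <- default_lipid_grid(n = 40)
  tr <- fluor_truth(Kp = 1.8e3, noise_cv = 0)
  s <- gen_fluor_titration(tr, grid, "intensity")
  expect_true(all(diff(s$signal) > 0))
  sa <- gen_fluor_titration(tr, grid, "anisotropy", band = "490-510")
  expect_true(all(diff(sa$signal) > 0))
})

test_that("spectral alpha_M estimator integrates band ratios", {
  wl <- 380:620
  base <- dnorm(wl, 500, 45)
  sp <- list(wavelengths = wl, I_water = base, I_membrane = 13 * base)
  expect_equal(estimate_alpha_m(sp, c(450, 470)), 13, tolerance = 1e-9)
  sp$I_membrane <- base
  expect_equal(estimate_alpha_m(sp, c(470, 490)), 1, tolerance = 1e-9)
  expect_error(estimate_alpha_m(sp, c(700, 720)), "outside")
  sp$I_water <- 0 * base
  expect_error(estimate_alpha_m(sp, c(450, 470)), "zero")

  # a blue-shifted membrane spectrum yields band-dependent, decreasing alphaM
  sp2 <- list(wavelengths = wl, I_water = dnorm(wl, 505, 40),
              I_membrane = 9 * dnorm(wl, 480, 40))
  a <- vapply(list(c(450, 470), c(470, 490), c(490, 510)),
              function(b) estimate_alpha_m(sp2, b), 0)
  expect_true(all(diff(a) < 0))
})

test_that("band-wise anisotropy fits agree when weighted by their alpha_M", {
  tr <- fluor_truth(Kp = 1.8e3, noise_cv = 0)
  grid <- default_lipid_grid()
  kps <- vapply(names(tr$alphaM_by_band), function(b) {
    s <- gen_fluor_titration(tr, grid, "anisotropy", band = b)
    fit_anisotropy(s, alphaM = tr$alphaM_by_band[[b]])$Kp
  }, 0)
  expect_equal(max(kps) / min(kps), 1, tolerance = 1e-6)
})

test_that("intensity and anisotropy routes agree on common noisy truth", {
  tr <- fluor_truth(Kp = 1.8e3, noise_cv = 0.02)
  grid <- default_lipid_grid()
  lk <- unlist(lapply(1:6, function(r) {
    si <- gen_fluor_titration(tr, grid, "intensity", seed = 100 + r)
    sa <- gen_fluor_titration(tr, grid, "anisotropy", band = "470-490",
                              seed = 200 + r)
    c(log10(fit_intensity(si)$Kp),
      log10(fit_anisotropy(sa, alphaM = 8)$Kp))
  }))
  ints <- lk[seq(1, 12, by = 2)]
  anis <- lk[seq(2, 12, by = 2)]
  expect_lt(abs(mean(ints) - mean(anis)), 0.02)
})

test_that("joint fit shares one Kp across bands and flags bad weighting", {
  tr <- fluor_truth(Kp = 1.8e3, noise_cv = 0)
  grid <- default_lipid_grid()
  series <- lapply(names(tr$alphaM_by_band), function(b)
    gen_fluor_titration(tr, grid, "anisotropy", band = b))
  am <- unname(tr$alphaM_by_band)
  jf <- joint_band_fit(series, am)
  expect_equal(jf$Kp, 1.8e3, tolerance = 1e-6)
  expect_lt(jf$residual_norm, 1e-8)

  # doubling one band's alphaM leaves residual the per-band fits don't have
  am_bad <- am; am_bad[1] <- 2 * am_bad[1]
  jf_bad <- joint_band_fit(series, am_bad)
  per_band <- sum(vapply(seq_along(series), function(i)
    fit_anisotropy(series[[i]], alphaM = am_bad[i])$residual_norm^2, 0))
  expect_gt(jf_bad$residual_norm^2, per_band + 1e-8)

  expect_error(joint_band_fit(list(), numeric(0)), "empty")
})
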