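# WHAM and PMF post-processing, checked against independent oracles:
# analytic biased-Gaussian window samplers, a brute-force likelihood
# optimizer, and closed-form Boltzmann integrals.

test_that("WHAM recovers a flat landscape from Gaussian-sampled windows", {
  wins <- gaussian_windows(seq(0, 4, 0.1), k = 3000, n = 4000, a0 = 0,
                           seed = 2)
  prof <- wham(wins)
  ok <- is.finite(prof$dG)
  expect_gt(sum(ok), 150)
  expect_lt(diff(range(prof$dG[ok])), 2.5)  # flat within sampling noise
})

test_that("WHAM recovers a quadratic landscape coefficient within 5%", {
  wins <- gaussian_windows(seq(0, 2, 0.1), k = 3000, n = 4000, a0 = 100,
                           seed = 3)
  prof <- wham(wins, z_range = c(0, 2), n_bins = 100, anchor = 0)
  sel <- is.finite(prof$dG)
  co <- coef(lm(prof$dG[sel] ~ I(prof$z[sel]^2)))[2]
  expect_equal(unname(co) * 2, 100, tolerance = 0.05)
})

test_that("WHAM equals brute-force likelihood optimization on a tiny instance", {
  wins <- gaussian_windows(c(1.0, 1.1), k = 3000, n = 20, seed = 7)
  prof <- wham(wins, n_bins = 40, z_range = c(0.8, 1.3), tol = 1e-14,
               max_iter = 1e6, anchor = 1.0)
  oracle <- brute_force_wham(wins, n_bins = 40, z_range = c(0.8, 1.3))
  got <- prof$dG[oracle$pop]
  expect_lt(max(abs((got - mean(got)) - oracle$dG)), 1e-6)
})

test_that("WHAM output is invariant under window reordering", {
  wins <- gaussian_windows(seq(0.5, 1.5, 0.1), k = 3000, n = 2000, a0 = 50,
                           seed = 5)
  p1 <- wham(wins, z_range = c(0, 2), n_bins = 100)
  p2 <- wham(rev(wins), z_range = c(0, 2), n_bins = 100)
  expect_equal(p1$dG, p2$dG, tolerance = 1e-6)
})

test_that("WHAM reports non-overlapping adjacent windows", {
  wins <- gaussian_windows(c(0.5, 3.5), k = 3000, n = 500, seed = 8)
  expect_error(wham(wins), "share only")
})

test_that("WHAM error converges with sample size for a quadratic landscape", {
  err <- vapply(c(1e3, 1e4, 1e5), function(n) {
    wins <- gaussian_windows(seq(0, 2, 0.1), k = 3000, n = n, a0 = 100,
                             seed = 11)
    prof <- wham(wins, z_range = c(0, 2), n_bins = 100, anchor = 0)
    sel <- is.finite(prof$dG) & prof$z < 1.5
    sqrt(mean((prof$dG[sel] - 50 * prof$z[sel]^2)^2))
  }, 0)
  expect_true(all(diff(err) < 0))
})

test_that("bootstrap error vanishes for deterministic resampling and grows
           with shrinking windows", {
  wins <- gaussian_windows(seq(0.5, 1.5, 0.1), k = 3000, n = 1000, seed = 13)
  # whole-window blocks: every replicate is the original data
  bp <- bootstrap_pmf(wins, n_boot = 5, seed = 1, block_len = 1000,
                      z_range = c(0, 2), n_bins = 100)
  expect_lt(max(bp$boot_err, na.rm = TRUE), 1e-9)
  # and the error is then invariant to the anchor choice
  bp0 <- bootstrap_pmf(wins, n_boot = 5, seed = 1, block_len = 1000,
                       z_range = c(0, 2), n_bins = 100, anchor = 1.0)
  expect_equal(bp$boot_err, bp0$boot_err, tolerance = 1e-9)

  b_small <- bootstrap_pmf(gaussian_windows(seq(0.5, 1.5, 0.1), 3000, 100,
                                            seed = 13),
                           n_boot = 30, seed = 2, z_range = c(0, 2),
                           n_bins = 100)
  b_large <- bootstrap_pmf(wins, n_boot = 30, seed = 2, z_range = c(0, 2),
                           n_bins = 100)
  expect_gt(median(b_small$boot_err, na.rm = TRUE),
            median(b_large$boot_err, na.rm = TRUE))
})

test_that("time-block profiles agree for stationary windows and expose drift", {
  wins <- gaussian_windows(seq(0.5, 1.5, 0.1), k = 3000, n = 4000, seed = 17)
  full <- wham(wins, z_range = c(0, 2), n_bins = 100)
  blocks <- convergence_series(wins, list(c(0, 2000), c(2000, 4000)),
                               z_range = c(0, 2), n_bins = 100)
  d12 <- abs(blocks[[1]]$dG - blocks[[2]]$dG)
  expect_lt(max(d12[is.finite(d12)]), 2.0)
  # the full time range reproduces the plain WHAM result
  whole <- convergence_series(wins, list(c(0, 4000)), z_range = c(0, 2),
                              n_bins = 100)[[1]]
  expect_equal(whole$dG, full$dG, tolerance = 1e-12)

  # non-stationary windows: second half shifted by 0.05 nm
  drift <- lapply(wins, function(w) {
    s <- w$samples
    s[(length(s) / 2 + 1):length(s)] <-
      s[(length(s) / 2 + 1):length(s)] + 0.05
    umbrella_window(w$center, w$force_const, s, w$dt_ps, w$t0_ps)
  })
  db <- convergence_series(drift, list(c(0, 2000), c(2000, 4000)),
                           z_range = c(0, 2), n_bins = 100)
  dd <- abs(db[[1]]$dG - db[[2]]$dG)
  expect_gt(max(dd[is.finite(dd)]), max(d12[is.finite(d12)]))

  expect_error(convergence_series(wins, list(c(1e7, 2e7)),
                                  z_range = c(0, 2)), "empty")
})

test_that("Boltzmann integration reproduces closed-form partition factors", {
  z <- seq(0.01, 3.99, by = 0.02)
  # flat profile: exactly 1
  expect_equal(kp_from_pmf(pmf_profile(z, rep(0, length(z)))), 1,
               tolerance = 1e-12)
  # square well, depth RT ln 10 over [1.0, 1.4]: (0.4*10 + 3.6)/4 = 1.9
  dG <- ifelse(z > 1.0 & z < 1.4, -RT298 * log(10), 0)
  expect_equal(kp_from_pmf(pmf_profile(z, dG, temperature = 298)), 1.9,
               tolerance = 1e-12)
  # Gaussian well against adaptive quadrature
  zf <- seq(0.0025, 3.9975, by = 0.005)
  well <- function(z) -8 * exp(-(z - 1.2)^2 / (2 * 0.15^2))
  kp_pkg <- kp_from_pmf(pmf_profile(zf, well(zf), temperature = 298))
  kp_orc <- integrate(function(z) exp(-well(z) / RT298), 0, 4,
                      subdivisions = 2000, rel.tol = 1e-12)$value / 4
  expect_equal(kp_pkg, kp_orc, tolerance = 1e-3)
  # masked gap inside [0, a] is an error
  dGg <- rep(0, length(z)); dGg[100] <- NA
  expect_error(kp_from_pmf(pmf_profile(z, dGg)), "masked")
})

test_that("kp_from_pmf obeys exact shift covariance", {
  z <- seq(0.01, 3.99, by = 0.02)
  dG <- -5 * exp(-(z - 1.4)^2 / 0.18)
  p0 <- pmf_profile(z, dG, temperature = 298)
  for (c. in c(-3, 1.7, 5)) {
    pc <- pmf_profile(z, dG + c., temperature = 298)
    expect_equal(kp_from_pmf(pc), kp_from_pmf(p0) * exp(-c. / RT298),
                 tolerance = 1e-9)
  }
})

test_that("delta_log_kp is a shift-invariant antisymmetric log contrast", {
  z <- seq(0.01, 3.99, by = 0.02)
  A <- pmf_profile(z, -6 * exp(-(z - 1.3)^2 / 0.1), temperature = 298)
  expect_equal(delta_log_kp(A, A), 0, tolerance = 1e-12)
  B <- pmf_profile(z, A$dG + 5, temperature = 298)
  expect_equal(delta_log_kp(A, B), 5 / (RT298 * log(10)), tolerance = 1e-9)
  expect_equal(delta_log_kp(A, B), 0.876, tolerance = 1e-3)
  expect_equal(delta_log_kp(A, B), -delta_log_kp(B, A), tolerance = 1e-12)
  # common additive shift of both profiles cancels
  A2 <- pmf_profile(z, A$dG + 2.2, temperature = 298)
  B2 <- pmf_profile(z, B$dG + 2.2, temperature = 298)
  expect_equal(delta_log_kp(A2, B2), delta_log_kp(A, B), tolerance = 1e-9)
  C <- pmf_profile(z, A$dG, temperature = 310)
  expect_error(delta_log_kp(A, C), "temperature")
})

test_that("PMF summaries report barriers the way a crossing profile is read", {
  z <- seq(0.02, 3.98, by = 0.04)
  # piecewise crossing profile: interior max +4 at 0.2, min -20 at 1.4
  dG <- numeric(length(z))
  dG[z <= 0.2] <- 3 + 5 * z[z <= 0.2]
  m <- z > 0.2 & z <= 1.4
  dG[m] <- 4 - 24 * (z[m] - 0.2) / 1.2
  m <- z > 1.4 & z <= 2
  dG[m] <- -20 + 20 * (z[m] - 1.4) / 0.6
  dG[z > 2] <- 0
  s <- summarize_pmf(pmf_profile(z, dG))
  expect_lt(abs(s$dG_min - -20), 0.5)
  expect_lt(abs(s$z_max - 0.2), 0.05)
  expect_lt(abs(s$barrier_from_min - 24), 0.6)
  expect_false(s$no_interior_max)

  # monotone toward the center: barrier to z = 0, flagged
  dG2 <- 10 * (1 - z / 4) - 10
  s2 <- summarize_pmf(pmf_profile(z, dG2))
  expect_true(s2$no_interior_max)
  expect_equal(s2$barrier_from_min, s2$dG_center - s2$dG_min)

  # flat: zero barrier
  s3 <- summarize_pmf(pmf_profile(z, rep(0, length(z))))
  expect_equal(s3$barrier_from_min, 0)
})
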