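# Potential-of-mean-force reconstruction from umbrella-sampling windows.
#
# Each window j holds samples of the reaction coordinate z under a harmonic
# bias w_j(z) = k_j/2 (z - c_j)^2.  WHAM finds the unbiased per-bin
# probability P(z) maximizing the pooled histogram likelihood via the
# self-consistent equations
#   P(z)  = sum_j n_j(z) / sum_j N_j f_j exp(-w_j(z)/RT)
#   1/f_j = sum_z P(z) exp(-w_j(z)/RT)
# iterated until the window free energies ln f_j stop moving.  The PMF is
# dG(z) = -RT ln P(z), shifted so that the bulk-water plateau is zero.

#' Umbrella-sampling window
#'
#' @param center bias center, nm.
#' @param force_const harmonic force constant, kJ mol^-1 nm^-2 (> 0).
#' @param samples numeric vector of reaction-coordinate samples, nm
#'   (non-empty, after any equilibration discard).
#' @param dt_ps sampling interval, ps.
#' @param t0_ps time of the first retained sample, ps (records how much
#'   equilibration was discarded upstream).
#' @return An `umbrella_window` object.
#' @export
umbrella_window <- function(center, force_const, samples, dt_ps = 1,
                            t0_ps = 0) {
  .chk_num1(center, "center")
  .chk_num1(force_const, "force_const", positive = TRUE)
  samples <- as.numeric(samples)
  if (!length(samples) || anyNA(samples))
    stop("samples must be non-empty and free of NA")
  structure(list(center = center, force_const = force_const,
                 samples = samples, dt_ps = dt_ps, t0_ps = t0_ps),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("umbrella_window: center %.3f nm, k = %g kJ/mol/nm^2, %d samples (dt = %g ps)\n",
              x$center, x$force_const, length(x$samples), x$dt_ps))
  invisible(x)
}

# sample times (ps) of a window
.window_times <- function(w) w$t0_ps + (seq_along(w$samples) - 1) * w$dt_ps

#' Free-energy profile container
#'
#' @param z bin centers, nm.
#' @param dG free energy per bin, kJ/mol (NA for unpopulated, masked bins).
#' @param temperature K.
#' @param anchor description or z-value of the zero anchor.
#' @param boot_err optional per-bin bootstrap standard deviation, kJ/mol.
#' @param counts optional per-bin pooled sample counts.
#' @return A `pmf_profile` object.
#' @export
pmf_profile <- function(z, dG, temperature = 298, anchor = NA,
                        boot_err = NULL, counts = NULL) {
  stopifnot(length(z) == length(dG))
  structure(list(z = as.numeric(z), dG = as.numeric(dG),
                 temperature = temperature, anchor = anchor,
                 boot_err = boot_err, counts = counts),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  ok <- is.finite(x$dG)
  cat(sprintf("pmf_profile: %d bins on [%.3g, %.3g] nm (%d populated), T = %g K\n",
              length(x$z), min(x$z), max(x$z), sum(ok), x$temperature))
  if (any(ok))
    cat(sprintf("  dG range: [%.3g, %.3g] kJ/mol%s\n",
                min(x$dG[ok]), max(x$dG[ok]),
                if (!is.null(x$boot_err)) "; bootstrap errors attached" else ""))
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, ..., xlab = "z (nm)",
                             ylab = expression(Delta * G ~ "(kJ/mol)")) {
  plot(x$z, x$dG, type = "l", xlab = xlab, ylab = ylab, ...)
  if (!is.null(x$boot_err)) {
    lines(x$z, x$dG + x$boot_err, lty = 3)
    lines(x$z, x$dG - x$boot_err, lty = 3)
  }
  invisible(x)
}

# histogram counts (bins x windows) on a common grid
.wham_counts <- function(windows, edges) {
  n_bins <- length(edges) - 1L
  vapply(windows, function(w) {
    s <- w$samples
    s <- s[s >= edges[1] & s <= edges[length(edges)]]
    if (!length(s)) return(numeric(n_bins))
    idx <- findInterval(s, edges, rightmost.closed = TRUE)
    tabulate(pmin(pmax(idx, 1L), n_bins), n_bins)
  }, numeric(n_bins))
}

.anchor_dG <- function(dG, z, anchor, z_hi) {
  ok <- is.finite(dG)
  if (identical(anchor, "bulk")) {
    idx <- ok & z >= z_hi - 0.5
    if (!any(idx)) idx <- seq_along(z) == max(which(ok))
  } else {
    .chk_num1(anchor, "anchor")
    i <- which(ok)[which.min(abs(z[ok] - anchor))]
    idx <- seq_along(z) == i
  }
  dG - mean(dG[idx])
}

#' WHAM reconstruction of a PMF from umbrella windows
#'
#' Self-consistent iteration of the weighted-histogram equations on a uniform
#' bin grid.  Bins that collect no samples are masked (`NA`).  The profile is
#' anchored either to the mean over the outermost 0.5 nm (`anchor = "bulk"`,
#' the bulk-water plateau) or to a user z-value.
#'
#' @param windows list of [umbrella_window()] objects (>= 2, with overlapping
#'   sampled ranges).
#' @param n_bins number of bins (default 200).
#' @param z_range numeric length-2 range of the reaction coordinate, nm
#'   (default `c(0, 4)`, i.e. 0.02 nm bins).
#' @param temperature K.
#' @param tol convergence tolerance on `max |delta ln f_j|` (default 1e-7).
#' @param max_iter iteration cap; exceeding it is an error.
#' @param anchor `"bulk"` or a numeric z-value, nm.
#' @param min_overlap minimum number of bins that each pair of adjacent
#'   windows (by center) must both populate; an informative error names the
#'   first failing pair.
#' @return A [pmf_profile()] with attributes `iterations` and `window_g`
#'   (converged `ln f_j`).
#' @references Kumar et al. (1992) J. Comput. Chem. 13:1011 (the WHAM
#'   equations); Hub, de Groot & van der Spoel (2010) J. Chem. Theory
#'   Comput. 6:3713 (g_wham conventions followed here).
#' @export
wham <- function(windows, n_bins = 200, z_range = c(0, 4), temperature = 298,
                 tol = 1e-7, max_iter = 1e5, anchor = "bulk",
                 min_overlap = 1) {
  if (length(windows) < 2) stop("need at least 2 windows")
  lapply(windows, function(w) stopifnot(inherits(w, "umbrella_window")))
  stopifnot(tol > 0, length(z_range) == 2, z_range[1] < z_range[2])
  edges <- seq(z_range[1], z_range[2], length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  RT <- rt_kj(temperature)

  counts <- .wham_counts(windows, edges)
  N <- colSums(counts)
  if (any(N == 0))
    stop("window(s) ", paste(which(N == 0), collapse = ", "),
         " have no samples inside z_range")

  # adjacent-window overlap diagnostic
  ord <- order(vapply(windows, `[[`, 0, "center"))
  for (i in seq_len(length(ord) - 1L)) {
    a <- ord[i]; b <- ord[i + 1L]
    shared <- sum(counts[, a] > 0 & counts[, b] > 0)
    if (shared < min_overlap)
      stop(sprintf(
        "windows centered at %.3f and %.3f nm share only %d populated bin(s) (< %d): increase sampling or window density",
        windows[[a]]$center, windows[[b]]$center, shared, min_overlap))
  }

  nb <- rowSums(counts)
  pop <- nb > 0
  cen_j <- vapply(windows, `[[`, 0, "center")
  k_j <- vapply(windows, `[[`, 0, "force_const")
  # bias Boltzmann factors on populated bins, bins x windows
  Wp <- 0.5 * outer(centers[pop], cen_j, "-")^2
  Wp <- sweep(Wp, 2, k_j, "*")
  C <- exp(-Wp / RT)
  nbp <- nb[pop]

  g <- numeric(length(windows))  # ln f_j
  it <- 0L
  repeat {
    it <- it + 1L
    denom <- as.vector(C %*% (N * exp(g)))
    P <- nbp / denom
    P <- P / sum(P)
    gnew <- -log(as.vector(crossprod(C, P)))
    gnew <- gnew - gnew[1]
    delta <- max(abs(gnew - (g - g[1])))
    g <- gnew
    if (delta < tol) break
    if (it >= max_iter)
      stop("WHAM did not converge in ", max_iter,
           " iterations (last max |delta ln f| = ", signif(delta, 3), ")")
  }

  dG <- rep(NA_real_, n_bins)
  dG[pop] <- -RT * log(P)
  dG <- .anchor_dG(dG, centers, anchor, z_range[2])
  out <- pmf_profile(centers, dG, temperature = temperature, anchor = anchor,
                     counts = nb)
  attr(out, "iterations") <- it
  attr(out, "window_g") <- g
  out
}

#' Bootstrap uncertainty for a WHAM profile
#'
#' Moving-block bootstrap within each window (preserving the window layout,
#' so no artificial coverage gaps appear), optionally combined with
#' resampling whole windows with replacement.  Each replicate profile is
#' re-anchored with the same rule before the per-bin standard deviation is
#' taken, so the reported error is invariant to the anchor choice.
#'
#' @inheritParams wham
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed integer RNG seed.
#' @param block_len block length in samples for the within-window moving-block
#'   resampling; default `max(1, floor(n/20))` per window.  Blocks respect
#'   serial correlation in the window time series.
#' @param resample_windows logical; also draw the window set with replacement
#'   (default FALSE: with sparsely overlapping windows, dropping a window
#'   opens an unsampled gap).
#' @return The full-data [wham()] profile with `boot_err` filled in (per-bin
#'   SD over replicates, NA where fewer than 2 replicates populated the bin).
#' @export
bootstrap_pmf <- function(windows, n_boot, seed = 1, block_len = NULL,
                          resample_windows = FALSE, n_bins = 200,
                          z_range = c(0, 4), temperature = 298, tol = 1e-7,
                          max_iter = 1e5, anchor = "bulk", min_overlap = 1) {
  if (length(windows) < 2) stop("need at least 2 windows")
  if (n_boot < 2) stop("n_boot must be >= 2")
  base <- wham(windows, n_bins, z_range, temperature, tol, max_iter, anchor,
               min_overlap)
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- if (resample_windows)
        sample.int(length(windows), replace = TRUE)
      else seq_along(windows)
      wb <- lapply(windows[idx], function(w) {
        n <- length(w$samples)
        bl <- if (is.null(block_len)) max(1L, n %/% 20L) else min(block_len, n)
        nblocks <- ceiling(n / bl)
        starts <- sample.int(n - bl + 1L, nblocks, replace = TRUE)
        pick <- as.vector(vapply(starts, function(s) s + seq_len(bl) - 1L,
                                 integer(bl)))[seq_len(n)]
        umbrella_window(w$center, w$force_const, w$samples[pick],
                        w$dt_ps, w$t0_ps)
      })
      tryCatch(
        wham(wb, n_bins, z_range, temperature, tol, max_iter, anchor,
             min_overlap)$dG,
        error = function(e) rep(NA_real_, n_bins))
    })
  })
  mat <- do.call(cbind, reps)
  n_ok <- rowSums(is.finite(mat))
  err <- apply(mat, 1, sd, na.rm = TRUE)
  err[n_ok < 2] <- NA_real_
  base$boot_err <- err
  base
}

#' Time-block convergence series of WHAM profiles
#'
#' Recomputes the PMF restricting every window to successive time blocks
#' (e.g. first vs second half of the sampling), on a common grid and anchor.
#' Stationary sampling yields block profiles that agree within their
#' bootstrap error; systematic drift shows up as disagreement.
#'
#' @inheritParams wham
#' @param time_blocks list of numeric length-2 `(t_start, t_end)` intervals in
#'   ps, interpreted against each window's sample times.
#' @return List of [pmf_profile()] objects, one per block.
#' @export
convergence_series <- function(windows, time_blocks, n_bins = 200,
                               z_range = c(0, 4), temperature = 298,
                               tol = 1e-7, max_iter = 1e5, anchor = "bulk",
                               min_overlap = 1) {
  stopifnot(length(time_blocks) >= 1)
  lapply(time_blocks, function(blk) {
    stopifnot(length(blk) == 2, blk[1] < blk[2])
    wb <- lapply(windows, function(w) {
      t <- .window_times(w)
      keep <- t >= blk[1] & t <= blk[2]
      if (!any(keep))
        stop(sprintf("time block [%g, %g] ps is empty for window at %.3f nm",
                     blk[1], blk[2], w$center))
      umbrella_window(w$center, w$force_const, w$samples[keep], w$dt_ps,
                      t0_ps = t[which(keep)[1]])
    })
    wham(wb, n_bins, z_range, temperature, tol, max_iter, anchor, min_overlap)
  })
}

#' Relative partition coefficient from a PMF (Boltzmann integration)
#'
#' \deqn{K_{P,rel} = \frac{1}{a} \int_0^a e^{-\Delta G(z)/RT}\, dz}
#' by trapezoidal quadrature on the bin grid (with half-bin end extensions so
#' the integral spans the full `[0, a]` bin support).  The 1/a normalization
#' makes a flat profile give exactly 1; because the absolute scale depends on
#' the choice of the bulk boundary `a` and of the anchoring, only ratios of
#' these estimates between solutes (see [delta_log_kp()]) are meaningful.
#'
#' @param profile a [pmf_profile()] anchored to zero in the bulk region
#'   near `a`.
#' @param a bulk-water boundary of the integration, nm (default 4.0).
#' @return Dimensionless relative partition coefficient.
#' @export
kp_from_pmf <- function(profile, a = 4.0) {
  stopifnot(inherits(profile, "pmf_profile"))
  .chk_num1(a, "a", positive = TRUE)
  sel <- profile$z >= 0 & profile$z <= a
  if (!any(sel)) stop("profile has no bins in [0, ", a, "]")
  z <- profile$z[sel]
  dG <- profile$dG[sel]
  if (anyNA(dG)) {
    gaps <- z[is.na(dG)]
    stop(sprintf("unpopulated (masked) bins inside [0, %g] at z = %s nm",
                 a, paste(signif(head(gaps, 5), 3), collapse = ", ")))
  }
  RT <- rt_kj(profile$temperature)
  .trapz_bins(z, exp(-dG / RT)) / a
}

#' log10 difference of two PMF-derived partition coefficients
#'
#' \eqn{\log_{10} K_{P,rel}(A) - \log_{10} K_{P,rel}(B)}; the common 1/a
#' normalization and any common additive shift of the two profiles cancel,
#' so this relative comparison is well defined even though the absolute
#' PMF-derived \eqn{K_P} is not.
#'
#' @param profile_A,profile_B [pmf_profile()] objects at the same temperature.
#' @param a common bulk boundary, nm.
#' @return Signed log10 difference (positive: A partitions more than B).
#' @export
delta_log_kp <- function(profile_A, profile_B, a = 4.0) {
  stopifnot(inherits(profile_A, "pmf_profile"),
            inherits(profile_B, "pmf_profile"))
  if (!isTRUE(all.equal(profile_A$temperature, profile_B$temperature)))
    stop("profiles have mismatched temperatures")
  log10(kp_from_pmf(profile_A, a)) - log10(kp_from_pmf(profile_B, a))
}

#' Barrier and extremum summary of a PMF
#'
#' Locates the global free-energy minimum, the maximum on the bilayer-center
#' side of it (z below the minimum, toward 0), and the crossing barrier
#' `dG_max - dG_min`.  For profiles that rise monotonically toward the center
#' with no interior maximum, the barrier is computed to the z = 0 value and
#' flagged.
#'
#' @param profile a populated [pmf_profile()].
#' @return A list with `z_min`, `dG_min`, `z_max`, `dG_max`,
#'   `barrier_from_min` (kJ/mol, >= 0), `dG_center` (value at the bin nearest
#'   z = 0) and `no_interior_max` flag.
#' @export
summarize_pmf <- function(profile) {
  stopifnot(inherits(profile, "pmf_profile"))
  ok <- which(is.finite(profile$dG))
  if (!length(ok)) stop("profile has no populated bins")
  z <- profile$z[ok]
  dG <- profile$dG[ok]
  i_min <- which.min(dG)
  i_ctr <- which.min(abs(z))
  side <- which(z < z[i_min])
  no_interior <- FALSE
  if (length(side)) {
    i_max <- side[which.max(dG[side])]
    # a maximum sitting at the innermost sampled bin is not interior
    if (i_max == min(side) && i_max == i_ctr) no_interior <- TRUE
  } else {
    i_max <- i_ctr
    no_interior <- TRUE
  }
  if (no_interior) i_max <- i_ctr
  structure(list(z_min = z[i_min], dG_min = dG[i_min],
                 z_max = z[i_max], dG_max = dG[i_max],
                 barrier_from_min = dG[i_max] - dG[i_min],
                 dG_center = dG[i_ctr],
                 no_interior_max = no_interior),
            class = "pmf_summary")
}

#' @export
print.pmf_summary <- function(x, ...) {
  cat(sprintf("pmf_summary: min %.3g kJ/mol at z = %.3g nm; max %.3g at z = %.3g; barrier %.3g kJ/mol%s\n",
              x$dG_min, x$z_min, x$dG_max, x$z_max, x$barrier_from_min,
              if (x$no_interior_max) " (no interior maximum; barrier to z = 0)" else ""))
  invisible(x)
}
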