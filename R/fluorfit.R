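# Partition-coefficient fitting from fluorescence titrations.
#
# Both observables follow a hyperbolic isotherm in the accessible lipid
# concentration L (mol/L), with membrane volume fraction Kp*Vbar*L:
#   intensity:  I = (Iw + Im*Kp*Vbar*L) / (1 + Kp*Vbar*L)
#   anisotropy: r = (rw + aM*rm*Kp*Vbar*L) / (1 + aM*Kp*Vbar*L)
# where aM is the membrane/water fluorescence intensity ratio in the detected
# wavelength band (the anisotropy is an intensity-weighted average of the two
# environments, hence the extra factor).

#' Titration series container
#'
#' One optical titration: lipid concentrations plus one signal (fluorescence
#' intensity or anisotropy) measured in a wavelength band.
#'
#' @param lipid numeric vector of lipid concentrations, mol/L, non-negative
#'   (stored in ascending order; fits do not depend on input order).
#' @param signal numeric vector of the same length; arbitrary intensity units
#'   or dimensionless anisotropy (anisotropy must lie in (-0.2, 0.4)).
#' @param kind `"intensity"` or `"anisotropy"`.
#' @param band wavelength-band label, e.g. `"450-470"`.
#' @param pH,temperature metadata (pH unitless; temperature K).
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(lipid, signal, kind = c("intensity", "anisotropy"),
                             band = "470", pH = 7, temperature = 298.15) {
  kind <- match.arg(kind)
  lipid <- as.numeric(lipid)
  signal <- as.numeric(signal)
  if (length(lipid) != length(signal))
    stop("'lipid' and 'signal' must have equal length")
  if (any(lipid < 0)) stop("lipid concentrations must be non-negative")
  if (is.unsorted(lipid)) {          # store ascending; fits are order-free
    o <- order(lipid)
    lipid <- lipid[o]
    signal <- signal[o]
  }
  if (kind == "anisotropy" && any(signal <= -0.2 | signal >= 0.4))
    stop("anisotropy values must lie in (-0.2, 0.4)")
  structure(list(lipid = lipid, signal = signal, kind = kind,
                 band = as.character(band), pH = pH,
                 temperature = temperature),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("titration_series: %d points, kind=%s, band=%s nm, pH=%g\n",
              length(x$lipid), x$kind, x$band, x$pH))
  invisible(x)
}

# forward isotherms -----------------------------------------------------------

.isotherm_intensity <- function(L, Iw, Im, Kp, Vbar, gamma = 1) {
  x <- Kp * Vbar * gamma * L
  (Iw + Im * x) / (1 + x)
}

.isotherm_anisotropy <- function(L, rw, rm, Kp, alphaM, Vbar, gamma = 1) {
  x <- alphaM * Kp * Vbar * gamma * L
  (rw + rm * x) / (1 + x)
}

# fit machinery ---------------------------------------------------------------

#' Partition fit result
#'
#' Returned by [fit_intensity()], [fit_anisotropy()] and [joint_band_fit()].
#' Holds the fitted partition coefficient (internally parameterized as
#' log10 Kp, so Kp is positive by construction), the signal endpoints of the
#' two environments, asymptotic standard errors, and an identifiability flag.
#'
#' @name partition_fit
#' @keywords internal
NULL

.new_partition_fit <- function(Kp, log10Kp_se, endpoint_low, endpoint_high,
                               endpoint_se, alphaM, residual_norm, n_points,
                               kind, unidentifiable = FALSE, message = "") {
  structure(list(
    Kp = Kp, log10Kp = log10(Kp), log10Kp_se = log10Kp_se,
    Kp_se = Kp * log(10) * log10Kp_se,
    endpoint_low = endpoint_low, endpoint_high = endpoint_high,
    endpoint_se = endpoint_se, alphaM = alphaM,
    residual_norm = residual_norm, n_points = n_points, kind = kind,
    unidentifiable = unidentifiable, message = message
  ), class = "partition_fit")
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf("partition_fit (%s): Kp = %.4g (log10 Kp = %.3f +/- %.3f)\n",
              x$kind, x$Kp, x$log10Kp, x$log10Kp_se))
  cat(sprintf("  endpoints: %.4g -> %.4g; alphaM = %s; n = %d; |resid| = %.3g\n",
              x$endpoint_low[1], x$endpoint_high[1],
              paste(signif(x$alphaM, 3), collapse = ","),
              x$n_points, x$residual_norm))
  if (x$unidentifiable)
    cat("  WARNING: fit flagged unidentifiable:", x$message, "\n")
  invisible(x)
}

# Levenberg-Marquardt over (log10Kp, low, high) with multistart on log10Kp.
# residual_fun(pars) -> residual vector; pars = c(lk, lows..., highs...)
.lm_multistart <- function(residual_fun, lk_starts, low0, high0) {
  best <- NULL
  for (lk in lk_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(lk, low0, high0), fn = residual_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("least-squares fit failed to converge from any start")
  best
}

# asymptotic standard errors from a central-difference Jacobian at the optimum
.lm_se <- function(fit, resid_fun) {
  p <- fit$par
  np <- length(p)
  dof <- length(fit$fvec) - np
  s2 <- if (dof > 0) fit$deviance / dof else 0
  J <- vapply(seq_len(np), function(k) {
    h <- 1e-6 * max(1, abs(p[k]))
    hi <- p; hi[k] <- hi[k] + h
    lo <- p; lo[k] <- lo[k] - h
    (resid_fun(hi) - resid_fun(lo)) / (2 * h)
  }, numeric(length(fit$fvec)))
  cv <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cv)) return(rep(NA_real_, np))
  d <- s2 * diag(cv)
  d[d < 0] <- 0
  sqrt(d)
}

.flat_signal <- function(signal) {
  diff(range(signal)) <= 1e-10 * max(abs(signal), 1)
}

.guess_lk <- function(lipid, signal, Vbar, alphaM = 1) {
  # lipid concentration at half signal change ~ 1/(alphaM*Kp*Vbar)
  lo <- signal[which.min(lipid)]
  hi <- signal[which.max(lipid)]
  mid <- (lo + hi) / 2
  i <- which.min(abs(signal - mid))
  Lh <- max(lipid[i], min(lipid[lipid > 0]))
  log10(1 / (alphaM * Vbar * Lh))
}

.fit_isotherm <- function(series, Vbar, gamma, alphaM, kind) {
  L <- series$lipid
  y <- series$signal
  if (length(unique(L)) < 4)
    stop("need at least 4 distinct lipid concentrations")
  if (.flat_signal(y)) {
    return(.new_partition_fit(
      Kp = 1, log10Kp_se = Inf, endpoint_low = y[1], endpoint_high = y[1],
      endpoint_se = c(NA_real_, NA_real_), alphaM = alphaM,
      residual_norm = 0, n_points = length(y), kind = kind,
      unidentifiable = TRUE,
      message = "signal carries no lipid dependence (flat series)"))
  }
  resid_fun <- function(p) {
    Kp <- 10^p[1]
    pred <- if (kind == "intensity")
      .isotherm_intensity(L, p[2], p[3], Kp, Vbar, gamma)
    else
      .isotherm_anisotropy(L, p[2], p[3], Kp, alphaM, Vbar, gamma)
    pred - y
  }
  lk0 <- .guess_lk(L, y, Vbar, if (kind == "intensity") 1 else alphaM)
  fit <- .lm_multistart(resid_fun, lk0 + c(-1.5, 0, 1.5),
                        y[which.min(L)], y[which.max(L)])
  se <- .lm_se(fit, resid_fun)
  p <- fit$par
  unid <- FALSE
  msg <- ""
  # endpoints indistinguishable => Kp unconstrained
  scale_y <- max(abs(y), 1e-12)
  if (abs(p[3] - p[2]) < 1e-6 * scale_y || (is.finite(se[1]) && se[1] > 2) ||
      !is.finite(se[1])) {
    unid <- TRUE
    msg <- "endpoints coincide or Kp uncertainty spans decades"
  }
  .new_partition_fit(
    Kp = 10^p[1], log10Kp_se = se[1], endpoint_low = p[2],
    endpoint_high = p[3], endpoint_se = se[2:3], alphaM = alphaM,
    residual_norm = sqrt(fit$deviance), n_points = length(y), kind = kind,
    unidentifiable = unid, message = msg)
}

#' Fit a partition coefficient to an intensity titration
#'
#' Least-squares fit of the intensity partition isotherm
#' \deqn{I = \frac{I_W + I_M K_P \bar{V} L}{1 + K_P \bar{V} L}}
#' over \eqn{(I_W, I_M, \log_{10} K_P)}.  The log parameterization keeps
#' \eqn{K_P} positive; three starts spanning three decades of \eqn{K_P} guard
#' against local minima.  Points are weighted uniformly.
#'
#' @param series a [titration_series()] with `kind = "intensity"`; needs at
#'   least 4 distinct lipid concentrations, ideally including a zero-lipid
#'   (free-solute) anchor.
#' @param Vbar lipid molar volume, L/mol (default 0.8, POPC).
#' @param gamma fraction of lipid accessible to the solute, in (0, 1];
#'   default 1 (full translocation between leaflets).
#' @return A `partition_fit`; `$unidentifiable` is set when the series is
#'   flat or the endpoints coincide so that \eqn{K_P} is unconstrained.
#' @seealso [fit_anisotropy()], [joint_band_fit()]
#' @export
#' @examples
#' tr <- fluor_truth(Kp = 1800, noise_cv = 0)
#' s <- gen_fluor_titration(tr, default_lipid_grid(), "intensity")
#' fit_intensity(s)
fit_intensity <- function(series, Vbar = 0.8, gamma = 1) {
  stopifnot(inherits(series, "titration_series"))
  if (series$kind != "intensity") stop("series kind must be 'intensity'")
  .chk_num1(Vbar, "Vbar", positive = TRUE)
  stopifnot(gamma > 0, gamma <= 1)
  .fit_isotherm(series, Vbar, gamma, alphaM = 1, kind = "intensity")
}

#' Fit a partition coefficient to an anisotropy titration
#'
#' Least-squares fit of the weighted anisotropy isotherm
#' \deqn{r = \frac{r_W + \alpha_M r_M K_P \bar{V} L}{1 + \alpha_M K_P \bar{V} L}}
#' over \eqn{(r_W, r_M, \log_{10} K_P)} with \eqn{\alpha_M} held fixed.
#' \eqn{\alpha_M} is the ratio of membrane to water fluorescence intensity in
#' the detected band (see [estimate_alpha_m()]); it enters because the
#' measured anisotropy is the intensity-weighted mean of the two environments.
#'
#' @inheritParams fit_intensity
#' @param series a [titration_series()] with `kind = "anisotropy"`.
#' @param alphaM membrane/water intensity ratio for the series band; > 0.
#' @return A `partition_fit`.
#' @export
fit_anisotropy <- function(series, alphaM, Vbar = 0.8, gamma = 1) {
  stopifnot(inherits(series, "titration_series"))
  if (series$kind != "anisotropy") stop("series kind must be 'anisotropy'")
  .chk_num1(alphaM, "alphaM", positive = TRUE)
  .chk_num1(Vbar, "Vbar", positive = TRUE)
  stopifnot(gamma > 0, gamma <= 1)
  .fit_isotherm(series, Vbar, gamma, alphaM = alphaM, kind = "anisotropy")
}

#' Joint fit of several titrations sharing one partition coefficient
#'
#' Pools any mixture of intensity and anisotropy series (e.g. the same
#' titration detected in several wavelength bands) into a single least-squares
#' problem with one shared \eqn{\log_{10} K_P} and per-series endpoints.
#'
#' @param series_list list of [titration_series()] objects (non-empty).
#' @param alphaM_list numeric vector, one \eqn{\alpha_M} per series (use 1 for
#'   intensity series).
#' @inheritParams fit_intensity
#' @return A `partition_fit` whose `endpoint_low`/`endpoint_high` are vectors
#'   (one entry per series).
#' @export
joint_band_fit <- function(series_list, alphaM_list, Vbar = 0.8, gamma = 1) {
  if (!length(series_list)) stop("empty series list")
  if (length(alphaM_list) != length(series_list))
    stop("need one alphaM per series")
  lapply(series_list, function(s) stopifnot(inherits(s, "titration_series")))
  ns <- length(series_list)
  all_y <- unlist(lapply(series_list, `[[`, "signal"))
  if (.flat_signal(all_y))
    return(.new_partition_fit(1, Inf, all_y[1], all_y[1],
                              c(NA_real_, NA_real_), alphaM_list, 0,
                              length(all_y), "joint", TRUE,
                              "all series flat"))
  resid_fun <- function(p) {
    Kp <- 10^p[1]
    unlist(lapply(seq_len(ns), function(i) {
      s <- series_list[[i]]
      lo <- p[1 + i]; hi <- p[1 + ns + i]
      pred <- if (s$kind == "intensity")
        .isotherm_intensity(s$lipid, lo, hi, Kp, Vbar, gamma)
      else
        .isotherm_anisotropy(s$lipid, lo, hi, Kp, alphaM_list[i], Vbar, gamma)
      pred - s$signal
    }))
  }
  lo0 <- vapply(series_list, function(s) s$signal[which.min(s$lipid)], 0)
  hi0 <- vapply(series_list, function(s) s$signal[which.max(s$lipid)], 0)
  lk0 <- median(vapply(seq_len(ns), function(i)
    .guess_lk(series_list[[i]]$lipid, series_list[[i]]$signal, Vbar,
              if (series_list[[i]]$kind == "intensity") 1 else alphaM_list[i]),
    0))
  fit <- .lm_multistart(resid_fun, lk0 + c(-1.5, 0, 1.5), lo0, hi0)
  se <- .lm_se(fit, resid_fun)
  p <- fit$par
  .new_partition_fit(
    Kp = 10^p[1], log10Kp_se = se[1],
    endpoint_low = p[2:(1 + ns)], endpoint_high = p[(2 + ns):(1 + 2 * ns)],
    endpoint_se = se[-1], alphaM = alphaM_list,
    residual_norm = sqrt(fit$deviance),
    n_points = length(all_y), kind = "joint")
}

#' Spectral weighting factor from an emission-spectrum pair
#'
#' \eqn{\alpha_M} for a detection band is the ratio of the band-integrated
#' fluorescence emission of the membrane-bound solute to that of the aqueous
#' solute, computed by trapezoidal integration of the two spectra over the
#' band (band edges are interpolated onto the wavelength grid).
#'
#' @param spectra list with numeric fields `wavelengths` (nm, ascending),
#'   `I_water` and `I_membrane` (non-negative, same length).
#' @param band numeric length-2 interval (nm) within the wavelength grid.
#' @return \eqn{\alpha_M}, a positive scalar.
#' @export
#' @examples
#' wl <- 400:600
#' sp <- list(wavelengths = wl, I_water = dnorm(wl, 500, 40),
#'            I_membrane = 13 * dnorm(wl, 500, 40))
#' estimate_alpha_m(sp, c(450, 470))  # 13
estimate_alpha_m <- function(spectra, band) {
  wl <- spectra$wavelengths
  Iw <- spectra$I_water
  Im <- spectra$I_membrane
  stopifnot(length(wl) == length(Iw), length(wl) == length(Im),
            !is.unsorted(wl), all(Iw >= 0), all(Im >= 0),
            length(band) == 2, band[1] < band[2])
  if (band[1] < min(wl) || band[2] > max(wl))
    stop("band [", band[1], ", ", band[2], "] outside the wavelength grid")
  grid <- sort(unique(c(band, wl[wl >= band[1] & wl <= band[2]])))
  iw <- pracma::trapz(grid, approx(wl, Iw, xout = grid)$y)
  im <- pracma::trapz(grid, approx(wl, Im, xout = grid)$y)
  if (iw <= 0) stop("water spectrum integrates to zero over the band")
  im / iw
}
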