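# ITC partition-model forward simulation and fitting.
#
# Uptake titration: lipid vesicles in the syringe are injected into a dilute
# solute solution in the cell.  Each injection both adds lipid and displaces
# cell content (perfusion-cell correction).  The simple-partition model
# assumes instantaneous equilibration of the solute between water and the
# membrane pseudo-phase after every injection; the heat of injection i is the
# enthalpy of the net solute transfer into the membrane plus a constant
# dilution heat.

#' ITC injection protocol
#'
#' @param cell_volume working cell volume, L (default 1.4195e-3, the VP-ITC
#'   nominal cell).
#' @param inj_volume volume per injection, L; must be smaller than the cell.
#' @param n_inj number of injections (>= 1).
#' @param lipid_syringe lipid concentration in the syringe, mol/L.
#' @param solute_cell initial solute concentration in the cell, mol/L.
#' @param temperature K.
#' @return An `itc_protocol` object.
#' @export
itc_protocol <- function(cell_volume = 1.4195e-3, inj_volume = 10e-6,
                         n_inj = 25, lipid_syringe = 10e-3,
                         solute_cell = 5e-6, temperature = 298.15) {
  .chk_num1(cell_volume, "cell_volume", positive = TRUE)
  .chk_num1(inj_volume, "inj_volume", positive = TRUE)
  .chk_num1(lipid_syringe, "lipid_syringe", positive = TRUE)
  .chk_num1(solute_cell, "solute_cell", positive = TRUE)
  .chk_num1(temperature, "temperature", positive = TRUE)
  if (inj_volume >= cell_volume) stop("inj_volume must be < cell_volume")
  n_inj <- as.integer(n_inj)
  if (n_inj < 1) stop("n_inj must be >= 1")
  structure(list(cell_volume = cell_volume, inj_volume = inj_volume,
                 n_inj = n_inj, lipid_syringe = lipid_syringe,
                 solute_cell = solute_cell, temperature = temperature),
            class = "itc_protocol")
}

#' @export
print.itc_protocol <- function(x, ...) {
  cat(sprintf(
    "itc_protocol: %d x %.3g uL into %.4g mL cell; [lipid]syr = %.3g mM, [solute]cell = %.3g uM, T = %.2f K\n",
    x$n_inj, x$inj_volume * 1e6, x$cell_volume * 1e3,
    x$lipid_syringe * 1e3, x$solute_cell * 1e6, x$temperature))
  invisible(x)
}

#' ITC experiment container
#'
#' @param protocol an [itc_protocol()].
#' @param heats numeric vector of integrated per-injection heats, J;
#'   length must equal `protocol$n_inj`.
#' @param normalized logical; `TRUE` if heats are per mole of injectant
#'   rather than raw J (readers convert before fitting).
#' @return An `itc_experiment` object.
#' @export
itc_experiment <- function(protocol, heats, normalized = FALSE) {
  stopifnot(inherits(protocol, "itc_protocol"))
  heats <- as.numeric(heats)
  if (length(heats) != protocol$n_inj)
    stop("length(heats) must equal protocol$n_inj")
  structure(list(protocol = protocol, heats = heats,
                 normalized = isTRUE(normalized)),
            class = "itc_experiment")
}

#' Forward model: per-injection heats of a partition uptake titration
#'
#' After injection \eqn{i} the displacement factor is
#' \eqn{d_i = (1 - v/V_0)^i}; total cell lipid is
#' \eqn{L_i = L_{syr} (1 - d_i)} and remaining solute \eqn{D_i = D_0 d_i}
#' (both solute and previously injected lipid are flushed by the overflow).
#' With bound fraction \eqn{f_i = K_P \bar{V} L_i / (1 + K_P \bar{V} L_i)}
#' and bound moles \eqn{n_i = V_0 D_i f_i}, the heat of injection \eqn{i} is
#' \deqn{q_i = \Delta H (n_i - n_{i-1}(1 - v/V_0)) + q_{dil}, \quad n_0 = 0.}
#'
#' @param protocol an [itc_protocol()].
#' @param Kp partition coefficient (> 0).
#' @param dH molar enthalpy of partition, kJ/mol.
#' @param q_dil constant dilution heat per injection, J.
#' @param Vbar lipid molar volume, L/mol.
#' @return Numeric vector of heats in J, length `protocol$n_inj`.
#' @export
#' @examples
#' p <- itc_protocol()
#' model_heats(p, Kp = 1e3, dH = -50)[1]  # ~ -1.88e-5 J
model_heats <- function(protocol, Kp, dH, q_dil = 0, Vbar = 0.8) {
  stopifnot(inherits(protocol, "itc_protocol"))
  .chk_num1(Kp, "Kp", positive = TRUE)
  .chk_num1(dH, "dH")
  .chk_num1(q_dil, "q_dil")
  .chk_num1(Vbar, "Vbar", positive = TRUE)
  V0 <- protocol$cell_volume
  v <- protocol$inj_volume
  keep <- 1 - v / V0
  i <- seq_len(protocol$n_inj)
  d <- keep^i
  L <- protocol$lipid_syringe * (1 - d)
  D <- protocol$solute_cell * d
  f <- Kp * Vbar * L / (1 + Kp * Vbar * L)
  n <- V0 * D * f
  nprev <- c(0, n[-length(n)])
  dH * 1000 * (n - nprev * keep) + q_dil
}

#' Total lipid concentration in the cell after each injection
#'
#' @inheritParams model_heats
#' @return Numeric vector, mol/L, strictly increasing.
#' @export
cumulative_lipid <- function(protocol) {
  stopifnot(inherits(protocol, "itc_protocol"))
  keep <- 1 - protocol$inj_volume / protocol$cell_volume
  protocol$lipid_syringe * (1 - keep^seq_len(protocol$n_inj))
}

#' Fit the partition model to an ITC titration
#'
#' Least squares of [model_heats()] against the observed heats over
#' \eqn{(\log_{10} K_P, \Delta H°)} and optionally the per-injection dilution
#' heat.  Multistart over three decades of \eqn{K_P} guards against local
#' minima; asymptotic standard errors come from the Jacobian at the optimum.
#'
#' @param exp an [itc_experiment()] with at least 5 injections spanning sub-
#'   to post-saturating lipid.
#' @param Vbar lipid molar volume, L/mol.
#' @param fit_q_dil logical; also fit a constant dilution heat (default TRUE).
#' @param drop_first logical; exclude the first injection from the residuals
#'   (common practice when the first aliquot is compromised); default FALSE.
#' @return An `itc_fit` with elements `Kp`, `dH` (kJ/mol), `q_dil` (J),
#'   standard errors, `residual_norm` and an `unidentifiable` flag (set for a
#'   flat thermogram).
#' @export
fit_itc <- function(exp, Vbar = 0.8, fit_q_dil = TRUE, drop_first = FALSE) {
  stopifnot(inherits(exp, "itc_experiment"))
  if (exp$normalized)
    stop("normalize heats to raw J before fitting (see read_itc_csv)")
  p <- exp$protocol
  if (p$n_inj < 5) stop("need at least 5 injections")
  y <- exp$heats
  use <- if (drop_first) seq_along(y)[-1] else seq_along(y)
  flat <- diff(range(y[use])) <= 1e-12 * max(abs(y[use]), 1e-300)
  if (flat) {
    out <- list(Kp = 1, log10Kp = 0, log10Kp_se = Inf, Kp_se = Inf,
                dH = 0, dH_se = NA_real_, q_dil = mean(y[use]),
                q_dil_se = NA_real_, residual_norm = 0,
                n_points = length(use), unidentifiable = TRUE,
                message = "flat thermogram: heats carry no lipid dependence")
    class(out) <- "itc_fit"
    return(out)
  }
  # crude dH start: total heat / total solute moles, in kJ/mol
  dH0 <- sum(y[use] - median(y[use]) * 0) / (p$cell_volume * p$solute_cell) / 1000
  resid_fun <- function(par) {
    q <- model_heats(p, 10^par[1], par[2],
                     q_dil = if (fit_q_dil) par[3] else 0, Vbar = Vbar)
    q[use] - y[use]
  }
  best <- NULL
  for (lk in c(1.5, 3, 4.5)) {
    par0 <- c(lk, dH0, if (fit_q_dil) 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 1000, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("ITC fit failed to converge from any start")
  se <- .lm_se(best, resid_fun)
  pr <- best$par
  unid <- !is.finite(se[1]) || se[1] > 2
  out <- list(Kp = 10^pr[1], log10Kp = pr[1], log10Kp_se = se[1],
              Kp_se = 10^pr[1] * log(10) * se[1],
              dH = pr[2], dH_se = se[2],
              q_dil = if (fit_q_dil) pr[3] else 0,
              q_dil_se = if (fit_q_dil) se[3] else 0,
              residual_norm = sqrt(best$deviance), n_points = length(use),
              unidentifiable = unid,
              message = if (unid) "Kp uncertainty spans decades" else "")
  class(out) <- "itc_fit"
  out
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("itc_fit: Kp = %.4g (+/- %.2g), dH = %.4g (+/- %.2g) kJ/mol, q_dil = %.3g J\n",
              x$Kp, x$Kp_se, x$dH, x$dH_se, x$q_dil))
  if (x$unidentifiable) cat("  WARNING: flagged unidentifiable:", x$message, "\n")
  invisible(x)
}

#' Per-injection table of observed vs modeled heats
#'
#' @param exp an [itc_experiment()].
#' @param fit an `itc_fit` from [fit_itc()].
#' @param Vbar lipid molar volume used in the fit.
#' @return A data.frame with one row per injection: `injection`, `lipid_M`
#'   (cumulative cell lipid, strictly increasing), `observed`, `modeled`,
#'   `residual` (all J).
#' @export
thermogram_summary <- function(exp, fit, Vbar = 0.8) {
  stopifnot(inherits(exp, "itc_experiment"), inherits(fit, "itc_fit"))
  q <- model_heats(exp$protocol, fit$Kp, fit$dH, fit$q_dil, Vbar)
  data.frame(injection = seq_len(exp$protocol$n_inj),
             lipid_M = cumulative_lipid(exp$protocol),
             observed = exp$heats, modeled = q,
             residual = exp$heats - q)
}
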