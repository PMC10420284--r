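# Thermodynamic bookkeeping and log-domain replicate aggregation.
#
# Kp is the dimensionless concentration-ratio partition coefficient defined
# with membrane volume Vbar*[lipid]; dG values carry that convention.

#' Standard free energy of partition from Kp
#'
#' \eqn{\Delta G° = -RT \ln K_P}, in kJ/mol
#' (R = 8.314 J mol^-1 K^-1).
#'
#' @param Kp partition coefficient (> 0).
#' @param temperature K (default 298.15).
#' @return kJ/mol; 0 for Kp = 1, negative for favorable partition.
#' @export
#' @examples
#' dG_from_kp(6.3e3)  # -21.7 kJ/mol
dG_from_kp <- function(Kp, temperature = 298.15) {
  if (any(!is.finite(Kp)) || any(Kp <= 0)) stop("Kp must be > 0")
  .chk_num1(temperature, "temperature", positive = TRUE)
  -rt_kj(temperature) * log(Kp)
}

#' Kp back from a standard free energy
#'
#' Inverse of [dG_from_kp()].
#'
#' @param dG kJ/mol.
#' @param temperature K.
#' @return Partition coefficient.
#' @export
kp_from_dG <- function(dG, temperature = 298.15) {
  exp(-dG / rt_kj(temperature))
}

#' Entropic term from enthalpy and free energy
#'
#' \eqn{T\Delta S° = \Delta H° - \Delta G°} (kJ/mol).
#'
#' @param dH,dG kJ/mol.
#' @return kJ/mol.
#' @export
tds_from <- function(dH, dG) dH - dG

#' Consistent thermodynamic record
#'
#' Builds the full (Kp, dG, dH, TdS) record from Kp and dH, enforcing
#' `dG = -RT ln Kp` and `TdS = dH - dG`.
#'
#' @param Kp partition coefficient.
#' @param dH molar enthalpy, kJ/mol.
#' @param temperature K.
#' @return A `thermo_record` list with `Kp`, `dG`, `dH`, `TdS`, `T`.
#' @export
thermo_record <- function(Kp, dH, temperature = 298.15) {
  dG <- dG_from_kp(Kp, temperature)
  structure(list(Kp = Kp, dG = dG, dH = dH, TdS = tds_from(dH, dG),
                 T = temperature),
            class = "thermo_record")
}

#' @export
print.thermo_record <- function(x, ...) {
  cat(sprintf("thermo_record @ %g K: Kp = %.3g, dG = %.3g, dH = %.3g, TdS = %.3g kJ/mol\n",
              x$T, x$Kp, x$dG, x$dH, x$TdS))
  invisible(x)
}

#' Log-domain summary of replicate partition coefficients
#'
#' Replicate Kp values are log-normally distributed, so the mean and SD are
#' taken over \eqn{\log_{10} K_P}; the reported average Kp is
#' \eqn{10^{\mu_{log}}} (the geometric mean), computed on unrounded values.
#'
#' @param replicate_Kps numeric vector of Kp values, all > 0, length >= 1.
#' @return A `log_kp_summary` with `n`, `mu_log`, `sigma_log` (0 for n = 1)
#'   and `Kp_mu = 10^mu_log`.
#' @export
#' @examples
#' summarize_log_kp(c(100, 10000))  # mu_log 3, Kp_mu 1000
summarize_log_kp <- function(replicate_Kps) {
  if (!length(replicate_Kps)) stop("empty replicate list")
  if (any(!is.finite(replicate_Kps)) || any(replicate_Kps <= 0))
    stop("all Kp values must be positive and finite")
  lk <- log10(replicate_Kps)
  structure(list(n = length(lk), mu_log = mean(lk),
                 sigma_log = if (length(lk) > 1) sd(lk) else 0,
                 Kp_mu = 10^mean(lk)),
            class = "log_kp_summary")
}

#' @export
print.log_kp_summary <- function(x, ...) {
  cat(sprintf("log_kp_summary: n = %d, log10 Kp = %.1f +/- %.2f, Kp = %.2g\n",
              x$n, x$mu_log, x$sigma_log, x$Kp_mu))
  invisible(x)
}

#' Aggregate a replicate table into per-condition log-Kp summaries
#'
#' @param df data.frame with columns `pH` and `Kp` (one row per replicate).
#' @return data.frame with one row per pH: `pH`, `N`, `mu_log`, `sigma_log`,
#'   `Kp_mu`, sorted by pH.
#' @export
aggregate_kp_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("pH", "Kp") %in% names(df)))
  out <- lapply(split(df, df$pH), function(g) {
    s <- summarize_log_kp(g$Kp)
    data.frame(pH = g$pH[1], N = s$n, mu_log = s$mu_log,
               sigma_log = s$sigma_log, Kp_mu = s$Kp_mu)
  })
  out <- do.call(rbind, out)
  out[order(out$pH), , drop = FALSE]
}
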