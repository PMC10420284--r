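# Workflow driver: chains the stages into the two end-to-end analyses
# (experimental partition fitting; umbrella-sampling PMF analysis) plus a
# simulate mode, from a single configuration list or JSON file.  Every
# applied default is echoed into the JSON report for provenance.

#' Package-wide physical defaults
#'
#' One table of the defaults applied implicitly anywhere in the pipeline;
#' [run_workflow()] echoes it into every report.
#'
#' @return Named list: `Vbar` (L/mol), `temperature` (K), `a` (nm, bulk
#'   boundary), `z_range`/`n_bins` (WHAM grid), `wham_tol`, `wham_max_iter`,
#'   `discard_frac`, `d_cut` (nm), `angle_cut` (deg).
#' @export
memparti_defaults <- function() {
  list(Vbar = 0.8, temperature = 298.15, a = 4.0,
       z_range = c(0, 4), n_bins = 200, wham_tol = 1e-7,
       wham_max_iter = 1e5, discard_frac = 1 / 3,
       d_cut = 0.35, angle_cut = 30)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.cfg_get <- function(cfg, key, default) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

#' Run a configured analysis workflow
#'
#' Supported workflows:
#' \describe{
#'   \item{`fluor`}{read a titration CSV (`input`), fit every series
#'     (intensity series with [fit_intensity()]; anisotropy series with
#'     [fit_anisotropy()] using the band's entry of the `alphaM` map),
#'     aggregate replicate Kp in log domain.}
#'   \item{`itc`}{read an ITC heat CSV (`input`) against a `protocol`
#'     (list of [itc_protocol()] arguments) and fit the partition model.}
#'   \item{`pmf`}{read umbrella windows (`windows` metadata path), run WHAM
#'     (optionally with `n_boot` bootstrap replicates), write the profile and
#'     report the relative Kp and barrier summary.}
#'   \item{`simulate`}{generate synthetic inputs: `what` is one of `fluor`,
#'     `itc`, `umbrella`; ground-truth parameters come from the config.}
#' }
#' Outputs are deterministic given the seeds in the config; the JSON report
#' (`report.json` in `out_dir`) records parameters, applied defaults, seeds
#' and the package version.  Stage failures propagate as errors prefixed
#' with the stage name.
#'
#' @param cfg configuration: a named list or a path to a JSON file.  Common
#'   fields: `workflow`, `input`, `out_dir`, `seed`, plus per-workflow
#'   parameters overriding [memparti_defaults()].
#' @return Invisibly, the report list (also written to
#'   `out_dir/report.json`).
#' @export
run_workflow <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1) {
    if (!file.exists(cfg)) stop("no such config file: ", cfg)
    cfg <- jsonlite::read_json(cfg, simplifyVector = TRUE)
  }
  stopifnot(is.list(cfg))
  wf <- cfg$workflow
  if (is.null(wf) ||
      !wf %in% c("fluor", "itc", "pmf", "simulate"))
    stop("unknown workflow name: ",
         if (is.null(wf)) "<missing>" else wf,
         " (expected fluor, itc, pmf or simulate)")
  out_dir <- .cfg_get(cfg, "out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  defs <- memparti_defaults()
  Vbar <- .cfg_get(cfg, "Vbar", defs$Vbar)
  temperature <- .cfg_get(cfg, "temperature", defs$temperature)
  seed <- as.integer(.cfg_get(cfg, "seed", 1L))

  report <- list(workflow = wf, seed = seed,
                 defaults_applied = defs,
                 package_version = as.character(utils::packageVersion("memparti")))

  if (wf == "fluor") {
    series <- .stage("read_titrations", read_titration_csv(cfg$input))
    alphaM <- .cfg_get(cfg, "alphaM", list())
    fits <- .stage("fit", lapply(series, function(s) {
      if (s$kind == "intensity") fit_intensity(s, Vbar = Vbar)
      else {
        am <- alphaM[[s$band]]
        if (is.null(am)) stop("no alphaM supplied for band ", s$band)
        fit_anisotropy(s, alphaM = am, Vbar = Vbar)
      }
    }))
    kps <- vapply(fits, `[[`, 0, "Kp")
    agg <- .stage("aggregate", summarize_log_kp(kps))
    report$fits <- lapply(fits, function(f)
      list(kind = f$kind, Kp = f$Kp, log10Kp = f$log10Kp,
           log10Kp_se = f$log10Kp_se, unidentifiable = f$unidentifiable))
    report$Kp_mu <- agg$Kp_mu
    report$mu_log <- agg$mu_log
    report$sigma_log <- agg$sigma_log
  } else if (wf == "itc") {
    proto <- .stage("protocol", do.call(itc_protocol,
                                        .cfg_get(cfg, "protocol", list())))
    exp <- .stage("read_heats", read_itc_csv(cfg$input, proto))
    fit <- .stage("fit", fit_itc(exp, Vbar = Vbar,
                                 fit_q_dil = .cfg_get(cfg, "fit_q_dil", TRUE),
                                 drop_first = .cfg_get(cfg, "drop_first",
                                                       FALSE)))
    rec <- thermo_record(fit$Kp, fit$dH, temperature)
    report$fit <- list(Kp = fit$Kp, Kp_se = fit$Kp_se, dH = fit$dH,
                       dH_se = fit$dH_se, q_dil = fit$q_dil,
                       dG = rec$dG, TdS = rec$TdS,
                       unidentifiable = fit$unidentifiable)
    utils::write.csv(thermogram_summary(exp, fit, Vbar),
                     file.path(out_dir, "thermogram.csv"), row.names = FALSE)
  } else if (wf == "pmf") {
    wins <- .stage("read_windows",
                   read_windows(cfg$windows,
                                discard_frac = .cfg_get(cfg, "discard_frac",
                                                        0)))
    n_boot <- .cfg_get(cfg, "n_boot", 0)
    prof <- .stage("wham", {
      if (n_boot >= 2)
        bootstrap_pmf(wins, n_boot = n_boot, seed = seed,
                      n_bins = .cfg_get(cfg, "n_bins", defs$n_bins),
                      z_range = .cfg_get(cfg, "z_range", defs$z_range),
                      temperature = temperature,
                      tol = .cfg_get(cfg, "wham_tol", defs$wham_tol))
      else
        wham(wins, n_bins = .cfg_get(cfg, "n_bins", defs$n_bins),
             z_range = .cfg_get(cfg, "z_range", defs$z_range),
             temperature = temperature,
             tol = .cfg_get(cfg, "wham_tol", defs$wham_tol))
    })
    write_pmf(prof, file.path(out_dir, "pmf.txt"))
    a <- .cfg_get(cfg, "a", defs$a)
    s <- summarize_pmf(prof)
    report$kp_rel <- .stage("kp_from_pmf", kp_from_pmf(prof, a))
    report$summary <- list(z_min = s$z_min, dG_min = s$dG_min,
                           z_max = s$z_max, dG_max = s$dG_max,
                           barrier_from_min = s$barrier_from_min,
                           dG_center = s$dG_center)
  } else if (wf == "simulate") {
    what <- .cfg_get(cfg, "what", "fluor")
    if (what == "fluor") {
      tr <- do.call(fluor_truth,
                    c(.cfg_get(cfg, "truth", list()), list(seed = seed)))
      grid <- .cfg_get(cfg, "lipid_concs", default_lipid_grid())
      kind <- .cfg_get(cfg, "kind", "intensity")
      band <- .cfg_get(cfg, "band", names(tr$alphaM_by_band)[1])
      s <- .stage("generate",
                  gen_fluor_titration(tr, grid, kind = kind, band = band))
      write_titration_csv(s, file.path(out_dir, "titration.csv"))
      report$truth <- list(Kp = tr$Kp, noise_cv = tr$noise_cv)
    } else if (what == "itc") {
      proto <- do.call(itc_protocol, .cfg_get(cfg, "protocol", list()))
      exp <- .stage("generate",
                    gen_itc_heats(proto, Kp = cfg$Kp, dH = cfg$dH,
                                  q_dil = .cfg_get(cfg, "q_dil", 0),
                                  noise_sd = .cfg_get(cfg, "noise_sd", 0),
                                  seed = seed, Vbar = Vbar))
      write_itc_csv(exp, file.path(out_dir, "heats.csv"))
      report$truth <- list(Kp = cfg$Kp, dH = cfg$dH)
    } else if (what == "umbrella") {
      depth <- .cfg_get(cfg, "well_depth", 0)
      pot <- square_well_potential(depth, z_on = 1.0, z_off = 1.4)
      spec <- brownian_spec(pot, seed = seed,
                            n_steps = .cfg_get(cfg, "n_steps", 4000))
      wins <- .stage("generate", gen_umbrella_windows(spec))
      report$windows_meta <- as.character(
        write_windows(wins, file.path(out_dir, "windows")))
      report$truth <- list(well_depth = depth)
    } else stop("unknown simulate target '", what, "'")
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
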