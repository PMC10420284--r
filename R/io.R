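# Readers and writers for the plain-text dialects the pipeline exchanges:
# titration CSV, ITC heat CSV, umbrella window pull files + metadata CSV,
# three-column PMF text, and multi-frame GRO/XYZ coordinates.  Every writer
# round-trips through its reader.

# --- titrations --------------------------------------------------------------

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing column(s) ", paste(miss, collapse = ", "), " in ", path)
}

.check_numeric_col <- function(df, col, path) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !is.na(df[[col]]))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                 df[[col]][bad[1]], bad[1], col, path))
  v
}

#' Read titration series from CSV
#'
#' Expects columns `lipid_M, signal, kind, band, pH`; rows are grouped into
#' one [titration_series()] per distinct `(kind, band, pH)` combination and
#' sorted by lipid concentration.
#'
#' @param path CSV file path.
#' @return List of [titration_series()].
#' @export
read_titration_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("lipid_M", "signal", "kind", "band", "pH"), path)
  if (!nrow(df)) stop("empty data section in ", path)
  df$lipid_M <- .check_numeric_col(df, "lipid_M", path)
  df$signal <- .check_numeric_col(df, "signal", path)
  df$pH <- .check_numeric_col(df, "pH", path)
  key <- interaction(df$kind, df$band, df$pH, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$lipid_M), ]
    titration_series(g$lipid_M, g$signal, kind = g$kind[1], band = g$band[1],
                     pH = g$pH[1])
  })
}

#' Write titration series to CSV
#'
#' @param series_list list of [titration_series()] (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series_list, path) {
  if (inherits(series_list, "titration_series"))
    series_list <- list(series_list)
  df <- do.call(rbind, lapply(series_list, function(s)
    data.frame(lipid_M = s$lipid, signal = s$signal, kind = s$kind,
               band = s$band, pH = s$pH)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- ITC ---------------------------------------------------------------------

#' Read integrated ITC heats from CSV
#'
#' Expects columns `injection, heat, unit`.  Units accepted: `"J"` (raw
#' joules), `"ucal"` (microcalories, x 4.184e-6 J), `"kcal/mol"` (kcal per
#' mole of injectant, converted using the protocol's injection volume and
#' syringe concentration).
#'
#' @param path CSV path.
#' @param protocol the [itc_protocol()] the heats belong to.
#' @return An [itc_experiment()] with heats in J.
#' @export
read_itc_csv <- function(path, protocol) {
  if (!file.exists(path)) stop("no such file: ", path)
  stopifnot(inherits(protocol, "itc_protocol"))
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("injection", "heat", "unit"), path)
  if (!nrow(df)) stop("empty data section in ", path)
  df$heat <- .check_numeric_col(df, "heat", path)
  df <- df[order(df$injection), ]
  mol_inj <- protocol$inj_volume * protocol$lipid_syringe
  q <- vapply(seq_len(nrow(df)), function(i) {
    switch(df$unit[i],
           "J" = df$heat[i],
           "ucal" = df$heat[i] * 4.184e-6,
           "kcal/mol" = df$heat[i] * 4184 * mol_inj,
           stop("unknown heat unit '", df$unit[i], "' at row ", i, " of ",
                path))
  }, 0)
  itc_experiment(protocol, q)
}

#' Write ITC heats to CSV (J)
#'
#' @param exp an [itc_experiment()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_itc_csv <- function(exp, path) {
  stopifnot(inherits(exp, "itc_experiment"))
  write.csv(data.frame(injection = seq_along(exp$heats), heat = exp$heats,
                       unit = "J"),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- umbrella windows (pull-file dialect) ------------------------------------

#' Read umbrella windows from pull files plus a metadata table
#'
#' The metadata CSV has columns `file, center, force_const`; each referenced
#' file is two-column whitespace text `(time_ps, z_nm)` resolved relative to
#' the metadata file's directory.  The first `discard_frac` of each window's
#' time span is dropped as equilibration (e.g. 1/3 of a 120 ns run keeps the
#' last 80 ns).
#'
#' @param meta_path metadata CSV path.
#' @param discard_frac fraction of the time span to discard, in [0, 1).
#' @return List of [umbrella_window()].
#' @export
read_windows <- function(meta_path, discard_frac = 0) {
  if (!file.exists(meta_path)) stop("no such file: ", meta_path)
  stopifnot(discard_frac >= 0, discard_frac < 1)
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  .require_cols(meta, c("file", "center", "force_const"), meta_path)
  base <- dirname(meta_path)
  lapply(seq_len(nrow(meta)), function(i) {
    if (meta$force_const[i] <= 0)
      stop("force constant <= 0 for window ", meta$file[i])
    f <- file.path(base, meta$file[i])
    if (!file.exists(f)) stop("missing sample file: ", f)
    d <- tryCatch(read.table(f, col.names = c("t", "z")),
                  error = function(e)
                    stop("window ", meta$file[i], ": ", conditionMessage(e)))
    if (!nrow(d)) stop("empty sample file for window ", meta$file[i])
    t0 <- min(d$t) + discard_frac * (max(d$t) - min(d$t))
    keep <- d$t >= t0
    if (!any(keep))
      stop("window ", meta$file[i], " has no samples after discard")
    dt <- if (sum(keep) > 1) median(diff(d$t[keep])) else 1
    umbrella_window(meta$center[i], meta$force_const[i], d$z[keep],
                    dt_ps = dt, t0_ps = d$t[keep][1])
  })
}

#' Write umbrella windows as pull files plus metadata
#'
#' @param windows list of [umbrella_window()].
#' @param dir output directory (created if needed).
#' @param prefix sample-file name prefix.
#' @return Path of the metadata CSV, invisibly.
#' @export
write_windows <- function(windows, dir, prefix = "window") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%03d.xvg", prefix, seq_along(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    write.table(data.frame(t = .window_times(w), z = w$samples),
                file.path(dir, files[i]),
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  meta <- data.frame(file = files,
                     center = vapply(windows, `[[`, 0, "center"),
                     force_const = vapply(windows, `[[`, 0, "force_const"))
  meta_path <- file.path(dir, "windows.csv")
  write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(meta_path)
}

# --- PMF text ----------------------------------------------------------------

#' Write a PMF profile as three-column text
#'
#' Columns: `z_nm dG_kJmol err_kJmol` (err is NA when no bootstrap error is
#' attached); masked bins are written with NA dG.
#'
#' @param profile a [pmf_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pmf <- function(profile, path) {
  stopifnot(inherits(profile, "pmf_profile"))
  err <- if (is.null(profile$boot_err)) rep(NA_real_, length(profile$z))
  else profile$boot_err
  write.table(data.frame(z_nm = profile$z, dG_kJmol = profile$dG,
                         err_kJmol = err),
              path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a PMF profile written by [write_pmf()]
#'
#' @param path input path.
#' @param temperature K to attach to the profile.
#' @return A [pmf_profile()].
#' @export
read_pmf <- function(path, temperature = 298) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.table(path, header = TRUE)
  err <- if (all(is.na(d$err_kJmol))) NULL else d$err_kJmol
  pmf_profile(d$z_nm, d$dG_kJmol, temperature = temperature,
              boot_err = err)
}

# --- coordinates (GRO / XYZ dialects) ----------------------------------------

#' Write a trajectory as concatenated multi-frame GRO
#'
#' Fixed-width GROMACS coordinate format, one frame block (title, atom
#' count, atom lines, box line) per frame; positions in nm.  Molecule ids
#' map to residue numbers and species labels to residue names.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$coords)[3]
  na <- dim(traj$coords)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(c(sprintf("frame %d", f), sprintf("%5d", na)), con)
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     traj$atoms$molecule %% 100000,
                     substr(traj$atoms$species, 1, 5),
                     substr(traj$atoms$name, 1, 5),
                     seq_len(na) %% 100000,
                     traj$coords[, 1, f], traj$coords[, 2, f],
                     traj$coords[, 3, f])
    writeLines(lines, con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$boxes[f, 1],
                       traj$boxes[f, 2], traj$boxes[f, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame GRO file into a trajectory
#'
#' GRO files carry no masses; supply them as a named vector keyed by atom
#' name.  Residue numbers become molecule ids and residue names species
#' labels.  The atom list must be identical across frames.
#'
#' @param path GRO path.
#' @param masses named numeric vector, amu, one entry per distinct atom name.
#' @return A [trajectory()].
#' @export
read_gro <- function(path, masses) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  frames <- list()
  boxes <- list()
  atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    na <- as.integer(trimws(lines[i + 1L]))
    al <- lines[(i + 2L):(i + 1L + na)]
    mol <- as.integer(substr(al, 1, 5))
    res <- trimws(substr(al, 6, 10))
    nm <- trimws(substr(al, 11, 15))
    x <- as.numeric(substr(al, 21, 28))
    y <- as.numeric(substr(al, 29, 36))
    z <- as.numeric(substr(al, 37, 44))
    if (is.null(atoms)) {
      if (!all(nm %in% names(masses)))
        stop("no mass supplied for atom name(s): ",
             paste(setdiff(nm, names(masses)), collapse = ", "))
      atoms <- data.frame(name = nm, mass = unname(masses[nm]),
                          molecule = mol, species = res,
                          stringsAsFactors = FALSE)
    }
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
    boxes[[length(boxes) + 1L]] <-
      as.numeric(strsplit(trimws(lines[i + 2L + na]), "\\s+")[[1]])[1:3]
    i <- i + 3L + na
  }
  coords <- array(0, dim = c(nrow(atoms), 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  trajectory(coords, do.call(rbind, boxes), atoms)
}

#' Write a trajectory in a plain XYZ-with-box dialect
#'
#' Per frame: an atom-count line, a comment line `box Lx Ly Lz`, then
#' `name x y z` lines (nm).
#'
#' @inheritParams write_gro
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$coords)[3]
  na <- dim(traj$coords)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(c(sprintf("%d", na),
                 sprintf("box %.5f %.5f %.5f", traj$boxes[f, 1],
                         traj$boxes[f, 2], traj$boxes[f, 3]),
                 sprintf("%-6s %12.6f %12.6f %12.6f", traj$atoms$name,
                         traj$coords[, 1, f], traj$coords[, 2, f],
                         traj$coords[, 3, f])), con)
  }
  invisible(path)
}

#' Read the plain XYZ-with-box dialect written by [write_xyz()]
#'
#' @param path input path.
#' @param atoms data.frame with `name`, `mass`, `molecule`, `species` for the
#'   atoms, in file order (the dialect itself carries names only).
#' @return A [trajectory()].
#' @export
read_xyz <- function(path, atoms) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  frames <- list(); boxes <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    na <- as.integer(trimws(lines[i]))
    boxes[[length(boxes) + 1L]] <-
      as.numeric(strsplit(trimws(lines[i + 1L]), "\\s+")[[1]][2:4])
    al <- strsplit(trimws(lines[(i + 2L):(i + 1L + na)]), "\\s+")
    frames[[length(frames) + 1L]] <-
      t(vapply(al, function(p) as.numeric(p[2:4]), numeric(3)))
    i <- i + 2L + na
  }
  coords <- array(0, dim = c(nrow(atoms), 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  trajectory(coords, do.call(rbind, boxes), atoms)
}
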