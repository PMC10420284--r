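# Observables from multi-frame coordinate data: mass-density profiles,
# transverse group positions, long-axis tilt, and hydrogen-bond fractional
# frequencies.  Coordinates are nm; the bilayer normal is z.

#' Trajectory container
#'
#' @param coords numeric array `n_atoms x 3 x n_frames`, nm.
#' @param boxes numeric matrix `n_frames x 3` of box lengths (Lx, Ly, Lz),
#'   nm, all positive.
#' @param atoms data.frame with one row per atom and columns `name`,
#'   `mass` (amu, > 0), `molecule` (integer id), `species` (label).
#' @return A `trajectory` object.
#' @export
trajectory <- function(coords, boxes, atoms) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[2] == 3)
  n_atoms <- dim(coords)[1]
  n_frames <- dim(coords)[3]
  boxes <- matrix(as.numeric(boxes), ncol = 3)
  if (nrow(boxes) == 1L) boxes <- boxes[rep(1L, n_frames), , drop = FALSE]
  stopifnot(nrow(boxes) == n_frames, all(boxes > 0))
  stopifnot(is.data.frame(atoms), nrow(atoms) == n_atoms,
            all(c("name", "mass", "molecule", "species") %in% names(atoms)),
            all(atoms$mass > 0))
  structure(list(coords = coords, boxes = boxes, atoms = atoms),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms x %d frames; species: %s\n",
              dim(x$coords)[1], dim(x$coords)[3],
              paste(unique(x$atoms$species), collapse = ", ")))
  invisible(x)
}

#' Group specification for trajectory analyses
#'
#' Names the atom selections the observables need: center-of-mass groups, the
#' solute long axis (tail -> head; by convention the head is the end expected
#' to point toward water), N-H donor pairs and acceptor oxygen classes.
#'
#' @param com_groups named list: group label -> character vector of atom
#'   names.
#' @param axis_pair character length-2 `(tail, head)` atom names (distinct).
#'   There is no default: the long axis is a per-molecule modelling choice.
#' @param donors data.frame with columns `donor` (N name) and `hydrogen`
#'   (bonded H name).
#' @param acceptor_classes named list: class label (e.g. phosphate, carbonyl,
#'   glycerol) -> acceptor O atom names.
#' @return A `group_spec` object.
#' @export
group_spec <- function(com_groups = list(), axis_pair = NULL, donors = NULL,
                       acceptor_classes = list()) {
  if (!is.null(axis_pair)) {
    stopifnot(length(axis_pair) == 2)
    if (axis_pair[1] == axis_pair[2]) stop("axis atoms must be distinct")
  }
  if (!is.null(donors))
    stopifnot(is.data.frame(donors),
              all(c("donor", "hydrogen") %in% names(donors)))
  structure(list(com_groups = com_groups, axis_pair = axis_pair,
                 donors = donors, acceptor_classes = acceptor_classes),
            class = "group_spec")
}

# --- selection helpers -------------------------------------------------------

.sel_atoms <- function(traj, names = NULL, molecule = NULL, species = NULL) {
  keep <- rep(TRUE, nrow(traj$atoms))
  if (!is.null(names)) keep <- keep & traj$atoms$name %in% names
  if (!is.null(molecule)) keep <- keep & traj$atoms$molecule %in% molecule
  if (!is.null(species)) keep <- keep & traj$atoms$species %in% species
  which(keep)
}

# mass-weighted COM z per frame for an atom-index selection
.com_z <- function(traj, idx) {
  if (!length(idx)) stop("empty atom selection")
  m <- traj$atoms$mass[idx]
  z <- matrix(traj$coords[idx, 3, , drop = FALSE], nrow = length(idx))
  colSums(z * m) / sum(m)
}

# bilayer COM z per frame (zero if no bilayer species is given: coordinates
# are then taken as already centered on the bilayer)
.bilayer_z <- function(traj, bilayer_species) {
  if (is.null(bilayer_species)) return(numeric(dim(traj$coords)[3]))
  idx <- .sel_atoms(traj, species = bilayer_species)
  if (!length(idx))
    stop("no atoms with species '", bilayer_species, "'")
  .com_z(traj, idx)
}

#' Center-of-mass z time series of a group
#'
#' Mass-weighted center-of-mass z of the selected atoms of one molecule, per
#' frame, signed relative to the bilayer center of mass.
#'
#' @param traj a [trajectory()].
#' @param group character vector of atom names (a center-of-mass group).
#' @param molecule molecule id.
#' @param bilayer_species species label of the bilayer whose COM defines
#'   z = 0; `NULL` (default) if coordinates are already bilayer-centered.
#' @return Numeric vector, nm, one value per frame.
#' @export
com_z_series <- function(traj, group, molecule, bilayer_species = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- .sel_atoms(traj, names = group, molecule = molecule)
  .com_z(traj, idx) - .bilayer_z(traj, bilayer_species)
}

#' Mass-density profile along the bilayer normal
#'
#' Frame-averaged histogram of atom masses in z slabs, converted to kg/m^3:
#' each bin holds `sum(mass) / (Lx * Ly * bin_width)` averaged over frames.
#' The integral of the profile over z times the box cross-section recovers
#' the total species mass per frame (mass conservation), independent of the
#' bin width.
#'
#' @param traj a [trajectory()].
#' @param species species label to profile.
#' @param bin_width slab thickness, nm (> 0).
#' @param bilayer_species optional species whose COM recenters z per frame.
#' @return A data.frame with `z` (bin centers, nm, relative to the bilayer
#'   center) and `density` (kg/m^3).
#' @export
mass_density_profile <- function(traj, species, bin_width = 0.1,
                                 bilayer_species = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  .chk_num1(bin_width, "bin_width", positive = TRUE)
  idx <- .sel_atoms(traj, species = species)
  if (!length(idx)) stop("no atoms with species '", species, "'")
  n_frames <- dim(traj$coords)[3]
  z0 <- .bilayer_z(traj, bilayer_species)
  z <- matrix(traj$coords[idx, 3, , drop = FALSE], nrow = length(idx))
  z <- sweep(z, 2, z0, "-")
  m <- traj$atoms$mass[idx]
  lo <- floor(min(z) / bin_width) * bin_width
  hi <- ceiling(max(z) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  acc <- numeric(length(centers))
  for (f in seq_len(n_frames)) {
    b <- findInterval(z[, f], edges, rightmost.closed = TRUE)
    b <- pmin(pmax(b, 1L), length(centers))
    acc <- acc + as.vector(tapply(m, factor(b, levels = seq_along(centers)),
                                  sum, default = 0))
  }
  area_nm2 <- mean(traj$boxes[, 1] * traj$boxes[, 2])
  vol_m3 <- area_nm2 * bin_width * 1e-27
  data.frame(z = centers,
             density = acc / n_frames * .AMU_KG / vol_m3)
}

#' Mean transverse distance to the bilayer center, per group
#'
#' For each center-of-mass group and each molecule, the time-average of |z|
#' is taken first; the across-molecule mean and t-based 95% confidence
#' interval are then reported (the molecule, not the frame, is the
#' independent unit).  |z| pools the two leaflets.
#'
#' @param traj a [trajectory()].
#' @param groups named list of atom-name vectors, or a [group_spec()] (its
#'   `com_groups` are used).
#' @param molecules integer vector of molecule ids to average over (>= 1);
#'   molecules excluded from analysis (e.g. aggregates) are simply left out
#'   of this vector.
#' @param bilayer_species optional bilayer species for recentring.
#' @param conf confidence level (default 0.95).
#' @return A data.frame with one row per group: `group`, `mean_abs_z` (nm),
#'   `ci_half_width` (nm; 0 when all molecules agree exactly or n = 1),
#'   `n_molecules`.
#' @export
group_positions <- function(traj, groups, molecules, bilayer_species = NULL,
                            conf = 0.95) {
  stopifnot(inherits(traj, "trajectory"), length(molecules) >= 1)
  if (inherits(groups, "group_spec")) groups <- groups$com_groups
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  z0 <- .bilayer_z(traj, bilayer_species)
  rows <- lapply(names(groups), function(g) {
    per_mol <- vapply(molecules, function(m) {
      idx <- .sel_atoms(traj, names = groups[[g]], molecule = m)
      mean(abs(.com_z(traj, idx) - z0))
    }, 0)
    n <- length(per_mol)
    half <- if (n > 1 && sd(per_mol) > 0)
      qt(1 - (1 - conf) / 2, n - 1) * sd(per_mol) / sqrt(n)
    else 0
    data.frame(group = g, mean_abs_z = mean(per_mol),
               ci_half_width = half, n_molecules = n)
  })
  do.call(rbind, rows)
}

#' Long-axis tilt distribution relative to the bilayer normal
#'
#' The tilt of a molecule in a frame is the angle between its (head - tail)
#' axis vector and the outward normal of the leaflet it occupies (+z for the
#' upper leaflet, -z for the lower, decided by the sign of the molecule COM z
#' re-evaluated every frame).  With this convention theta < 90 deg always
#' means "head pointing toward water", in either leaflet.
#'
#' @param traj a [trajectory()].
#' @param axis_pair character `(tail, head)` atom names.
#' @param molecules molecule ids to pool.
#' @param bin_width_deg histogram bin width, degrees (default 5).
#' @param bilayer_species optional bilayer species for recentring.
#' @return A list of class `tilt_distribution`: `theta_bins` (deg, centers on
#'   `[0, 180]`), `density` (probability density per degree; sums to 1 when
#'   multiplied by the bin width), `mean_theta` (deg), `theta` (all pooled
#'   angles).
#' @export
tilt_distribution <- function(traj, axis_pair, molecules, bin_width_deg = 5,
                              bilayer_species = NULL) {
  stopifnot(inherits(traj, "trajectory"), length(axis_pair) == 2)
  .chk_num1(bin_width_deg, "bin_width_deg", positive = TRUE)
  z0 <- .bilayer_z(traj, bilayer_species)
  thetas <- unlist(lapply(molecules, function(m) {
    it <- .sel_atoms(traj, names = axis_pair[1], molecule = m)
    ih <- .sel_atoms(traj, names = axis_pair[2], molecule = m)
    if (length(it) != 1 || length(ih) != 1)
      stop("axis atoms must resolve to exactly one atom each in molecule ", m)
    imol <- .sel_atoms(traj, molecule = m)
    leaflet <- sign(.com_z(traj, imol) - z0)
    leaflet[leaflet == 0] <- 1
    v <- traj$coords[ih, , ] - traj$coords[it, , ]   # 3 x n_frames
    v <- matrix(v, nrow = 3)
    len <- sqrt(colSums(v^2))
    if (any(len == 0)) stop("zero-length axis vector in molecule ", m)
    cosang <- (v[3, ] * leaflet) / len
    acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }))
  edges <- seq(0, 180, by = bin_width_deg)
  if (max(edges) < 180) edges <- c(edges, 180)
  h <- tabulate(pmin(pmax(findInterval(thetas, edges, rightmost.closed = TRUE),
                          1L), length(edges) - 1L), length(edges) - 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  widths <- diff(edges)
  structure(list(theta_bins = centers,
                 density = h / sum(h) / widths,
                 mean_theta = mean(thetas),
                 theta = thetas),
            class = "tilt_distribution")
}

#' @export
print.tilt_distribution <- function(x, ...) {
  cat(sprintf("tilt_distribution: %d angles, mean theta = %.1f deg\n",
              length(x$theta), x$mean_theta))
  invisible(x)
}

# --- hydrogen bonding --------------------------------------------------------

# squared distance between two atoms across frames, minimum image in x/y only
# (z unwrapped: the bilayer is centered by construction)
.pair_dist <- function(traj, i, j) {
  d <- traj$coords[j, , ] - traj$coords[i, , ]
  d <- matrix(d, nrow = 3)
  for (k in 1:2) {
    L <- traj$boxes[, k]
    d[k, ] <- d[k, ] - round(d[k, ] / L) * L
  }
  d
}

#' Hydrogen-bond fractional frequencies, donors x acceptor classes
#'
#' A donor-acceptor pair is bonded in a frame iff the donor-acceptor distance
#' is <= `d_cut` and the hydrogen-donor-acceptor angle is <= `angle_cut`
#' (geometric criterion; defaults 0.35 nm and 30 degrees, the common
#' MD-analysis convention).  The fractional frequency entry for (donor d,
#' class c) is the bonded-pair count summed over all acceptors of class c,
#' averaged over frames and over the analyzed solute molecules, i.e. mean
#' bonds per frame per molecule.
#'
#' @param traj a [trajectory()].
#' @param donors data.frame with columns `donor` and `hydrogen` (atom names
#'   within each solute molecule).
#' @param acceptor_classes named list: class -> acceptor atom names (searched
#'   in `acceptor_species` molecules).
#' @param d_cut donor-acceptor distance cutoff, nm.
#' @param angle_cut H-donor-acceptor angle cutoff, degrees.
#' @param donor_species species label of the solute carrying the donors.
#' @param acceptor_species species label(s) carrying the acceptors.
#' @param molecules optional solute molecule ids to analyze (default: all
#'   molecules of `donor_species`); pass a subset to exclude e.g. aggregated
#'   molecules.
#' @return An [hbond_summary()].
#' @export
hbond_frequencies <- function(traj, donors, acceptor_classes, d_cut = 0.35,
                              angle_cut = 30, donor_species = "solute",
                              acceptor_species = "lipid", molecules = NULL) {
  stopifnot(inherits(traj, "trajectory"), d_cut > 0, angle_cut > 0,
            is.data.frame(donors), length(acceptor_classes) >= 1)
  if (is.null(molecules))
    molecules <- sort(unique(
      traj$atoms$molecule[traj$atoms$species %in% donor_species]))
  if (!length(molecules)) stop("no molecules of species '", donor_species, "'")
  n_frames <- dim(traj$coords)[3]
  cos_cut <- cos(angle_cut * pi / 180)
  freq <- matrix(0, nrow = nrow(donors), ncol = length(acceptor_classes),
                 dimnames = list(donors$donor, names(acceptor_classes)))
  acc_idx <- lapply(acceptor_classes, function(nm)
    .sel_atoms(traj, names = nm, species = acceptor_species))
  for (m in molecules) {
    for (di in seq_len(nrow(donors))) {
      id <- .sel_atoms(traj, names = donors$donor[di], molecule = m)
      ih <- .sel_atoms(traj, names = donors$hydrogen[di], molecule = m)
      if (length(id) != 1)
        stop("donor '", donors$donor[di], "' does not resolve uniquely in molecule ", m)
      if (length(ih) != 1)
        stop("missing hydrogen '", donors$hydrogen[di], "' for donor '",
             donors$donor[di], "' in molecule ", m)
      vdh <- .pair_dist(traj, id, ih)
      for (ci in seq_along(acc_idx)) {
        for (ia in acc_idx[[ci]]) {
          vda <- .pair_dist(traj, id, ia)
          dda <- sqrt(colSums(vda^2))
          near <- dda <= d_cut
          if (!any(near)) next
          cosang <- colSums(vdh[, near, drop = FALSE] *
                              vda[, near, drop = FALSE]) /
            (sqrt(colSums(vdh[, near, drop = FALSE]^2)) * dda[near])
          freq[di, ci] <- freq[di, ci] + sum(cosang >= cos_cut)
        }
      }
    }
  }
  hbond_summary(freq / (n_frames * length(molecules)),
                n_donors = nrow(donors))
}

#' Hydrogen-bond summary container
#'
#' @param freq numeric matrix, donor groups (rows) x acceptor classes
#'   (columns), of fractional frequencies (mean bonds per frame per
#'   molecule); all entries >= 0.
#' @param n_donors number of N-H donor groups on the solute (>= 1 for
#'   [per_donor_frequency()]).
#' @return An `hbond_summary` with the matrix plus row/column totals and the
#'   grand total.
#' @export
hbond_summary <- function(freq, n_donors = nrow(freq)) {
  freq <- as.matrix(freq)
  if (any(freq < 0)) stop("frequencies must be non-negative")
  structure(list(freq = freq,
                 n_donors = n_donors,
                 donor_totals = rowSums(freq),
                 class_totals = colSums(freq),
                 grand_total = sum(freq)),
            class = "hbond_summary")
}

#' @export
print.hbond_summary <- function(x, ...) {
  cat(sprintf("hbond_summary: %d donor group(s), grand total %.3g bonds/frame/molecule\n",
              x$n_donors, x$grand_total))
  print(round(x$freq, 3))
  invisible(x)
}

#' Mean H-bond frequency per donor group
#'
#' Grand total of the frequency matrix divided by the number of N-H donor
#' groups; the rounded 2-decimal display value is attached as an attribute.
#'
#' @param summary an [hbond_summary()] with `n_donors >= 1`.
#' @return Bonds per frame per molecule per donor (full precision), with
#'   attribute `display` rounded to 2 decimals.
#' @export
per_donor_frequency <- function(summary) {
  stopifnot(inherits(summary, "hbond_summary"))
  if (summary$n_donors < 1) stop("n_donors must be >= 1")
  out <- summary$grand_total / summary$n_donors
  attr(out, "display") <- round(out, 2)
  out
}

#' Acceptor-class percentages of total H bonding
#'
#' @param summary an [hbond_summary()] with positive grand total.
#' @return Named numeric vector of percentages (sums to 100).
#' @export
acceptor_class_fractions <- function(summary) {
  stopifnot(inherits(summary, "hbond_summary"))
  if (summary$grand_total <= 0) stop("grand total is zero")
  100 * summary$class_totals / summary$grand_total
}
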