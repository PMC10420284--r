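# Synthetic-data generators with known ground truth.  Every input class the
# pipeline consumes can be produced here, so each fitting stage is testable
# by parameter recovery without any external data.  All generators take an
# explicit integer seed and never touch the caller's RNG state.

#' Ground truth for fluorescence titration generation
#'
#' Holds the forward-model parameters of the intensity and anisotropy
#' partition isotherms.  The defaults are the conditions of a pH 6
#' Hoechst/POPC titration: Kp = 1.8e3, band intensity ratios alphaM = 13, 8
#' and 5 for detection at 450-470, 470-490 and 490-510 nm, water/membrane
#' intensity endpoints in the ratio of the bluest band, and anisotropy
#' endpoints typical of a free vs membrane-bound small dye.
#'
#' @param Kp true partition coefficient (> 0).
#' @param Iw,Im intensity endpoints (all-aqueous / all-membrane), a.u.
#' @param rw,rm anisotropy endpoints, each in [-0.2, 0.4].
#' @param alphaM_by_band named numeric vector of band intensity ratios
#'   (all > 0).
#' @param Vbar lipid molar volume, L/mol.
#' @param noise_cv coefficient of variation of the multiplicative Gaussian
#'   noise (>= 0); intensities span orders of magnitude across bands, so the
#'   noise scales with the signal.
#' @param seed integer RNG seed.
#' @return A `fluor_truth` object.
#' @export
fluor_truth <- function(Kp = 1.8e3, Iw = 1, Im = 13, rw = 0.05, rm = 0.25,
                        alphaM_by_band = c("450-470" = 13, "470-490" = 8,
                                           "490-510" = 5),
                        Vbar = 0.8, noise_cv = 0.02, seed = 1L) {
  .chk_num1(Kp, "Kp", positive = TRUE)
  .chk_num1(Vbar, "Vbar", positive = TRUE)
  .chk_num1(noise_cv, "noise_cv", nonneg = TRUE)
  if (any(alphaM_by_band <= 0)) stop("every alphaM must be > 0")
  if (any(c(rw, rm) < -0.2 | c(rw, rm) > 0.4))
    stop("anisotropy endpoints must lie in [-0.2, 0.4]")
  structure(list(Kp = Kp, Iw = Iw, Im = Im, rw = rw, rm = rm,
                 alphaM_by_band = alphaM_by_band, Vbar = Vbar,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "fluor_truth")
}

#' Default lipid-concentration grid for titrations
#'
#' A 12-point geometric grid from 1e-5 to 2e-3 M, covering roughly from
#' one-tenth of the half-saturation lipid concentration of a Kp ~ 1e3 solute
#' to well past saturation, with an added zero-lipid anchor.
#'
#' @param n number of nonzero points.
#' @param from,to grid limits, mol/L.
#' @param zero_anchor include a leading 0 (the free-solute signal).
#' @return Ascending numeric vector, mol/L.
#' @export
default_lipid_grid <- function(n = 12, from = 1e-5, to = 2e-3,
                               zero_anchor = TRUE) {
  g <- exp(seq(log(from), log(to), length.out = n))
  if (zero_anchor) c(0, g) else g
}

#' Generate a fluorescence titration from known truth
#'
#' Evaluates the intensity or (band-weighted) anisotropy partition isotherm
#' at the given lipid concentrations and applies multiplicative Gaussian
#' noise `signal * (1 + eps)`, `eps ~ N(0, noise_cv^2)`.  Deterministic for a
#' given seed.
#'
#' @param truth a [fluor_truth()].
#' @param lipid_concs non-negative ascending lipid concentrations, mol/L.
#' @param kind `"intensity"` or `"anisotropy"`.
#' @param band band label; for anisotropy it must name an entry of
#'   `truth$alphaM_by_band`.
#' @param pH metadata carried on the series.
#' @param seed RNG seed (defaults to `truth$seed`).
#' @return A [titration_series()].
#' @export
gen_fluor_titration <- function(truth, lipid_concs, kind = c("intensity",
                                                             "anisotropy"),
                                band = names(truth$alphaM_by_band)[1],
                                pH = 6, seed = truth$seed) {
  stopifnot(inherits(truth, "fluor_truth"))
  kind <- match.arg(kind)
  if (any(lipid_concs < 0)) stop("negative lipid concentration")
  if (is.unsorted(lipid_concs)) stop("lipid concentrations must be ascending")
  if (kind == "anisotropy" && !band %in% names(truth$alphaM_by_band))
    stop("unknown band label '", band, "'")
  mu <- if (kind == "intensity")
    .isotherm_intensity(lipid_concs, truth$Iw, truth$Im, truth$Kp, truth$Vbar)
  else
    .isotherm_anisotropy(lipid_concs, truth$rw, truth$rm, truth$Kp,
                         truth$alphaM_by_band[[band]], truth$Vbar)
  sig <- if (truth$noise_cv > 0)
    withr::with_seed(seed, mu * (1 + rnorm(length(mu), 0, truth$noise_cv)))
  else mu
  titration_series(lipid_concs, sig, kind = kind, band = band, pH = pH)
}

#' Generate an ITC uptake titration from known truth
#'
#' Forward heats from [model_heats()] (same recursion the fitter uses) plus
#' additive Gaussian noise.  Deterministic for a given seed.
#'
#' @param protocol an [itc_protocol()].
#' @param Kp,dH,q_dil true partition coefficient, molar enthalpy (kJ/mol) and
#'   per-injection dilution heat (J).
#' @param noise_sd additive noise standard deviation, J (>= 0).
#' @param seed integer RNG seed.
#' @param Vbar lipid molar volume, L/mol.
#' @return An [itc_experiment()].
#' @export
gen_itc_heats <- function(protocol, Kp, dH, q_dil = 0, noise_sd = 0,
                          seed = 1L, Vbar = 0.8) {
  .chk_num1(noise_sd, "noise_sd", nonneg = TRUE)
  q <- model_heats(protocol, Kp, dH, q_dil, Vbar)
  if (noise_sd > 0)
    q <- withr::with_seed(seed, q + rnorm(length(q), 0, noise_sd))
  itc_experiment(protocol, q)
}

#' Specification of a 1-D biased Brownian sampler
#'
#' Stands in for umbrella-sampling MD: overdamped Langevin dynamics on a
#' user-supplied free-energy landscape `G(z)` (kJ/mol) with a harmonic window
#' bias.  The default window layout is the standard protocol for a 4 nm
#' half-bilayer coordinate: 41 centers from 0 to 4.0 nm spaced 0.1 nm, force
#' constant 3000 kJ mol^-1 nm^-2.
#'
#' @param potential vectorized function z -> G(z), kJ/mol.
#' @param centers window centers, nm.
#' @param force_const harmonic force constant, kJ mol^-1 nm^-2.
#' @param diffusion diffusion coefficient, nm^2/ps.  The relaxation time of
#'   a window is RT/(D k); the defaults give a few hundred thousand
#'   decorrelated samples across the run, which the window-matching step of
#'   WHAM needs when adjacent windows overlap only in their tails.
#' @param dt time step, ps; the Euler-Maruyama stationary variance is
#'   inflated by about D k dt / (2 RT), ~2\% at the defaults.
#' @param n_steps integration steps per window.
#' @param sample_every store every n-th step (thinning; the discarded steps
#'   are more correlated than the window relaxation time, so thinning loses
#'   no information).
#' @param discard_frac fraction of initial steps discarded as equilibration,
#'   in [0, 1).
#' @param seed integer RNG seed.
#' @param grad optional analytic gradient of `potential` (taken from
#'   `attr(potential, "grad")` when present); a central difference
#'   (h = 1e-5 nm) is used otherwise.
#' @return A `brownian_spec`.  Construction asserts the per-step RMS
#'   displacement `sqrt(2 D dt)` is below the window spacing (step
#'   stability).
#' @export
brownian_spec <- function(potential, centers = seq(0, 4, by = 0.1),
                          force_const = 3000, diffusion = 0.02, dt = 0.002,
                          n_steps = 1e6, sample_every = 10L,
                          discard_frac = 1 / 3, seed = 1L, grad = NULL) {
  stopifnot(is.function(potential))
  .chk_num1(force_const, "force_const", positive = TRUE)
  .chk_num1(diffusion, "diffusion", positive = TRUE)
  .chk_num1(dt, "dt", positive = TRUE)
  stopifnot(discard_frac >= 0, discard_frac < 1, n_steps >= 1,
            sample_every >= 1)
  spacing <- if (length(centers) > 1) min(diff(sort(centers))) else Inf
  if (sqrt(2 * diffusion * dt) >= spacing)
    stop("per-step RMS displacement sqrt(2 D dt) = ",
         signif(sqrt(2 * diffusion * dt), 3),
         " nm is not below the window spacing ", signif(spacing, 3),
         " nm: reduce dt or diffusion")
  if (is.null(grad)) grad <- attr(potential, "grad")
  structure(list(potential = potential, centers = as.numeric(centers),
                 force_const = force_const, diffusion = diffusion, dt = dt,
                 n_steps = as.integer(n_steps),
                 sample_every = as.integer(sample_every),
                 discard_frac = discard_frac,
                 seed = as.integer(seed), grad = grad),
            class = "brownian_spec")
}

#' Generate umbrella windows by biased Brownian dynamics
#'
#' Metropolis-adjusted overdamped Langevin dynamics (MALA) in the total
#' potential `G(z) + k/2 (z - z0_i)^2`, all windows propagated in parallel
#' from their centers.  Each step proposes the Euler-Maruyama move
#' \deqn{z' = z - \frac{D}{RT}\,\partial_z G_{tot}(z)\,dt
#'   + \sqrt{2 D dt}\,\xi}
#' and accepts it with the Metropolis-Hastings probability, so the sampled
#' stationary distribution is \emph{exactly}
#' \eqn{\propto e^{-G_{tot}(z)/RT}} at any step size (plain Euler-Maruyama
#' inflates the stationary variance by O(D k dt / RT), which measurably
#' distorts steep features).  The first `discard_frac` of the retained steps
#' is dropped.  For quadratic total potentials the samples are Gaussian with
#' mean at the biased minimum and variance RT/k_tot.
#'
#' @param spec a [brownian_spec()].
#' @param temperature K (default 298, giving RT = 2.478 kJ/mol).
#' @return List of [umbrella_window()] objects, one per center; the mean
#'   Metropolis acceptance rate is attached as attribute `accept_rate`.
#' @export
gen_umbrella_windows <- function(spec, temperature = 298) {
  stopifnot(inherits(spec, "brownian_spec"))
  RT <- rt_kj(temperature)
  gradG <- if (!is.null(spec$grad)) spec$grad else {
    h <- 1e-5
    function(z) (spec$potential(z + h) - spec$potential(z - h)) / (2 * h)
  }
  k <- spec$force_const
  D <- spec$diffusion
  dt <- spec$dt
  nw <- length(spec$centers)
  cen <- spec$centers
  step_var <- 2 * D * dt
  thin <- spec$sample_every
  n_keep <- spec$n_steps %/% thin
  mob <- (D / RT) * dt
  u_tot <- function(z) spec$potential(z) + 0.5 * k * (z - cen)^2
  g_tot <- function(z) gradG(z) + k * (z - cen)
  n_acc <- 0
  traj <- withr::with_seed(spec$seed, {
    z <- cen
    uz <- u_tot(z)
    gz <- g_tot(z)
    out <- matrix(NA_real_, nrow = n_keep, ncol = nw)
    chunk <- 10000L
    done <- 0L
    while (done < spec$n_steps) {
      m <- min(chunk, spec$n_steps - done)
      noise <- matrix(rnorm(m * nw, sd = sqrt(step_var)), nrow = m)
      lu <- matrix(log(runif(m * nw)), nrow = m)
      for (s in seq_len(m)) {
        mu_f <- z - mob * gz
        zp <- mu_f + noise[s, ]
        up <- u_tot(zp)
        gp <- g_tot(zp)
        mu_r <- zp - mob * gp
        log_alpha <- (uz - up) / RT +
          ((zp - mu_f)^2 - (z - mu_r)^2) / (2 * step_var)
        acc <- lu[s, ] < log_alpha
        if (any(acc)) {
          z[acc] <- zp[acc]
          uz[acc] <- up[acc]
          gz[acc] <- gp[acc]
          n_acc <- n_acc + sum(acc)
        }
        tot <- done + s
        if (tot %% thin == 0L) out[tot %/% thin, ] <- z
      }
      done <- done + m
    }
    out
  })
  discard <- floor(spec$discard_frac * n_keep)
  wins <- lapply(seq_len(nw), function(i)
    umbrella_window(cen[i], k, traj[(discard + 1):n_keep, i],
                    dt_ps = dt * thin, t0_ps = discard * dt * thin))
  attr(wins, "accept_rate") <- n_acc / (spec$n_steps * nw)
  wins
}

# --- toy trajectories --------------------------------------------------------

#' Specification of a toy trajectory with known observables
#'
#' Builds multi-frame coordinates whose density, positions, tilt and H-bond
#' statistics are known by construction, for exercising the trajectory
#' observables.
#'
#' @param box numeric length-3 box (Lx, Ly, Lz), nm.
#' @param n_frames number of frames.
#' @param placements data.frame with one row per atom: `name`, `mass` (amu,
#'   > 0), `molecule`, `species`, `rule` (`"fixed"` or `"gaussian"`), `z`
#'   (fixed value or Gaussian mean, nm), `z_sd` (Gaussian SD, >= 0; ignored
#'   for fixed), and optional `x`, `y` (default: box center).
#' @param axis_pairs optional data.frame defining long-axis geometry per
#'   molecule: `molecule`, `tail`, `head` (atom names present in
#'   `placements`), `length` (nm), `theta_deg` (tilt from the outward leaflet
#'   normal; `NA` draws the axis direction uniformly on the sphere each
#'   frame).  The head atom's coordinates are overridden each frame.
#' @param hbond_pairs optional data.frame defining donor-acceptor pairs with
#'   target bonded fraction: `molecule`, `donor`, `hydrogen`, `acceptor`
#'   (atom names in `placements`; the acceptor may live in another molecule),
#'   `occupancy` in [0, 1].  Bonded frames place the acceptor 0.25 nm from
#'   the donor along the donor-hydrogen direction (inside the 0.35 nm / 30
#'   deg criterion); unbonded frames place it at 0.55 nm (>= 1.5 x cutoff).
#'   Frames are chosen by an even deterministic (Bresenham) schedule, so the
#'   measured fraction is `round(occupancy * n_frames) / n_frames` exactly.
#' @param seed integer RNG seed (used only by Gaussian placements and
#'   spherical axis draws).
#' @return A `toy_traj_spec`.
#' @export
toy_traj_spec <- function(box, n_frames, placements, axis_pairs = NULL,
                          hbond_pairs = NULL, seed = 1L) {
  stopifnot(length(box) == 3, all(box > 0), n_frames >= 1,
            is.data.frame(placements),
            all(c("name", "mass", "molecule", "species", "rule", "z") %in%
                  names(placements)))
  if (!"z_sd" %in% names(placements)) placements$z_sd <- 0
  if (!"x" %in% names(placements)) placements$x <- NA_real_
  if (!"y" %in% names(placements)) placements$y <- NA_real_
  if (any(placements$mass <= 0)) stop("masses must be > 0")
  if (any(placements$z_sd < 0)) stop("z_sd must be >= 0")
  if (!is.null(hbond_pairs)) {
    stopifnot(is.data.frame(hbond_pairs),
              all(c("molecule", "donor", "hydrogen", "acceptor",
                    "occupancy") %in% names(hbond_pairs)))
    if (any(hbond_pairs$occupancy < 0 | hbond_pairs$occupancy > 1))
      stop("hbond occupancies must lie in [0, 1]")
  }
  if (!is.null(axis_pairs))
    stopifnot(is.data.frame(axis_pairs),
              all(c("molecule", "tail", "head", "length", "theta_deg") %in%
                    names(axis_pairs)))
  structure(list(box = as.numeric(box), n_frames = as.integer(n_frames),
                 placements = placements, axis_pairs = axis_pairs,
                 hbond_pairs = hbond_pairs, seed = as.integer(seed)),
            class = "toy_traj_spec")
}

# deterministic even schedule of k = round(occ*n) bonded frames among n
.bresenham_frames <- function(occ, n) {
  k <- round(occ * n)
  f <- seq_len(n)
  floor(f * k / n) > floor((f - 1) * k / n)
}

#' Generate a toy trajectory from its specification
#'
#' @param spec a [toy_traj_spec()].
#' @return A [trajectory()].
#' @export
gen_toy_trajectory <- function(spec) {
  stopifnot(inherits(spec, "toy_traj_spec"))
  pl <- spec$placements
  n_atoms <- nrow(pl)
  nf <- spec$n_frames
  coords <- array(NA_real_, dim = c(n_atoms, 3, nf))
  withr::with_seed(spec$seed, {
    for (a in seq_len(n_atoms)) {
      x <- if (is.na(pl$x[a])) spec$box[1] / 2 else pl$x[a]
      y <- if (is.na(pl$y[a])) spec$box[2] / 2 else pl$y[a]
      z <- if (pl$rule[a] == "gaussian" && pl$z_sd[a] > 0)
        rnorm(nf, pl$z[a], pl$z_sd[a]) else rep(pl$z[a], nf)
      coords[a, 1, ] <- x
      coords[a, 2, ] <- y
      coords[a, 3, ] <- z
    }
    # long-axis geometry: head = tail + L * direction(theta, phi)
    if (!is.null(spec$axis_pairs)) {
      for (r in seq_len(nrow(spec$axis_pairs))) {
        ap <- spec$axis_pairs[r, ]
        it <- which(pl$name == ap$tail & pl$molecule == ap$molecule)
        ih <- which(pl$name == ap$head & pl$molecule == ap$molecule)
        if (length(it) != 1 || length(ih) != 1)
          stop("axis atoms must resolve uniquely in molecule ", ap$molecule)
        s <- sign(coords[it, 3, ])
        s[s == 0] <- 1
        if (is.na(ap$theta_deg)) {
          ct <- runif(nf, -1, 1)           # uniform direction on the sphere
          phi <- runif(nf, 0, 2 * pi)
        } else {
          ct <- rep(cos(ap$theta_deg * pi / 180), nf)
          phi <- rep(0, nf)
        }
        st <- sqrt(pmax(0, 1 - ct^2))
        coords[ih, 1, ] <- coords[it, 1, ] + ap$length * st * cos(phi)
        coords[ih, 2, ] <- coords[it, 2, ] + ap$length * st * sin(phi)
        coords[ih, 3, ] <- coords[it, 3, ] + ap$length * ct * s
      }
    }
  })
  # H-bond geometry: deterministic bonded/unbonded placement along +x
  if (!is.null(spec$hbond_pairs)) {
    for (r in seq_len(nrow(spec$hbond_pairs))) {
      hp <- spec$hbond_pairs[r, ]
      id <- which(pl$name == hp$donor & pl$molecule == hp$molecule)
      ih <- which(pl$name == hp$hydrogen & pl$molecule == hp$molecule)
      ia <- which(pl$name == hp$acceptor)
      if (length(id) != 1 || length(ih) != 1 || length(ia) != 1)
        stop("hbond atoms must resolve uniquely (pair row ", r, ")")
      bonded <- .bresenham_frames(hp$occupancy, nf)
      dist <- ifelse(bonded, 0.25, 0.55)
      coords[ih, 1, ] <- coords[id, 1, ] + 0.10
      coords[ih, 2, ] <- coords[id, 2, ]
      coords[ih, 3, ] <- coords[id, 3, ]
      coords[ia, 1, ] <- coords[id, 1, ] + dist
      coords[ia, 2, ] <- coords[id, 2, ]
      coords[ia, 3, ] <- coords[id, 3, ]
    }
  }
  trajectory(coords, matrix(spec$box, nrow = 1),
             data.frame(name = pl$name, mass = pl$mass,
                        molecule = pl$molecule, species = pl$species,
                        stringsAsFactors = FALSE))
}

#' Smoothed square-well free-energy landscape
#'
#' A well of given depth between `z_on` and `z_off` with tanh-smoothed edges
#' (width `edge_width`), suitable for Brownian sampling where a hard step
#' would have an undefined gradient.  The analytic gradient is attached and
#' picked up by [gen_umbrella_windows()].
#'
#' @param depth well depth, kJ/mol (> 0 for an attractive well).
#' @param z_on,z_off inner and outer well edges, nm.
#' @param edge_width tanh edge width, nm (default 0.02; the Boltzmann
#'   integral of the smoothed well differs from the hard-edged one by a
#'   fraction of a percent at this width).
#' @return A function `z -> G(z)` (kJ/mol) with attribute `grad`.
#' @export
square_well_potential <- function(depth, z_on = 1.0, z_off = 1.4,
                                  edge_width = 0.02) {
  stopifnot(z_on < z_off, edge_width > 0)
  f <- function(z)
    -depth / 2 * (tanh((z - z_on) / edge_width) -
                    tanh((z - z_off) / edge_width))
  attr(f, "grad") <- function(z)
    -depth / (2 * edge_width) *
      (1 / cosh((z - z_on) / edge_width)^2 -
         1 / cosh((z - z_off) / edge_width)^2)
  f
}
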