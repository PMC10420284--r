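---
title: "Membrane partition analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane partition analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memparti)
```

# The problem

Amphiphilic solutes — drugs, dyes, probes such as the DNA stain Hoechst
33342 — distribute between the aqueous phase and lipid bilayers.  The
partition coefficient

$$K_P = \frac{[\mathrm{solute}]_{membrane}}{[\mathrm{solute}]_{water}}$$

with the membrane pseudo-phase volume taken as $\bar{V}\,[\mathrm{lipid}]$
($\bar{V}$ = lipid molar volume, 0.8 L/mol for POPC) controls membrane
uptake, and hence permeation and access to membrane proteins.  For
ionizable solutes $K_P$ depends on pH through the protonation state, and —
unlike octanol/water partition — charged forms can remain strongly
membrane-associated because bilayer headgroup regions offer electrostatic
and hydrogen-bonding partners.  `memparti` implements the three
complementary routes by which this is quantified (fluorescence titration,
titration calorimetry, free-energy profiles from biased simulations), the
trajectory observables used to rationalize the results, and a
synthetic-data module that generates each input class with known ground
truth, so every estimator in the package is validated by parameter
recovery.

# Fluorescence titrations

Titrating a dilute solute solution with lipid vesicles changes the
fluorescence signal as the bound fraction grows.  With
$x = K_P \bar{V} L$ (all lipid assumed accessible; an accessibility
factor $\gamma \in (0,1]$ is exposed and defaults to 1), the intensity
follows

$$I(L) = \frac{I_W + I_M\,x}{1 + x},$$

a three-parameter hyperbola in the lipid concentration $L$.  The
anisotropy is the *intensity-weighted* mean of the free and bound
environments, so the bound term carries the ratio $\alpha_M$ of bound to
free emission intensity in the detected wavelength band:

$$r(L) = \frac{r_W + \alpha_M\, r_M\, x}{1 + \alpha_M\, x}.$$

$\alpha_M$ and $K_P$ enter this expression only through their product, so
a mis-specified $\alpha_M$ silently rescales the fitted $K_P$ band by
band; conversely, correct per-band weights make the fitted $K_P$
independent of the detection wavelength, which is the practical
consistency check (`joint_band_fit()` makes it explicit by sharing one
$K_P$ across bands).  `estimate_alpha_m()` computes $\alpha_M$ as the
ratio of band-integrated emission spectra of the bound and free solute
(trapezoidal rule, band edges interpolated); a user-supplied value is
accepted everywhere.

Fitting choices (`fit_intensity()`, `fit_anisotropy()`):

* Levenberg–Marquardt least squares on $(\log_{10} K_P,\,\text{endpoints})$;
  the log parameterization keeps $K_P$ positive and makes the replicate
  distribution approximately normal.
* Three starts spanning three decades of $K_P$ around a half-saturation
  heuristic guard against local minima.
* Uniform point weights (the variance structure of a real instrument is
  band- and signal-dependent; with no variance model, uniform weights are
  the neutral choice).
* Standard errors from a central-difference Jacobian at the optimum.
* Identifiability: a flat series, coincident endpoints, or a
  $\log_{10} K_P$ standard error above 2 decades sets an
  `unidentifiable` flag instead of returning a spurious estimate.

Replicate $K_P$ values are aggregated in log space
(`summarize_log_kp()`): the mean and SD are taken over $\log_{10} K_P$
and the reported average is $10^{\mu_{\log}}$, the geometric mean, since
$K_P$ estimates are log-normally distributed.

# Isothermal titration calorimetry

In an uptake titration, lipid vesicles are injected into the solute
solution and each injection releases the heat of the solute transferred
into the newly added membrane.  `model_heats()` implements the
perfusion-cell recursion: after injection $i$, with displacement factor
$d_i = (1-v/V_0)^i$,

$$L_i = L_{syr}(1-d_i), \quad D_i = D_0 d_i, \quad
  f_i = \frac{K_P \bar{V} L_i}{1 + K_P \bar{V} L_i}, \quad
  n_i = V_0 D_i f_i,$$

$$q_i = \Delta H^\circ\,(n_i - n_{i-1}(1 - v/V_0)) + q_{dil}.$$

Both the solute and the previously injected lipid are flushed by the
overflow (the standard perfusion-cell convention).  The defaults mirror a
VP-ITC-style experiment: 1.4195 mL cell, 25 × 10 µL injections, 10 mM
lipid syringe, 5 µM solute.  `fit_itc()` runs the same multistart
Levenberg–Marquardt machinery over $(\log_{10} K_P, \Delta H^\circ)$ and,
by default, a constant per-injection dilution heat; `--drop-first`-style
exclusion of the first injection is available (`drop_first = TRUE`).
Thermodynamic bookkeeping is completed by
$\Delta G^\circ = -RT \ln K_P$ and
$T\Delta S^\circ = \Delta H^\circ - \Delta G^\circ$ (`thermo_record()`).
In the saturation limit the summed heats converge on
$\Delta H^\circ V_0 D_0$ up to displacement losses, a conservation
property the tests assert.

# Free-energy profiles and WHAM

Umbrella-sampling windows restrain the solute at depths $z_j$ along the
bilayer normal with harmonic biases $w_j(z) = \tfrac{k}{2}(z-z_j)^2$.
`wham()` solves the weighted-histogram equations

$$P(z) = \frac{\sum_j n_j(z)}{\sum_j N_j f_j e^{-w_j(z)/RT}},
  \qquad f_j^{-1} = \sum_z P(z)\, e^{-w_j(z)/RT}$$

by direct self-consistent iteration until
$\max_j |\Delta \ln f_j| < 10^{-7}$ (configurable; the iteration cap is an
error, not a silent truncation), on 0.02 nm bins over $[0, 4]$ nm by
default.  Unpopulated bins are masked rather than interpolated, and a
minimum-overlap diagnostic names the first adjacent window pair that
shares no populated bins.  The profile is anchored by setting the mean
over the outermost 0.5 nm — the bulk-water plateau — to zero; profiles
are one-sided (no symmetrization).  The test suite checks the solver
against a brute-force maximization of the pooled histogram likelihood on
a small instance (agreement to $10^{-6}$ kJ/mol per bin) and against
analytic biased-Gaussian window samplers for flat and quadratic
landscapes.

Uncertainty (`bootstrap_pmf()`) uses a moving-block bootstrap *within*
each window, which preserves the window layout; resampling whole windows
with replacement is available (`resample_windows = TRUE`) but is off by
default because windows whose Gaussian widths
($\sqrt{RT/k} \approx 0.03$ nm at $k = 3000$ kJ mol$^{-1}$ nm$^{-2}$)
overlap only in their tails leave unsampled gaps when one is dropped.
Replicate profiles are re-anchored before the per-bin SD is taken.
Convergence is examined by recomputing the profile on successive time
blocks of every window (`convergence_series()`).

The profile converts to a *relative* partition coefficient by Boltzmann
integration,

$$K_{P,rel} = \frac{1}{a} \int_0^a e^{-\Delta G(z)/RT}\, dz,
  \qquad a = 4.0\ \text{nm},$$

via the trapezoidal rule on bin centers with half-bin end extensions, so
a flat profile gives exactly 1 and step-wise profiles whose edges fall on
bin edges integrate exactly.  The $1/a$ prefactor is a convention: the
absolute scale depends on the choice of $a$ and of the anchoring, so only
differences between solutes (`delta_log_kp()`, exactly invariant to any
common shift) are physically meaningful.  `summarize_pmf()` reads off the
minimum, the maximum on the bilayer-center side of it and the crossing
barrier; a profile whose maximum sits at the center itself (no interior
maximum) is flagged and the barrier taken to $z = 0$.

# The synthetic-data module

The generators produce exactly the input classes the fitters consume,
with stated ground truth:

* **Titrations** — forward curves of the two isotherms on a 12-point
  geometric lipid grid, $10^{-5}$–$2\times10^{-3}$ M plus a zero-lipid
  anchor (instrument series rarely publish their grids; this spans
  one-tenth of half-saturation to well past saturation for
  $K_P \sim 10^3$).  Noise is *multiplicative* Gaussian
  (`signal * (1 + eps)`), because optical intensities span orders of
  magnitude across bands and instrument noise scales with signal.  The
  default truth is a pH 6-like condition: $K_P = 1.8\times10^3$,
  $\alpha_M = 13/8/5$ for 450–470/470–490/490–510 nm, endpoints
  $I_M/I_W = 13$ (consistent with the bluest band's $\alpha_M$) and
  $r_W = 0.05 \rightarrow r_M = 0.25$, typical of a small dye
  immobilized by binding.
* **ITC heats** — the `model_heats()` recursion plus *additive* Gaussian
  noise (calorimeter noise does not scale with the heat).
* **Umbrella windows** — one-dimensional biased Brownian dynamics on a
  user potential, standing in for the restrained MD: 41 windows spaced
  0.1 nm on $[0, 4]$ nm with $k = 3000$ kJ mol$^{-1}$ nm$^{-2}$, first
  third discarded as equilibration.
* **Toy trajectories** — atoms placed by fixed or Gaussian rules,
  two-atom long axes with prescribed (or uniformly spherical) tilt, and
  donor–H–acceptor triplets switched between a bonded (0.25 nm, collinear)
  and an unbonded (0.55 nm $\geq 1.5 \times$ cutoff) geometry on an even
  deterministic schedule, so a requested occupancy is *measured* exactly
  as `round(occupancy * n_frames) / n_frames`.

Every generator takes an explicit integer seed and restores the caller's
RNG state (`withr::with_seed`), so runs are reproducible and
order-independent.

## The Brownian sampler is Metropolis-adjusted

The window sampler propagates all windows in parallel with the
Euler–Maruyama proposal
$z' = z - \frac{D}{RT} \partial_z G_{tot}\, dt + \sqrt{2Ddt}\,\xi$
*accepted or rejected by a Metropolis–Hastings step* (MALA).  Plain
Euler–Maruyama inflates the stationary variance by
$\mathcal{O}(Dk\,dt/RT)$ — about 5% per unit of $\theta\,dt$ — which is
invisible for smooth landscapes but measurably distorts steep features:
in development runs a smoothed square well came out several tenths of a
kJ/mol too deep because the well edges have local curvatures far above
the restraint constant.  The Metropolis correction makes the sampled
distribution exact at any step size, at the cost of one extra potential
evaluation per step; acceptance rates at the defaults
($D = 0.02$ nm²/ps, $dt = 0.002$ ps) exceed 99%.

Two facts drive the problem sizes used in the tests.  First, the window
relaxation time is $\tau = RT/(Dk) \approx 21$ steps, so the number of
*effective* samples is $\sim n_{steps}/2\tau$.  Second, adjacent windows
at 0.1 nm spacing with $\sqrt{RT/k} \approx 0.029$ nm widths overlap only
in their tails, so the WHAM window-matching information is a small
fraction of the effective samples and statistical error accumulates as a
random walk along the 41-window chain.  The square-well recovery check
therefore uses $10^7$ steps per window (thinned 50×), giving a
well-to-bulk uncertainty of a few tenths of a kJ/mol and a relative-$K_P$
scatter under 2%; the unit tests of WHAM itself use the analytic
biased-Gaussian sampler instead, which is both faster and an independent
oracle.

## The calibrated smoothed well

A hard-edged square well has no usable gradient, so the recovery fixture
uses `square_well_potential()`: tanh edges of width 0.01 nm.  Smoothing
removes a sliver of Boltzmann weight, so the fixture widens the well by
the offset (≈ 0.0054 nm per edge, solved at run time) that makes the
smoothed well's integral $\frac{1}{a}\int e^{-G/RT}dz$ equal the ideal
hard-edged value of 1.9 for a depth of $RT \ln 10$ over 0.4 nm.  The
recovered profile is thus compared against the analytic value of the well
the sampler actually embodies.

# Trajectory observables

All coordinate analyses take nm-scale coordinates with the bilayer normal
along z and use the molecule, not the frame, as the independent unit
where confidence intervals are reported:

* `mass_density_profile()` — per-slab $\sum m / (L_x L_y \Delta z)$
  averaged over frames, in kg/m³; the z-integral times the box
  cross-section returns the species mass, independent of bin width.
* `group_positions()` — time-average of $|z|$ per molecule first, then
  mean and t-based 95% CI across molecules; $|z|$ pools the two leaflets.
* `tilt_distribution()` — angle between the (head − tail) axis and the
  *outward* normal of the molecule's leaflet (sign of the molecule COM z,
  re-evaluated per frame), so $\theta < 90°$ always means head-toward-
  water in either leaflet.
* `hbond_frequencies()` — geometric criterion: donor–acceptor distance
  ≤ 0.35 nm *and* H–donor–acceptor angle ≤ 30°, the common MD-analysis
  default; both cutoffs are arguments so sensitivity can be reported.
  Frequencies are donor × acceptor-class means per frame per molecule;
  `per_donor_frequency()` and `acceptor_class_fractions()` derive the
  per-donor rate and class percentages.  Molecules to analyze are an
  explicit argument, so aggregated or otherwise compromised molecules are
  excluded by listing, never by silent detection.

Periodic boundaries are applied as minimum-image in x/y only; z is
treated as unwrapped, which presumes a bilayer-centered box — the
convention of the upstream simulation, not something the analysis can
recover.

# I/O and workflows

Plain-text dialects only: titration and ITC CSVs (with µcal and
kcal-per-mole-of-injectant unit conversion on read), two-column
pull-style window files plus a metadata CSV, three-column PMF text, and
multi-frame GRO or XYZ-with-box coordinates (GRO carries no masses; they
are supplied by name on read).  Every writer round-trips through its
reader, and `run_workflow()` chains simulate → fit → report from a single
JSON/list configuration, echoing the full defaults table
(`memparti_defaults()`) and all seeds into `report.json` for provenance.

# What the synthetic validation does and does not show

Parameter recovery on generated data proves the estimators invert their
own forward models at realistic noise — it cannot certify the forward
models against a real instrument (inner-filter effects, scatter,
incomplete inter-leaflet equilibration, baseline drifts are all outside
the generators), and the 1-D Brownian stand-in exercises WHAM but not the
sampling pathologies of real membrane MD (slow orientational
relaxation, hidden orthogonal degrees of freedom).  Statistics that
genuinely require large-scale simulation — tens of kJ/mol center
barriers, tilt distributions, H-bond frequencies of a real solute — are
covered here by *recovery fixtures*: trajectories constructed to possess
a statistic exactly, which the observables must then reproduce exactly.

# Known limitations

* Single-site simple-partition models only: no multi-site binding, no
  spectral deconvolution, no raw power-trace integration.
* WHAM only (no MBAR), 1-D profiles, no permeability calculation.
* The PMF-derived $K_P$ is relative by construction; absolute values
  require a defensible standard state for both phases.
* The H-bond criterion is geometric; energetic definitions will differ
  near the cutoffs.
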