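---
title: "Reaction-coordinate biomarkers from longitudinal metabolomic trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-coordinate biomarkers from longitudinal metabolomic trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfep)
library(dplyr)
```

## The model

`cfep` treats the clinical evolution of a patient — here, recovery after
kidney transplantation monitored through daily ¹H NMR spectra of blood
erythrocyte extracts — as a realization of a Markov (memoryless)
stochastic process in a very high-dimensional state space. The goal is a
single scalar *reaction coordinate* `R(X)` summarizing that state, such
that the dynamics projected on `R` is simple diffusion on a
one-dimensional free-energy profile and the probability of each clinical
outcome can be read off the coordinate value alone. A coordinate with
this property is an *optimal* biomarker: it carries all the predictive
information of the full process that matters for the outcome.

The coordinate is a linear combination of basis functions,
`R(X) = sum_k alpha_k f_k(X) + alpha_0`, where `f_k` are the
log-transformed, total-intensity-normalized mean intensities of
fixed-width chemical-shift bins. The package's criterion of optimality
is variational: among all coordinates, the optimal one has the *highest*
cut-based free-energy profile (equivalently, the smallest cut partition
function). For Gaussian step distributions — i.e. diffusive dynamics —
this criterion has two closed-form solutions, and those closed forms are
what `fit_coordinate()` implements:

* **Supervised.** Minimize the summed squared projection increments
  `sum_(n,i) (R(x_{n,i+1}) - R(x_{n,i}))^2`, with each trajectory
  constrained to continue to its terminal value `b_n` (0 or 1, the
  clinical outcome class) on the step after the data end. The minimizer
  approximates the committor: the probability of reaching the `b = 1`
  outcome before the `b = 0` outcome from the current state. The
  quadratic is solved as a single linear least-squares system with a
  minimum-norm SVD pseudo-solution (relative singular-value cutoff
  `1e-10`), so collinear bases (e.g. indicator features summing to one)
  are handled deterministically.
* **Unsupervised.** Minimize the same increments under a unit-variance
  constraint on the projection. This is a generalized eigenvalue problem
  `A v = lambda B v` with `A` the step-increment second-moment matrix and
  `B` the pooled covariance; the smallest nontrivial eigenvalue is the
  slowest relaxation mode of the sampled dynamics, which approximates
  the committor in the transition (barrier) region when one barrier
  dominates. Mode 2 is the default; mode 3 addresses the second-slowest
  process.

A PCA projection is included purely as the baseline it is: it maximizes
static variance and ignores the temporal ordering, so a slow,
low-variance direction — exactly what a recovery coordinate tends to
be — is invisible to it.

## Cut-based free-energy profiles

For a scalar time series ensemble, `cut_profile()` evaluates at each
grid point `y`:

* `Z_C(y)`: half the number of trajectory steps crossing `y`,
* `Z_C1(y) = Z_plus + Z_minus`: half the summed step lengths `|dx|` over
  crossing steps, split by direction,
* `Z_H(y)`: the occupancy density (histogram),

and the corresponding profiles `F = -ln Z` in units of kT (kT = 1).
The crossing indicator uses a half-open rule — a step `x_i -> x_{i+1}`
crosses upward iff `x_i < y <= x_{i+1}` — so crossing counts are pure
order statistics: `Z_C` is *exactly* invariant under any strictly
increasing re-parameterization of the coordinate, which is the property
that makes profile height a meaningful criterion at all. Two useful
identities follow directly and are enforced by tests: per trajectory,
`n_up - n_down = 1[x_last >= y] - 1[x_first >= y]`, and
`Z_C1 = Z_plus + Z_minus` everywhere.

In the diffusive small-interval limit, `Z_C1` per step equals
`Z_H(y) D(y) dt`, giving the coordinate-dependent diffusion coefficient
estimator `D(y) = Z_C1 / (n_steps Z_H dt)` (`estimate_diffusion()`).
`msd_diagnostic()` provides the standard memory check: sub-linear mean
squared displacement growth flags a sub-optimal coordinate.

## Equilibrium landscape from non-equilibrium cohorts

Patient trajectories are not equilibrium samples: everyone starts near
the barrier (surgery) and drains into an outcome basin. The observed
occupancy is therefore a steady-state distribution, and
`-ln Z_H` would be a distorted free energy. Assuming diffusive dynamics,
the one-dimensional continuity relation
`J(y) = -D e^{-F} d/dy (P_ss e^{F})` can be inverted by quadrature:
`reconstruct_landscape()` measures the net flux `J` from directional
crossing counts, integrates `G(y) = P_ss e^F` along the grid, and
anchors `min F_eq = 0`. When `J = 0` this reduces *exactly* to
`F_eq = -ln P_ss + const`. The same relation holds for time-averaged
transient ensembles (integrating the Fokker–Planck equation over the
observation window term by term), which is why the validation suite can
recover the generating double-well profile both from equilibrium runs
and from source/sink and first-passage ensembles, while the naive
histogram profile of the same steady-state data is visibly wrong.

`rescale_unit_diffusion()` applies `ytilde = int dy / sqrt(D(y))`, after
which the re-estimated diffusion coefficient is unity and the free
energy carries over pointwise. On the unit-diffusion coordinate the
outcome probability is the classical splitting probability
`q(x) = int_x^right e^F dy / int_left^right e^F dy`
(`committor_from_profile()`, trapezoidal quadrature on a 201-point grid
by default). The trajectory-based counterpart
(`empirical_outcome_probability()`) counts, per coordinate bin, the
trajectories that visited the bin and ended on either side of the
barrier, and applies the add-two-successes-and-two-failures
(Agresti–Coull) estimate with a multiplier of exactly 2 for the 95%
band.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `bin_width` | 0.32 ppm | ~30 basis functions over a 0–9.6 ppm window; small enough to resolve metabolite regions, large enough that ~150 cohort samples identify ~30 weights. 0.1 ppm is accepted and demonstrably over-fits at cohort scale. |
| `floor_epsilon` | 1e-12 | intensity floor (on the unit-total scale) before the log; keeps near-empty baseline bins finite instead of erroring. |
| `ev` | 2 | eigenvector reported by the unsupervised fit; 3 probes the second-slowest process. |
| `boundary_weight` | 1 | weight of the virtual terminal step. 1 matches truncated (patient-style) trajectories; 2 restores equilibrium link counting for ensembles terminated on arrival in an end state, under which the minimizer is the chain committor (see below). |
| `threshold` (`loocv`) | 0.8 | median held-out/full-fit &#124;correlation&#124; at or above which a fit is called stable. |
| `n_grid` (`cut_profile`) | 101 | profile evaluation grid; the pipeline uses 25 for ~150-point cohorts so occupancy cells stay populated. |
| `n_grid` (`committor_from_profile`) | 201 | quadrature grid for the splitting probability. |

Orientation of the coordinate is conventionally fixed so that the
recovering (PF-like, `b = 0`) class projects to negative values when
labels are available, otherwise so the largest-magnitude weight is
positive; eigenvectors and committor-scale choices are otherwise
arbitrary up to affine maps, and all comparisons in the package
(LOOCV, supervised-vs-unsupervised) are affine-invariant correlations.

## Numerical choices

* **Generalized eigenproblem.** `B` is eigendecomposed and the problem
  whitened on the span of `B` above a relative cutoff of `1e-10`. Null
  directions — the constant function under an indicator or
  sum-constrained basis, unsampled subspaces — drop out of the problem
  entirely. A diagonal ridge was considered and rejected: it resurrects
  exact null directions as spurious near-zero eigenvalues, which would
  then be selected as the "slowest mode". A genuine deficiency beyond
  the expected constant direction is reported with a warning.
* **Boundary term and link counting.** The supervised boundary
  condition is one virtual step from each trajectory's last point to its
  label. For ensembles terminated *on arrival* in an end state, every
  interior link of the dynamics is sampled in both directions while each
  boundary link is sampled only inward; the virtual step then stands in
  for exactly half of the equilibrium boundary-link weight, so
  `boundary_weight = 2` makes the quadratic stationarity conditions
  coincide with the committor equations. Patient-style cohorts are
  truncated, not absorbed, and keep the default weight 1.
* **Crossing ties.** A sample exactly at `y` belongs to the upper side
  (half-open rule), mirroring the half-open bin convention; both are
  deterministic and preserve exact invariance under monotone maps.
* **Degenerate inputs.** All-zero spectra, empty bins, non-overlapping
  ppm windows, single-label cohorts, constant ensembles and
  non-increasing maps raise typed errors; non-finite steps are skipped
  with a message; patients with one time point are dropped with a
  warning.
* **Basin detection.** The two local minima of `F_eq` with the most
  prominent barrier between them define the basins; prominence (barrier
  minus the higher of the two minima) is robust to small-sample noise
  wiggles inside one basin.

## The synthetic cohort generator

`generate_cohort()` provides ground-truth data in the same CSV layout
the preprocessing reads, so synthetic and real cohorts are
interchangeable. The latent disease coordinate diffuses on a quartic
double well `F(x) = h (x^2 - 1)^2` with barrier `h = 3` kT, wells at
±1 and `D = 0.5` per day — relaxation from the barrier top into a well
then takes one to two days, matching the observation that outcome
classes become distinguishable about two days after surgery, while
spontaneous basin switching within a nine-day window stays rare.
Integration uses Euler–Maruyama at `dt = 0.01` day with daily
subsampling (the blood-draw schedule). Each patient starts near the
barrier top (`x0 ~ N(0, 0.1)`), runs for up to nine days (day −1 to 7),
and is labeled by the basin reached on the last *observed* day
(rejection sampling per class quota); about a third of patients have
shortened series. The class quotas are 9:9 for the two-class preset and
9:5:4 (PF:DGF:AR) for the three-class preset, a realistic class balance
for a transplant cohort of this size ("paper scale" refers to these
18-patient, nine-day dimensions). AR patients evolve in a shallow harmonic trap at
the barrier top — a stand-in for dynamics unresolved within the
observation window, explicitly not a biological model.

The spectral embedding writes channel `k` as
`baseline_k exp(loading_k x + noise)`, with log-scale channel noise of
sd 0.1: strictly positive intensities, exactly log-linear in the latent
coordinate at zero noise (so preprocessing plus a linear coordinate can
recover `x` perfectly, a property the tests assert), and a smooth
loading pattern dominated by one channel near 4 ppm with weaker
structure elsewhere. The `pca_blind` preset adds a memoryless nuisance
latent on a direction orthogonalized against the loading; it dominates
the static covariance (defeating PCA) while carrying no slow dynamics
(leaving the eigenvector coordinate unaffected). `overfit_probe` tiles
the same smooth loading over ~100 channels, the fine-binning analogue.

What the generator does *not* emulate: NMR lineshapes, multiplets,
peak shifts, baseline drift, metabolite correlations, inter-patient
baseline heterogeneity, or any real AR biology. Passing tests therefore
demonstrate that the estimators recover the assumed diffusive
generative model at cohort scale — not that real spectra satisfy that
model.

## Validation problem sizes

The validation suite and `scripts/acceptance.R` use deliberately
desk-scale problems: 5-state and 4-state chains with ~10^5 pooled steps
against exact linear-solve and eigendecomposition oracles; 10^6-step
equilibrium and ~10^6-step source/sink double-well simulations for
profile recovery (RMS agreement well under 0.3 kT where the true
profile is below 4 kT); 200 first-passage trajectories for the
committor-versus-empirical band comparison; and 18-patient, ≤9-day
cohorts for the classification, cross-validation and over-fitting
demonstrations. These sizes give sampling error comfortably inside the
assertion tolerances while keeping the whole suite under a minute of
computation.

## Known limitations

* Two terminal states only; no multi-basin committor systems and no
  kinetic (mean first-passage time) estimation.
* The linear basis is the only one shipped; the abstraction would admit
  nonlinear features but none are provided.
* The diffusion estimator assumes the sampling interval is within the
  diffusive regime of the coordinate; daily sampling of a process with
  sub-daily structure will fold that structure into the estimate.
* Leave-one-out correlation is a coarse over-fitting probe: with very
  short held-out series (under three points) a fold is uninformative
  and reported as `NA`.
* The non-equilibrium correction enters only through the landscape
  reconstruction; the coordinate optimization itself uses the
  equilibrium objective, on the assumption that non-equilibrium
  sampling mainly reweights regions rather than reshaping the optimum.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- list(
  input = list(simulate = "paper_scale_two_class"),
  mode = "unsupervised",
  seed = 4,
  output_dir = "runs/demo")
res <- run_pipeline(cfg)

glance(res$model)        # fit summary
glance(res$loocv)        # stability verdict
glance(res$landscape)    # basins and barrier height
autoplot(res$landscape, committor = res$committor)
plot_trajectories(res$projections)
```

The same stages are available piecewise — `build_trajectories()`,
`fit_coordinate()`, `project_coordinate()`, `cut_profile()`,
`reconstruct_landscape()`, `committor_from_profile()`,
`empirical_outcome_probability()` — and every result is a tibble or
carries `tidy()`/`glance()` methods, so the natural habitat is a dplyr
pipeline.
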