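# cfep

Optimal reaction coordinates and cut-based free-energy profiles for
longitudinal metabolomic trajectories.

## The problem

After an intervention such as a kidney transplant, a patient's condition
evolves as a noisy, high-dimensional stochastic process. Serial blood
samples — here, daily ¹H NMR spectra of erythrocyte extracts from just
before surgery to a week after — trace one realization of that process
per patient, and the clinical question is predictive: from today's
sample, what is the probability that this patient recovers promptly
(primary function) rather than needing dialysis (delayed graft
function)?

`cfep` answers this by treating disease dynamics explicitly as dynamics.
It learns a single scalar **reaction coordinate** — a dynamical
biomarker — from a cohort of short multivariate trajectories, describes
the projected dynamics as diffusion on a one-dimensional free-energy
landscape, and converts the landscape into outcome probabilities. It is
aimed at quantitative biologists and metabolomics analysts working with
short longitudinal cohorts, and at anyone who needs the underlying
machinery (cut-based free-energy profiles, committor estimation,
slowest-mode dimensionality reduction) on scalar time-series ensembles.

## The method

Spectra are normalized to unit total intensity, coarse-grained into
0.32-ppm bins, and log-transformed; the coordinate is a linear
combination of the bin features, `R(X) = Σₖ αₖ fₖ(X) + α₀`. The weights
are chosen variationally so that the **cut-based free-energy profile**
(CFEP) along the coordinate is as high as possible:

- `Z_C(y)` — half the number of trajectory steps crossing `y`;
  `F_C = −ln Z_C` (kT = 1). Crossing counts are order statistics, so the
  profile is exactly invariant under monotone re-parameterizations.
- Supervised optimum: minimize `Σ (ΔR)²` with every trajectory
  constrained to continue to its clinical outcome label (0/1) one step
  after the data end — a committor-like, boundary-constrained least
  squares.
- Unsupervised optimum: minimize `Σ (ΔR)²` at unit projection variance —
  a generalized eigenvalue problem whose smallest nontrivial mode is the
  slowest relaxation mode of the sampled dynamics.

The distance-weighted profile `Z_C1` together with the occupancy `Z_H`
gives the coordinate-dependent diffusion coefficient
`D(y) = Z_C1/(N Z_H Δt)`. Because patient cohorts are not at
equilibrium, the equilibrium profile is reconstructed from the
steady-state relation `J = −D e^{−F} ∂(P_ss e^{F})`, using the net flux
measured from directional crossings; the coordinate is then rescaled to
unit diffusion, and the probability of a successful outcome is the 1-D
splitting probability `q(x) = ∫ₓ e^F / ∫ e^F`, cross-checked against the
trajectory counts with add-two-successes-and-two-failures
(Agresti–Coull) 95% intervals. Leave-one-out cross-validation guards
against over-fitting (0.1-ppm binning reliably fails it at cohort
scale). A synthetic-cohort generator with exact finite-state oracles
(dense committor solves, transition-matrix eigendecompositions)
validates every stage.

## Worked example

```r
library(cfep)

sim <- generate_cohort("paper_scale_two_class", seed = 4)   # 18 patients, ≤9 days
coh <- build_trajectories(sim$spectra, sim$metadata)         # 30 log-bin features

fit <- fit_coordinate(coh, mode = "unsupervised")
fit
#> <cfep_coordinate> mode=unsupervised, 30 features
#>   eigenvalue (mode 2): 0.3154

proj <- project_coordinate(coh, fit)
head(proj, 4)
#> # A tibble: 4 × 4
#>   patient_id   day clinical_class      x
#>   <chr>      <int> <chr>           <dbl>
#> 1 patient_01    -1 PF             -0.164
#> 2 patient_01     0 PF             -1.14
#> 3 patient_01     1 PF             -0.740
#> 4 patient_01     2 PF             -0.525

loocv(coh, mode = "unsupervised")
#> <cfep_loocv> mode=unsupervised, 18 folds, median |cor| = 0.970 -> stable

prof <- proj |> cut_profile(n_grid = 25) |> estimate_diffusion() |> net_flux()
land <- prof |> reconstruct_landscape() |> rescale_unit_diffusion()
land
#> <cfep_landscape> 22 grid points, basins at -0.819 / 0.993, barrier 3.04 kT
#>   (unit-diffusion rescaled)

committor_from_profile(land, x = c(-0.5, 0, 0.5))
#> # A tibble: 3 × 2
#>       x q_model
#>   <dbl>   <dbl>
#> 1  -0.5   0.953
#> 2   0     0.601
#> 3   0.5   0.184
```

Reading: PF patients drift to negative coordinate values, DGF to
positive ones (the projection is oriented that way by convention); the
held-out projections track the full-cohort fit (median |r| = 0.97, no
over-fitting at 30 features); two basins emerge in the reconstructed
landscape separated by a ~3 kT barrier; and a patient sitting at
`x = −0.5` has a 95% model probability of reaching the recovery basin
first.

An end-to-end run with artifacts (model JSON, profile/landscape/outcome
TSVs, a markdown report) is one call:

```r
run_pipeline(list(input = list(simulate = "paper_scale_two_class"),
                  mode = "unsupervised", seed = 4,
                  output_dir = "runs/demo"))
```

or, from a shell, `Rscript inst/cli/cfep-pipeline.R --config run.yaml`.
Real cohorts enter the same way through CSV files (long-format spectra:
`patient_id, day, ppm, intensity`; metadata: `patient_id,
clinical_class`).

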