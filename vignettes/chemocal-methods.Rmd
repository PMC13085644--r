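---
title: "chemocal: models, design choices and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chemocal: models, design choices and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemocal)
```

## The problem

UV spectra of co-formulated drugs overlap heavily, so no single wavelength
quantifies one analyte alone. The package implements the standard
chemometric answer for a three-analyte system (cinnarizine CIN 4--20
ug/mL, domperidone DOM 3--15 ug/mL, and the carcinogenic degradation
product benzophenone BNZ 1--5 ug/mL, measured at 220--300 nm in 1 nm
steps, 81 points): calibrate multivariate models on a designed mixture
set, validate on an independent optimally chosen set, and report the full
validation sheet of figures of merit. Because no measured spectra are
publicly deposited for this system, the package carries a synthetic
Beer--Lambert generator that stands in for the instrument; every
statistical claim made by the test suite is a claim about that stated
synthetic world, not about any laboratory data.

## Calibration design

`generate_brereton_design()` builds the multilevel multifactor cyclic
design: for f factors at L levels it returns L^2 runs whose first run is
the all-midpoint mixture and whose factor columns are successive cyclic
shifts (over runs 2..L^2) of one generator sequence. The 5-level,
24-term generator is a fixed package constant chosen so that the design
has the two properties the construction exists for, verified exactly in
integer arithmetic by the tests: every coded level appears exactly L
times per column, and all coded columns are mutually orthogonal (zero
pairwise dot products), i.e. analyte concentration profiles are
uncorrelated. A 3-level generator was found once by exhaustive search
over the balanced multiset with zero cyclic lag-1 autocorrelation and is
also frozen; other level counts raise an unsupported-design error rather
than silently producing an unbalanced design.

Coded levels map to concentrations by `midpoint + coded * step` with
`step = (c_max - c_min)/(n_levels - 1)`; the map is exactly invertible on
the grid and `concentration_to_code()` refuses off-grid values.

## D-optimal validation selection

`d_optimal_select()` picks the validation mixtures by maximizing
`det(X'X)` of the model matrix over subsets of a candidate grid. Four
choices here were genuinely open and are package conventions:

* **Candidate set.** The full coded factorial grid of the factors (125
  points for 3 factors at 5 levels), from `enumerate_candidates()`.
* **Model order.** Full quadratic by default (intercept, 3 linear, 3
  interaction, 3 quadratic terms; p = 10), consistent with a 13-run
  selection; configurable through `model_spec()`.
* **Scale.** Selection operates on coded (scale-free) levels, so the
  determinant is not dominated by the widest concentration range.
* **Exchange variant.** Best-improvement single-row Fedorov exchange:
  every (selected row, candidate row) swap is scored by the rank-one
  determinant-ratio identity `(1 + d_jj)(1 - d_ii) + d_ij^2`, the best
  swap is applied, and the sweep repeats until no swap improves. Ties
  break toward the lowest candidate index; 20 seeded random starts by
  default; determinants are accumulated in log space and singular
  subsets carry log-det -Inf. Selected rows are unique (no replicate
  runs).

The exchange result is checked two independent ways in the tests:
exhaustive enumeration of all subsets on every grid with at most 12
candidates, and dominance over 1000 seeded random 13-subsets on the
125-point grid. The 13-mixture validation set printed for the real
system ships as `validation_design_13()`, as a fixture only: its original
candidate set and model are unknown, so the algorithm is required to
match or beat its log-determinant, not reproduce its rows.

## The synthetic spectra generator

`simulate_mixtures()` produces `D = C S + baseline + E` with
`E ~ N(0, sd^2)` i.i.d. and seeded. Pure spectra are sums of Gaussian
bands (`default_component_library()`); the functional form is a package
choice -- only qualitative features of the real spectra are published.
The defaults emulate exactly those features: a CIN-like dual peak in
240--260 nm, a DOM-like maximum near 285 nm with a secondary 225--235 nm
feature, a BNZ-like single band near 250 nm, and a weak broad background
band under each component so that the three spectra overlap strongly
without being collinear (pairwise cosine similarity between 0.3 and
0.98). Amplitudes are in AU mL/ug and sized so the designed mixtures
reach roughly 1 AU, a realistic UV working regime.

The default noise level is `sd = 0.003` AU, homoscedastic, chosen once as
a typical double-beam UV noise floor; it produces low-percent relative
prediction errors of the same order as real validation sheets without
claiming to reproduce any printed value. What the generator does *not*
model -- detector saturation, stray light, wavelength-calibration error,
heteroscedastic shot noise, solvent blanks -- bounds what a green test
establishes: correctness of the algorithms under bilinear data with
additive Gaussian noise, no more.

`perturb_instrument()` supplies the three robustness perturbations as
operators on spectra: re-interpolation through a 1.1 nm grid, Gaussian
slit-function convolution (kernel renormalized at the edges so total
absorbance is conserved to 0.1 %), and seeded additive scan-speed noise.

## Calibration engines

**CLS.** Per-wavelength regression of absorbance on the known
concentrations (`A ~ [1 | C]`), giving the K matrix and, optionally, an
intercept spectrum; prediction projects an unknown spectrum onto the K
rows by least squares. The intercept enters symmetrically in calibration
and prediction. The "moving window" preprocessing is implemented as
moving-average smoothing whose width (5--30 nm, odd multiples of the
grid step) is selected by cross-validation; the alternative reading --
wavelength sub-setting -- was considered and not adopted, since the
width-selection criterion is explicitly a smoothing level. Noiseless
data tie all widths at zero error and the tie rule returns the smallest
width; ties are declared within `max(1e-8, 1e-6 * min)` so the noiseless
case behaves as a tie despite rounding.

**PLS.** Mean-centered NIPALS PLS2 (no autoscaling -- absorbances share
units), deterministic because the start vector is the largest-variance
response column. The regression matrix `b = W (P'W)^{-1} Q'` reproduces
training predictions and powers the net-analyte-signal detection limits.
`rmsecv_curve()` pools cross-validation errors over analytes and folds;
venetian blinds (sample i to fold i mod k, k = 5 by default) and
leave-one-out are both available. LV selection defaults to the global
minimum with ties resolved toward fewer LVs, where "tie" means within
one standard error of the minimum (fold-to-fold scatter attached to the
curve); without that convention the flat tail of the curve beyond the
true rank is a coin flip among 3..10 LVs under i.i.d. noise. The
parsimonious F-rule (smallest k whose PRESS ratio to the minimum is
below the F quantile, alpha = 0.25) is provided as the alternative.

**MCR-ALS.** Alternating constrained least squares on `D = C S + E`.
Constraints: non-negativity on either mode (active-set NNLS per row /
column), closure (row renormalization of C after its update; off by
default because designed calibration mixtures are not mass-closed),
unimodality on spectra (pool-adjacent-violators monotone regression on
each side of the mode), and selectivity (zeroing foreign components in
stated windows, or pinning a component to a reference spectrum).
Spectral profiles are renormalized to unit Euclidean norm each iteration
so the scale ambiguity lands in C. Convergence: relative change of the
residual standard deviation below 0.20 % (default), at most 50
iterations; non-convergence is a flag on the returned model, not an
exception.

Initialization is worth a note. Evolving factor analysis (`efa()`) is
implemented with the normalized log10-eigenvalue threshold (-4) and
envelope-based initial concentration windows, and it correctly ranks the
data. But designed calibration mixtures have *no evolving structure* --
every component is present in every sample -- so the EFA windows are
degenerate by construction and the envelope columns nearly collinear.
`fit_mcr_als(init = "efa")` therefore falls back to seeded random
spectra when it detects that degeneracy. The quantification pipeline
instead initializes from reference (pure-component) spectra, mirroring
the bench situation where pure standards are measured independently and
used as selectivity/correlation information; on bilinear data this also
removes the rotational indeterminacy that random starts would leave.

Quantification (`mcr_quantify()`) fits the row-wise augmented matrix
[calibration; test], matches resolved components to analytes by maximal
total cosine similarity against the reference spectra (exhaustive over
assignments; a tied optimum with different assignments is an error), and
calibrates each analyte by univariate regression of its resolved
concentration column on the known values -- any admissible rescaling of
the resolved profiles is absorbed by that regression, which the tests
verify by permuting and rescaling the initialization.

## Figures of merit

All validation-sheet metrics are implemented from their defining sums:
RMSE with the n denominator; bias as the mean signed error; SEC as the
bias-corrected calibration error with n-1; RRMSEP as
`100 sqrt(sum(e^2)/sum(E^2))`. The BCRMSEP denominator is not published
anywhere we could rely on; the package adopts the n denominator on the
validation set, which makes `bias^2 + BCRMSEP^2 = RMSEP^2` an exact
algebraic identity (asserted on every random instance in the tests) --
that Pythagorean structure is the reason this convention was chosen.
Detection limits use the net-analyte-signal form `LOD = 3.3 sd ||b||`,
`LOQ = 10 sd ||b||`, so LOQ/LOD = 10/3.3, consistent with the published
LOD/LOQ ratios for this system; the noise level defaults to the
simulator's sd and is configurable. The bias t-test is
`t = |100 - mean(R)| sqrt(n) / sd(R)` against two-tailed Student
quantiles. One-way ANOVA is the textbook between/within decomposition,
cross-checked against `stats::anova` and the two-group `F = t^2`
identity.

## Diagnostics

**EJCR.** The joint (slope, intercept) region
`(beta - betahat)' X'X (beta - betahat) <= 2 s^2 F(2, n-2, 1-alpha)` from
the OLS fit of predicted on true values; the method is declared unbiased
when (0, 1) lies inside. Area is `pi * 2 s^2 F / sqrt(det(X'X))`. The
Monte-Carlo coverage of the region under Gaussian errors is asserted at
95 % within 1 % over 10^4 replicates.

**Rotational ambiguity.** For each component the signal-contribution
function `f_c(T) = ||C t_c|| ||t_c^- S|| / ||C S||_F` is extremized over
invertible transforms T with unit diagonal (the diagonal scale is
immaterial because f is invariant to row scaling of T), subject to the
active constraints. AFS% is `100 (f_max - f_min)`. For two components
the two off-diagonal entries are searched on a dense grid with two local
refinement passes -- this is also the independent oracle the optimizer
(penalized Nelder--Mead, 20 seeded starts) is tested against at 1e-3.
The per-wavelength feasible band width (max and mean, in AU of the
mean-sample contribution) gives Max/Avg RFS and the critical wavelength;
the selectivity index is defined here as `1 - (f_max - f_min)/f_max`, a
package convention, not a reproduction of any published definition.
Constraint monotonicity -- nested constraint sets give nested bands --
is asserted on toy systems, since the grid evaluates the same transform
set under both feasibility filters.

**Local rank.** Sliding-window SVD with the same normalized
log10-eigenvalue threshold as EFA. Note that with an 11-point window the
effective local rank of fully mixed regions can drop below the global
rank: within a narrow window two of the three component shapes become
nearly collinear. The tests assert the pattern (rank 3 reached, rank >= 2
in the overlap region, rank 1 on a single-component shoulder) rather
than a constant.

## Numerical choices, degenerate inputs, limitations

* Determinants only in log space; singular information matrices are
  -Inf, never an exception during search.
* NNLS is the Lawson--Hanson active-set algorithm; constraint residuals
  of returned MCR models are at most 1e-10.
* Seeds: every stochastic element (exchange starts, noise, random init,
  multi-start optimizer) takes an explicit integer seed; sub-seeds
  derive from a master seed through a Lehmer step modulo 2^31 - 1.
* Degenerate inputs produce typed errors naming the offence (collinear
  concentration columns, off-grid coded levels, zero-variance spectra,
  all-zero truth vectors) except where the contract says flag-not-throw
  (non-convergence, undefined correlations, infeasible band optimization,
  infinite t).
* The run configuration is JSON (jsonlite), not YAML: no YAML parser is
  available in the supported dependency set, and the configuration is a
  flat key-value structure that JSON serves equally well.
* Known limitations: no wavelength-subset selection for CLS, no
  nonlinear/kernel PLS, no trilinear models, no full AFS polygon (band
  extrema only), no saturation or stray-light physics in the simulator,
  and printed validation-sheet values of the real system are expressly
  not reproduction targets because the measured spectra they derive from
  are unpublished.
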