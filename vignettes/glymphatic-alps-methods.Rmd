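---
title: "Methods: DTI-ALPS glymphatic analysis on synthetic phantoms and cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DTI-ALPS glymphatic analysis on synthetic phantoms and cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`glymphalps` implements the analysis chain used to study glymphatic function
in Cushing's disease (CD): the DTI-ALPS index as a non-invasive proxy of
perivascular fluid transport, white-matter microstructure (FA/MD) across 42
tracts, their covariate-adjusted group statistics, and a causal mediation
model linking nocturnal cortisol, ALPS and tract FA. Because patient-level
imaging and laboratory data of this kind are not publicly depositable, the
package pairs every analysis stage with a synthetic generator whose ground
truth is known exactly; this vignette records the models, the parameter
choices, and what the synthetic results do and do not establish.

## The ALPS model

At the level of the lateral ventricles, the deep medullary veins run along
the image x axis (left-right), perpendicular to both the projection fibers
(superior-inferior, z) and the association fibers (anterior-posterior, y)
that flank them. Diffusivity along x in those two fiber populations is
therefore dominated by perivascular-space water, while the y diffusivity in
projection fibers and the z diffusivity in association fibers are ordinary
fiber-perpendicular diffusivities. The index

$$\mathrm{ALPS} = \frac{\mathrm{mean}(D_{x,\mathrm{proj}}, D_{x,\mathrm{assoc}})}
{\mathrm{mean}(D_{y,\mathrm{proj}}, D_{z,\mathrm{assoc}})}$$

is 1 when there is no preferential perivascular diffusion and rises above 1
with intact glymphatic transport. `Dx, Dy, Dz` are read as the tensor
diagonal entries `Dxx, Dyy, Dzz` in the image frame, the standard reading of
"apparent diffusion coefficients along the axes". The package computes the
index per axial slice from cube ROIs and averages three consecutive
left-hemisphere slices (`alps_from_tensor()`), the hemisphere with the more
stable ROI placement in practice.

Two ROI conventions deserve note. First, ROI protocols are commonly stated
in millimetres (3 x 3 x 3 mm^3) although acquisitions use 2 mm isotropic
voxels; a 1.5-voxel cube does not exist, so `alps_roi_spec()` defines cubes
by voxel edge count (default 3, i.e. 6 mm at default resolution) and records
the convention rather than silently resampling. Second, the per-slice ROI is
a 2-D edge x edge patch so the three-slice averaging is explicit;
`mode = "cube"` gives the single-3D-cube alternative. On the uniform-slab
phantom the two agree exactly.

## The phantom

`generate_dwi_phantom()` builds the minimal scene that realises the ALPS
geometry: an isotropic background (eigenvalues 0.8 x 10^-3 mm^2/s), a
CSF-like ventricle block (3.0), and two fiber slabs with eigenvalues
(1.4, 0.55, 0.32) x 10^-3 mm^2/s, the principal axis along z in the
projection slab and along y in the association slab, the middle eigenvalue
along x in both. These are plausible white-matter values, and they fix the
analytic index at 0.55/0.32 = 1.71875 — inside the 1.69-1.76 range the
emulated cohorts use. Slabs are axis-aligned boxes in the left (low-x,
RAS) half, at least three voxels wide so a 3^3 ROI fits strictly inside:
partial-volume effects are deliberately excluded so that the noiseless
phantom is an exact oracle (fitted tensors and ALPS agree with ground truth
to 10^-9, tested).

Signals follow the single-tensor model `S = S0 exp(-b g' D g)` over 64
Fibonacci-sphere directions at b = 1000 s/mm^2 plus four b = 0 volumes,
with Rician noise `sqrt((S+e1)^2 + e2^2)` at a b = 0 SNR of 30 (sigma =
S0/SNR; SNR 0 = noiseless). What the phantom does *not* emulate: partial
volume, crossing fibers, eddy/motion artefacts, spatially varying noise.
Passing tests on it therefore validate the estimator wiring and numerics,
not robustness to real acquisition artefacts.

## Tensor fitting

`fit_tensor_loglinear()` uses unweighted log-linear least squares — the
plain reading of "linear least-squares" tensor fitting — with a
weighted (`S^2`) option behind a flag. b = 0 volumes enter the regression
as b = 0 rows rather than being pre-averaged (equivalent at the optimum,
simpler provenance). Numerical choices:

* signals are floored at `1e-6 * S0` before the log, so empty voxels do not
  produce `-Inf`; all-zero voxels are flagged out of `valid_mask` instead;
* the design matrix mixes O(1) and O(b) columns, so columns are normalised
  before the shared QR factorisation — this keeps the noiseless inversion
  at machine precision rather than ~1e-7;
* negative fitted eigenvalues are *kept* for diffusivity/ALPS purposes
  (they are apparent diffusivities) and clamped to zero only inside the FA
  formula, which requires positive semidefiniteness; clamped voxels are
  reported via an attribute.

Eigenvalues are sorted descending and the principal eigenvector's sign is
normalised (nonnegative z, then y, then x) so DEC maps
(`fa * |v|` -> RGB) are reproducible across runs.

## Rater simulation and ICC

Manual ROI placement is emulated by `simulate_rater_perturbation()`:
integer jitter of each cube center within +/- `max_shift_voxels` per
in-plane axis plus one shared axial shift. Agreement between two simulated
raters is summarised by ICC(2,1) — two-way random effects, absolute
agreement, single measure — computed from the subjects x raters mean
squares in closed form (`interrater_icc()`). The variance-component
identity ICC = sigma_subject^2 / (sigma_subject^2 + sigma_error^2) is
tested at subject SD 0.2 vs rater SD 0.1 (ICC 0.8). On small phantom
studies the between-subject variance comes only from noise realisations,
so the ICC there is attenuated relative to real cohorts, where anatomy
varies; the closed-form test is the calibrated check.

## The cohort generator

`generate_cohort()` draws 69 CD and 64 HC subjects by default, with group
marginals encoding the emulated study population: age 40.94 +/- 10.99 vs
41.91 +/- 12.87 years, ED 11.78 +/- 4.28 vs 10.83 +/- 3.62 years, BMI
26.32 +/- 4.08 vs 22.78 +/- 3.33 kg/m^2, TBV 1,321,560 +/- 116,853 vs
1,384,687 +/- 94,081 mm^3, ALPS 1.69 +/- 0.20 vs 1.76 +/- 0.17. Morning
cortisol is right-skewed and reported as median (IQR), so it is simulated
log-normal with `meanlog = log(median)` and
`sdlog = log(Q3/Q1) / (2 z_{0.75})` (683.36 (524.74, 869.58) nmol/L in CD,
330.36 (268.21, 411.30) in HC); 4 p.m. cortisol likewise (CD only);
midnight cortisol is reported as mean +/- SD and simulated normal
(549.46 +/- 221.59 nmol/L) truncated at zero. Controls carry no afternoon
or midnight cortisol — those cells are missing by design, and CD-only
analyses restrict to complete rows with the n used always reported.

One quirk is inherited knowingly: the reference demographic summary lists
6 male and 60 female CD patients (66 total) against a stated group size of
69. The generator keeps n = 69 and allocates
`round(69 * 6/66) = 6` males deterministically, so both the group size and
the male count match the source numbers; the proportion is treated as the
truth.

Tract metrics: each of the 42 tracts gets a fixed healthy baseline
(FA 0.32-0.53, MD 0.68-0.80 x 10^-3 mm^2/s, deterministic per tract) with
within-group SD 0.03, and CD means are shifted by the planted template —
by default 25 tracts at -0.8 SD in FA and 40 tracts at +0.8 SD in MD, with
the middle cerebellar peduncle and anterior commissure spared on MD. A 0.8
SD shift is a strong but realistic effect for chronic hypercortisolism and
gives the 42-tract panels essentially full power at n = 500/group while
reproducing partial recovery (about 24-25 FA, 37-40 MD flags) at the
study's own n = 69/64.

### The mediation path

Within CD, standardized midnight cortisol `z0` drives ALPS with
standardized slope `path_a` (default -0.354, so `corr(z0, ALPS) = path_a`),
and ALPS drives right SLF III FA. `path_b` (default 0.42) is stated on the
*partial-correlation* scale — the correlation between ALPS and SLF III_R
FA after removing cortisol — because that is the scale on which such
associations are reported and recovered by the package's correlation
stage. The generator converts it to the structural slope `beta` of
standardized ALPS by solving

$$\beta^2 (1 - p_a^2 + \rho^2 p_a^2) + 2 \rho^2 p_a d\, \beta + \rho^2 (d^2 - 1) = 0,$$

with `rho = path_b` and `d = direct_effect` (default 0), picking the root
with the sign of `rho`; at the defaults `beta = 0.4435`. This keeps both
targets honest at once: the partial-correlation stage converges to
`path_b` exactly, and with `d = 0` the structural direct effect is exactly
zero, so mediation is *full* by construction and ACME converges to
`path_a * beta = -0.157` (within 0.01 of the naive product
`path_a * path_b = -0.149`). Residual variances are chosen so ALPS and the
FA outcome keep unit standardized variance. Covariate effects on ALPS and
FA default to zero (configurable), so path recovery is exactly identified.

## Statistics

* **Demographics** (`demographics_table()`): per-group Shapiro-Wilk screen
  at alpha 0.05 routes continuous variables to Welch t (unequal variances —
  the safer default where only a "t test" is specified; pooled Student t
  behind a flag) or Mann-Whitney U (normal approximation, tie-corrected);
  sex by Pearson chi-square with continuity correction only when an
  expected cell is < 5.
* **Adjusted comparisons** (`adjusted_group_difference()`,
  `tract_panel_comparison()`): OLS of the outcome on a CD indicator plus
  age, sex (male indicator), ED, BMI and TBV; listwise deletion with
  `n_used` recorded; rank deficiency is an error naming the collinear
  columns. FDR families are: the 42 tracts of one metric; the 42-outcome
  ALPS-FA correlation panel; and the single ALPS comparison as a family of
  size one (its "FDR-corrected" p equals the raw p).
* **Adjusted correlations** (`partial_correlation()`): both variables are
  residualised on the covariates and the Pearson correlation of residuals
  is tested with `df = n - k - 2`. "Adjusting for" is implemented as
  partial correlation (the symmetric reading), not as correlating one
  outcome's regression residuals with a raw variable; with zero covariates
  it reproduces plain Pearson to 1e-12. The cortisol-ALPS correlations
  adjust for the five demographics only; the ALPS-tract panel additionally
  adjusts for all three cortisol time points, as each analysis states.
* **Mediation** (`fit_mediation()`): product-of-coefficients on two OLS
  models (`M ~ X + C`, `Y ~ X + M + C`, no interaction), with
  `TE = ACME + ADE` holding as an algebraic identity (tested at 1e-10).
  No named estimator beyond "simple mediation" is assumed; the
  nonparametric percentile bootstrap (rows resampled with replacement,
  default 5000 replicates, fixed seed, degenerate resamples redrawn and
  counted) supplies CIs and two-sided p-values floored at `2/n_boot`.
  Treatment, mediator *and* outcome are z-scored by default so ACME/ADE/TE
  are standardized and comparable across configurations — the scale on
  which such effects are reported without units; raw scale is a flag.
  Classification: *full* if the ACME interval excludes 0 and the ADE
  interval does not, *partial* if both exclude 0, *none* otherwise.

## Reproducibility and problem sizes

One master seed feeds named substreams (`substream_seed()`) for phantom
geometry, noise, cohort draws and bootstrap, so stages can be regenerated
independently and full runs are byte-identical under a fixed seed. The
test and acceptance workloads are sized for a laptop-class single core:
template recovery uses 500 subjects/group (power ~1 at 0.8 SD effects),
path recovery 5000 CD subjects with a 1000-replicate bootstrap, type-I
error 1000 null replicates at 200/group, FDR control 200 null cohorts at
100/group, and the ICC identity 10^4 subjects.

## Limitations

The synthetic cohort draws covariates independently of outcomes (unless
configured otherwise), so it cannot probe confounding-driven bias in the
adjusted models; the phantom cannot probe registration, tractography or
partial-volume error, all of which sit upstream of this package's scope in
a real study (tract segmentation is consumed here as a precomputed metric
table). The ALPS index itself is a regional diffusion proxy whose
biological specificity for glymphatic flow is still debated; this package
treats it strictly as a defined image statistic.
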