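---
title: "Methods: global signal topography of the self and its behavioural link"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: global signal topography of the self and its behavioural link}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the model behind each stage, the assumptions it rests on, the
parameters a user may want to change, and the numerical and design choices
that were genuinely open.

## The measurement model

The global signal (GS) is the per-volume mean BOLD signal over gray-matter
voxels. For a region with mean time series $x$ and GS $y$ over $n$ volumes,

$$\rho = \frac{n\sum xy - \sum x \sum y}
{\sqrt{\left[n\sum x^2 - (\sum x)^2\right]\left[n\sum y^2 - (\sum y)^2\right]}},
\qquad Z_{\mathrm{GSCORR}} = \tfrac{1}{2}\ln\frac{1+\rho}{1-\rho}.$$

$Z_{\mathrm{GSCORR}}$ measures how strongly the region represents global
brain activity. `compute_gscorr()` evaluates $\rho$ with `stats::cor()` (the
tests verify term-by-term agreement with the sum formula to $10^{-10}$) and
clips $\rho$ to $\pm(1-10^{-12})$ before the log, so a region identical to
the GS yields a large finite value (`atanh(1 - 1e-12)` $\approx 13.9$)
instead of infinity — invisible at any realistic correlation.

Regions come in two forms. The three *self layers* are compound ROIs: 8 mm
spheres around meta-analytic MNI coordinates — interoceptive: right insula
(34, 14, 12) and left insula (−40, −2, 2); exteroceptive: right TPJ
(−48, −38, 36) and MPFC (−6, 60, 22); mental: PCC (−4, −54, 28) and pACC
(−6, 48, 0) — merged by `layer_timeseries()` before averaging. A voxel
belongs to a sphere when its centre's Euclidean MNI distance is at most the
radius (boundary inclusive); distances use voxel-centre coordinates from the
NIfTI affine. The layers must be pairwise disjoint
(`assert_disjoint_layers()`), which holds for these six coordinates at 8 mm
on 3 mm and 6 mm grids. Alternatively, `parcel_gscorr_map()` accepts any
integer label volume (e.g. a 360-region anatomical parcellation resampled to
the BOLD grid), so atlas-based whole-brain maps drop in without the package
shipping any atlas.

Two ordering choices were open and are fixed as follows: the GS is extracted
from the *same* temporally preprocessed data as the region series (filtering
first, correlation second), and ROI voxels are *not* excluded from the GS.
Both follow the described processing order; neither is consequential for the
layer ROIs, which cover under 2% of gray matter.

## Temporal preprocessing

`temporal_filter()` implements the two frequency variants: the infra-slow
band-pass (0.01–0.1 Hz), and a high-pass-only control (0.01 Hz lower edge,
no upper edge) that admits the faster frequencies. The filter is a
forward–backward (zero-phase) Butterworth of order 2 per pass with reflect
padding of up to 100 samples to suppress edge transients. The exact kernel
of the original processing chain is not specified anywhere, so the filter is
specified by verifiable properties instead: pass-band amplitude preserved
within 5% (measured 0.993 at 0.05 Hz, TR = 2 s), amplitude one octave beyond
the cutoff attenuated by more than 90% (measured ratio 0.002 at 0.2 Hz), no
temporal shift, and linearity to $10^{-8}$. Cutoffs must respect
$0 < f_{\mathrm{low}} < f_{\mathrm{high}} < 1/(2\,\mathrm{TR})$.

`nuisance_regress()` projects out an arbitrary regressor matrix (e.g. six
motion parameters and their derivatives) plus an intercept by least squares;
collinear columns are dropped with a warning. `global_signal_regression()`
residualizes every voxel on the GS; because projection is idempotent and the
residual is exactly orthogonal to the regressor, every region's GSCORR
against the regressed GS is numerically zero afterwards ($|z| < 10^{-8}$ in
the acceptance tests). That exact collapse is the *control logic* of the
analysis: a group difference that survives GSR cannot be carried by the
global component.

Because masked averaging, filtering, volume discard and regression are all
linear in the voxel data, `run_pipeline()` extracts region series once and
filters/residualizes at the series level; the tests confirm this equals the
voxelwise route to $10^{-8}$.

## Group inference

Group sizes of 17 and 14 motivate rank-based tests. `wilcoxon_rank_sum()`
returns the exact two-sided p-value when the combined sample is at most 25
without ties, and a tie-corrected normal approximation with continuity
correction otherwise; the effect size is the common
$r = |z^\ast|/\sqrt{N}$ with $z^\ast$ the standardized rank-sum statistic
(no effect-size definition is standard here; this is the usual convention).
Within-group layer contrasts use the *paired* signed-rank variant
(`wilcoxon_signed_rank()`), since the same subjects contribute all three
layers; zero differences are dropped and an all-zero contrast returns
$p = 1$. Families of layer tests are corrected with the step-down Holm
procedure (`holm_adjust()`, monotone, capped at 1).

`ancova_group_effect()` fits `value ~ group + covariate` and reports the
partial group test with adjusted means at the grand covariate mean. One
caveat the synthetic experiments make visible: when the covariate (HAMD)
nearly separates the groups, group and covariate are close to collinear and
the partial group test loses power even for real effects — the rank test
carries the detection in that regime, and the ANCOVA answers only the
narrower question of an effect *beyond* what the covariate explains.

### The resampling pFDR procedure

For parcelwise comparison, `pfdr_parcelwise()` (1) computes the observed
Wilcoxon p-value per parcel, (2) permutes the subject group labels
`n_resamples` times (default 100), recomputing every parcel's p-value to
form a per-parcel null distribution, and (3) declares a parcel significant
when the fraction of its null p-values at or below its observed p is smaller
than the expected false discovery rate (default 0.05). The resampling unit
was an open question; subject-level label permutation is the standard
exchangeable null under the no-group-difference hypothesis and is what is
implemented. Fewer than 20 resamples is refused (the null would be too
coarse to estimate a 5% fraction). Under a 360-parcel global-null simulation
the significant fraction averages about 0.04–0.05 over 20 seeded runs, and a
parcel with a 5-SD group separation is flagged in ≥ 95% of runs.

## Behavioural analysis

Severity ratings (weak = 1 … strong = 4) are cleaned by `clean_responses()`:
only the first button press per rating period counts, unanswered trials are
dropped, and a subject who pressed in all four 2-s windows on *every* trial
is excluded entirely (the operationalization of the always-press rule; the
generator plants one such subject by default, so a 31-subject cohort yields
30 analyzable ones). `chi_square_test()` is the plain Pearson chi-square on
the 2 × 4 group-by-severity table (no continuity correction, df = 3), and
`standardized_residuals()` returns the adjusted residuals
$r_{ij} = (O_{ij}-E_{ij})/\sqrt{E_{ij}(1-p_{i\cdot})(1-p_{\cdot j})}$, whose
two-sided normal cutoffs 1.96 / 3.29 / 3.89 correspond to p = 0.05 / 0.001 /
0.0001. Under simulated independence about 5% of cells exceed 1.96.

## The neural→behaviour link

One multinomial logistic regression per condition (negative-attend,
negative-reappraise, neutral-attend) regresses trial-level severity on the
subject's three layer-GSCORR values plus a group indicator. The reference
category is the modal response — mild for negative stimuli, weak for neutral.
`fit_multinomial()` is a full Newton maximizer with step-halving
(log-likelihood never decreases), convergence at $\Delta\ell < 10^{-8}$ or
200 iterations, no regularization. Complete separation is detected (fitted
probabilities at 0/1, i.e. $\ell$ at numerical zero, or runaway
coefficients) and flagged as non-convergence rather than penalized away.
The tests verify agreement with an independent optimizer
(`nnet::multinom`) to $10^{-4}$ on shared fits and recovery of known
generative coefficients within ±0.3 at $n = 10{,}000$ trials.
`relative_risk_ratios()` exponentiates the coefficient matrix.

`cross_validate()` runs stratified k-fold cross-validation (default 10-fold,
5 repeats; stratification by outcome category is a package choice — fold
schemes were not otherwise specified) and reports per-fold held-out
accuracy. Whether a printed model accuracy refers to fold-averaged CV
accuracy or whole-data resubstitution accuracy is ambiguous in this design,
so the report carries both; the confusion matrix and the one-sided exact
binomial test against the no-information rate (largest class share) use the
whole-data predictions of the final whole-data fit, mirroring the described
procedure. A deliberate simplification inherited from the analysis being
modelled: trials within a subject share the subject's GSCORR predictors, and
this within-subject dependence is ignored — p-values from the MLR are
anti-conservative to an unknown degree, which is why the package treats the
model primarily as a descriptive/predictive device.

## The synthetic-data generator

The generator exists so that every stage can be tested against ground truth.
Its defaults *are* the study conditions: 17 MDD + 14 control subjects, 96
trials of 22 s (30 negative-reappraise, 18 negative-attend, 48
neutral-attend — the neutral count is inferred as the remainder), hence 1056
volumes at TR = 2 s; synthetic HAMD uniform on 7–17 (MDD) vs 0–5 (control),
used only to exercise the covariate path.

Per subject, each voxel in region $r$ (the three layers plus background gray
matter) follows

$$x_v(t) = \lambda_r\, g(t) + \sqrt{1-\lambda_r^2}\, h_r(t) +
\sigma\,\varepsilon_v(t),$$

where $g$ is the subject's shared global component (white noise band-passed
to 0.01–0.1 Hz and z-scored — the simplest process with the required
spectrum), $h_r$ an independent band-limited regional innovation, and
$\varepsilon_v$ white voxel noise with $\sigma = 1$. The subject's layer
loading $\lambda_r$ is drawn from a group mean with between-subject SD 0.22.
$g$ and the $h_r$ are Gram–Schmidt orthonormalized *in sample*, so with
$\sigma = 0$ the pipeline GSCORR equals the closed-form loading-implied
correlation (`analytic_layer_gscorr()`) to machine precision — the
round-trip invariant is tested at $10^{-6}$ and holds at $10^{-12}$.

Default group loadings (background 0.9; interoceptive 0.03/0.08,
exteroceptive 0.00/0.34, mental 0.02/0.28 for control/MDD) are calibrated so
the measured layer Fisher-z values reproduce the reported group profile —
near-zero exteroceptive/mental means in controls versus ≈ 0.3 and ≈ 0.25 in
MDD with between-subject SD ≈ 0.2, i.e. a gap of about 1.5 SD, which is what
the published adjusted means and their standard errors imply. Behavioural
responses are drawn from the published per-condition multinomial slopes
applied to each subject's model-implied layer GSCORR; the unpublished
intercepts are fixed so the reference category is modal (the stated
rationale for its choice), and the one unprinted neutral-strong slope is
recovered from its printed RRR.

The generator deliberately does **not** simulate hemodynamics, task-evoked
responses (a hook exists but defaults off, since GSCORR uses the whole
filtered series), head motion, physiological or scanner noise, or spatial
autocorrelation. Passing tests therefore demonstrate correctness of the
statistical machinery under the generative model, not robustness to
real-data artifacts such as motion or respiration-coupled global signal.

Two problem-size choices keep experiments tractable and are package
decisions, documented here: the default simulation grid uses 6 mm isotropic
voxels on a 19 × 24 × 11 box covering all six spheres plus margin (a
31-subject voxel-level cohort is then ≈ 1.3 GB; 3 mm is available via
`voxel_size`), and seed-intensive power studies use
`simulate_layer_gscorr()`, a region-level fast path that is
distribution-exact because every pipeline step is linear in the voxel data —
it simulates the region mean series and their correctly correlated
region-mean/GS noise directly. Its agreement with the voxel route is itself
tested. With these defaults, 200 seeded cohorts give detection power above
0.8 for both elevated layers at n = 17/14 and reproduce the
Int < Ext ≅ Ment ordering in the MDD arm only.

## Degenerate inputs and numerical edges

* Constant series: correlation errors out; a constant GS cannot be
  regressed; a constant ANCOVA covariate falls back to the plain two-group
  model with a warning.
* Empty masks (sphere outside the grid, empty gray-matter mask, absent
  parcel label) raise errors or logged warnings rather than silent `NaN`s.
* All-tied rank tests return $p = 1$ with zero effect size.
* Zero chi-square margins are errors; zero expected cells yield `NA`
  residuals.
* Rank-deficient designs: nuisance regression drops collinear columns with a
  warning; a singular MLR design is an error.
* Seeds: every stochastic function takes an explicit seed (or derives
  per-subject seeds below $2^{31}$ from the configuration seed) via
  `withr::with_seed`, leaving the caller's RNG state untouched; identical
  seeds give bit-identical output, including byte-identical pipeline tables.
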