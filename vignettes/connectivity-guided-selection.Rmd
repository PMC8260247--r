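---
title: "Connectivity-guided voxel selection: models, simulation and inference"
author: "connsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-guided voxel selection: models, simulation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connsel)
```

## The question the package operationalizes

Category-preferring regions of occipito-temporal cortex (fusiform and
occipital face areas, parahippocampal and occipital place areas, medial
fusiform and posterior middle-temporal tool regions) carry multivoxel
response patterns that discriminate visual categories. The analysis
implemented here asks whether *distal functional connectivity* indexes
that local discriminability: if we rank the voxels of a target region by
the strength of their residual-timecourse correlation with distal
same-category seed regions, do the 100 most-connected voxels support
better split-half pattern decoding than the 100 least-connected ones —
and does that advantage survive controls for univariate activation and
temporal signal-to-noise?

The package implements the full analysis chain — block-design GLM,
task-regressed band-passed connectivity, leave-one-split-out voxel
selection, split-half correlation decoding, activation-matched
permutation controls, tSNR comparison, a good-seed searchlight with
sign-flip TFCE group inference — together with a synthetic-cohort
generator that plants each of the ingredients the analysis is supposed
to detect. Human data for this design are not publicly deposited, so the
generator is the package's test bed: every pipeline stage is validated
against data whose ground truth is known by construction.

## The task and first-level model

Subjects complete six runs of a blocked design: two 6 s blocks per
intact category (tools, faces, places, animals) and one 6 s block per
phase-scrambled variant, each block followed by 6 s of fixation, with
16 s of fixation opening and closing each run. At TR = 2 s this gives
176 s = 88 volumes per run; block order is randomized per run. The
number of scrambled conditions is one per intact category — the reading
that reproduces the 176 s run length exactly.

Run-wise GLMs use one regressor per condition: the condition boxcar
convolved with the conventional double-gamma canonical HRF (response
gamma with shape 6, undershoot with shape 16, unit dispersions,
undershoot ratio 1/6, 32 s kernel, peak-normalized; no temporal or
dispersion derivatives). The high-pass filter is realized as a
discrete-cosine drift basis inside the design matrix — components with
full period 2T/k above the 256 s cutoff — which is the same projection
as pre-filtering but keeps provenance in one place. With T = 176 s the
basis holds exactly one drift term; the basis is empty once the cutoff
exceeds twice the run length. Six simulated rigid-motion regressors and
an intercept complete the design. Estimation is ordinary least squares;
AR(1) prewhitening is deliberately omitted because the generator's noise
is white by construction, and the downstream contrasts (selection and
decoding) do not depend on it. Contrast t maps use
t = c'b / sqrt(s^2 c'(X'X)^-1 c); category-preference contrasts weight
the preferred intact category 1 and the other three intact categories
-1/3 (scrambled conditions 0), the sum-to-zero reading of
"tools > [faces + places + animals]".

## Connectivity

Functional connectivity is computed on denoised residuals: each run is
regressed on the task design (condition regressors, drift, intercept)
plus nuisance series — the six motion regressors, their first-order
temporal derivatives, and a global-signal proxy formed as the mean over
the layout's non-gray voxels (one combined regressor; outlier-scan
removal is not modelled because no outliers are simulated). Residuals
are then band-passed to 0.01–0.1 Hz with a Fourier-domain zero-phase
filter: unit passband gain, raised-cosine transitions (roll-on from
half the low edge, roll-off completed by 1.25 times the high edge), DC
exactly zero. A frequency-domain filter was chosen over a zero-phase
IIR because an 88-sample run leaves little room for IIR edge
transients, the gain contract (passband within 10%, below 10% gain at
twice the upper edge) is met exactly, and the operation vectorizes over
all voxels at once. Filtering is applied per run; runs of a split are
concatenated afterwards.

For a target region, the seed pool concatenates, over every
same-category region (the other target of that category plus its
dedicated distal seeds), the 100 most-activated voxels of that region
by the category-preference contrast of the selection split. Pearson
correlations between each target voxel and each seed voxel are
Fisher-z transformed (r clipped to ±(1 − 1e-7) so z stays finite;
ordering is unaffected), and the per-voxel mean z across all seed
voxels is the selection score. Zero-variance voxels are flagged and
excluded from selection.

## Selection, decoding and the split scheme

The six runs form three splits of two runs; each fold uses one split
for selection (connectivity scores and activation t values) and the two
remaining splits for decoding, so selection and decoding data never
mix. Within a fold the package selects the 100 most-connected and 100
least-connected voxels (disjoint by construction; ties broken by
ascending voxel index) and, per binary comparison, the 100
most-activated voxels by the comparison-specific pairwise contrast
(overlap with the connectivity sets deliberately unconstrained).

Decoding is split-half correlation decoding: condition patterns are
run-averaged betas per decoding split, restricted to the voxel set;
the 2x2 split-by-category correlation matrix yields
accuracy = mean(within-category r) − mean(between-category r), a
statistic bounded by [-2, 2] and positive when patterns discriminate
the categories. Patterns are raw betas — no percent-signal rescaling
and no mean-pattern subtraction — matching the plain split-half
formulation. Fold accuracies are averaged per subject before group
inference. Two comparisons are scored per region (preferred category
against each other analyzed category), six regions in the default
layout.

## The matched-activation control

To decouple connectivity from univariate activation, target voxels are
median-split by mean connectivity; 10,000 random pairs of 100-voxel
subsets (one subset per half) are drawn, and a pair is retained only if
the two subsets' mean activation t values do not differ under the
threshold in force: liberal (two-tailed pooled-t p > 0.10),
intermediate (t in [-0.5, 0.5]) or strict (t in [-0.5, 0], the
strongly connected set at most as activated as the weak one). The
matching test is Student's pooled-variance two-sample t; a degenerate
zero-variance draw is defined as t = 0 and passes. Decoding accuracy is
averaged over all retained pairs; an empty retention set drops that
subject/region from the corresponding group analysis (listwise), and
retained-subject counts are reported. Under exact independence of
activation and connectivity the liberal retention rate is
P(p > 0.10) = 0.90; this identity is used as a calibration target for
the generator (below). The activation values used for matching are the
comparison-specific contrast t values for every region — the stricter,
comparison-aligned reading. The matching draws use an RNG stream
independent of the simulation stream.

## Good-seed searchlight and group inference

The searchlight asks the converse question: which locations, used as
seeds, make connectivity-guided selection work? Every gray voxel
outside the target region centers a neighborhood of the k nearest gray
voxels (k = 100 by default, the fixed-size analogue of "about 100
contiguous voxels"; ties broken by ascending index). The neighborhood's
mean residual time course is the single seed series; target voxels are
ranked by Fisher z to it, top/bottom sets are decoded with a single
odd/even-runs fold (circularity is benign here because activation plays
no selective role), and the accuracy lands on the center voxel. The
module is deterministic given the data.

Group inference on most-minus-least difference maps uses one-sample
sign-flip permutation: the observed statistic is the TFCE-enhanced
t map (TFCE with E = 0.5, H = 2, dh = max/100, face connectivity — the
method's conventional defaults), the null is its distribution under
random per-subject sign flips, and each voxel's familywise-corrected p
is the fraction of permutation *maxima* reaching its observed value,
converted to a z score and thresholded at z > 1.65. Permutation p
values live in [1/(nPerm+1), 1]; the z conversion caps p away from 1 so
z stays finite. Repeated-measures ANOVAs (up to three within factors)
are fitted with per-effect subject-interaction error strata and
reported with uncorrected degrees of freedom and partial eta squared;
sphericity corrections are not applied. Post hoc paired t tests use
Bonferroni-corrected thresholds (alpha/m).

## The synthetic generator

`simulateSubject()` builds, per voxel, baseline + task response +
noise:

* **Activation.** Every voxel of a region responds to its region's
  preferred category with amplitude `activationGain` times a voxel
  lognormal gain (sdlog 0.3), giving a realistic activation topography
  and meaningful most-activated selection in both target and seed
  regions.
* **Patterns.** The informative fraction (`fracInformative`, default
  0.5) of each target region's voxels additionally carries fixed
  Gaussian per-condition pattern values scaled by `patternSnr` (in
  noise-SD units) for all four intact categories — the substrate of
  split-half decoding.
* **Coupling.** Each category has a shared latent signal, band-limited
  to 0.01–0.1 Hz so it survives the pipeline's band-pass. Coupled
  voxels (all dedicated seed-region voxels and the informative target
  voxels) mix this latent with private noise at SD ratio
  `couplingStrength` (share a^2 = c^2/(1+c^2) of the non-task
  variance).
* **Noise symmetry.** Two constraints make activation, tSNR and
  coupling independently plantable, and both were forced by explicit
  failure modes rather than taste. First, latents are constructed in
  the orthogonal complement of each run's full first-level design span
  and norm-matched to the white-noise residual expectation; otherwise
  the latent's overlap with the (low-frequency) task and motion
  regressors perturbs residual variances and makes activation t values
  systematically co-vary with coupling. Second, when coupling is on,
  *every* voxel receives the same band-limited variance share — coupled
  voxels share the category latent, all other voxels get a private
  latent of identical construction — so the residual-variance estimator
  has the same distribution everywhere. With either constraint dropped,
  the measured liberal matched-activation retention fell to 0.69 and
  0.44 respectively; with both in place it is 0.904 ± 0.005, against
  the theoretical 0.90 under independence.
* **Motion and global proxy.** Six smooth random-walk motion series per
  run exercise the nuisance interfaces but carry no signal; non-gray
  voxels are baseline + noise and exist to supply the global-signal
  proxy.

Ground truth (informative indices, pattern values, gains, latents) is
stored in the dataset's truth record, which analysis code never reads —
only tests do.

Defaults are `couplingStrength = 0.5` (informative-to-seed residual
correlation about 0.2 before band-passing), `fracInformative = 0.5`,
`patternSnr = 0.3`, `activationGain = 1`, `noiseSd = 1`, `baseline =
100` (so tSNR is realistically scaled). A calibration run prescribed
for the generator — 200 subjects at `patternSnr = 1` — gave positive
informative-voxel decoding in 100% of subjects (the target is at least
95%).

What the generator does *not* emulate: physiological (cardiac or
respiratory) noise, temporally autocorrelated noise, scanner drift
beyond what the DCT basis absorbs, image-domain motion artifacts,
outlier volumes, anatomical variability, or spatial autocorrelation of
noise. Passing tests therefore certify the *logic* of the pipeline —
selection, cross-validation hygiene, statistics, calibration under the
generator's assumptions — not robustness to every artifact of real
fMRI.

## Numerical and design choices

* Fisher z of |r| = 1 diverges; r is clipped at 1 − 1e-7.
* Zero-variance voxels: flagged ineligible for selection; zero-variance
  patterns make accuracy undefined (NA, dropped with listwise deletion
  downstream); zero-variance matching draws pass with t = 0.
* Ties in any top-k selection and in searchlight neighborhoods break by
  ascending voxel index, making every selection deterministic.
* The drift-basis count follows the standard DCT convention
  K = floor(2T/cutoff); a cutoff above twice the run length yields no
  drift term.
* `selectTopK()` requires 2k eligible voxels by default so most/least
  sets are always disjoint; `requireDisjoint = FALSE` permits selection
  from smaller pools (e.g. seed definition in 123-voxel regions).
* Seed-region "100 most-activated" definitions use the selection split
  only, with run-wise t maps averaged over the split's runs.
* Matched-pair results are stored as index matrices
  (`MatchedPairSet`), not thousands of pair objects, so decoding over
  ~9,000 retained pairs stays vectorized; `pairVoxelSets()` recovers
  individual pairs.
* TFCE and the matching draws are implemented in C++ (Rcpp); the
  sampler uses R's RNG so `set.seed()` governs everything.
* All master seeds spawn per-consumer child seeds below 2^31;
  simulation, matching draws and permutation flips use separate
  streams.

## Problem sizes used by the tests

The test and acceptance suites scale the study down to run on one CPU
in minutes while keeping every contract intact: the full ten-region
layout (45 x 34 x 12 grid, six 515-voxel targets, four 257-voxel seed
regions) with 20 subjects for planted-effect recovery; a one-category
257-voxel layout for calibration loops (100 null cohorts of 10 subjects
for the type-I check); 12 subjects for the matched-activation
calibration; and reduced 12^3/10^3 whole-gray grids for the
searchlight, with neighborhoods scaled to the grid (33 voxels ~ radius
2) and 1,000 sign-flip permutations against the 10,000 used at full
scale. Group-level searchlight
localization is asserted against the effect's exact support — the
centers whose searchlight neighborhood reaches into the planted seed,
plus the one-voxel fringe TFCE's contiguity integration can lift — with
the group-mean peak required inside the seed dilated by the scaled
neighborhood radius (two voxels).

## Known limitations

* OLS instead of AR(1) prewhitening (harmless for white synthetic
  noise; real data would need prewhitening for valid single-subject t
  values).
* The rm-ANOVA reports uncorrected degrees of freedom; no
  Greenhouse–Geisser correction, no mixed-effects pooling, so fractional
  error df from pooled post hoc machinery are out of scope.
* The searchlight evaluates one target region per call and the group
  map is one-sided (most > least).
* NIfTI export writes unsmoothed native-grid volumes; no spatial
  normalization is modelled anywhere.
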