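---
title: "Predicting longitudinal cognitive decline from EEG, MRI and neuropsychology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting longitudinal cognitive decline from EEG, MRI and neuropsychology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodecline)
```

# The prediction problem

Whether a patient with mild cognitive impairment, subjective cognitive
complaints or temporal lobe epilepsy will show measurable cognitive
decline over the following 18 months is a clinically central question:
it decides follow-up intensity, counselling and treatment planning.
`neurodecline` implements a multimodal machine-learning pipeline for
this question. Candidate predictors are drawn from three modalities
measured at baseline:

* **EEG functional connectivity** — frequency-domain interaction
  measures between 17 scalp electrodes, computed per 1-second segment
  from a multivariate autoregressive (MVAR) model;
* **structural MRI** — per-region normalized volumetry plus two
  texture families (three-plane local binary patterns and stationary
  wavelet transform coefficients summarized by generalized Gaussian
  densities) over an 83-region parcellation;
* **baseline neuropsychology** — normative z-scores of a 23-subscale
  battery.

The outcome is a binary *decline label* per cognitive domain
(executive functions, visual-verbal memory, divided attention,
worsening of depressive symptoms), derived from baseline and 18-month
follow-up testing. Prediction quality is reported as sensitivity and
specificity with a 70% benchmark on both, below which a result is
treated as a classifier artifact rather than a finding.

Because clinical cohorts of this kind cannot be redistributed, the
package ships a synthetic-cohort generator with planted, known ground
truth. Every pipeline stage is therefore testable end to end: the
generator defines what signal exists, and the tests check that the
pipeline recovers exactly that signal and nothing else.

# EEG preprocessing

`rereferenceAverageEarlobes()` rebuilds the reference as the mean of
the two earlobe electrodes and subtracts it from every analysis
channel, removing the bias of the original recording reference.

`filterEEG()` applies a zero-phase high-pass at 1 Hz with a 48 dB/oct
rolloff and a 50 Hz notch. 48 dB/oct corresponds to an 8th-order
Butterworth; we apply it forward-backward for zero phase and accept
the doubled effective attenuation. A *numerical* point worth
recording: an 8th-order Butterworth with a cutoff at 1/250 of Nyquist
is unusable in polynomial transfer-function form (coefficient
round-off makes the filter explode), so the filter is realized as a
cascade of four analytically derived second-order sections, each
applied with odd-reflection end padding so boundary transients of the
slow poles die inside the pad. The notch is a second-order Butterworth
band-stop of 2 Hz width centered at 50 Hz; width and order are our
choice, as only the center frequency is dictated by the mains.

`detectArtifacts()` marks samples by three amplitude rules, unioned
over channels, windows sliding with 1-sample stride:

1. voltage step above 50 µV between consecutive samples — marked with
   a ±100 ms surround;
2. max–min range above 200 µV within any 200 ms window — the window is
   marked;
3. max–min range below 0.5 µV within any 100 ms window (flatline) —
   marked with a ±500 ms surround.

`segmentEEG()` cuts 1000 ms segments: event-locked from 100 ms before
to 900 ms after each stimulus onset, or consecutive non-overlapping
windows through rest blocks, starting at the block onset (overlap and
offset for rest epochs are unconstrained by the source protocol;
non-overlapping from block start is our choice). Any segment touching
a marked sample is dropped.

# MVAR connectivity

Each segment (17 channels × 500 samples at 500 Hz) is fitted with an
MVAR model of order 10,
\[
x_t = \sum_{k=1}^{p} A_k x_{t-k} + e_t, \qquad e_t \sim (0, \Sigma),
\]
using the Vieira–Morf lattice estimator (geometric-mean normalization
of the partial-correlation recursion) with unbiased $1/(N-\mathrm{lag})$
covariance scaling. The lattice route is the standard choice for short
segments at this order because it guarantees a stable fit in practice
and is far better conditioned than least squares on 500 samples × 170
regressors. The residual covariance $\Sigma$ is computed from the
empirical one-step residuals of the fitted model, so the advertised
identity "filtering the segment through the model gives residuals with
covariance $\Sigma$" holds by construction.

`spectralSet()` evaluates, on a 1 Hz grid from 2 to 125 Hz (124
points), the coefficient polynomial $\bar A(f) = I - \sum_k A_k
e^{-i2\pi fk/f_s}$, the transfer function $H(f) = \bar A(f)^{-1}$ and
the cross-spectrum $S(f) = H(f)\,\Sigma\,H(f)^H$. From these,
`computeMeasure()` derives the interaction measures: auto/cross
spectrum; complex, real and imaginary coherence; partial coherence
(pCOH, from $S^{-1}$, ridge-regularized with a logged epsilon if
singular); the partial directed coherence family (PDC, PDCF, gPDC;
column-normalized functions of $\bar A$); the directed transfer
function family (DTF, full-frequency ffDTF, and dDTF = ffDTF × |pCOH|);
Geweke–Granger causality; and the raw transfer function and
coefficient polynomial magnitudes. Directed tensors are indexed
[target, source].

Band averaging uses the closed integer bands delta 2–4, theta 5–7,
alpha 8–13, beta 14–30, gamma 31–80, high gamma 81–125 Hz. Complex
measures are averaged as magnitudes, except complex coherence, whose
real and imaginary parts are averaged separately and exported as
(re, im) feature pairs — whether magnitudes were taken before or after
band averaging is not decidable from the source description, so the
choice is made explicit here. "Direct causality" is implemented as
dDTF's direct-influence convention (the reference chain for the term
is ambiguous); it can simply be omitted from the measure list where
unwanted. Vectorization keeps the nonredundant entries: upper triangle
for symmetric measures (diagonal only for the spectrum), all ordered
off-diagonal pairs for directed ones — 816 respectively 1632 values
per measure for 17 channels over 6 bands.

One model per segment, no averaging across segments: each segment
becomes one classification sample.

# MRI features

**Volumetry.** Region volume is divided by the *sum of all segmented
region volumes* (global brain volume), deliberately not by total
intracranial volume: intracranial volume is insensitive to disease,
whereas global brain volume shrinks with neurodegeneration, making
fractions of it the more sensitive normalization.

**Local binary patterns.** For each voxel, plain 8-neighbor radius-1
LBP codes are computed on the three orthogonal planes through that
voxel (bit order E, NE, N, NW, W, SW, S, SE, comparison ≥). Per
region, the three 256-bin histograms over voxels whose center lies in
the region mask are normalized to frequencies and concatenated (768
values per region). Uniform-pattern reduction is *not* applied, and
histograms are normalized — both are explicit choices where the source
is silent; normalization buys scale comparability across regions of
different size.

**Wavelet texture.** A stationary (undecimated) separable 3D Haar
transform with 2 levels produces 8 subbands per level (all low/high
combinations per axis; level 2 decomposes the level-1 all-lowpass
band). The wavelet family and depth are unspecified in the source; the
Haar pair at 2 levels is the default and both are configurable. Per
region × subband, a zero-mean generalized Gaussian is fitted to the
masked coefficients by moment matching: with $m_1 = E|x|$, $m_2 =
E x^2$, the shape $\beta$ solves
$\Gamma(2/\beta)^2/(\Gamma(1/\beta)\Gamma(3/\beta)) = m_1^2/m_2$
(monotone in $\beta$, solved by root finding on [0.05, 20] with
boundary flagging), and $\alpha = m_1\Gamma(1/\beta)/\Gamma(2/\beta)$.
All-lowpass subbands are mean-centered per region before fitting;
detail subbands are fitted raw. Regions under 30 voxels are kept but
flagged unreliable. Two levels give 16 subbands and hence 32
parameters per region.

# Neuropsychology

Raw subscale scores are converted to normative z-scores, $(x -
\mu_{norm})/\sigma_{norm}$, with the sign flipped for higher-is-worse
scales (depression inventory, error and miss counts) so that a larger
z is uniformly better. This centralized direction table is what makes
the decline rule uniform across domains, including depression: a
worsening of ≥ 1 SD in symptoms is just a z-drop of ≥ 1.

A participant is labelled *declined* in a domain iff
$z_{followup} - z_{baseline} \le -1$ on at least one member subscale.
The threshold is applied to the *change* in normative z — the literal
reading of "a decline of at least one standard deviation according to
the test manuals"; thresholding baseline-z instead would measure
impairment, not decline. Improvements and sub-threshold changes count
as no-decline. The default battery (23 subscales with editable norms)
and the domain memberships (executive 7, memory 5, divided attention
3, depression = BDI) are configuration tables. The divided-attention
membership is genuinely ambiguous in the source description; the
default (flexibility summary plus the two condition-2 task summary
scores) is an explicit, editable choice. The error/miss scales are
treated as counts with higher-worse direction — what matters
downstream is the flip mechanism, not the particular norms, and both
are config.

# Classification and nested cross-validation

`assembleSamples()` builds the sample table: one sample per EEG
segment (participant-constant MRI/neuropsychology vectors are
replicated onto each of that participant's segments), or one per
participant in designs without EEG. Columns are *not* standardized at
assembly; standardization is fitted on training rows only, inside
every cross-validation layer, because fitting it globally would leak
test-set statistics into training.

The classifier is a linear 2-norm soft-margin SVM
\[
\min_{w,b}\; \tfrac12\|w\|^2 + C\sum_i \max(0,\, 1 - y_i(w^\top x_i + b))^2,
\]
trained by the finite-Newton active-set method (exact quadratic solve
on the current violator set with backtracking). The squared hinge
makes every zero-loss point irrelevant to the solution — removing a
non-support vector provably leaves the decision function unchanged,
which the tests exercise. $C = 1$ by default; inverse-class-frequency
weighting of $C$ is available for imbalanced designs.

Cross-validation has three layers, all *participant-grouped* (all
segments of one participant stay in one partition — segments within a
participant are far more similar than between participants, so
ungrouped folds would leak identity) and label-stratified:

* **outer** — one split holding out 20% of participants for final
  testing;
* **middle** — 5-fold over the remaining 80%; each run performs
  feature subset selection on its training folds and records the
  selected subset, measuring selection *consistency*;
* **inner** — 5-fold inside the selection procedure itself.

`greedyFSS()` is greedy forward selection: start empty, add the
feature maximizing mean inner-fold balanced accuracy, stop at a cap of
30 features or when no candidate improves the score by more than 1e-4;
ties break toward the lower column index for determinism. The cap of
30 is roughly two-thirds of the typical sample count and is the
overfitting control. The five middle-run subsets are combined by
frequency-ranked union truncated to the cap (how the runs combine into
one final model is not specified by the source; ranking by selection
frequency preserves the consistency interpretation of the
frequency maps), retrained on the full 80%, and evaluated once on the
held-out 20%.

`cvMetrics()` reports accuracy, sensitivity (decliners correctly
classified) and specificity (non-decliners correctly classified) at
both the segment level and the participant level (majority vote over a
participant's segments, ties to the positive class); the
participant-level numbers are the headline, and a result is flagged
*reportable* only when both sensitivity and specificity reach 70%.

# The synthetic cohort generator

`generateCohort()` draws five diagnostic groups (default sizes
19/4/6/3/18 — MCI, subjective complaints, right/left temporal lobe
epilepsy, healthy controls), assigns decliners per domain at
configurable fractions (defaults 0.54 executive / 0.46 memory / 0.49
attention / 0.15 depression, the approximate ratios of a cohort in
which depression worsening is rare), and generates:

* **EEG**: each channel an AR(2) alpha-band oscillator, directed
  coupling entries planted at lag 1 (stability is checked via the
  companion spectral radius and violations are a hard error);
  decliners of a designated domain get their coupling strengths scaled
  — a recoverable connectivity signature. Sessions follow the task
  layout: a 3-minute rest block, then 72 trials per condition
  (learning/recall/recognition) at 2.5 s spacing. Optional artifact
  injection adds steps, high-amplitude excursions and flatlines at
  known times, with a warning when the requested amplitude is below
  the detector's thresholds.
* **MRI**: 83 ellipsoidal parcels on a jittered grid (the packing is
  overlap-free by construction and errors out otherwise). Real atlas
  geometry is irrelevant to the feature math, which only sees
  label-masked statistics. Per-region mean intensity, oriented grating
  texture and voxel noise; decliners get designated regions shrunk
  (volume signature) and their grating contrast shifted (texture
  signature).
* **Neuropsychology**: baseline scores around the norms; decliners
  receive a baseline deficit and a ≥ 1 SD follow-up drop on one
  designated subscale of their domain, while all benign changes stay
  within ±0.5 SD, strictly below the criterion. Each domain's planted
  subscale belongs to no other domain, so planted labels are exact —
  the generator's ground truth provably equals `declineLabels()` of
  its own output.

All randomness flows from one root seed through a documented linear
congruential expansion (per participant × modality), so identical
specs give bit-identical cohorts.

What the generator does *not* emulate: volume-conducted mixing and
realistic source geometry in EEG, real anatomy and scanner artifacts
in MRI, practice effects and item-level dependence in test scores, and
any correlation between modalities beyond the planted decline effects.
Passing recovery tests therefore demonstrates that the pipeline's
inference machinery is correct and leak-free — not that comparable
accuracy is attainable on clinical data, where effect sizes are
unknown and the noise models above all bite. The synthetic effect
sizes are free parameters, not estimates of any study's.

# Numerical choices and degenerate inputs

* Companion spectral radius ≥ 1: simulation and generation stop with
  an explicit stability error, never silent divergence.
* Constant channels make the lattice recursion rank-deficient; the fit
  aborts naming the offending channel.
* Singular cross-spectra in partial coherence are ridge-regularized
  with a logged epsilon; singular $\bar A(f)$ reports the frequency.
* The GGD moment equation is solved on β ∈ [0.05, 20]; moment ratios
  outside the solvable range return the boundary with a flag, and
  all-equal samples are an error.
* Feature standardization guards zero-variance columns (unit divisor).
* Greedy selection ties break to the lower column index; participant
  fold assignment deals shuffled class members round-robin.

# Problem sizes used by the tests and the acceptance script

The shipped verification uses deliberately small instances chosen to
exercise every contract while keeping the whole suite fast: spectral
oracle agreement on bivariate AR systems at 10^5 samples (compared in
the 8–13 Hz resonant band, where the normalized measures are of order
1 and agreement in the third significant digit is a meaningful
criterion); LBP equality against a brute-force per-voxel oracle on
volumes up to 16³; GGD recovery at 10^5 coefficients for shapes 0.75,
1, 2, 4; artifact-detector recall on ~25 injected events over five
1-minute recordings; 100 seeded nested-CV runs on a 12-participant
table for the leakage count; and planted-effect recovery on a
50-participant cohort with a 2.5 SD baseline deficit. Full-scale
cohorts (default group sizes, 3-minute rest, 72 trials) run with the
same code paths and are exercised piecewise in the unit tests.

# Known limitations

* The supplementary description of the original selection algorithm is
  not public; greedy forward selection with inner-CV balanced accuracy
  is this package's documented reading of "feature subset selection
  with a cap of 30".
* Printed clinical accuracies depend on the unavailable cohort and are
  out of scope; the package verifies machinery, not clinical effect
  sizes.
* MVAR connectivity is sensor-space; volume conduction inflates
  zero-lag symmetric measures (one reason imaginary coherence is in
  the measure set). Source-space analysis is out of scope.
* The atlas registration/label-fusion chain that produces real labeled
  volumes is an external-tool pipeline and out of scope; the package
  consumes its output format (co-registered intensity + label NIfTI).
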