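---
title: "Methods behind imepipe: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind imepipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`imepipe` packages the four quantitative readouts of a chronic
intracortical microelectrode (IME) study with systemic nanoparticle drug
delivery: (1) single-unit electrophysiology quality control and metrics,
(2) active-electrode-yield (AEY) statistics across treatment arms and
study phases, (3) concentric-ring immunohistochemistry quantification
around the implant site, and (4) nanoparticle drug chemistry
(encapsulation efficiency and in vitro release kinetics). Because the in
vivo raw data cannot be regenerated at a desk, every stage is paired with
a synthetic-data generator with known ground truth; the test suite and
the acceptance script run the full chains against those generators.

This vignette records the models, the tunable parameters and the design
decisions that were genuinely open, in enough detail that a maintainer
can judge what passing tests do and do not establish.

## 1. Electrophysiology stage

### Signal model of the generator

A recording block is `n_channels x samples` in microvolts at
24.414 kHz, the acquisition rate of the emulated hardware, whose
300-3000 Hz acquisition band-pass is treated as part of the signal
model: generated noise is Gaussian (optionally mixed with a 1/f
component, default 30% of variance) and then band-passed with a
zero-phase 4th-order Butterworth (2nd order run forward and backward).
The default pre-filter noise sigma of 12 uV leaves an in-band RMS near
5 uV, typical of good chronic cortical recordings.

Spikes are negative-leading biphasic templates of 1.6 ms (three shape
variants differing in the repolarisation lobe), inserted at
gamma(shape 2) interspike intervals with a hard 1.5 ms refractory floor
whose mean equals the unit's nominal rate. Defaults place six units of
80-140 uV on a 16-channel probe at 4-12 Hz.

Two artifact classes are generated. Over-range artifacts are
single-channel deflections of 550-900 uV, beyond the +/-500 uV
physiological limit. Coincident motion artifacts are wave packets (one
2.5 kHz cycle, in-band) hitting 15 or 16 channels within 0.2 ms at
250-400 uV with *balanced random polarity* across channels. The polarity
choice is deliberate: a motion artifact modelled as an identical
common-mode waveform would be annihilated by the common-median reference
(and mirrored onto non-hit channels), leaving nothing for the
coincidence rule to do; with balanced polarity the across-channel median
stays near zero, the artifact survives referencing, and — as in the
emulated analysis chain — it is the "more than 14 channels in a short
window" rule that removes it.

### Analysis chain

The pipeline order is fixed: common-median reference, per-channel mean
subtraction, robust-sigma threshold detection, over-range rejection,
coincidence rejection, waveform extraction, PCA/k-means unit isolation,
amplitude validation, per-channel metrics.

* **Robust sigma.** The detection threshold is `-4 * sigma` with
  `sigma = median(|x|) / 0.6745` of the referenced, mean-subtracted
  trace. The sigma estimator of the original proprietary software is not
  recoverable; the MAD estimator is the standard spike-robust choice.
* **Detection.** One event per maximal sub-threshold run, at its most
  negative sample; 1 ms lockout. Only negative-going crossings are
  detected, matching the negative threshold convention.
* **Artifact rules.** Events with |peak| strictly greater than 500 uV
  are over-range. Any window of 0.5 ms total width containing events on
  more than 14 distinct channels is a motion artifact and all its events
  are removed. Both rules are pure filters, so their order does not
  change the surviving set (asserted in tests).
* **Waveforms and sorting.** Snippets of 0.6 ms before / 1.8 ms after
  the peak are projected onto two principal components; k-means is
  scanned over k = 1..5 with a fixed internal seed and k chosen by mean
  silhouette, with k = 1 forced below 8 snippets or when no k reaches a
  silhouette of 0.5. This is a reproducible, deterministic stand-in for
  interactive cluster scanning.
* **Validation.** Units with mean-waveform Vpp below 40 uV are
  non-putative and dropped (exactly 40 is kept). There is no manual
  verification step: the deterministic rules are the whole QC. A
  consequence worth knowing: at a threshold of exactly -4 sigma,
  Gaussian noise alone produces tens of sub-40-uV threshold crossings
  per channel; these form low-amplitude clusters that the validation
  rule removes. Detection accuracy statements in the tests (recall and
  precision at least 0.9 for units of at least 8 sigma) therefore refer
  to the spikes of validated units, the pipeline's actual output.
* **Noise and metrics.** Noise is the RMS of the trace with +/-1.2 ms
  around every detected event excised. Per unit, SNR = Vpp / noise RMS
  and spike rate = 1 / median(ISI) (undefined below two spikes). Channel
  metrics average over that channel's validated units; a channel is
  active when it has at least one.
* **ROUT outlier removal.** Unit SNRs are pooled — per recording by
  default, or per cohort/phase pool when the caller assembles one, which
  matches how such pools are reported — and filtered by the ROUT recipe:
  median centre, robust scale RSDR (68.27th percentile of absolute
  residuals times N/(N-1)), t-distributed residual p-values with N-1
  degrees of freedom, and a Benjamini-Hochberg-style pass at Q = 5%
  flagging the largest residuals first. On a null Gaussian sample the
  false-flag fraction stays near or below Q (asserted by simulation).
  In practice ROUT is what removes rare units whose waveform windows
  were contaminated by an adjacent artifact.

## 2. Yield statistics

The study table records, for every (arm, animal, channel, week), whether
the channel carried at least one validated unit. Channels malfunctioning
from the outset and channels never active across the whole study are
excluded from every denominator ("viable" channels); "never active" is
judged over the entire record, not per phase, matching the reported
bookkeeping (e.g. 7 animals x 16 channels = 112, minus exclusions,
giving weekly Ns like 107). Weekly AEY is active / viable; a phase pools
channel-weeks (107 viable x 4 weeks = 428). The phase decline is
`100 (p1 - p2) / p1`.

Arm comparisons use the pooled two-proportion z-test without continuity
correction (the conventional default at these sample sizes); `z^2`
equals the uncorrected chi-square statistic, which the tests use as an
independent oracle, plus an exhaustive binomial enumeration at n = 5
with a documented approximation bound. Mixed-effects models and
ANOVA/post-hoc chains are deliberately not re-implemented: the pipeline
exports tidy CSVs for standard statistics tools.

The study generator draws weekly activity as Bernoulli with a single
linear weekly trend per arm whose phase means equal the arm's two
configured probabilities — the simplest trajectory consistent with
phase-aggregate reporting. The arm defaults (0.610/0.5063, 0.520/0.390,
0.450/0.2835, 0.470/0.2162 for 7/7/7/8 animals, 4.5% dead channels) are
two-point calibrations to the published phase declines (17/25/37/54%)
and relative statements (36% and 82% advantages of the treated arm);
per-week probabilities are not published, so these are calibrated, not
measured. With 4.5% dead channels, 7 x 16 = 112 channels yield ~107
viable ones, reproducing the printed weekly N.

## 3. Histology quantification

Rings are 50 um annuli of Euclidean distance from the *edge* of the
implant hole (not its centroid), computed by an exact distance transform
of the hole complement; bins are half-open, `[0,50) ... [600,650)`, and
pixels at 650 um or beyond are unlabeled. The 600-650 um ring is the
background bin: far enough to be healthy tissue. Intensity profiles are
per-ring means over non-artifact pixels, normalized as
`mean / mean_bg - (1 - f)` with marker factor f = 1 for the astrocyte
marker (present in healthy tissue) and f = 0 for activated-microglia and
IgG markers (absent from healthy tissue), so the background bin maps to
exactly f. Neuron density divides per-ring counts by usable ring area;
artifact-masked pixels are excluded from both the counts and the area
denominator (the alternative — excluding them from counts only — would
bias density low wherever artifacts occur; the published description
does not say which was done).

Neuron centroids come from a deterministic Laplacian-of-Gaussian blob
detector at the soma scale (Gaussian smoothing at sigma = soma radius/2,
negative discrete Laplacian, local maxima above median + 6 MAD of the
response). Masked regions are filled with the background median before
filtering so the hole rim and saturated artifact patches do not ring
through the filter — without this, rim responses masquerade as a dense
ring of false somata in the first bin. Learned segmentation (the
published workflow used a trained Cellpose model) is intentionally not
embedded; externally produced centroid CSVs are accepted equivalently,
so the density arithmetic is identical whichever detector produced the
points.

The NeuN generator renders a Poisson point process whose density follows
a per-ring step profile — the step form makes the per-ring expected
density equal the configured value exactly, avoiding discretization bias
in calibration-recovery tests. Defaults: 800 neurons/mm^2 background
(typical of NeuN counts in 20 um rat cortical sections), near-hole
retention 59% (treated arm) or 21% (vehicle arm) rising linearly to
background at 600 um, 200 um hole radius, 0.65 um/px, somata as 2 um
Gaussian blobs of amplitude 3000 over a background of 500 with noise
sigma 100 (16-bit range). At these settings the 0-50 um ring holds only
~20-35 neurons per image, so single-image normalized densities carry
~15-20% relative noise; recovery tests therefore average 10-24 images.
What these tests show is that ring geometry, masking, counting and
normalization are unbiased at realistic densities — not that the
detector would match a trained segmenter on real stained tissue
(overlapping somata, staining gradients and out-of-focus light are not
modelled).

## 4. Release chemistry

Encapsulation efficiency is `100 (total - unencapsulated) / total`. The
unencapsulated mass is quantified by internal-standard HPLC calibration:
ordinary least squares of peak-area ratios on concentration ratios,
inverted at the unknown's area ratio and scaled by the internal-standard
concentration; negative inversions clip to zero with a warning. The
batch generator draws true EE from N(78.7, 5.5) truncated to [0, 100]
(7 batches by default, 4 mg load), a detector line with 2% multiplicative
noise, and standards spanning the unknowns.

The release assay emulates the dialysis-membrane method: a device in a
14 mL bath; at each sample time 1 mL is withdrawn for quantification and
replaced with blank buffer. Released mass follows the biexponential law
in continuous time between samples, and the withdrawn drug is tracked
exactly, which makes total mass conservation exact (asserted to 1e-9
relative). The withdrawal-corrected reconstruction
`released_i = C_i V_bath + sum_(j<i) C_j V_aliquot` is the package's
second, independent implementation of the same mass balance; the two
agreeing to 1e-6 is a deliberate cross-check. Whether the original
analysis applied this correction is not stated; the corrected formula is
the default and the uncorrected variant is simply the first term.

Default kinetics `F(t) = 0.62 (1 - e^{-3.78 t}) + 0.38 (1 - e^{-0.1227 t})`
(t in days) are the unique two-point solution through the published
anchors, 65% released at 1 day and 98% at 24 days. Fitting uses
Levenberg-Marquardt least squares on fractions (no weighting scheme is
published), initialized from the log-linear tail slope; a fit collapsing
to a single exponential is returned with the burst fraction near 1 and
the sustained rate clamped just below the burst rate to keep the
parameter invariants.

## 5. Reproducibility and problem sizes

Every generator takes an explicit seed and evaluates under an isolated
RNG scope; identical configuration and seed give bit-identical output.
The end-to-end runner fans one seed out to per-stage child seeds by
fixed offsets, so any stage can be re-run alone and reproduce its part.

Problem sizes are chosen to make sampling error comfortably smaller than
the tolerances they are tested against: 10 s recordings with six units
(hundreds of spikes per unit cluster), 20 simulated studies for phase
declines (per-study standard error ~5 percentage points, so the mean is
good to ~1), 20 HPLC replicates of 7 batches, and 10-24 NeuN images per
arm (per-image bin-0 noise ~0.1, so the mean is good to ~0.03). The
acceptance script prints each quantity with the problem size used.

## 6. Known limitations

* The synthetic recordings contain no electrode impedance drift, no
  unit waveform drift, no bursting, and artifacts of only two stylized
  classes; detection figures on them bound the pipeline's bookkeeping,
  not its performance on real tissue.
* Spike sorting is per-channel; no cross-channel (stereotrode-style)
  sorting.
* The activity generator treats channels independently; real probes
  show within-animal correlation, so simulated confidence intervals are
  narrower than in vivo ones.
* The hole detector assumes a dark, roughly convex hole well inside the
  image; anything else deserves a manual mask (always honoured).
* Proprietary acquisition formats are out of scope; recordings exchange
  as flat float32 + JSON sidecar.
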