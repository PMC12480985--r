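# imepipe

Analysis pipeline for chronic intracortical microelectrode (IME)
studies with nanoparticle drug delivery.

Chronic IMEs lose recording performance over weeks as neuroinflammation
degrades the electrode-tissue interface. Studies that test
anti-inflammatory interventions against this decline lean on four
quantitative readouts, and `imepipe` implements all four as one tested,
reusable pipeline for electrophysiologists and quantitative histologists:

1. **Single-unit electrophysiology QC and metrics** — common-median
   referencing, spike detection at a −4σ robust threshold
   (σ = median(|x|)/0.6745), rejection of over-range events
   (|peak| > 500 µV) and of motion artifacts (events on >14 channels
   within 0.5 ms), PCA + k-means unit isolation with silhouette model
   selection, validation (Vpp ≥ 40 µV), and per-channel Vpp, noise RMS,
   SNR = Vpp/noise and spike rate = 1/median(ISI), with ROUT outlier
   removal (FDR Q = 5%) on pooled unit SNRs.
2. **Active electrode yield (AEY)** — per-week and per-phase proportions
   of active channels over viable channels (dead-from-outset and
   never-active channels excluded), phase declines
   100·(p₁ − p₂)/p₁, and pooled two-proportion z-tests.
3. **Concentric-ring histology** — 50 µm distance-transform annuli from
   the implant-hole edge out to 650 µm, per-ring marker intensity with
   artifact masking, normalization to the 600–650 µm background bin
   (factor 1 for GFAP, 0 for CD68/IgG), blob-based neuron counting and
   neuron density per mm² normalized to background.
4. **Release chemistry** — internal-standard HPLC calibration and
   encapsulation efficiency EE = 100·(total − unencapsulated)/total,
   withdrawal-corrected cumulative release from a dialysis sink
   (released(tᵢ) = Cᵢ·V_bath + Σ_{j<i} Cⱼ·V_aliquot), and biexponential
   kinetics F(t) = f·(1 − e^{−k_b t}) + (1 − f)·(1 − e^{−k_s t}).

A synthetic-data module generates every input with known ground truth —
multichannel recordings with spikes and artifacts, 8-week 4-arm study
tables, implant-site NeuN/CD68/GFAP/IgG images, and HPLC/release
measurements — so the full pipeline is testable end to end without any
external data.

## Worked example

```r
library(imepipe)

# -- release kinetics: simulate a dialysis assay, reconstruct, fit
rel <- gen_release(release_truth(seed = 1))
fit <- fit_biexponential(rel$t_days, rel$cumulative_fraction)
fit
#> <biexp_params> f_burst = 0.617, k_burst = 3.699 /d, k_sustained = 0.133 /d
round(100 * eval_release_model(default_release_params(), c(1, 24)))
#> [1] 65 98

# -- encapsulation efficiency over 7 simulated manufacturing batches
batches <- gen_hplc_batches(hplc_batch_config(seed = 1))
round(sapply(batches, function(b) estimate_ee(b)$ee_percent), 1)
#> [1] 74.9 81.8 79.7 82.2 80.6 77.4 77.3

# -- an 8-week, 4-arm study: phase proportions and declines
tab <- gen_study(study_config(seed = 1))
p1 <- phase_proportion(tab, 1:4); p2 <- phase_proportion(tab, 5:8)
data.frame(arm = p1$arm, decline = round(phase_decline(p1$proportion, p2$proportion), 1))
#>          arm decline
#> 1   DEXSPPIN    14.5
#> 2        PIN    31.3
#> 3    DILUENT    34.8
#> 4 Free DEXSP    44.4
two_prop_ztest(p1$n_active[1], p1$n_total[1], p1$n_active[3], p1$n_total[3])
#> two-proportion z-test: p1 = 0.5872, p2 = 0.4951, z = 2.688, p = 0.00719

# -- spike pipeline on a synthetic recording
rec <- gen_recording(recording_config(seed = 1))
out <- ephys_pipeline(rec$block)
head(out$units, 3)
#>   channel cluster_id n_spikes      vpp      snr spike_rate rout_outlier
#> 1       1          1       61 162.2486 32.76308   7.523575        FALSE
#> 2       3          2       79 133.0376 26.39514  10.331782        FALSE
#> 3       5          1       45 174.9159 34.79540   4.831107        FALSE

# -- histology: neuron density vs distance from the implant hole
im  <- gen_ihc_image(default_neun_config("DEXSPPIN", seed = 1))
lab <- ring_labels(im$hole_mask, microns_per_pixel = 0.65)
cent <- detect_centroids(im$image, 0.65, hole_mask = im$hole_mask,
                         artifact_mask = im$artifact_mask)
prof <- density_profile(cent, lab, artifact_mask = im$artifact_mask)
round(prof$normalized[c(1, 13)], 2)   # 0-50 um ring vs background ring
#> [1] 0.79 1.00
```

Interpretation: the single-seed study above shows a 14.5% early-to-late
decline for the treated arm versus 44.4% for free drug (the generator's
calibrated means are 17% and 54%; single studies scatter by ±5 points),
and the z-test confirms the treated arm's early-phase advantage over
vehicle. The recording yields the six ground-truth units with SNR well
above 5; the image recovers a near-hole neuron density around 0.6-0.8 of
background for the treated arm in a single section.

An end-to-end run that writes all tables plus a summary:

```r
run_end_to_end(NULL, outdir = "out", seed = 1)
```

or from the shell: `exec/imepipe reproduce --seed 1 --out out`.

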