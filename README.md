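# sodiumAT — quantitative sodium MRI of the Achilles tendon

Sodium (²³Na) MRI probes the glycosaminoglycan content of tendon
tissue, because negatively charged GAG chains bind Na⁺ ions. Raw ²³Na
signal-to-noise ratios are hard to compare across coils and sequences,
so the quantity of interest is the **apparent tissue sodium
concentration (aTSC)**: the concentration inferred from the image after
calibration against reference vials and correction for coil
sensitivity, relaxation weighting and partial volume. This package
implements that full analysis chain for the Achilles tendon — together
with the ²³Na relaxometry needed to drive it — and a synthetic
digital-phantom study generator with ground truth for end-to-end
validation. It is aimed at researchers developing or auditing X-nucleus
quantification pipelines.

## The models at the core

ROI-mean ²³Na relaxometry uses the saturation-recovery law and, because
²³Na is a spin-3/2 nucleus, a biexponential transverse decay:

    S(TR) = S0 · (1 − exp(−TR/T1)) + offset
    S(TE) = S0 · (ps·exp(−TE/T2s*) + (1−ps)·exp(−TE/T2l*)) + offset,  0 < ps < 1

fitted by bounded Levenberg–Marquardt with deterministic multi-starts.
aTSC on the quantification scan (TR 15 ms, TE 0.1 ms) is assembled per
voxel as

    aTSC = (S − intercept)/slope · f_phantom/f_tissue · 1/⟨tendon fraction⟩

with the calibration line from four vials (50/75/100/125 mM), the
relaxation-weighting factor
`f = (1−exp(−TR/T1))·(ps·exp(−TE/T2s*)+(1−ps)·exp(−TE/T2l*))`
evaluated per region, and the mean fraction of high-resolution tendon
voxels per 2 mm sodium voxel. SNR is the tendon ROI mean divided by the
SD of a dedicated noise region. Regional INS/MID/MTJ differences are
tested with a Friedman gate followed by Bonferroni-corrected paired
Wilcoxon tests.

With block-average downsampling, uniform sensitivity, zero-signal
surroundings and no noise, the whole chain returns the generating
concentration *exactly* — the package's central self-consistency
property, enforced by tests for arbitrary tendon placements.

## Worked example

A complete synthetic subject at the default study conditions
(180 mm FOV, 2 mm ²³Na voxels, true whole-tendon SNR 11.7, surface-coil
falloff field):

```r
library(sodiumAT)

study <- generate_study(phantom_spec(seed = 1))
smap  <- estimate_sensitivity_map(study$volumes$sensitivity)
p3c   <- apply_sensitivity_correction(study$volumes$p3, smap)

calib <- fit_calibration(vial_roi_means(p3c, study$fine_mask),
                         study$config$vial_concentrations_mM)
quant <- compute_atsc(p3c, calib, study$fine_mask)
quant$table[, c("roi", "atsc_mM", "atsc_rel_sd_pct", "pv_fraction")]
```

prints (seed 1):

```
    roi   atsc_mM atsc_rel_sd_pct pv_fraction
1   INS 113.98707        27.50096   0.8461538
2   MID  78.34124        28.04884   0.8461538
3   MTJ  57.39889        32.46564   0.8461538
4 Total  85.37374        44.82587   0.8461538
```

The generating concentrations were 112.9 / 77.3 / 55.3 mM: the chain
recovers each region to within ~2 mM at protocol noise, the mean tendon
fraction shows the ~15% partial-volume dilution being corrected, and
the within-ROI SD lands near the ~28% reported in vivo. The same
objects feed the relaxometry fits (`roi_mean_series()` +
`fit_t1_saturation_recovery()` / `fit_t2star_biexponential()`) and the
SNR estimator (`compute_snr()`).

The `analysis/` directory holds the full study as numbered drivers —
`01_simulate.R` through `05_cohort_stats.R` (simulation, preprocessing,
relaxometry, quantification, ten-subject cohort statistics) — each
writing its tables under `results/`.

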