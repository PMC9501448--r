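---
title: "Quantitative sodium MRI of the Achilles tendon: models, corrections and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative sodium MRI of the Achilles tendon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

The sodium content of tendon tissue tracks its glycosaminoglycan (GAG)
density, because the negatively charged GAG side chains attract Na⁺
ions. ²³Na MRI can therefore probe the biochemical state of the
Achilles tendon before morphological changes appear. The raw ²³Na
signal-to-noise ratio, however, depends on coil, sequence and scanner,
so the quantity of interest is the *apparent tissue sodium
concentration* (aTSC): the tissue concentration inferred from the image
after calibrating against reference vials of known concentration and
correcting for everything that biases the tissue-to-vial signal ratio.
"Apparent" flags what remains uncorrected — possible MR-invisible
sodium pools and residual quadrupolar effects.

Three acquisitions feed the analysis (all with an ultrashort-TE 3-D
radial sequence on a dual-tuned ¹H/²³Na surface coil, modelled here in
image space):

* **Protocol 1** — five repetition times TR ∈ {8, 9, 10, 15, 25} ms at
  TE = 0.1 ms, for T1.
* **Protocol 2** — twelve echo times (three interleaved four-echo runs:
  0.1–21.3 ms) at TR = 30 ms, for the biexponential T2*.
* **Protocol 3** — TR = 15 ms, TE = 0.1 ms, for SNR and aTSC, plus a
  four-echo ¹H acquisition (0.1/3/6/9 ms) for voxel-wise ¹H T2*.

## Signal models

Longitudinal recovery under repeated 90° excitation follows the
saturation-recovery law, fitted on ROI-mean signals:

$$S(\mathrm{TR}) = S_0\,\bigl(1 - e^{-\mathrm{TR}/T_1}\bigr) + \text{offset}.$$

Because ²³Na is a spin-3/2 nucleus, its transverse decay in ordered
tissue is biexponential, with a short component \(T_{2s}^*\) from the
satellite transitions and a long component \(T_{2l}^*\) from the
central transition:

$$S(\mathrm{TE}) = S_0\,\bigl(p_s\,e^{-\mathrm{TE}/T_{2s}^*}
  + (1-p_s)\,e^{-\mathrm{TE}/T_{2l}^*}\bigr) + \text{offset},
  \qquad 0 < p_s < 1.$$

For a single pool of spin-3/2 nuclei the satellite:central intensity
split is 3:4:3, so \(p_s = 3/5\); agarose vials sit near this value,
tendon tissue well below it. The additive "offset" in both models is a
fitted constant absorbing the noise floor of magnitude images — it is a
free parameter, not a noise distribution. ¹H T2* is mapped voxel-wise
with a monoexponential plus offset.

`fit_t1_saturation_recovery()` and `fit_t2star_biexponential()` use
bounded Levenberg–Marquardt (via `minpack.lm`) with deterministic
multi-starts, so results are exactly reproducible:

* T1: bounds \(S_0 \ge 0\), \(T_1 \in [0.1, 500]\) ms; starts from a
  two-point log estimate plus fixed alternatives at 5/20/50 ms.
* Biexponential: \(0 < p_s < 1\), both components in \([0.05, 200]\)
  ms; five starts (\(p_s \in \{0.3, 0.6\}\) × \(T_{2s} \in \{1, 5\}\)
  ms at \(T_{2l} = 15\) ms, plus a tail-slope data-driven start), best
  SSE wins. The ordering \(T_{2s}^* \le T_{2l}^*\) is restored through
  the model's label symmetry (swap components and \(p_s \to 1-p_s\)),
  which changes nothing about the optimum. Fits whose two components
  coincide within 10⁻³ ms are flagged degenerate: \(p_s\) is then
  unidentifiable and only the common T2* is meaningful.

Fitting ROI means rather than single voxels is deliberate: at
whole-tendon SNR ≈ 12 voxel-wise biexponential fits are unstable, while
ROI means recover all four parameters to ≲10⁻⁴ relative error on
noise-free data (verified as a property test across the valid
parameter space).

## From signal to concentration

aTSC is assembled in three steps on the protocol-3 image, after
coil-sensitivity correction:

1. **Calibration.** The four vial ROI means (50/75/100/125 mM) are
   regressed on concentration by ordinary least squares *with*
   intercept; the intercept absorbs the noise floor, and per-voxel
   `aTSC_raw = (S − intercept)/slope`. Vial ROIs are transferred to the
   sodium grid keeping interior voxels only (inclusion threshold 1),
   emulating manually drawn interior ROIs; rim voxels would dilute the
   slope through partial volume.
2. **Relaxation weighting.** Tissue and vials relax differently, so at
   finite TR and nonzero TE their signals are attenuated by different
   factors
   \(f = (1-e^{-TR/T_1})(p_s e^{-TE/T_{2s}^*} + (1-p_s)e^{-TE/T_{2l}^*})\in(0,1]\).
   Each voxel's raw concentration is multiplied by
   \(f_\text{phantom}/f_\text{tissue}\), with region-specific tissue
   factors (INS/MID/MTJ reference means; the pooled row for the whole
   tendon) and one pooled phantom factor, mirroring the averaging the
   in-vivo study applied across vials and participants.
3. **Partial volume.** The ¹H-resolution tendon mask is counted into
   each 2 mm sodium voxel; voxels with a tendon fraction ≥ 0.5 form the
   sodium-grid ROI, and the ROI-mean fraction divides the aTSC. Signal
   mean and fraction mean always use the same ROI, which is what makes
   the chain exactly invertible (below).

SNR is the ROI mean of the raw protocol-3 image divided by the unbiased
SD of a dedicated signal-free noise region (≥ 3000 sodium voxels in the
default phantom); both numerator and denominator live on the same raw
scale, so SNR is computed before sensitivity correction.

## The synthetic study generator

No public dataset accompanies the in-vivo study, so the package ships a
digital phantom whose defaults *are* the study conditions: 180 mm³ FOV,
1 mm ¹H and 2 mm ²³Na grids; a 90 mm tendon tube of radius 4 mm split
into three 30 mm segments with the reported control concentrations
(INS 112.9, MID 77.3, MTJ 55.3 mM) and region relaxation values;
four agarose-like vials (r = 5 mm, h = 35 mm) at 50–125 mM sharing the
pooled phantom relaxation; a 30 mm cubic noise box; signal scale
1 a.u./mM. The tendon axis is deliberately placed off the sodium-grid
lattice so its rim spans fractional voxels, as in vivo — the resulting
ROI-mean tendon fraction is ≈ 0.85, and the within-ROI aTSC SD lands
near the ~28% the in-vivo study reports.

Rendering composes: closed-form relaxation-weighted signal per
compartment → multiplicative coil-sensitivity field → optional
integer-voxel motion shift → downsampling to the sodium grid →
additive noise. Choices worth knowing:

* **Sensitivity** defaults to an exponential falloff
  \(e^{-z/100\,\text{mm}}\) from the coil face at the distal end of the
  slice axis. The real coil's field is unpublished; this surrogate is
  smooth, invertible and produces the INS > MID > MTJ SNR gradient seen
  in vivo. The homogeneous 154 mM calibration scan is emulated as a
  full-FOV phantom (the physical study tiled several phantoms around
  the coil), measured with 20 averages.
* **Noise** defaults to additive Gaussian, consistent with the fitted
  additive offset in both signal equations; a Rician option emulates
  magnitude images. The noise level is set through the *true SNR*
  rule: σ = (noise-free protocol-3 tendon ROI mean)/11.7, the
  whole-tendon control value, and this identity is exact by
  construction before any noise is drawn.
* **Downsampling** defaults to block averaging (the mean of the 2³ fine
  voxels in each sodium voxel); a Gaussian-PSF mode smooths before
  averaging for robustness experiments. Under block averaging, zero
  surroundings, uniform sensitivity and no noise, ROI-mean signal
  equals slope · C · f_tissue/f_phantom-consistent weighting · mean
  fraction *identically*, so the full aTSC chain returns the generating
  concentration exactly for any tube placement — the package's central
  self-consistency property, tested for random placements and enforced
  end-to-end.
* **Skin** (reported TSC 30–60 mM, directly abutting the tendon) is
  available as an optional shell but off by default: with it on, the
  exact-inversion property intentionally breaks, quantifying how
  neighbouring signal biases aTSC.
* **Motion** is integer-voxel translation only, matching the
  translation-only registration; per-acquisition seeds derive from the
  study seed by position in the manifest, so any single volume is
  reproducible in isolation.

What the generator does **not** emulate: radial k-space acquisition,
gridding and Hann-filter point-spread functions, B0/B1 inhomogeneity,
residual quadrupolar line shapes, physiological texture inside
compartments, and sub-voxel motion. Passing tests therefore validate
the *analysis chain* — they do not certify accuracy on scanner data,
where those effects add bias the chain cannot see.

## Preprocessing choices

The sensitivity map is the homogeneous scan smoothed with a 6 mm FWHM
Gaussian (mask-renormalised separable kernel: constants are preserved
exactly and edges are not darkened), normalised by its maximum; voxels
below 5% of the maximum are invalid, become `NA` after division and
are excluded — and counted — in every downstream ROI statistic. How
the original study turned its sensitivity measurements into a
correction is not stated; voxel-wise division by the smoothed,
normalised map is this package's choice, the simplest one consistent
with a multiplicative reception field.

Registration searches integer shifts in a ±2 voxel window maximising
normalised cross-correlation over the overlap, ties broken by smaller
magnitude then lexicographic order. It is exact for all integer shifts
on noise-free renders and ≥ 95% exact at protocol SNR (property test
over 100 seeded trials). Correlations below 0.1 raise a warning: a
sparse tendon in a mostly empty FOV yields modest global correlations
(~0.2) even when alignment is exact, while pure-noise pairs stay below
~0.07 on the grids used here.

## Regional statistics

Per parameter (aTSC, SNR, ¹H T2*, and their within-ROI SD%), the three
regions are compared with a Friedman test across subjects; only when
its p < 0.05 are the three paired Wilcoxon signed-rank tests (INS–MID,
INS–MTJ, MID–MTJ) run, their two-sided p-values multiplied by three
(Bonferroni, capped at 1). The in-vivo report calls these "rank-sum"
tests, but the design is paired — the same subjects contribute all
three regions — and the printed uniform 0.015 is exactly the
asymptotic paired signed-rank value for n = 10 same-sign differences
without continuity correction (2 × Φ(−2.803) × 3). The package
therefore defaults to the paired test with the normal approximation and
no continuity correction, and offers the exact distribution behind a
flag; for fully tied tables the statistic is defined as 0 and p = 1.
At n = 6 the normal approximation stays within 0.1 of the exact
sign-enumeration null over every attainable statistic, the bound the
tests document.

## Degenerate inputs and numerical conventions

Constant fit series set a degenerate flag instead of returning
parameters; empty ROIs after exclusions raise errors rather than
silent `NaN`s; negative per-voxel concentrations (noise) are kept —
they average out — but tallied in QC; all SDs use the unbiased n−1
estimator; R² is computed against the sample-mean baseline including
the fitted offset; tendon segmentation uses half-open 30 mm runs from
the most distal occupied slice, leaving any remainder beyond 90 mm
unlabelled, and refuses tendons shorter than three segments naming the
available length; mask transfer labels a coarse voxel at fraction ≥
threshold (boundary included), ties going to the more distal segment.

## Problem sizes

The shipped analysis scripts run the full default geometry (180³ mm,
5.8 M fine voxels, 23 volumes per study; a ten-subject cohort in
roughly ten minutes). The test suite exercises identical code paths on
reduced fields of view (72 × 72 × 120 mm and 48 × 48 × 96 mm) with the
same voxel sizes, concentrations, relaxation values and true SNR, which
keeps the full suite at a few minutes; the cohort-significance property
runs 50 seeded ten-subject cohorts at protocol noise on the compact
geometry. The acceptance script uses the full default geometry.

## Known limitations

Beyond the generator's idealisations listed above: the relaxation
correction assumes one relaxation quadruple per region (diseased tissue
may differ, biasing patient aTSC); the partial-volume correction cannot
remove signal *added* by neighbouring structures, only dilution by
signal-free ones — this includes tendon tissue extending beyond the
labelled 9 cm, whose signal biases boundary voxels of the proximal
segment, so the exact-inversion property holds only when the segment
partition covers the whole tube; translation registration cannot capture rotation or
deformation; and absolute validation of aTSC against chemical analysis
is outside what any simulation can provide.
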