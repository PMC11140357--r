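---
title: "Quantifying donor chimerism from STR-PAGE gels"
author: "strchim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying donor chimerism from STR-PAGE gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strchim)
```

## The measurement

After an allogeneic haematopoietic stem cell transplant the recipient's
blood should be repopulated by donor-derived cells. Reappearing
recipient-derived cells (decreasing donor chimerism) can precede graft
failure or relapse, so chimerism is monitored serially. The gel-based
measurement works in three steps:

1. **Informative locus.** Donor and recipient (usually siblings) are typed
   at a panel of autosomal STR loci. A locus is *informative* when at least
   one allele is exclusive to one of them; quantifying returning recipient
   tissue additionally requires a *recipient*-exclusive allele, since that
   band is the recipient-specific signal. `classify_alleles()` partitions the
   two genotypes' allele union into recipient-exclusive, donor-exclusive and
   shared sets; both an `informative` flag (either direction, the symmetric
   reading) and a `fully_informative` flag (both directions) are exposed so
   either convention can be applied.
2. **Densitometry.** The post-transplant sample is amplified at the chosen
   locus, separated on polyacrylamide (migration distance is approximately
   linear in `log10` fragment size), silver-stained and photographed. Each
   lane is reduced to a 1D intensity profile and its peaks are integrated.
3. **Chimerism.** In simple-complement mode the recipient percentage is the
   recipient-exclusive peaks' share of all labelled peak area at the locus,
   and donor% = 100 − recipient%. This denominator — shared plus both
   exclusive classes — is the only reading consistent with worked two-band
   (60.6/39.4) and three-band (79.4/20.6) gel evaluations, where the
   reported percentages sum to 100 over all visible peaks. No dosage
   correction is applied to shared bands carrying two donor copies; the
   paired-informative mode (`donor_chimerism_paired()`), which uses only
   exclusive peaks and can divide areas by allele copy number, is provided
   for cross-checking at fully informative loci.

Multi-locus results can be averaged with `aggregate_chimerism()` (unweighted
mean, per-locus values always reported); gel practice typically quantifies a
single informative locus per sample, so aggregation is an extension and is
labelled as such in reports.

## Densitometry pipeline and its numerical choices

`quantify_lane()` chains the stages below; each is exported separately.

**Profile extraction** (`extract_lane_profile`). Per-row mean over the
lane's pixel columns (0-based, half-open intervals; row 0 at the wells),
inverted for silver-stain polarity so bands are positive excursions, then
denoised with a 5-sample moving average. The denoiser is linear, so band
areas and their ratios are unaffected; without it, photographic noise
survives lane averaging and produces spurious local maxima on low-contrast
lanes.

**Baseline subtraction** (`subtract_baseline`). The background of a
photographed gel is a smooth, slowly varying gradient. The baseline is a
morphological opening — rolling minimum then rolling maximum, half-width 10
px by default — lightly smoothed, then re-centred on the median of the
residuals. The opening reproduces any background wider than the window
exactly (a linear gradient leaves zero residual, which a plain
rolling-minimum baseline does not), and the median re-centring makes the
baseline pass through the middle of the noise rather than its lower
envelope, so residual noise is zero-centred before clipping at zero. The
window must exceed the band width by a comfortable factor (10 px ≈ 6.7
band sigmas at the default render) or peaks are eroded; peaks narrow
relative to the window are preserved to well within 2% of area.

**Peak detection** (`detect_peaks`). Local maxima (plateau centres) with
topographic prominence at least `min_prominence_frac` (default 0.02) of the
profile's global maximum, separated by at least `min_separation_px`
(default 4 px), numbered from the well downward. The default threshold is
set by the most extreme routine case: a 95:5 two-band lane puts the minor
peak's prominence at ~0.053 of the maximum, so the threshold must sit well
below that while staying above the noise floor. A flat profile yields zero
peaks, not an error.

**Integration** (`integrate_peaks`). Boundaries at the valley (profile
minimum) between adjacent apices; trapezoidal integration on the pixel grid
with half-open intervals and no sub-pixel refinement. Each peak's extent is
additionally capped where the profile falls below 0.2% of that peak's own
height, and at 20 px from the apex: an unbounded interval would otherwise
integrate clipped noise over hundreds of empty pixels and corrupt the area
shares. Because the cap is relative to each peak's height it removes the
same negligible tail fraction from every peak, leaving ratios intact.
`area_percent` is normalized to sum exactly 100 per lane. For bands that
merge, `method = "gaussian"` fits a sum of Gaussians and uses the analytic
component areas instead of the valley split.

**Sizing and labelling** (`calibrate_sizes`, `assign_peak_sizes`,
`match_peaks_to_alleles`). A ladder lane with at least three known fragment
sizes gives a least-squares fit of `position = a − b·log10(size)`; synthetic
scenes may use the renderer's own migration model as an exact calibration.
Peaks are matched to expected allele sizes by nearest distance within half a
repeat unit (±2 bp for tetranucleotide loci), so adjacent STR alleles can
never claim one peak; a peak within tolerance of two expected alleles is an
explicit ambiguity error, and unmatched peaks are labelled `unassigned` and
excluded from the chimerism normalization (whether the original gel software
excluded artifact bands before normalizing is unknowable; this package
normalizes over detected, labelled peaks only).

Degenerate inputs are explicit errors with stage names: locus mismatches,
empty genotype tables, lane indices out of range, baseline windows narrower
than 3 px or wider than the profile, ladders with fewer than three bands or
a band/size count mismatch, peak sets with zero total area.

## The synthetic gel model

`render_gel()` emulates a photographed silver-stained PAGE: dark bands on a
light background. Each band is a 2D Gaussian (sigma 1.5 px along migration,
lane width/6 across) whose integrated intensity is exactly
`amount × amount_gain`; the background is `offset + slope·row`
(default 200 + 0.02/row on the 8-bit scale); noise is additive Gaussian
(default SD 1 intensity unit), clipped to the bit depth — a model of
photographic grain, not photon counting. Rendering is deterministic given
the spec's seed, and every scene returns a ground-truth table (band centre,
integrated area) against which the densitometry chain is validated.

Default geometry: 512-px gel, 24-px lanes, migration
`row = 2183 − 850·log10(size_bp)`, i.e. a usable window of roughly 110–360
bp in which a single-repeat (4 bp) allele difference at ≤250 bp separates
band centres by ≥6 sigma — the resolution STR-PAGE is used for. The source
gels give no resolution or sizing model, so these are documented package
constants, not reproduced values.

`make_chimera_lane()` converts an informative call plus a designed donor
fraction into band amounts: recipient-exclusive bands carry
`1 − donor_fraction` of the lane total (split by recipient allele dosage),
all other bands carry `donor_fraction` (split by combined dosage, so a
homozygous donor renders as one thick band). Ground truth uses raw area with
no dosage correction, matching how such gels are read.

`make_table1_fixture()` generates the 20-pair genotype cohort. The pair ×
locus informativeness incidence is a fixed design (greedy fill with
prescribed margins): per-locus informative counts of 8, 8, 5, 5, 4, 3, 2, 2,
1, 1 out of 20, at least one informative locus per pair, per-pair counts
spanning 1 to 8. The seed randomizes only the genotypes that realize this
design, so different seeds give different allele tables with identical
marginal statistics.

`make_range_cohort()` is a pipeline-throughput check across designed donor
fractions from 13.2% to 98.9%. The extremes put the minor band near the gel
method's ~1% detection limit, so those lanes are rendered as narrow (12 px),
heavily loaded lanes — maximizing band surface density, as a laboratory
would — and quantified with a sensitive prominence threshold (0.005). The
strong band may saturate the 8-bit range there, as overloaded silver stains
do; the resulting bias is small because the saturated band dominates the
denominator. This cohort demonstrates range coverage of the pipeline, not a
reproduction of any patient series.

**What the simulation does not model:** PCR stutter and heteroduplex bands,
gel smile/curvature, lane-boundary drift, staining saturation
nonlinearity (other than clipping), and inter-gel variability. Passing the
test suite therefore shows the image-analysis arithmetic is correct under a
faithful but idealized gel model; it does not certify performance on
degraded real-world gels, where stutter in particular biases STR
quantification.

## Problem sizes and test design

The validation suite runs entirely on synthesized data: 512 × 36 px
single-lane scenes; the mixture-recovery study uses designed donor fractions
{5, 10, 25, 50, 75, 90, 95}% × 20 seeds at the default noise level and
requires recovery within ±2 percentage points end to end; allele
classification is checked against a brute-force membership oracle over all
66² genotype pairs on alleles {8..18}; ladder calibration must recover the
generative migration coefficients to 1 part in 10³ on noise-free renders.
The worked two-band and three-band scenes must reproduce their designed
60.6% and 79.4% donor percentages within 0.5 points through the full
image-to-report chain.

## Known limitations

* Lane geometry is declared in configuration, not detected from the image.
* The valley rule misallocates area when bands overlap heavily (closer than
  ~4 band sigmas); the Gaussian-fit option mitigates but is not the default.
* Fragment sizing assumes log-linear migration; strongly curved gels need a
  ladder on the same gel, and accuracy beyond ~1 bp is not attempted.
* The "complete chimerism" flag threshold (donor ≥ 95%) is a reporting
  convention, configurable and not derived from any measured quantity.
* Chimerism below a few percent of recipient signal is at the method's
  detection limit; capillary electrophoresis or qPCR-based assays are the
  appropriate tools there.
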