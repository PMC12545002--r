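---
title: "Wash-in parametric imaging for CEUS: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wash-in parametric imaging for CEUS: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ticmapr)
```

## The problem

Contrast-enhanced ultrasound (CEUS) of the prostate records the transit of a
microbubble bolus through the gland as a cineloop: a stack of intensity
frames over two minutes or more. Conventional quantitative CEUS places one
hand-drawn region of interest and summarises its time-intensity curve (TIC),
which is both subjective and blind to spatial heterogeneity — the hallmark
of tumour angiogenesis. `ticmapr` instead computes a TIC for *every pixel*
inside a whole-gland ROI, reduces each TIC to a single wash-in parameter,
and renders the result as a colour-coded parametric map whose spatial
pattern is then graded automatically.

## The wash-in parameter

For a pixel trace \(y(t)\) the package detects three landmarks on a smoothed
copy of the trace:

* **baseline** \(b\): the mean of the first \(\max(3, \lceil 0.05\,n\rceil)\)
  samples. Start detection needs a baseline and the baseline window should
  precede the start; this initial-window rule breaks the circularity in one
  pass and is recomputed against nothing further (a second pass moves the
  estimate by less than the sampling interval on bolus-shaped curves).
* **peak** \((t_{pk}, y_{pk})\): the earliest global maximum of the smoothed
  trace. Earliest, because wash-in semantics make the first attainment of
  the maximum the end of the rising phase. A maximum on the final frame
  means washout was never observed; the pixel is flagged `censored_peak`
  and excluded from the map rather than silently extrapolated.
* **enhancement start** \(t_s\): the first time the smoothed trace crosses
  \(b + f\,(y_{pk} - b)\), linearly interpolated between samples. The
  threshold is a *fraction* \(f\) of peak enhancement (default 0.05) rather
  than an absolute intensity, so it is invariant to gain.

The headline parameter is the **mean gradient to peak** — the average slope
of the TIC over the wash-in phase. Because the mean of a derivative over an
interval is the endpoint difference over the interval length,

\[
\mathrm{MGP} \;=\; \frac{y_{pk} - y(t_s)}{t_{pk} - t_s},
\]

in intensity units per second. The lower endpoint is configurable
(`gradient_from`): the default uses the threshold-crossing intensity
\(y(t_s)\), reading "from the start of enhancement" literally; the
alternative uses the baseline. Whether vendor software anchors at the
crossing or the baseline is generally undocumented, so both are exposed.
Pixels whose total enhancement does not exceed `noise_floor` are flagged
`no_enhancement`; values are finite exactly on the ok-quality in-ROI set.

The pipeline assumes intensities linear in microbubble concentration
(echo power). If an export is log-compressed, `meta$log_compressed` triggers
\(I \mapsto 10^{I/k}\) (`delinearize()`, \(k = 10\) by default) before
analysis; nothing in the chain can detect compression on its own, so the
flag is an explicit part of the data contract.

### Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `smooth_window` | 5 | frames | centred moving average; shortest window that tames speckle without displacing a bolus peak by more than half a window |
| `threshold_frac` | 0.05 | – | start threshold as fraction of peak enhancement; gain-invariant |
| `noise_floor` | 0 | intensity | minimum enhancement counting as perfusion |
| `gradient_from` | `start_intensity` | – | lower endpoint of the wash-in slope |

Smoothing uses truncated (renormalised) windows at the edges so the first
and last frames remain usable; ties at the peak go to the earliest frame.

## Motion compensation

Transrectal probe geometry makes small in-plane translation the dominant
motion artifact, so the model is rigid translation per frame, estimated by
exhaustive normalised cross-correlation over integer shifts within
`±max_shift`, with subpixel refinement by a quadratic fit around the peak of
the correlation surface. Two preprocessing steps matter:

* correlation runs on **log intensity with the local spatial mean removed**
  (box half-width 2 px). During wash-in the global enhancement dwarfs the
  stationary echotexture; removing the local mean puts the texture — the
  anatomically anchored signal — back in charge of the match.
* the **integer search** uses a temporally smoothed copy (window 3) for
  speckle robustness, but the **subpixel refinement** uses the unsmoothed
  frame: averaging frames taken at different displacements biases the
  fractional estimate precisely when intensity changes fastest.

Ties in the correlation peak break toward the smaller displacement norm and
then lexicographically, so estimates are deterministic. A numerically
perfect correlation skips refinement (the surface's edge asymmetry would
otherwise perturb an exact match). Correction resamples each frame by the
inverse shift (bilinear; exact pass-through for integer shifts),
edge-clamped and flagged in `meta`. Frames with zero variance cannot anchor
a correlation and are rejected as degenerate references.

## Discreteness grading

Hyper-perfused ("hot") pixels are the in-ROI ok pixels at or above a
threshold — the 75th percentile of in-ROI values by default, or Otsu's
threshold on the in-ROI histogram. Hot pixels form 8-connected components
(visual contiguity of rendered blobs); components below `min_area` (5 px)
are treated as speckle and dropped.

The four-tier grading of spatial discreteness is, in its clinical origin, a
qualitative reading of the map. This package makes it quantitative with a
declared decision rule on two features, the component count \(n\) and the
dominant fraction \(d\) (largest component area over total hot area):

* grade 1 — completely concentrated: \(n = 1\);
* grade 2 — predominantly concentrated: \(2 \le n \le 4\) and \(d \ge 0.70\);
* grade 4 — completely discrete: \(n \ge 6\) and \(d < 0.35\);
* grade 3 — predominantly discrete: otherwise.

All cutpoints are configuration, not constants; the full feature vector
(including a dispersion feature — mean pairwise centroid distance over the
ROI-equivalent diameter — which the default rule reports but does not use)
is always returned so a human can audit any grade. The cutpoints are
declared choices, not values fitted to any dataset: "a few satellites" is
read as up to three, "numerous" as six or more, and the dominant-fraction
cuts separate "one dominant area" (≥ 70%) from "no dominant area" (< 35%).
Merging two components can only decrease or preserve the grade, and
relabelling components never changes it.

## The synthetic cineloop generator

`make_phantom()` emulates what the analysis chain needs to be tested
against, with known ground truth:

* **kinetics**: each pixel follows a gamma-variate bolus curve
  \(b + y_{max}\tau^\alpha e^{\alpha(1-\tau)}\), the standard
  indicator-dilution form; the pipeline itself is model-free, so the
  simulator's kinetic family only needs realism. Defaults: background
  arrival 8 s, peak 28 s, enhancement 12 over baseline 2; lesions rise in
  half the time with twice the enhancement (analytic mean gradients 0.6 and
  2.4 intensity/s). These lesion-to-background ratios are stated
  configuration, not a claim about any cohort. The default acquisition is
  240 frames at 0.5 s — 120 s of transit.
* **geometry**: an elliptical "prostate" ROI; lesion archetypes reproduce
  the grading geometry — one disc (type 1), a dominant disc with three
  small satellites (type 2), four equal discs (type 3), seven scattered
  foci (type 4) — placed on seeded, jittered ring layouts totalling ~25% of
  the ROI.
* **echotexture**: a static smooth multiplicative field (default relative
  amplitude 0.4, grain of a few pixels) scales each pixel's whole curve, as
  tissue echogenicity scales echo power. It gives registration something
  anatomically anchored to lock onto at every phase of the transit; the
  per-pixel analytic ground-truth map carries the same factor, so parameter
  recovery is assessed pixel-by-pixel against it.
* **speckle**: frame-wise multiplicative Gaussian noise
  \(I(1 + \sigma\varepsilon)\), clipped at zero. Full Rayleigh speckle is
  out of scope; this stresses smoothing and thresholding, which is its job.
* **motion**: smooth sinusoidal rigid drift, rescaled so the maximum
  displacement from the reference frame equals the stated amplitude.

Everything is deterministic given `seed`, and the generator restores the
caller's RNG state.

What the phantom does *not* emulate: acoustic point-spread functions,
nonlinear microbubble response, attenuation shadowing, out-of-plane motion,
washout-phase pathology. Passing the recovery suites therefore shows the
estimators are correct and stable under speckle, drift, and discretisation —
not that they are validated on clinical loops.

## Reader-study statistics

The agreement and performance battery is implemented from the definitional
formulas, with base R supplying reference distributions, and each statistic
is cross-checked in the test suite against an independent oracle
(brute-force ANOVA sums of squares for the ICC, exhaustive summation for
Fleiss' kappa and Cochran-Armitage, a bootstrap for the DeLong variance,
`pROC` for paired AUC comparisons).

Choices that were genuinely open:

* **ICC form**: two-way random effects, absolute agreement. The
  single-measure form ICC(A,1) is the default — conventional when an
  individual reader's reproducibility is at issue — with `form = "average"`
  available. Confidence intervals use the F-distribution method.
* **binary-call AUC**: with a single operating point, the Mann-Whitney AUC
  with tie-halving equals \((Se + Sp)/2\) exactly; this identity is a
  property test. Panel AUCs pool the \(k\) raters' calls as \(kn\)
  observations (per-rater averages are reported alongside), and paired AUCs
  are compared with DeLong's method.
* **McNemar**: uncorrected \((b-c)^2/(b+c)\) by default, switching to the
  exact two-sided binomial when \(b + c < 25\); both variants and the
  continuity-corrected one are selectable.
* **proportion CIs**: Clopper-Pearson exact by default (Wilson optional).
* **two-panel agreement** is reported two ways — Fleiss' kappa over the
  pooled panel and Cohen's kappa between majority calls — because "kappa
  between groups" is constructionally ambiguous.
* **multiplicity**: no adjustment is applied, and the report says so in its
  metadata.

Degenerate inputs return flags, not exceptions: zero between-case variance
(ICC 0), a single rating category (Fleiss kappa undefined), zero
discordance (McNemar p = 1), a single-outcome trend table (zero-variance
flag), identical score vectors (DeLong p = 1).

## Validation problem sizes

The acceptance suite exercises: parameter recovery on a 128 × 128, 240-frame
phantom at 0.5 s sampling (every noiseless pixel within 5% of the
closed-form oracle; the median pixel within 15% under 10% speckle — under
multiplicative noise the per-pixel maximum is dominated by the extreme
upper tail of the smoothed-maximum bias, so the typical-pixel error is the
meaningful summary); exact recovery of injected integer shifts and
sub-half-pixel recovery of 3 px sinusoidal drift; 50 seeded phantoms per
archetype at 10% speckle with at least 45 of 50 graded correctly; the
\((Se+Sp)/2\) identity on 500 random ratings tables; pooled AUCs at the
reference operating points (sens 0.20/spec 0.65 and sens 0.94/spec 0.79,
4 raters × 620 cases) recovered within ±0.03; and 5% ± 2 null calibration
of McNemar and Cochran-Armitage at 2000 simulated tables each.

## Known limitations

* Rigid translation only; no rotation or elastic deformation, and no
  out-of-plane motion detection — loops with such artifacts should be
  excluded upstream.
* The wash-in estimator is sample-based (no curve fitting); under heavy
  speckle the smoothed-maximum peak estimate is biased upward, which is
  why the speckle recovery criterion is stated for the typical pixel.
* No washout parameters (washout rate, mean transit time) and no dB-domain
  analytics.
* DICOM support covers the basic multi-frame layout (explicit VR little
  endian) only; vendor private contrast tags are ignored, and DICOM is
  read-only.
* The discreteness cutpoints are declared, not learned; sensitivity to them
  can be explored through `discreteness_rule()`, including the
  dispersion-aware variant.
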