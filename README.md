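# ticmapr

Pixel-wise time-intensity curve (TIC) parametric imaging for
contrast-enhanced ultrasound (CEUS) of the prostate.

Conventional quantitative CEUS summarises one hand-drawn region of
interest, which is subjective and blind to the spatial heterogeneity that
characterises tumour angiogenesis. `ticmapr` computes a TIC for every pixel
inside a whole-gland ROI of a bolus-transit cineloop, reduces each TIC to
the **mean gradient to peak** — the average wash-in slope

```
MGP = (y_peak − y(t_start)) / (t_peak − t_start)     [intensity/s]
```

with landmarks (baseline, enhancement start, peak) detected on a smoothed
copy of each trace — renders the result as a colour-coded parametric map,
and grades the spatial **discreteness** of the hyper-perfused regions on a
four-tier ordinal scale (1 = completely concentrated … 4 = completely
discrete) using a declared, auditable decision rule on the hot-component
count and dominant-area fraction.

The package also provides:

* rigid motion compensation (normalised cross-correlation with subpixel
  refinement) so each pixel tracks one anatomical location;
* cineloop I/O: a lossless portable container, basic multi-frame DICOM
  reading, PNG/CSV masks;
* a synthetic cineloop simulator with analytic per-pixel ground truth and
  the four spatial archetypes, plus a synthetic reader-ratings generator;
* a reader-study statistical battery implemented from the definitional
  formulas: two-way random absolute-agreement ICC, Fleiss' and Cohen's
  kappa, McNemar's paired test, the Cochran-Armitage trend test, binary-call
  diagnostic metrics with exact CIs, Mann-Whitney AUC and the DeLong test
  for paired AUCs, assembled by `reader_study_report()`.

## Worked example

Simulate a noisy, drifting cineloop with a "predominantly discrete"
(type 3) perfusion pattern, correct motion, map the wash-in gradient, and
grade the pattern:

```r
library(ticmapr)

ph    <- make_phantom(shape = c(64, 64), n_frames = 120, frame_interval = 1,
                      lesion_type = "3", noise_sigma = 0.1,
                      motion_amplitude = 2, seed = 42)
trace <- estimate_motion(ph$loop, max_shift = 5)
loop  <- apply_motion(ph$loop, trace)
map   <- compute_map(loop, ph$mask)
map
#> <parametric_map> mean_gradient_to_peak, 64 x 64 px, 2284 ok / 2284 in ROI
#>   range [0.3744, 3.069], median 0.6726

classify_map(map, ph$mask)
#> <discreteness_result> grade 3 (predominantly discrete)
#>   3 components, dominant fraction 0.51, dispersion 0.32
```

The background's analytic mean gradient is 0.6 intensity/s and the lesions'
is 2.4, modulated by the phantom's echotexture — the map's range and median
sit where the simulation put them, and the grade matches the simulated
archetype. `render_map(map, "map.png")` writes the colour-coded image
(cool = slow perfusion, hot = rapid) with an embedded colour bar;
`autoplot(map)` gives the ggplot2 version.

Reader statistics work on cases × raters tables (simulated here at a
sensitivity/specificity of 0.94/0.79 and prevalence 11/62):

```r
rt <- make_ratings(62, 4, prevalence = 11/62, sens = 0.94, spec = 0.79,
                   seed = 1)
p  <- pool_ratings(rt)
tidy(diagnostic_metrics(p$calls, p$truth))
#> # A tibble: 7 × 4
#>   metric      estimate conf.low conf.high
#> 1 sensitivity    0.972    0.855     0.999
#> 2 specificity    0.835    0.778     0.882
#> 3 ppv            0.5      0.378     0.622
#> 4 npv            0.994    0.969     1.000
#> 5 accuracy       0.855    0.805     0.896
#> 6 auc            0.904    0.867     0.941
#> 7 youden         0.807   NA        NA

icc_absolute(rt)
#> ICC(A,1) = 0.368 (95% CI 0.238-0.509), p = 2.56e-10  [n = 62 cases, k = 4 raters]
```

For binary calls the pooled AUC equals `(Se + Sp)/2` exactly — here the
empirical operating point gives 0.904. `reader_study_report()` assembles
the full battery (pooled and per-rater performance, ICC, kappas, McNemar on
correctness, DeLong on pooled AUCs) across named sessions.

A thin command-line wrapper ships in `inst/cli/ticmapr` with subcommands
`simulate`, `motion`, `ticmap`, `classify`, `reader-stats`, and `run`
(the end-to-end pipeline, also available as `run_pipeline()`).

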