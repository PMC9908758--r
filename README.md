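# evtopo

Reference-independent ("electrical neuroimaging") analysis of multichannel
evoked potentials in R: topographic clustering of scalp maps, single-subject
template fitting, the topographic consistency test, a distributed inverse
with local autoregressive (LAURA-type) regularization, and permutation-based
factorial statistics with spatial cluster thresholding — plus a
forward-model generator of complete synthetic somatosensory evoked potential
(SEP) studies so the whole chain can be validated against known ground
truth.

## Who this is for

EEG researchers analyzing stimulus-locked multichannel data who want the
topographic analysis chain — rather than per-electrode waveforms — as
composable, tested R functions: each stage takes and returns plain data
structures (tibbles wherever the data are tabular), results have
`tidy()`/`glance()` methods and `autoplot()` figures, and a single
`run_study()` call executes the canonical order on simulated or imported
data.

## The analysis in brief

For an average-referenced potential map $u$ over $N$ electrodes, the global
field power is the spatial standard deviation
$\mathrm{GFP} = \sqrt{\tfrac1N \sum_i (u_i - \bar u)^2}$; topographies are
compared by their spatial Pearson correlation (signed — polarity matters
for evoked data). The pipeline:

1. preprocess epochs (512 Hz, 1–40 Hz zero-phase band-pass, average
   reference, pre-stimulus baseline, ±20 µV rejection);
2. cluster the concatenated group-average topographies of all conditions
   (AAHC), keeping the smallest number of template maps explaining ≥ 90% of
   the GFP-weighted variance,
   $\mathrm{GEV} = \sum_t (\mathrm{GFP}_t r_t)^2 / \sum_t \mathrm{GFP}_t^2$;
3. test topographic consistency per condition by permutation (shuffle
   potentials across electrodes within each subject; the GFP of the
   grand average is the statistic);
4. select the analysis window where a stable map set, all-condition
   consistency, and the GFP peak coincide;
5. fit templates to single subjects (winner-take-all by spatial
   correlation), extract per-map duration and GFP;
6. estimate sources over the window with a LAURA-regularized linear
   inverse on a spherical grid and take per-node current density;
7. run permutation 2×2 repeated-measures ANOVAs
   ($F(1,n-1) = n\bar c^2/\widehat{\mathrm{Var}}(c)$ from within-subject
   contrasts; cells permuted within subjects) on durations, GFP, node
   densities (≥ 17 contiguous significant nodes required) and behavioral
   outcomes, with paired post-hocs (Cohen's d) and Pearson correlations.

## Worked example

```r
library(evtopo)

cfg <- study_config(seed = 5)       # the full emulated protocol:
                                    # 10 subjects, 2x2 design, 480
                                    # stimulations/condition, 64 ch @ 512 Hz
report <- run_study(cfg, progress = TRUE)
report
#> <study_report>
#>   subjects: 10, epochs/condition: 480 (rejected 2.2%)
#>   maps: q* = 4 (GEV 0.979)
#>   window: [43.75, 67.1875) ms
#>   duration congruency: F = 2869.14, p = 0.0001
#>   retained node clusters: 1 (largest 291 nodes)
#>   agency: p(congruency) = 0.0031, p(synchrony) = 0.0003
```

Reading the output: the clustering kept four template maps explaining 97.9%
of the variance; the selected analysis window (43.75–67.19 ms) covers the
early SEP components, where the congruent and incongruent conditions are
labelled by different maps; the permutation ANOVA on that map's presence
shows a congruency main effect (p = 10⁻⁴ at 10,000 resamplings); the
node-wise source ANOVA retains one spatial cluster for congruency (291
nodes at the 16 mm validation grid); and the behavioral agency ratings show
the planted congruency and synchrony effects. `tidy()`, `glance()` and
`autoplot()` work on the per-stage results (`report$duration_anova`,
`report$tct`, `report$fitting`, `report$clusters`, ...).

A command-line wrapper for the same flow lives in `inst/cli/evtopo.R`
(`evtopo.R run|simulate|convert`).

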