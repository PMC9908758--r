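---
title: "Electrical neuroimaging of evoked potentials with evtopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrical neuroimaging of evoked potentials with evtopo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evtopo)
```

## The analysis problem

Multichannel evoked potentials are usually analyzed waveform by waveform,
which makes every result depend on the chosen reference electrode and on
which sensors the analyst happens to inspect. *Electrical neuroimaging*
replaces this with reference-independent measures of the whole scalp field:
the **global field power** (GFP, the spatial standard deviation of the
average-referenced map at one instant) quantifies field strength, and the
**topography** (the map shape, independent of strength) indexes the
configuration of the underlying generators. Two conditions that differ in
topography must differ in their intracranial sources; two conditions that
differ only in GFP may share sources at different gain.

`evtopo` implements this analysis chain end to end for a 2×2 within-subject
somatosensory evoked potential (SEP) experiment — factors *congruency*
(spatial match between an executed and a displayed hand movement) and
*synchrony* (temporal match) — together with a forward-model based
generator of synthetic studies, so every stage can be validated against
known ground truth without human recordings.

The stages, in pipeline order:

1. **Preprocessing** (`preprocess_epochs()`): downsample to 512 Hz,
   zero-phase 1–40 Hz band-pass, average reference, baseline correction
   over the 50 ms pre-stimulus interval, and rejection of epochs exceeding
   ±20 µV on any channel.
2. **Topographic clustering** (`aahc_cluster()`): atomize-and-agglomerate
   hierarchical clustering (AAHC) of the group-average topographies of all
   four conditions, concatenated; map count chosen as the smallest q whose
   assignment explains ≥ 90% of the GFP-weighted variance
   (`select_n_maps()`), with a Krzanowski–Lai style score reported as an
   advisory diagnostic.
3. **Topographic consistency test** (`tct_test()`): a permutation test for
   evoked activity at each time point, per condition — shuffling potentials
   across electrodes within each subject destroys cross-subject alignment
   while preserving each subject's GFP, so the grand-average GFP serves as
   the consistency statistic.
4. **Window selection** (`select_window()`): the analysis window is a
   period over which a fixed *set* of template maps labels the conditions,
   every sample is TCT-consistent in all conditions, and the grand-average
   GFP peaks.
5. **Fitting** (`fit_templates()`): winner-take-all spatial-correlation
   assignment of templates to each subject × condition waveform inside the
   window, yielding per-map *duration* (presence in ms) and mean GFP — two
   orthogonal features, tested with the permutation ANOVA below.
6. **Source estimation** (`build_laura_inverse()`, `estimate_sources()`):
   a distributed linear inverse on a regular grid in a spherical volume,
   with local autoregressive regularization — each source is constrained
   toward the inverse-square-distance weighted average of its neighbors,
   following the physics of potential decay. The evoked data are averaged
   over the analysis window before inversion (one topography per subject
   and condition), and per-node current density is the norm of the
   three-component dipole moment.
7. **Statistics** (`perm_rm_anova_2x2()`, `nodewise_anova()`,
   `spatial_cluster_filter()`, `posthoc_paired()`,
   `pearson_correlation()`): permutation-based 2×2 repeated-measures ANOVA
   (10,000 resamplings by default), run per scalar outcome and per source
   node, with node-level significance requiring p < 0.05 *and* membership
   in a cluster of at least 17 contiguous nodes.

`run_study()` executes all of this from one `study_config()`.

## The permutation ANOVA

For a 2×2 within-subject design each effect has one degree of freedom, so
the classical repeated-measures F is computed through per-subject contrast
scores: with cell means $y_{s,jk}$, the congruency contrast is
$c_s = (y_{s,11} + y_{s,12} - y_{s,21} - y_{s,22})/2$ and

$$F(1, n-1) = \frac{n\,\bar c^2}{\widehat{\mathrm{Var}}(c)},
\qquad \eta^2_p = \frac{F}{F + n - 1}.$$

This is algebraically identical to the textbook decomposition (each effect
tested against its subject-by-effect interaction); the test suite verifies
it against `aov()` with the matching `Error()` strata to 10 decimal places.
The permutation null permutes the four cell values independently within
each subject — the global exchangeability null, the simplest scheme that is
valid for all three effects at once — and
$p = (1 + \#\{F^* \ge F\})/(1 + B)$, which can never fall below $1/(B+1)$.
Node-wise tests re-use a single permutation schedule across nodes so the
resulting p-maps are spatially coherent. The permutation scheme is recorded
in each result's metadata; no correction is applied beyond the
cluster-extent rule, and post-hoc paired t tests are reported uncorrected.

## The synthetic study and what it does (not) emulate

Since no recordings ship with the package, `simulate_evoked_study()`
generates the full factorial study from a known forward model:

* **Protocol**: 10 subjects, 4 conditions, 480 stimulations per condition
  (2 Hz × 15 s trials × 4 repetitions/condition/block × 4 blocks), 64
  channels (geodesic 10-10 positions) at 512 Hz, epochs −50…+300 ms.
* **Generators**: three dipoles in the spherical source space — a left
  central source peaking at 45 ms (the P45-like component), a right
  posterior source at 40 ms, and a weaker polarity-reversed central source
  at 180 ms standing in for the long-latency response, so the consistency
  trace shows the early and late windows well separated, as SEP data do.
* **The planted congruency effect** is a *rotation* of the early source
  mixture: congruent cells gain the posterior dipole up (×2 by default) and
  the central one down, incongruent cells the reverse. The constants were
  chosen once from the forward geometry so that the two condition
  topographies correlate ≈ 0.70 while their GFPs differ by only ≈ 10% — the
  effect is topographic (different generator configurations), not a gross
  amplitude change. Setting `congruent_gain = 1` makes the design exactly
  effect-free, which the specificity tests use.
* **Between-subject variability**: one multiplicative gain (SD 0.1) and one
  latency shift (SD 2 ms) per subject, drawn once per subject — not per
  epoch — consistent with the averaging model of evoked responses.
* **Noise**: white sensor noise (4 µV), spatially correlated background
  (2 µV, exponential covariance over electrode distance), and occasional
  80 µV artifacts (2% of epochs) to exercise the rejection rule.
* **Behavior**: truncated-normal ratings on the 0–10 scale with planted
  main effects of congruency and synchrony on agency (Δ = 2, SD = 1 per
  cell), a flat control question, and kinematics around a 10.6 cm
  trajectory norm and 6.7 cm/s velocity with a small congruency × synchrony
  interaction on the trajectory norm. Two subjects' control ratings are
  marked missing by default, so the control analysis runs on n − 2 subjects
  by listwise exclusion.

What the generator does **not** emulate: realistic head anatomy (a single
homogeneous sphere replaces a template brain; real lead fields can be
supplied via `lead_field_matrix()`), ocular/muscle artifact morphology,
ICA-based cleanup (visual-inspection-guided component selection is not
reproducible; `preprocess_epochs()` accepts an externally supplied
projection as a hook), or single-trial amplitude dynamics. Passing tests
therefore demonstrate that the *analysis chain* is correct and calibrated —
not that it would be this powerful on real recordings, where lower SNR,
non-stationary noise and inter-subject anatomical variability all cut into
effect sizes.

## Numerical and design choices

* **Polarity** is signed everywhere: a map and its inverse are different
  maps, the convention for stimulus-locked data (spontaneous-EEG microstate
  analysis would ignore polarity instead).
* **AAHC details**: a cluster's template is the GFP-weighted mean of its
  member topographies renormalized to unit GFP; its contribution is
  $\sum_t (\mathrm{GFP}_t \cdot r_t)^2$; the minimum-contribution cluster is
  atomized and members reassigned by highest signed correlation, all
  against the templates as they stand after the atomization. Explained
  variance is non-decreasing in q along the hierarchy, which makes the
  ≥ 90% selector well defined.
* **Fitting ties** go to the lowest map index; durations over maps sum
  *exactly* to the window length in every cell.
* **Window stability** is defined on the label *set* across conditions, not
  the per-condition label tuple: within a two-map period the conditions may
  cross between the period's maps a few samples apart, and the tuple-based
  definition would fragment the period at every such crossing.
* **LAURA weighting**: the constraint operator has diagonal
  $(N_{max}/|N(i)|)\sum_k d_{ik}^{-2}$ and off-diagonals $-d_{ij}^{-2}$. A
  strictly row-normalized variant (unit diagonal, off-diagonals summing to
  −1) has the constant vector in its null space and is singular for every
  graph, so it cannot define a source metric; the classical weighting keeps
  interior rows balanced while boundary rows are diagonally dominant. The
  distance exponent (2, potential decay) and the regularization
  $\alpha = 0.01\,\mathrm{tr}(L M^{-1} L^\top)/n_{ch}$ are configurable.
  At $\alpha = 0$ every interior node of the test grids localizes a
  noiseless source to itself or an immediate neighbor (within one grid
  step, matching the grid-size accuracy expected of distributed inverses).
* **Filtering**: the band-pass is a 4th-order Butterworth applied forward
  and backward (zero phase), implemented as a row-vectorized recursion with
  odd-reflection edge padding so that a 480-epoch × 64-channel cell filters
  in one pass. Its measured 50 Hz attenuation (≈ 18 dB relative to 10 Hz
  for the two-pass cascade) is tested against the designed transfer
  function, not against a round number.
* **Trajectory norm** is read as the displacement magnitude between
  successive direction reversals of the principal movement axis (not the
  arc length — that is what the separately reported velocity integrates);
  partial strokes before the first and after the last reversal are
  excluded. Both conventions are computable from
  `trajectory_features()`'s output (`velocity_cm_s` × duration recovers
  path length).
* **Degenerate inputs** fail loudly: cells losing every epoch, incomplete
  designs, zero-variance topographies, dipoles outside the source space and
  out-of-range ratings are all hard errors naming the offending unit.

## Problem sizes

The default `study_config()` reproduces the full protocol (480
epochs/condition, 10 subjects, 64 channels, 10,000 ANOVA resamplings, 1,000
TCT shuffles) on a 16 mm source grid (≈ 365 nodes) and runs in a few
minutes on one core; a 2 mm grid like a template-brain solution space
(thousands of nodes) is configurable but makes the dense inverse operator
expensive. Replicated validation runs in the test suite scale the epoch
count down (12–24 per cell) while scaling single-trial noise by
$\sqrt{N_{epochs}/480}$, which preserves the evoked-level SNR of the full
protocol; permutation counts are reduced to a few hundred where only
calibration, not fine p-resolution, is at stake. The vignette and README
state these sizes as the package's validation choices.

## A worked run

```{r, eval = FALSE}
cfg <- study_config(seed = 7)
report <- run_study(cfg, progress = TRUE)
report
#> <study_report>
#>   subjects: 10, epochs/condition: 480 (rejected 2.2%)
#>   maps: q* = 4 (GEV 0.977)
#>   window: [43.75, 67.1875) ms
#>   duration congruency: F = 2869.14, p = 0.0001
#>   retained node clusters: 1 (largest 291 nodes)
#>   agency: p(congruency) = 0.0031, p(synchrony) = 0.0003

ggplot2::autoplot(report$evoked)          # butterfly + GFP per condition
ggplot2::autoplot(report$tct)             # 1 - p consistency traces
ggplot2::autoplot(report$fitting)         # per-map durations by condition
plot_template_maps(report$templates, report$evoked$montage)
tidy(report$duration_anova)
glance(report$clusters)
```

(The numbers shown are from a full-scale run with seed 5; your exact values
depend on the seed.) The pattern mirrors the phenomenon the synthetic study
plants: a congruency effect on early map duration, a stronger posterior
source in the congruent cells surviving the cluster threshold, agency
modulated by both factors, and a flat control question.

## Known limitations

* The spherical forward model is adequate for validating the inverse
  pipeline but not for anatomical claims; node clusters have no anatomical
  labels by design.
* AAHC is greedy; for data whose transition structure is adversarial the
  recorded hierarchy is a good, not optimal, segmentation. The advisory KL
  score helps flag indecisive map counts.
* The exact "modified" Krzanowski–Lai variant used by the original
  segmentation software is not published; here the KL score is advisory
  only and the ≥ 90% explained-variance rule is the operative selector.
* EEGLAB `.set` import is not supported (MATLAB v5 container); BrainVision
  and EDF importers cover the common interchange cases, and the canonical
  directory format round-trips bit-exactly.
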