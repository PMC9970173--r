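---
title: "EEG microstate cue-reactivity analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG microstate cue-reactivity analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`microstatr` implements a complete EEG microstate analysis for two-condition
cue-reactivity designs — from raw multichannel EEG to microstate templates,
segmentation parameters, condition contrasts, craving correlations and a
posterior-alpha mediation model — together with a synthetic-cohort generator
whose ground truth makes every stage testable. This vignette explains the
underlying models, the tunable parameters and the design decisions, in the
spirit of a methods section.

## The microstate model

Spontaneous scalp EEG topography does not change continuously: it remains
quasi-stable for brief periods (~80–120 ms) and then transitions abruptly to
another configuration. These stable periods are *microstates*; in eyes-closed
rest and many task settings four canonical classes (A–D) recur and explain
most of the topographic variance. The analysis pipeline follows the standard
modified k-means approach:

1. **Global field power (GFP).** At each time point the GFP is the population
   standard deviation of the potentials across the $N$ electrodes,
   $GFP = \sqrt{\tfrac{1}{N}\sum_i (\mu_i - \bar\mu)^2}$. GFP troughs mark
   transitions between topographies; GFP peaks are moments of maximal
   signal-to-noise and their maps are the clustering material (`gfp()`,
   `gfp_series()`, `detect_gfp_peaks()`).
2. **Polarity-invariant modified k-means** (`modified_kmeans()`). Peak maps
   are average-referenced and unit-normalised, so only topographic *shape*
   matters. A map and its sign-flip count as the same topography (standard
   for spontaneous EEG, where generators oscillate): assignment maximises
   the squared spatial correlation, and each template update is the first
   principal eigenvector of its members, which is polarity-blind. The best
   of `n_restarts` (default 20) random initialisations by explained
   variance is kept.
3. **Choosing the number of classes** (`select_k_kl()`). For each $k$ in the
   search range (default 2–8) the cluster dispersion
   $W(k)=\sum_m (1-r^2(m, t_m))$ feeds the Krzanowski–Lai criterion:
   $DIFF(k) = (k-1)^{2/p}W(k-1) - k^{2/p}W(k)$ and
   $KL(k) = |DIFF(k)|/|DIFF(k+1)|$ with $p$ the electrode count. On typical
   data the KL curve is high at the $k=2$ boundary, dips, then peaks at the
   optimal $k$; the boundary point is the curve's first maximum and the
   chosen $k$ is its **second maximum** — implemented as the interior local
   maximum with the largest KL value, falling back to the global maximum
   when no interior maximum exists. We measured the alternatives on
   synthetic four-class peak maps: taking the second local maximum in
   ascending $k$ regardless of magnitude picks small noise ripples at
   $k=6$–$7$ (whose KL is 10–50× smaller than $KL(4)$) in most template
   draws, and the "second-largest value" reading never recovers $k=4$
   because $KL(4)$ *is* the largest value. The dominant-interior-maximum
   rule recovers $k=4$ in 95–100% of draws; the second-largest reading
   stays available via `rule = "second_largest"` and the whole curve is
   returned for audit.
4. **Permutation averaging** (`permutation_average()`,
   `build_level_templates()`). Individual template sets are averaged within
   each condition, then across conditions, after choosing for each set the
   label permutation and per-map polarity signs that maximise the total
   squared correlation with the evolving mean (exhaustive over permutations
   for $K \le 7$); the mean per class is the polarity-aligned principal
   eigenvector of the aligned maps. Class labels A–D are assigned to the
   overall maps by best bijective match either to idealised canonical
   topographies (two diagonals, an anterior–posterior gradient, and a
   fronto-central peak) or, for synthetic cohorts, to the generator's
   ground-truth templates so that recovered and generated classes share an
   identity.
5. **Back-fitting and parameters** (`backfit()`, `compute_parameters()`,
   `compute_gev()`). Each GFP-peak map is labelled with the class of maximal
   polarity-invariant correlation; every other sample inherits the label of
   its temporally nearest peak within the same epoch (ties go to the earlier
   peak), and epochs without any peak remain unassigned. No minimum-duration
   smoothing is applied. Per class we report `duration_ms` (mean segment
   length), `occurrence_per_s` (segments per labelled second) and
   `contribution` (fraction of labelled time); segments never cross 1 s
   epoch boundaries, and boundary-truncated segments are included by default
   (`include_truncated = FALSE` excludes them from duration/occurrence;
   contribution always uses all labelled samples). With truncated runs
   included, `contribution = occurrence * duration` holds exactly — the
   package asserts it. Global explained variance is GFP-weighted,
   $GEV = \sum_t (GFP_t r_t)^2 / \sum_t GFP_t^2$, computed over the labelled
   GFP peaks by default (the domain the templates were fitted on); a
   sample-based variant is available.

## Preprocessing

The canonical order mirrors standard practice for this design and is fixed
(`preprocess_recording()`): 0.1–80 Hz broadband filter → epoch −1 to 90 s
around each trial onset with a −1–0 s baseline → retain 1–89 s (88 s per
trial) → optional EOG regression → 1 s segmentation → ±100 µV amplitude
rejection → downsample to 250 Hz → 2–20 Hz analysis band → average
reference. Pipeline-order invariance is *not* assumed. Notes:

* All band-passes are zero-phase (forward–backward) Butterworth filters,
  4th-order prototypes, applied as a high-pass/low-pass cascade — cascading
  is numerically robust at very low cut-offs (0.1 Hz at 250 Hz sampling)
  where a single band-pass design is fragile. Zero-phase filtering
  preserves microstate timing.
* The rejection threshold is interpreted in microvolts (±100 µV); a
  millivolt-scale threshold would reject nothing physiological. Both an
  absolute-amplitude and a peak-to-peak criterion are implemented
  (`criterion = "both"` by default) because "amplitude changes" is
  ambiguous between the two readings; rejection is monotone in the
  threshold.
* Posterior alpha power (`posterior_alpha_power()`) is Welch's estimate
  with 1 s Hann segments matching the epoching, integrated over 8–12 Hz
  and averaged over a nine-electrode parieto-occipital set
  (O1, O2, Oz, PO3, PO4, POz, P3, P4, Pz — configurable; the published
  electrode choice for this quantity is only marked graphically, so a
  standard parieto-occipital set is used). The normalisation makes a pure
  in-band sinusoid of amplitude $A$ integrate to $A^2/2$, which the tests
  verify against an independent direct-DFT oracle.
* Blink handling is an optional multi-channel EOG linear regression
  (`regress_eog()`), off by default: synthetic data contains no ocular
  artifacts, and adaptive (recursive least squares) correction of real EOG
  is not reproducible without real EOG recordings.

## The synthetic cohort generator

Every downstream claim in this package is tested against recoverable ground
truth, which the generator (`make_ground_truth()`, `generate_cohort()`)
provides. It emulates a 40-subject, two-condition (neutral vs smoking),
four-trial guided-imagery cue-reactivity study, 88 s of usable EEG per trial
at 250 Hz over a 64-channel 10–20 montage:

* **State sequence**: a semi-Markov chain; dwell times are gamma-distributed
  (shape 4, i.e. CV = 0.5) with class- and condition-specific means near
  100 ms. Gamma rather than exponential dwell makes mean duration tunable
  independently of occurrence and avoids implausibly short segments. The
  next class is drawn among the others with configurable *entry weights* —
  without them, uniform switching cannot dissociate occurrence effects
  from duration effects (lengthening a class's dwell lowers *every* class's
  occurrence), whereas the study-like pattern requires class D's occurrence
  to hold up while A–C drop.
* **Signal**: `data = template[label_t] * g_t`, where the envelope $g_t$
  oscillates within each run as $\sin(\pi m u)$ ($u$ the position in the
  run, $m$ half-cycles at ~14 Hz) — exactly zero at every transition and
  peaking inside stable segments, with polarity reversals inside runs. This
  realises the microstate phenomenology the model assumes (GFP troughs at
  transitions, ~20 GFP peaks/s): an envelope generated independently of the
  state sequence puts many GFP peaks at segment boundaries, where the
  band-passed map is a mixture of two templates, and identifiability
  collapses (~65% peak accuracy instead of ~98% at the default SNR). The
  14 Hz carrier is deliberately outside the 8–12 Hz alpha band so the
  microstate signal does not confound the spectral alpha measurements.
* **Templates** are smooth dipolar patterns over the montage (signed
  distance to a random dipole plane through a saturating nonlinearity),
  redrawn until all pairwise $|r| \le 0.7$; white-noise maps would make
  clustering unrealistically easy.
* **Noise** is temporally pink (1/f) with inter-electrode spatial
  correlation from a squared-exponential kernel over electrode distances
  (length scale 0.6 head radii), added at SNR 2 (signal RMS : noise RMS).
* **Alpha**: a 10 Hz sinusoid on the posterior electrode set, amplitude
  1.2 µV in the neutral condition and +0.4 µV (plus linkage, below) in the
  smoking condition. The amplitudes are deliberately modest relative to
  the per-channel microstate signal (~2 µV RMS): condition-asymmetric alpha
  contamination otherwise shortens all smoking-condition segments
  (misassigned peaks chop runs) and masks the dwell effects the generator
  is supposed to encode.
* **Behavioural linkage** (full-mediation structure): each subject's
  alpha-amplitude change is linear in their *realised* class-C dwell-time
  change plus noise, and the craving change is linear in the realised
  alpha-*power* change plus noise, with no direct dwell→craving path.
  Years of smoking is generated correlated with the class-D dwell change.
  Craving and vividness are 0–10 ratings; nicotine-dependence covariates
  are drawn in realistic ranges.
* **Effect sizes** are not published quantities; the defaults (smoking
  dwell multipliers 1.00/1.15/1.18/1.25 for A–D, entry weights
  0.85/1/1/1.45) were calibrated once so that the qualitative sign pattern
  of the study's condition contrasts — longer B/C/D durations, lower A/B/C
  occurrence, lower A and higher D contribution — is recoverable by the
  pipeline; the magnitudes carry no claim. `null_effects()` zeroes
  everything for calibration studies.
* With `signal = "labels"` the generator skips EEG synthesis and returns
  the realised per-subject parameters computed from the true label
  sequences — sufficient and fast for statistical calibration.

What the generator does **not** emulate: ocular/muscle artifacts, volume
conduction from realistic dipole physics, non-stationary noise, inter-subject
topographic variability of the template maps themselves, or microstate
syntax (the transition structure is uniform apart from entry weights).
Passing recovery tests on these cohorts therefore demonstrates the
correctness of the algorithms, not robustness to every pathology of real
recordings.

## Statistical layer

`analyze_cohort()` reproduces the analysis structure of a cue-reactivity
study in order: paired contrasts of craving/vividness (and alpha power);
per-measure 2×4 repeated-measures ANOVA (condition × class, both within
subject) fitted via `stats::aov` error strata, with Greenhouse–Geisser
epsilon and corrected p-values reported alongside the uncorrected headline
values; per-class post-hoc paired t-tests run **only when the interaction is
significant** (p < .05; the gate can be forced with a logged message) and
Benjamini–Hochberg corrected within each measure's four classes; condition
difference variables (smoking − neutral) are created **only** for
measures/classes with a significant contrast; Pearson correlations of the
craving change and of the addiction covariates with those differences (raw
p-values primary, BH-adjusted alongside — such correlation families are
conventionally reported uncorrected in this literature); and the mediation
model.

`mediation_model4()` is a simple-mediation (three-variable) path model on
standardised variables: $m = ax$, $y = c'x + bm$, $y = cx$, with a
percentile bootstrap (default B = 5000, subject resampling, fixed seed) for
the indirect effect $ab$. Percentile rather than BCa intervals are the
default, matching the common macro default for this model. Verdict: *full*
mediation when the CI excludes 0 and the direct path is non-significant
(p ≥ .05), *partial* when both are significant, *none* otherwise.

Numerical notes: the rm-ANOVA is validated against an independent
sum-of-squares decomposition to 1e-9; `fdr_bh()` against a brute-force
step-up implementation; the paired t and Pearson r against closed forms;
degenerate inputs (zero-variance differences, all-identical maps, epochs
with no GFP peaks, empty clusters) raise informative errors or are handled
by documented rules (empty clusters are re-seeded from the worst-fitted
map, never twice from the same map).

## Pipeline and reproducibility

`run_pipeline(config, out_dir)` executes simulate → preprocess → microstate
→ statistics and writes a deterministic artifact directory (`params.csv`,
`cohort.csv`, `report.json`, templates, per-sample segmentations, a config
copy and a log with stage timings, record counts and the config hash).
Every source of randomness flows from the single config seed; re-running
with the same config reproduces `params.csv` and `report.json` byte for
byte. `validate_config()` rejects unknown keys and out-of-range values
(e.g. a k-search range starting below 2, non-positive SNR).
`default_config()` holds the study-default sizes (40 subjects, 4 × 90 s
trials); individual-level KL selection runs on a configurable subset of
subject/conditions (default 8) and the consensus (modal) k is refit for
everyone.

## Problem sizes used in tests

The test-suite and the acceptance script exercise the full pipeline at
reduced, fixed sizes chosen to keep runs short while leaving every effect
detectable: 20-subject cohorts with 2 × 20 s trials per condition for
end-to-end recovery (grand-template correlation, class-C duration rank
recovery), 200 label-level null cohorts of 12 subjects for type-I-error
calibration, 20-seed Monte-Carlo runs for KL model-order recovery, the
Table-2-style sign-pattern reproduction (20 subjects, 2 × 30 s), and
mediation recovery at n = 40 with B = 2000 bootstrap resamples. The
statistical thresholds these runs are held to do not depend on the sizes;
larger cohorts only make them pass more comfortably.

## Known limitations

* The KL "second maximum" rule is an interpretive choice (see above);
  both implemented readings are reported in the returned curve.
* Whether published duration statistics include epoch-boundary-truncated
  segments is unknowable from the outside; both modes are implemented and
  the exact `contribution = occurrence × duration` identity holds only
  when truncated runs are included.
* GEV is peak-based by default (the fitting domain); sample-based GEV is
  available and agrees closely on clean data but is systematically lower
  on noisy data (non-peak samples are noisier).
* The EDF reader is out of scope: recordings interchange as raw float32
  matrices with a JSON sidecar, plus whitespace-delimited montage files.
* Real-EEG idiosyncrasies listed under the generator's non-goals are not
  simulated; claims about robustness to them require real data.
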