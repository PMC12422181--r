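---
title: "Analysing sound-evoked awakening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing sound-evoked awakening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neawake)
```

## Scope

`neawake` implements the analysis chain of a mouse sound-evoked-awakening
(SEA) experiment in which extracellular norepinephrine (NE) is monitored by
fiber photometry in two locus coeruleus (LC) target regions — the pontine
reticular nucleus (PRN, brainstem) and the basal forebrain (BF) — while
EEG/EMG and video determine whether each auditory stimulus wakes the animal.
Four statistical components form the core: (1) event-locked response-window
detection on ΔF/F traces with a one-sided many-to-one multiple-comparison
correction; (2) rule-based trial-outcome scoring and sleep-state transition
curves; (3) event-related spectral perturbation (ERSP) and EMG
root-mean-square features with cluster-based permutation inference; and (4)
a yield-normalized Monte Carlo permutation framework comparing the
anatomical distributions of projection-defined LC subpopulations. A seeded
synthetic-data generator supplies ground-truth-bearing inputs for all of
them.

## Photometry preprocessing

The recorded 465-nm sensor channel and the 405-nm isosbestic control share
motion and photobleaching components but only the sensor channel tracks NE.
Per LED-on block, the isosbestic trace is least-squares fitted to the
sensor trace (`fit_isosbestic()`, coefficients `a`, `b`) and the fitted
trace serves as the reference `f0`; then

ΔF/F = (signal − f0) / f0 × 100 %.

Fitting per block rather than per session tracks the block-wise bleaching
state that hour-long LED duty cycles produce; a session-wide fit is
available with `per_block = FALSE`. Samples outside LED-on epochs are
masked and never analysed. Epoching (`epoch_trials()`) subtracts each
trial's 5-s pre-stimulus baseline mean, so baselined epochs average zero
over the baseline to machine precision. Traces are decimated by 10 (from
1017.25 Hz to ≈101.7 Hz) before epoching; because the acquisition chain
low-passes at 6 Hz, decimation without further filtering cannot alias.

## Response-window detection

The detector asks where, relative to sound onset, the trial-averaged ΔF/F
is elevated above baseline consistently across mice:

1. Each mouse's trial-averaged trace is cut into 0.3-s bins over
   (0, 3.9] s. The span honours the 13-bin family — 13 × 0.3 s = 3.9 s —
   rather than the nominal 4-s endpoint, because the bin count fixes the
   size of the multiple-comparison family; both numbers are exposed as
   arguments.
2. A Kruskal–Wallis omnibus test (midranks, tie-corrected) across the bins
   gates the procedure at `alpha`.
3. Each bin's across-mouse values are tested one-sided against zero with a
   many-to-one (Dunnett-style) family correction: the joint null is an
   equicorrelated multivariate t with df = n − 1 whose common correlation
   is estimated as the mean pairwise between-bin correlation. The default
   method evaluates the max-statistic tail probability with
   `mvtnorm::pmvt()`; `method = "mc"` simulates the same maximum and is
   retained as a cross-checkable fallback. The equicorrelation projection
   is deliberate: with 7 mice and 13 bins the sample correlation matrix is
   rank-deficient, and a single pooled correlation is the stable summary.
4. Maximal runs of significant bins become response windows
   (`detect_response_windows()`); non-adjacent significant bins are never
   merged.

Per-mouse means (not pooled trials) enter the test, matching an
across-mice inference. Window scores (`score_elements()`) are per-trial
means within a window; the drop score is the minimum over the 2 s after
the window's end — the post-surge dip has no formally defined window in
the source analyses, and 2 s covers its reported latency with margin.

## Trial-outcome rules

`classify_trial()` maps channel-activation evidence gathered over the 3-s
response window to one of six labels: unstable baselines are `discarded`;
EEG + EMG + movement jointly persisting to ≥ 3 s after onset is
`awakening`; all three present but shorter is `short_awakening`; exactly
one electrophysiological channel is `eeg_activation` / `emg_activation`;
no change is `maintained`. Two rule gaps required decisions: two-of-three
activations are labeled by channel precedence EEG > EMG (with a warning),
and movement-only trials — which activate no electrophysiological channel
and are covered by no stated rule — default to `discarded`, mirroring the
exclusion of inconsistent semi-awakening cases from downstream analyses;
both behaviours are configurable. "Lasted at least 3 s" is interpreted
against the response window: the joint activation must persist from its
onset to at least `min_duration_s` (default 3 s) after trial onset.

Awakening probability is the fraction of awakening outcomes among
NREM-baseline trials under a condition filter. Transition curves
(`transition_probabilities()`) follow trials whose state 5 s before onset
matches the base state and report the per-second state occupancy over the
next 60 s; rows sum to one by construction. Hypnograms are fixed at 1-s
resolution.

## EEG/EMG features and cluster inference

`compute_ersp()` computes Hanning-tapered short-time log power around
onsets (−30..60 s, 1–50 Hz), averages log power over trials (no
single-trial normalization), and subtracts the per-frequency mean log
power over the −30..0 s baseline, reported as dB (10·log10). Using the
log-domain baseline makes baseline columns exactly 0 dB and renders the
map invariant to rescaling the raw trace. The taper window is the fixed
10-s cap of the original computation — a fixed-window FFT spectrogram, not
a wavelet — with the hop exposed as `step_s`. Window centers are placed
only where the full taper fits inside the trial window, so the time axis
shrinks by half a window at each end.

`emg_rms()` bins the EMG into 100-ms bins over −5..15 s, computes each
bin's RMS, subtracts the pre-onset bin mean per trial, and averages
0–4 s post-onset into the muscle-tone scalar.

`cluster_permutation_test()` compares per-mouse condition maps against
paired sham maps: a paired t-map is thresholded at the parametric
one-sided critical value for `alpha_cluster = 0.1`, supra-threshold cells
are grouped by 4-connectivity and scored by summed t (cluster mass), and
the max-cluster-mass null is built from sign-flips of the per-mouse
difference maps; cluster p = (1 + #{null ≥ observed}) / (n_perm + 1), so p
is bounded below by 1/(n_perm + 1). Connectivity and the mass statistic
are not specified by the source analyses; 4-connectivity and summed t are
the common defaults of time–frequency cluster inference. The "cluster
alpha / configuration alpha" pair of the original toolbox is read as the
cluster-forming threshold (0.1, one-sided), the only self-consistent
interpretation available. `cluster_mean_power()` averages each mouse's map
within a cluster mask and compares conditions by one-way ANOVA with
many-to-one (Dunnett) post hoc contrasts against sham.

## Anatomical distribution comparison

Counts of retrogradely labeled LC neurons live on an anteroposterior
(slice) × dorsoventral (100-µm strip) grid, with different slices
available per animal. `normalize_counts()` applies the yield-normalization
chain: per location, the expected yield is the mean count over
contributing animals; per animal, the animal yield is its total count and
the normal yield the sum of expected yields over its available locations;
each count is divided by expected yield × animal yield / normal yield.
Missing slices stay missing — they are never imputed as zero. Group
distributions are the group mean of normalized gradients times the
average (expected-yield) distribution, renormalized to a probability mass.

The overall two-group statistic is the square root of the weighted mean
squared difference between the two group maps (`diff_statistic()`),
following the prose definition; the printed formula block of the source is
typographically garbled, and the weighted root-mean-square reading is the
one its text states. Weights are the per-location fraction of animals
(both groups pooled) with numeric data — the natural reading of the
per-location animal-count weighting — with the unweighted variant behind
`weighted = FALSE`. `anatomy_permutation_test()` reallocates animals to
groups with sizes fixed: one-tailed for the overall statistic (reject for
large differences), two-tailed for the distribution-weighted mean DV/AP
location differences, computed on the joint AP × DV grid. When
choose(n, n1) ≤ 10,000 the null is enumerated exactly; otherwise 100,000
Monte Carlo draws are used by default, with ties counted against rejection.

Colocalization: per slice, the BF ratio is colocalized / BF-tagged cells
and the PRN ratio colocalized / PRN-tagged; per-mouse mean ratios are
tested against 1 by a one-sample t (one-sided, ratio < 1), the reading
under which the reported degrees of freedom (df = n − 1) are consistent.

## Synthetic data: what it emulates, and what it does not

`sim_config()` pins the generator to the study's conditions: 1017.25-Hz
sampling low-passed at 6 Hz, trials every 60 ± 0.5 s at 73/80/88 dB SPL
drawn uniformly, per-intensity awakening probabilities 27.94/34.44/38.16 %,
hourly LED on/off cycling, a 0.3–0.6-s surge and 1.8–3-s rise added to the
sensor channel on awakening trials, and exponential photobleaching shared
by both channels. Noise is iid Gaussian shaped by a 2nd-order 6-Hz
Butterworth low-pass (matching the acquisition chain's corner frequency)
and rescaled to `noise_sd` (default 0.3 % ΔF/F). Injected responses are
boxcars locked to the onset's nearest sample — stimulus delivery is
clocked by the acquisition DSP — so the injected window is recoverable
exactly. EEG is a sum of state-gated band-limited noise components (delta
and sigma in NREM, theta in REM, low-amplitude broadband in wake); EMG is
white noise with state-dependent amplitude. Cell counts are negative
binomial with a per-animal log-normal yield and whole slices missing at
random — the sources state no count noise model, and overdispersion
deliberately stresses the normalization chain. Inter-animal variance of
awakening probability is not reported anywhere; the generator therefore
leaves it a free parameter (per-intensity probabilities shared across
mice by default).

None of this is a biophysical model: there is no LC spiking, hemodynamics,
sensor kinetics, or realistic sleep microstructure. Passing tests
demonstrate that the statistical machinery is correct and calibrated under
known ground truth — not that the generator reproduces real recordings.

All generator randomness derives from one session seed split into
independent child seeds (`split_seed()`), so every artifact is
bit-reproducible.

## Numerical choices

* Kruskal–Wallis uses midranks with the tie-corrected statistic
  (`stats::kruskal.test`).
* The equicorrelation estimate is clipped to [0, 0.99]; zero-variance bins
  get t = 0.
* Exact permutation p-values are #{null ≥ observed}/K with the observed
  assignment included; Monte Carlo p-values use the add-one form. Ties
  count toward the null (conservative).
* Cluster t-maps set cells with zero variance to t = 0, so identical maps
  give an empty cluster set rather than 0/0.
* `epoch_trials()` drops (and logs) trials whose window leaves the valid
  span; an all-dropped epoch set is an error, as are degenerate fits,
  non-positive ΔF/F references (reported with their sample range), empty
  permutation groups and zero-variance ratio sets.
* Complete separation in the outcome model is detected by coefficient
  blow-up and answered by a flagged refit with weight decay 0.01.

## Problem sizes used in validation

The packaged validation suite runs, per fixed seed: 500 null cell-count
cohorts (8 vs 7 animals, 2,000 permutations each) for calibration of the
overall anatomical test; 100 recovery and 500 null window-detection
cohorts (7 mice × 40 trials); 20 instances of the many-to-one correction
against a 100,000-draw simulated max-statistic null; 200 exchangeable-null
paired map sets (15 × 20 cells, 6 mice, 199 sign-flip permutations) plus
injected-effect sets for the cluster engine; and full enumeration of the
discretized evidence space for the outcome rules. These sizes give
two-sided binomial 95% intervals tight enough to detect miscalibration of
a nominal 0.05 level while keeping the default suite quick to run on a
laptop; all of them scale up by changing one argument.

## Known limitations

* The many-to-one correction assumes equicorrelated bins; strongly
  structured correlation (e.g. long autocorrelation at coarse bin counts)
  is summarized by its mean.
* The ERSP uses a single fixed window length, so spectral resolution is
  constant across frequency.
* The behavior rules operate on already-extracted evidence intervals;
  deriving those intervals from raw EEG/EMG (automated sleep scoring) is
  out of scope, as are spike sorting, image processing and pupil analyses.
* With very sparse cell-count tables (many missing slices) some locations
  may have data from one group only; such locations carry low validity
  weight but are not excluded.
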