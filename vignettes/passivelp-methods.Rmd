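---
title: "Methods: passive EEG assays of low-level language processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: passive EEG assays of low-level language processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(passivelp)
```

## The two assays

`passivelp` implements two passive-listening EEG measures of low-level
language processing and the aggregation and cohort bookkeeping needed to use
them in disorders-of-consciousness populations. Both operate on the same
preprocessed recording of a subject listening to ~148 s of narrated speech,
and both produce *frequency maps* — channels × points matrices in [0, 1]
giving the fraction of comparisons (pairs, trials, or subjects) significant
at each cell.

**Differential phoneme-class response (DPR).** Phonemes annotated with their
start/end times are grouped into five manner-of-articulation classes:
approximants (A), fricatives (F), nasals (N), plosives (P), vowels (V). The
record is cut into 500 ms epochs starting at each phoneme onset
(`onset sample = round(start_s * rate) + 1`, 125 samples at 250 Hz); since
phonemes last ~79.5 ms on average the epochs overlap heavily, which is
intended — each epoch is a response to a phoneme *in context*. Epochs whose
window leaves the record or touches an artifact-masked sample are dropped and
counted; epochs containing any |amplitude| > 10 (standardized units) are
rejected as residual artifact. For each of the 10 class pairs, at each
(channel, timepoint), the across-epoch amplitude distributions are compared
with a two-tailed Wilcoxon rank-sum test; the Benjamini–Hochberg (BH)
step-up rule at α = 0.05 is applied across the 125 timepoints *within each
channel* (a global-scope family over all channels × timepoints is available
as an option). The trial map averages the ten 0/1 masks.

**Natural speech envelope (NSE) tracking.** The stimulus envelope is the
magnitude of the analytic signal of the (binaural-averaged) waveform,
anti-alias low-passed, interpolated onto the EEG grid, then put through the
same 2–15 Hz band-pass and standardization as the EEG. EEG and envelope are
cut into aligned non-overlapping 2 s segments; the statistic at channel `c`
and lag `L ∈ {0, 4, …, 500}` ms is the mean over segments of the
within-segment Pearson correlation between the envelope and the EEG delayed
by `L`. The null is built by re-pairing EEG segment `i` with envelope
segment `π(i)` for 10,000 random permutations `π` (the identity permutation,
which would reproduce the observed pairing, is excluded and re-drawn), and
the two-tailed empirical p-value is `(1 + #{|null| ≥ |obs|}) / (n_shuffles
+ 1)`, never exactly zero. Significance again uses within-channel BH-FDR.

## Preprocessing

Both assays share one cascade (`preprocess()`): a zero-phase 4th-order
Butterworth band-stop at 60 ± 2 Hz (mains), a zero-phase 4th-order
Butterworth band-pass 2–15 Hz, and per-channel standardization to zero mean
and unit variance. Zero-phase (forward–backward) filtering matters because
the assays interpret latencies down to 30–60 ms; a causal filter would shift
them. The forward–backward pass uses odd reflection padding at both ends to
suppress edge transients. Standardization statistics are computed over
non-artifact samples only.

Artifacts are handled by *masking, not deletion*: samples are flagged and
every epoch or segment touching a flagged sample is excluded downstream.
Deleting samples would silently shift all later annotation-to-sample
alignments. A trial is screened out entirely if more than 15 s is masked.

## Statistical choices

- **Rank-sum implementation.** For group sizes ≤ 8 the exact permutation
  distribution of the rank sum is enumerated on tie-adjusted mid-ranks (so
  the exact branch remains valid under ties); otherwise the normal
  approximation with tie and continuity correction is used. Degenerate cells
  (all amplitudes identical) get p = 1. The suite checks the exact branch
  against an independent enumeration oracle and the approximate branch
  against a uniformity check under the null.
- **BH step-up.** `k* = max{i : p_(i) ≤ i·α/m}`, rejecting the `k*`
  smallest p-values; ties at the threshold are all rejected. Implemented via
  `p.adjust(·, "BH") ≤ α`, verified against a brute-force implementation of
  the definition.
- **Chance level.** Under independence, BH at α over m points per channel
  yields ≈ α expected false-positive points per channel (0.05), i.e. a
  significant-cell frequency ≈ α/m ≈ 0.0004 for m = 125. This is the
  reference line attached to every frequency map.
- **Lag convention.** Only non-negative lags (EEG after audio) 0–500 ms are
  scanned, because physiological envelope-following responses occur at
  positive latencies.
- **Cross-correlation statistic.** The mean of per-segment Pearson
  correlations rather than one pooled covariance: per-segment normalization
  makes the statistic invariant to slow level drifts between segments and to
  any rescaling of a channel or the envelope.

## Aggregation and categorization

Trial maps are combined within subject by cellwise mean; subject maps are
combined by cellwise mean with **equal subject weight**, so a subject's
influence does not grow with their number of recordings. Group maps carry
`n_s` (subjects) and `n_v` (visits). Patient subjects are categorized by a
decision tree: **CF+** if any visit has a positive EEG or fMRI
motor-imagery command-following result; **LP+** if CF+ *or* any visit is
behaviourally MCS+ or eMCS; otherwise **LP−**. `not_done` contributes no
evidence in either direction — the tree asks for *evidence of* command
following, so an untested modality neither helps nor hurts. Tallies are
emitted at both subject level (any-visit evidence, each subject once) and
visit level, because cohort counts are reported both ways in practice and
subjects can change category between visits.

The packaged cohort fixture (`inst/extdata/subject_visits_table1.tsv`)
yields 24 patient subjects and 8 healthy controls over 31 visits, with 16
CF+ and 19 LP+ subjects.

## The synthetic-data generator

The generator (`synth_config()`, `generate_dataset()`) emulates the features
both analyses rely on; its defaults are the study conditions:

- **Annotation**: contiguous phonemes tiling the record; durations from a
  log-normal distribution truncated to [30, 320] ms whose truncated mean is
  exactly 79.5 ms (the log-scale spread, 0.4, is a realistic speech-timing
  value; the truncated-mean constraint fixes the location parameter by root
  finding). Class probabilities default to the narrative stimulus
  distribution A 163 : F 264 : N 147 : P 355 : V 617; concrete ARPAbet
  labels are drawn within class. Default duration 148 s, one presentation.
- **Envelope / audio**: per-phoneme loudness (class-dependent level with
  log-normal jitter) held over the interval, smoothed with a 10 ms Gaussian
  (hence non-negative); audio is a carrier tone amplitude-modulated by this
  envelope, so the envelope extractor can be tested end to end against the
  generating signal.
- **EEG**: unit-variance 1/f-shaped Gaussian noise band-passed to 2–15 Hz
  (so post-preprocessing variance is well defined), plus per-class half-sine
  evoked bumps (amplitude in SD units, onset latency and duration in ms,
  weighted across channels), plus the standardized envelope convolved with a
  half-sine kernel whose peak sits at a configurable lag, plus optional
  high-amplitude artifact bursts with ground truth returned as a mask.
  Half-sine templates are smooth, band-limited and analytically simple; the
  real study measures brain responses and has no generative model, so any
  smooth bump family is equally defensible.
- Default 8 channels (a compact 10–20 montage) keeps simulations fast; a
  37-channel mode mirrors the full recording montage.

What the generator does **not** emulate: phonetically realistic audio,
between-channel correlation structure of real EEG, realistic artifact
morphologies, subject-level anatomical variability. Passing recovery tests
therefore demonstrates correctness of the *statistical machinery* at
realistic SNR, not clinical performance on patient data.

Recovery behaviour worth knowing: with envelope coupling injected at kernel
peak lag T, the lag of maximum |statistic| recovers T to within ±8 ms (one
to two samples), but the *significant region* extends well to both sides of
T — the band-limited envelope autocorrelates over ~60 ms, so neighbouring
lags carry real correlation too. Recovery is therefore asserted on the peak
lag, not on the earliest significant lag.

## Null calibration: what we measured

`calibrate_dpr_null()` draws white-noise epochs (independent timepoints) for
the five classes at the stimulus class counts and runs the rank-sum + BH
stage. Measured (20 replicates × 10 pairs × 8 channels = 1600 channel-maps):
**0.054 false-positive points per channel** and an overall frequency of
**0.00044** — matching the independence approximation 0.05 and 0.0004.

`calibrate_nse_null()` simulates noise-only EEG against an unrelated
synthetic envelope and runs the full NSE stage. Here the measured
significant-lag frequency is **~0.003 (SE ~0.001, 60 replicates)** — an
order of magnitude above α/m. This is not a defect of the shuffle null (the
empirical p-values are valid and super-uniform, which the suite checks):
because both signals are band-limited to 2–15 Hz, the statistic and its
p-values are smooth across lags, and within-channel BH rejections arrive in
clusters of ~5–45 contiguous lags. The probability that a channel has *any*
rejection stays ≈ α (FDR remains controlled under this positive
dependence), but the expected *count* of rejected cells — which is what the
frequency measures — is several times α/m. Substituting white-noise EEG
changes little (~0.0025), since the envelope's own autocorrelation already
produces the clustering. The α/m chance line is therefore an
*independence approximation*: exact for the DPR null on white noise, but an
underestimate of the expected null frequency for lag-smooth statistics. Maps
should be read accordingly: isolated NSE cells at chance level are weaker
evidence than the same count scattered in a DPR map.

## Numerical and engineering notes

- Sample indices are 1-based (R convention); time stamps are seconds;
  intervals are half-open `[start, end)`. The sample at index `i` covers
  `[(i-1)/rate, i/rate)`.
- Subinterval summaries default to bins 0–80, 84–148, 152–300, 304–400,
  404–500 ms on the 4 ms grid (the 125-sample window spans 0–496 ms, so the
  last bin holds samples 101–124). Bin bounds must fall on the grid, must
  not overlap, and must cover every point.
- The shuffle null is computed exactly, not by looping: all pairwise
  (envelope i, EEG j) segment correlations are computed once per lag via a
  BLAS product, and each permutation's statistic is a sparse-matrix gather,
  which makes 10,000 shuffles over 126 lags × 8 channels take seconds.
- EDF output quantizes to 16 bits over each channel's physical range
  (relative error ~3 × 10⁻⁵); the delimited dialect is lossless. The whole
  record is stored as a single EDF data record so any duration keeps its
  exact sample count.
- Simulation sizes in the test suite (20 replicates for the DPR null, 20–40
  for the NSE null, single fixed-seed trials for recovery) were chosen to
  give Monte-Carlo standard errors comfortably inside the ±50% tolerances
  quoted for the calibration quantities while keeping a full run in the
  minutes range on one core.

## Known limitations

- Inter-subject variability in real cohorts is substantial; the group-level
  machinery here aggregates but does not model it.
- Phoneme-level (as opposed to class-level) contrasts, interactions with the
  preceding phoneme, frequency-band-resolved envelope tracking and
  temporal-response-function estimation are out of scope.
- Automated artifact detection is not provided; artifact intervals are an
  input (the study workflow uses visual inspection).
- The affricates CH and JH are unmapped in the default class map — their
  manner assignment is genuinely ambiguous (plosive onset, fricative
  release) and the published class counts do not pin it down; pass a custom
  map to include them.
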