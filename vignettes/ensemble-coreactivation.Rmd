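---
title: "Offline ensemble co-reactivation analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Offline ensemble co-reactivation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensemblelink)
```

## The problem

Single-cell calcium imaging with head-mounted miniscopes lets the same CA1
population be followed across days: a neutral context exposure, an aversive
experience, the offline home-cage periods that follow, and later recall
tests. After cross-registration of cell identities between sessions, cells
recorded during an offline period can be sorted into four memory ensembles:
**neutral** (matched only to cells active during neutral-context encoding),
**aversive** (matched only to aversive encoding), **overlap** (matched to
both), and **remaining** (matched to neither). `ensemblelink` implements the
offline analyses that ask how these ensembles behave during synchronous
population events, whether they co-reactivate, and whether that
co-reactivation predicts context-specific recall — together with the
supporting machinery: sleep scoring from EEG/EMG telemetry, linear-SVM
context decoding, and chemogenetic identification of putative inhibitory
neurons.

Because the recordings such analyses are designed for are not publicly
deposited, the package ships a first-class synthetic-experiment generator
(`simulate_experiment()`) that plants every effect the analyses are supposed
to detect — ensembles, population bursts, pairwise co-bursting, locomotion
dips, hypnograms, CNO responses — and returns the ground truth next to the
data. All statistical validation in the test suite runs against that ground
truth.

## Population bursts and participation

The burst detector follows the standard double z-score construction. Each
cell's deconvolved event train is z-scored along time (so no
high-amplitude cell dominates), the mean across cells is taken, and that
one-dimensional trace is z-scored again. Maximal runs of frames with the
trace strictly above `z = 2` are burst events; the peak is the largest
frame in the run, earliest on ties. There is no merging of nearby runs and
no minimum duration: the run definition is applied literally. Cells with
zero variance (silent cells) contribute all-zero rows rather than being
dropped, which keeps ensemble denominators stable; `population_trace()`
warns on an all-zero matrix instead of failing.

A cell *participates* in an event if its own z-scored trace exceeds
`z = 2` on at least one frame of the event (`cell_participation()`); the
any-frame reading was chosen over a mean-over-event reading because the
events last only a few frames at 30 Hz and a single deconvolved transient
is the natural unit of "being active during the event". Ensemble
participation (`ensemble_participation()`) averages, over events, the
fraction of each ensemble's cells participating.

Two properties of this construction are worth keeping in mind when reading
results:

* **Thresholds are relative.** Everything is z-scored per session, so a
  manipulation that adds variance to one trace (say, frequent co-bursting
  of one ensemble during wake) *raises that trace's threshold in raw
  units* everywhere, including during sleep. The state-resolved tests below
  show a measurable version of this effect.
* **Run counts are not monotone in the threshold.** Lowering the threshold
  can merge two events across a valley, so the event *count* may go up or
  down; what is monotone is supra-threshold time, and higher-threshold
  events always nest inside lower-threshold ones. The tests assert the
  nesting property, not count monotonicity.

### The circular-shift null

`shuffle_null()` rotates every cell's event train by an independent
uniform offset, preserving each cell's rate and autocorrelation while
destroying synchrony, and re-runs detection. Synchrony concentrates a
session's activity into few long, large threshold crossings; surrogates
spread the same events over many brief crossings of a flatter trace (any
unimodal trace spends roughly 2% of frames above its own 2-SD line). The
observed event count therefore sits in the **lower** tail of the null when
real synchrony is present, and `p_value` is the add-one lower-tail
probability on the count; `p_peak` (upper tail on the maximum z) is
returned as a complementary synchrony measure. On temporally independent
activity the observed count is a draw from its own null, which the
calibration test confirms (coverage of the central 95% interval ≈ 95%
over 100 simulations).

## Co-participation and cross-correlation

For co-bursting, the z-scored mean trace of each tracked ensemble
(neutral, aversive, overlap) is computed by the same per-cell z-score →
mean → z-score route, and an ensemble participates in a burst if its
trace exceeds `z = 2` within the event. *Independent* participation means
no other tracked ensemble participated in that event (remaining cells are
ignored for this purpose); a *pair* co-participates when both members
exceed threshold in the same event, regardless of the third.

Non-burst periods are made comparable to burst periods by partitioning the
frames outside all events into contiguous windows whose length equals the
session's median burst duration (remainders dropped), and applying the
same rule per window. The window length choice is the package's own: it
matches the temporal granularity of the burst statistic so that the
burst/non-burst contrast is interpretable. A frame-wise alternative was
considered and rejected because it conflates window count with window
length.

Time-lagged cross-correlations between ensemble traces use 120-s bins;
within each bin the Pearson correlation is evaluated at every integer lag
up to 5 frames (~160 ms at 30 Hz), the signed maximum over lags is taken,
and per-bin maxima are averaged. Trailing partial bins are dropped and
zero-variance bins are skipped with a count. For designs with repeated
10-minute offline recordings, `concatenate_offline()` joins per-session
ensemble traces into a pseudocontinuous series, re-z-scores it, and
records the join frames so that no burst event ever spans two recordings.

## Reactivation and population-vector statistics

`offline_ensemble_activity()` z-scores the offline matrix along both axes
(time, then cells), averages within ensembles and then within time bins
(default 60 s — the binning is only for display/summary granularity and is
exposed in the call). `recall_reactivation_fractions()` computes, among
cells active (≥ 1 event) in a recall session, the fraction previously in
each encoding ensemble; the reactivation index is the neutral-recall minus
novel-recall difference, positive when reactivation is context-specific.

One denominator subtlety drives the package's choice of null in the tests:
the reactivation fractions share a denominator (all recall-active cells),
so raising the *neutral* ensemble's reactivation in neutral recall
mechanically lowers the *overlap* fraction there even if overlap
reactivation is unchanged. A proper null therefore plants identical
reactivation probabilities in both contexts; the planted-effect arm plants
a genuine overlap preference (0.5 vs 0.15).

Encoding-to-recall similarity uses Kendall's tau-b (tie-corrected —
deconvolved mean vectors contain many zeros) between the whole-session
encoding mean vector and per-30-s-bin recall vectors, averaged over bins.
`stats::cor(method = "kendall")` computes tau-b; the test suite pins this
against an explicit O(n²) concordant/discordant pair count before relying
on it. The encoding discriminability matrix (`encoding_pv_matrix()`) bins
both encoding sessions, correlates all bin pairs (Pearson by default —
no flavour is canonical for this matrix, and the `method` argument exposes
the choice), and summarizes mean intra- versus inter-session correlations.

## Context decoding

`build_context_dataset()` aligns cells active in both encoding sessions
via the match table and trims the longer session from the end so classes
are balanced. `svm_decode()` runs 50 stratified random 50/50 splits of a
linear SVM (libsvm through e1071, cost 1 — the conventional default,
recorded in the result), reporting the held-out accuracy distribution;
`shuffled_control()` permutes labels independently per repeat. Frame
vectors are individual frames by default; `bin_s` optionally pools frames
(1-s bins make planted rate patterns nearly separable, single frames are
dominated by all-zero columns at 30 Hz — both regimes are tested).
Per-cell standardization using training-split statistics is on by default
and switchable. `decode_by_chemotag_fraction()` repeats decoding on fifths
of the cells ranked by tagging-day responsiveness, each with its own
shuffled control; ties in rank break by cell id so band membership is
deterministic.

## Sleep scoring

`score_sleep()` bins the 100-Hz record into 6-s epochs (enough slow-wave
cycles per epoch). Per-epoch EMG power is fit with a two-component
Gaussian mixture on the log scale; the lower-mean component is sleep.
Within sleep epochs the theta (5–9 Hz) to delta (0.5–4 Hz) band-power
ratio — band-pass filtered with a 4th-order zero-phase Butterworth filter —
is fit with a second two-component mixture; the higher component is REM.
Working on log power makes the scoring invariant to any global gain
applied jointly to both channels. Mixtures are fit with mclust, whose
model-based hierarchical initialization is deterministic, giving
reproducible component ordering without seeding. A fit is declared
degenerate when the two-component model fails to beat a single Gaussian by
BIC (or the components are closer than half a pooled SD); degenerate EMG
fits fall back to all-wake and degenerate ratio fits to all-NREM, each
with a prominent warning. Epochs with more than half their samples
missing become `unknown`, and frames outside any scored epoch are
`unknown` and excluded from state-specific statistics. Burst events take
the state of their peak frame.

## Chemotagging

`rank_chemotag()` min–max normalizes each cell's continuous CNO-session
trace to [0, 1] (absorbing any per-cell affine gain) and counts prominent
peaks within minutes 10–40. Prominence is the standard topographic
definition (height above the higher of the two base minima toward the
nearest higher terrain), with a default threshold of 0.3 of the normalized
range and a 2-s minimum peak spacing; both defaults are declared
parameters, not literature values, and are recorded in the result's
attributes. Cells are ranked by count (ties by id) and the top 10%
flagged, matching the anatomical inhibitory fraction in the CA1 pyramidal
layer. `propagate_labels()` carries counts to another session through the
match table; unmatched target cells receive zero activity (a receptor-
expressing cell would have responded to the agonist) and rank last.
Ensemble enrichment is assessed with an exact hypergeometric
over-representation test — the package's choice of test where no canonical
one exists.

## The synthetic experiment

`sim_config()` holds every generative knob. The defaults define the
simulated study conditions used throughout the tests:

* 60–300 cells per session; ensembles at roughly 10–17% each with a 10%
  overlap ensemble, the rest remaining.
* Background activity: per-cell homogeneous Bernoulli events at 0.05
  events/s with log-normal amplitudes — sparse deconvolved output.
* Bursts: 4/min, 0.5-s boxcars. Each burst recruits a baseline 15% of the
  whole population (a population burst is a population-level event) plus
  the cells of participating ensembles (overlap 0.9, neutral/aversive 0.5,
  remaining 0.1 at the ensemble level; 0.8 per cell within a participating
  ensemble). Firing cells receive one guaranteed event plus per-frame
  extras at 0.3, so planted bursts dominate the trace variance; without
  that, the frame-count discreteness of sparse event trains drowns any
  boxcar of single events.
* Pairwise co-bursting is planted through the joint law: overlap
  participates with probability 0.9 and the partner ensemble joins with
  conditional probability `c / 0.9`, making the planted joint probability
  exactly the configured coincidence. Participation-flag rows that come up
  all-false are redrawn (an empty burst is not a burst). When the
  requested marginal participation is incompatible with the joint law it
  is clamped to the nearest feasible value.
* Locomotion: a smoothed baseline with a raised-cosine dip starting 1 s
  before each burst peak and recovering 2 s after.
* Hypnograms: a Markov chain with mean dwell times of 20/15/5 epochs for
  wake/NREM/REM and REM entered only from NREM; EEG/EMG synthesized as
  state-scaled band-limited oscillations plus Gaussian noise (SD 0.3).
* Chemotag session: continuous traces at 2 Hz for 45 min; responding
  inhibitory cells emit ~3 prominent transients/min inside minutes 10–40,
  others 0.2/min, and every cell emits at least one spontaneous transient
  somewhere so that [0, 1] normalization is anchored by a real transient
  rather than amplifying recorder noise on a silent cell.

What the generator does *not* emulate: calcium indicator dynamics and
deconvolution artefacts, spatial footprints and registration errors (match
tables are ground truth unless configured otherwise), behaviour-dependent
rate changes outside bursts, and realistic EEG spectra beyond the two
scored bands. Passing tests therefore demonstrate that the analysis code
recovers the structure the analyses are defined on — not that the
generator is a biophysical model of CA1.

## Simulated design sizes used by the tests

The property suite and the acceptance script use deliberately scaled-down
designs, chosen once as the package's simulated study conditions:

* Co-bursting arms: 100 simulated mice per arm, 60 cells, 10-min offline
  sessions (~40 bursts each). Real offline periods are 1 h; at 5 min the
  per-mouse co-burst fraction rests on ~20 bursts and its sampling noise,
  not the method, limits recovery.
* Reactivation index: 100 mice per arm with 300-cell populations (a
  realistic miniscope yield; a 100-cell sketch left the ~10-cell overlap
  ensemble dominated by counting noise).
* Sleep scoring: one 2-h record (1,200 epochs) at default noise plus a
  noiseless-limit check.
* State-resolved co-bursting: 100 mice, 15-Hz imaging, 10-min sessions
  with planted wake-only coincidence.
* Decoding: 20 shared cells, 400/360-frame sessions, 1-s bins, 50 repeats.
* Null calibration: 100 noise sessions (30 cells × 100 s) × 100 shuffles.

## Known limitations

* The non-burst windowing rule (median burst duration) is one defensible
  reading of "the same computation for non-burst periods"; others exist.
* The cell-participation criterion is any-frame exceedance; a mean-over-
  event reading would be stricter for long events.
* Relative (z-scored) thresholds couple conditions across a session: in
  the wake-only co-bursting simulation the sleep-state overlap × neutral
  co-participation runs slightly *below* its counterpart because wake
  co-bursting inflates the neutral trace's variance. Analyses comparing
  states should keep this coupling in mind.
* The greedy reuse-cap repair in `align_calcium_to_target()` minimizes the
  worst single displacement, not the total; with a cap of 2 and realistic
  jitter it coincides with the exhaustive optimum in all tested cases
  where the cap does not bind.
* `Mclust`-based scoring assumes both states are present in the record;
  single-state records trigger the documented fallback rather than an
  attempt at single-sided inference.
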