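---
title: "Recognizing hand grips and movements from surface EMG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing hand grips and movements from surface EMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgrip)
```

## The problem

`semgrip` recognizes which of 25 hand activities — 24 grips and movements
organized in eight grip families, plus the neutral/rest posture (`NR`) — is
being performed, from eight channels of surface electromyogram (sEMG)
recorded over the forearm and biceps at 2 kHz. Two 3-axis accelerometers on
the back of the hand (148.1 Hz) provide no classification features; they
exist to tell *when* movements start, which drives labeling.

The collection protocol is a timed script: eight 120 s runs, one per grip
family, each containing 12 ten-second repetitions. A repetition engages the
family's base grip for 2–3 s, performs the family's one or two follow-on
movements at the 3 s and 5 s marks, and rests until the next repetition.
Two script slots are *hybrid* (grip-or-rest, movement-or-rest): the protocol
deliberately left them free, so no ground truth exists for them.

## The pipeline

### MAV features

The only EMG feature is the mean absolute value (MAV). For channel $j$ with
samples $f_j(iT_1)$, $T_1 = 1/2000$ s, instance $k$ is

$$g_j(kT) = \frac{1}{2N}\sum_{i=-N+1}^{N} \left|f_j(kT + iT_1)\right|,
\qquad T = 1/20 \text{ s}, \; N = 100,$$

a 100 ms window stepped every 50 ms: 20 instances/s, 2400 per 120 s run.
Windows at the end of a record are truncated and averaged over the samples
present, which is what makes the count exactly $\lfloor \text{dur}/T
\rfloor$. One instance is an 8-tuple, one per channel.

### Accelerometer-assisted labeling

The label evidence is the *summed absolute change* of the six hand-ACC
channels between consecutive points of a decimated grid (every 7th sample,
i.e. ≈21.1 steps/s; the decimation stride is our reconstruction of that
stated rate, which is not otherwise derivable from 148.1 Hz). A step is
motion evidence when it strictly exceeds **twice the run median**;
above-threshold steps closer than 150 ms merge into events (the merge gap is
a package choice; the protocol only speaks of "sequences" of changes).

Movements are dynamic, so their onset is an event *start*. Grips are
quasi-static: what the accelerometer sees is the reach toward the object,
ending when the grip is established — so a grip's start is the nearest
event *end* to its scheduled time. Both adjustments are clamped to ±500 ms
of the schedule; with no event in range the scheduled time is used and
counted as a fallback. Grip labels are sustained up to 3 s or until the
first movement onset; movements last until the next onset or their
scheduled duration; everything else is `NR`.

Hybrid slots are resolved to their first-named activity on both the
generation and the labeling side: the grip's ≤3 s sustain spans the
grip-or-rest second, and a movement's scheduled duration includes its
sustain second, with detected onsets always overriding scheduled boundaries.
A per-slot rest override would contradict the generator's default and there
is no protocol rule to prefer it; the inconsistency this introduces when a
subject actually rested in a hybrid slot is an inherent labeling limit, not
a resolvable one.

Rest dominates the raw track (≈40 %). Only NR instances from the run-start
window are kept — the one stretch where the subject is certainly resting.
The protocol's description of that window is internally inconsistent
("seconds one and three", "≈60 (3×20) per run", "seconds one to four"); we
keep seconds $[1, 4)$, matching the 60-per-run count: 480 NR instances over
eight runs. Each labeled activity is then cut into segments and truncated
to 40 instances (4 s), the cap that makes whole-segment comparison
tractable; all three approaches use the dataset in this form.

### SAX words

Each instance becomes an 8-letter *word*: per channel, the value is binned
into one of $n$ equal-probability intervals whose breakpoints are the
$k/n$ training quantiles (type 1, inverse empirical CDF; boundary values
fall to the lower interval — deterministic under ties). Codebooks are
fitted per channel across all classes on unnormalized MAV values: quantile
binning is invariant to affine channel scaling, so a prior z-score would be
redundant (a configuration flag allows it anyway). Alphabets are capped at
26 for letter rendering; internally words are integer rank tuples.

Two word distances matter:

* plain lexical distance $d_l(a,b) = \sum_k |a_k - b_k|$, used for
  nearest-word imputation;
* the modified lexical distance $D(a,b) = \sum_k \max(|a_k - b_k| - 1, 0)$,
  the DTW local cost. Adjacent symbols cost nothing — two values close to a
  shared bin boundary should not be a full symbol apart. $D$ is symmetric
  and nonnegative but deliberately not a metric (identity of indiscernibles
  fails for adjacent symbols).

### The affinity matrix (approach 2)

Training words and labels build a class-by-word count matrix $A$;
$\bar{A}$ row-normalizes it (each class row sums to 1) and $\hat{A}$ scales
each column of $\bar{A}$ to a unit vector. "Unit" is interpreted as
Euclidean by default — the conventional reading of "unit vector" — with L1
available via an option since nothing in the construction forces either
choice. A test word's evidence row is its $\hat{A}$ column; an
unseen word gets the unit-normalized sum of the columns of its nearest
vocabulary words under $d_l$, cached per classification call and never
written back into the model.

Classification of a word sequence sums, at position $i$, the evidence rows
of the current word and its $w$ predecessors (fewer near the start), and
takes the class of the largest summed value, ties toward the lower class
index. The summation sequence is one *labeled activity sequence* (≤ 40
words), not the concatenated run: the truncated-sum rule for the first $w$
positions, and a window parameter swept over 3–40 words (the segment cap),
both presuppose sequences that restart at activity boundaries. We verified
the alternative — summing across a concatenated test stream — and it fails
structurally: once $w$ exceeds a movement's 20 words, the previous
segment's evidence outvotes the current segment for its first $w/2$
positions regardless of how sharp the evidence is.

### Banded DTW (approach 3)

Whole segments are classified by 1-nearest-neighbor under dynamic time
warping over word sequences with local cost $D$: symmetric
match/insert/delete steps (no step weighting is specified, so the unweighted
pattern is used), boundary-aligned ends, and a Sakoe–Chiba band of ±5
(total width 11). Distances are not length-normalized, and distance ties go
to the earliest training segment. Recognition latency is probed by prefix
evaluation: for each prefix length $p$, the test prefix truncated to
$\min(p, \text{training length})$ is compared against every training
segment's equal-length prefix — so every comparison is equal-length, and
all prefix distances are the diagonal of a single dynamic program (the Rcpp
kernel returns that diagonal in one pass).

### Instance baselines (approach 1)

For context, individual instances are classified in isolation under
stratified 10-fold cross-validation, with channels z-scored by
training-fold statistics (population standard deviation; a degenerate
zero-variance channel is an error, never a silent division). Methods: CART
decision tree, 1-NN on normalized Euclidean distance, random forest with 25
trees, and an RBF-kernel SVM with cost 5. Pearson-universal-kernel (PUK)
SVMs are popular for this task in Java-based toolkits, but no R
implementation of that kernel exists; since the baselines are context
rather than contribution, the standard RBF kernel with the same cost
stands in.

## The protocol simulator

No public recordings exist for this protocol, so the package ships a
simulator whose outputs have known truth. The signal model is chosen so
downstream features have closed forms:

$$\text{emg}_j(t) = e_j(t)\,c(t)\,m_j(t) + \varepsilon_j(t)$$

* $e_j$: the envelope — per-interval class amplitudes (a 25×8 profile
  matrix, mV MAV scale) with 200 ms linear ramps;
* $c$: a ±1 carrier alternating every sample, so $|\text{emg}|$ recovers
  the envelope and the MAV of a constant stretch equals the class amplitude
  exactly when noise is off — the property the oracle tests use;
* $m_j$: lognormal force modulation in 50 ms blocks (instance-scale
  variability) plus a lognormal per-repetition effort scale;
* $\varepsilon_j$: white Gaussian noise.

Hand accelerometers carry 300 ms raised-cosine transients on all six
channels: full amplitude at movement onsets, half amplitude in the 300 ms
*preceding* a grip onset (the reach, ending when the grip is established —
which is exactly the cue the labeler uses). Scheduled boundaries are
jittered uniformly within ±300 ms (the protocol states its timings are only
accurate to a few hundred milliseconds; the bound must stay ≤500 ms). All
randomness derives from one integer seed; per-run seeds are master + group
index.

### Default subjects and calibration

Three stock profiles (`default_profile(1:3)`) mirror the three-subject
reporting structure. Their structure encodes two facts about real
recordings:

1. *Within-family similarity.* A family's movements are performed while its
   grip is held, so a movement's amplitude vector is 90 % of the family's
   grip vector plus bursts on the movement's own top-3 recruitment
   channels. Instantaneous amplitudes therefore overlap heavily within a
   family — which is where real confusions concentrate.
2. *Sequential firing.* Each movement class has per-channel activation
   peak times (Gaussian bumps over the interval, floor 0.55 of peak):
   classes that look alike at any instant differ in time course.

The noise scales (additive sd 0.02 mV, modulation CV 0.35, repetition CV
0.2) were calibrated once so that the instance-level baseline lands in the
70–85 % band reported for real subjects on this task, then frozen. Without
that calibration a plateau-envelope simulation is near-perfectly separable
instance by instance, a regime in which temporal context cannot help and
which contradicts every published account of this problem. The qualitative
behaviors the test suite asserts (context window helping, the
DTW ≥ affinity ≥ instance-baseline ordering) were *not* themselves tuned;
they emerge from this structure or they fail.

Two special profiles exist for verification: `noiseless_profile()` (all
stochastic elements off, flat envelopes — exact recovery: truth onsets on
scheduled seconds, MAV equal to class amplitude, 100 % onset detection
within one 50 ms step) and `separable_profile()` (near-orthogonal
activation patterns on distinct channel pairs, minimal noise — both
sequence classifiers should exceed 95 %).

What the simulator does *not* emulate: motor-unit physiology, electrode
crosstalk, fatigue drift, electrode lift artifacts, or inter-subject
electrode placement variability. Passing tests therefore demonstrate that
the *algorithms* behave as specified on data with the protocol's
statistical structure; they say nothing about accuracy on any particular
human recording.

## Evaluation

Both sequence classifiers use leave-one-repetition-out: 12 folds, fold $k$
testing on the $k$-th repetition's segments from all eight runs. The
retained 480 run-start NR instances are partitioned sequentially into
twelve disjoint 40-word chunks, one per fold (≈5–6 % of a fold's words):
rest is represented in every split while folds stay disjoint. (Adding
*all* NR words to every fold, the literal alternative, would leak test rest
into training.) Codebooks, channel statistics and affinity counts are
always fitted on the 11 training folds only.

Affinity accuracy is word-level over all test sequences; DTW accuracy is
segment-level, scored at prefix $\min(20, \text{length})$ — 20 words (1 s)
being where the accuracy-by-word-count curve flattens — with the full curve
pooled across folds. Confusion matrices (rows = truth) are summed across
folds, and accuracy always equals trace/total of the summed matrix by
construction. Multi-profile sweeps report per-cell low–high ranges across
profiles (`sweep_report()`), the conventional multi-subject presentation.

Instance baselines use stratified 10-fold cross-validation on the pooled
instance dataset (truncated segment instances plus retained NR), each
class's instances spread within one instance of evenly across folds.

## Numerical choices and degenerate inputs

* Quantile type 1 everywhere; values equal to a breakpoint take the lower
  symbol; a constant channel collapses to the lowest rank.
* Argmax ties break toward the lower class index in catalogue order; at
  `w = 0` the affinity classifier bypasses the cumulative-sum window
  entirely so that exact ties resolve identically to the per-instance rule
  (cumulative sums would otherwise perturb ties by round-off).
* Nearest-instant matching between the ACC and MAV grids resolves exact
  midpoints to the earlier instant.
* 1-NN distance ties go to the earliest training segment.
* DTW on length-mismatched sequences whose difference exceeds the band is
  an error (no path exists); equal-length comparisons are always feasible.
* All simulation, fold assignment and stochastic learners are seeded;
  repeated calls are bit-identical.

## Problem sizes used in the shipped tests

The test suite simulates full-protocol sessions (eight 120 s runs, 2400
instances each) for a handful of seeds and profiles, which keeps the
complete suite in the low minutes on one core: oracle-equivalence checks
use 1000 random word-sequence pairs of length ≤ 12, and the
qualitative-ordering checks use five sessions with a majority-of-seeds
criterion, reflecting that single-session orderings are stochastic.

## Known limitations

* The ACC summary rate (every 7th sample) is a reconstruction of a stated
  21.1/s figure whose derivation is not documented.
* Hybrid protocol slots have no ground truth by design; any resolution
  (ours: first-named activity) mislabels the occasions a subject did the
  alternative.
* The affinity classifier's per-activity-sequence summation assumes segment
  boundaries are known at test time (they come from the same ACC labeling
  that produced the training segments); a fully streaming deployment would
  need an online segmenter.
* Baseline SVM results use an RBF kernel rather than a Pearson-universal
  kernel and are context only, not a kernel-for-kernel comparison with
  other toolkits.
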