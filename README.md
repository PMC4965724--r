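# semgrip

Recognition of hand grips and movements from multichannel surface
electromyograms (sEMG), for researchers in myoelectric control and
upper-extremity rehabilitation who need a tested, reproducible
reference implementation of a symbolic-stream recognition pipeline.

The task is a 25-class problem: 24 grips and movements of the hand and
wrist, organized in eight grip families (hammer, tip pinch, 3-jaw chuck,
key, scissors, door knob, jar lid, ball), plus the neutral/rest posture.
Inputs are eight sEMG channels at 2 kHz from the forearm and biceps and two
3-axis hand accelerometers at 148.1 Hz used only for labeling.

## The methods

**Features.** Each channel is reduced to mean absolute values over 100 ms
windows stepped every 50 ms:

    g_j(kT) = (1/2N) * sum_{i=-N+1..N} |f_j(kT + i*T1)|,   T = 1/20 s, N = 100

giving 20 eight-tuple instances per second. Instances are discretized into
8-letter *words* by per-channel equal-probability (quantile) binning over an
n-symbol alphabet.

**Classifiers**, in increasing order of temporal context:

1. *Instance baselines* — decision tree, 1-NN, random forest (25 trees),
   SVM (cost 5) on isolated instances, stratified 10-fold CV.
2. *Affinity matrix* — a class-by-word count matrix `A` is row-normalized
   (`Ā`, rows sum to 1) then column-normalized to unit vectors (`Â`).
   A word's evidence row is its `Â` column (nearest-word imputation under
   lexical distance `d_l(a,b) = Σ|a_k − b_k|` for unseen words); the
   prediction at stream position i is the argmax of the evidence summed
   over the current and the previous `w` words of the activity sequence.
3. *Banded DTW 1-NN* — whole activity segments (≤ 40 words) compared by
   dynamic time warping with a Sakoe–Chiba band of ±5 (width 11) and the
   modified lexical local cost

       D(a,b) = Σ_k d(a_k, b_k),  d = 0 if equal, |a_k − b_k| − 1 otherwise

   (adjacent symbols cost nothing), evaluated at every prefix length to
   measure how quickly a movement becomes recognizable.

Because no public recordings exist for this protocol, the package includes
a protocol simulator (`generate_run()`, `generate_dataset()`) that produces
synthetic eight-run sessions — 12 ten-second scripted repetitions per run,
accelerometer transients at movement onsets, a few hundred milliseconds of
timing jitter — with known ground truth, plus the accelerometer-assisted
labeling chain used on real exports (onset = summed ACC change exceeding
twice the run median).

## A worked example

Simulate one synthetic subject's full session, label it from the schedule
plus accelerometer evidence, and evaluate all three approaches with
leave-one-repetition-out folds:

```r
library(semgrip)
data  <- prepare_subject_data(default_profile(1), seed = 42)
folds <- make_repetition_folds(data)

rf  <- run_baseline(data$instances, data$instance_labels, "rf", seed = 42)
aff <- evaluate_affinity(data, folds, n = 11, w = 30)
dtw <- evaluate_dtw(data, folds, n = 15)
```

Output:

```
instance RF(25):    89.26 %
affinity n=11 w=30: 91.62 %
DTW n=15 @20 words: 95.66 %
DTW curve: 81.6 % at 3 words -> 95.3 % at 20 words
```

Reading: classifying isolated 100 ms instances leaves errors concentrated
within grip families (movements of one family overlap instant-by-instant);
summing affinity evidence over a 30-word window within each activity
sequence recovers part of that; matching whole word sequences with DTW does
best, and its accuracy-by-word-count curve shows most of the benefit is
already present one second (20 words) into a movement. The same ordering —
DTW ≥ affinity ≥ instance baseline, with context windows helping — is what
the test suite asserts across seeds.

A command-line front end covering the pipeline stage by stage (simulate,
featurize, label, sax-fit, affinity-train/-classify, dtw-classify,
evaluate, sweep) is installed under `inst/cli/semgrip`.

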