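---
title: "Speaker verification risk for pathological speech: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speaker verification risk for pathological speech: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinical speech recordings are a biomarker: dysglossia, dysarthria,
dysphonia and cleft lip and palate (CLP) all leave measurable traces in the
acoustic signal. The same traces that make speech clinically useful also
make it identifying. This package studies that tension quantitatively: it
implements a text-independent automatic speaker verification (ASV) system
and an experiment harness that measures, via the equal error rate (EER),
how re-identifiable speakers are under controlled conditions — pathology
group, microphone channel, age structure, training-set size, and speech
intelligibility (word recognition rate, WRR). A lower EER means an attacker
can more reliably link a voice to a patient, i.e. less anonymity.

Because real clinical corpora of this kind cannot be redistributed, the
package ships a synthetic-corpus generator that reproduces the statistical
structure the analysis depends on, so every downstream stage is fully
testable from code alone.

## The verification model

The encoder maps a sequence of 40-dimensional log-mel filterbank frames to
a unit-norm embedding (d-vector) through stacked LSTM layers and a final
linear projection; the full architecture is 3 layers x 768 hidden units
projected to 256 dimensions, and all of these are reducible for desk-scale
runs (`encoder_config()`). Training uses the generalized end-to-end (GE2E)
objective. A batch holds `N` speakers with `M` partial utterances each;
with `e_ji` the embedding of utterance `i` of speaker `j` and `c_k` the
arithmetic-mean centroid of speaker `k`, the similarity matrix is

    S[j,i,k] = w * cos(e_ji, c_k) + b

with trainable scale `w > 0` and offset `b`, and the centroid of the *true*
speaker computed leave-one-out (the probe embedding is excluded) to keep
training stable. The loss is the mean softmax cross-entropy over the
similarity rows:

    L(e_ji) = -S[j,i,j] + log sum_k exp(S[j,i,k])
    L_G     = mean over (j, i) of L(e_ji)

`similarity_matrix()` and `ge2e_loss()` expose exactly these definitions in
R; training (`ge2e_train()`) runs the same forward pass plus analytic
backpropagation in compiled code, verified in the test suite against
finite differences and against naive scalar re-implementations.

Optimization is Adam with the global gradient L2 norm clipped at 3,
Xavier-normal weight initialization with zero biases (including the LSTM
forget gates — initialized literally to zero), and training always starts
from scratch. The similarity parameters start at `(w, b) = (10, -5)`, the
convention of the GE2E method this system adopts, and `w` is clamped to
stay positive after each step so similarity remains increasing in cosine.
The projection takes the top layer's final-frame output; per-layer
projections of the original recurrent architecture are deliberately not
replicated, matching the single-projection variant implemented here. The
published learning-rate range for the full architecture is 1e-5 to 1e-4
(default 5e-5); reduced desk-scale encoders are trained at 1e-3 to 2e-3,
chosen the same way the full rates were — so that the network converges
well within the step budget.

Training runs a fixed step budget rather than early stopping on a held-out
loss: at desk scale a held-out GE2E loss estimated from a handful of
synthetic speakers is noisier than the compute it saves, and a fixed budget
makes every run exactly reproducible from its seed.

## Front-end

`prune_low_energy()` removes 10 ms frames more than 30 dB below the
utterance's peak frame level. The dB reference is the utterance's own peak
because absolute sound pressure is unrecoverable from digital samples.

`detect_voice_activity()` is a short-time-energy VAD with the three
published constants: 30 ms energy windows, silent gaps of up to 6 ms
bridged, and an 8 ms moving-average smoothing of the activity decision. The
threshold adapts to the signal (35 dB below the peak envelope). The
original system cited an external VAD whose internals are unpublished;
this one is behavior-compatible (honors the three stated constants), not
bit-compatible.

`extract_partials()` keeps contiguous voiced stretches of at least 1825 ms
(29200 samples at 16 kHz). `log_mel()` uses a 25 ms periodic Hann window,
10 ms hop, 512-point FFT and 40 triangular mel filters. Unstated dialect
choices are pinned in `frontend_config()`: Slaney-style mel scale, 0 Hz to
Nyquist band edges, no padding or centering (so a waveform of `n` samples
yields `1 + floor((n - 400) / 160)` frames), and `max(energy, 1e-10)`
before the log so features are always finite.

`make_training_batch()` samples `N` speakers and `M` distinct partials per
speaker and crops all of them to one common length drawn uniformly from a
configured range — 140 to 180 frames by default, which keeps crops inside
the minimum partial length; desk-scale runs use shorter ranges to cut
training cost linearly in sequence length.

## Evaluation

For evaluation, an utterance's partials are concatenated, a 160-frame
window with 50% overlap slides over the features, each window is encoded,
and the window d-vectors are averaged element-wise and re-normalized to
unit length (the re-normalization is the adopted method's convention; the
averaged vector itself is not unit-norm). With the default `eval_M = 2`
each test speaker contributes one enrollment utterance (the speaker model)
and one probe; which utterances play which role is a seeded random choice
per repetition. Every probe is scored with the cosine score against every
enrolled speaker model — its own gives the genuine trial, all others give
impostor trials — so the evaluation batch spans the whole test set.

`compute_eer()` sweeps all observed scores as thresholds; FAR is the
fraction of impostor scores at or above the threshold, FRR the fraction of
genuine scores below it. The EER is the common value at the FAR/FRR
crossing, linearly interpolated between the bracketing thresholds, ties
broken toward the lower threshold. The EER is therefore invariant under
any strictly increasing transform of the scores, and the implementation is
tested against an exhaustive sweep oracle.

## The synthetic corpus generator

`synth_corpus()` emulates the statistical structure of a clinical speech
corpus without any speech content:

* **Identity.** Each speaker has a stable vocal signature: base f0 (set by
  sex and age), a formant pattern scaled by a per-speaker vocal-tract
  factor with per-formant idiosyncrasy, bandwidths and speaking rate.
  Between-speaker parameter distances exceed within-speaker variation, so
  identity exists for the verifier to find.
* **Synthesis.** Classic source-filter synthesis: a glottal pulse train
  with cycle-to-cycle jitter and shimmer, -6 dB/oct spectral tilt,
  aspiration noise, and a cascade of second-order formant resonators whose
  targets move per syllable. A trained text-to-speech system would be
  heavier and no more useful here: the study needs speaker-discriminative
  structure, not intelligible German.
* **Pathology.** Group labels are operationalized at the level the ASV
  front-end can see: dysphonia as high jitter/shimmer/breathiness, CLP as
  hypernasality (a nasal resonance plus an antiresonance notch),
  dysarthria as slowed articulation with reduced formant-transition depth,
  dysglossia as persistent formant-target displacement.
* **Channels.** Each microphone label (`dnt`, `plant`, `logi`) applies a
  fixed, distinct coloration FIR and noise floor. No acoustic measurements
  of the physical headsets exist, so the filters are arbitrary-but-fixed
  distinguishable confounds.
* **Demographics.** Ages and WRR are drawn per cohort from normal
  distributions whose means and spreads follow the corpus statistics of
  the study population (adult pathology groups around 60 years, children
  2-20 years, WRR means between roughly 48% and 74%), clipped to valid
  ranges. WRR is sampled independently of every identity parameter — the
  structural ground truth behind the near-zero EER-WRR correlations.
* **Structure for the front-end.** Utterances are 3.2-4.2 s with one or
  two silent gaps of 0.1-0.3 s, so voiced content stays above 2.5 s and
  every utterance survives voice activity detection with at least one
  partial of 1825 ms. Speakers default to 10 utterances, comfortably above
  the 8-utterance exclusion rule.
* **Seeding.** Seeds are hierarchical (master -> speaker -> utterance), so
  any subset of the corpus is reproducible independently and regeneration
  is byte-identical.

What the generator does **not** emulate: phonetic content and
intelligibility (WRR is metadata, not a property of the audio), room
acoustics, recording-session drift, or the heavy-tailed quality problems
of field recordings. Passing tests on this corpus therefore demonstrate
that the pipeline is correct and that the experimental logic behaves as
designed — not that the specific EER levels of any real clinical corpus
are reproduced. Real-data EERs cannot be recomputed without the private
corpus.

## Corpus curation rules

`apply_exclusion_filters()` mirrors the curation of the clinical corpus:
speakers missing WRR, diagnosis, age, microphone or recording environment
are purged; utterances flagged noisy, test-irrelevant or containing
multiple speakers are dropped (the manifest carries these as categorical
quality flags — the original human judgments are not re-derivable from
audio); speakers left with fewer than 8 utterances are excluded. The
8-utterance minimum is counted after the utterance-level drops. The age
split assigns speakers above 20 years to the adults subset and 2-20 years
(inclusive on both ends) to children; age exactly 20 is a child.

## Experiment harness

`run_experiment()` follows the study protocol: per repetition, sample the
cohort (optionally steering ages toward a target distribution by weighted
sampling — used for children, where the population allows matching), split
speakers 80/20 into disjoint training and test sets, train from scratch,
and evaluate the EER on the held-out speakers, recording the test set's
mean WRR alongside. Results aggregate as mean ± sd over repetitions (the
study protocol uses 20). `training_size_sweep()` repeats this across
speaker counts; `fit_log_regression()` fits `EER = a + b ln(n)` by
ordinary least squares.

`compare_groups()` runs Shapiro-Wilk normality checks and a two-tailed
unpaired t-test, pooled-variance Student's t by default (the textbook
unpaired test) with a Welch switch; significance is declared at P <= 0.05
and no multiple-testing correction is applied across group comparisons,
matching the study's analysis. `correlate_eer_wrr()` pairs each
repetition's EER with its test set's mean WRR — the study does not state
whether its correlations were computed across repetitions, speakers or
experiments, and the per-repetition pairing is the documented choice here.

## Desk-scale problem sizes

The test suite and the acceptance script run the full pipeline at sizes a
single CPU handles in minutes, chosen once: corpora of 15-80 speakers with
8-10 utterances each; a reduced encoder of 2 LSTM layers x 64 hidden units
and 32-dimensional embeddings (16-dimensional for the correlation study);
120-200 training steps at learning rate 1e-3; batch crops of 80-120 frames
(40-60 for the correlation study). Under these conditions the desk-scale
study reaches mean EERs of a few percent on held-out speakers, the
training-size sweep shows the qualitative logarithmic trend, and the
EER-WRR correlation stays near zero. Two desk-scale caveats are worth
naming: with 10-speaker corpora the 2-speaker test set makes the EER
nearly always zero (a test-difficulty floor, not a training effect), and
per-repetition EERs are coarsely quantized at small test sizes, which is
why trend assertions are made within one pooled standard deviation.

## Known limitations

* The VAD and microphone channels are behaviorally plausible stand-ins,
  not reproductions of the original tooling or hardware.
* The synthetic corpus cannot validate claims about real pathological
  speech — only about the pipeline and experimental design.
* WRR is treated as manifest metadata; the speech-recognition system that
  produces it in the clinical setting is out of scope.
* Supplementary evaluation with more enrollment utterances (`eval_M > 2`)
  is supported by the same code path but not exercised by the shipped
  studies.
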