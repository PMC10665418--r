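# pathasv

Speaker-verification risk analysis for pathological speech.

Clinical speech recordings (dysglossia, dysarthria, dysphonia, cleft lip
and palate) are increasingly used as biomarkers — and the same acoustic
traces that carry clinical signal also identify the patient. `pathasv`
implements a text-independent automatic speaker verification (ASV) system
and the experiment harness needed to quantify re-identification risk as an
equal error rate (EER): the lower the EER, the easier it is to link a
voice to a patient.

The core is a d-vector system trained with the generalized end-to-end
(GE2E) loss. A stacked-LSTM encoder maps 40-band log-mel features to
unit-norm embeddings `e_ji`; a batch of `N` speakers x `M` partial
utterances forms the similarity matrix

```
S[j,i,k] = w · cos(e_ji, c_k) + b
```

against the speaker centroids `c_k` (leave-one-out for the true speaker),
and the loss is the mean of `-S[j,i,j] + log Σ_k exp(S[j,i,k])`. Training
(Adam, gradient-norm clipping at 3, Xavier-normal init) runs in compiled
code with analytic backpropagation, cross-checked in the tests against
finite differences and brute-force oracles. Evaluation slides a 160-frame
window (50% overlap) over each utterance, averages window d-vectors,
scores probes against enrollment centroids by cosine, and sweeps the
threshold for the FAR/FRR crossing.

Because the clinical corpus this design targets is not redistributable,
the package includes a source-filter speech synthesizer that generates
corpora with the statistical structure the analysis needs: stable
per-speaker vocal signatures, group-specific pathology perturbations,
distinct microphone channels, realistic age/WRR distributions, and
silences that exercise the voice-activity-detection stage.

## Worked example

```r
library(pathasv)

# a small synthetic corpus: 30 speakers across all pathology groups
cfg <- synth_config(groups = default_group_table(c(4, 4, 4, 3, 3, 6, 6)),
                    master_seed = 501)
dir <- tempfile()
manifest <- synth_corpus(cfg, dir)
manifest
#> <corpus_manifest> 30 speakers, 300 utterances (mixed subset)
#>   speakers by group: CLP=6, control=12, dysarthria=4, dysglossia=4, dysphonia=4

features <- prepare_features(manifest, dir)

# 20 training / 10 test speakers, 5 resampling repetitions,
# reduced encoder (2 LSTM x 64 hidden, 32-d embeddings)
spec <- experiment_spec("desk-30", n_speakers = 30, train_fraction = 2/3,
                        repetitions = 5, seed = 1)
res <- run_experiment(
  manifest, spec, features = features,
  encoder_cfg = encoder_config(2, 64, 32),
  train_cfg = train_config(learning_rate = 1e-3, steps = 200, N = 16, M = 4,
                           crop_frames = c(80L, 120L)))
res
#> <experiment_result> desk-30: EER 3.78 +/- 2.93 % (5 repetitions)
res$eers
#> [1] 5.555556 3.333333 0.000000 7.777778 2.222222
```

A mean EER of a few percent on held-out synthetic speakers means the
encoder has learned channel- and pathology-robust speaker identity — on
this corpus a speaker is re-identified against 9 impostors with ~96%
reliability at the operating point. The per-repetition spread reflects
which speakers land in the 10-speaker test set.

The statistical layer reproduces the published logarithmic relationship
between training-set size and EER exactly from its four operating points:

```r
fit_log_regression(c(50, 500, 1500, 3000), c(5.19, 1.87, 1.15, 0.90))
#> <regression_fit> y = 9.154324 -1.080997 * ln(x), R^2 = 0.9525
```

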