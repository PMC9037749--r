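# weakbeat

Beat-by-beat ECG arrhythmia detection (AAMI classes N / SVEB / VEB) trained
from **record-level labels only**. Expert beat-level annotation is scarce;
record-level findings ("contains ventricular ectopy") are abundant in
clinical archives. `weakbeat` turns such coarse labels into a beat-level
detector for cardiology and physiological-signal researchers working with
single-lead ECG.

## Method

A 1D residual convolutional network produces per-sample class probabilities
ŷ<sub>i,c</sub> over {N, S, V}, fused with two knowledge-based feature maps
computed from the R-peak sequence:

* **relative RR interval** I<sub>R</sub> = s·(I<sub>N</sub> − I<sub>A</sub>)/I<sub>N</sub>,
  the scaled shortening of the current RR interval I<sub>A</sub> against the
  mean I<sub>N</sub> of a 60-interval context (premature beats positive);
* **RR entropy**: sample entropy (m = 1, r = 0.05) of the median-normalized
  RR series in sliding 60-interval windows (rhythm irregularity).

Record-level supervision reaches the beats through **masked global max
pooling (MGMP)**: the per-class global score is
f<sub>c</sub> = max<sub>i∈R</sub> ŷ<sub>i,c</sub> over the R-peak set R, optimized with a
class-weighted multi-label binary cross-entropy on the record's label set
(weights 4 / 2 / 0.1 for records with both, one, or no ectopic classes).
GAP, GMP and LSE(b) pooling are included as ablation baselines. An optional
supervised pre-training stage (categorical cross-entropy at annotated R
peaks, 10 epochs on a small finely annotated set) stabilizes the otherwise
ill-posed weak training. Evaluation is beat-level: sensitivity,
specificity, positive predictivity, accuracy, F1 and precision-recall /
average precision per class, with F and Q beats excluded.

A seeded synthetic single-lead ECG generator (Gaussian-bump morphologies,
rhythm grammars with compensatory vs non-compensatory pauses, AF-like
irregularity, bigeminy, baseline wander and noise) provides fully annotated
benchmark corpora; see the methods vignette
(`vignettes/weakbeat-methods.Rmd`) for the model, parameter and generator
details.

## Worked example

Train a detector on 120 synthetic records with record labels only (plus 20
finely annotated records for pre-training) and evaluate on held-out data:

```r
library(weakbeat)

train <- prepare_records(generate_dataset(120, seed = 101)$records)
val   <- prepare_records(generate_dataset(40,  seed = 202)$records)
test  <- prepare_records(generate_dataset(40,  seed = 303)$records)

set.seed(1)
model <- wb_model()
fit <- two_stage_train(model, train[1:20], train, val,
                       train_config(seed = 1), aggregation_config("MGMP"))
evaluate_beats(fit$model, test)
#> <metrics_report> 1033 evaluated beats
#>   N: Sen 0.994  Spe 0.821  Ppr 0.982  Acc 0.978  F1 0.988  AP 0.999
#>   S: Sen 0.696  Spe 0.994  Ppr 0.867  Acc 0.978  F1 0.772  AP 0.886
#>   V: Sen 1.000  Spe 1.000  Ppr 1.000  Acc 1.000  F1 1.000  AP 1.000
```

Ventricular ectopy (wide QRS) is recovered perfectly from record labels
alone; supraventricular ectopy — whose evidence is contextual RR shortening,
not morphology — is harder and improves with corpus size (the 400-record
benchmark below reaches S F1 around 0.8-0.95). Per-beat
probabilities are available via `local_predict(fit$model, test[[1]])`, and
`beat_decisions()` reads the class at each R peak.

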