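---
title: "Weakly supervised beat-by-beat arrhythmia detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised beat-by-beat arrhythmia detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Beat-level annotation of ECG recordings — marking every heartbeat as normal
(N), supraventricular ectopic (SVEB, class S) or ventricular ectopic (VEB,
class V) under the AAMI EC57 grouping — is expensive: experts must agree on
every single beat. Record-level annotation ("this recording contains VEB")
is vastly cheaper and already exists at scale in clinical archives.
`weakbeat` trains a *beat-by-beat* detector from *record-level* label sets
only, by combining per-sample local prediction with an aggregation step that
ties beat-level behavior to the record-level supervision.

## Model

An input recording is preprocessed, then two feature streams are computed
and fused:

1. **Learned features.** A 1D residual convolutional network. An initial
   convolution projects the single lead to 32 channels; each of 4 residual
   blocks applies Conv–BatchNorm–ReLU–Dropout–Conv–BatchNorm, adds the block
   input, applies ReLU, and halves the length with max-pooling (nine
   convolutional layers in total, 32 kernels of length 8, dropout 0.25, He
   initialization). The output is upsampled back to the input length by
   nearest-neighbor repetition so it aligns per sample with the input.
2. **Knowledge features.** Two per-sample maps built from the R-peak
   sequence (see below): the relative RR interval and the RR sample
   entropy.

A time-distributed dense layer over the concatenated 32 + 2 channels emits
3 logits per sample; a per-sample softmax gives the local probabilities
`y[i, c]`. The class of a beat is read off at its R peak.

### Aggregation

Training only has record labels, so local predictions must be reduced to a
per-class global score `f_c ∈ [0, 1]`:

* **GAP** — mean of `y[·, c]`: dilutes rare events (one ectopic beat in a
  20 s strip barely moves the mean);
* **GMP** — max of `y[·, c]`: the class is present if it occurs anywhere;
* **LSE(b)** — `(1/b) log mean exp(b·y)`: a smooth compromise, approaching
  GAP as `b → 0` and GMP as `b → ∞`. Note the exact bias
  `|LSE(b) − GMP| ≤ log(n)/b`: at `b = 1000` and `n = 2500` samples this is
  ~8e-3, which is the attainable agreement, not a defect;
* **MGMP** (the default) — GMP restricted to the R-peak samples. Only the
  R-peak predictions receive gradient, so after training the prediction at
  each R peak is representative of its beat; the hypothesis space shrinks
  by orders of magnitude because reference points are sparse.

### Losses

Multiple rhythms can coexist, so the record loss is a multi-label mean
binary cross-entropy over the three classes, with `t_c = 1` when class `c`
is in the record's label set. Aggregated scores are clamped to
`[1e-7, 1 − 1e-7]` before the logarithms because GMP/MGMP can emit exact 0
or 1. Class imbalance is countered by per-record weights: 4 when the label
set contains both S and V, 2 for exactly one of them, 0.1 for neither.

Supervised pre-training minimizes categorical cross-entropy of the local
predictions at annotated R peaks (excluded F/Q beats are skipped). The
two-stage strategy — a fixed 10-epoch supervised stage on a small finely
annotated set, then weak training — exists because weak training is
ill-posed: several labelings of the beats can satisfy the record labels,
and runs may converge to the wrong one. Pre-training anchors the hypothesis.

## Knowledge features

Both features need R-peak positions. When beat annotations exist they are
used directly; otherwise a classical detector (5–18 Hz band-limited energy,
150 ms integration, adaptive threshold, 200 ms refractory) stands in. Each
beat owns the region between the midpoints of its neighboring RR intervals;
feature values are painted constant over beat regions, giving maps exactly
as long as the signal.

**Relative RR interval** `I_R = s · (I_N − I_A) / I_N`, with `I_A` the RR
interval ending at the beat's R peak and `I_N` the mean of up to 60 RR
intervals in a window centered on the current one (clamped at the record
edges; all intervals when fewer than 60 exist). `s = 10` amplifies the
feature so the classifier does not ignore it. The sign convention makes
*premature* beats positive, which ReLU-based networks pick up more readily.
The first beat owns no interval and inherits the second beat's value — the
alternative (zero or an edge value) would paint an artificial spike at
record start.

**RR entropy**: sample entropy (`m = 1`, match threshold `r = 0.05`,
Chebyshev distance, the standard convention in which both template lengths
use the first `n − m` starting positions) of the median-normalized RR
series, computed in sliding 60-interval windows; each value is painted on
the window's central (31st) beat and edge beats take their nearest painted
neighbor. When fewer than 60 intervals exist a single window covers them
all. Undefined values (no template matches) are capped at `log(P + 1)`
(`P` = number of template pairs) so maps stay finite — the paper-standard
alternative of `Inf` would poison the dense layer. Regular sinus rhythm
gives values near 0; atrial-fibrillation-like irregularity and (jittered)
bigeminy give clearly higher values. A perfectly deterministic alternation
would have entropy 0 — predictability, not variance, is what SampEn
measures — which is why the synthetic generator jitters its pauses.

## Preprocessing

Fixed order: (1) baseline estimate by a centered 1 s moving average
(shrinking windows at the edges avoid phase shift), subtracted; (2)
zero-phase 2nd-order Butterworth band-pass 0.1–30 Hz (forward–backward, so
R peaks do not move — the masked aggregation depends on this); (3) Fourier
resampling to 125 Hz, skipped when the native rate is within 3 Hz (so
128 Hz recordings pass through); the band-limiting in step 2 prevents
aliasing, and the frequency-domain method is phase-exact so beat positions
rescale exactly; (4) standardization to mean 0, variance 1 (population
convention). Records are zero-padded or truncated to 20 s for batch
processing; a per-record validity count excludes padding from aggregation.
Feature maps are computed before padding and padded with zeros alongside.

The pipeline is *not* exactly idempotent: the moving-average baseline
estimator has gain `sinc(f · 1 s)` inside the pass band (≈ 0.64 at 0.5 Hz),
so a second application removes a little real low-frequency content. This
is intrinsic to moving-average detrending, not a filter choice; the test
suite asserts the honest version (a second pass perturbs the signal far
less than the first and leaves R-peak timing intact).

**Label complementation.** Coarse labels of a recording containing ectopy
usually omit the sinus label. If a label set contains S or V and neither
supraventricular tachyarrhythmia nor idioventricular rhythm, N is added:
under those conditions normal beats are almost certainly present too. The
two auxiliary tags block the rule because in those rhythms ectopic beats
can occur in runs without interleaved sinus beats.

## Training protocol

Adam (`lr = 0.001`, `β₁ = 0.9`, `β₂ = 0.999`), batches of 16 records in
the weak stage. The supervised stage uses small batches
(`pretrain_batch_size = 4`): finely annotated sets are small by design
(tens of records), and at the weak-stage batch size the fixed 10-epoch
budget would deliver only a handful of optimizer updates — far too few to
anchor the weak stage, which is the entire purpose of pre-training. With
~50 updates the anchor works and the weak stage converges in roughly half
the epochs. Validation runs after every epoch using mean beat-level F1
over the three
classes (beat-level because validation sets carry beat annotations; a
record-level alternative is available via `val_metric`). Early stopping
with patience 10 restores the best-epoch parameters. Weak training runs at
most `max_epochs = 15` epochs by default: on the bundled 400-record
benchmark validation F1 passes 0.95 within about 12 epochs, and the cap
keeps a full multi-seed experiment affordable on one CPU core; raise it for
larger or harder corpora. All stochastic elements (initialization via the
caller's `set.seed`, shuffling, dropout) draw from the single R random
stream, so a seed reproduces a run exactly.

## The synthetic benchmark

The generator builds 20 s single-lead records at 125 Hz with known
beat-level truth. Beat templates are sums of Gaussian bumps: N has a P
wave, a narrow (< 100 ms) QRS and an upright T; S is the same narrow QRS
*without* a timely P wave — deliberately overlapping N in amplitude so
morphology alone cannot separate them and the RR-context features must
carry the signal, which mirrors real SVEB; V has a wide (> 140 ms),
high-amplitude QRS with a discordant T. Rhythm grammars encode the
distinguishing context: S beats arrive early (preceding RR uniform in
0.55–0.8 of the sinus cycle) with a non-compensatory pause (next RR is an
ordinary sinus interval), V beats arrive early with a compensatory pause
(the flanking intervals sum to ≈ 2 sinus cycles, plus physiological
jitter); `af_like` draws i.i.d. RR from 0.6–1.1 of the cycle; bigeminy
alternates normal and ectopic beats. Sinus RR jitter is 0.02 s (beat-to-beat
variability of a resting rhythm), baseline wander 0.1 mV at 0.3 Hz, white
noise 0.03 mV — visible but non-destructive.

Corpora are drawn with a category mix (S-only / V-only / both / neither
records, default 0.2/0.2/0.1/0.5, the 'neither' group including AF-like
records so high RR entropy alone never implies ectopy). Category
assignments are shuffled so any subset — such as the 20 records used for
pre-training — is representative; a category whose random draw produced no
required ectopic gets one forced in. Per-record seeds derive from the
master seed, so corpora are reproducible and disjoint seeds give disjoint
records.

What the generator does *not* emulate: real QRS morphology variability
across patients and leads, bundle-branch-block N beats, fusion beats,
electrode artifacts, atrial activity during AF. Passing the recovery
benchmark therefore shows the *mechanism* works — record labels plus masked
aggregation suffice to recover beat-level structure when the class evidence
is present — not that the trained weights transfer to hospital data.

## Benchmark problem sizes

The recovery experiment trains on 400 records (100 validation, 100 test,
mix as above), two-stage with pre-training on 20 finely annotated records,
repeated over 4 seeds. Supporting experiments are run compact: the 10-seed
stability comparison (weak-only versus pre-trained) uses 64/24/24 records
with 10 epochs, and the single-seed aggregation ablation uses 120/32/32
records with 10 epochs. These sizes are the package's chosen benchmark
conditions; the stability and ablation checks are qualitative direction
checks, and their compact corpora make the contrast visible while a full
multi-seed run at the recovery scale remains available to users via the
exported functions.

## Numerical choices and degenerate inputs

* Argmax ties at a beat resolve to N, the a-priori majority class —
  conservative toward fewer false ectopic alarms.
* 0/0 metric ratios (e.g. positive predictivity with no positive calls)
  report 0 with a flag, so mean-F1 early stopping never sees NaN.
* Average precision uses the step-wise sum over distinct-score thresholds;
  it is exactly invariant to monotone score transforms, and undefined (NA,
  flagged) when a class has no positive beats.
* Constant signals normalize to zeros with a warning; records with fewer
  than two R peaks get all-zero feature maps with a warning; empty label
  sets after mapping are surfaced with a warning and left to the caller.
* Backbone pooling uses floor division (2500 → 156 at the defaults);
  upsampling repeats each feature 16× and right-pads by repetition to the
  exact input length.
* Max-pooling ties take the first index; this only affects subgradient
  routing, not values.
* Detector-mode evaluation matches detected peaks to reference annotations
  within 150 ms (nearest peak); with annotated peaks no matching is needed.

A caveat on the compact stability comparison: the interesting regime is the
one where pure weak training is *polarized* — succeeding on some seeds and
collapsing on others (large spread) — while the pre-trained variant is
consistently good (small spread). That regime needs corpora and training
budgets well beyond the compact sizes above; at compact scale pure weak
training collapses uniformly for the S class, and a uniform failure has a
deceptively small standard deviation. The spread comparison is therefore
only meaningful alongside the means, which at every scale we have run show
the pre-training rescue effect clearly.

## Known limitations

* The S class remains the hardest: its evidence is contextual, and
  supraventricular runs (SVTA-like) where prematurity fades are not part of
  the generator's grammar.
* Training is single-lead; lead selection prefers lead II/MLII and falls
  back to the first lead.
* The hand-written network targets this architecture family
  (Conv/BN/ReLU/Dropout residual blocks with max-pooling); swapping in
  arbitrary backbones requires implementing their backward passes.
* WFDB support covers headers, signal formats 212 and 16, and MIT-format
  beat annotations — enough to read the common arrhythmia databases' lead-II
  signals, not the full format zoo.
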