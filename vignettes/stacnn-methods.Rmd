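---
title: "Decoding a two-stage audio-assisted visual speller with a spatial-temporal attention CNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding a two-stage audio-assisted visual speller with a spatial-temporal attention CNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stacnn)
```

## The speller paradigm

`stacnn` implements an event-related-potential (ERP) brain–computer
interface speller that selects one of 40 characters in two stages.

**Stage 1 — group selection by SDMA coding.** The 40 characters are split
into 8 groups of 5, laid out at fixed positions in the visual field. Every
group is assigned a distinct 3-bit code; in each of three 0.5 s sub-trials
(a 0.3 s motion-onset stimulus followed by a 0.2 s gap), all groups whose
code has that bit set emit a simultaneous moving-bar stimulus. This is
space-division multiple access (SDMA): the eight spatial locations share
the same 1.5 s stimulation window, and the attended group is identified by
which code sequence the brain responses match. Motion-onset stimuli evoke
the mVEP complex — P1 (~90 ms), N2 (~130 ms), P2 (~195 ms) over
temporo-occipital/parietal cortex with right-hemisphere dominance — on
sub-trials where the attended group moves, and (approximately) nothing on
sub-trials where it does not.

**Stage 2 — character selection by an audio-assisted oddball.** The five
characters of the chosen group are presented one at a time, in random
order, each moving bar accompanied by the spoken name of the character
(0.5 s slot, 2.5 s total). Attending one character among five is an oddball
paradigm: the attended presentation evokes the mVEP components at shortened
latencies (~50/90/180 ms, an audiovisual-integration effect) plus a P300 at
~350 ms.

A character therefore costs 8 stimulus presentations (3 + 5). If group and
within-group position were both coded in parallel the information-theoretic
floor would be ceil(log2 8) + ceil(log2 5) = 6; a classical row/column
matrix speller of the same 40 characters needs 5 + 8 = 13 flashes. Chance
level is 1/40 = 2.5%.

Only one group code is fixed by the published material: the group
containing "A" carries "101". The remaining assignment of the eight 3-bit
codes (including "000", the never-flashing group) to groups in reading
order is a package convention, overridable via `build_codebook(codes =
...)`. Likewise "40 alphanumeric characters" under-determines the set (26
letters + 10 digits = 36); the default charset appends four punctuation
marks (`. ? ! _`), as in common 40-target speller layouts.

## The synthetic session generator

No public recordings accompany the paradigm, so the package ships a
generator that produces complete sessions with ground truth
(`simulate_session()`):

* **Evoked responses** are sums of Gaussian components
  (amplitude × exp(−(t − latency)² / 2σ²)) with σ = 20 ms (50 ms for the
  P300) and ±5 µV default amplitudes, scaled by `snr_scale`. Topographies
  fall off as a Gaussian from a right-parietal centroid ("P4", falloff 0.45
  in schematic head coordinates), giving the right-dominant
  parietal/temporo-occipital pattern of mVEP and P300 components.
  Nontarget templates are empty: stage-1 sub-trials in which the attended
  group does not move still contain stimulation elsewhere in the visual
  field, but the non-attended responses are modelled as fully
  attention-gated (no evoked signal), matching the flat nontarget grand
  averages the paradigm produces.
* **Background EEG** is 1/f^α noise (α = 1 by default, RMS 10 µV per
  channel), generated by frequency-domain shaping of white Gaussian noise,
  independent across the 64 recorded channels (62 scalp + mastoids M1/M2).
  Spatial correlation, ocular/muscle artifacts, and alpha rhythms are not
  modelled: tests passing on this substrate demonstrate correctness of the
  pipeline and the claimed qualitative behaviours, not performance on real
  EEG.
* **Trial-to-trial variability**: `latency_jitter_sd` shifts each evoked
  response by a per-trial Gaussian delay (truncated at 2.5 sd) and
  `amplitude_jitter_sd` scales it (Gaussian around 1, floored at 0.2).
  Both default to 0 — so the grand average of target epochs converges
  exactly to the rendered template — but single-trial ERP latency and
  amplitude are famously variable, and that variability is the stated
  motivation for attention-based decoding; the ablation experiments below
  therefore enable it explicitly.
* Every source of randomness (noise, stage-2 presentation orders, jitter)
  derives from one master seed; identical configurations reproduce
  sessions bit-exactly.

Sessions mimic the acquisition geometry: 64 channels at 1000 Hz with
markers at every stimulus onset, 8 per character, 3 + 5 across the two
stages. A 467-character session reproduces the paradigm's segment
bookkeeping: 467 target and 4 × 467 = 1868 nontarget stage-2 epochs; the
stage-1 target count is the summed popcount of the attended groups' codes,
which depends on the spelled text.

## Preprocessing

`preprocess_pipeline()` replicates the published chain in order:

1. **Re-reference** to the mean of the bilateral mastoids (M1/M2), dropping
   them (64 → 62 channels). Re-referencing precedes filtering.
2. **Band-pass 1–30 Hz**, 4th-order Butterworth applied forward–backward
   (`signal::filtfilt`). The band is prescribed; the realisation is not —
   zero-phase filtering is chosen because it preserves ERP latencies, which
   matter downstream. The 30 Hz edge also anti-aliases the next step.
3. **Resample to 200 Hz** by decimation (keep every 5th sample); event
   indices are remapped by `round(index / 5)` (0-based convention on disk,
   1-based inside R).
4. **Epoch**: −0.1 to 0.5 s around each marker; the mean of the −0.1–0 s
   baseline is subtracted per channel; the stored epoch covers 0–0.5 s.
   At 200 Hz that is a 62 × 100 matrix. A 0.6 s window at 200 Hz would be
   120 samples; the 100-sample contract is only consistent with the
   baseline segment being dropped after correction, which is what the
   package does. Events too close to a recording edge are skipped with a
   warning and counted.

## The STA-CNN decoder

The decoder is a four-module CNN operating on single 62 × 100 epochs,
binary target/nontarget output:

| module | layers | output (filters, channels, time) |
|---|---|---|
| 1 | reshape, conv (1, 50) pad (24, 25), batch-norm, ELU | (16, 62, 100) |
| 2 | temporal attention, conv (1, 51), batch-norm, ELU, dropout 0.5 | (32, 62, 50) |
| 3 | spatial attention, conv (62, 1), batch-norm, ELU, max-pool (1, 5)/5, dropout 0.5 | (4, 1, 10) |
| 4 | flatten (40), dense, softmax | 2 |

Both attention blocks share one mechanism: average-pool the feature map
over the complementary axis (channels for temporal attention, time for
spatial attention), push each filter's pooled vector through a bottleneck
(`Linear1` + tanh, then `Linear2`), and softmax along the attended axis.
The resulting probability vector reweights the feature map elementwise;
only average pooling feeds the attention (no max-pooling branch), which is
deliberate — max statistics are noise-sensitive on EEG.

Because no deep-learning framework is available to (or wanted by) this
package, the forward and backward passes are implemented directly on R's
BLAS: time convolutions are banded-matrix GEMMs, the spatial convolution is
a tensor contraction, and a small set of C++ kernels handles the
elementwise hot path. All gradients are verified against central finite
differences in the test suite (relative agreement ~1e−8 on a reduced
geometry).

Choices the architecture description leaves open, fixed as follows:

* **Attention bottleneck width**: half the attended axis, rounded up (50
  temporal, 31 spatial), configurable. A mild squeeze regularises without
  starving the block.
* **Linear layers carry biases**; attention weights are shared across
  filters (the pooled-statistics formulation indexes no filter-specific
  weights).
* **No rescaling after the attention product**: multiplying by a
  probability vector shrinks activations by ~1/axis-length; the following
  batch-norm absorbs exactly that scale. This makes the attention-free CNN
  variant equivalent to an STA-CNN forced to emit uniform weights — a
  property the test suite checks with the batch-norm stability constant
  `bn_eps` set to 0, because a nonzero eps breaks exact scale invariance
  (with the default 1e−5 the agreement is only ~5%, which is the expected
  size of the eps perturbation at 1/100 scaling, not a bug).
* **Convolutions carry no bias terms**: every convolution feeds a
  batch-norm, which makes a conv bias exactly redundant (its gradient under
  train-mode batch statistics is identically zero).
* **Batch-norm** eps 1e−5, momentum 0.1, unbiased running variance; **ELU**
  α = 1; weight init is seeded uniform fan-in (bound 1/sqrt(fan_in)).
* **Attention output layers are zero-initialised**, so the initial attention
  is exactly uniform over its axis and every deviation from uniformity is
  data-driven. This matters for interpretability: with random init the
  softmax retains arbitrary bumps at latencies/channels that carry no
  class information (the gradient there is ~0, so they are never erased),
  which contaminates the averaged attention profiles. It also means the
  full model starts training from the CNN variant's function class and can
  only depart from it where attention reduces the loss.
* Softmax is computed with max subtraction; inputs up to 1e4 in magnitude
  do not overflow.

Ablation variants mirror the published ones: `CNN` (both attention blocks
replaced by identity), `TA-CNN` (temporal only), `SA-CNN` (spatial only),
`STA-CNN` (both). Parameter counts are strictly ordered CNN < TA-CNN,
SA-CNN < STA-CNN.

## Training and decoding

Training (`train_decoder()`) uses Adam (default learning rate 1e−3, batch
64 — unstated upstream, conventional here) on the categorical
cross-entropy, for up to `max_passes` full passes ("300 training
iterations" is read as 300 passes); after each pass the validation loss is
evaluated and the weights with the lowest validation loss are retained —
checkpointing, not early stopping. The validation set is a seeded
stratified 10% of the training epochs. Stage-2 training targets are
replicated 3 extra times so 300 targets balance 1200 nontargets. Splits are
by character block: the first 300 spelled characters feed train+validation,
the remaining 167 are the test set.

Decoding is offline copy-spelling:

* **Stage 1**: the three sub-trial target probabilities are matched against
  all eight group codes by Bernoulli log-likelihood,
  argmax_g Σ_k [bit_k(g) log p_k + (1 − bit_k(g)) log(1 − p_k)], ties to
  the lowest group index (a hard-threshold Hamming rule is available via
  `rule = "hamming"`). The published description ("the group code
  corresponding classifier output was chosen") does not pin the rule;
  likelihood matching dominates hard thresholding and degrades gracefully.
* **Stage 2**: argmax of the five slot probabilities, ties to the lowest
  index.
* A character is correct iff both stages are correct; stage 2 is always
  decoded against the true group's five presented characters, since the
  stage accuracies are defined independently in copy-spelling.

`evaluate_decoding()` reports per-stage and total accuracies plus
epoch-level accuracy/F1 with target as the positive class;
`paired_ttest()` wraps the two-sided paired t-test used for
between-method comparisons and turns the zero-variance case into an
explicit error. `attention_report()` averages the temporal and spatial
attention probability vectors over test epochs and filters, the quantity
used to relate learned weights to component latencies and active channels.

## Numerical and scale choices in the test suite

The packaged experiments are sized for a single CPU:

* The architecture contract, decoding rules, attention normalisation and
  gradient checks are exact and cheap.
* Parameter-recovery experiments train on one simulated 467-character
  session (300 train / 167 test characters) at high SNR (`snr_scale = 3`,
  10 µV noise). The stage-2 decoder trains for one pass at batch 32 (67
  Adam steps — the separable high-SNR substrate converges within a pass;
  held-out epoch accuracy ≈ 0.999); the stage-1 decoder used for the
  attention analysis trains for four passes at learning rate 3e−3. The
  full 300-pass protocol remains available via `train_config()`.
* The ablation comparison (STA-CNN vs CNN) runs on one shared 60-character
  session at `snr_scale = 2` with trial-level jitter (latency sd 20 ms,
  amplitude sd 0.25) — the inter-trial variability regime that motivates
  attention — with 10 paired training seeds (24 training characters,
  batch 16, 3 passes each) and a one-sided sign test on the per-seed
  test-accuracy differences. At this scale the qualitative ordering
  reproduces (STA-CNN ahead in most seeds) but a sign test with n = 10
  needs 9 one-sided wins, so the significance check is underpowered; a
  larger per-seed training budget sharpens it at proportionally higher
  cost.

## Known limitations

* The simulator's noise is spatially independent and stationary; no
  artifacts, no alpha; nontarget responses are exactly zero. Real-EEG
  performance claims cannot be made from these tests.
* The published subject-level accuracies (e.g. 59.6% / 77.7% / 45.2%)
  require the original recordings, which are available only on request;
  they are out of scope here.
* Attention-weight localisation is an emergent property of training, not
  an architectural guarantee: module-1 kernels span ±125 ms around each
  output sample, so a feature (and hence its attention peak) can be offset
  from the underlying component latency, especially at short training
  budgets.
* EDF input/output is not implemented (no EDF library in the supported
  stack); the portable binary container with a JSON sidecar is the
  interchange format.
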