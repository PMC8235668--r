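---
title: "Methods: hierarchical cascade detection of gait events from smart-insole telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical cascade detection of gait events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A sensorised insole reports 20 channels at an average 4 Hz: 16 piezoelectric
plantar-pressure sensors arrayed heel to toe, one temperature sensor and a
3-axis accelerometer. From short histories of these channels the system must
decide, in near real time, which of six walking behaviours the wearer is
performing — sitting, standing still, standing with imbalance, walking,
running, or stumbling — and raise an alert on the two fall-risk behaviours
(imbalance and stumbling). `gaitcascade` implements the full pipeline:
telemetry ingestion, window construction, a seeded synthetic-data generator,
five small binary neural classifiers arranged in a decision cascade,
hyperparameter search with a ranked registry for sensor-failure fallback,
streaming inference, and the evaluation suite.

## Ingestion and timestamp alignment

Each device message is a JSON object with a timestamp and exactly 16
pressure readings. Two timestamp dialects are accepted — the firmware's
colon-before-fraction form (`17:12:24:6847`) and standard dot notation —
and all output is normalised to ISO-8601 with a dot.

The accelerometer and temperature readings arrive with an unspecified delay
relative to the pressure messages. Alignment is last-observation-carried-
forward: each pressure timestamp takes the auxiliary reading nearest
at-or-before it, so every frame shares the pressure clock. Interpolation was
deliberately avoided: the delay magnitude is unknown and LOCF never
fabricates values. Pressure frames preceding the first auxiliary reading
have nothing to carry forward; they are dropped and counted, a bounded head
loss consistent with discarding the historyless start of each recording.
Device units are treated as opaque throughout — no physical calibration is
attempted.

## Windows and splits

A classifier input is the matrix of the last $w$ frames (rows, oldest
first) by the selected channels (columns, fixed order: pressures 0–15,
temperature, three acceleration axes), with $4 \le w \le 32$. Windows never
cross recording boundaries and the first $w-1$ frames of a recording yield
no window. The stride between prediction instants defaults to 1 (maximal
data) and is configurable.

The 60/20/20 train/validation/test split is stratified per class with
largest-remainder allocation, which keeps every partition within one sample
of its target proportion (ties favour train, so small remainders tend to
enlarge the training set). Two split units are offered:

* `by = "window"` (default) splits individual windows, matching the way the
  collected samples were originally divided;
* `by = "recording"` assigns whole recordings to one partition. Overlapping
  windows from a single recording are nearly identical, so window-level
  splits leak temporal context between partitions and flatter the measured
  performance; the recording-level mode is the honest choice when enough
  recordings exist.

## The synthetic generator

No recordings are distributed with the method, so the package ships a
seeded generator (`gait_sim_config()`, `simulate_recording()`,
`simulate_dataset()`) whose defaults define the test-bench conditions used
throughout the test suite and the acceptance script. The signal families
are deliberately simple — sinusoidal gait waves, Gaussian noise,
Poisson-timed bursts — chosen to give each event a distinguishing temporal
structure rather than biomechanical fidelity:

* **sitting** — low constant pressure (30 device units, sd 5) with
  occasional foot-shift bursts;
* **standing still** — static heel (350) and forefoot (250) load, midfoot
  120, near-zero acceleration variance, rare small foot taps;
* **standing with imbalance** — the standing baseline modulated by a
  0.4 Hz sway (±120) of opposite sign on medial and lateral sensor bands,
  with a matched acceleration oscillation (0.3 g);
* **walking** — a squared raised-cosine pressure wave (amplitude 450) at
  1.0 Hz cadence sweeping heel to toe via per-sensor phase offsets spanning
  0.35 of the cycle, plus periodic acceleration (0.35 g);
* **running** — the same wave at 1.7 Hz and amplitude 800 with a 35 %
  flight-phase duty cycle during which total pressure collapses to noise,
  and stronger acceleration (0.9 g);
* **stumbling** — the walking signal with transient anomalies at 0.6
  bursts/s: a ~3 g acceleration spike over 3 frames plus irregular pressure
  jitter (±300) on a random half of the sensors.

The squared raised cosine keeps the fundamental frequency dominant in the
periodogram of summed pressure, so cadence is spectrally identifiable. The
running cadence defaults to 1.7 Hz rather than a typical two-footed step
rate: only one shoe is instrumented, so the relevant rate is single-foot
strides, and the 4 Hz sampling clock imposes a 2 Hz Nyquist limit above
which any configured cadence would alias and become unmeasurable.
Temperature is a slow random walk (lag-1 autocorrelation above 0.9).
Pressures are clipped at zero.

What the generator does **not** emulate: subject-to-subject variability,
sensor drift and saturation, gait asymmetries, transitions between
behaviours within one recording, and packet loss. Tests passing on this
generator therefore demonstrate that the pipeline is correct and that the
learning problems are well-posed — not that the shipped configurations
would reach any particular accuracy on real recordings.

## The classifiers

Each cascade node is a small binary network built from a configuration in
the search space: 1–11 hidden dense layers of 1–64 units (tanh or selu),
optionally preceded by a 1-D convolution over time (1–50 filters, kernel
2–32, selu or sigmoid, optional size-2 max pooling) or an LSTM (1–50
units); learning rate in {0.1, 0.01, 0.001}; sgd, adam or rmsprop; batch
size 1–50; window length 4–32; and any non-empty channel subset. The
output head is always a single sigmoid unit.

Wiring order is fixed and documented rather than searched: convolution
(plus pooling) → LSTM → dense stack → head. When neither convolution nor
LSTM is present, the hidden dense layers are time-distributed over the
window (the same weights applied to every frame) and flattened before the
head; this preserves the temporal axis for purely dense models instead of
collapsing it at the input.

Training minimises binary cross-entropy with natural logarithms,
probabilities clipped to $[10^{-7}, 1-10^{-7}]$. Regularisation follows
common practice where the method leaves details open: dropout 0.2 after
each hidden dense layer, early stopping on validation loss with patience 10
(5 in the desk-scale runs) and best-epoch weight restoration. Channels are
z-scored with statistics fitted on the training partition only and stored
in the model — raw device units are O(100–1000) and unscaled gradient
training fails. Class weighting is off by default (optional
inverse-frequency weights are available); thresholding happens downstream
in the cascade. Weight initialisation is Glorot-uniform under the model
seed, and the engine is plain deterministic R, so training is exactly
reproducible given (seed, configuration, data). The reverse-mode gradients
of every layer type are verified against central-difference numerical
differentiation in the test suite.

## Hyperparameter search and the registry

`run_search()` samples configurations either uniformly at random or with a
tree-structured Parzen estimator. The TPE here is the independent
per-parameter variant: after a startup phase of random trials, trials are
ranked by validation AUC and divided into a good fraction (top 30 %) and
the rest; numeric parameters draw candidates from a Gaussian kernel
density over the good values and keep the candidate maximising the
good/bad density ratio, categorical parameters maximise the smoothed
count ratio, and each of the 20 channels is toggled as its own binary
parameter (with one channel forced on if all fall off). The trial budget
defaults to 50; desk-scale runs and the tests use far fewer.

Every trained model is inserted into a registry sorted per node by
validation AUC (descending; earlier trials win ties — a stable sort).
`best_without(registry, node, failed_channels)` returns the top-ranked
model whose inputs avoid the failed channels; if none exists the node
reports itself unavailable. This is the sensor-failure fallback: the
detector keeps running on the best surviving model.

## The cascade

Six events are decided by five binary nodes in a fixed tree. The root
separates sitting from everything else; the non-sitting branch separates
still from moving; still splits into stable vs imbalance; moving splits
into stumbling vs gait; gait splits into walking vs running. Class 0 is
always the calmer pole. Each node thresholds its sigmoid output at 0.5 by
default (the decision rule is configurable; no other cut-off is implied by
the method). Each visited node may use its own window length and channel
subset; the streaming buffer is sized to the largest selected window and
each node slices its own suffix.

A prediction carries its decision path and a path probability: the product
of taken-branch probabilities ($p$ on 1-branches, $1-p$ on 0-branches), a
confidence-like score in $[0,1]$. For one-vs-rest AUCs each event receives
the product of branch probabilities along its leaf path; these leaf scores
sum to at most 1 over events. Risk events are standing imbalance and
stumbling; streaming inference forwards each risk-flagged result exactly
once to an abstract alert sink (a collector and a JSON-lines file sink ship
with the package).

Enumerating all decision vectors shows the tree reaches exactly the six
events, and with perfect oracle node models the cascade reconstructs every
label — the hierarchy itself loses no information.

## Metrics

From confusion counts: accuracy, precision, recall, specificity, NPV and
F1, each by its defining formula; a zero denominator yields an explicit
undefined value (never 0), flagged in the report. AUC is the rank-based
Mann–Whitney statistic with ties counted one half, exactly the pairwise
positive-vs-negative comparison. For the whole cascade two labelled
aggregates are reported, because neither is derivable from the other:
six-class accuracy with macro-averaged one-vs-rest AUC over the leaf
scores, and the per-node binary metric table. Events absent from the truth
are excluded from the macro average with a warning.

## Reference configurations

The package ships the five originally reported best-model configurations
as YAML fixtures. Two carry internal inconsistencies in the printed
source: the unbalanced-node units list has 9 entries for 11 declared
layers, with two values (5034, 624) outside the searchable [1, 64] range,
and the stumbling node pairs a convolution window of 10 with a window
length of 4. The loader preserves the printed values verbatim and flags
both issues; networks are built from a mechanical repaired variant (units
clamped into range and padded by repeating the final entry; convolution
window clamped to the window length at build time). The repair is
deliberately mechanical — no attempt is made to guess the intended values.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which every property is meaningfully exercised: training
corpora of 28 recordings of 30 s (4 Hz) across the six events, roughly
mirroring the uneven event mix of the original collection; held-out
evaluation on 12 fresh recordings of 20 s (780 windows); node training
with a 2-layer perceptron (24, 12 units) over 16-frame windows, adam at
0.01, batch 32, at most 25–30 epochs with patience 5. Under these
conditions each node reaches validation AUC ≥ 0.9 and the full cascade
exceeds 0.8 six-class accuracy, while a shuffled-label control collapses
to chance-level AUC. Larger budgets (more trials, longer recordings,
recording-level splits) are a matter of configuration, not code.

Other fixed numerical choices: cross-entropy clipping $10^{-7}$; sd floor
$10^{-6}$ in the channel scaler; max pooling of size 2; adam/rmsprop with
standard moment constants ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\rho = 0.9$, $\epsilon = 10^{-8}$); pooling ties resolved to the earlier
frame; recordings shorter than the window yield an empty window set (not
an error).

## Known limitations

* The synthetic generator bounds what the green tests prove about real
  recordings (see above).
* Window-level splitting, though it mirrors the original sample division,
  is optimistic under overlapping windows; prefer `by = "recording"` when
  data allow.
* The LSTM layer is exercised by gradient checks and smoke training but no
  shipped reference configuration uses it.
* The cascade evaluates nodes sequentially per instant; throughput is
  ample at 4 Hz but the implementation is not vectorised across a batch of
  streams.
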