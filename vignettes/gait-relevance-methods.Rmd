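---
title: "Interpretable gait classification: models, relevance rules and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable gait classification: models, relevance rules and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

gaitxai studies how gait deteriorates — with Parkinson's disease severity or
under a concurrent cognitive task — by (1) classifying spatiotemporal
ground-reaction-force (GRF) windows with small convolutional networks,
(2) explaining the classifications with layer-wise relevance propagation
(LRP) and gradient saliency, (3) validating the explanations with
most-relevant-first (MoRF) perturbation, and (4) translating relevance back
into clinical gait-cycle vocabulary (events A–G). This vignette documents
the models, their assumptions, the numerical choices, and — at length — the
synthetic data generator, because the generator is what makes every stage
of the pipeline testable against a known ground truth.

## 1. The gait phase model

One gait cycle of a reference foot runs from heel strike to the next heel
strike. `gait_phase_model()` partitions the phase axis $[0, 1)$ into seven
half-open event intervals:

| event | name | default interval |
|---|---|---|
| A | heel strike | [0, 0.02) |
| B | loading response | [0.02, 0.10) |
| C | mid-stance (single support) | [0.10, 0.30) |
| D | terminal stance | [0.30, 0.50) |
| E | pre-swing (second double support) | [0.50, 0.60) |
| F | initial/mid-swing (toe-off) | [0.60, 0.87) |
| G | terminal swing | [0.87, 1.00) |

Stance (A–E, ground contact) ends exactly at `stance_fraction` (default
0.60, the classical 60/40 stance/swing division); interval widths follow
standard clinical gait-phase conventions rescaled to that split. Pre-swing
is treated as stance because the toe is still loaded during the second
double-support interval. The contralateral foot runs the same cycle at a
phase offset (default 0.5).

The vertical GRF waveform over stance is the classical double bump: two
raised-cosine humps centred near 25% and 75% of stance over a sinusoidal
mid-stance valley, zero throughout swing, and continuous at heel strike and
toe-off. The form is a modelling choice — it is smooth, differentiable, and
has the qualitative shape of spatially averaged force traces; no
musculoskeletal realism is claimed.

## 2. The synthetic generator and what it does (and does not) emulate

Two scenarios mirror the two sensing modalities:

* **pd** — force-platform style: 100 frames/s, 500-frame windows, 19 raw
  columns (timestamp, 8 heel-to-toe sensors per foot, 2 per-foot sums; 18
  channels after timestamp removal), four severity classes (healthy 0 and
  Hoehn–Yahr 2 / 2.5 / 3, a subject-level label), defaults of 10 subjects
  per class × 20 windows = 800 windows.
* **cognitive** — floor-sensor style: 20 frames/s, 100-frame windows, 116
  channels in three plies of 22/47/47 sensors, five walking manners
  (normal, listening, serial-7 subtraction, texting, talking), 21 subjects
  × 5 × 10 = 1,050 windows.

Per-foot force is spread over 8 heel-to-toe sensors whose Gaussian
activation windows advance linearly through stance (σ = 0.15 of stance);
the per-foot sum columns are computed from the sensors, so the sum identity
holds exactly in every generated frame. The 116 floor channels mix the two
feet with smoothed, seeded per-channel gains per ply.

**Class effects.** Each non-reference class deviates at one named event:
severity 2 at mid-stance (C), 2.5 at the loading response (B), 3 at
terminal swing (G); the dual tasks at heel strike (A, listening), toe-off
(F, subtraction), terminal swing (G, texting) and pre-swing (E, talking).
The effect is applied to all channels in the frames where the reference
foot's phase lies in the event interval: a temporal reading, chosen because
swing-phase events carry no ipsilateral force, so a per-foot amplitude
change would be a no-op for them. The applied (post-jitter) frame intervals
are recorded per window as ground truth.

The effect itself multiplies the window by
$s - a\,\cos(2\pi f\,(t - t_{mid}))$ with attenuation $s = 0.5$, tremor
amplitude $a = 0.45 < s$ and tremor frequency $f = 8$ Hz, phase-locked so
the deepest trough sits at the window centre. Three properties motivated
this form, each found the hard way while building the benchmark:

1. *The expected amplitude inside the window is exactly $s$ times the
   template* (the cosine averages out and $a < s$ keeps the multiplier
   positive), so affected windows carry strictly lower mean absolute force
   at their event — the clinically expected attenuation.
2. *A pure attenuation cannot be localized by any relevance method.* A dip
   is an absence feature; relevance credits present activations, and on a
   minimal location-only dip contrast every composite placed < 30% of the
   mass a presence-coded contrast achieves. The tremor (4–10 Hz is the
   physiological band for Parkinsonian action tremor) is the presence-coded
   counterpart of the same deviation.
3. *Phase-locking keeps the planted waveform identical across cycle
   occurrences*, which keeps single-peak estimates from wandering across
   event boundaries; a random tremor phase made each occurrence a different
   waveform.

**Nuisance structure.** Amplitudes vary at three levels, all log-normal and
class-independent: a subject weight factor (log-uniform over
`subject_weight_scale_range`), a per-trial factor (sdlog 0.25; step-to-step
speed and placement variability), independent per-foot factors (sdlog 0.25;
step asymmetry) and per-sensor gains (sdlog 0.25; coupling variability),
plus additive sensor noise (sd 0.05) with non-negativity clamping. This
nuisance structure is not decoration: without it, the per-channel energy
fingerprint of the localized attenuation separates the classes perfectly (a
four-feature multinomial fit reaches 100%), every classifier shortcuts to
global energy, and relevance maps index amplitude instead of events. With
it, channel-energy statistics fall to ~70% accuracy while the localized
waveform deformation remains clean, so a CNN that reaches ~0.95 macro-F1
must be reading the planted temporal structure. Passing tests on this
generator therefore shows that the pipeline recovers *localized,
presence-coded* class structure under realistic amplitude nuisance; it does
not show robustness to real inter-subject GRF variance spectra, sensor
artefacts, or pathology beyond the planted single-event model.

Determinism: one integer seed; all draws flow through a counter-based
seed-splitting scheme, so per-subject and per-trial streams do not depend
on generation order, and identical configurations reproduce bit-identical
tensors.

## 3. Preprocessing

Raw recordings are windowed into non-overlapping 500-frame chunks (trailing
remainders discarded), the timestamp column is dropped, and every channel
is standardized to mean 0, standard deviation 1 with the population
convention, fitted dataset-wide before splitting. Splits are window-level
random by default (60/20/20; 70/10/20 supported), with subject-level and
leave-subjects-out modes for transfer experiments. Window-level splitting
of per-subject labels leaks subject identity into the test set; the
generator counters this by making subjects share the template up to
amplitude factors that per-trial jitter masks, but for real data the
subject-level mode is the defensible choice.

## 4. The layer graph and training

All three architectures are typed layer DAGs over one-channel
time × sensor inputs: `single` (four conv + average-pool pairs and a
two-layer dense head; 10 stacked layers), `parallel` (two inception-style
stages of four conv(+pool) streams fused by concatenation; 18 stacked
layers), `quadruplet` (four independent streams, two max-pool and two
average-pool paths). The stacked-layer counting convention includes conv,
pool and dense layers only. Batch normalization and dropout (0.3) sit
after the flatten, before the dense head. Convolution uses the
flipped-kernel (true convolution) orientation; since kernels are learned
this is observationally equivalent to cross-correlation, and the unit tests
pin the convention.

Filter counts and kernel sizes are not canonical and are exposed as
hyperparameters. The parallel defaults — stage-1 kernels
(7×3), (9×1), (5×3), (1×5) with 8 filters per stream, stage-2 3×3-class
kernels, 4×2 average pooling in both stages — were chosen so that receptive
fields stay comparable to the narrowest event width (8 frames at 100
frames/s): relevance maps inherit the network's receptive-field geometry,
and long stage-2 kernels on a pooled grid (60-frame effective windows)
visibly smeared event attributions without improving accuracy.

Training minimizes categorical cross-entropy with Adam (learning rate
0.002, β₁ 0.9, β₂ 0.999, ε 1e-8), batches of 100, Glorot-uniform
initialization with zero biases. The package-level default of 200 epochs
is the conventional full-length setting; the bundled synthetic experiments use 20
epochs, which saturates validation accuracy on the easy-regime benchmark
at its 800-window size. Training is deterministic under a fixed seed on a
fixed platform; exact cross-platform reproducibility is not promised
(BLAS summation order).

Classical baselines (a linear softmax model trained by the same stochastic
gradient machinery, k-nearest-neighbour, Gaussian-process classification)
operate on flattened windows and delegate to standard implementations
(`class::knn`, `kernlab::gausspr`, GPC subsampled to ≤ 500 training
points). A recurrent baseline is out of scope.

## 5. Relevance propagation

`explain()` removes the softmax, keeps the chosen class's pre-softmax
score, zeroes the others, and walks the graph in reverse topological order
under a per-layer rule assignment:

* epsilon rule: proportional redistribution stabilized by
  $\epsilon\,\mathrm{sign}(z)$ (sign(0) = +1);
* alpha–beta: positive/negative pre-activation contributions weighted
  α / −β with α − β = 1; α = 1, β = 0 is the z⁺ rule, which on ReLU
  networks coincides with deep Taylor decomposition;
* flat: uniform redistribution over the receptive field;
* zB box rule at the input layer for the bounded deep-Taylor composite;
* max pooling: winner-take-all along the forward switches (ties to the
  lowest index, which matters because standardized signals can tie at 0);
  average pooling: proportional redistribution (uniform under the flat
  composite);
* flatten/concat/dropout pass through; batch normalization is folded into
  the effective weights of the adjacent dense layer before propagation
  (an explicit fold, checked against folding-by-hand to 1e-8).

The LRP-SPF composite ("sequential preset A, flat input layer") uses
epsilon (0.1) on dense layers, α1β0 on conv layers and flat at the first
layer; these parameter values are common toolkit defaults, configurable,
and documented as assumptions. Bias relevance is absorbed rather than
redistributed; the resulting conservation leak is surfaced through
`conservation_residual()` instead of hidden — the residual is exactly 0
for the flat composite and for α1β0 on zero-bias stacks, and grows
monotonically with ε otherwise. Guided backprop and deconvnet are
modified-ReLU gradient backpasses (both gate by upstream-gradient sign;
guided additionally by forward activation); they are saliency baselines and
are not conserving. Units eliminated at the output (zero relevance on a
zero pre-activation) propagate zero relevance rather than NaN.

## 6. MoRF perturbation

`morf_curve()` tiles each window into 7×7 regions (partial edge blocks
kept), ranks regions per sample by summed relevance, and cumulatively
replaces the top-t regions with Gaussian noise, re-predicting the test set
at every step; `order = "random"` gives the baseline. Replacement noise is
standard normal in standardized units by default (the level is
configurable), redrawn at the step where a region is first perturbed, and
fully seeded. Region order is computed per sample from that sample's own
map. Accuracy is overall accuracy. Model selection takes the largest
mean-centred early decline; method selection takes the largest
baseline-minus-curve early-window mean (default 15 steps, the point where
curves typically recover). On the synthetic benchmark the LRP-SPF curve is
selected, the relevance-ordered curve collapses toward chance while random
removal stays near the unperturbed accuracy, and replacing every region
drives accuracy to 1/K.

## 7. From relevance to gait events

Interpretation converts maps to clinical vocabulary in four steps.

1. *Spatial averaging*: per-frame mean over channels, for both the signal
   and the relevance map.
2. *Cycle segmentation* (`segment_cycles()`): heel strikes are upward
   crossings of 0.2 × peak with a 0.5 s refractory period, refined by
   backtracking along an 11-frame smoothed copy to the foot of the rising
   edge with a capped forward re-adjustment. The smoothing matters when the
   deviating event is the loading response itself: an oscillating rise
   crosses the raw threshold late, and the smoothed walk-down restores the
   onset. `reference_cycles()` additionally segments the contralateral sum
   channel and uses whichever foot has the more regular strike spacing,
   mapping contralateral strikes back through the foot phase offset. All
   thresholds are relative, so segmentation is amplitude-invariant.
   Detected boundaries land within ±2 frames of ground truth on clean
   synthetic force trains. The cognitive scenario's 20 Hz windows contain
   4–5 steps and segment identically with the rate-scaled refractory.
3. *Peak assignment* (`assign_relevance_events()`): local maxima of the
   lightly smoothed (width 3) relevance SA inside complete cycles, each
   converted to a phase fraction and labelled by `phase_to_event()`.
4. *Per-window vote* (`window_event_vote()`): each cycle votes with its
   top peak's event; the majority wins. Voting across a window's ~5 cycles
   averages out per-cycle jitter that a single global peak inherits.

Two asymmetries deserve explanation. First, the event stage defaults to
the magnitude of the guided-backprop map rather than the MoRF-selected
composite: LRP redistributes proportionally to activations, so on events
that sit on a rising force slope the single-peak estimate drifts toward
the high-amplitude neighbour (measured on the benchmark: the same planted
events, identical modal recovery, but ~0.60 individual agreement under
LRP-SPF against ~0.78 under |guided backprop|). MoRF answers "which regions
carry decision-critical information", peak assignment answers "where
exactly on the cycle axis" — different questions, different best tools;
`event_rule = NULL` restores the selected composite. Second, histograms are
computed over true-positive predictions only, because a heatmap of a wrong
prediction explains the wrong decision.

On the default benchmark the modal assigned event matches the planted
event for every severity class, with the healthy class excluded — it is
the unmodified reference and has no planted window; its heel-strike
signature arises only as the absence of the other classes' deviations.

## 8. Experiments

`run_experiment_1()`–`run_experiment_4()` orchestrate the four designs:
severity staging (CNNs + baselines), pooled five-class cognitive load
(reporting the normal-class true-positive rate separately, since on real
dual-task data the shared normal template is predicted reliably while
subject-specific task responses confuse a pooled model), per-subject
five-class classification, and binary normal-vs-task transfer under
leave-1/2/4 subjects-out and a random 70/10/20 split. Note a generator
limitation here: at the default subject-signature strength (log-normal
effect modulation, sdlog 0.15) the synthetic dual tasks remain separable
by a pooled model, so the benchmark reproduces the high normal-class
true-positive rate but not the between-task confusion seen on real
heterogeneous subjects. Every report embeds its seed and
a configuration hash. The interpretation pipeline (`run_xai_pipeline()`)
chains maps, curves, selection, segmentation and histograms into one
report object.

## 9. Serialization and problem sizes

Objects are plain R lists serialized with RDS (`save_gait_object()`), with
a JSON sidecar holding the generator configuration; raw recordings use the
whitespace-delimited 19-column text dialect, which round-trips exactly
through the reader and makes the real-data reader testable on generated
fixtures. Tabular results (curves, score tables, event assignments) are
tibbles via `tidy()`/`glance()` and export to CSV/JSON with the usual
writers.

The bundled test and acceptance runs use the benchmark at 4 × 200 = 800
PD-style windows with a 20-epoch parallel CNN (~4 minutes on one CPU),
100-window perturbation sets over 15 steps and 3 seeds, and the full
1,050-window cognitive dataset with a 10-epoch run; these sizes saturate
the relevant behaviours (validation accuracy, curve separation, event
recovery) on this benchmark. Known limitations: no recurrent baseline, no
LRP for non-CNN models, no resampling between the 100 Hz and 20 Hz
domains, no claim of clinical validity for event timings on real patients,
and no left/right asymmetry analysis (spatial averaging pools both feet).
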