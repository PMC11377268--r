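# gaitxai

Interpretable convolutional classification of ground-reaction-force (GRF)
gait signals: who is deteriorating, and *which part of the gait cycle*
gives it away.

Gait recorded by force platforms or sensor floors is a spatiotemporal
signal — frames × sensor channels — and small CNNs classify it well
(Parkinson's disease severity stages, walking under a concurrent cognitive
task). But a clinician needs more than a label: the question is which
gait-cycle events (heel strike, loading response, mid-stance, terminal
stance, pre-swing, swing, terminal swing — A through G) carry the
deviation. gaitxai implements the full chain:

* a **synthetic gait generator** with a clinical 60/40 stance/swing phase
  model, a double-bump vertical GRF waveform, two sensor layouts (19-column
  force-platform dialect at 100 Hz; 116-channel sensor-floor layout at
  20 Hz) and *plantable class effects*: each class deviates at one named
  event via a tremor-modulated attenuation, with the applied frame windows
  recorded as ground truth — so classification, explanation, perturbation
  and event assignment are all testable without any data download;
* **preprocessing**: windowing into fixed 500-frame chunks, timestamp
  removal, per-channel standardization `x' = (x − μ)/ϑ` (population
  convention, fitted dataset-wide), window-/subject-level and
  leave-subjects-out splits;
* a **typed layer graph** (conv2d / avg- and max-pool / dense / flatten /
  concat / batchnorm / dropout / softmax) with three architectures —
  `single` (10 stacked layers), inception-style `parallel` (18) and
  `quadruplet` (four independent streams) — trained by Adam
  (α = 0.002, β₁ = 0.9, β₂ = 0.999, ε = 1e-8) on categorical
  cross-entropy, Glorot-uniform init, all in package code with
  Rcpp/Armadillo convolution kernels;
* a **layer-wise relevance propagation (LRP) engine**: for each layer the
  class score `f_c(x)` is redistributed to the inputs under selectable
  rules — epsilon `R_j = Σ_k a_j w_jk / (z_k + ε·sign z_k) · R_k`,
  alpha–beta (α − β = 1; α1β0 = the z⁺ / deep-Taylor rule), flat, the zB
  box rule, winner-take-all unpooling — plus guided-backprop and deconvnet
  gradient baselines, with the conservation residual
  `|Σ_i R_i − f_c| / |f_c|` reported for every map;
* **MoRF perturbation**: 7×7 input regions are replaced by Gaussian noise
  most-relevant-first, accuracy is re-measured at each step and compared
  with random-order removal — the validation used both to select the
  architecture and the explanation method;
* **gait-event interpretation**: spatial averaging
  `SA[n] = (1/C) Σ_i x_i[n]`, heel-strike cycle segmentation with
  onset refinement, relevance-peak → phase → event assignment with a
  per-cycle majority vote, and per-class event histograms;
* **experiment drivers** for severity staging, pooled and per-subject
  cognitive-load classification, and binary normal-vs-task transfer with
  leave-subjects-out splits.

## Worked example

Generate the severity benchmark (4 classes × 200 windows of 500 frames ×
18 channels), train the parallel CNN, and run the interpretation pipeline.
About 6 minutes on one CPU.

```r
library(gaitxai)

cfg   <- generator_config("pd", seed = 1)      # 10 subjects/class x 20 trials
ds    <- generate_pd_dataset(cfg) |> standardize() |> split_dataset(seed = 1)
graph <- build_architecture("parallel", dim(ds$values)[2:3], 4)
model <- train(graph, ds, training_config(epochs = 20, seed = 1))

test <- dataset_split(ds, "test")
macro_f1(test$labels, predict(model, test), ds$classes)
#> [1] 0.9648804

report <- run_xai_pipeline(model, ds, n_steps = 15, seed = 1)
report$selected_method
#> [1] "deep_taylor"
report$modal_events
#> # A tibble: 4 x 3
#>   class event  freq
#>   <chr> <chr> <dbl>
#> 1 0     G     0.421
#> 2 2     C     1
#> 3 2.5   B     0.891
#> 4 3     G     1
round(report$baseline$step_accuracies - report$curves$lrp_spf$step_accuracies, 2)
#>  [1] 0.00 0.01 0.03 0.04 0.09 0.14 0.16 0.20 0.23 0.24 0.28 0.29 0.32 0.31
#> [15] 0.31 0.32
```

Reading the output: the held-out macro-F1 (0.96) says the four severity
stages separate cleanly; MoRF ranks the conserving LRP composites ahead of
the gradient baselines (here the deep-Taylor z+ composite wins by a
hair over LRP-SPF), and relevance-ordered removal opens a gap over random
removal of ~32 accuracy points by step 15 — the maps point at
decision-critical regions. The modal assigned event per severity class
(2 → C mid-stance, 2.5 → B loading response, 3 → G terminal swing)
recovers exactly the events the generator planted, with 96% of
true-positive windows agreeing individually; the healthy reference class
has no planted event and shows the expected diffuse profile.

Every result object has broom-style accessors (`tidy()`, `glance()`) and
`autoplot()` methods:

```r
library(ggplot2)
autoplot(report$curves$lrp_spf)              # accuracy vs perturbation step
plot_morf_comparison(report$curves, report$baseline)
tidy(report$curves$lrp_spf)                  # tibble: step, accuracy, order
glance(model)                                # parameters, final losses
```

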