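#' Experiment orchestration
#'
#' Thin drivers over the package's stages reproducing the four study
#' designs on synthetic (or pre-assembled) data: severity staging,
#' cross-subject cognitive load, per-subject cognitive load, and binary
#' normal-vs-dual-task with leave-subjects-out transfer. Every report
#' carries its seed and a configuration hash so runs are reproducible
#' end-to-end.
#'
#' @name experiments
NULL

flatten_split <- function(dataset, which) {
  ds <- dataset_split(dataset, which)
  d <- dim(ds$values)
  list(x = matrix(ds$values, d[1], d[2] * d[3]), y = ds$labels)
}

fit_eval_baseline <- function(name, dataset, seed = 1L, gpc_max_n = 500) {
  tr <- flatten_split(dataset, "train")
  te <- flatten_split(dataset, "test")
  pred <- switch(name,
    knn = class::knn(tr$x, te$x, tr$y, k = 5),
    gpc = {
      idx <- if (nrow(tr$x) > gpc_max_n)
        local_seed(derive_seed(seed, 31L),
                   sample.int(nrow(tr$x), gpc_max_n)) else seq_len(nrow(tr$x))
      fit <- kernlab::gausspr(tr$x[idx, , drop = FALSE],
                              factor(tr$y[idx], levels = dataset$classes))
      kernlab::predict(fit, te$x)
    },
    abort(paste0("unknown baseline: ", name)))
  confusion(te$y, pred, dataset$classes)
}

fit_eval_graph <- function(graph, dataset, training) {
  model <- train(graph, dataset, training)
  te <- dataset_split(dataset, "test")
  cm <- confusion(te$labels, predict(model, te), dataset$classes)
  list(model = model, confusion = cm)
}

experiment_report <- function(id, results, confusions, models, seed,
                              config) {
  structure(list(experiment = id, results = results,
                 confusions = confusions, models = models, seed = seed,
                 config_hash = rlang::hash(config)),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> experiment %s (seed %d, config %s)\n",
              x$experiment, x$seed, substr(x$config_hash, 1, 8)))
  print(x$results)
  invisible(x)
}

#' Severity-staging experiment
#'
#' Four-class severity classification (healthy, 2, 2.5, 3) on PD-style
#' windows: trains the configured CNN architectures and baselines on a
#' standardized window-level split and reports per-model test scores.
#'
#' @param dataset A PD-style [gait_dataset()]; generated synthetically when
#'   `NULL`.
#' @param architectures Character vector of [build_architecture()] names.
#' @param baselines Any of `"linear"`, `"knn"`, `"gpc"`.
#' @param training A [training_config()].
#' @param hyperparams Passed to [build_architecture()].
#' @param fractions Split fractions (train, val, test).
#' @param seed Integer seed for data generation and splitting.
#' @param generator Optional [generator_config()] for synthetic data.
#' @return An `experiment_report`: `results` tibble (one row per model),
#'   `confusions`, `models`.
#' @export
run_experiment_1 <- function(dataset = NULL,
                             architectures = "parallel",
                             baselines = character(),
                             training = training_config(epochs = 15,
                                                        seed = 1L),
                             hyperparams = list(),
                             fractions = c(0.6, 0.2, 0.2),
                             seed = 1L,
                             generator = NULL) {
  if (is.null(dataset)) {
    generator <- generator %||% generator_config("pd", seed = seed)
    dataset <- generate_pd_dataset(generator, seed = seed)
  }
  if (!"0" %in% dataset$classes || nlevels(dataset$labels) < 2)
    abort("severity labels missing")
  dataset <- split_dataset(standardize(dataset), fractions, seed = seed)
  d <- dim(dataset$values)

  rows <- list(); confs <- list(); models <- list()
  for (arch in architectures) {
    g <- build_architecture(arch, d[2:3], length(dataset$classes),
                            hyperparams)
    fe <- fit_eval_graph(g, dataset, training)
    confs[[arch]] <- fe$confusion; models[[arch]] <- fe$model
    sc <- scores(fe$confusion)
    rows[[arch]] <- tibble::tibble(
      model = arch, dataset_tag = dataset$dataset_tag,
      accuracy = overall_accuracy(fe$confusion),
      macro_f1 = sc$f1[sc$class == "macro"])
  }
  for (bl in baselines) {
    cm <- if (bl == "linear") {
      g <- build_linear_baseline(d[2:3], length(dataset$classes))
      fit_eval_graph(g, dataset, training)$confusion
    } else fit_eval_baseline(bl, dataset, seed)
    confs[[bl]] <- cm
    sc <- scores(cm)
    rows[[bl]] <- tibble::tibble(
      model = bl, dataset_tag = dataset$dataset_tag,
      accuracy = overall_accuracy(cm),
      macro_f1 = sc$f1[sc$class == "macro"])
  }
  experiment_report("1", dplyr::bind_rows(rows), confs, models, seed,
                    list(architectures, baselines, training, fractions))
}

#' Cross-subject cognitive-load experiment
#'
#' Five-class walking-manner classification pooled across subjects. The
#' headline contrast is the normal-gait (M1) true-positive rate against the
#' dual-task classes, whose subject-specific signatures confuse a pooled
#' model.
#'
#' @inheritParams run_experiment_1
#' @param dataset A cognitive-style [gait_dataset()]; synthetic when `NULL`.
#' @return An `experiment_report`; `results` has one row per class recall
#'   plus the macro summary, and `normal_tp_rate` is stored alongside.
#' @export
run_experiment_2 <- function(dataset = NULL,
                             architectures = "parallel",
                             training = training_config(epochs = 15,
                                                        seed = 1L),
                             hyperparams = list(),
                             fractions = c(0.6, 0.2, 0.2),
                             seed = 1L,
                             generator = NULL) {
  if (is.null(dataset)) {
    generator <- generator %||% generator_config("cognitive", seed = seed)
    dataset <- generate_cognitive_dataset(generator, seed = seed)
  }
  dataset <- split_dataset(standardize(dataset), fractions, seed = seed)
  d <- dim(dataset$values)
  arch <- architectures[1]
  g <- build_architecture(arch, d[2:3], length(dataset$classes), hyperparams)
  fe <- fit_eval_graph(g, dataset, training)
  sc <- scores(fe$confusion)
  rep <- experiment_report("2", sc, list(fe$confusion),
                           setNames(list(fe$model), arch), seed,
                           list(arch, training, fractions))
  rep$normal_tp_rate <- sc$recall[sc$class == dataset$classes[1]]
  rep$macro_f1 <- sc$f1[sc$class == "macro"]
  rep
}

#' Per-subject cognitive-load experiment
#'
#' Trains and evaluates a model within each subject separately (all five
#' manners, the subject's own trials split train/val/test) and tabulates
#' per-subject F1.
#'
#' @inheritParams run_experiment_2
#' @param min_per_class Minimum trials per class for a subject to be
#'   evaluated; smaller subjects are skipped with a warning.
#' @return An `experiment_report` with one `results` row per subject.
#' @export
run_experiment_3 <- function(dataset = NULL,
                             architectures = "parallel",
                             training = training_config(epochs = 15,
                                                        seed = 1L),
                             hyperparams = list(),
                             fractions = c(0.6, 0.2, 0.2),
                             seed = 1L,
                             generator = NULL) {
  if (is.null(dataset)) {
    generator <- generator %||% generator_config("cognitive", seed = seed)
    dataset <- generate_cognitive_dataset(generator, seed = seed)
  }
  dataset <- standardize(dataset)
  d <- dim(dataset$values)
  arch <- architectures[1]
  rows <- list(); confs <- list()
  for (sid in unique(dataset$subject_id)) {
    ds <- subset_dataset(dataset, dataset$subject_id == sid)
    if (min(table(ds$labels)) < 2) {
      warn(paste0("subject ", sid, " skipped: too few samples per class"))
      next
    }
    ds <- split_dataset(ds, fractions, seed = derive_seed(seed, 41L,
                                                          nchar(sid)))
    g <- build_architecture(arch, d[2:3], length(dataset$classes),
                            hyperparams)
    fe <- fit_eval_graph(g, ds, training)
    sc <- scores(fe$confusion)
    confs[[sid]] <- fe$confusion
    rows[[sid]] <- tibble::tibble(subject = sid,
                                  n_test = sum(fe$confusion),
                                  macro_f1 = sc$f1[sc$class == "macro"])
  }
  experiment_report("3", dplyr::bind_rows(rows), confs, list(), seed,
                    list(arch, training, fractions))
}

#' Binary normal-vs-dual-task transfer experiment
#'
#' For each dual-task group (normal vs one of the four tasks) the model is
#' trained under four split regimes: leave 1, 2 or 4 subjects out entirely
#' (subject transfer), and a random window-level 70/10/20 split. Reports
#' the F1 grid.
#'
#' @inheritParams run_experiment_2
#' @param regimes Named list of regimes; each either
#'   `list(test_subjects = k)` or `list(fractions = c(tr, va, te))`.
#' @return An `experiment_report` with a `results` row per (group, regime).
#' @export
run_experiment_4 <- function(dataset = NULL,
                             architectures = "parallel",
                             training = training_config(epochs = 15,
                                                        seed = 1L),
                             hyperparams = list(),
                             regimes = list(
                               test_1 = list(test_subjects = 1),
                               test_2 = list(test_subjects = 2),
                               test_4 = list(test_subjects = 4),
                               random = list(fractions = c(0.7, 0.1, 0.2))),
                             seed = 1L,
                             generator = NULL) {
  if (is.null(dataset)) {
    generator <- generator %||% generator_config("cognitive", seed = seed)
    dataset <- generate_cognitive_dataset(generator, seed = seed)
  }
  dataset <- standardize(dataset)
  d <- dim(dataset$values)
  arch <- architectures[1]
  reference <- dataset$classes[1]
  rows <- list()
  for (task in dataset$classes[-1]) {
    ds0 <- subset_dataset(dataset, dataset$labels %in% c(reference, task))
    ds0$classes <- c(reference, task)
    ds0$labels <- factor(as.character(ds0$labels), levels = ds0$classes)
    for (rg in names(regimes)) {
      spec_ <- regimes[[rg]]
      ds <- if (!is.null(spec_$test_subjects)) {
        subs <- unique(ds0$subject_id)
        held <- local_seed(derive_seed(seed, 51L, match(task,
                                                        dataset$classes)),
                           sample(subs, spec_$test_subjects))
        split_dataset(ds0, c(0.85, 0.15, 0), seed = seed,
                      test_subjects = held)
      } else split_dataset(ds0, spec_$fractions, seed = seed)
      g <- build_architecture(arch, d[2:3], 2L, hyperparams)
      fe <- fit_eval_graph(g, ds, training)
      sc <- scores(fe$confusion)
      rows[[paste(task, rg)]] <- tibble::tibble(
        group = paste0(reference, " vs ", task), regime = rg,
        n_test = sum(fe$confusion),
        macro_f1 = sc$f1[sc$class == "macro"])
    }
  }
  experiment_report("4", dplyr::bind_rows(rows), list(), list(), seed,
                    list(arch, training, regimes))
}

#' Full interpretation pipeline
#'
#' From a trained model and its dataset: relevance maps for the configured
#' rule composites on true-positive test windows, MoRF and random-order
#' perturbation curves, explanation-method selection, spatial averaging,
#' cycle segmentation and per-class gait-event histograms.
#'
#' Method selection and event attribution answer different questions: MoRF
#' ranks composites by how much classification-critical information their
#' top-scoring regions carry, while peak-to-event conversion needs
#' temporally calibrated maps. LRP mass is weighted by activations, which
#' drags single-peak estimates toward high-amplitude neighbours of an
#' event, so the event stage defaults to the magnitude of the
#' guided-backprop map (`event_rule`); set `event_rule = NULL` to use the
#' MoRF-selected composite instead.
#'
#' @param model A trained model.
#' @param dataset The standardized, split [gait_dataset()] it was trained
#'   on (raw values are used for cycle segmentation).
#' @param rule_names Rule composites compared by perturbation.
#' @param event_rule Rule used for event attribution (default
#'   `"guided_backprop"`); `NULL` = the MoRF-selected composite.
#' @param n_steps Perturbation steps.
#' @param noise Replacement-noise `c(mean, sd)`.
#' @param seed Integer seed.
#' @param cycle_channel Raw channel used for heel-strike detection (default
#'   17, the left-foot sum of the 18-channel PD layout); `NULL` averages
#'   all channels.
#' @param alt_cycle_channel Contralateral force channel for robust
#'   segmentation (default 18); see [reference_cycles()].
#' @param max_tp Cap on true-positive windows analysed per run.
#' @return A `xai_report`: selected method, per-method `morf_result`s and
#'   decay statistics, per-window event assignments (majority vote over
#'   cycles) and per-class histograms.
#' @export
run_xai_pipeline <- function(model, dataset,
                             rule_names = c("lrp_spf", "deep_taylor",
                                            "guided_backprop"),
                             event_rule = "guided_backprop",
                             n_steps = 20, noise = c(0, 1), seed = 1L,
                             cycle_channel = 17L, alt_cycle_channel = 18L,
                             max_tp = 200L) {
  te <- dataset_split(dataset, "test")
  pred <- predict(model, te)
  tp <- which(as.character(pred) == as.character(te$labels))
  if (!length(tp)) abort("no true-positive test windows to analyse")
  if (length(tp) > max_tp)
    tp <- sort(local_seed(derive_seed(seed, 61L), sample(tp, max_tp)))
  tpd <- subset_dataset(te, tp)

  grid <- tile_regions(dim(te$values)[2:3])
  curves <- list(); maps_by_rule <- list()
  for (rn in rule_names) {
    rs <- make_ruleset(rn)
    maps <- explain_batch(model, tpd$values, target_class = tpd$labels,
                          rules = rs)
    maps_by_rule[[rn]] <- maps
    curves[[rn]] <- morf_curve(model, tpd, maps, grid, n_steps,
                               order = "morf", noise = noise, seed = seed)
  }
  baseline <- morf_curve(model, tpd, NULL, grid, n_steps, order = "random",
                         noise = noise, seed = seed)
  selected <- select_xai_method(curves, baseline,
                                early_steps = min(15, n_steps))

  er <- event_rule %||% selected
  maps <- maps_by_rule[[er]] %||%
    explain_batch(model, tpd$values, target_class = tpd$labels,
                  rules = make_ruleset(er))
  assignments <- assign_dataset_events(maps, tpd, cycle_channel,
                                       alt_cycle_channel,
                                       dataset$phase_model)
  hist <- event_histogram(assignments)
  structure(list(selected_method = selected, event_rule = er,
                 curves = curves, baseline = baseline,
                 decay = lapply(curves, decay_statistic, baseline = baseline),
                 assignments = assignments, histogram = hist,
                 modal_events = if (nrow(hist)) modal_events(hist)
                 else tibble::tibble(),
                 seed = seed,
                 config_hash = rlang::hash(list(rule_names, event_rule,
                                                n_steps, noise))),
            class = "xai_report")
}

#' Per-window event attribution over a set of relevance maps
#'
#' For every window: spatially average the relevance magnitude (positive
#' part for conserving LRP composites, absolute value for gradient maps),
#' segment the raw window into reference-foot cycles, collect each cycle's
#' relevance peaks, and take the majority event over the per-cycle top
#' peaks ([window_event_vote()]).
#'
#' @param maps List of `relevance_map`s, one per dataset window.
#' @param dataset The matching [gait_dataset()] subset (raw values used for
#'   segmentation).
#' @param cycle_channel,alt_channel Channels for [reference_cycles()].
#' @param phase_model A [gait_phase_model()]; taken from the dataset when
#'   `NULL`.
#' @return Tibble with one row per window that produced peaks: `sample`,
#'   `class`, `event`, plus the top peak's `frame`, `phase`, `score`.
#' @export
assign_dataset_events <- function(maps, dataset, cycle_channel = 17L,
                                  alt_channel = 18L, phase_model = NULL) {
  pm <- phase_model %||% dataset$phase_model %||% gait_phase_model()
  gradient_rule <- maps[[1]]$rule %in% c("guided_backprop", "deconvnet")
  rows <- list()
  for (i in seq_along(maps)) {
    seg <- reference_cycles(dataset$raw[i, , ], dataset$sample_rate,
                            channel = cycle_channel,
                            alt_channel = alt_channel, phase_model = pm)
    sc <- if (gradient_rule) abs(maps[[i]]$scores)
      else pmax(maps[[i]]$scores, 0)
    ea <- assign_relevance_events(spatial_average(sc), seg, pm,
                                  top_k = 1000L)
    if (!nrow(ea$peaks)) next
    top <- ea$peaks[1, ]
    rows[[length(rows) + 1]] <- tibble::tibble(
      sample = i, class = as.character(dataset$labels[i]),
      event = window_event_vote(ea), frame = top$frame,
      phase = top$phase, score = top$score)
  }
  if (!length(rows))
    return(tibble::tibble(sample = integer(), class = character(),
                          event = character()))
  dplyr::bind_rows(rows)
}

#' @export
print.xai_report <- function(x, ...) {
  cat(sprintf("<xai_report> selected method: %s\n", x$selected_method))
  if (nrow(x$modal_events)) {
    cat("modal events per class:\n")
    print(x$modal_events)
  }
  invisible(x)
}
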