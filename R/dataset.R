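#' Raw multi-channel gait recording
#'
#' A variable-length recording in one of two dialects: `"gaitpdb-19col"`
#' (timestamp + 8 force sensors per foot + 2 per-foot sums, 100 frames/s) or
#' `"pof-116col"` (116 floor-sensor channels, 20 frames/s).
#'
#' @param values Numeric frames x columns matrix.
#' @param dialect `"gaitpdb-19col"` or `"pof-116col"`.
#' @param sample_rate Frames per second.
#' @param source_id Identifier (subject/record), e.g. the file stem.
#' @param has_timestamp Whether column 1 is a timestamp (gaitpdb dialect).
#' @return A `raw_recording` object.
#' @export
raw_recording <- function(values, dialect = c("gaitpdb-19col", "pof-116col"),
                          sample_rate = NULL, source_id = "synthetic",
                          has_timestamp = dialect == "gaitpdb-19col") {
  dialect <- match.arg(dialect)
  values <- as.matrix(values)
  expected <- if (dialect == "gaitpdb-19col") 19L else 116L
  if (has_timestamp && dialect != "gaitpdb-19col")
    abort("only the gaitpdb dialect carries a timestamp column")
  if (!has_timestamp && dialect == "gaitpdb-19col") expected <- 18L
  if (ncol(values) != expected)
    abort(sprintf("dialect %s expects %d columns, got %d",
                  dialect, expected, ncol(values)))
  if (is.null(sample_rate))
    sample_rate <- if (dialect == "gaitpdb-19col") 100 else 20
  if (has_timestamp && nrow(values) > 1 && any(diff(values[, 1]) <= 0))
    abort("timestamp column must be strictly increasing")
  structure(list(values = values, dialect = dialect,
                 sample_rate = sample_rate, source_id = source_id,
                 has_timestamp = has_timestamp),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s, %d frames x %d columns @ %g frames/s (%s)\n",
              x$dialect, nrow(x$values), ncol(x$values), x$sample_rate,
              x$source_id))
  invisible(x)
}

#' Drop the timestamp column of a raw recording
#'
#' Removes column 1 of a gaitpdb-dialect recording (it carries no gait
#' information), leaving the 18 signal channels in their original order
#' (L1..L8, R1..R8, Lsum, Rsum). Idempotent: a recording without a timestamp
#' is returned unchanged with a warning.
#'
#' @param raw A [raw_recording()].
#' @return The recording without its timestamp column.
#' @export
drop_timestamp <- function(raw) {
  stopifnot(inherits(raw, "raw_recording"))
  if (!raw$has_timestamp) {
    warn("recording has no timestamp column; returning unchanged")
    return(raw)
  }
  raw$values <- raw$values[, -1, drop = FALSE]
  raw$has_timestamp <- FALSE
  raw
}

#' Window a recording into fixed-length samples
#'
#' Splits a recording into non-overlapping consecutive windows of
#' `window_len` frames starting at frame 1; a trailing remainder shorter
#' than `window_len` is discarded, so the number of windows is
#' `floor(frames / window_len)`.
#'
#' @param raw A [raw_recording()].
#' @param window_len Window length in frames.
#' @return List of windows; each a list with `values`
#'   (`window_len` x columns matrix), `window_index` and `source_id`.
#' @export
chunk <- function(raw, window_len = 500) {
  stopifnot(inherits(raw, "raw_recording"), window_len >= 1)
  n <- floor(nrow(raw$values) / window_len)
  if (n == 0) return(list())
  lapply(seq_len(n), function(k) {
    idx <- ((k - 1) * window_len + 1):(k * window_len)
    list(values = raw$values[idx, , drop = FALSE],
         window_index = k, source_id = raw$source_id)
  })
}

#' Gait dataset of fixed-length windows
#'
#' The central container: a 3-d array of windows `(n_samples, window_len,
#' n_channels)` with labels, subject ids and (for synthetic data) the
#' ground-truth frame windows where each class effect was planted. The
#' tabular face of the dataset -- one row per window -- is available via
#' [tibble::as_tibble()].
#'
#' @param values `(n, window_len, n_channels)` array (raw, unstandardized).
#' @param labels Factor of class labels (length `n`).
#' @param subject_id Character vector of subject identifiers.
#' @param classes Ordered class vocabulary.
#' @param window_index Ordinal of each window within its source recording.
#' @param dataset_tag Provenance tag (`"synthetic"`, `"Ga"`, `"cognitive"`, ...).
#' @param sample_rate Frames per second.
#' @param event_windows Per-sample tibble of planted `(start, end)` frame
#'   intervals (may be `NULL` for real data).
#' @param planted_event Per-sample planted event label (or `NA`).
#' @param phase_model,config Generator provenance (optional).
#' @return A `gait_dataset`.
#' @export
gait_dataset <- function(values, labels, subject_id, classes = levels(labels),
                         window_index = NULL, dataset_tag = "synthetic",
                         sample_rate = 100, event_windows = NULL,
                         planted_event = NULL, phase_model = NULL,
                         config = NULL) {
  stopifnot(length(dim(values)) == 3, dim(values)[1] == length(labels),
            length(subject_id) == length(labels))
  if (is.null(window_index)) window_index <- seq_along(labels)
  ds <- structure(list(
    values = values, raw = values, labels = labels,
    subject_id = subject_id, classes = classes,
    window_index = as.integer(window_index), dataset_tag = dataset_tag,
    sample_rate = sample_rate, event_windows = event_windows,
    planted_event = planted_event, phase_model = phase_model,
    config = config, split = rep(NA_character_, length(labels)),
    stats = NULL), class = "gait_dataset")
  ds
}

#' @export
print.gait_dataset <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<gait_dataset> %d windows of %d frames x %d channels (%s)\n",
              d[1], d[2], d[3], x$dataset_tag))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  if (!all(is.na(x$split)))
    cat("  split:", paste(names(table(x$split)), table(x$split),
                          sep = "=", collapse = ", "), "\n")
  if (!is.null(x$stats)) cat("  standardized (per-channel mean 0, sd 1)\n")
  invisible(x)
}

#' @export
as_tibble.gait_dataset <- function(x, ...) {
  tibble::tibble(sample = seq_along(x$labels), label = x$labels,
                 subject_id = x$subject_id, window_index = x$window_index,
                 dataset_tag = x$dataset_tag, split = x$split,
                 planted_event = x$planted_event %||%
                   rep(NA_character_, length(x$labels)))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of samples in a dataset
#' @param dataset A [gait_dataset()].
#' @return Integer count.
#' @export
n_samples <- function(dataset) dim(dataset$values)[1]

#' Standardize a dataset per channel
#'
#' Rescales every channel to mean 0 and standard deviation 1 over the whole
#' fitting population (all windows and frames), using the population
#' convention (divide by N). Standardization is fitted dataset-wide before
#' any split; the fitted statistics are retained in `$stats` so they can be
#' reused on further data.
#'
#' @param dataset A [gait_dataset()].
#' @param stats Optional precomputed statistics (list with `mu`, `theta`) to
#'   apply instead of fitting.
#' @return The dataset with standardized `values` (the raw values stay in
#'   `$raw`) and `stats = list(mu, theta)`.
#' @export
standardize <- function(dataset, stats = NULL) {
  stopifnot(inherits(dataset, "gait_dataset"))
  d <- dim(dataset$raw)
  flat <- matrix(aperm(dataset$raw, c(2, 1, 3)), d[1] * d[2], d[3])
  if (is.null(stats)) {
    mu <- colMeans(flat)
    theta <- sqrt(colMeans(sweep(flat, 2, mu)^2))  # population sd
    bad <- which(theta <= 0 | !is.finite(theta))
    if (length(bad))
      abort(paste0("zero-variance channel(s): ", paste(bad, collapse = ", ")))
    stats <- list(mu = mu, theta = theta)
  }
  flat <- sweep(sweep(flat, 2, stats$mu), 2, stats$theta, "/")
  dataset$values <- aperm(array(flat, c(d[2], d[1], d[3])), c(2, 1, 3))
  dataset$stats <- stats
  dataset
}

#' Split a dataset into train/validation/test sets
#'
#' Window-level random split by default (the fractions are honoured exactly
#' up to rounding), or subject-level splits for transfer experiments:
#' `mode = "subject"` assigns whole subjects to the three sets, and
#' `test_subjects` holds out named subjects entirely (leave-subjects-out;
#' remaining subjects are split train/val by the first two fractions).
#'
#' @param dataset A [gait_dataset()].
#' @param fractions Length-3 numeric `(train, val, test)` summing to 1.
#' @param seed Integer seed; the assignment is reproducible.
#' @param mode `"window"` or `"subject"`.
#' @param test_subjects Optional character vector of held-out subject ids
#'   (implies subject-level test assignment).
#' @return The dataset with `$split` filled with
#'   `"train"`/`"val"`/`"test"`.
#' @export
split_dataset <- function(dataset, fractions = c(0.6, 0.2, 0.2), seed = 1L,
                          mode = c("window", "subject"),
                          test_subjects = NULL) {
  mode <- match.arg(mode)
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  n <- n_samples(dataset)
  if (!is.null(test_subjects)) {
    is_test <- dataset$subject_id %in% test_subjects
    if (!any(is_test)) abort("no samples belong to the held-out subjects")
    rest <- which(!is_test)
    fr <- fractions[1:2] / sum(fractions[1:2])
    split <- rep("test", n)
    split[rest] <- local_seed(derive_seed(seed, 9L),
                              exact_assignment(length(rest), c(fr, 0)))[
                                seq_along(rest)]
    dataset$split <- split
    return(dataset)
  }
  if (mode == "window") {
    if (n < sum(fractions > 0)) abort("fewer samples than split groups")
    dataset$split <- local_seed(derive_seed(seed, 9L),
                                exact_assignment(n, fractions))
  } else {
    subj <- unique(dataset$subject_id)
    if (length(subj) < sum(fractions > 0))
      abort("fewer subjects than split groups")
    sa <- local_seed(derive_seed(seed, 9L),
                     exact_assignment(length(subj), fractions))
    dataset$split <- sa[match(dataset$subject_id, subj)]
  }
  dataset
}

# exact counts: floor + largest remainders, then a seeded permutation
exact_assignment <- function(n, fractions) {
  counts <- floor(n * fractions)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_rem <- order(n * fractions - counts, decreasing = TRUE)
    counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1
  }
  sample(rep(c("train", "val", "test"), counts))
}

#' Subset a dataset
#'
#' @param dataset A [gait_dataset()].
#' @param idx Integer or logical index over samples.
#' @return The reduced dataset.
#' @export
subset_dataset <- function(dataset, idx) {
  if (is.logical(idx)) idx <- which(idx)
  dataset$values <- dataset$values[idx, , , drop = FALSE]
  dataset$raw <- dataset$raw[idx, , , drop = FALSE]
  dataset$labels <- dataset$labels[idx]
  dataset$subject_id <- dataset$subject_id[idx]
  dataset$window_index <- dataset$window_index[idx]
  dataset$split <- dataset$split[idx]
  if (!is.null(dataset$event_windows))
    dataset$event_windows <- dataset$event_windows[idx]
  if (!is.null(dataset$planted_event))
    dataset$planted_event <- dataset$planted_event[idx]
  dataset
}

#' Extract one split of a dataset
#' @param dataset A split [gait_dataset()].
#' @param which One of `"train"`, `"val"`, `"test"`.
#' @return The reduced dataset.
#' @export
dataset_split <- function(dataset, which = c("train", "val", "test")) {
  which <- match.arg(which)
  if (all(is.na(dataset$split))) abort("dataset has not been split")
  subset_dataset(dataset, dataset$split == which)
}
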