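#' Tile a window into perturbation regions
#'
#' Row-major tiling of a `frames x channels` window into rectangular index
#' blocks (default 7 x 7); partial blocks at the edges are kept, so the
#' blocks are disjoint and cover the window.
#'
#' @param window_shape `c(frames, channels)`.
#' @param region_shape Block shape `c(frames, channels)`, default `c(7, 7)`.
#' @return A `region_grid`: list with `regions` (list of index pairs
#'   `list(rows, cols)`), `window_shape`, `region_shape`.
#' @export
tile_regions <- function(window_shape, region_shape = c(7, 7)) {
  stopifnot(all(window_shape >= 1), all(region_shape >= 1))
  if (all(region_shape > window_shape))
    abort("region larger than the window in both dimensions")
  rs <- pmin(region_shape, window_shape)
  row_starts <- seq(1, window_shape[1], by = rs[1])
  col_starts <- seq(1, window_shape[2], by = rs[2])
  regions <- list()
  for (r0 in row_starts)      # row-major: sweep columns within each row band
    for (c0 in col_starts)
      regions[[length(regions) + 1]] <-
        list(rows = r0:min(r0 + rs[1] - 1, window_shape[1]),
             cols = c0:min(c0 + rs[2] - 1, window_shape[2]))
  structure(list(regions = regions, window_shape = window_shape,
                 region_shape = rs), class = "region_grid")
}

#' @export
print.region_grid <- function(x, ...) {
  cat(sprintf("<region_grid> %d blocks of <=%dx%d tiling %dx%d\n",
              length(x$regions), x$region_shape[1], x$region_shape[2],
              x$window_shape[1], x$window_shape[2]))
  invisible(x)
}

#' Score regions by summed relevance
#'
#' @param map A `relevance_map` (or a plain score matrix).
#' @param grid A [tile_regions()] grid matching the map's shape.
#' @return Numeric vector: each region's summed relevance.
#' @export
region_scores <- function(map, grid) {
  sc <- if (inherits(map, "relevance_map")) map$scores else map
  stopifnot(all(dim(sc) == grid$window_shape))
  vapply(grid$regions, function(rg) sum(sc[rg$rows, rg$cols]), numeric(1))
}

#' Most-relevant-first perturbation curve
#'
#' The "greedy" heatmap validation: regions of each test window are
#' replaced by Gaussian noise in decreasing order of their summed relevance
#' (`order = "morf"`) or in a random order (`order = "random"`), cumulatively
#' -- at step `t` the `t` top regions of every sample are perturbed -- and
#' the model's accuracy on the perturbed set is recorded at each step. Step
#' 0 is the unperturbed accuracy. Noise is redrawn each step from
#' `N(noise_mean, noise_sd)`; everything is deterministic under `seed`.
#'
#' @param model A trained model.
#' @param dataset A standardized [gait_dataset()] (typically the test
#'   split), or a `(n, frames, channels)` array plus `labels`.
#' @param maps List of `relevance_map`s, one per sample (ignored for the
#'   random order).
#' @param grid A [tile_regions()] grid.
#' @param n_steps Number of perturbation steps (clipped to the region count
#'   with a warning).
#' @param order `"morf"` or `"random"`.
#' @param noise `c(mean, sd)` of the replacement noise, in standardized
#'   units.
#' @param seed Integer seed.
#' @param labels Class labels when `dataset` is a plain array.
#' @return A `morf_result` with `step_accuracies` (length `n_steps + 1`)
#'   and the protocol metadata.
#' @export
morf_curve <- function(model, dataset, maps = NULL, grid = NULL,
                       n_steps = 30, order = c("morf", "random"),
                       noise = c(0, 1), seed = 1L, labels = NULL) {
  order <- match.arg(order)
  x <- if (inherits(dataset, "gait_dataset")) dataset$values else dataset
  if (is.null(labels)) labels <- dataset$labels
  n <- dim(x)[1]
  if (is.null(grid)) grid <- tile_regions(dim(x)[2:3])
  nr <- length(grid$regions)
  if (n_steps > nr) {
    warn(sprintf("n_steps clipped from %d to the region count %d",
                 n_steps, nr))
    n_steps <- nr
  }
  if (order == "morf") {
    if (is.null(maps) || length(maps) != n)
      abort("morf order needs one relevance map per sample")
    ranks <- lapply(maps, function(m)
      order(region_scores(m, grid), decreasing = TRUE))
  } else {
    ranks <- local_seed(derive_seed(seed, 21L),
                        lapply(seq_len(n), function(i) sample.int(nr)))
  }
  truth <- match(as.character(labels),
                 if (inherits(dataset, "gait_dataset")) dataset$classes
                 else model$classes)
  acc <- numeric(n_steps + 1)
  pred0 <- forward(model, x)$probs
  acc[1] <- mean(max.col(pred0, ties.method = "first") == truth)
  xp <- x
  local_seed(derive_seed(seed, 22L), {
    for (t in seq_len(n_steps)) {
      for (i in seq_len(n)) {
        rg <- grid$regions[[ranks[[i]][t]]]  # newly added region this step
        xp[i, rg$rows, rg$cols] <-
          rnorm(length(rg$rows) * length(rg$cols), noise[1], noise[2])
      }
      pr <- forward(model, xp)$probs
      acc[t + 1] <- mean(max.col(pr, ties.method = "first") == truth)
    }
  })
  structure(list(order = order, step_accuracies = acc, n_steps = n_steps,
                 noise_params = noise, seed = seed,
                 region_order = ranks, grid = grid),
            class = "morf_result")
}

#' @export
print.morf_result <- function(x, ...) {
  cat(sprintf("<morf_result> %s order, %d steps, accuracy %.3f -> %.3f\n",
              x$order, x$n_steps, x$step_accuracies[1],
              x$step_accuracies[length(x$step_accuracies)]))
  invisible(x)
}

#' Accuracy-decay statistic of a perturbation curve
#'
#' Summarizes a MoRF curve against a baseline (typically the random-order
#' curve): the mean per-step decline of the mean-centred curve, and the
#' step-wise `baseline - curve` accuracy differences. Larger values mean a
#' steeper, better-localized explanation.
#'
#' @param result,baseline `morf_result`s computed under the same protocol.
#' @return List with `mean_decline` (scalar) and `step_differences`
#'   (length `n_steps + 1`).
#' @export
decay_statistic <- function(result, baseline = NULL) {
  a <- result$step_accuracies
  centred <- a - mean(a)
  mean_decline <- -mean(diff(centred))
  step_differences <- NULL
  if (!is.null(baseline)) {
    if (length(baseline$step_accuracies) != length(a))
      abort("curves have different numbers of steps")
    step_differences <- baseline$step_accuracies - a
  }
  list(mean_decline = mean_decline, step_differences = step_differences)
}

#' Select the architecture most amenable to relevance analysis
#'
#' Given one MoRF curve per candidate model (identical protocol), returns
#' the candidate whose accuracy declines fastest over the early steps --
#' the model that concentrates its evidence in the most compact regions.
#'
#' @param candidates Named list of `morf_result`s (or of
#'   `list(model, curve)` pairs).
#' @param early_steps Number of initial steps scored (default 15).
#' @return Name (or index) of the winning candidate.
#' @export
select_model <- function(candidates, early_steps = 15) {
  if (!length(candidates)) abort("empty candidate list")
  scores <- vapply(candidates, function(cd) {
    cur <- if (inherits(cd, "morf_result")) cd else cd$curve
    a <- cur$step_accuracies[seq_len(min(early_steps + 1,
                                         length(cur$step_accuracies)))]
    -mean(diff(a - mean(a)))
  }, numeric(1))
  if (is.null(names(candidates))) which.max(scores) else
    names(candidates)[which.max(scores)]
}

#' Select the preferred explanation method
#'
#' Ranks per-method MoRF curves by their baseline-subtracted early decline:
#' the mean of `baseline - curve` over the early window (default steps
#' 1-15). Centring makes the ranking invariant to constant offsets.
#'
#' @param method_curves Named list of `morf_result`s, one per method.
#' @param baseline The random-order `morf_result` under the same protocol.
#' @param early_steps Early-window length.
#' @return Name of the winning method.
#' @export
select_xai_method <- function(method_curves, baseline, early_steps = 15) {
  if (!length(method_curves)) abort("empty method list")
  scores <- vapply(method_curves, function(cur) {
    d <- decay_statistic(cur, baseline)$step_differences
    mean(d[1 + seq_len(min(early_steps, length(d) - 1))])
  }, numeric(1))
  names(method_curves)[which.max(scores)]
}
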