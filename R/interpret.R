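#' Spatial average of a multichannel window
#'
#' Per-frame arithmetic mean across the sensor channels (the SA metric):
#' `SA[n] = (1/C) * sum_i x_i[n]`, with the divisor equal to the actual
#' channel count. Collapsing the spatial dimension aligns heatmaps and
#' signals with the temporal gait-event structure.
#'
#' @param matrix_ A `window_len x n_channels` matrix (signal or relevance
#'   scores), or a `relevance_map`.
#' @param source `"signal"` or `"relevance"` (metadata only; inferred for
#'   relevance maps).
#' @return An `sa_curve`: list with `values` (length `window_len`),
#'   `source`, `n_channels_averaged`.
#' @export
spatial_average <- function(matrix_, source = c("signal", "relevance")) {
  if (inherits(matrix_, "relevance_map")) {
    source <- "relevance"
    matrix_ <- matrix_$scores
  } else source <- match.arg(source)
  matrix_ <- as.matrix(matrix_)
  if (!length(matrix_)) abort("empty matrix")
  structure(list(values = rowMeans(matrix_), source = source,
                 n_channels_averaged = ncol(matrix_)),
            class = "sa_curve")
}

#' @export
print.sa_curve <- function(x, ...) {
  cat(sprintf("<sa_curve> %s, %d frames (mean of %d channels)\n",
              x$source, length(x$values), x$n_channels_averaged))
  invisible(x)
}

#' Segment a force curve into gait cycles
#'
#' Detects heel strikes of the reference foot as upward crossings of an
#' adaptive threshold (a fraction of the curve's peak) separated by a
#' refractory period, then refines each strike to the onset of its rising
#' edge: the crossing is backtracked along a lightly smoothed copy of the
#' curve to the foot of the rise (robust to oscillatory corruption of the
#' loading response), with a small forward re-adjustment, capped at half the
#' smoothing width, onto the last frame still below `onset_frac` of the
#' peak. All thresholds are relative, so the segmentation is invariant to
#' amplitude scaling. Designed for force-like (signal) curves of a single
#' foot, e.g. the per-foot sum channel.
#'
#' @param sa An `sa_curve` from a force-like source (or a numeric vector).
#' @param sample_rate Frames per second.
#' @param threshold_frac Detection threshold as a fraction of the peak
#'   (default 0.2).
#' @param refractory_s Minimum spacing of detected strikes in seconds.
#' @param min_cycle_s,max_cycle_s Plausible cycle-duration band; cycles
#'   outside it are discarded.
#' @param smooth_width Moving-average width (frames) of the copy used for
#'   onset backtracking; 1 disables the refinement.
#' @param onset_frac Onset level as a fraction of the peak.
#' @return A `cycle_segmentation`: `cycle_boundaries` (strike frames) and
#'   `complete_cycles` (tibble with `start`, `end`; `[start, end)` frames).
#' @export
segment_cycles <- function(sa, sample_rate, threshold_frac = 0.2,
                           refractory_s = 0.5, min_cycle_s = 0.5,
                           max_cycle_s = 2, smooth_width = 11,
                           onset_frac = 0.05) {
  v <- if (inherits(sa, "sa_curve")) sa$values else as.numeric(sa)
  peak <- max(v)
  if (peak <= 0) {
    warn("flat or non-positive curve: no cycles detected")
    return(structure(list(cycle_boundaries = integer(),
                          complete_cycles = tibble::tibble(
                            start = integer(), end = integer())),
                     class = "cycle_segmentation"))
  }
  thr <- threshold_frac * peak
  up <- which(v[-1] >= thr & v[-length(v)] < thr) + 1L
  strikes <- integer()
  refr <- refractory_s * sample_rate
  for (f in up)
    if (!length(strikes) || f - strikes[length(strikes)] >= refr)
      strikes <- c(strikes, f)
  if (smooth_width > 1 && length(strikes)) {
    sm <- moving_average(v, smooth_width)
    lvl <- onset_frac * peak
    cap <- smooth_width %/% 2
    strikes <- vapply(strikes, function(f) {
      while (f > 1 && sm[f - 1] < sm[f]) f <- f - 1L  # walk down the rise
      steps <- 0L
      while (f < length(v) && v[f + 1] < lvl && steps < cap) {
        f <- f + 1L; steps <- steps + 1L
      }
      f
    }, integer(1))
    strikes <- sort(unique(strikes))
  }
  if (length(strikes) < 2) {
    warn("fewer than 2 heel strikes detected: no complete cycles")
    cycles <- tibble::tibble(start = integer(), end = integer())
  } else {
    cycles <- tibble::tibble(start = strikes[-length(strikes)],
                             end = strikes[-1])
    len_s <- (cycles$end - cycles$start) / sample_rate
    cycles <- cycles[len_s >= min_cycle_s & len_s <= max_cycle_s, ]
  }
  structure(list(cycle_boundaries = strikes, complete_cycles = cycles),
            class = "cycle_segmentation")
}

#' Reference-foot cycles from a raw multichannel window
#'
#' Builds the reference-foot cycle segmentation of one raw (unstandardized)
#' window. When an alternate (contralateral) force channel is given, both
#' feet are segmented and the foot with the more regular strike spacing is
#' used; contralateral strikes are mapped back to the reference foot by the
#' phase-model foot offset. This keeps segmentation reliable when the
#' reference foot's loading response is itself the deviating event.
#'
#' @param window `window_len x n_channels` raw matrix.
#' @param sample_rate Frames per second.
#' @param channel Reference-foot force channel (e.g. 17, the left-foot sum
#'   of the 18-channel layout); `NULL` uses the spatial average of all
#'   channels.
#' @param alt_channel Optional contralateral force channel (e.g. 18).
#' @param phase_model A [gait_phase_model()] (for the foot phase offset).
#' @param ... Passed to [segment_cycles()].
#' @return A `cycle_segmentation`.
#' @export
reference_cycles <- function(window, sample_rate, channel = NULL,
                             alt_channel = NULL,
                             phase_model = gait_phase_model(), ...) {
  sig <- if (is.null(channel)) rowMeans(window) else window[, channel]
  seg <- suppressWarnings(segment_cycles(sig, sample_rate, ...))
  if (!is.null(alt_channel)) {
    seg_alt <- suppressWarnings(
      segment_cycles(window[, alt_channel], sample_rate, ...))
    reg <- function(s) if (length(s) < 3) Inf else stats::sd(diff(s))
    if (reg(seg_alt$cycle_boundaries) + 0.5 <
        reg(seg$cycle_boundaries)) {
      med <- stats::median(diff(seg_alt$cycle_boundaries))
      s <- sort(unique(pmax(1L, as.integer(
        seg_alt$cycle_boundaries -
          round(phase_model$foot_phase_offset * med)))))
      if (length(s) >= 2) {
        cyc <- tibble::tibble(start = s[-length(s)], end = s[-1])
        len_s <- (cyc$end - cyc$start) / sample_rate
        seg <- structure(list(cycle_boundaries = s,
                              complete_cycles = cyc[len_s >= 0.5 &
                                                      len_s <= 2, ]),
                         class = "cycle_segmentation")
      }
    }
  }
  seg
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf("<cycle_segmentation> %d strikes, %d complete cycles\n",
              length(x$cycle_boundaries), nrow(x$complete_cycles)))
  invisible(x)
}

moving_average <- function(v, width = 3) {
  if (width <= 1) return(v)
  sm <- as.numeric(stats::filter(v, rep(1 / width, width), sides = 2))
  sm[is.na(sm)] <- v[is.na(sm)]
  sm
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer())
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Assign relevance peaks to gait events
#'
#' Finds the most prominent local maxima of a relevance SA curve inside the
#' complete gait cycles, converts each peak frame to a phase fraction within
#' its cycle, and labels it with the gait event whose interval contains the
#' phase. Peaks are local maxima after light smoothing (moving average,
#' width 3 frames by default).
#'
#' @param relevance_sa An `sa_curve` of relevance scores (or numeric
#'   vector).
#' @param segmentation A [segment_cycles()] result for the same sample.
#' @param phase_model A [gait_phase_model()].
#' @param top_k Number of peaks to keep (by relevance value).
#' @param smooth_width Moving-average width in frames.
#' @return An `event_assignment`: tibble `peaks` with columns `frame`,
#'   `phase`, `event`, `score`, `cycle_index`, plus a `degenerate` flag set
#'   when the curve has no usable local maxima (e.g. uniform relevance).
#' @export
assign_relevance_events <- function(relevance_sa, segmentation,
                                    phase_model = gait_phase_model(),
                                    top_k = 3, smooth_width = 3) {
  v <- if (inherits(relevance_sa, "sa_curve")) relevance_sa$values
    else as.numeric(relevance_sa)
  cycles <- segmentation$complete_cycles
  empty <- tibble::tibble(frame = integer(), phase = numeric(),
                          event = character(), score = numeric(),
                          cycle_index = integer())
  if (!nrow(cycles))
    return(structure(list(peaks = empty, degenerate = FALSE),
                     class = "event_assignment"))
  sm <- moving_average(v, smooth_width)
  rows <- list()
  for (ci in seq_len(nrow(cycles))) {
    rng <- cycles$start[ci]:(cycles$end[ci] - 1L)
    loc <- local_maxima(sm[rng])
    if (!length(loc)) next
    fr <- rng[loc]
    ph <- (fr - cycles$start[ci]) / (cycles$end[ci] - cycles$start[ci])
    rows[[length(rows) + 1]] <-
      tibble::tibble(frame = fr, phase = ph,
                     event = phase_to_event(ph, phase_model),
                     score = sm[fr], cycle_index = ci)
  }
  if (!length(rows))
    return(structure(list(peaks = empty, degenerate = TRUE),
                     class = "event_assignment"))
  peaks <- dplyr::arrange(dplyr::bind_rows(rows),
                          dplyr::desc(.data$score))
  peaks <- utils::head(peaks, top_k)
  structure(list(peaks = peaks, degenerate = FALSE),
            class = "event_assignment")
}

#' @export
print.event_assignment <- function(x, ...) {
  if (x$degenerate) cat("<event_assignment> degenerate (no usable peaks)\n")
  else {
    cat(sprintf("<event_assignment> %d peak(s)\n", nrow(x$peaks)))
    print(x$peaks)
  }
  invisible(x)
}

#' Majority event over a window's cycles
#'
#' Reduces an event assignment to one event label per window: each complete
#' cycle votes with its top-scoring peak's event, and the most frequent
#' event wins (ties broken by total peak score). Voting across the ~4-5
#' cycles of a window averages out per-cycle peak jitter.
#'
#' @param assignment An [assign_relevance_events()] result (use a large
#'   `top_k` so every cycle's maxima are present).
#' @return Single event label, or `NA` when the assignment is empty.
#' @export
window_event_vote <- function(assignment) {
  pk <- assignment$peaks
  if (!nrow(pk)) return(NA_character_)
  best <- pk |>
    dplyr::group_by(.data$cycle_index) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$event) |>
    dplyr::summarise(n = dplyr::n(), total = sum(.data$score)) |>
    dplyr::arrange(dplyr::desc(.data$n), dplyr::desc(.data$total))
  best$event[1]
}

#' Per-class gait-event frequency table
#'
#' Aggregates top-1 event assignments into normalized per-class
#' frequencies, supporting statements of the form "class k's modal event is
#' E". Callers should restrict the input to true-positive predictions so
#' the heatmaps explain correct decisions.
#'
#' @param assignments Tibble (or data frame) with columns `class` and
#'   `event`, one row per sample's top-1 peak.
#' @return Tibble with `class`, `event`, `n`, `freq` (frequencies sum to 1
#'   within each class) -- classes with no assignments are omitted with a
#'   warning.
#' @export
event_histogram <- function(assignments) {
  assignments <- tibble::as_tibble(assignments)
  stopifnot(all(c("class", "event") %in% names(assignments)))
  if (!nrow(assignments)) {
    warn("no assignments supplied")
    return(tibble::tibble(class = character(), event = character(),
                          n = integer(), freq = numeric()))
  }
  assignments |>
    dplyr::count(.data$class, .data$event, name = "n") |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Modal event per class
#' @param histogram An [event_histogram()] table.
#' @return Tibble `class`, `event` (the most frequent event), `freq`.
#' @export
modal_events <- function(histogram) {
  histogram |>
    dplyr::group_by(.data$class) |>
    dplyr::slice_max(.data$freq, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("class", "event", "freq")
}
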