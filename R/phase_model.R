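#' Gait-cycle phase model
#'
#' Describes one gait cycle of a reference foot as a partition of the phase
#' axis `[0, 1)` into the seven named gait events A--G. The stance phase
#' (events A--E, ground contact) occupies `stance_fraction` of the cycle and
#' the swing phase (F, G) the remainder; with the default 0.60 this is the
#' classical 60/40 stance/swing division. Event interval widths within each
#' phase follow standard clinical gait-phase conventions, rescaled so that the
#' stance events end exactly at `stance_fraction`:
#'
#' * A heel strike, B loading response, C mid-stance (single support),
#'   D terminal stance, E pre-swing (second double support) -- stance;
#' * F initial/mid-swing, G terminal swing -- swing.
#'
#' @param cycle_duration Mean cycle duration in seconds (subject level).
#' @param stance_fraction Fraction of the cycle spent in stance, in (0, 1).
#' @param cadence_jitter_sd Relative standard deviation of per-cycle duration
#'   (fraction of `cycle_duration`), used by the synthetic generator.
#' @param foot_phase_offset Phase offset of the contralateral foot (fraction
#'   of one cycle; 0.5 = perfectly alternating feet).
#' @return An object of class `gait_phase_model`: a list with the arguments
#'   plus `event_boundaries`, a tibble with columns `event`, `lo`, `hi`
#'   (half-open phase intervals `[lo, hi)` ordered A--G covering `[0, 1)`).
#' @examples
#' pm <- gait_phase_model()
#' pm$event_boundaries
#' phase_to_event(c(0, 0.2, 0.95), pm)
#' @export
gait_phase_model <- function(cycle_duration = 1.0,
                             stance_fraction = 0.60,
                             cadence_jitter_sd = 0.02,
                             foot_phase_offset = 0.5) {
  stopifnot(cycle_duration > 0,
            stance_fraction > 0, stance_fraction < 1,
            cadence_jitter_sd >= 0,
            foot_phase_offset >= 0, foot_phase_offset < 1)
  # canonical event edges at the clinical 60/40 split
  stance_edges <- c(0, 0.02, 0.10, 0.30, 0.50, 0.60) / 0.60 # A..E within stance
  swing_edges  <- c(0.60, 0.87, 1.00)                        # F..G edges (cycle)
  lo <- c(stance_edges[1:5] * stance_fraction,
          stance_fraction + (swing_edges[1:2] - 0.60) / 0.40 * (1 - stance_fraction))
  hi <- c(lo[-1], 1)
  model <- list(
    cycle_duration = cycle_duration,
    stance_fraction = stance_fraction,
    cadence_jitter_sd = cadence_jitter_sd,
    foot_phase_offset = foot_phase_offset,
    event_boundaries = tibble::tibble(event = LETTERS[1:7], lo = lo, hi = hi)
  )
  class(model) <- "gait_phase_model"
  validate_phase_model(model)
  model
}

validate_phase_model <- function(model) {
  b <- model$event_boundaries
  stopifnot(nrow(b) == 7, identical(b$event, LETTERS[1:7]))
  if (b$lo[1] != 0 || b$hi[7] != 1 || any(b$lo[-1] != b$hi[-7]))
    abort("event intervals must be disjoint, ordered A-G and cover [0, 1)")
  if (abs(b$hi[5] - model$stance_fraction) > 1e-12)
    abort("stance events A-E must end exactly at stance_fraction")
  invisible(model)
}

#' @export
print.gait_phase_model <- function(x, ...) {
  cat(sprintf("<gait_phase_model> cycle %.3g s, stance %.0f%% / swing %.0f%%\n",
              x$cycle_duration, 100 * x$stance_fraction,
              100 * (1 - x$stance_fraction)))
  print(x$event_boundaries)
  invisible(x)
}

#' Map a cycle phase to its gait event
#'
#' Returns, for each phase fraction, the unique event A--G whose half-open
#' interval contains it under the given phase model.
#'
#' @param phase Numeric vector of phase fractions in `[0, 1)`.
#' @param phase_model A [gait_phase_model()].
#' @return Character vector of event labels (`"A"` .. `"G"`).
#' @export
phase_to_event <- function(phase, phase_model = gait_phase_model()) {
  if (any(phase < 0 | phase >= 1))
    abort("phase must lie in [0, 1)")
  b <- phase_model$event_boundaries
  idx <- findInterval(phase, b$lo)
  b$event[idx]
}

#' Vertical ground-reaction-force waveform over one cycle
#'
#' Smooth double-bump ("M"-shaped) vertical GRF profile: two raised-cosine
#' bumps centred near 25% and 75% of the stance interval over a sinusoidal
#' mid-stance valley, and identically zero over the swing interval. The
#' profile is continuous at heel strike and toe-off (force 0 at both stance
#' boundaries).
#'
#' @param phase Numeric vector of phase fractions in `[0, 1)`.
#' @param phase_model A [gait_phase_model()]; only `stance_fraction` is used.
#' @param params List of waveform parameters: `amplitude` (peak scale),
#'   `valley` (mid-stance valley level relative to the bump peak).
#' @return Numeric vector of forces (unitless until scaled by body weight).
#' @examples
#' pm <- gait_phase_model()
#' grf_waveform(c(0.15, 0.45, 0.8), pm)
#' @export
grf_waveform <- function(phase, phase_model = gait_phase_model(),
                         params = list(amplitude = 1, valley = 0.6)) {
  if (any(phase < 0 | phase >= 1))
    abort("phase must lie in [0, 1)")
  sf <- phase_model$stance_fraction
  s <- phase / sf                               # position within stance, [0,1)
  f <- numeric(length(phase))
  in_stance <- phase < sf
  bump <- function(s, centre, width) {
    ifelse(abs(s - centre) < width,
           0.5 * (1 + cos(pi * (s - centre) / width)), 0)
  }
  sv <- s[in_stance]
  f[in_stance] <- params$amplitude *
    (bump(sv, 0.25, 0.25) + bump(sv, 0.75, 0.25) +
       params$valley * sin(pi * sv))
  f
}
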