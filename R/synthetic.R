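#' Synthetic gait dataset configuration
#'
#' Configuration for the synthetic GRF generator. Two scenarios are
#' supported, matching the two sensing modalities the analysis targets:
#'
#' * `"pd"` -- force-platform style recordings: 100 frames/s, 500-frame
#'   windows, 19 raw columns (timestamp + 8 heel-to-toe sensors per foot +
#'   2 per-foot sums; 18 channels after timestamp removal), four severity
#'   classes (healthy `0`, Hoehn--Yahr `2`, `2.5`, `3`). Severity is a
#'   subject-level label: each subject belongs to one class.
#' * `"cognitive"` -- floor-sensor style recordings: 20 frames/s, 100-frame
#'   windows, 116 channels in three plies of 22/47/47 sensors, five walking
#'   manners (`M1` normal, `M2` listening, `M3` serial-7 subtraction,
#'   `M4` texting, `M5` talking); every subject performs all five.
#'
#' Per-subject body-weight amplitude factors are drawn log-uniformly from
#' `subject_weight_scale_range`. On top of the subject factor, every trial
#' draws an independent log-normal amplitude factor
#' (`trial_amplitude_jitter_sd`, sd on the log scale) emulating step-to-step
#' force variability (walking speed, sensor placement); without it, overall
#' signal energy alone would betray the planted class effects and the
#' discriminative signal would not be localized at the target events.
#'
#' @param scenario `"pd"` or `"cognitive"`.
#' @param n_subjects Subjects per class (`pd`) or total subjects (`cognitive`).
#' @param trials_per_subject_per_class Windows per subject and class.
#' @param sample_rate,window_len,n_channels Scenario geometry; defaults are
#'   filled from the scenario and should normally be left alone.
#' @param subject_weight_scale_range Length-2 interval for the log-uniform
#'   per-subject amplitude factor.
#' @param trial_amplitude_jitter_sd Standard deviation (log scale) of the
#'   per-trial amplitude factor.
#' @param foot_asymmetry_jitter_sd Standard deviation (log scale) of the
#'   independent per-foot amplitude factors drawn each trial (step-to-step
#'   left/right asymmetry; `pd` scenario).
#' @param channel_gain_jitter_sd Standard deviation (log scale) of the
#'   independent per-sensor gain factors drawn each trial (sensor coupling
#'   variability).
#' @param noise_sd Additive sensor noise standard deviation, relative to the
#'   unit force amplitude.
#' @param seed Integer seed; all draws derive from it deterministically.
#' @return A `generator_config` list.
#' @export
generator_config <- function(scenario = c("pd", "cognitive"),
                             n_subjects = if (scenario == "pd") 10 else 21,
                             trials_per_subject_per_class = if (scenario == "pd") 20 else 10,
                             sample_rate = if (scenario == "pd") 100 else 20,
                             window_len = if (scenario == "pd") 500 else 100,
                             n_channels = if (scenario == "pd") 19 else 116,
                             subject_weight_scale_range = c(0.8, 1.25),
                             trial_amplitude_jitter_sd = 0.25,
                             foot_asymmetry_jitter_sd = 0.25,
                             channel_gain_jitter_sd = 0.25,
                             noise_sd = 0.05,
                             seed = 1L) {
  scenario <- match.arg(scenario)
  cfg <- list(scenario = scenario, n_subjects = as.integer(n_subjects),
              trials_per_subject_per_class = as.integer(trials_per_subject_per_class),
              sample_rate = sample_rate, window_len = as.integer(window_len),
              n_channels = as.integer(n_channels),
              subject_weight_scale_range = subject_weight_scale_range,
              trial_amplitude_jitter_sd = trial_amplitude_jitter_sd,
              foot_asymmetry_jitter_sd = foot_asymmetry_jitter_sd,
              channel_gain_jitter_sd = channel_gain_jitter_sd,
              noise_sd = noise_sd, seed = as.integer(seed))
  stopifnot(cfg$n_subjects >= 1, cfg$trials_per_subject_per_class >= 1,
            cfg$window_len >= 1, length(subject_weight_scale_range) == 2,
            all(subject_weight_scale_range > 0), noise_sd >= 0,
            trial_amplitude_jitter_sd >= 0, foot_asymmetry_jitter_sd >= 0,
            channel_gain_jitter_sd >= 0)
  if (scenario == "pd" && cfg$n_channels != 19L)
    abort("pd scenario uses 19 raw columns (timestamp + 16 sensors + 2 sums)")
  if (scenario == "cognitive" && cfg$n_channels != 116L)
    abort("cognitive scenario uses 116 channels")
  class(cfg) <- "generator_config"
  cfg
}

#' Class-discriminative gait effect
#'
#' One planted deviation: inside the frames where the reference foot's phase
#' lies in `target_event`'s interval, all channels are multiplied by
#' `amplitude_scale - tremor_amplitude * cos(2*pi*tremor_hz*(t - t_mid))`
#' -- an
#' attenuation carrying a tremor-like oscillation, the presence-coded form
#' of a local gait deviation (phase-locked so the deepest trough sits at the window centre). The window
#' placement is jittered in time by a Gaussian draw with `timing_jitter_sd`
#' seconds per occurrence. Because `tremor_amplitude < amplitude_scale`, the
#' expected absolute amplitude inside the window is exactly
#' `amplitude_scale` times the unmodified template (strictly lower than the
#' reference when `amplitude_scale < 1`), and because the tremor parameters
#' are shared across classes, the window's location (the target event) is
#' the only class-discriminative cue. The reference class of a scenario
#' carries no effect.
#'
#' @param applies_to Class label the effect belongs to.
#' @param target_event Gait event label `"A"` .. `"G"`.
#' @param amplitude_scale Positive multiplier (< 1 attenuates).
#' @param timing_jitter_sd Timing jitter standard deviation in seconds.
#' @param tremor_amplitude Amplitude of the oscillatory modulation; must be
#'   < `amplitude_scale` so the multiplier stays positive.
#' @param tremor_hz Tremor frequency in Hz.
#' @return A `class_effect` list.
#' @export
class_effect <- function(applies_to, target_event, amplitude_scale = 0.5,
                         timing_jitter_sd = 0.01, tremor_amplitude = 0.45,
                         tremor_hz = 8) {
  stopifnot(amplitude_scale > 0, timing_jitter_sd >= 0,
            tremor_amplitude >= 0, tremor_amplitude < amplitude_scale,
            tremor_hz > 0, target_event %in% LETTERS[1:7])
  structure(list(applies_to = as.character(applies_to),
                 target_event = target_event,
                 amplitude_scale = amplitude_scale,
                 timing_jitter_sd = timing_jitter_sd,
                 tremor_amplitude = tremor_amplitude,
                 tremor_hz = tremor_hz),
            class = "class_effect")
}

#' Default planted effects
#'
#' The per-class gait-event markers: severities 2, 2.5 and 3 deviate at
#' mid-stance (C), loading response (B) and terminal swing (G) respectively;
#' the four dual tasks deviate at heel strike (A, listening), toe-off
#' (F, serial-7 subtraction), terminal swing (G, texting) and pre-swing /
#' double support (E, talking).
#'
#' @param amplitude_scale,timing_jitter_sd Shared effect parameters.
#' @return List of [class_effect()]s.
#' @export
default_pd_effects <- function(amplitude_scale = 0.5, timing_jitter_sd = 0.01) {
  list(class_effect("2",   "C", amplitude_scale, timing_jitter_sd),
       class_effect("2.5", "B", amplitude_scale, timing_jitter_sd),
       class_effect("3",   "G", amplitude_scale, timing_jitter_sd))
}

#' @rdname default_pd_effects
#' @export
default_cognitive_effects <- function(amplitude_scale = 0.5,
                                      timing_jitter_sd = 0.02) {
  list(class_effect("M2", "A", amplitude_scale, timing_jitter_sd),
       class_effect("M3", "F", amplitude_scale, timing_jitter_sd),
       class_effect("M4", "G", amplitude_scale, timing_jitter_sd),
       class_effect("M5", "E", amplitude_scale, timing_jitter_sd))
}

# Run code under a derived seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Counter-based sub-seed so per-unit streams are independent of order.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- (as.double(seed) %% 2147483629) + 1
  for (k in seq_along(idx))
    s <- (s * 48271 + as.double(idx[k]) * 16807 + k) %% 2147483629
  as.integer(s)
}

# Piecewise-linear phase trajectory of the reference (left) foot.
# Returns per-frame phase in [0,1), cycle index, and cycle start frames.
sim_phase_trajectory <- function(n_frames, sample_rate, phase_model,
                                 cycle_duration = phase_model$cycle_duration,
                                 phase0 = 0) {
  t_end <- n_frames / sample_rate
  n_cyc <- ceiling(t_end / cycle_duration) + 3
  durs <- cycle_duration *
    pmax(0.5, 1 + rnorm(n_cyc, 0, phase_model$cadence_jitter_sd))
  starts <- -phase0 * durs[1] + c(0, cumsum(durs[-n_cyc]))
  tt <- (seq_len(n_frames) - 1) / sample_rate
  cyc <- findInterval(tt, starts)
  phase <- (tt - starts[cyc]) / durs[cyc]
  phase <- pmin(pmax(phase, 0), 1 - 1e-9)
  list(phase = phase, cycle = cyc, starts = starts, durations = durs)
}

#' Distribute per-foot forces over sensor channels
#'
#' Renders a two-foot force time series into the raw channel layout of the
#' configured scenario. For `"pd"`, each foot's force is spread over 8
#' heel-to-toe sensors whose Gaussian activation windows advance linearly
#' through stance, then the timestamp and the two per-foot sum columns are
#' added (19 columns; the sum columns equal the sum of that foot's 8 sensors
#' at every frame). For `"cognitive"`, the two-foot force field is projected
#' onto 116 channels in three plies of 22/47/47 sensors with smoothed
#' per-channel gains. Amplitudes are scaled by `weight`.
#'
#' @param per_foot_force List with numeric vectors `left` and `right` and the
#'   matching stance positions `s_left`, `s_right` (in `[0,1)`, `NA` in
#'   swing).
#' @param config A [generator_config()].
#' @param phase_model A [gait_phase_model()].
#' @param weight Per-subject amplitude factor.
#' @param gains For the cognitive scenario, the fixed 116 x 2 channel gain
#'   matrix (see `cognitive_channel_gains()`).
#' @return A [raw_recording()] in the scenario's dialect (no noise applied).
#' @export
render_channels <- function(per_foot_force, config, phase_model,
                            weight = 1, gains = NULL) {
  n <- length(per_foot_force$left)
  if (config$scenario == "pd") {
    sens <- matrix(0, n, 16)
    centres <- (seq_len(8) - 0.5) / 8
    for (side in 1:2) {
      force <- if (side == 1) per_foot_force$left else per_foot_force$right
      s <- if (side == 1) per_foot_force$s_left else per_foot_force$s_right
      s_ok <- ifelse(is.na(s), Inf, s)
      for (k in 1:8) {
        w <- exp(-(s_ok - centres[k])^2 / (2 * 0.15^2))
        sens[, (side - 1) * 8 + k] <- weight * force * w
      }
    }
    values <- cbind((seq_len(n) - 1) / config$sample_rate, sens,
                    rowSums(sens[, 1:8, drop = FALSE]),
                    rowSums(sens[, 9:16, drop = FALSE]))
    raw_recording(values, dialect = "gaitpdb-19col",
                  sample_rate = config$sample_rate)
  } else {
    if (is.null(gains)) gains <- cognitive_channel_gains(config$seed)
    values <- weight * (outer(per_foot_force$left, gains[, 1]) +
                          outer(per_foot_force$right, gains[, 2]))
    raw_recording(values, dialect = "pof-116col",
                  sample_rate = config$sample_rate)
  }
}

# Fixed spatial gain layout of the 116 floor-sensor channels: one ply of 22
# and two of 47, each channel mixing the two feet with smoothed random gains.
cognitive_channel_gains <- function(seed) {
  local_seed(derive_seed(seed, 116L), {
    ply <- rep(1:3, times = c(22, 47, 47))
    g <- matrix(runif(116 * 2, 0.2, 1), 116, 2)
    for (p in 1:3) {       # smooth within each ply (spatially coherent gains)
      idx <- which(ply == p)
      for (j in 1:2) g[idx, j] <- stats::filter(g[idx, j], rep(1 / 5, 5),
                                                circular = TRUE)
    }
    g
  })
}

# Frames (1-based, inclusive) where the reference foot's phase sits inside
# the event interval, one row per cycle occurrence, after timing jitter.
event_frame_windows <- function(traj, phase_model, event,
                                jitter_sd = 0, sample_rate = 100) {
  b <- phase_model$event_boundaries
  row <- b[b$event == event, ]
  inside <- traj$phase >= row$lo & traj$phase < row$hi
  centre <- (row$lo + row$hi) / 2
  out <- list()
  for (cy in unique(traj$cycle)) {
    f <- which(inside & traj$cycle == cy)
    if (!length(f)) {
      # at coarse sampling a narrow event can fall between frames: plant on
      # the frame nearest the interval centre so every occurrence is marked
      fc <- which(traj$cycle == cy)
      if (!length(fc)) next
      f <- fc[which.min(abs(traj$phase[fc] - centre))]
    }
    shift <- if (jitter_sd > 0) round(rnorm(1, 0, jitter_sd * sample_rate)) else 0L
    lo <- min(f) + shift; hi <- max(f) + shift
    lo <- max(1L, lo); hi <- min(length(traj$phase), hi)
    if (lo <= hi) out[[length(out) + 1]] <- c(lo, hi)
  }
  if (!length(out)) return(tibble::tibble(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

# Simulate one raw window for a subject: forces, channels, planted effect.
simulate_window <- function(config, phase_model, effect, weight,
                            cycle_duration, gains = NULL) {
  n <- config$window_len
  phase0 <- runif(1)
  traj <- sim_phase_trajectory(n, config$sample_rate, phase_model,
                               cycle_duration, phase0)
  sf <- phase_model$stance_fraction
  phL <- traj$phase
  phR <- (phL + phase_model$foot_phase_offset) %% 1
  force <- list(left = grf_waveform(phL, phase_model),
                right = grf_waveform(phR, phase_model),
                s_left = ifelse(phL < sf, phL / sf, NA_real_),
                s_right = ifelse(phR < sf, phR / sf, NA_real_))
  rec <- render_channels(force, config, phase_model, weight, gains)
  sens_cols <- sensor_columns(rec)
  # per-trial sensor-level nuisance gains (step asymmetry, sensor coupling)
  chg <- exp(rnorm(length(sens_cols), 0, config$channel_gain_jitter_sd))
  if (config$scenario == "pd") {
    fg <- exp(rnorm(2, 0, config$foot_asymmetry_jitter_sd))
    chg <- chg * rep(fg, each = 8)
  }
  rec$values[, sens_cols] <- sweep(rec$values[, sens_cols, drop = FALSE],
                                   2, chg, "*")
  windows <- tibble::tibble(start = integer(), end = integer())
  if (!is.null(effect)) {
    windows <- event_frame_windows(traj, phase_model, effect$target_event,
                                   effect$timing_jitter_sd, config$sample_rate)
    for (r in seq_len(nrow(windows))) {
      idx <- windows$start[r]:windows$end[r]
      # tremor phase-locked so the deepest trough falls at the window
      # centre: every occurrence carries the same symmetric deviation
      # waveform (action tremor resets at movement transitions)
      t_mid <- (idx[1] + idx[length(idx)]) / 2
      mod <- effect$amplitude_scale - effect$tremor_amplitude *
        cos(2 * pi * effect$tremor_hz * (idx - t_mid) / config$sample_rate)
      rec$values[idx, sens_cols] <- rec$values[idx, sens_cols] * mod
    }
  }
  if (config$noise_sd > 0) {
    ns <- matrix(rnorm(n * length(sens_cols), 0, config$noise_sd * weight),
                 n, length(sens_cols))
    rec$values[, sens_cols] <- pmax(rec$values[, sens_cols] + ns, 0)
  }
  if (rec$dialect == "gaitpdb-19col") {  # keep the sum-column identity exact
    rec$values[, 18] <- rowSums(rec$values[, 2:9, drop = FALSE])
    rec$values[, 19] <- rowSums(rec$values[, 10:17, drop = FALSE])
  }
  list(recording = rec, event_windows = windows, trajectory = traj)
}

sensor_columns <- function(rec) {
  if (rec$dialect == "gaitpdb-19col") 2:17 else seq_len(ncol(rec$values))
}

#' Generate a synthetic Parkinson's-severity gait dataset
#'
#' Produces balanced 500-frame, 18-channel windows (timestamp already
#' removed, per-foot sum columns recomputed) for the four severity classes
#' `0` (healthy reference, unmodified), `2`, `2.5` and `3`. Each non-healthy
#' class deviates from the shared template only inside its planted gait-event
#' windows (see [class_effect()]); the ground-truth frame intervals where the
#' effect was applied are returned per window. Output is bit-reproducible for
#' a fixed `(config, seed)`.
#'
#' @param config A [generator_config()] with `scenario = "pd"`.
#' @param effects List of [class_effect()]s covering classes 2, 2.5, 3.
#' @param phase_model A [gait_phase_model()].
#' @param seed Overrides `config$seed` when given.
#' @return A [gait_dataset()] with `values` of shape
#'   `(n_samples, window_len, 18)`, labels, subject ids and per-window
#'   ground-truth `event_windows`.
#' @export
generate_pd_dataset <- function(config = generator_config("pd"),
                                effects = default_pd_effects(),
                                phase_model = gait_phase_model(),
                                seed = config$seed) {
  stopifnot(config$scenario == "pd")
  classes <- c("0", "2", "2.5", "3")
  check_effects(effects, setdiff(classes, "0"), phase_model)
  generate_dataset(config, effects, phase_model, seed, classes,
                   reference = "0", tag = "synthetic",
                   subjects_per_class = TRUE)
}

#' Generate a synthetic cognitive-load gait dataset
#'
#' 21 subjects x 5 walking manners x 10 trials by default, 100-frame
#' 116-channel windows at 20 frames/s. `M1` (normal gait) is the unmodified
#' reference; each dual task `M2`--`M5` deviates at its planted gait event,
#' with a subject-specific effect magnitude and timing so each subject has an
#' individual dual-task signature.
#'
#' @inheritParams generate_pd_dataset
#' @param config A [generator_config()] with `scenario = "cognitive"`.
#' @param effects List of [class_effect()]s covering `M2`--`M5`.
#' @return A [gait_dataset()] with `values` of shape
#'   `(n_subjects * 5 * trials, window_len, 116)`.
#' @export
generate_cognitive_dataset <- function(config = generator_config("cognitive"),
                                       effects = default_cognitive_effects(),
                                       phase_model = gait_phase_model(),
                                       seed = config$seed) {
  stopifnot(config$scenario == "cognitive")
  classes <- paste0("M", 1:5)
  check_effects(effects, classes[-1], phase_model)
  generate_dataset(config, effects, phase_model, seed, classes,
                   reference = "M1", tag = "cognitive",
                   subjects_per_class = FALSE)
}

check_effects <- function(effects, needed, phase_model) {
  got <- vapply(effects, function(e) e$applies_to, character(1))
  if (!setequal(got, needed) || anyDuplicated(got))
    abort(paste0("effects must cover exactly the non-reference classes: ",
                 paste(needed, collapse = ", ")))
  evs <- vapply(effects, function(e) e$target_event, character(1))
  if (!all(evs %in% phase_model$event_boundaries$event))
    abort("effect targets an event label absent from the phase model")
  invisible(TRUE)
}

generate_dataset <- function(config, effects, phase_model, seed, classes,
                             reference, tag, subjects_per_class) {
  effect_of <- setNames(effects, vapply(effects, `[[`, "", "applies_to"))
  n_trials <- config$trials_per_subject_per_class
  n_chan_out <- if (config$scenario == "pd") 18L else 116L
  gains <- if (config$scenario == "cognitive")
    cognitive_channel_gains(seed) else NULL

  subjects <- if (subjects_per_class) {
    unlist(lapply(classes, function(cl)
      paste0("S", cl, "_", seq_len(config$n_subjects))))
  } else paste0("S", seq_len(config$n_subjects))
  subj_class <- if (subjects_per_class)
    rep(classes, each = config$n_subjects) else NULL

  # subject-level draws
  wr <- config$subject_weight_scale_range
  subj_attr <- lapply(seq_along(subjects), function(i)
    local_seed(derive_seed(seed, 1L, i), {
      list(weight = exp(runif(1, log(wr[1]), log(wr[2]))),
           cycle_duration = phase_model$cycle_duration *
             (1 + rnorm(1, 0, 0.05)),
           # individual dual-task signature (cognitive scenario)
           effect_mod = exp(rnorm(length(classes), 0, 0.15)))
    }))

  grid <- list()
  for (i in seq_along(subjects)) {
    cls <- if (subjects_per_class) subj_class[i] else classes
    for (cl in cls)
      grid[[length(grid) + 1]] <- list(subject = i, class = cl)
  }

  n_samples <- length(grid) * n_trials
  values <- array(0, c(n_samples, config$window_len, n_chan_out))
  labels <- character(n_samples); subj_ids <- character(n_samples)
  windex <- integer(n_samples); event_windows <- vector("list", n_samples)
  planted <- character(n_samples)

  row <- 0L
  for (g in grid) {
    at <- subj_attr[[g$subject]]
    eff <- effect_of[[g$class]]
    if (!is.null(eff) && !subjects_per_class) {
      # subject-specific dual-task response
      k <- match(g$class, classes)
      eff$amplitude_scale <- min(0.95, eff$amplitude_scale * at$effect_mod[k])
    }
    for (tr in seq_len(n_trials)) {
      row <- row + 1L
      sw <- local_seed(derive_seed(seed, 2L, g$subject,
                                   match(g$class, classes), tr), {
        trial_gain <- exp(rnorm(1, 0, config$trial_amplitude_jitter_sd))
        simulate_window(config, phase_model, eff, at$weight * trial_gain,
                        at$cycle_duration, gains)
      })
      vals <- sw$recording$values
      if (config$scenario == "pd") vals <- vals[, -1, drop = FALSE]
      values[row, , ] <- vals
      labels[row] <- g$class
      subj_ids[row] <- subjects[g$subject]
      windex[row] <- tr
      event_windows[[row]] <- sw$event_windows
      planted[row] <- if (is.null(eff)) NA_character_ else eff$target_event
    }
  }

  gait_dataset(values = values, labels = factor(labels, levels = classes),
               subject_id = subj_ids, classes = classes,
               window_index = windex, dataset_tag = tag,
               sample_rate = config$sample_rate,
               event_windows = event_windows, planted_event = planted,
               phase_model = phase_model, config = config)
}

#' Simulate one raw multi-channel gait recording
#'
#' Convenience wrapper used for fixtures and reader round-trips: a single
#' subject walking for `n_frames` frames in the configured dialect, without
#' planted effects.
#'
#' @param config A [generator_config()].
#' @param n_frames Recording length in frames.
#' @param phase_model A [gait_phase_model()].
#' @param seed Integer seed.
#' @return A [raw_recording()].
#' @export
simulate_recording <- function(config = generator_config("pd"),
                               n_frames = 1000,
                               phase_model = gait_phase_model(),
                               seed = config$seed) {
  cfg <- config
  cfg$window_len <- as.integer(n_frames)
  local_seed(derive_seed(seed, 3L), {
    weight <- exp(runif(1, log(cfg$subject_weight_scale_range[1]),
                        log(cfg$subject_weight_scale_range[2])))
    sw <- simulate_window(cfg, phase_model, NULL, weight,
                          phase_model$cycle_duration,
                          if (cfg$scenario == "cognitive")
                            cognitive_channel_gains(seed) else NULL)
    sw$recording
  })
}
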