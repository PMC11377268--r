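small_pd_cfg <- function(seed = 7, subj = 3, trials = 4)
  generator_config("pd", n_subjects = subj,
                   trials_per_subject_per_class = trials, seed = seed)

test_that("severity dataset has the documented geometry and is balanced", {
  ds <- generate_pd_dataset(small_pd_cfg())
  expect_equal(dim(ds$values), c(3 * 4 * 4, 500, 18))
  expect_equal(as.vector(table(ds$labels)), rep(12, 4))
  expect_identical(ds$classes, c("0", "2", "2.5", "3"))
  expect_equal(length(unique(ds$subject_id)), 12)
  # every non-reference window records where its effect was applied
  eff <- ds$labels != "0"
  expect_true(all(vapply(ds$event_windows[eff], nrow, integer(1)) > 0))
  expect_true(all(vapply(ds$event_windows[!eff], nrow, integer(1)) == 0))
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- small_pd_cfg(seed = 11)
  expect_identical(generate_pd_dataset(cfg)$values,
                   generate_pd_dataset(cfg)$values)
  cfg2 <- small_pd_cfg(seed = 12)
  expect_false(identical(generate_pd_dataset(cfg)$values,
                         generate_pd_dataset(cfg2)$values))
})

test_that("raw channels are non-negative and sum columns are exact", {
  ds <- generate_pd_dataset(small_pd_cfg())
  expect_true(min(ds$raw) >= 0)
  for (i in sample(dim(ds$raw)[1], 5)) {
    w <- ds$raw[i, , ]
    expect_equal(w[, 17], rowSums(w[, 1:8]))
    expect_equal(w[, 18], rowSums(w[, 9:16]))
  }
})

test_that("render_channels obeys its constructed identities", {
  cfg <- generator_config("pd", seed = 1)
  pm <- gait_phase_model()
  n <- 50
  force <- list(left = rep(1, n), right = rep(2, n),
                s_left = rep(0.3, n), s_right = rep(0.4, n))
  rec <- render_channels(force, cfg, pm, weight = 1)
  expect_equal(ncol(rec$values), 19)
  expect_equal(rec$values[, 18], rowSums(rec$values[, 2:9]))
  expect_equal(rec$values[, 19], rowSums(rec$values[, 10:17]))
  # doubling the weight doubles every sensor value
  rec2 <- render_channels(force, cfg, pm, weight = 2)
  expect_equal(rec2$values[, -1], 2 * rec$values[, -1])
  # zero force in -> zero sensors out
  z <- render_channels(list(left = numeric(n), right = numeric(n),
                            s_left = rep(NA_real_, n),
                            s_right = rep(NA_real_, n)), cfg, pm)
  expect_true(all(z$values[, -1] == 0))
})

test_that("planted effects are localized: no expected difference outside windows, lower amplitude inside", {
  # Monte-Carlo over paired healthy / severity-3 windows sharing seeds
  cfg <- generator_config("pd", n_subjects = 5,
                          trials_per_subject_per_class = 10, seed = 21,
                          trial_amplitude_jitter_sd = 0,
                          foot_asymmetry_jitter_sd = 0,
                          channel_gain_jitter_sd = 0)
  ds <- generate_pd_dataset(cfg)
  h <- which(ds$labels == "0"); s3 <- which(ds$labels == "3")
  inside_diff <- c(); outside_h <- c(); outside_s <- c()
  for (i in s3) {
    ew <- ds$event_windows[[i]]
    inwin <- rep(FALSE, 500)
    for (r in seq_len(nrow(ew))) inwin[ew$start[r]:ew$end[r]] <- TRUE
    outside_s <- c(outside_s, mean(abs(ds$raw[i, !inwin, 1:16])))
    inside_diff <- c(inside_diff, mean(abs(ds$raw[i, inwin, 1:16])))
  }
  for (i in h) outside_h <- c(outside_h, mean(abs(ds$raw[i, , 1:16])))
  # outside the planted windows the two classes have the same expectation
  se <- sqrt(stats::var(outside_s) / length(outside_s) +
               stats::var(outside_h) / length(outside_h))
  expect_lt(abs(mean(outside_s) - mean(outside_h)), 3 * se)
  # inside the windows the attenuated class is strictly lower on average
  expect_lt(mean(inside_diff), 0.8 * mean(outside_h))
})

test_that("cognitive dataset has 21 x 5 x 10 structure with subject signatures", {
  cfg <- generator_config("cognitive", n_subjects = 4,
                          trials_per_subject_per_class = 3, seed = 9)
  ds <- generate_cognitive_dataset(cfg)
  expect_equal(dim(ds$values), c(4 * 5 * 3, 100, 116))
  expect_equal(unique(as.vector(table(ds$subject_id))), 5 * 3)
  expect_identical(ds$classes, paste0("M", 1:5))
  expect_identical(ds$values, generate_cognitive_dataset(cfg)$values)
  # M2 deviates from M1 only around its planted windows, in expectation
  m2 <- which(ds$labels == "M2")
  expect_true(all(vapply(ds$event_windows[m2], nrow, integer(1)) > 0))
})

test_that("effect and config validation reject malformed inputs", {
  expect_error(class_effect("2", "Z"), "target_event")
  expect_error(class_effect("2", "C", amplitude_scale = 0))
  expect_error(class_effect("2", "C", tremor_amplitude = 0.9),
               "tremor_amplitude")
  expect_error(generator_config("pd", n_channels = 18), "19")
  expect_error(generator_config("cognitive", n_channels = 19), "116")
  # effects must cover exactly the non-reference classes
  expect_error(generate_pd_dataset(small_pd_cfg(),
                                   effects = default_pd_effects()[1:2]),
               "cover")
})
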