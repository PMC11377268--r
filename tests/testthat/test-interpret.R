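test_that("spatial averaging is the per-frame channel mean and is linear", {
  expect_equal(spatial_average(matrix(3, 10, 5))$values, rep(3, 10))
  withr::with_seed(17, {
    x <- matrix(rnorm(60), 10, 6); y <- matrix(rnorm(60), 10, 6)
    sx <- spatial_average(x)$values
    # brute-force per-frame mean
    expect_equal(sx, vapply(1:10, function(i) mean(x[i, ]), numeric(1)))
    # linearity
    expect_equal(spatial_average(2 * x + 3 * y)$values,
                 2 * sx + 3 * spatial_average(y)$values)
  })
  expect_equal(spatial_average(matrix(1:4, 4, 1))$n_channels_averaged, 1)
  expect_error(spatial_average(matrix(numeric(0), 0, 0)), "empty")
})

test_that("cycle segmentation recovers known strike frames within 2 frames", {
  pm <- gait_phase_model(cadence_jitter_sd = 0)
  rate <- 100
  tt <- (0:599) / rate
  truth <- c(51, 151, 251, 351, 451, 551)   # strikes at t = 0.5, 1.5, ...
  phase <- ((tt - 0.5) %% 1)
  force <- grf_waveform(phase, pm)
  force[tt < 0.5] <- 0
  seg <- segment_cycles(force, rate)
  det <- seg$cycle_boundaries
  expect_gte(length(det), 5)
  for (f in det) expect_lte(min(abs(f - truth)), 2)
  expect_equal(nrow(seg$complete_cycles), length(det) - 1)
  # relative threshold: amplitude scaling leaves boundaries unchanged
  expect_identical(segment_cycles(force * 7, rate)$cycle_boundaries, det)
  expect_warning(seg0 <- segment_cycles(numeric(100), rate), "no cycles")
  expect_equal(nrow(seg0$complete_cycles), 0)
})

test_that("relevance peaks are labelled by their cycle phase", {
  pm <- gait_phase_model()
  # two identical cycles of 100 frames starting at frames 1 and 101
  seg <- structure(list(cycle_boundaries = c(1L, 101L, 201L),
                        complete_cycles = tibble::tibble(
                          start = c(1L, 101L), end = c(101L, 201L))),
                   class = "cycle_segmentation")
  rel <- numeric(201)
  rel[c(21, 121)] <- 1           # phase 0.20 -> event C in both cycles
  ea <- assign_relevance_events(rel, seg, pm, top_k = 2, smooth_width = 1)
  expect_equal(nrow(ea$peaks), 2)
  expect_setequal(ea$peaks$event, "C")
  expect_equal(sort(ea$peaks$phase), c(0.2, 0.2))
  expect_equal(window_event_vote(ea), "C")
  # uniform relevance has no local maxima: degenerate flag
  ea0 <- assign_relevance_events(rep(1, 201), seg, pm, smooth_width = 1)
  expect_true(ea0$degenerate)
  expect_equal(nrow(ea0$peaks), 0)
  expect_true(is.na(window_event_vote(ea0)))
  # no complete cycles -> empty assignment
  seg_empty <- structure(list(cycle_boundaries = integer(),
                              complete_cycles = tibble::tibble(
                                start = integer(), end = integer())),
                         class = "cycle_segmentation")
  expect_equal(nrow(assign_relevance_events(rel, seg_empty, pm)$peaks), 0)
})

test_that("event histograms normalize within class and expose modal events", {
  one <- tibble::tibble(class = "2", event = "C")
  h1 <- event_histogram(one)
  expect_equal(h1$freq, 1)
  many <- tibble::tibble(class = rep(c("2", "3"), c(4, 6)),
                         event = c("C", "C", "C", "B", rep("G", 5), "F"))
  h <- event_histogram(many)
  sums <- tapply(h$freq, h$class, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  m <- modal_events(h)
  expect_equal(m$event[m$class == "2"], "C")
  expect_equal(m$event[m$class == "3"], "G")
  expect_warning(event_histogram(tibble::tibble(class = character(),
                                                event = character())),
                 "no assignments")
})

test_that("contralateral boundaries rescue an irregular reference channel", {
  pm <- gait_phase_model(cadence_jitter_sd = 0)
  rate <- 100
  tt <- (0:599) / rate
  left <- grf_waveform((tt - 0.5) %% 1, pm); left[tt < 0.5] <- 0
  right <- grf_waveform(tt %% 1, pm)
  win <- cbind(left, right)
  # corrupt the left rises so left-foot detection degrades
  for (s in c(51, 151, 251, 351, 451, 551))
    left[s:(s + 10)] <- left[s:(s + 10)] * runif(11, 0, 0.3)
  win_bad <- cbind(left, right)
  seg <- reference_cycles(win_bad, rate, channel = 1, alt_channel = 2, pm)
  truth <- c(51, 151, 251, 351, 451, 551)
  det <- seg$cycle_boundaries
  expect_gte(length(det), 4)
  expect_lt(stats::median(vapply(det, function(f) min(abs(f - truth)),
                                 numeric(1))), 6)
})
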