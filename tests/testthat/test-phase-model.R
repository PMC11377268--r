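test_that("event intervals partition the cycle and stance ends at the stance fraction", {
  for (sf in c(0.55, 0.60, 0.65)) {
    pm <- gait_phase_model(stance_fraction = sf)
    b <- pm$event_boundaries
    expect_identical(b$event, LETTERS[1:7])
    expect_equal(b$lo[1], 0)
    expect_equal(b$hi[7], 1)
    expect_equal(b$lo[-1], b$hi[-7])          # disjoint, ordered, covering
    expect_equal(b$hi[5], sf)                 # stance events A-E end at sf
  }
})

test_that("phase_to_event is total, single-valued and matches the interval map", {
  pm <- gait_phase_model()
  expect_equal(phase_to_event(c(0, 0.2, 0.95), pm), c("A", "C", "G"))
  expect_error(phase_to_event(1, pm), "phase")
  expect_error(phase_to_event(-0.1, pm), "phase")
  # property: dense grid maps every phase to exactly one event
  ph <- seq(0, 0.9999, by = 1e-3)
  ev <- phase_to_event(ph, pm)
  expect_true(all(ev %in% LETTERS[1:7]))
  b <- pm$event_boundaries
  for (k in 1:7)
    expect_true(all(ph[ev == b$event[k]] >= b$lo[k] &
                      ph[ev == b$event[k]] < b$hi[k]))
})

test_that("GRF waveform is zero in swing, continuous at toe-off, with the two stance bumps", {
  pm <- gait_phase_model()
  expect_equal(grf_waveform(0.80, pm), 0)            # swing carries no force
  expect_equal(grf_waveform(pm$stance_fraction, pm), 0)  # continuity at toe-off
  expect_lt(grf_waveform(pm$stance_fraction - 1e-6, pm), 1e-4)
  expect_lt(grf_waveform(1e-6, pm), 1e-4)            # continuity at heel strike
  # dense grid search: the two local maxima sit near 25% and 75% of stance
  ph <- seq(0, pm$stance_fraction - 1e-4, by = 1e-4)
  f <- grf_waveform(ph, pm)
  n <- length(f)
  loc <- which(f[2:(n - 1)] > f[1:(n - 2)] & f[2:(n - 1)] >= f[3:n]) + 1
  maxima <- sort(ph[loc])
  expect_length(maxima, 2)
  expect_equal(maxima[1], 0.25 * pm$stance_fraction, tolerance = 0.15)
  expect_equal(maxima[2], 0.75 * pm$stance_fraction, tolerance = 0.05)
  expect_true(all(f >= 0))
  expect_error(grf_waveform(1.2, pm), "phase")
})

test_that("phase model rejects inconsistent configurations", {
  expect_error(gait_phase_model(stance_fraction = 0), "stance_fraction")
  expect_error(gait_phase_model(cycle_duration = -1))
})
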