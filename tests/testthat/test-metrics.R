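test_that("spike detection finds clean spikes and ignores artifacts", {
  fx <- make_fixtures("two_spike_trace")
  st <- detect_spikes(fx$time, fx$vm)
  expect_length(st$times_ms, fx$truth$n_spikes)
  expect_equal(st$times_ms, fx$truth$spike_times, tolerance = 0.05)
  # sub-threshold stimulus artifacts are not counted
  fa <- make_fixtures("artifact_trace")
  expect_length(detect_spikes(fa$time, fa$vm)$times_ms, 0)
  # a flat resting trace yields an empty train
  expect_length(detect_spikes(c(0, 1, 2), rep(-66, 3))$times_ms, 0)
})

test_that("detection is insensitive to threshold over overshooting spikes", {
  ts <- short_run()
  counts <- vapply(c(-20, -10, 0), function(thr)
    length(detect_spikes(ts$time, ts$vm$node_1, threshold_mV = thr)$times_ms),
    numeric(1))
  expect_equal(length(unique(counts)), 1)
})

test_that("the refractory window merges double crossings", {
  t <- seq(0, 5, by = 0.01)
  vm <- -66 + 100 * (exp(-((t - 2) / 0.1)^2) + exp(-((t - 2.3) / 0.1)^2))
  expect_length(detect_spikes(t, vm, refractory_ms = 1)$times_ms, 1)
  expect_length(detect_spikes(t, vm, refractory_ms = 0.1)$times_ms, 2)
})

test_that("effectiveness requires conduction to both ends", {
  pulses <- c(10, 20, 30)
  s1 <- structure(list(times_ms = c(11, 21)), class = "spike_train")
  s21 <- structure(list(times_ms = c(11.01, 31)), class = "spike_train")
  eff <- effective_aps(s1, s21, pulses)
  expect_equal(eff, c(TRUE, FALSE, FALSE))
  # no spikes at all: nothing effective
  none <- structure(list(times_ms = numeric(0)), class = "spike_train")
  expect_equal(effective_aps(none, none, pulses), rep(FALSE, 3))
  # a spike is assigned to at most one pulse
  s_dbl <- structure(list(times_ms = 10.4), class = "spike_train")
  expect_equal(effective_aps(s_dbl, s_dbl, c(10, 10.5)),
               c(TRUE, FALSE))
})

test_that("induction ratio follows the reciprocal-gap definition", {
  # an AP on pulse k and the next after three further pulses -> 33%
  eff <- rep(FALSE, 10); eff[c(2, 5)] <- TRUE
  ir <- induction_ratio(eff)
  expect_equal(ir$value, 100 / 3, tolerance = 1e-12)
  # every pulse effective -> constant 100%
  ir100 <- induction_ratio(rep(TRUE, 8))
  expect_true(all(ir100$value == 100))
  # period-4 firing -> steady 25%
  fx <- make_fixtures("periodic_flags", n_pulses = 40, period = 4)
  ir25 <- induction_ratio(fx$flags, fx$pulse_times_ms)
  expect_true(all(ir25$value == fx$truth$induction_ratio))
  # values always in (0, 100]
  expect_true(all(ir25$value > 0 & ir25$value <= 100))
})

test_that("synchronization ratio counts axons per pulse and smooths by 10", {
  fx <- make_fixtures("checkerboard_flags", n_pulses = 40, n_axons = 11)
  sr <- synchronization_ratio(fx$flags, fx$pulse_times_ms)
  expect_equal(sr$value, fx$truth$raw)
  # smoothed series settles at 50% for the alternating pattern
  expect_equal(sr$smoothed[10:40], rep(fx$truth$smoothed, 31))
  # per-pulse values take only the n+1 rational values k/n * 100
  allowed <- 100 * (0:11) / 11
  expect_true(all(sr$value %in% allowed))
  expect_true(all(sr$smoothed >= 0 & sr$smoothed <= 100, na.rm = TRUE))
  # all axons effective on a pulse -> 100%; none -> 0%
  full <- synchronization_ratio(matrix(TRUE, 1, 11))
  expect_equal(full$value, 100)
  # mismatched pulse grids are an error
  expect_error(synchronization_ratio(list(c(TRUE, FALSE), TRUE)),
               "pulse grid")
  expect_error(synchronization_ratio(fx$flags, 1:5), "mismatch")
})

test_that("steady-state summaries average inside the window only", {
  s <- induction_ratio(rep(c(TRUE, FALSE, FALSE, FALSE), 25),
                       pulse_times_ms = seq(0, by = 30, length.out = 100))
  expect_equal(steady_state_value(s, c(1500, Inf)), 25)
  expect_error(steady_state_value(s, c(5000, 6000)), "outside")
  expect_error(steady_state_value(s, c(100, 50)), "increasing")
})
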