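# Fixture generators and their embedded ground truth.

test_that("blood traces are seeded, mean-reverting and match the stationary sd", {
  spec <- blood_trace_spec(duration = 5e4, dt = 0.5, seed = 11L)
  tr1 <- ou_blood_trace(spec)
  tr2 <- ou_blood_trace(spec)
  expect_identical(tr1, tr2)
  # long-run sample sd within 5% of the specified stationary sd
  expect_equal(sd(tr1$GLC), spec$sd[["GLC"]], tolerance = 0.05)
  expect_equal(mean(tr1$GLC), spec$mean[["GLC"]], tolerance = 0.02)
  # zero-noise trace is constant at the mean
  s0 <- blood_trace_spec(sd = c(GLC = 0, LAC = 0, bHB = 0), duration = 100)
  tr0 <- ou_blood_trace(s0)
  expect_true(all(tr0$GLC == s0$mean[["GLC"]]))
  expect_error(blood_trace_spec(sd = c(GLC = 3, LAC = 0.1, bHB = 0.01)),
               "sd must be")
})

test_that("voltage fixtures embed recoverable spike ground truth", {
  fx <- fixture_voltage(10, c(1, 2), n_after = 3, dt = 1e-4)
  st <- detect_spikes(fx$trace, stim_window = c(1, 2))
  expect_length(st$times, 10)
  expect_equal(st$afterdischarge_count, 3)
  expect_lt(max(abs(sort(st$times) - sort(fx$spike_times))), 2e-3)
  # degenerate cases
  flat <- fixture_voltage(0, c(1, 2), 0)
  expect_length(detect_spikes(flat$trace)$times, 0)
  one <- fixture_voltage(1, c(1, 2), n_after = 1)
  expect_equal(detect_spikes(one$trace, stim_window = c(1, 2))$afterdischarge_count, 1)
  expect_error(fixture_voltage(3, c(1, 1.004), 0), "overlapping")
  expect_error(fixture_voltage(2, c(1, 2), 3), "n_after")
})

test_that("sinusoidal fixtures have the analytic coefficient of variation", {
  fx <- fixture_timeseries(mean = 2, rel_amp = 0.2, period = 10,
                           duration = 100, dt = 0.001)
  cv <- compute_cv(data.frame(t = fx$t, x = fx$x))
  expect_equal(cv$cv, 0.2 / sqrt(2), tolerance = 0.01)
  # amplitude zero: constant series
  fx0 <- fixture_timeseries(rel_amp = 0)
  expect_equal(compute_cv(fx0$x)$cv, 0)
  # scale invariance of the CV
  fx2 <- fixture_timeseries(mean = 20, rel_amp = 0.2, period = 10,
                            duration = 100, dt = 0.001)
  expect_equal(compute_cv(fx2$x)$cv, cv$cv, tolerance = 1e-10)
})
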