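test_that("expected peak speed follows the saturating amplitude relation", {
  ms <- main_sequence_params(600, 0.15, "saccade")
  # frozen arithmetic: 600 * (1 - 1/1.75)
  expect_equal(expected_peak_speed(ms, 5), 600 * 3 / 7, tolerance = 1e-12)
  # vanishes at zero amplitude, saturates at a_ms
  expect_lt(expected_peak_speed(ms, 1e-9), 1e-3)
  expect_equal(expected_peak_speed(ms, 1e7), 600, tolerance = 1e-4)
  # strictly increasing and concave on a grid
  v <- expected_peak_speed(ms, seq(0.5, 30, by = 0.5))
  expect_true(all(diff(v) > 0))
  expect_true(all(diff(diff(v)) < 0))
  expect_error(expected_peak_speed(ms, -1), "amplitude")
})

test_that("noiseless fits recover the generating constants exactly", {
  ms <- main_sequence_params(600, 0.15, "saccade")
  set.seed(11)
  amp <- runif(500, 1, 15)
  fit <- fit_main_sequence(amp, expected_peak_speed(ms, amp), "saccade")
  expect_lt(abs(fit$a_ms - 600) / 600, 1e-3)
  expect_lt(abs(fit$b_ms - 0.15) / 0.15, 1e-3)
})

test_that("fits recover constants under 10% multiplicative noise", {
  ms <- main_sequence_params(600, 0.15, "saccade")
  set.seed(77)
  amp <- runif(5000, 1, 15)
  speed <- expected_peak_speed(ms, amp) * exp(rnorm(5000, 0, 0.10))
  fit <- fit_main_sequence(amp, speed, "saccade")
  expect_lt(abs(fit$a_ms - 600) / 600, 0.05)
  expect_lt(abs(fit$b_ms - 0.15) / 0.15, 0.05)
  vig <- compute_vigor(speed, amp, fit)
  expect_lt(abs(mean(vig) - 1), 0.02)
})

test_that("degenerate inputs are rejected", {
  ms <- main_sequence_params(600, 0.15, "saccade")
  amp <- rep(5, 100)
  expect_error(fit_main_sequence(amp, expected_peak_speed(ms, amp), "saccade"),
               "degenerate|unidentifiable")
  expect_error(fit_main_sequence(runif(10, 1, 5), runif(10, 10, 20), "saccade"),
               "at least 50")
})

test_that("vigor is the speed ratio and is scale-free", {
  ms <- main_sequence_params(600, 0.15, "saccade")
  amp <- c(2, 5, 11)
  on_curve <- expected_peak_speed(ms, amp)
  expect_equal(compute_vigor(on_curve, amp, ms), rep(1, 3))
  # a movement 10% faster than expected has vigor 1.10
  expect_equal(compute_vigor(on_curve * 1.1, amp, ms), rep(1.1, 3))
  # rescaling speeds and the asymptote together changes nothing
  ms_scaled <- main_sequence_params(600 * 3.7, 0.15, "saccade")
  expect_equal(compute_vigor(on_curve * 3.7 * 1.05, amp, ms_scaled),
               compute_vigor(on_curve * 1.05, amp, ms))
})

test_that("robust fitting tolerates heavy-tailed outliers", {
  ms <- main_sequence_params(200, 0.12, "lick_protraction")
  set.seed(5)
  amp <- runif(800, 3, 14)
  speed <- expected_peak_speed(ms, amp) * exp(rnorm(800, 0, 0.08))
  speed[1:20] <- speed[1:20] * 4  # gross outliers
  fit_r <- fit_main_sequence(amp, speed, "lick_protraction", robust = TRUE)
  fit_p <- fit_main_sequence(amp, speed, "lick_protraction", robust = FALSE)
  err_r <- abs(fit_r$a_ms - 200) / 200
  err_p <- abs(fit_p$a_ms - 200) / 200
  expect_lt(err_r, err_p)
  expect_lt(err_r, 0.05)
})
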