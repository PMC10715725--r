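test_that("detector finds injected saccades with accurate onsets", {
  onsets <- seq(0.3, 4.8, by = 0.5)
  set.seed(3)
  amps <- runif(10, 4, 10)
  tr <- make_gaze_trace(onsets, amps)
  det <- detect_saccades(tr$time_s, tr$x_deg, tr$y_deg)
  expect_equal(nrow(det), 10)
  expect_true(all(abs(det$onset_s - tr$true_onsets) <= 0.002))
  # amplitudes recovered to within the smoothing error
  expect_equal(det$amplitude_deg, amps, tolerance = 0.05)
})

test_that("a flat trace yields no events and garbage is rejected", {
  t <- seq(0, 2, by = 1e-3)
  det <- detect_saccades(t, rep(1.5, length(t)), rep(-0.5, length(t)))
  expect_equal(nrow(det), 0)
  x <- rep(0, length(t)); x[seq(1, length(t), by = 3)] <- NA
  expect_error(detect_saccades(t, x, x), "missing")
})

test_that("saccades closer than the merge gap fuse into one event", {
  tr <- make_gaze_trace(c(0.3, 0.35), c(6, 6))  # 10 ms apart after offsets
  det <- detect_saccades(tr$time_s, tr$x_deg, tr$y_deg, merge_gap_s = 0.02)
  expect_equal(nrow(det), 1)
  expect_equal(det$amplitude_deg, 12, tolerance = 0.1)
  # with no merging they are two
  det2 <- detect_saccades(tr$time_s, tr$x_deg, tr$y_deg, merge_gap_s = 0.001)
  expect_equal(nrow(det2), 2)
})

test_that("saccade classification applies the criterion radius", {
  targets <- tibble::tibble(type = c("center", "primary"),
                            x_deg = c(0, 5), y_deg = c(0, 0))
  hit <- classify_saccade(5, 1.0, targets)   # 1.0 deg from the primary
  expect_equal(hit$subtype, "primary")
  expect_true(hit$success)
  expect_equal(c(hit$err_x_deg, hit$err_y_deg), c(0, 1))
  miss <- classify_saccade(5, 1.3, targets)  # 1.3 deg: outside 1.25
  expect_false(miss$success)
  # the Methods' wider 1.5-deg criterion is configurable
  expect_true(classify_saccade(5, 1.3, targets,
                               criterion_radius_deg = 1.5)$success)
  far <- classify_saccade(20, 20, targets)
  expect_equal(far$subtype, "task_irrelevant")
  expect_warning(classify_saccade(5, 0, targets[0, ]), "task_irrelevant")
})

test_that("lick classification is geometric about the tube aperture", {
  mj <- function(apex, n = 60) {
    tau <- seq(0, 1, length.out = n)
    prof <- 3 * tau^2 - 2 * tau^3
    prof <- c(prof, rev(prof)[-1])
    list(t = seq(0, by = 0.002, length.out = 2 * n - 1),
         x = apex[1] * prof, y = apex[2] * prof)
  }
  tube <- c(10, 0)  # 10 mm straight ahead, 4.4 mm aperture
  deep <- mj(c(11.5, 0))
  got <- classify_lick(deep$t, deep$x, deep$y, tube)
  expect_equal(got$subtype, "inner_tube")
  expect_true(got$success)       # penetrates past the food depth
  shallow <- mj(c(10.3, 0.5))
  got <- classify_lick(shallow$t, shallow$x, shallow$y, tube)
  expect_equal(got$subtype, "inner_tube")
  expect_false(got$success)      # in the aperture but short of the food
  under <- mj(c(9.5, -3.4))
  got <- classify_lick(under$t, under$x, under$y, tube)
  expect_equal(got$subtype, "under_tube")
  expect_false(got$success)
  groom <- mj(c(3, -7))          # directed well away from the tube
  expect_equal(classify_lick(groom$t, groom$x, groom$y, tube)$subtype,
               "grooming")
  tiny <- mj(c(0.8, 0.2))        # never leaves the mouth region
  expect_equal(nrow(classify_lick(tiny$t, tiny$x, tiny$y, tube)), 0)
})

test_that("protraction and retraction peak speeds straddle the apex", {
  t <- seq(0, 0.2, by = 0.002)
  x <- ifelse(t <= 0.05, 12 * t / 0.05, 12 * (1 - (t - 0.05) / 0.15))
  got <- classify_lick(t, x, rep(0, length(t)), c(10, 0))
  expect_gt(got$peak_speed_pro_mmps, got$peak_speed_ret_mmps)
})
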