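test_that("binned relation preserves an exact identity line", {
  set.seed(31)
  x <- runif(2000, 0.6, 1.4)
  b <- binned_relation(x, x, bin_size = 0.05)
  expect_equal(b$mean_y, b$bin_center, tolerance = 0.025)  # within half a bin
  expect_true(all(b$n >= 10))
  empty <- binned_relation(numeric(0), numeric(0))
  expect_equal(nrow(empty), 0)
})

test_that("binned correlation separates coupled from uncoupled data", {
  set.seed(32)
  x <- runif(5000, 0.6, 1.4)
  coupled <- binned_correlation(x, 2 * (x - 1) + rnorm(5000, 0, 0.3))
  expect_gt(coupled$r, 0.9)
  uncoupled <- binned_correlation(x, rnorm(5000, 0, 0.3))
  expect_lt(abs(uncoupled$r), 0.2)
})

test_that("endpoint-error stats recover an isotropic error scale", {
  set.seed(33)
  n <- 20000
  sigma <- 0.4
  vig <- runif(n, 0.8, 1.2)
  st <- endpoint_error_stats(vig, rnorm(n, 0, sigma), rnorm(n, 0, sigma),
                             bin_size = 0.1)
  # det of an isotropic 2x2 covariance is sigma^4
  expect_equal(st$det_cov, rep(sigma^4, nrow(st)), tolerance = 0.1)
  # mean |error| of an isotropic Gaussian is sigma * sqrt(pi/2)
  expect_equal(st$mean_abs_error, rep(sigma * sqrt(pi / 2), nrow(st)),
               tolerance = 0.03)
  # identical errors give a singular covariance
  st0 <- endpoint_error_stats(rep(1, 50), rep(0.3, 50), rep(-0.1, 50),
                              bin_size = 0.05, min_n = 10)
  expect_equal(st0$det_cov, 0)
})

test_that("accuracy built to improve with vigor is recovered", {
  set.seed(34)
  n <- 20000
  vig <- runif(n, 0.8, 1.2)
  sdv <- 0.5 * (1 - 1 * (vig - 1))  # error shrinks as vigor grows
  st <- endpoint_error_stats(vig, rnorm(n, 0, sdv), rnorm(n, 0, sdv),
                             bin_size = 0.1)
  expect_true(all(diff(st$mean_abs_error) < 0))
  expect_true(all(diff(st$det_cov) < 0))
})

test_that("conditional vigor change isolates the reinforcement effect", {
  set.seed(35)
  delta <- 0.05
  bouts <- lapply(1:400, function(b) {
    n <- 12
    succ <- runif(n) < 0.3
    vig <- 1 + delta * c(0, cumsum(succ))[seq_len(n)] + rnorm(n, 0, 0.04)
    tibble::tibble(bout_id = sprintf("B%03d", b), vigor = vig, success = succ)
  })
  licks <- dplyr::bind_rows(bouts)
  vc <- conditional_vigor_change(licks)
  ps <- vc[vc$condition == "post_success", ]
  pf <- vc[vc$condition == "post_failure", ]
  expect_lt(abs(ps$mean_delta - delta), 2 * ps$sem)
  expect_lt(abs(pf$mean_delta), 2 * pf$sem)
  # shuffling the outcome labels erases the contrast
  set.seed(36)
  licks$success <- sample(licks$success)
  vc0 <- conditional_vigor_change(licks)
  d0 <- diff(vc0$mean_delta[match(c("post_failure", "post_success"),
                                  vc0$condition)])
  expect_lt(abs(d0), 2 * sqrt(sum(vc0$sem^2)))
  # degenerate inputs
  const <- tibble::tibble(bout_id = "B1", vigor = rep(1, 6),
                          success = rep(c(TRUE, FALSE), 3))
  vc1 <- conditional_vigor_change(const)
  expect_true(all(vc1$mean_delta == 0))
  expect_equal(nrow(conditional_vigor_change(const[1, ])), 0)
})

test_that("period summaries aggregate by grouping keys", {
  per <- tibble::tibble(
    period_id = c("W001", "H001", "W002", "H002"),
    kind = c("work", "harvest", "work", "harvest"),
    start_s = c(0, 10, 20, 30), end_s = c(9, 19, 29, 39),
    n_attempted = c(8L, 0L, 10L, 0L), n_success = c(4L, 0L, 6L, 0L),
    n_licks = c(0L, 15L, 0L, 18L), partial = FALSE,
    tube_distance = 7)
  licks <- tibble::tibble(period_id = rep(c("H001", "H002"), each = 15),
                          vigor = rep(c(1.0, 1.1), each = 15))
  sm <- period_summaries(per, licks, "tube_distance")
  work <- sm[sm$kind == "work", ]
  expect_equal(work$mean_attempted, 9)
  expect_equal(work$mean_success, 5)
  # food cached is exactly increment x successes
  expect_equal(work$mean_food_cached, 0.015 * 5)
  harv <- sm[sm$kind == "harvest", ]
  expect_equal(harv$mean_licks, 16.5)
  # keyed by trials succeeded in the preceding work period
  sm2 <- period_summaries(per, licks, "prior_work_trials")
  harv2 <- sm2[sm2$kind == "harvest", ]
  expect_equal(harv2$group, c(4L, 6L))
  expect_equal(harv2$mean_lick_vigor, c(1.0, 1.1))
  expect_error(period_summaries(per[, setdiff(names(per), "tube_distance")],
                                licks, "tube_distance"), "tube_distance")
})
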