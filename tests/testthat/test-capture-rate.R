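test_that("capture rate matches independent hand computation", {
  p <- base_params()
  # frozen: (20*0.5*4*(1 - 1/3.4) - 8*0.5 - 16*0.5) / (8*0.2 + 4*1)
  expect_equal(capture_rate(p, 4, 8), 2.89915966386555, tolerance = 1e-12)
  # no licks: no reward, only work cost over work time
  expect_equal(capture_rate(p, 4, 0), -2)
  # worthless reward cannot yield a positive rate
  p0 <- base_params(); p0$alpha <- 0
  for (ns in c(1, 3, 7)) for (nl in c(0, 5, 40)) {
    expect_lte(capture_rate(p0, ns, nl), 0)
  }
})

test_that("capture rate agrees with an independently coded evaluator", {
  # second implementation, written term by term from the model definition
  eval2 <- function(alpha, beta_s, beta_l, c_s, T_s, T_l, c_l, ns, nl) {
    harvested_fraction <- beta_l * nl / (1 + beta_l * nl)
    reward <- alpha * beta_s * ns * harvested_fraction
    effort <- c_l * nl + c_s * ns * ns
    time <- T_l * nl + T_s * ns
    (reward - effort) / time
  }
  set.seed(424242)
  for (i in 1:1000) {
    alpha <- runif(1, 0, 40); beta_s <- runif(1, .05, 1)
    beta_l <- runif(1, .05, 1); c_s <- runif(1, 0, 2)
    T_s <- runif(1, .2, 3); T_l <- runif(1, .05, 1); c_l <- runif(1, 0, 3)
    ns <- runif(1, 1, 15); nl <- runif(1, 0, 60)
    p <- policy_params(alpha, beta_s, beta_l, c_s, T_s, T_l, c_l)
    expect_equal(capture_rate(p, ns, nl),
                 eval2(alpha, beta_s, beta_l, c_s, T_s, T_l, c_l, ns, nl),
                 tolerance = 1e-12)
  }
})

test_that("capture rate rejects invalid policies", {
  p <- base_params()
  expect_error(capture_rate(p, 0.5, 8), "n_s")
  expect_error(capture_rate(p, 4, -1), "n_l")
  pd <- distance_params()
  expect_error(capture_rate(pd, 4, 8), "per-lick cost")
})

test_that("lick effort cost and its minimizer are exact", {
  expect_equal(lick_effort_cost(d = 0.2, T_l = 0.2, k = 1), 0.4)
  # zero distance leaves the pure time cost
  expect_equal(lick_effort_cost(0, T_l = c(.1, .5, 2), k = 1), c(.1, .5, 2))
  expect_error(lick_effort_cost(0.2, T_l = 0, k = 1), "T_l")
  # analytic argmin d/sqrt(k), checked against numeric minimization,
  # and linear in d at fixed k
  ds <- seq(0.1, 0.3, by = 0.05)
  mins <- vapply(ds, function(d) {
    optimize(function(T) lick_effort_cost(d, T, 1), c(1e-4, 5))$minimum
  }, numeric(1))
  expect_equal(mins, lick_cost_minimizer(ds, 1), tolerance = 1e-4)
  expect_equal(diff(lick_cost_minimizer(ds, 1)), rep(0.05, 4))
  expect_equal(lick_cost_minimizer(0.2, 4), 0.1)
})

test_that("closed-form stationary n_s solves the first-order condition", {
  p <- base_params()
  for (nl in c(2, 8, 20)) {
    ns0 <- stationary_ns(p, nl)
    h <- 1e-5
    dJ <- (capture_rate(p, ns0 + h, nl) - capture_rate(p, ns0 - h, nl)) / (2 * h)
    expect_lt(abs(dJ), 1e-6)
  }
  expect_true(is.na(stationary_ns(p, 0)))
})
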