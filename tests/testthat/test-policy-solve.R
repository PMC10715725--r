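test_that("integer-grid search finds the low-cost and high-cost optima", {
  sol <- optimal_policy_fixed_cost(base_params(0.5))
  expect_equal(sol$n_s, 4)
  expect_equal(sol$n_l, 8)   # frozen from exhaustive grid ns 1..15, nl 0..60
  expect_true(sol$feasible)
  expect_equal(sol$J, capture_rate(base_params(0.5), sol$n_s, sol$n_l))
  # higher lick cost: work longer before harvesting
  sol2 <- optimal_policy_fixed_cost(base_params(2))
  expect_equal(sol2$n_s, 5)
  # the Methods' alternative high-effort value gives the same response
  expect_equal(optimal_policy_fixed_cost(base_params(2.5))$n_s, 5)
  # higher cost of licking reduces the peak capture rate
  expect_lt(sol2$J, sol$J)
})

test_that("worthless reward makes every policy infeasible", {
  p <- base_params(); p$alpha <- 0
  expect_false(optimal_policy_fixed_cost(p)$feasible)
  expect_false(optimal_policy_fixed_cost(p, "continuous")$feasible)
})

test_that("a boundary optimum raises a warning", {
  expect_warning(optimal_policy_fixed_cost(base_params(0.5), ns_max = 3),
                 "boundary")
})

test_that("continuous solver agrees with a fine grid oracle", {
  set.seed(1331)
  n_ok <- 0
  while (n_ok < 50) {
    p <- policy_params(alpha = runif(1, 10, 30), beta_s = runif(1, .3, .8),
                       beta_l = runif(1, .15, .5), c_s = runif(1, .2, 1),
                       T_s = runif(1, .5, 1.5), T_l = runif(1, .1, .4),
                       c_l = runif(1, .2, 2))
    sol <- suppressWarnings(optimal_policy_fixed_cost(p, "continuous"))
    if (!sol$feasible) next
    ns <- seq(1, 15, by = 0.05)
    nl <- seq(0, 60, by = 0.05)
    Jg <- outer(ns, nl, function(a, b) capture_rate(p, a, b))
    i <- which(Jg == max(Jg), arr.ind = TRUE)[1, ]
    if (i[1] >= length(ns) - 1 || i[2] >= length(nl) - 1) next  # boundary case
    n_ok <- n_ok + 1
    # refine the grid oracle around its own argmax
    ns2 <- seq(max(1, ns[i[1]] - 0.06), ns[i[1]] + 0.06, by = 0.002)
    nl2 <- seq(max(0, nl[i[2]] - 0.06), nl[i[2]] + 0.06, by = 0.002)
    Jg2 <- outer(ns2, nl2, function(a, b) capture_rate(p, a, b))
    i2 <- which(Jg2 == max(Jg2), arr.ind = TRUE)[1, ]
    expect_lt(abs(sol$J - max(Jg2)) / abs(max(Jg2)), 1e-3)
    expect_lt(abs(sol$n_s - ns2[i2[1]]), 0.05)
    expect_lt(abs(sol$n_l - nl2[i2[2]]), 0.05)
  }
  expect_equal(n_ok, 50)
})

test_that("distance-parameterized optimum: integer and continuous agree", {
  pd <- distance_params(0.2)
  si <- optimal_policy_with_distance(pd)
  sc <- optimal_policy_with_distance(pd, "continuous")
  expect_true(si$feasible && sc$feasible)
  expect_lt(abs(si$J - sc$J) / sc$J, 5e-3)  # integer rounding only
  expect_gte(sc$J, si$J - 1e-9)             # relaxation can only do better
  # the achieved J re-evaluates exactly at the reported policy
  expect_equal(si$J,
               capture_rate(pd, si$n_s, si$n_l, T_l = si$T_l,
                            c_l = lick_effort_cost(0.2, si$T_l, 1)),
               tolerance = 1e-9)
})

test_that("comparative statics over tube distance", {
  dgrid <- c(0.10, 0.15, 0.20, 0.25, 0.30)
  for (mode in c("integer", "continuous")) {
    sw <- sweep_policy(distance_params(), "d", dgrid, mode = mode)
    expect_true(all(sw$feasible))
    expect_true(all(diff(sw$n_s) >= -1e-6))        # work longer
    expect_true(all(diff(sw$n_l) <= 1e-6))         # harvest shorter
    expect_true(all(diff(sw$T_l) > 0))             # lick slower
    expect_true(all(diff(diff(sw$T_l)) > 0))       # faster than linearly
    # more vigorous than the energetic optimum
    expect_true(all(sw$T_l < lick_cost_minimizer(dgrid, 1)))
  }
})

test_that("hunger (higher reward value) promotes work and lick vigor", {
  dgrid <- c(0.10, 0.15, 0.20, 0.25, 0.30)
  sated <- sweep_policy(distance_params(alpha = 20), "d", dgrid,
                        mode = "continuous")
  hungry <- sweep_policy(distance_params(alpha = 25), "d", dgrid,
                         mode = "continuous")
  expect_true(all(hungry$n_s > sated$n_s))
  expect_true(all(hungry$T_l < sated$T_l))
})

test_that("sweeps are consistent and flag infeasible points", {
  sw1 <- sweep_policy(distance_params(), "d", 0.2)
  sol <- optimal_policy_with_distance(distance_params(0.2))
  expect_equal(sw1$n_s, sol$n_s)
  expect_equal(sw1$T_l, sol$T_l, tolerance = 1e-9)
  # a lick cost too high for any positive-rate policy is flagged, not dropped
  sw2 <- sweep_policy(base_params(), "c_l", c(0.5, 50))
  expect_equal(nrow(sw2), 2)
  expect_true(sw2$feasible[1])
  expect_false(sw2$feasible[2])
  expect_named(sw2, c("vary", "value", "n_s", "n_l", "T_l", "J",
                      "feasible", "method"))
})

test_that("multiplicative utility: optimal duration is reward-invariant", {
  u <- function(T) 0.2^2 / T + T
  Ts <- vapply(c(1, 5, 25), function(a) {
    multiplicative_optimal_duration(u, alpha = a)$T_star
  }, numeric(1))
  expect_lt(max(Ts) - min(Ts), 1e-6)
  # frozen: root of 2 T^3 + T^2 = d^2 (first-order condition), d = 0.2
  expect_equal(Ts[1], 0.172461, tolerance = 1e-3)
  # utility itself scales linearly in reward
  j1 <- multiplicative_optimal_duration(u, alpha = 3)$J_star
  j2 <- multiplicative_optimal_duration(u, alpha = 6)$J_star
  expect_equal(j2, 2 * j1, tolerance = 1e-9)
  expect_error(
    suppressWarnings(multiplicative_optimal_duration(function(T) log(T - 5))),
    "finite")
})
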