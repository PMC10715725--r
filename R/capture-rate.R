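#' Capture rate of a work/harvest policy
#'
#' The net rate of utility: reward acquired minus effort expended, divided by
#' time. During work, `n_s` trials each succeed with probability `beta_s`
#' and accumulate food of value `alpha`; the food cache is then consumed
#' hyperbolically by `n_l` licks (a fraction `1 - 1/(1 + beta_l * n_l)` of
#' the cache is harvested); licking costs `c_l` per lick and working costs
#' `c_s * n_s^2`, the supra-linear growth encoding that long work periods
#' deplete utility faster than they consume time.
#'
#' \deqn{J(n_s, n_l) = \frac{\alpha \beta_s n_s \left(1 - \frac{1}{1 +
#'   \beta_l n_l}\right) - n_l c_l - n_s^2 c_s}{n_l T_l + n_s T_s}}
#'
#' Non-integer `n_s`, `n_l` are accepted (continuous relaxation). When
#' `T_l` or `c_l` are given they override the values in `params`, which is
#' how the distance-parameterized problem scores candidate lick durations.
#'
#' @param params A [policy_params()] object with a fixed `c_l` (or `c_l`
#'   supplied via the override argument).
#' @param n_s Number of work trials, >= 1 (vectorized).
#' @param n_l Number of licks, >= 0 (vectorized).
#' @param T_l,c_l Optional overrides of the lick duration and per-lick cost.
#' @return Capture rate (utility per unit time), vectorized over
#'   `n_s`/`n_l`.
#' @examples
#' p <- policy_params(20, 0.5, 0.3, c_s = 0.5, T_s = 1, T_l = 0.2, c_l = 0.5)
#' capture_rate(p, 4, 8)        # ~2.899
#' capture_rate(p, 4, 0)        # negative: worked, not yet harvested
#' @export
capture_rate <- function(params, n_s, n_l, T_l = NULL, c_l = NULL) {
  stopifnot(inherits(params, "policy_params"))
  T_l <- if (is.null(T_l)) params$T_l else T_l
  c_l <- if (is.null(c_l)) params$c_l else c_l
  if (is.null(c_l)) {
    stop("no per-lick cost: supply `c_l` or use the distance-parameterized solver",
         call. = FALSE)
  }
  if (any(n_s < 1)) stop("n_s must be >= 1", call. = FALSE)
  if (any(n_l < 0)) stop("n_l must be >= 0", call. = FALSE)
  if (any(T_l <= 0)) stop("T_l must be > 0", call. = FALSE)
  denom <- n_l * T_l + n_s * params$T_s
  if (any(denom <= 0)) stop("nonpositive time denominator", call. = FALSE)
  gain <- params$alpha * params$beta_s * n_s *
    (1 - 1 / (1 + params$beta_l * n_l))
  (gain - n_l * c_l - n_s^2 * params$c_s) / denom
}

#' Energetic cost of a single lick as a function of its duration
#'
#' A concave-upward duration cost, `d^2 / T_l + k * T_l`: fast licks to a
#' distant tube are expensive (first term), and so are very slow ones
#' (second term). The duration minimizing the cost is `d / sqrt(k)`, which
#' grows linearly with tube distance at fixed `k`.
#'
#' @param d Tube distance (distance units), >= 0.
#' @param T_l Lick duration (time units), > 0 (vectorized).
#' @param k Cost growth rate with duration, >= 0.
#' @return Effort cost of one lick (utility units).
#' @seealso [lick_cost_minimizer()]
#' @examples
#' lick_effort_cost(d = 0.2, T_l = 0.2, k = 1)  # 0.4
#' @export
lick_effort_cost <- function(d, T_l, k) {
  stopifnot(is.numeric(d), d >= 0, is.numeric(k), k >= 0)
  if (any(T_l <= 0)) stop("T_l must be > 0", call. = FALSE)
  d^2 / T_l + k * T_l
}

#' Duration minimizing the energetic cost of a lick
#'
#' Closed form `d / sqrt(k)`: setting the derivative of
#' `d^2/T + k*T` to zero gives `T = d/sqrt(k)`. Linear in `d` at fixed `k`.
#'
#' @inheritParams lick_effort_cost
#' @return The cost-minimizing lick duration.
#' @export
lick_cost_minimizer <- function(d, k) {
  stopifnot(d >= 0, k > 0)
  d / sqrt(k)
}

#' Closed-form stationary work-period length at a fixed harvest policy
#'
#' Setting the derivative of the capture rate with respect to `n_s` to zero
#' and solving yields a quadratic in `n_s`; the positive root is
#' \deqn{n_s = \frac{-c_s T_l n_l + \sqrt{c_s^2 T_l^2 n_l^2 +
#'   c_s T_s n_l (\alpha \beta_s f(n_l) T_l + c_l T_s)}}{c_s T_s}}
#' with `f(n_l) = 1 - 1/(1 + beta_l n_l)`. The `c_l T_s` term under the
#' radical is where the work period's square-root growth with the cost of
#' licking originates: at a fixed harvest policy, `n_s` grows as
#' `sqrt(c_l)` once `c_l` dominates the other terms.
#'
#' @inheritParams capture_rate
#' @return Stationary `n_s` (continuous), or `NA` if `n_l = 0` makes the
#'   expression degenerate.
#' @export
stationary_ns <- function(params, n_l, T_l = NULL, c_l = NULL) {
  stopifnot(inherits(params, "policy_params"))
  T_l <- if (is.null(T_l)) params$T_l else T_l
  c_l <- if (is.null(c_l)) params$c_l else c_l
  if (is.null(c_l)) stop("a per-lick cost is required", call. = FALSE)
  A <- params$alpha * params$beta_s
  f <- 1 - 1 / (1 + params$beta_l * n_l)
  disc <- params$c_s^2 * T_l^2 * n_l^2 +
    params$c_s * params$T_s * n_l * (A * f * T_l + c_l * params$T_s)
  out <- (-params$c_s * T_l * n_l + sqrt(pmax(disc, 0))) /
    (params$c_s * params$T_s)
  out[n_l <= 0] <- NA_real_
  out
}
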