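#' @keywords internal
policy_solution <- function(n_s, n_l, T_l = NA_real_, J, feasible, method) {
  structure(
    list(n_s = n_s, n_l = n_l, T_l = T_l, J = J,
         feasible = feasible, method = method),
    class = "policy_solution"
  )
}

#' @export
print.policy_solution <- function(x, ...) {
  cat("<policy_solution>", if (!x$feasible) "(infeasible)", "\n")
  cat(sprintf("  n_s* = %.4g, n_l* = %.4g", x$n_s, x$n_l))
  if (!is.na(x$T_l)) cat(sprintf(", T_l* = %.4g", x$T_l))
  cat(sprintf("\n  capture rate J* = %.6g  [%s]\n", x$J, x$method))
  invisible(x)
}

default_bounds <- function() {
  list(ns = c(1, 15), nl = c(0, 60), Tl = c(0.01, 10))
}

#' Optimal work/harvest policy at a fixed per-lick cost
#'
#' Maximizes the capture rate over the number of work trials `n_s` and licks
#' `n_l`, with the per-lick cost `c_l` and lick duration `T_l` held fixed.
#'
#' In `"integer"` mode (the default, matching how per-`n_s` capture-rate
#' curves are constructed), the search enumerates integer `n_s` in
#' `[1, ns_max]` and integer `n_l` in `[0, nl_max]`; ties within 1e-12 of
#' the maximum break toward the smallest `n_s`, then the smallest `n_l`. In
#' `"continuous"` mode the relaxation is solved by quasi-Newton ascent from
#' multiple starts, and the result is accepted only when it is an interior
#' stationary point (gradient check) that beats every search-boundary
#' value; otherwise the solution is flagged infeasible.
#'
#' @param params A [policy_params()] with a fixed `c_l`.
#' @param mode `"integer"` or `"continuous"`.
#' @param ns_max,nl_max Search bounds; the optimum must be interior.
#' @return A `policy_solution`: `n_s`, `n_l`, `J` (achieved capture rate),
#'   `feasible`, `method`.
#' @examples
#' p <- policy_params(20, 0.5, 0.3, c_s = 0.5, T_s = 1, T_l = 0.2, c_l = 0.5)
#' optimal_policy_fixed_cost(p)  # n_s* = 4
#' @export
optimal_policy_fixed_cost <- function(params, mode = c("integer", "continuous"),
                                      ns_max = 15, nl_max = 60) {
  stopifnot(inherits(params, "policy_params"))
  if (is.null(params$c_l)) stop("fixed-cost solver needs `c_l`", call. = FALSE)
  mode <- match.arg(mode)
  if (mode == "integer") {
    solve_integer_grid(params, ns_max, nl_max)
  } else {
    solve_continuous(params, ns_max, nl_max)
  }
}

solve_integer_grid <- function(params, ns_max, nl_max, tie_tol = 1e-12) {
  ns <- seq_len(ns_max)
  nl <- 0:nl_max
  J <- outer(ns, nl, function(a, b) capture_rate(params, a, b))
  jmax <- max(J)
  hits <- which(J >= jmax - tie_tol, arr.ind = TRUE)
  # smallest n_s, then smallest n_l, among ties
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  i <- hits[1, 1]; j <- hits[1, 2]
  if (i == ns_max || j == nl_max + 1L) {
    warning("integer-grid optimum lies on the search boundary; enlarge ns_max/nl_max",
            call. = FALSE)
  }
  feasible <- jmax > 0
  policy_solution(n_s = ns[i], n_l = nl[j], J = jmax,
                  feasible = feasible, method = "integer_grid")
}

grad_num <- function(f, x, lo, hi, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    step <- h * max(1, abs(x[i]))
    step <- min(step, (x[i] - lo[i]) / 2, (hi[i] - x[i]) / 2)
    if (step <= 0) return(Inf)  # pinned to the boundary: not stationary
    e <- numeric(length(x)); e[i] <- step
    (f(x + e) - f(x - e)) / (2 * e[i])
  }, numeric(1))
}

solve_continuous <- function(params, ns_max, nl_max) {
  lo <- c(1, 1e-6); hi <- c(ns_max, nl_max)
  obj <- function(x) capture_rate(params, x[1], x[2])
  seed_int <- solve_integer_grid(params, ns_max, nl_max)
  # coarse continuous grid locates the right basin before polishing
  cg_ns <- seq(1, ns_max, by = 0.25)
  cg_nl <- seq(0.25, nl_max, by = 0.25)
  cg <- outer(cg_ns, cg_nl, function(a, b) capture_rate(params, a, b))
  cg_i <- which(cg == max(cg), arr.ind = TRUE)[1, ]
  starts <- list(c(cg_ns[cg_i[1]], cg_nl[cg_i[2]]),
                 c(max(seed_int$n_s, 1.5), max(seed_int$n_l, 0.5)),
                 c(4, 8), c(2, 2), c(8, 20))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(s, lo), hi), function(x) -obj(x),
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(factr = 10, pgtol = 1e-10, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || -fit$value > best$J) {
      best <- list(par = fit$par, J = -fit$value)
    }
  }
  if (is.null(best)) {
    return(policy_solution(1, 0, J = capture_rate(params, 1, 0),
                           feasible = FALSE, method = "continuous_stationary"))
  }
  # boundary value: best capture rate achievable on the edges of the box
  edge <- max(
    capture_rate(params, 1, 0),
    max(capture_rate(params, seq(lo[1], hi[1], length.out = 200), 0)),
    max(capture_rate(params, lo[1], seq(0, hi[2], length.out = 200)))
  )
  interior <- all(best$par > lo + 1e-4) && all(best$par < hi - 1e-4)
  stationary <- interior && {
    g <- grad_num(obj, best$par, lo, hi)
    sqrt(sum(g^2)) < 1e-2 * max(1, abs(best$J))
  }
  feasible <- interior && stationary && best$J > edge
  policy_solution(n_s = best$par[1], n_l = best$par[2], J = best$J,
                  feasible = feasible, method = "continuous_stationary")
}

#' Optimal policy when the lick cost depends on lick duration
#'
#' Inserts the duration cost `d^2/T_l + k*T_l` into the capture rate, so
#' that the per-lick effort is no longer fixed and the optimal policy is a
#' triple `(n_s*, n_l*, T_l*)`: how long to work, how long to harvest, and
#' how vigorously to lick. In `"integer"` mode, each integer `(n_s, n_l)`
#' candidate is scored at its continuously optimized lick duration
#' (golden-section search over `Tl_range`); in `"continuous"` mode all
#' three variables are relaxed and solved by bounded quasi-Newton ascent
#' with a stationarity check.
#'
#' @param params A [policy_params()] carrying `d` and `k` (its `c_l` is
#'   ignored).
#' @inheritParams optimal_policy_fixed_cost
#' @param Tl_range Positive search interval for the lick duration.
#' @return A `policy_solution` including `T_l`.
#' @examples
#' p <- policy_params(20, 0.5, 0.3, c_s = 0.5, T_s = 1, T_l = 0.2,
#'                    d = 0.2, k = 1)
#' optimal_policy_with_distance(p)
#' @export
optimal_policy_with_distance <- function(params,
                                         mode = c("integer", "continuous"),
                                         ns_max = 15, nl_max = 60,
                                         Tl_range = c(0.01, 10)) {
  stopifnot(inherits(params, "policy_params"))
  if (is.null(params$d) || is.null(params$k)) {
    stop("distance-parameterized solver needs `d` and `k`", call. = FALSE)
  }
  mode <- match.arg(mode)
  stopifnot(length(Tl_range) == 2, Tl_range[1] > 0, diff(Tl_range) > 0)
  d <- params$d; k <- params$k
  J_at <- function(ns, nl, Tl) {
    capture_rate(params, ns, nl, T_l = Tl, c_l = lick_effort_cost(d, Tl, k))
  }
  if (mode == "integer") {
    best <- list(J = -Inf)
    at_Tl_edge <- FALSE
    for (ns in seq_len(ns_max)) {
      for (nl in 0:nl_max) {
        if (nl == 0) {
          val <- capture_rate(params, ns, 0, c_l = 0)
          Tl <- NA_real_
        } else {
          opt <- stats::optimize(function(Tl) J_at(ns, nl, Tl),
                                 Tl_range, maximum = TRUE, tol = 1e-9)
          val <- opt$objective; Tl <- opt$maximum
        }
        if (val > best$J) best <- list(ns = ns, nl = nl, Tl = Tl, J = val)
      }
    }
    if (!is.na(best$Tl) &&
        (best$Tl < Tl_range[1] + 1e-6 || best$Tl > Tl_range[2] - 1e-6)) {
      warning("optimal lick duration lies at the edge of Tl_range", call. = FALSE)
    }
    if (best$ns == ns_max || best$nl == nl_max) {
      warning("integer-grid optimum lies on the search boundary", call. = FALSE)
    }
    policy_solution(best$ns, best$nl, best$Tl, J = best$J,
                    feasible = best$J > 0, method = "integer_grid")
  } else {
    seed <- optimal_policy_with_distance(params, "integer", ns_max, nl_max,
                                         Tl_range)
    lo <- c(1, 1e-6, Tl_range[1]); hi <- c(ns_max, nl_max, Tl_range[2])
    obj <- function(x) J_at(x[1], x[2], x[3])
    starts <- list(
      c(max(seed$n_s, 1.5), max(seed$n_l, 0.5),
        if (is.na(seed$T_l)) 0.1 else seed$T_l),
      c(4, 9, 0.1), c(3, 12, 0.05))
    best <- NULL
    for (s in starts) {
      fit <- tryCatch(
        stats::optim(pmin(pmax(s, lo), hi), function(x) -obj(x),
                     method = "L-BFGS-B", lower = lo, upper = hi,
                     control = list(factr = 10, pgtol = 1e-10, maxit = 500)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || -fit$value > best$J) {
        best <- list(par = fit$par, J = -fit$value)
      }
    }
    interior <- all(best$par > lo + 1e-4) && all(best$par < hi * (1 - 1e-4))
    stationary <- interior && {
      g <- grad_num(obj, best$par, lo, hi)
      sqrt(sum(g^2)) < 1e-2 * max(1, abs(best$J))
    }
    policy_solution(best$par[1], best$par[2], best$par[3], J = best$J,
                    feasible = interior && stationary && best$J > 0,
                    method = "continuous_stationary")
  }
}

#' Solve whichever policy problem the parameters describe
#'
#' Dispatches to [optimal_policy_fixed_cost()] when `params` carries a fixed
#' `c_l`, and to [optimal_policy_with_distance()] when the lick cost is
#' given by the duration cost (`d` and `k` present, `c_l` absent).
#'
#' @inheritParams optimal_policy_fixed_cost
#' @param ... Passed to the dispatched solver.
#' @return A `policy_solution`.
#' @export
optimal_policy <- function(params, mode = c("integer", "continuous"), ...) {
  mode <- match.arg(mode)
  if (!is.null(params$c_l)) {
    optimal_policy_fixed_cost(params, mode = mode, ...)
  } else {
    optimal_policy_with_distance(params, mode = mode, ...)
  }
}

#' Sweep one model parameter and collect the optimal policies
#'
#' Re-solves the policy problem along a grid of one parameter, holding all
#' others fixed: the comparative-statics tool. Varying `d` (tube distance)
#' uses the distance-parameterized problem; varying `c_l` uses the
#' fixed-cost problem; varying `alpha` (reward value; hunger) uses
#' whichever problem the remaining parameters describe.
#'
#' @inheritParams optimal_policy_fixed_cost
#' @param vary One of `"d"`, `"c_l"`, `"alpha"`.
#' @param grid Strictly increasing numeric grid for the varied parameter.
#' @param ... Passed to the solver.
#' @return A tibble with columns
#'   `vary, value, n_s, n_l, T_l, J, feasible, method`, one row per grid
#'   value. Infeasible grid points are flagged, never dropped.
#' @examples
#' p <- policy_params(20, 0.5, 0.3, c_s = 0.5, T_s = 1, T_l = 0.2,
#'                    d = 0.2, k = 1)
#' sweep_policy(p, "d", c(0.1, 0.2, 0.3))
#' @export
sweep_policy <- function(params, vary = c("d", "c_l", "alpha"), grid,
                         mode = c("integer", "continuous"), ...) {
  vary <- match.arg(vary)
  mode <- match.arg(mode)
  stopifnot(is.numeric(grid), length(grid) >= 1, !is.unsorted(grid, strictly = TRUE))
  rows <- lapply(grid, function(v) {
    p <- params
    if (vary == "d") {
      p$d <- v
      p$c_l <- NULL  # the distance problem defines the lick cost
      if (is.null(p$k)) stop("varying `d` requires `k`", call. = FALSE)
    } else if (vary == "c_l") {
      p$c_l <- v
    } else {
      p$alpha <- v
    }
    sol <- optimal_policy(p, mode = mode, ...)
    tibble::tibble(vary = vary, value = v, n_s = sol$n_s, n_l = sol$n_l,
                   T_l = sol$T_l, J = sol$J, feasible = sol$feasible,
                   method = sol$method)
  })
  dplyr::bind_rows(rows)
}

#' Optimal movement duration under a multiplicative reward-effort utility
#'
#' The competing utility divides reward by effort instead of subtracting
#' it: `J(T) = alpha / ((1 + T) * U(T))`, where reward `alpha` is
#' discounted hyperbolically with movement duration `T` and `U(T)` is a
#' concave-upward effort-vs-duration cost. Because `alpha` merely scales
#' this utility, the maximizing duration is invariant to reward value --
#' which is why a multiplicative interaction cannot explain reward
#' invigorating movements.
#'
#' @param effort_fn Function mapping duration to effort cost; must be
#'   finite and positive on `interval`.
#' @param alpha Reward value (> 0). Affects `J` linearly, never `T*`.
#' @param interval Positive search interval for the duration.
#' @return A list: `T_star` (optimal duration), `J_star` (utility there).
#' @examples
#' u <- function(T) 0.2^2 / T + T
#' multiplicative_optimal_duration(u, alpha = 1)$T_star
#' @export
multiplicative_optimal_duration <- function(effort_fn, alpha = 1,
                                            interval = c(1e-3, 10)) {
  stopifnot(is.function(effort_fn), alpha > 0,
            length(interval) == 2, interval[1] > 0, diff(interval) > 0)
  probe <- effort_fn(seq(interval[1], interval[2], length.out = 25))
  if (any(!is.finite(probe))) {
    stop("effort_fn is not finite on the search interval", call. = FALSE)
  }
  J <- function(T) alpha / ((1 + T) * effort_fn(T))
  opt <- stats::optimize(J, interval, maximum = TRUE, tol = 1e-10)
  list(T_star = opt$maximum, J_star = opt$objective)
}
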