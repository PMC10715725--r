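#' Economic parameters of the work/harvest capture-rate model
#'
#' Bundles every parameter of the capture rate and of the effort cost of a
#' lick into a validated list. The capture rate describes a forager that
#' alternates between a *work* period (`n_s` trials, each succeeding with
#' probability `beta_s`, earning food increment `alpha`, costing effort
#' `c_s` per trial squared and time `T_s` per trial) and a *harvest* period
#' (`n_l` licks, each succeeding with probability `beta_l`, costing effort
#' `c_l` and time `T_l` per lick).
#'
#' The per-lick effort `c_l` may be supplied directly (fixed-cost problem),
#' or derived from the lick-duration cost `d^2 / T_l + k * T_l`, in which
#' case `d` (tube distance) and `k` (cost growth rate) must be supplied and
#' the lick duration `T_l` becomes a free policy variable.
#'
#' @param alpha Reward value of one successful trial (utility units).
#' @param beta_s Trial success probability, in (0, 1].
#' @param beta_l Lick success probability, in (0, 1].
#' @param c_s Work effort coefficient (utility per trial squared).
#' @param T_s Duration of one trial (time units).
#' @param T_l Duration of one lick (time units).
#' @param c_l Per-lick effort cost (utility units), or `NULL` when the cost
#'   is to be derived from `d` and `k`.
#' @param d Tube distance (distance units); only used by the
#'   distance-parameterized problem.
#' @param k Growth rate of the lick cost with duration (utility * time).
#'
#' @return An object of class `policy_params` (a named list).
#' @examples
#' p <- policy_params(alpha = 20, beta_s = 0.5, beta_l = 0.3,
#'                    c_s = 0.5, T_s = 1, T_l = 0.2, c_l = 0.5)
#' capture_rate(p, n_s = 4, n_l = 8)
#' @export
policy_params <- function(alpha, beta_s, beta_l, c_s, T_s, T_l,
                          c_l = NULL, d = NULL, k = NULL) {
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
    is.numeric(beta_s), beta_s > 0, beta_s <= 1,
    is.numeric(beta_l), beta_l > 0, beta_l <= 1,
    is.numeric(c_s), c_s >= 0,
    is.numeric(T_s), T_s > 0,
    is.numeric(T_l), T_l > 0
  )
  if (!is.null(c_l)) stopifnot(is.numeric(c_l), c_l >= 0)
  if (!is.null(d)) stopifnot(is.numeric(d), d >= 0)
  if (!is.null(k)) stopifnot(is.numeric(k), k >= 0)
  if (is.null(c_l) && (is.null(d) || is.null(k))) {
    stop("supply either a fixed `c_l` or both `d` and `k`", call. = FALSE)
  }
  structure(
    list(alpha = alpha, beta_s = beta_s, beta_l = beta_l,
         c_s = c_s, T_s = T_s, T_l = T_l, c_l = c_l, d = d, k = k),
    class = "policy_params"
  )
}

#' @export
print.policy_params <- function(x, ...) {
  cat("<policy_params>\n")
  cat(sprintf("  reward alpha = %g, success beta_s = %g, beta_l = %g\n",
              x$alpha, x$beta_s, x$beta_l))
  cat(sprintf("  effort c_s = %g, durations T_s = %g, T_l = %g\n",
              x$c_s, x$T_s, x$T_l))
  if (!is.null(x$c_l)) cat(sprintf("  fixed lick cost c_l = %g\n", x$c_l))
  if (!is.null(x$d)) cat(sprintf("  tube distance d = %g, cost rate k = %g\n",
                                 x$d, if (is.null(x$k)) NA else x$k))
  invisible(x)
}

#' Read or write policy parameters as JSON
#'
#' Configuration files mirror the `policy_params` field names exactly.
#'
#' @param path File path.
#' @return `read_policy_params()` returns a `policy_params` object.
#' @export
read_policy_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("alpha", "beta_s", "beta_l", "c_s", "T_s", "T_l", "c_l", "d", "k")
  extra <- setdiff(names(raw), allowed)
  if (length(extra)) {
    stop("unknown fields in parameter file: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(policy_params, raw[intersect(allowed, names(raw))])
}

#' @rdname read_policy_params
#' @param params A `policy_params` object.
#' @export
write_policy_params <- function(params, path) {
  stopifnot(inherits(params, "policy_params"))
  jsonlite::write_json(params[!vapply(params, is.null, logical(1))],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
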