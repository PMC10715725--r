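#' Expected peak speed from the amplitude-velocity main sequence
#'
#' Movements obey a stereotyped saturating relation between amplitude `x`
#' and peak speed: `v = a_ms * (1 - 1/(1 + b_ms * x))`. The curve is
#' strictly increasing and concave in amplitude, and saturates at the
#' asymptotic speed `a_ms`.
#'
#' @param params A `main_sequence_params` object from
#'   [main_sequence_params()] or [fit_main_sequence()].
#' @param amplitude Movement amplitude, > 0 (deg for saccades, mm for
#'   licks); vectorized.
#' @return Expected peak speed in the units of `a_ms`.
#' @examples
#' ms <- main_sequence_params(a_ms = 600, b_ms = 0.15, movement_type = "saccade")
#' expected_peak_speed(ms, 5)  # ~257.14 deg/s
#' @export
expected_peak_speed <- function(params, amplitude) {
  stopifnot(inherits(params, "main_sequence_params"))
  if (any(amplitude <= 0)) stop("amplitude must be > 0", call. = FALSE)
  params$a_ms * (1 - 1 / (1 + params$b_ms * amplitude))
}

#' Main-sequence parameters
#'
#' @param a_ms Asymptotic peak speed (> 0); deg/s for saccades, mm/s for
#'   licks.
#' @param b_ms Curvature (> 0); 1/deg or 1/mm.
#' @param movement_type One of `"saccade"`, `"lick_protraction"`,
#'   `"lick_retraction"`.
#' @param subject_id Optional subject label.
#' @param converged Logical fit-convergence flag.
#' @return A `main_sequence_params` object.
#' @export
main_sequence_params <- function(a_ms, b_ms,
                                 movement_type = c("saccade",
                                                   "lick_protraction",
                                                   "lick_retraction"),
                                 subject_id = NA_character_,
                                 converged = NA) {
  stopifnot(is.numeric(a_ms), a_ms > 0, is.numeric(b_ms), b_ms > 0)
  movement_type <- match.arg(movement_type)
  structure(
    list(a_ms = a_ms, b_ms = b_ms, movement_type = movement_type,
         subject_id = subject_id, converged = converged),
    class = "main_sequence_params"
  )
}

#' @export
print.main_sequence_params <- function(x, ...) {
  cat(sprintf("<main_sequence_params> %s%s\n", x$movement_type,
              if (is.na(x$subject_id)) "" else paste0(" / ", x$subject_id)))
  cat(sprintf("  a_ms = %.4g, b_ms = %.4g (converged: %s)\n",
              x$a_ms, x$b_ms, x$converged))
  invisible(x)
}

#' Fit the main sequence to a population of movements
#'
#' Nonlinear least squares of peak speed on amplitude under the saturating
#' model `v = a_ms * (1 - 1/(1 + b_ms * x))`, pooled across sessions for
#' one subject and movement type. Fitting uses Levenberg-Marquardt; with
#' `robust = TRUE`, a few rounds of Huber reweighting down-weight
#' heavy-tailed peak-speed outliers.
#'
#' @param amplitude,peak_speed Numeric vectors (> 0) of equal length;
#'   at least 50 movements spanning a positive amplitude range.
#' @param movement_type,subject_id Labels stored on the result.
#' @param robust Apply Huber-type iterative reweighting (default `FALSE`).
#' @param start Optional named starting values `c(a_ms =, b_ms =)`;
#'   otherwise derived from the data.
#' @return A `main_sequence_params` with the fitted constants.
#' @examples
#' ms <- main_sequence_params(600, 0.15, "saccade")
#' amp <- runif(200, 2, 12)
#' fit_main_sequence(amp, expected_peak_speed(ms, amp), "saccade")
#' @export
fit_main_sequence <- function(amplitude, peak_speed,
                              movement_type = c("saccade", "lick_protraction",
                                                "lick_retraction"),
                              subject_id = NA_character_,
                              robust = FALSE, start = NULL) {
  movement_type <- match.arg(movement_type)
  ok <- is.finite(amplitude) & is.finite(peak_speed)
  amplitude <- amplitude[ok]; peak_speed <- peak_speed[ok]
  if (length(amplitude) < 50) {
    stop("need at least 50 movements to fit the main sequence", call. = FALSE)
  }
  if (any(amplitude <= 0) || any(peak_speed <= 0)) {
    stop("amplitudes and peak speeds must be positive", call. = FALSE)
  }
  if (diff(range(amplitude)) < sqrt(.Machine$double.eps)) {
    stop("degenerate amplitude range: the fit is unidentifiable", call. = FALSE)
  }
  if (is.null(start)) {
    a0 <- max(peak_speed) * 1.2
    # invert the model at the median point for a curvature guess
    med_a <- stats::median(amplitude); med_v <- stats::median(peak_speed)
    ratio <- min(med_v / a0, 0.95)
    b0 <- ratio / ((1 - ratio) * med_a)
    start <- c(a_ms = a0, b_ms = max(b0, 1e-3))
  }
  dat <- data.frame(x = amplitude, v = peak_speed)
  w <- rep(1, nrow(dat))
  fit <- NULL
  n_irls <- if (robust) 4L else 1L
  for (iter in seq_len(n_irls)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ a_ms * (1 - 1 / (1 + b_ms * x)),
                        data = dat, start = as.list(start), weights = w,
                        lower = c(a_ms = 1e-8, b_ms = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      stop("main-sequence fit failed to converge (start a_ms=",
           signif(start[["a_ms"]], 4), ", b_ms=", signif(start[["b_ms"]], 4),
           "): ", conditionMessage(fit), call. = FALSE)
    }
    if (robust && iter < n_irls) {
      r <- stats::residuals(fit)
      s <- stats::mad(r) + .Machine$double.eps
      u <- abs(r) / (1.345 * s)
      w <- ifelse(u <= 1, 1, 1 / u)
      start <- stats::coef(fit)
    }
  }
  co <- stats::coef(fit)
  main_sequence_params(co[["a_ms"]], co[["b_ms"]], movement_type,
                       subject_id, converged = fit$convInfo$isConv %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Vigor of a movement
#'
#' The ratio of a movement's actual peak speed to the peak speed expected
#' from the main sequence at its amplitude. Vigor 1.10 means the movement
#' was 10% faster than a typical movement of that amplitude. The measure is
#' scale-free: rescaling all speeds (and `a_ms`) leaves it unchanged.
#'
#' @param peak_speed Observed peak speed(s), > 0.
#' @param amplitude Movement amplitude(s), > 0.
#' @param params Fitted [main_sequence_params()] for the matching movement
#'   type.
#' @return Dimensionless vigor, vectorized.
#' @examples
#' ms <- main_sequence_params(600, 0.15, "saccade")
#' compute_vigor(expected_peak_speed(ms, 5) * 1.1, 5, ms)  # 1.1
#' @export
compute_vigor <- function(peak_speed, amplitude, params) {
  expected <- expected_peak_speed(params, amplitude)
  if (any(expected <= 0)) stop("expected peak speed must be > 0", call. = FALSE)
  peak_speed / expected
}
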