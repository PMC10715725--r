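#' Binned mean of one event measure against another
#'
#' Bins events by `x` into fixed-width bins (centers at multiples of
#' `bin_size`) and reports the mean of `y` per bin with its standard
#' error. Used for lick-vigor vs. pupil, saccade-vigor vs. trial number,
#' and endpoint-error vs. vigor relations. Bins with fewer than `min_n`
#' events are dropped.
#'
#' @param x,y Numeric vectors of equal length, one value per event.
#' @param bin_size Bin width in units of `x`. Default 0.05 (vigor units).
#' @param min_n Minimum events per retained bin. Default 10.
#' @return Tibble: `bin_center`, `mean_y`, `sem_y`, `n`.
#' @export
binned_relation <- function(x, y, bin_size = 0.05, min_n = 10) {
  stopifnot(length(x) == length(y), bin_size > 0)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!length(x)) {
    return(tibble::tibble(bin_center = numeric(), mean_y = numeric(),
                          sem_y = numeric(), n = integer()))
  }
  centers <- round(x / bin_size) * bin_size
  out <- tibble::tibble(bin_center = centers, y = y) |>
    dplyr::group_by(.data$bin_center) |>
    dplyr::summarise(
      mean_y = mean(.data$y),
      sem_y = stats::sd(.data$y) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$bin_center)
  out[out$n >= min_n, ]
}

#' Pearson correlation of binned means
#'
#' Convenience wrapper: bins with [binned_relation()] and correlates the
#' bin centers with the bin means (standard closed-form Pearson r with
#' its t-test p-value; no multiple-testing correction).
#'
#' @inheritParams binned_relation
#' @return A list: `r`, `p`, `n_bins`, and the `bins` table.
#' @export
binned_correlation <- function(x, y, bin_size = 0.05, min_n = 10) {
  bins <- binned_relation(x, y, bin_size, min_n)
  if (nrow(bins) < 3) {
    return(list(r = NA_real_, p = NA_real_, n_bins = nrow(bins), bins = bins))
  }
  ct <- stats::cor.test(bins$bin_center, bins$mean_y)
  list(r = unname(ct$estimate), p = ct$p.value, n_bins = nrow(bins),
       bins = bins)
}

#' Saccade endpoint accuracy as a function of vigor
#'
#' Bins saccades by vigor and reports, per bin, the mean endpoint-error
#' magnitude and the determinant of the 2x2 endpoint-error covariance (a
#' scalar measure of endpoint variability). Bins with fewer than three
#' saccades (covariance undefined) or fewer than `min_n` are dropped; the
#' number dropped is reported as an attribute.
#'
#' @param vigor Per-saccade vigor.
#' @param err_x,err_y Endpoint-error components (deg).
#' @param bin_size Vigor bin width. Default 0.05.
#' @param min_n Minimum saccades per retained bin. Default 10.
#' @return Tibble: `bin_center`, `n`, `mean_abs_error`, `det_cov`; with
#'   attribute `n_dropped_bins`.
#' @export
endpoint_error_stats <- function(vigor, err_x, err_y, bin_size = 0.05,
                                 min_n = 10) {
  stopifnot(length(vigor) == length(err_x), length(err_x) == length(err_y))
  ok <- is.finite(vigor) & is.finite(err_x) & is.finite(err_y)
  vigor <- vigor[ok]; err_x <- err_x[ok]; err_y <- err_y[ok]
  centers <- round(vigor / bin_size) * bin_size
  dat <- tibble::tibble(bin_center = centers, err_x = err_x, err_y = err_y)
  all_bins <- dat |>
    dplyr::group_by(.data$bin_center) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_abs_error = mean(sqrt(.data$err_x^2 + .data$err_y^2)),
      det_cov = if (dplyr::n() >= 3) {
        det(stats::cov(cbind(.data$err_x, .data$err_y)))
      } else NA_real_,
      .groups = "drop") |>
    dplyr::arrange(.data$bin_center)
  keep <- all_bins$n >= max(min_n, 3) & !is.na(all_bins$det_cov)
  out <- all_bins[keep, ]
  attr(out, "n_dropped_bins") <- sum(!keep)
  out
}

#' Lick-to-lick vigor change conditioned on the previous lick's outcome
#'
#' Within each harvest bout, forms consecutive lick pairs and computes the
#' change in vigor from one lick to the next, split by whether the earlier
#' lick contacted food. A reinforcement effect appears as a positive
#' post-success change relative to the post-failure change.
#'
#' @param licks Tibble with `bout_id` (or `period_id`), `vigor`,
#'   `success`, time-ordered within bout.
#' @return Tibble with rows `post_success` and `post_failure`:
#'   `mean_delta`, `sem`, `n`. Zero-row tibble when no qualifying pairs
#'   exist.
#' @export
conditional_vigor_change <- function(licks) {
  id_col <- if ("bout_id" %in% names(licks)) "bout_id" else "period_id"
  stopifnot(all(c(id_col, "vigor", "success") %in% names(licks)))
  deltas <- numeric(0); after_success <- logical(0)
  for (b in split(licks, licks[[id_col]])) {
    if (nrow(b) < 2) next
    d <- diff(b$vigor)
    deltas <- c(deltas, d)
    after_success <- c(after_success, b$success[-nrow(b)])
  }
  if (!length(deltas)) {
    return(tibble::tibble(condition = character(), mean_delta = numeric(),
                          sem = numeric(), n = integer()))
  }
  summarise_side <- function(d) {
    tibble::tibble(mean_delta = mean(d),
                   sem = stats::sd(d) / sqrt(length(d)),
                   n = length(d))
  }
  dplyr::bind_rows(
    dplyr::mutate(summarise_side(deltas[after_success]),
                  condition = "post_success", .before = 1),
    dplyr::mutate(summarise_side(deltas[!after_success]),
                  condition = "post_failure", .before = 1))
}

#' Grouped summaries of work and harvest periods
#'
#' Aggregates segmented periods by an experimental grouping: tube
#' distance (effort cost of harvest), session time (early/middle/late
#' thirds), or the number of successfully completed trials in the
#' preceding work period (reward magnitude available at harvest).
#'
#' @param periods Period table from [segment_periods()]; must carry the
#'   grouping column for `group_by = "tube_distance"` (join it from the
#'   session metadata first). Partial periods are excluded.
#' @param licks Optional lick table with `period_id` and `vigor`, used
#'   for per-harvest mean lick vigor.
#' @param group_by One of `"tube_distance"`, `"session_time"`,
#'   `"prior_work_trials"`.
#' @param food_increment_mL Food earned per successful trial. Default
#'   0.015.
#' @return A tibble of group means and standard errors: for work periods,
#'   attempted and successful trials and food cached; for harvests, licks
#'   per harvest and (when `licks` is given) mean lick vigor.
#' @export
period_summaries <- function(periods, licks = NULL,
                             group_by = c("tube_distance", "session_time",
                                          "prior_work_trials"),
                             food_increment_mL = 0.015) {
  group_by <- match.arg(group_by)
  periods <- periods[!periods$partial, ]
  periods$food_cached <- food_increment_mL * periods$n_success
  # per-harvest mean lick vigor
  if (!is.null(licks) && all(c("period_id", "vigor") %in% names(licks))) {
    lv <- licks |>
      dplyr::group_by(.data$period_id) |>
      dplyr::summarise(mean_lick_vigor = mean(.data$vigor), .groups = "drop")
    periods <- dplyr::left_join(periods, lv, by = "period_id")
  } else {
    periods$mean_lick_vigor <- NA_real_
  }
  key <- switch(group_by,
    tube_distance = {
      if (!"tube_distance" %in% names(periods)) {
        stop("periods lack a `tube_distance` column; join session metadata first",
             call. = FALSE)
      }
      periods$tube_distance
    },
    session_time = {
      br <- stats::quantile(periods$start_s, c(0, 1 / 3, 2 / 3, 1))
      cut(periods$start_s, unique(br), include.lowest = TRUE,
          labels = c("early", "middle", "late")[seq_len(length(unique(br)) - 1)])
    },
    prior_work_trials = {
      prior <- rep(NA_integer_, nrow(periods))
      last_work_succ <- NA_integer_
      for (i in order(periods$start_s)) {
        if (periods$kind[i] == "work") {
          last_work_succ <- periods$n_success[i]
        } else {
          prior[i] <- last_work_succ
        }
      }
      prior
    })
  periods$group <- key
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  work <- periods |>
    dplyr::filter(.data$kind == "work", !is.na(.data$group)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      kind = "work", n_periods = dplyr::n(),
      mean_attempted = mean(.data$n_attempted), sem_attempted = sem(.data$n_attempted),
      mean_success = mean(.data$n_success), sem_success = sem(.data$n_success),
      mean_food_cached = mean(.data$food_cached),
      .groups = "drop")
  harvest <- periods |>
    dplyr::filter(.data$kind == "harvest", !is.na(.data$group)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      kind = "harvest", n_periods = dplyr::n(),
      mean_licks = mean(.data$n_licks), sem_licks = sem(.data$n_licks),
      mean_lick_vigor = mean(.data$mean_lick_vigor, na.rm = TRUE),
      sem_lick_vigor = sem(.data$mean_lick_vigor[!is.na(.data$mean_lick_vigor)]),
      .groups = "drop")
  dplyr::bind_rows(work, harvest)
}
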