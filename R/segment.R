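#' Segment a session into alternating work and harvest periods
#'
#' Foraging sessions alternate between *work* (runs of visually guided
#' saccade trials that accumulate food) and *harvest* (bouts of licks that
#' consume it). A harvest begins at the first reward-seeking lick after at
#' least one trial, and ends when the next trial's center-target saccade
#' occurs or when an inter-lick gap exceeds the bout threshold; work is
#' the complement. A session that begins mid-harvest yields a leading
#' partial period, flagged so summaries can exclude it.
#'
#' @param saccades Saccade event table (columns `onset_s`, `subtype`,
#'   `trial_id`, `success`), time-sorted.
#' @param licks Lick event table (columns `onset_s`, `subtype`,
#'   `success`), time-sorted.
#' @param bout_gap_s Inter-lick gap that ends a harvest. Default 0.5.
#' @param grooming_breaks Should grooming licks be ignored when forming
#'   harvests? Default `TRUE` (they neither start nor extend a bout).
#' @return A list:
#'   * `periods`: tibble with `period_id`, `kind` (`work`/`harvest`),
#'     `start_s`, `end_s`, `n_attempted`, `n_success`, `n_licks`,
#'     `partial`;
#'   * `saccades`, `licks`: the input tables with a derived `period_id`
#'     column.
#' @export
segment_periods <- function(saccades, licks, bout_gap_s = 0.5,
                            grooming_breaks = TRUE) {
  req_s <- c("onset_s", "subtype", "trial_id", "success")
  req_l <- c("onset_s", "subtype", "success")
  stopifnot(all(req_s %in% names(saccades)), all(req_l %in% names(licks)))
  if (is.unsorted(saccades$onset_s) || is.unsorted(licks$onset_s)) {
    stop("event tables must be time-sorted", call. = FALSE)
  }
  ev <- dplyr::bind_rows(
    tibble::tibble(kind = "saccade", onset_s = saccades$onset_s,
                   subtype = saccades$subtype, idx = seq_len(nrow(saccades))),
    tibble::tibble(kind = "lick", onset_s = licks$onset_s,
                   subtype = licks$subtype, idx = seq_len(nrow(licks))))
  ev <- ev[order(ev$onset_s), ]
  if (grooming_breaks) {
    ev <- ev[!(ev$kind == "lick" & ev$subtype == "grooming"), ]
  }
  n <- nrow(ev)
  if (n == 0) {
    return(list(periods = tibble::tibble(
      period_id = character(), kind = character(), start_s = numeric(),
      end_s = numeric(), n_attempted = integer(), n_success = integer(),
      n_licks = integer(), partial = logical()),
      saccades = saccades, licks = licks))
  }
  period_of <- integer(n)
  kind_of <- character(0)
  partial <- logical(0)
  cur <- 0L
  cur_kind <- ""
  seen_trial <- FALSE
  last_lick_t <- -Inf
  for (i in seq_len(n)) {
    e_kind <- ev$kind[i]
    open_new <- FALSE
    if (cur == 0L) {
      open_new <- TRUE
    } else if (e_kind == "saccade" && cur_kind == "harvest") {
      open_new <- TRUE
    } else if (e_kind == "lick" && cur_kind == "work") {
      open_new <- TRUE
    } else if (e_kind == "lick" && cur_kind == "harvest" &&
               (ev$onset_s[i] - last_lick_t) > bout_gap_s) {
      open_new <- TRUE  # bout threshold exceeded: new harvest
    }
    if (open_new) {
      cur <- cur + 1L
      cur_kind <- if (e_kind == "saccade") "work" else "harvest"
      kind_of[cur] <- cur_kind
      # a harvest with no preceding trial is a leading partial period
      partial[cur] <- cur_kind == "harvest" && !seen_trial
    }
    if (e_kind == "saccade") seen_trial <- TRUE else last_lick_t <- ev$onset_s[i]
    period_of[i] <- cur
  }
  labels <- character(cur)
  w <- 0L; h <- 0L
  for (p in seq_len(cur)) {
    if (kind_of[p] == "work") {
      w <- w + 1L; labels[p] <- sprintf("W%03d", w)
    } else {
      h <- h + 1L; labels[p] <- sprintf("H%03d", h)
    }
  }
  ev$period <- labels[period_of]
  sac_pid <- rep(NA_character_, nrow(saccades))
  lick_pid <- rep(NA_character_, nrow(licks))
  sev <- ev[ev$kind == "saccade", ]
  lev <- ev[ev$kind == "lick", ]
  sac_pid[sev$idx] <- sev$period
  lick_pid[lev$idx] <- lev$period
  # grooming licks inherit the period active at their onset, if any
  if (any(is.na(lick_pid)) && nrow(ev) > 0) {
    starts <- vapply(split(ev$onset_s, period_of), min, numeric(1))
    for (i in which(is.na(lick_pid))) {
      p <- findInterval(licks$onset_s[i], starts)
      lick_pid[i] <- if (p >= 1) labels[p] else NA_character_
    }
  }
  per <- lapply(seq_len(cur), function(p) {
    pid <- labels[p]
    in_s <- which(sac_pid == pid)
    in_l <- which(lick_pid == pid)
    t_all <- c(saccades$onset_s[in_s], licks$onset_s[in_l])
    trials <- saccades[in_s, ]
    n_att <- length(unique(trials$trial_id[!is.na(trials$trial_id)]))
    succ_tr <- unique(trials$trial_id[trials$success & !is.na(trials$trial_id)])
    tibble::tibble(
      period_id = pid, kind = kind_of[p],
      start_s = min(t_all), end_s = max(t_all),
      n_attempted = n_att, n_success = length(succ_tr),
      n_licks = length(in_l), partial = partial[p])
  })
  saccades$period_id <- sac_pid
  licks$period_id <- lick_pid
  list(periods = dplyr::bind_rows(per), saccades = saccades, licks = licks)
}
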