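#' Event-locked pupil measures, normalized within session
#'
#' Averages pupil area over a window centered on each anchoring event
#' (reward-relevant saccade onsets and lick apexes), then standardizes the
#' per-event means against their distribution within the same session.
#' Because the z-score is computed per session, it is invariant to affine
#' transforms of the raw trace (gain and offset of the pupil camera), and
#' sessions with different baselines but identical fluctuations yield
#' identical profiles.
#'
#' @param pupil Tibble with `time_s` and `area` (session pupil recording).
#' @param anchors Event anchor times in seconds.
#' @param window_s Half-width of the averaging window. Default 0.25
#'   (a +/-250 ms window).
#' @return A tibble, one row per retained anchor: `anchor_s`, `raw_mean`,
#'   `z`. Anchors whose window extends outside the recording are dropped
#'   with a warning.
#' @export
pupil_zscore <- function(pupil, anchors, window_s = 0.25) {
  stopifnot(all(c("time_s", "area") %in% names(pupil)), window_s > 0)
  if (length(anchors) == 0) {
    return(tibble::tibble(anchor_s = numeric(), raw_mean = numeric(),
                          z = numeric()))
  }
  lo <- min(pupil$time_s); hi <- max(pupil$time_s)
  inside <- anchors - window_s >= lo & anchors + window_s <= hi
  if (any(!inside)) {
    warning(sum(!inside), " event window(s) extend outside the recording; dropped",
            call. = FALSE)
  }
  kept <- anchors[inside]
  t <- pupil$time_s
  raw <- vapply(kept, function(a) {
    i <- findInterval(a - window_s, t) + 1L
    j <- findInterval(a + window_s, t)
    if (j < i) return(NA_real_)
    mean(pupil$area[i:j])
  }, numeric(1))
  mu <- mean(raw, na.rm = TRUE)
  sdv <- stats::sd(raw, na.rm = TRUE)
  z <- if (is.na(sdv) || sdv == 0) rep(0, length(raw)) else (raw - mu) / sdv
  tibble::tibble(anchor_s = kept, raw_mean = raw, z = z)
}
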