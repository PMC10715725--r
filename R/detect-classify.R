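#' Detect saccades in a sampled gaze trace
#'
#' Velocity-threshold detection with hysteresis. Gaze positions are
#' smoothed by a Savitzky-Golay local polynomial before differentiation;
#' an event opens where speed exceeds `onset_threshold`, extends in both
#' directions while speed stays above `offset_threshold`, must last at
#' least `min_duration_s`, and events separated by less than `merge_gap_s`
#' are merged into one.
#'
#' @param time_s Sample times in seconds, uniformly spaced.
#' @param x_deg,y_deg Horizontal and vertical gaze position in degrees.
#' @param onset_threshold Speed (deg/s) that opens an event. Default 50.
#' @param offset_threshold Speed (deg/s) below which an event closes.
#'   Default 30.
#' @param min_duration_s Minimum event duration. Default 0.010.
#' @param merge_gap_s Events closer than this are merged. Default 0.020.
#' @param sg_window Savitzky-Golay window length (odd samples). Default 7.
#' @return A tibble, one row per saccade: `onset_s`, `offset_s`,
#'   `amplitude_deg` (onset-to-offset displacement), `peak_speed_dps`,
#'   `end_x_deg`, `end_y_deg`.
#' @export
detect_saccades <- function(time_s, x_deg, y_deg,
                            onset_threshold = 50, offset_threshold = 30,
                            min_duration_s = 0.010, merge_gap_s = 0.020,
                            sg_window = 7) {
  n <- length(time_s)
  stopifnot(length(x_deg) == n, length(y_deg) == n)
  if (n < sg_window + 2 || anyNA(time_s)) {
    stop("gaze trace too short or has missing times", call. = FALSE)
  }
  if (mean(is.na(x_deg) | is.na(y_deg)) > 0.1) {
    stop("gaze trace is riddled with missing samples", call. = FALSE)
  }
  dt <- stats::median(diff(time_s))
  fs <- 1 / dt
  xs <- signal::sgolayfilt(x_deg, p = 3, n = sg_window)
  ys <- signal::sgolayfilt(y_deg, p = 3, n = sg_window)
  vx <- c(0, diff(xs)) * fs
  vy <- c(0, diff(ys)) * fs
  speed <- sqrt(vx^2 + vy^2)
  above <- speed >= onset_threshold
  if (!any(above)) {
    return(tibble::tibble(onset_s = numeric(), offset_s = numeric(),
                          amplitude_deg = numeric(), peak_speed_dps = numeric(),
                          end_x_deg = numeric(), end_y_deg = numeric()))
  }
  # extend each supra-threshold run down to the offset threshold (hysteresis)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg <- cbind(starts[runs$values], ends[runs$values])
  low <- speed < offset_threshold
  for (r in seq_len(nrow(seg))) {
    i <- seg[r, 1]
    while (i > 1 && !low[i - 1]) i <- i - 1L
    j <- seg[r, 2]
    while (j < n && !low[j + 1]) j <- j + 1L
    seg[r, ] <- c(i, j)
  }
  seg <- unique(seg)
  seg <- seg[order(seg[, 1]), , drop = FALSE]
  # merge events separated by less than merge_gap_s
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) {
    for (r in 2:nrow(seg)) {
      gap <- (seg[r, 1] - merged[nrow(merged), 2]) * dt
      if (gap < merge_gap_s) {
        merged[nrow(merged), 2] <- seg[r, 2]
      } else {
        merged <- rbind(merged, seg[r, ])
      }
    }
  }
  keep <- (merged[, 2] - merged[, 1]) * dt >= min_duration_s
  merged <- merged[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(merged)), function(r) {
    i <- merged[r, 1]; j <- merged[r, 2]
    tibble::tibble(
      onset_s = time_s[i], offset_s = time_s[j],
      amplitude_deg = sqrt((xs[j] - xs[i])^2 + (ys[j] - ys[i])^2),
      peak_speed_dps = max(speed[i:j]),
      end_x_deg = xs[j], end_y_deg = ys[j])
  })
  dplyr::bind_rows(out)
}

#' Classify a saccade against the displayed targets and score success
#'
#' Assigns the saccade to the nearest concurrently displayed target
#' (`center`, `primary`, or `corrective`) and scores success when the
#' endpoint lands within the criterion radius of that target's center.
#' Saccades with no concurrent target are task-irrelevant.
#'
#' @param end_x_deg,end_y_deg Saccade endpoint.
#' @param targets A data frame of concurrently displayed targets with
#'   columns `type` (one of `"center"`, `"primary"`, `"corrective"`),
#'   `x_deg`, `y_deg`; may have zero rows.
#' @param criterion_radius_deg Success radius in degrees. Default 1.25.
#' @param assign_radius_deg A saccade farther than this from every target
#'   is task-irrelevant. Default 4.
#' @return A one-row tibble: `subtype`, `success`, `err_x_deg`,
#'   `err_y_deg` (endpoint minus assigned target center; `NA` when
#'   task-irrelevant).
#' @export
classify_saccade <- function(end_x_deg, end_y_deg, targets,
                             criterion_radius_deg = 1.25,
                             assign_radius_deg = 4) {
  if (is.null(targets) || nrow(targets) == 0) {
    warning("no target information: labeling saccade task_irrelevant",
            call. = FALSE)
    return(tibble::tibble(subtype = "task_irrelevant", success = FALSE,
                          err_x_deg = NA_real_, err_y_deg = NA_real_))
  }
  stopifnot(all(c("type", "x_deg", "y_deg") %in% names(targets)))
  dist <- sqrt((targets$x_deg - end_x_deg)^2 + (targets$y_deg - end_y_deg)^2)
  i <- which.min(dist)
  if (dist[i] > assign_radius_deg) {
    return(tibble::tibble(subtype = "task_irrelevant", success = FALSE,
                          err_x_deg = NA_real_, err_y_deg = NA_real_))
  }
  tibble::tibble(
    subtype = as.character(targets$type[i]),
    success = dist[i] <= criterion_radius_deg,
    err_x_deg = end_x_deg - targets$x_deg[i],
    err_y_deg = end_y_deg - targets$y_deg[i])
}

#' Classify a lick from the tongue-tip trajectory
#'
#' Finds the trajectory apex (maximum displacement from the mouth, at the
#' origin) and classifies the lick geometrically against the reward tube:
#' `inner_tube` if the apex falls inside the tube aperture, `outer_edge`
#' if it lands on the rim annulus, `under_tube` if it passes below the
#' aperture, and `grooming` when the movement is not directed at the tube.
#' An inner-tube lick succeeds when the tongue reaches the food; any lick
#' whose apex touches the aperture region may contact food that has
#' accumulated at the tube opening, so outer-edge contact counts as
#' success when `food_at_edge` is `TRUE`.
#'
#' @param time_s,x_mm,y_mm Tongue-tip trajectory relative to the mouth
#'   marker; `x_mm` is the outward axis toward the tube.
#' @param tube_center_mm Length-2 vector, tube aperture center.
#' @param tube_diameter_mm Aperture diameter. Default 4.4.
#' @param food_depth_mm How far beyond the aperture plane the food sits;
#'   an inner-tube lick succeeds when its apex penetrates this far.
#'   Default 1.
#' @param food_at_edge Does food at the rim make outer-edge contact a
#'   success? Default `FALSE`.
#' @param min_displacement_mm Trajectories never exceeding this
#'   displacement produce no event. Default 2.
#' @return A one-row tibble: `subtype`, `success`, `amplitude_mm` (apex
#'   displacement), `peak_speed_pro_mmps`, `peak_speed_ret_mmps` (peak
#'   speeds before/after the apex), `apex_s`; or a zero-row tibble when
#'   the tongue never leaves the mouth region.
#' @export
classify_lick <- function(time_s, x_mm, y_mm, tube_center_mm,
                          tube_diameter_mm = 4.4, food_depth_mm = 1,
                          food_at_edge = FALSE, min_displacement_mm = 2) {
  n <- length(time_s)
  stopifnot(length(x_mm) == n, length(y_mm) == n, length(tube_center_mm) == 2)
  disp <- sqrt(x_mm^2 + y_mm^2)
  empty <- tibble::tibble(subtype = character(), success = logical(),
                          amplitude_mm = numeric(),
                          peak_speed_pro_mmps = numeric(),
                          peak_speed_ret_mmps = numeric(), apex_s = numeric())
  if (max(disp) < min_displacement_mm) return(empty)
  i_apex <- which.max(disp)
  apex <- c(x_mm[i_apex], y_mm[i_apex])
  dt <- stats::median(diff(time_s))
  speed <- c(0, sqrt(diff(x_mm)^2 + diff(y_mm)^2)) / dt
  pro <- max(speed[seq_len(i_apex)])
  ret <- if (i_apex < n) max(speed[(i_apex + 1):n]) else NA_real_
  r_ap <- tube_diameter_mm / 2
  # bearing of the apex relative to the tube direction
  ang <- acos(sum(apex * tube_center_mm) /
                (sqrt(sum(apex^2)) * sqrt(sum(tube_center_mm^2))))
  off <- apex - tube_center_mm
  miss <- sqrt(sum(off^2))
  tube_dist <- sqrt(sum(tube_center_mm^2))
  if (ang > pi / 4) {
    subtype <- "grooming"; success <- FALSE
  } else if (miss <= r_ap ||
             (sqrt(sum(apex^2)) >= tube_dist &&
              abs(off[2]) <= r_ap && off[1] >= 0)) {
    # apex inside the aperture, or penetrated past the aperture plane
    subtype <- "inner_tube"
    success <- sqrt(sum(apex^2)) >= tube_dist + food_depth_mm
  } else if (off[2] < -r_ap) {
    subtype <- "under_tube"; success <- FALSE
  } else {
    subtype <- "outer_edge"
    success <- isTRUE(food_at_edge) && miss <= 1.5 * r_ap
  }
  tibble::tibble(subtype = subtype, success = success,
                 amplitude_mm = disp[i_apex],
                 peak_speed_pro_mmps = pro, peak_speed_ret_mmps = ret,
                 apex_s = time_s[i_apex])
}
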