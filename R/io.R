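saccade_schema <- c(event_id = "character", session_id = "character",
                    onset_s = "numeric", subtype = "character",
                    amplitude_deg = "numeric", peak_speed_dps = "numeric",
                    success = "logical", err_x_deg = "numeric",
                    err_y_deg = "numeric", trial_id = "character",
                    period_id = "character")
lick_schema <- c(event_id = "character", session_id = "character",
                 onset_s = "numeric", subtype = "character",
                 amplitude_mm = "numeric", peak_speed_pro_mmps = "numeric",
                 peak_speed_ret_mmps = "numeric", success = "logical",
                 bout_id = "character", period_id = "character")
pupil_schema <- c(time_s = "numeric", area = "numeric")
meta_schema <- c(session_id = "character", subject_id = "character",
                 tube_distance_mm = "numeric", tube_side_schedule = "character",
                 food_increment_mL = "numeric")

check_table <- function(df, schema, file, sorted_by = NULL) {
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in names(schema)) {
    cast <- switch(schema[[col]],
                   numeric = as.numeric, character = as.character,
                   logical = as.logical)
    df[[col]] <- cast(df[[col]])
    bad <- which(is.na(df[[col]]) & schema[[col]] != "character")
    if (schema[[col]] != "character" && length(bad)) {
      stop(sprintf("%s: column %s has missing/unparseable value at row %d",
                   file, col, bad[1]), call. = FALSE)
    }
  }
  if (!is.null(sorted_by)) {
    if (is.unsorted(df[[sorted_by]])) {
      stop(sprintf("%s: %s must be nonnegative and sorted", file, sorted_by),
           call. = FALSE)
    }
    if (nrow(df) && min(df[[sorted_by]]) < 0) {
      stop(sprintf("%s: %s must be nonnegative and sorted", file, sorted_by),
           call. = FALSE)
    }
  }
  df
}

#' Read a session directory into validated event tables
#'
#' A session lives in a directory of four delimited files --
#' `saccades.csv`, `licks.csv`, `pupil.csv`, `meta.csv` -- with the
#' documented schemas. Tables are type-checked on read; unknown columns
#' are preserved; missing required columns are fatal with the file,
#' column, and row named. A missing pupil table degrades gracefully:
#' the session loads with pupil analyses disabled and a warning.
#'
#' @param path Session directory.
#' @return A `session_tables` list: `saccades`, `licks`, `pupil` (possibly
#'   `NULL`), `meta`.
#' @seealso [write_session()]
#' @export
read_session <- function(path) {
  stopifnot(dir.exists(path))
  rd <- function(f) {
    utils::read.csv(file.path(path, f), stringsAsFactors = FALSE,
                    comment.char = "#") |> tibble::as_tibble()
  }
  for (f in c("saccades.csv", "licks.csv", "meta.csv")) {
    if (!file.exists(file.path(path, f))) {
      stop("session is missing required file: ", f, call. = FALSE)
    }
  }
  saccades <- check_table(rd("saccades.csv"), saccade_schema,
                          "saccades.csv", sorted_by = "onset_s")
  licks <- check_table(rd("licks.csv"), lick_schema,
                       "licks.csv", sorted_by = "onset_s")
  pupil <- NULL
  if (file.exists(file.path(path, "pupil.csv"))) {
    pupil <- check_table(rd("pupil.csv"), pupil_schema, "pupil.csv",
                         sorted_by = "time_s")
  } else {
    warning("no pupil.csv: pupil analyses disabled for this session",
            call. = FALSE)
  }
  meta <- check_table(rd("meta.csv"), meta_schema, "meta.csv")
  if (nrow(meta) != 1) stop("meta.csv must have exactly one row", call. = FALSE)
  structure(list(saccades = saccades, licks = licks, pupil = pupil,
                 meta = meta),
            class = "session_tables")
}

#' Write session tables to a directory of CSV files
#'
#' @param session A `session_tables` list (ground truth, if present, is
#'   written to `ground_truth_periods.csv` alongside; the label marks the
#'   tables as synthetic).
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) {
    utils::write.csv(df, file.path(path, f), row.names = FALSE)
  }
  wr(session$saccades, "saccades.csv")
  wr(session$licks, "licks.csv")
  if (!is.null(session$pupil)) wr(session$pupil, "pupil.csv")
  wr(session$meta, "meta.csv")
  if (!is.null(session$ground_truth)) {
    wr(session$ground_truth$periods, "ground_truth_periods.csv")
  }
  invisible(path)
}
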