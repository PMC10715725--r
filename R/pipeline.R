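#' Analysis configuration
#'
#' Every threshold of the behavioral pipeline in one place.
#'
#' @param criterion_radius_deg Saccade success radius. Default 1.25.
#' @param bout_gap_s Inter-lick gap that ends a harvest. Default 0.5.
#' @param vigor_bin Bin width for vigor-binned tables. Default 0.05.
#' @param bin_floor Minimum events per retained bin. Default 10.
#' @param pupil_window_s Half-width of the event-locked pupil window.
#'   Default 0.25.
#' @param lick_anchor Pupil anchor for licks: `"apex"` (moment of peak
#'   tongue displacement; default) or `"onset"`.
#' @param velocity_threshold_dps,velocity_offset_dps Saccade-detection
#'   onset and offset speed thresholds. Defaults 50 and 30.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(criterion_radius_deg = 1.25, bout_gap_s = 0.5,
                            vigor_bin = 0.05, bin_floor = 10,
                            pupil_window_s = 0.25,
                            lick_anchor = c("apex", "onset"),
                            velocity_threshold_dps = 50,
                            velocity_offset_dps = 30) {
  lick_anchor <- match.arg(lick_anchor)
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the full behavioral analysis pipeline on one session
#'
#' Orchestrates the session-level analyses: fits the saccade and lick
#' main sequences (pooled over the session's movements), computes
#' per-movement vigor, segments the session into work and harvest
#' periods, computes event-locked pupil z-scores, and produces the binned
#' summaries -- lick vigor vs. pupil, saccade vigor vs. trial number,
#' endpoint accuracy vs. vigor -- the conditional (post-success vs.
#' post-failure) lick-vigor change, and period summaries. Deterministic
#' for deterministic inputs.
#'
#' @param session A `session_tables` list from [read_session()] or
#'   [generate_session()].
#' @param config An [analysis_config()].
#' @param ms_saccade,ms_lick Optional pre-fitted main-sequence parameters
#'   (e.g. pooled across sessions); fitted from this session's data when
#'   absent.
#' @return A `pipeline_results` list: `periods`, `saccades`, `licks`
#'   (with `vigor`, `pupil_z`, derived `period_id`), `ms_fits`,
#'   `binned` (list of binned tables), `correlations` (tibble),
#'   `vigor_change`, `summaries`, `config_hash`.
#' @export
run_pipeline <- function(session, config = analysis_config(),
                         ms_saccade = NULL, ms_lick = NULL) {
  stopifnot(inherits(session, "session_tables"),
            inherits(config, "analysis_config"))
  sac <- session$saccades
  lick <- session$licks
  ## --- vigor ---
  rr <- sac$subtype %in% c("center", "primary", "corrective")
  if (is.null(ms_saccade)) {
    ms_saccade <- fit_main_sequence(sac$amplitude_deg[rr],
                                    sac$peak_speed_dps[rr], "saccade",
                                    subject_id = session$meta$subject_id[1])
  }
  sac$vigor <- compute_vigor(sac$peak_speed_dps, sac$amplitude_deg, ms_saccade)
  if (nrow(lick) >= 50) {
    if (is.null(ms_lick)) {
      ms_lick <- fit_main_sequence(lick$amplitude_mm,
                                   lick$peak_speed_pro_mmps,
                                   "lick_protraction",
                                   subject_id = session$meta$subject_id[1])
    }
    lick$vigor <- compute_vigor(lick$peak_speed_pro_mmps, lick$amplitude_mm,
                                ms_lick)
    lick$vigor_ret <- compute_vigor(lick$peak_speed_ret_mmps,
                                    lick$amplitude_mm, ms_lick)
  } else {
    ms_lick <- NULL
    lick$vigor <- rep(NA_real_, nrow(lick))
    lick$vigor_ret <- rep(NA_real_, nrow(lick))
  }
  ## --- segmentation (re-derived from events, generator labels ignored) ---
  seg <- segment_periods(
    dplyr::select(sac, -dplyr::any_of("period_id")),
    dplyr::select(lick, -dplyr::any_of("period_id")),
    bout_gap_s = config$bout_gap_s)
  periods <- seg$periods
  periods$tube_distance <- session$meta$tube_distance_mm[1]
  sac <- seg$saccades
  lick <- seg$licks
  ## --- pupil ---
  have_pupil <- !is.null(session$pupil)
  if (have_pupil) {
    lick_anchor <- if (config$lick_anchor == "apex" &&
                       "apex_s" %in% names(lick)) {
      lick$apex_s
    } else {
      # apex approximated as onset + half the inter-lick interval floor
      lick$onset_s + 0.05
    }
    pz_s <- pupil_zscore(session$pupil, sac$onset_s[rr],
                         window_s = config$pupil_window_s)
    pz_l <- pupil_zscore(session$pupil, lick_anchor,
                         window_s = config$pupil_window_s)
    sac$pupil_z <- NA_real_
    sac$pupil_z[which(rr)[match(pz_s$anchor_s, sac$onset_s[rr])]] <- pz_s$z
    lick$pupil_z <- pz_l$z[match(lick_anchor, pz_l$anchor_s)]
  } else {
    sac$pupil_z <- NA_real_
    lick$pupil_z <- NA_real_
  }
  ## --- binned relations ---
  binned <- list()
  correlations <- list()
  if (have_pupil && any(is.finite(lick$vigor))) {
    bc <- binned_correlation(lick$vigor, lick$pupil_z,
                             bin_size = config$vigor_bin,
                             min_n = config$bin_floor)
    binned$lick_vigor_pupil <- bc$bins
    correlations$lick_vigor_pupil <- tibble::tibble(
      relation = "lick_vigor_pupil", r = bc$r, p = bc$p, n = bc$n_bins)
  }
  if ("trial_index_in_period" %in% names(sac)) {
    prim <- sac[sac$subtype == "primary", ]
    binned$saccade_vigor_by_trial <- prim |>
      dplyr::group_by(trial_index = .data$trial_index_in_period) |>
      dplyr::summarise(mean_vigor = mean(.data$vigor),
                       sem = stats::sd(.data$vigor) / sqrt(dplyr::n()),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::filter(.data$n >= config$bin_floor)
  }
  prim <- sac[sac$subtype == "primary" & is.finite(sac$err_x_deg), ]
  if (nrow(prim) > 0) {
    binned$endpoint_error <- endpoint_error_stats(
      prim$vigor, prim$err_x_deg, prim$err_y_deg,
      bin_size = config$vigor_bin, min_n = config$bin_floor)
  }
  # work-period duration vs mean pupil during the period
  if (have_pupil) {
    wp <- periods[periods$kind == "work" & !periods$partial, ]
    mean_pz <- vapply(wp$period_id, function(pid) {
      mean(sac$pupil_z[sac$period_id == pid], na.rm = TRUE)
    }, numeric(1))
    dur <- wp$n_attempted
    okp <- is.finite(mean_pz)
    if (sum(okp) >= 3) {
      ct <- stats::cor.test(dur[okp], mean_pz[okp])
      correlations$work_duration_pupil <- tibble::tibble(
        relation = "work_duration_pupil", r = unname(ct$estimate),
        p = ct$p.value, n = sum(okp))
    }
  }
  ## --- conditional vigor change & summaries ---
  vigor_change <- if (any(is.finite(lick$vigor))) {
    conditional_vigor_change(lick[is.finite(lick$vigor), ])
  } else {
    conditional_vigor_change(lick[0, ])
  }
  summaries <- list(
    by_tube_distance = period_summaries(
      periods, lick, "tube_distance",
      food_increment_mL = session$meta$food_increment_mL[1]),
    by_prior_work = period_summaries(
      periods, lick, "prior_work_trials",
      food_increment_mL = session$meta$food_increment_mL[1]))
  structure(
    list(periods = periods, saccades = sac, licks = lick,
         ms_fits = list(saccade = ms_saccade, lick = ms_lick),
         binned = binned,
         correlations = dplyr::bind_rows(c(
           list(tibble::tibble(relation = character(), r = numeric(),
                               p = numeric(), n = integer())),
           unname(correlations))),
         vigor_change = vigor_change, summaries = summaries,
         config_hash = rlang::hash(config)),
    class = "pipeline_results")
}

#' @export
print.pipeline_results <- function(x, ...) {
  cat("<pipeline_results>\n")
  cat(sprintf("  %d periods (%d work, %d harvest)\n", nrow(x$periods),
              sum(x$periods$kind == "work"), sum(x$periods$kind == "harvest")))
  if (nrow(x$correlations)) {
    for (i in seq_len(nrow(x$correlations))) {
      cat(sprintf("  %s: r = %.3f (n = %d)\n", x$correlations$relation[i],
                  x$correlations$r[i], x$correlations$n[i]))
    }
  }
  invisible(x)
}

#' Write pipeline results as figure-ready CSV files
#'
#' Each output table carries the analysis config hash in a leading
#' comment line, so results can be traced to the exact thresholds used.
#'
#' @param results A `pipeline_results` list.
#' @param path Output directory.
#' @param seed Optional seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_pipeline_results <- function(results, path, seed = NA) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# config_hash: %s; seed: %s", results$config_hash, seed)
  wr <- function(df, f) {
    con <- file(file.path(path, f), "w")
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  wr(results$periods, "periods.csv")
  wr(results$correlations, "correlations.csv")
  wr(results$vigor_change, "vigor_change.csv")
  for (nm in names(results$binned)) {
    wr(results$binned[[nm]], paste0("binned_", nm, ".csv"))
  }
  for (nm in names(results$summaries)) {
    wr(results$summaries[[nm]], paste0("summary_", nm, ".csv"))
  }
  invisible(path)
}
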