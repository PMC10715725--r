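#' Configuration for the synthetic-session generator
#'
#' Defines the statistical structure of a generated foraging session:
#' alternating work periods (about 8--9 attempted saccade trials, half of
#' them successful) and harvest periods (about 17 licks, roughly 30%
#' contacting food), amplitude--velocity main-sequence kinematics with
#' multiplicative vigor noise, slow within-period vigor dynamics, a
#' vigor-coupled pupil trace, post-success lick reinforcement, a
#' vigor-dependent saccade endpoint-error scale, and a per-session tube
#' distance condition. Every random quantity derives from `seed`.
#'
#' @param seed Integer seed; mandatory, there is no implicit randomness.
#' @param n_cycles Work--harvest pairs in the session. Default 50.
#' @param policy Either `list(mode = "fixed", attempts_mean, attempts_sd,
#'   licks_mean, licks_sd)` (defaults 8.5, 1.5, 17, 2) or
#'   `list(mode = "model", params = policy_params(...))`, in which case
#'   the mean counts come from the optimal policy at the session's tube
#'   distance.
#' @param tube_distance_mm Tube-to-mouth distance condition. Default 7.
#' @param beta_s,beta_l Trial and lick success probabilities. Defaults
#'   0.5 and 0.30.
#' @param ms_saccade,ms_lick Main-sequence parameters used to draw
#'   kinematics (see [main_sequence_params()]).
#' @param retraction_gain Multiplier on lick retraction speed relative to
#'   the shared lick main sequence (retraction is the more vigorous
#'   phase). Default 1.1.
#' @param vigor_noise_sdlog SD of the multiplicative (lognormal) speed
#'   noise. Default 0.10.
#' @param work_vigor_start,work_vigor_decay Saccade-vigor level at the
#'   first trial of a work period and its per-trial decline. Defaults
#'   1.05 and 0.01.
#' @param harvest_vigor_start,harvest_vigor_peak,harvest_vigor_decay
#'   Lick-vigor level at the first lick, the peak reached by the third
#'   lick, and the per-lick decline thereafter. Defaults 0.95, 1.05,
#'   0.005.
#' @param lick_vigor_gain Overall multiplier on lick vigor (the tube
#'   distance condition acts here). Default 1.
#' @param reward_magnitude_gain Fractional increase in the harvest's
#'   lick-vigor level per successful trial cached beyond four. Default
#'   0.05.
#' @param reinforcement_delta Persistent lick-vigor increment after a
#'   successful (food-contacting) lick. Default 0.03.
#' @param pupil_baseline,pupil_gain,pupil_noise_sd Pupil area baseline,
#'   gain of the affine vigor-to-pupil coupling (fraction of baseline per
#'   unit vigor), and white-noise SD. Defaults 1000, 0.5, 15. Set
#'   `pupil_gain = 0` for a coupling-off session.
#' @param error_sd_deg,accuracy_gain Saccade endpoint-error SD at vigor 1
#'   and its fractional decrease per unit vigor above 1 (accuracy
#'   improves with vigor). Defaults 0.5 and 1.
#' @param food_increment_mL Food per successful trial. Default 0.015.
#' @param trial_duration_s,inter_lick_s,period_gap_s Timing. Defaults
#'   1.25, 0.33, 1.
#' @param pupil_rate_hz Pupil sampling rate. Default 50.
#' @param session_id,subject_id Labels.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed,
                             n_cycles = 50,
                             policy = list(mode = "fixed", attempts_mean = 8.5,
                                           attempts_sd = 1.5, licks_mean = 17,
                                           licks_sd = 2),
                             tube_distance_mm = 7,
                             beta_s = 0.5, beta_l = 0.30,
                             ms_saccade = main_sequence_params(600, 0.15, "saccade"),
                             ms_lick = main_sequence_params(180, 0.12, "lick_protraction"),
                             retraction_gain = 1.1,
                             vigor_noise_sdlog = 0.10,
                             work_vigor_start = 1.05, work_vigor_decay = 0.01,
                             harvest_vigor_start = 0.95,
                             harvest_vigor_peak = 1.05,
                             harvest_vigor_decay = 0.005,
                             lick_vigor_gain = 1,
                             reward_magnitude_gain = 0.05,
                             reinforcement_delta = 0.03,
                             pupil_baseline = 1000, pupil_gain = 0.5,
                             pupil_noise_sd = 15,
                             error_sd_deg = 0.5, accuracy_gain = 1,
                             food_increment_mL = 0.015,
                             trial_duration_s = 1.25, inter_lick_s = 0.33,
                             period_gap_s = 1, pupil_rate_hz = 50,
                             session_id = "S001", subject_id = "synthA") {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(n_cycles >= 1, beta_s > 0, beta_s <= 1, beta_l > 0, beta_l <= 1,
            vigor_noise_sdlog >= 0, trial_duration_s > 0, inter_lick_s > 0,
            pupil_rate_hz > 0, tube_distance_mm >= 0)
  structure(as.list(environment()), class = "generator_config")
}

# deterministic per-cycle policy draws
draw_counts <- function(cfg) {
  if (identical(cfg$policy$mode, "model")) {
    sol <- optimal_policy(cfg$policy$params)
    att <- sol$n_s / cfg$beta_s
    lk <- sol$n_l
    sd_a <- 1.5; sd_l <- 2
  } else {
    att <- cfg$policy$attempts_mean; sd_a <- cfg$policy$attempts_sd
    lk <- cfg$policy$licks_mean; sd_l <- cfg$policy$licks_sd
  }
  list(
    attempts = pmax(3L, pmin(14L, round(stats::rnorm(cfg$n_cycles, att, sd_a)))),
    licks = pmax(5L, pmin(40L, round(stats::rnorm(cfg$n_cycles, lk, sd_l)))))
}

#' Generate one synthetic foraging session
#'
#' Produces the full bundle of session tables -- saccade events, lick
#' events, a pupil trace, session metadata -- plus a ground-truth record
#' (true period boundaries, true vigor levels, true couplings) for
#' parameter-recovery testing. Deterministic given the config seed: the
#' same config yields identical tables.
#'
#' @param config A [generator_config()].
#' @return A list of class `session_tables` with elements `saccades`,
#'   `licks`, `pupil`, `meta`, and a `ground_truth` list (`periods`,
#'   `config`, true per-event vigor levels inside the event tables'
#'   `true_vigor` column).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)
  counts <- draw_counts(cfg)
  sac_rows <- list(); lick_rows <- list(); per_rows <- list()
  t <- 1.0  # session clock, s
  ev <- 0L
  noise <- function(n) exp(stats::rnorm(n, 0, cfg$vigor_noise_sdlog))
  for (cy in seq_len(cfg$n_cycles)) {
    ## ---- work period ----
    n_att <- counts$attempts[cy]
    succ <- stats::runif(n_att) < cfg$beta_s
    w_start <- t
    for (tr in seq_len(n_att)) {
      level <- cfg$work_vigor_start - cfg$work_vigor_decay * (tr - 1)
      subtypes <- c("center", "primary", "corrective")
      amps <- c(stats::runif(1, 3, 8), stats::runif(1, 4, 7),
                stats::runif(1, 1, 2.5))
      onsets <- t + c(0, 0.45, 0.8) + stats::runif(3, 0, 0.03)
      vig <- level * noise(3)
      spd <- expected_peak_speed(cfg$ms_saccade, amps) * vig
      esd <- cfg$error_sd_deg *
        pmax(0.2, 1 - cfg$accuracy_gain * (vig - 1))
      err <- cbind(stats::rnorm(3, 0, esd), stats::rnorm(3, 0, esd))
      sac_rows[[length(sac_rows) + 1L]] <- tibble::tibble(
        event_id = sprintf("sac%05d", ev + seq_len(3)),
        session_id = cfg$session_id, onset_s = onsets, subtype = subtypes,
        amplitude_deg = amps, peak_speed_dps = spd,
        success = succ[tr], err_x_deg = err[, 1], err_y_deg = err[, 2],
        trial_id = sprintf("T%04d", (cy - 1L) * 20L + tr),
        period_id = sprintf("W%03d", cy),
        trial_index_in_period = tr, true_vigor = vig)
      ev <- ev + 3L
      t <- t + cfg$trial_duration_s
    }
    w_end <- t - cfg$trial_duration_s +
      0.8 + 0.03  # last corrective onset upper bound
    n_succ <- sum(succ)
    per_rows[[length(per_rows) + 1L]] <- tibble::tibble(
      period_id = sprintf("W%03d", cy), kind = "work",
      start_s = w_start, end_s = w_end,
      n_attempted = n_att, n_success = n_succ, n_licks = 0L)
    t <- t + cfg$period_gap_s
    ## ---- harvest period ----
    n_lk <- counts$licks[cy]
    h_start <- t
    base <- cfg$lick_vigor_gain *
      (1 + cfg$reward_magnitude_gain * (n_succ - 4) / 4)
    ramp <- ifelse(seq_len(n_lk) <= 3,
                   cfg$harvest_vigor_start +
                     (cfg$harvest_vigor_peak - cfg$harvest_vigor_start) *
                     (seq_len(n_lk) - 1) / 2,
                   cfg$harvest_vigor_peak -
                     cfg$harvest_vigor_decay * (seq_len(n_lk) - 3))
    lk_succ <- stats::runif(n_lk) < cfg$beta_l
    # persistent within-bout reinforcement after each food contact
    boost <- cfg$reinforcement_delta *
      c(0, cumsum(lk_succ))[seq_len(n_lk)]
    level <- base * ramp + boost
    amps <- pmax(1, cfg$tube_distance_mm + stats::rnorm(n_lk, 0, 0.8))
    vig <- level * noise(n_lk)
    pro <- expected_peak_speed(cfg$ms_lick, amps) * vig
    ret <- pro * cfg$retraction_gain * exp(stats::rnorm(n_lk, 0, 0.03))
    subtype <- sample(c("inner_tube", "outer_edge", "under_tube"),
                      n_lk, replace = TRUE, prob = c(0.55, 0.28, 0.17))
    onsets <- t + (seq_len(n_lk) - 1) * cfg$inter_lick_s
    lick_rows[[length(lick_rows) + 1L]] <- tibble::tibble(
      event_id = sprintf("lick%05d", ev + seq_len(n_lk)),
      session_id = cfg$session_id, onset_s = onsets, subtype = subtype,
      amplitude_mm = amps, peak_speed_pro_mmps = pro,
      peak_speed_ret_mmps = ret, success = lk_succ,
      bout_id = sprintf("B%03d", cy), period_id = sprintf("H%03d", cy),
      lick_index_in_bout = seq_len(n_lk), true_vigor = vig)
    ev <- ev + n_lk
    t <- onsets[n_lk]
    per_rows[[length(per_rows) + 1L]] <- tibble::tibble(
      period_id = sprintf("H%03d", cy), kind = "harvest",
      start_s = h_start, end_s = t,
      n_attempted = 0L, n_success = 0L, n_licks = n_lk)
    t <- t + cfg$period_gap_s
  }
  saccades <- dplyr::bind_rows(sac_rows)
  licks <- dplyr::bind_rows(lick_rows)
  ## ---- pupil trace: baseline + event-locked vigor coupling + noise ----
  t_end <- t + 2
  times <- seq(0, t_end, by = 1 / cfg$pupil_rate_hz)
  area <- rep(cfg$pupil_baseline, length(times))
  # +/-150 ms plateau per event: narrower than the inter-event spacing, so
  # no event's window is contaminated by its neighbor's coupling
  bump <- function(anchor, vig) {
    i <- findInterval(anchor - 0.15, times) + 1L
    j <- findInterval(anchor + 0.15, times)
    if (j >= i) {
      area[i:j] <<- cfg$pupil_baseline *
        (1 + cfg$pupil_gain * (vig - 1))
    }
  }
  rr <- saccades$subtype %in% c("center", "primary", "corrective")
  for (i in which(rr)) bump(saccades$onset_s[i], saccades$true_vigor[i])
  for (i in seq_len(nrow(licks))) bump(licks$onset_s[i], licks$true_vigor[i])
  area <- area + stats::rnorm(length(times), 0, cfg$pupil_noise_sd)
  pupil <- tibble::tibble(time_s = times, area = area)
  meta <- tibble::tibble(
    session_id = cfg$session_id, subject_id = cfg$subject_id,
    tube_distance_mm = cfg$tube_distance_mm,
    tube_side_schedule = "left", food_increment_mL = cfg$food_increment_mL)
  structure(
    list(saccades = saccades, licks = licks, pupil = pupil, meta = meta,
         ground_truth = list(
           periods = dplyr::bind_rows(per_rows),
           reinforcement_delta = cfg$reinforcement_delta,
           pupil_gain = cfg$pupil_gain,
           lick_vigor_gain = cfg$lick_vigor_gain,
           retraction_gain = cfg$retraction_gain,
           config = cfg)),
    class = "session_tables")
}

#' @export
print.session_tables <- function(x, ...) {
  cat("<session_tables>", x$meta$session_id[1], "\n")
  cat(sprintf("  %d saccades, %d licks, %d pupil samples\n",
              nrow(x$saccades), nrow(x$licks), nrow(x$pupil)))
  if (!is.null(x$ground_truth)) {
    cat(sprintf("  ground truth: %d periods\n", nrow(x$ground_truth$periods)))
  }
  invisible(x)
}

#' Canned fixture suite for recovery tests
#'
#' Generates a named set of small sessions covering the cases the
#' analysis pipeline must recover: pupil--vigor coupling on and off,
#' three tube-distance conditions (near/mid/far, with more trials worked
#' and lower lick vigor as the tube moves away), and a zero-lick edge
#' case. Regenerates identically from `base_seed`.
#'
#' @param base_seed Integer; each fixture uses a fixed offset from it.
#' @param n_cycles Cycles per fixture. Default 40.
#' @return Named list of `session_tables`.
#' @export
make_fixture_suite <- function(base_seed, n_cycles = 40) {
  fix <- list(
    coupling_on = generator_config(seed = base_seed + 1L,
                                   n_cycles = n_cycles,
                                   session_id = "FIX-ON"),
    coupling_off = generator_config(seed = base_seed + 2L,
                                    n_cycles = n_cycles, pupil_gain = 0,
                                    session_id = "FIX-OFF"),
    near = generator_config(seed = base_seed + 3L, n_cycles = n_cycles,
                            tube_distance_mm = 5, lick_vigor_gain = 1.05,
                            policy = list(mode = "fixed", attempts_mean = 7,
                                          attempts_sd = 1.5, licks_mean = 18,
                                          licks_sd = 2),
                            session_id = "FIX-NEAR"),
    mid = generator_config(seed = base_seed + 4L, n_cycles = n_cycles,
                           tube_distance_mm = 7, lick_vigor_gain = 1,
                           session_id = "FIX-MID"),
    far = generator_config(seed = base_seed + 5L, n_cycles = n_cycles,
                           tube_distance_mm = 10, lick_vigor_gain = 0.92,
                           policy = list(mode = "fixed", attempts_mean = 10,
                                         attempts_sd = 1.5, licks_mean = 16,
                                         licks_sd = 2),
                           session_id = "FIX-FAR"))
  out <- lapply(fix, generate_session)
  # zero-lick edge case: a single work period, no harvest
  zl <- generate_session(generator_config(seed = base_seed + 6L,
                                          n_cycles = 1,
                                          session_id = "FIX-ZEROLICK"))
  zl$licks <- zl$licks[0, ]
  zl$ground_truth$periods <-
    zl$ground_truth$periods[zl$ground_truth$periods$kind == "work", ]
  out$zero_lick <- zl
  out
}
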