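# Shared fixtures, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

base_params <- function(c_l = 0.5) {
  policy_params(alpha = 20, beta_s = 0.5, beta_l = 0.3,
                c_s = 0.5, T_s = 1, T_l = 0.2, c_l = c_l)
}

distance_params <- function(d = 0.2, alpha = 20) {
  policy_params(alpha = alpha, beta_s = 0.5, beta_l = 0.3,
                c_s = 0.5, T_s = 1, T_l = 0.2, d = d, k = 1)
}

# Suite used by the pipeline-recovery tests; seed fixed and documented.
get_suite <- function(n_cycles = 120) {
  key <- paste0("suite", n_cycles)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- make_fixture_suite(101, n_cycles = n_cycles)
  }
  .fixture_env[[key]]
}

get_pipeline <- function(which = "coupling_on", n_cycles = 120) {
  key <- paste0("pipe.", which, n_cycles)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- run_pipeline(get_suite(n_cycles)[[which]])
  }
  .fixture_env[[key]]
}

# Minimum-jerk gaze trace with saccades injected at known times (1 kHz).
# Ground-truth onset = first sample where the noiseless speed reaches the
# detection threshold.
make_gaze_trace <- function(onsets_s, amplitudes_deg, duration_s = 0.04,
                            total_s = NULL, fs = 1000,
                            onset_threshold = 50) {
  if (is.null(total_s)) total_s <- max(onsets_s) + 0.5
  t <- seq(0, total_s, by = 1 / fs)
  x <- numeric(length(t))
  true_onsets <- numeric(length(onsets_s))
  pos <- 0
  for (i in seq_along(onsets_s)) {
    tau <- (t - onsets_s[i]) / duration_s
    tau <- pmin(pmax(tau, 0), 1)
    prof <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
    x <- x + amplitudes_deg[i] * prof
    v <- amplitudes_deg[i] / duration_s *
      (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
    true_onsets[i] <- t[which(v >= onset_threshold)[1]]
  }
  list(time_s = t, x_deg = x, y_deg = numeric(length(t)),
       true_onsets = true_onsets)
}
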