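#' Simulation configuration for dynein-like stepping traces
#'
#' Builds and validates the parameter set consumed by [simulate_trace()].
#' Defaults describe the stepping behaviour reported for endogenous dynein
#' tracked at nanometre precision in live neurons: ~8.7 nm forward steps with
#' 3.8 nm spread, backstep probability 0.04, single-exponential dwell times at
#' 90 s^-1, isotropic localization noise of 3.5 nm, millisecond sampling, and
#' exponential photobleach truncation of traces up to 3 s long.
#'
#' The motion-state chain has four states: `retrograde`, `anterograde`,
#' `pause`, `reversal`. State durations are exponential with the configured
#' means. By default transitions follow the run/event alternation of axonal
#' cargo: a processive run is interrupted by a pause (resuming the same
#' direction) or a reversal (after which the direction flips); the
#' `transition_weights` rows for pause and reversal are then resolved by this
#' memory rule rather than sampled (set `memory_rules = FALSE` to sample them
#' from the matrix instead).
#'
#' @param states character vector of motion states (fixed set, order free).
#' @param state_means_ms named numeric, mean duration (ms) per state.
#' @param transition_weights row-stochastic matrix of exit weights between
#'   states (no self transitions; diagonal must be 0).
#' @param memory_rules logical; if `TRUE`, pauses resume the preceding
#'   direction and reversals flip it.
#' @param start_state state the trace starts in.
#' @param step_mean_nm,step_sd_nm,step_min_nm forward step-size
#'   truncated-normal parameters (nm). The default lower bound of 4 nm
#'   matches the observed on-axis step-size support (4-16 nm) of dynein
#'   under load in cells; note the truncated distribution's mean then
#'   exceeds `step_mean_nm` (use [truncnorm_mu_for_mean()] to configure an
#'   exact target mean).
#' @param p_back probability that a step is backward (against the current
#'   run direction).
#' @param off_axis_sd_nm spread (nm) of the zero-mean Gaussian off-axis
#'   component of every step.
#' @param p_off_jump,off_jump_nm probability and magnitude of additional
#'   large lateral jumps (protofilament/track changes, > 25 nm scale).
#' @param dwell_model one of `"exp1"`, `"erlang2"`, `"hypoexp2"`.
#' @param dwell_rates_s numeric rates in s^-1 (one rate for exp1/erlang2,
#'   two distinct rates for hypoexp2).
#' @param p_tug probability that a pause/reversal event contains tug-of-war
#'   stepping (alternating +/- full-size steps with no net displacement).
#' @param sigma_loc_nm isotropic Gaussian localization noise sd (nm).
#' @param dt_ms sampling interval (ms).
#' @param bleach_mean_s mean of the exponential photobleach lifetime (s).
#' @param max_duration_ms maximum trace duration (ms); the realised duration
#'   is `min(max_duration_ms, bleach time)`.
#' @param axis_angle_rad lab-frame angle of the retrograde direction
#'   (radians); the default `pi` points retrograde along -x.
#' @param seed integer seed; mandatory so simulated cohorts are reproducible.
#'
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$step_mean_nm
#' @export
sim_config <- function(states = c("retrograde", "anterograde", "pause", "reversal"),
                       state_means_ms = c(retrograde = 500, anterograde = 400,
                                          pause = 150, reversal = 15),
                       transition_weights = NULL,
                       memory_rules = TRUE,
                       start_state = "retrograde",
                       step_mean_nm = 8.7,
                       step_sd_nm = 3.8,
                       step_min_nm = 4,
                       p_back = 0.04,
                       off_axis_sd_nm = 3,
                       p_off_jump = 0.01,
                       off_jump_nm = 30,
                       dwell_model = c("exp1", "erlang2", "hypoexp2"),
                       dwell_rates_s = 90,
                       p_tug = 0.102,
                       sigma_loc_nm = 3.5,
                       dt_ms = 1,
                       bleach_mean_s = 1.5,
                       max_duration_ms = 3000,
                       axis_angle_rad = pi,
                       seed = NULL) {
  dwell_model <- match.arg(dwell_model)
  known <- c("retrograde", "anterograde", "pause", "reversal")
  if (!all(states %in% known)) {
    stopf("states must be drawn from {%s}", paste(known, collapse = ", "))
  }
  if (is.null(transition_weights)) {
    transition_weights <- default_transition_weights(states)
  }
  transition_weights <- as.matrix(transition_weights)
  cfg <- structure(list(
    states = states,
    state_means_ms = state_means_ms[states],
    transition_weights = transition_weights,
    memory_rules = isTRUE(memory_rules),
    start_state = start_state,
    step_mean_nm = step_mean_nm, step_sd_nm = step_sd_nm,
    step_min_nm = step_min_nm,
    p_back = p_back,
    off_axis_sd_nm = off_axis_sd_nm,
    p_off_jump = p_off_jump, off_jump_nm = off_jump_nm,
    dwell_model = dwell_model, dwell_rates_s = dwell_rates_s,
    p_tug = p_tug,
    sigma_loc_nm = sigma_loc_nm,
    dt_ms = dt_ms,
    bleach_mean_s = bleach_mean_s,
    max_duration_ms = max_duration_ms,
    axis_angle_rad = axis_angle_rad,
    seed = seed
  ), class = "sim_config")
  validate_sim_config(cfg)
}

default_transition_weights <- function(states) {
  n <- length(states)
  w <- matrix(0, n, n, dimnames = list(states, states))
  half <- function(targets) {
    avail <- intersect(targets, states)
    if (length(avail) == 0) return(NULL)
    rep(1 / length(avail), length(avail))
  }
  for (s in intersect(c("retrograde", "anterograde"), states)) {
    tg <- intersect(c("pause", "reversal"), states)
    if (length(tg) == 0) tg <- setdiff(states, s)
    if (length(tg) > 0) w[s, tg] <- 1 / length(tg)
  }
  for (s in intersect(c("pause", "reversal"), states)) {
    tg <- intersect(c("retrograde", "anterograde"), states)
    w[s, tg] <- 1 / length(tg)
  }
  # single-state chains have no exits; keep an all-zero row (never used)
  w
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (any(!is.finite(state_means_ms)) || any(state_means_ms <= 0)) {
      stopf("state mean durations must be positive")
    }
    if (!start_state %in% states) stopf("start_state not in states")
    if (!identical(dim(transition_weights),
                   c(length(states), length(states)))) {
      stopf("transition_weights must be %d x %d", length(states),
            length(states))
    }
    if (any(diag(transition_weights) != 0)) {
      stopf("transition_weights diagonal must be zero (no self transitions)")
    }
    if (length(states) > 1) {
      rs <- rowSums(transition_weights)
      if (any(abs(rs - 1) > 1e-8)) {
        stopf("transition weight rows must sum to 1 (got %s)",
              paste(signif(rs, 4), collapse = ", "))
      }
    }
    if (step_sd_nm < 0 || step_mean_nm <= 0) {
      stopf("forward step-size parameters must be positive")
    }
    if (p_back < 0 || p_back > 1) stopf("p_back must lie in [0, 1]")
    if (p_tug < 0 || p_tug > 1) stopf("p_tug must lie in [0, 1]")
    if (off_axis_sd_nm < 0 || off_jump_nm < 0 ||
        p_off_jump < 0 || p_off_jump > 1) {
      stopf("off-axis parameters out of range")
    }
    if (sigma_loc_nm < 0) stopf("sigma_loc_nm must be >= 0")
    if (dt_ms <= 0) stopf("sampling interval must be > 0")
    if (bleach_mean_s <= 0) stopf("bleach_mean_s must be > 0")
    if (max_duration_ms <= 0) stopf("max_duration_ms must be > 0")
    check_dwell_rates(dwell_model, dwell_rates_s)
  })
  cfg
}

check_dwell_rates <- function(model_id, rates) {
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stopf("dwell rates must be positive and finite")
  }
  n_expected <- switch(model_id, exp1 = 1L, erlang2 = 1L, hypoexp2 = 2L,
                       stopf("unknown dwell model '%s'", model_id))
  if (length(rates) != n_expected) {
    stopf("model '%s' needs %d rate(s), got %d", model_id, n_expected,
          length(rates))
  }
  if (model_id == "hypoexp2" && rates[1] == rates[2]) {
    stopf("hypoexp2 requires two distinct rates (use erlang2 for equal rates)")
  }
  invisible(rates)
}
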