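#' Simulate dwell times from the candidate kinetic models
#'
#' Draws i.i.d. waiting times from one of the three stepping-kinetics models:
#' `exp1` (single exponential, density k e^(-k tau)), `erlang2` (convolution
#' of two exponentials with equal rates, k^2 tau e^(-k tau)) and `hypoexp2`
#' (convolution with unequal rates k1 != k2). Rates are in s^-1; samples are
#' returned in ms.
#'
#' @param model_id `"exp1"`, `"erlang2"` or `"hypoexp2"`.
#' @param rates_s rate constant(s) in s^-1 (two distinct values for
#'   `hypoexp2`).
#' @param n number of samples.
#' @param seed optional integer seed.
#' @return Numeric vector of `n` dwell times in ms.
#' @examples
#' mean(simulate_dwell_times("exp1", 90, 1e4, seed = 1)) # ~ 1000/90 ms
#' @export
simulate_dwell_times <- function(model_id, rates_s, n, seed = NULL) {
  if (!is_count(n)) stopf("n must be a positive integer")
  check_dwell_rates(model_id, rates_s)
  set_seed(seed)
  1000 * switch(model_id,
    exp1    = rexp(n, rate = rates_s[1]),
    erlang2 = rgamma(n, shape = 2, rate = rates_s[1]),
    hypoexp2 = rexp(n, rate = rates_s[1]) + rexp(n, rate = rates_s[2])
  )
}

#' Simulate a dynein-like stepping trace with ground truth
#'
#' Generates one 2D localization trace: a semi-Markov motion-state chain
#' (processive retrograde/anterograde runs, pauses, direction reversals)
#' emits steps as a renewal process driven by the configured dwell-time
#' model. Forward step sizes follow a truncated normal; backsteps occur with
#' probability `p_back`; every step carries an off-axis component (Gaussian
#' plus rare large lateral jumps). The true position is piecewise constant
#' between step events; observed positions are the true staircase sampled at
#' the configured cadence plus isotropic Gaussian localization noise. The
#' trace ends at `min(max_duration_ms, exponential bleach time)`.
#'
#' Pauses emit no net steps; reversals flip the run direction at the end of
#' the event. With probability `p_tug` an event instead contains tug-of-war
#' stepping: alternating full-size forward/backward steps with no net
#' displacement.
#'
#' @param config a [sim_config()].
#' @param trace_id identifier for the emitted trace.
#' @param seed integer seed; defaults to `config$seed`.
#' @return A list with elements `trace` (a [localization_trace()]) and
#'   `truth` (class `"ground_truth"`: per-step records with
#'   retrograde-positive on-axis sizes, motion-state intervals tiling the
#'   trace duration, the bleach time and the true axis).
#' @export
simulate_trace <- function(config, trace_id = "sim-1", seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set_seed(seed)
  dt <- config$dt_ms
  bleach_ms <- rexp(1, rate = 1 / (config$bleach_mean_s * 1000))
  total_ms <- min(config$max_duration_ms, bleach_ms)
  if (total_ms < dt) {
    stopf("trace duration %.3f ms is shorter than one sampling interval (%g ms)",
          total_ms, dt)
  }

  ang <- config$axis_angle_rad
  retro_dir <- c(cos(ang), sin(ang))
  perp_dir <- c(-sin(ang), cos(ang))

  intervals <- draw_state_intervals(config, total_ms)
  steps <- draw_steps(config, intervals)

  # true staircase -> sampled, noisy observation
  n_samp <- floor(total_ms / dt) + 1L
  t_samp <- (seq_len(n_samp) - 1L) * dt
  if (nrow(steps) > 0) {
    dx <- steps$s_on_nm * retro_dir[1] + steps$s_off_nm * perp_dir[1]
    dy <- steps$s_on_nm * retro_dir[2] + steps$s_off_nm * perp_dir[2]
    idx <- findInterval(t_samp, steps$t_ms)
    true_x <- c(0, cumsum(dx))[idx + 1L]
    true_y <- c(0, cumsum(dy))[idx + 1L]
  } else {
    true_x <- true_y <- rep(0, n_samp)
  }
  obs_x <- true_x + rnorm(n_samp, 0, config$sigma_loc_nm)
  obs_y <- true_y + rnorm(n_samp, 0, config$sigma_loc_nm)

  trace <- localization_trace(
    trace_id, t_samp, obs_x, obs_y,
    metadata = list(label_site = "DHC", dt_ms = dt, retro_dir = retro_dir)
  )
  truth <- structure(list(
    steps = steps,
    states = intervals,
    bleach_ms = bleach_ms,
    duration_ms = total_ms,
    retro_dir = retro_dir,
    axis_angle_rad = ang
  ), class = "ground_truth")
  list(trace = trace, truth = truth)
}

# exponential-duration semi-Markov state sequence tiling [0, total_ms]
draw_state_intervals <- function(config, total_ms) {
  states <- config$states
  processive <- c("retrograde", "anterograde")
  state <- config$start_state
  prev_dir <- if (state %in% processive) state else "retrograde"
  t0 <- 0
  rec <- list()
  repeat {
    dur <- rexp(1, rate = 1 / config$state_means_ms[[state]])
    t1 <- min(t0 + dur, total_ms)
    rec[[length(rec) + 1L]] <- data.frame(state = state, t_start_ms = t0,
                                          t_end_ms = t1)
    if (state %in% processive) prev_dir <- state
    if (t1 >= total_ms) break
    state <- next_state(config, state, prev_dir)
    t0 <- t1
  }
  do.call(rbind, rec)
}

next_state <- function(config, state, prev_dir) {
  if (length(config$states) == 1L) return(state)
  if (config$memory_rules && state == "pause") return(prev_dir)
  if (config$memory_rules && state == "reversal") {
    return(if (prev_dir == "retrograde") "anterograde" else "retrograde")
  }
  w <- config$transition_weights[state, ]
  if (sum(w) <= 0) return(state)
  sample(config$states, 1L, prob = w)
}

# renewal-process step emission over the state intervals
draw_steps <- function(config, intervals) {
  cols <- c("t_ms", "s_on_nm", "s_off_nm", "state", "is_backstep")
  empty <- data.frame(t_ms = numeric(0), s_on_nm = numeric(0),
                      s_off_nm = numeric(0), state = character(0),
                      is_backstep = logical(0))
  out <- list(empty)
  for (i in seq_len(nrow(intervals))) {
    st <- intervals$state[i]
    a <- intervals$t_start_ms[i]
    b <- intervals$t_end_ms[i]
    if (st %in% c("retrograde", "anterograde")) {
      tms <- renewal_times(config, a, b)
      if (length(tms) == 0) next
      size <- rtruncnorm_lower(length(tms), config$step_mean_nm,
                               config$step_sd_nm, config$step_min_nm)
      back <- runif(length(tms)) < config$p_back
      # retrograde-positive sign convention
      run_sign <- if (st == "retrograde") 1 else -1
      s_on <- run_sign * ifelse(back, -size, size)
      out[[length(out) + 1L]] <- data.frame(
        t_ms = tms, s_on_nm = s_on, s_off_nm = draw_off_axis(config, length(tms)),
        state = st, is_backstep = back)
    } else if (runif(1) < config$p_tug) {
      # tug-of-war stepping inside a pause/reversal: alternating +/- steps
      tms <- renewal_times(config, a, b)
      if (length(tms) == 0) next
      size <- rtruncnorm_lower(length(tms), config$step_mean_nm,
                               config$step_sd_nm, config$step_min_nm)
      sign_seq <- rep_len(c(1, -1), length(tms))
      out[[length(out) + 1L]] <- data.frame(
        t_ms = tms, s_on_nm = sign_seq * size,
        s_off_nm = draw_off_axis(config, length(tms)),
        state = st, is_backstep = sign_seq < 0)
    }
  }
  steps <- do.call(rbind, out)
  steps <- steps[order(steps$t_ms), , drop = FALSE]
  rownames(steps) <- NULL
  steps[, cols]
}

# sequential dwell sampling (renewal process) of step event times in (a, b)
renewal_times <- function(config, a, b) {
  mean_ms <- 1000 * sum(1 / config$dwell_rates_s) *
    (if (config$dwell_model == "erlang2") 2 else 1)
  times <- numeric(0)
  t <- a
  repeat {
    batch <- max(8L, ceiling(1.5 * (b - t) / mean_ms))
    d <- simulate_dwell_times(config$dwell_model, config$dwell_rates_s, batch)
    tt <- t + cumsum(d)
    keep <- tt < b
    times <- c(times, tt[keep])
    if (!all(keep)) break
    t <- tt[length(tt)]
  }
  times
}

draw_off_axis <- function(config, n) {
  off <- rnorm(n, 0, config$off_axis_sd_nm)
  jump <- runif(n) < config$p_off_jump
  off[jump] <- off[jump] +
    sample(c(-1, 1), sum(jump), replace = TRUE) * config$off_jump_nm
  off
}

#' Location parameter of a lower-truncated normal with a target mean
#'
#' Solves for `mu` such that the truncated normal `N(mu, sd)` restricted to
#' `[lower, Inf)` has expectation `target_mean`. Used to configure the
#' forward step-size generator so that the *realised* mean step size equals
#' a reported value despite the lower bound.
#'
#' @param target_mean desired mean of the truncated distribution.
#' @param sd normal spread.
#' @param lower truncation bound.
#' @return The location parameter `mu`.
#' @examples
#' mu <- truncnorm_mu_for_mean(8.7, 3.8, 4)
#' @export
truncnorm_mu_for_mean <- function(target_mean, sd, lower) {
  if (sd <= 0) return(target_mean)
  if (target_mean <= lower) stopf("target mean must exceed the lower bound")
  tr_mean <- function(mu) {
    a <- (lower - mu) / sd
    mu + sd * stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
  }
  stats::uniroot(function(mu) tr_mean(mu) - target_mean,
                 lower = target_mean - 8 * sd, upper = target_mean,
                 extendInt = "upX", tol = 1e-10)$root
}

#' Simulate a single-run staircase trace with controlled plateau lengths
#'
#' Constructs a processive retrograde staircase directly in sample space:
#' plateau lengths are drawn uniformly from `plateau_samples` (default
#' 8–12 samples, i.e. ~10 samples per plateau at the configured cadence),
#' step sizes from the truncated normal `N(step_mean_nm, step_sd_nm)` with
#' lower bound `step_min_nm`, backsteps with probability `p_back`, plus the
#' usual off-axis component and isotropic localization noise. Unlike
#' [simulate_trace()] there is no motion-state chain and the dwell-time
#' distribution is *not* one of the kinetic models — this is the controlled
#' input for characterising the step detector itself (recall/precision,
#' size and sign recovery), where short kinetic dwells below the detector's
#' resolution would confound the measurement.
#'
#' @param n_steps number of true steps.
#' @param config a [sim_config()] providing step-size, backstep, off-axis,
#'   noise, cadence and axis parameters.
#' @param plateau_samples integer vector of admissible plateau lengths
#'   (samples); drawn uniformly.
#' @param seed optional integer seed.
#' @return As [simulate_trace()]: list with `trace` and `truth`.
#' @export
simulate_staircase <- function(n_steps, config = sim_config(seed = 1),
                               plateau_samples = 8:12, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is_count(n_steps)) stopf("n_steps must be a positive integer")
  if (any(plateau_samples < 1)) stopf("plateau lengths must be >= 1 sample")
  set_seed(seed)
  dt <- config$dt_ms
  len <- if (length(plateau_samples) == 1L) {
    rep(as.integer(plateau_samples), n_steps + 1L)
  } else {
    sample(plateau_samples, n_steps + 1L, replace = TRUE)
  }
  starts <- cumsum(c(1L, len))            # sample index of each new plateau
  n_samp <- starts[n_steps + 2L] - 1L
  t_samp <- (seq_len(n_samp) - 1L) * dt
  step_t <- (starts[2:(n_steps + 1L)] - 1L) * dt - dt / 2
  size <- rtruncnorm_lower(n_steps, config$step_mean_nm, config$step_sd_nm,
                           config$step_min_nm)
  back <- runif(n_steps) < config$p_back
  s_on <- ifelse(back, -size, size)       # retrograde-positive
  s_off <- draw_off_axis(config, n_steps)
  ang <- config$axis_angle_rad
  retro_dir <- c(cos(ang), sin(ang))
  perp_dir <- c(-sin(ang), cos(ang))
  dx <- s_on * retro_dir[1] + s_off * perp_dir[1]
  dy <- s_on * retro_dir[2] + s_off * perp_dir[2]
  idx <- findInterval(t_samp, step_t)
  true_x <- c(0, cumsum(dx))[idx + 1L]
  true_y <- c(0, cumsum(dy))[idx + 1L]
  trace <- localization_trace(
    "staircase", t_samp,
    true_x + rnorm(n_samp, 0, config$sigma_loc_nm),
    true_y + rnorm(n_samp, 0, config$sigma_loc_nm),
    metadata = list(label_site = "DHC", dt_ms = dt, retro_dir = retro_dir))
  truth <- structure(list(
    steps = data.frame(t_ms = step_t, s_on_nm = s_on, s_off_nm = s_off,
                       state = "retrograde", is_backstep = back,
                       step_index = starts[2:(n_steps + 1L)]),
    states = data.frame(state = "retrograde", t_start_ms = 0,
                        t_end_ms = t_samp[n_samp]),
    bleach_ms = Inf, duration_ms = t_samp[n_samp],
    retro_dir = retro_dir, axis_angle_rad = ang
  ), class = "ground_truth")
  list(trace = trace, truth = truth)
}

#' Simulate a cohort of stepping traces
#'
#' Convenience wrapper around [simulate_trace()] drawing per-trace child
#' seeds deterministically from `seed`, so cohorts are reproducible and
#' individual traces re-simulatable.
#'
#' @param config a [sim_config()].
#' @param n_traces number of traces.
#' @param seed cohort seed; defaults to `config$seed`.
#' @return List with `traces` (named list of traces) and `truths`.
#' @export
simulate_cohort <- function(config, n_traces, seed = config$seed) {
  if (!is_count(n_traces)) stopf("n_traces must be a positive integer")
  set_seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, n_traces)
  traces <- vector("list", n_traces)
  truths <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    sim <- simulate_trace(config, trace_id = sprintf("sim-%04d", i),
                          seed = child[i])
    traces[[i]] <- sim$trace
    truths[[i]] <- sim$truth
  }
  names(traces) <- names(truths) <-
    vapply(traces, function(tr) tr$trace_id, character(1))
  list(traces = traces, truths = truths)
}

#' Render a synthetic kymograph with known line truth
#'
#' Draws anti-aliased constant-speed lines (one moving particle each) into a
#' time-by-position intensity image and adds exponential background noise
#' with the given mean. By the package convention, rows are time, columns
#' are position along the axon with the soma at low column index, so
#' negative slope (position decreasing with time) is retrograde.
#'
#' @param lines data.frame with columns `t0_ms`, `x0_um`, `speed_um_s`,
#'   `intensity` and optionally `t1_ms` (default: end of image).
#' @param n_time,n_pos image dimensions (rows, columns).
#' @param dt_ms,dx_um pixel sizes (ms per row, um per column).
#' @param noise_level mean background intensity (0 = noiseless).
#' @param seed optional integer seed.
#' @return List with `kymograph` (a [kymograph()]) and `lines` (the truth
#'   lines actually rendered, with realised endpoints after clipping).
#' @export
simulate_kymograph <- function(lines, n_time, n_pos, dt_ms = 100,
                               dx_um = 0.1, noise_level = 0, seed = NULL) {
  if (dt_ms <= 0 || dx_um <= 0) stopf("pixel sizes must be > 0")
  set_seed(seed)
  img <- matrix(0, n_time, n_pos)
  truth <- list()
  n_lines <- if (is.null(lines) || nrow(lines) == 0) 0L else nrow(lines)
  for (i in seq_len(n_lines)) {
    ln <- lines[i, ]
    t1 <- if ("t1_ms" %in% names(lines) && is.finite(ln$t1_ms)) ln$t1_ms
          else (n_time - 1) * dt_ms
    rows <- which((seq_len(n_time) - 1L) * dt_ms >= ln$t0_ms &
                  (seq_len(n_time) - 1L) * dt_ms <= t1)
    if (length(rows) == 0) next
    t_row <- (rows - 1L) * dt_ms
    x_um <- ln$x0_um + ln$speed_um_s * (t_row - ln$t0_ms) / 1000
    col_f <- x_um / dx_um + 1
    inb <- col_f >= 1 & col_f <= n_pos
    if (any(!inb)) {
      warnf("kymograph line %d extends outside the image; clipped", i)
    }
    rows <- rows[inb]; col_f <- col_f[inb]; t_row <- t_row[inb]
    if (length(rows) == 0) next
    lo <- floor(col_f); frac <- col_f - lo
    ok_lo <- lo >= 1 & lo <= n_pos
    ok_hi <- (lo + 1) >= 1 & (lo + 1) <= n_pos
    img[cbind(rows[ok_lo], lo[ok_lo])] <-
      img[cbind(rows[ok_lo], lo[ok_lo])] + ln$intensity * (1 - frac[ok_lo])
    img[cbind(rows[ok_hi], lo[ok_hi] + 1)] <-
      img[cbind(rows[ok_hi], lo[ok_hi] + 1)] + ln$intensity * frac[ok_hi]
    truth[[length(truth) + 1L]] <- data.frame(
      t0_ms = t_row[1], x0_um = (col_f[1] - 1) * dx_um,
      t1_ms = t_row[length(t_row)],
      x1_um = (col_f[length(col_f)] - 1) * dx_um,
      speed_um_s = ln$speed_um_s, intensity = ln$intensity)
  }
  if (noise_level > 0) {
    img <- img + matrix(rexp(n_time * n_pos, rate = 1 / noise_level),
                        n_time, n_pos)
  }
  truth_df <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(t0_ms = numeric(0), x0_um = numeric(0), t1_ms = numeric(0),
               x1_um = numeric(0), speed_um_s = numeric(0),
               intensity = numeric(0))
  list(kymograph = kymograph(img, dt_ms, dx_um), lines = truth_df)
}
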