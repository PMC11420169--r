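# shared fixtures, all generated in code

# ideal 3-plateau staircase along -x (retrograde), 20 samples per level
noiseless_staircase <- function() {
  x <- rep(c(0, -8, -16), each = 20)
  localization_trace("stair", 0:59, x, rep(0, 60),
                     metadata = list(retro_dir = c(-1, 0)))
}

# constant noisy trace for false-positive checks
constant_trace <- function(seed, n = 100, sigma = 3.5) {
  set.seed(seed)
  localization_trace(paste0("const", seed), seq_len(n) - 1,
                     rnorm(n, 0, sigma), rnorm(n, 0, sigma))
}

# config for clean fixed-size stepping (no backsteps, no off-axis)
fixed_step_config <- function(step = 8, sigma = 3.5) {
  sim_config(seed = 1, step_mean_nm = step, step_sd_nm = 0, step_min_nm = 0,
             p_back = 0, off_axis_sd_nm = 0, p_off_jump = 0,
             sigma_loc_nm = sigma)
}

# build a step_fit-like object directly from given step times and on-axis
# sizes (perfect-detector stand-in for unit tests of downstream modules)
synthetic_step_fit <- function(t_ms, s_on, t_end = max(t_ms) + 50,
                               trace_id = "synt") {
  n_steps <- length(t_ms)
  steps <- data.frame(
    step_index = seq_len(n_steps) * 10L,
    t_ms = t_ms,
    dx_nm = -s_on, dy_nm = 0,
    size_nm = abs(s_on),
    tau_ms = c(t_ms[1], diff(t_ms)),
    tau_censored = c(TRUE, rep(FALSE, n_steps - 1L)),
    sigma_step_nm = 0.5,
    s_on_nm = s_on, s_off_nm = 0)
  structure(list(
    trace_id = trace_id,
    t_ms = seq(0, t_end, by = 1),
    x_nm = numeric(0), y_nm = numeric(0),
    plateaus = NULL, steps = steps,
    rss = 0, n_steps = n_steps, min_plateau_points = 3L,
    selection = list(forced = TRUE),
    metadata = list(retro_dir = c(-1, 0)), axes = NULL
  ), class = "step_fit")
}

# motion_segmentation built by hand
synthetic_segmentation <- function(classes, durations_ms, trace_id = "synt") {
  t0 <- cumsum(c(0, durations_ms[-length(durations_ms)]))
  t1 <- cumsum(durations_ms)
  disp <- ifelse(classes == "retrograde", 80,
                 ifelse(classes == "anterograde", -80, 0))
  structure(list(trace_id = trace_id, segments = data.frame(
    class = classes, t_start_ms = t0, t_end_ms = t1,
    net_disp_nm = disp, duration_ms = durations_ms,
    speed_um_s = ifelse(classes %in% c("retrograde", "anterograde"),
                        abs(disp) / durations_ms, NA_real_)),
    rules = segmentation_rules(), diagnostic = NULL),
    class = "motion_segmentation")
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%g close to %g (tol %g)", object, expected,
                              tol))
}
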