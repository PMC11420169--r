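test_that("dwell-time samples match the analytic means of all three models", {
  n <- 50000
  cases <- list(
    list(model = "exp1", rates = 100, mean_ms = 10),
    list(model = "erlang2", rates = 100, mean_ms = 20),
    # mean of a sum of independent exponentials: 1/90 + 1/1000 s
    list(model = "hypoexp2", rates = c(90, 1000),
         mean_ms = 1000 * (1 / 90 + 1 / 1000)))
  for (cs in cases) {
    d <- simulate_dwell_times(cs$model, cs$rates, n, seed = 42)
    se <- sd(d) / sqrt(n)
    expect_close(mean(d), cs$mean_ms, 3 * se)
    expect_true(all(d > 0))
  }
})

test_that("dwell-time sampling rejects invalid parameters", {
  expect_error(simulate_dwell_times("exp1", -5, 10), "positive")
  expect_error(simulate_dwell_times("hypoexp2", c(100, 100), 10), "distinct")
  expect_error(simulate_dwell_times("hypoexp2", 100, 10), "rate")
  expect_error(simulate_dwell_times("nope", 100, 10), "unknown")
  expect_error(simulate_dwell_times("exp1", 100, 0), "positive integer")
})

test_that("empirical dwell CDF converges to the analytic exponential CDF", {
  for (n in c(500, 50000)) {
    d <- simulate_dwell_times("exp1", 90, n, seed = 7) / 1000
    ks <- max(abs(seq_len(n) / n - pexp(sort(d), rate = 90)))
    # KS distance shrinks like 1/sqrt(n); allow 3x that scale
    expect_lt(ks, 3 / sqrt(n))
  }
})

test_that("noiseless single-state trace is an exact staircase with -8 nm x-increments", {
  cfg <- sim_config(seed = 2, states = "retrograde",
                    state_means_ms = c(retrograde = 1e9),
                    step_mean_nm = 8, step_sd_nm = 0, step_min_nm = 0,
                    p_back = 0, off_axis_sd_nm = 0, p_off_jump = 0,
                    sigma_loc_nm = 0, max_duration_ms = 400,
                    bleach_mean_s = 1e6)
  sim <- simulate_trace(cfg, seed = 5)
  tr <- sim$trace
  truth <- sim$truth
  # sampled increments are whole numbers of -8 nm steps (two steps can
  # fall inside a single 1 ms sampling bin)
  incr <- diff(tr$x_nm)
  expect_true(all(incr < 1e-12))
  expect_true(all(abs(incr / 8 - round(incr / 8)) < 1e-12))
  expect_true(all(abs(tr$y_nm) < 1e-12))
  # observed staircase ends where the signed sum of true steps says
  expect_equal(tr$x_nm[length(tr$x_nm)], -sum(truth$steps$s_on_nm))
  expect_equal(sum(round(-incr / 8)), nrow(truth$steps))
})

test_that("ground truth is internally consistent", {
  cfg <- sim_config(seed = 9)
  sim <- simulate_trace(cfg, seed = 9)
  truth <- sim$truth
  expect_true(all(diff(truth$steps$t_ms) > 0))
  st <- truth$states
  expect_equal(st$t_start_ms[1], 0)
  expect_equal(st$t_end_ms[nrow(st)], truth$duration_ms)
  if (nrow(st) > 1) {
    expect_equal(st$t_start_ms[-1], st$t_end_ms[-nrow(st)])
  }
  expect_lte(truth$duration_ms, cfg$max_duration_ms)
  expect_lte(truth$duration_ms, truth$bleach_ms)
})

test_that("backstep incidence matches the configured probability", {
  cfg <- sim_config(seed = 3, states = "retrograde",
                    state_means_ms = c(retrograde = 1e9),
                    max_duration_ms = 3000, bleach_mean_s = 1e6, p_tug = 0)
  back <- unlist(lapply(1:30, function(i) {
    simulate_trace(cfg, seed = 100 + i)$truth$steps$is_backstep
  }))
  n <- length(back)
  expect_gt(n, 1000)
  ci <- qnorm(0.995) * sqrt(0.04 * 0.96 / n)
  expect_close(mean(back), 0.04, ci)
})

test_that("true dwell times follow the configured exp1 rate", {
  cfg <- sim_config(seed = 4, states = "retrograde",
                    state_means_ms = c(retrograde = 1e9),
                    max_duration_ms = 3000, bleach_mean_s = 1e6, p_tug = 0)
  taus <- unlist(lapply(1:20, function(i) {
    diff(simulate_trace(cfg, seed = 500 + i)$truth$steps$t_ms)
  }))
  se <- sd(taus) / sqrt(length(taus))
  expect_close(mean(taus), 1000 / 90, 3 * se)
})

test_that("same seed and config give byte-identical traces", {
  cfg <- sim_config(seed = 6)
  a <- simulate_trace(cfg, seed = 6)
  b <- simulate_trace(cfg, seed = 6)
  expect_identical(a, b)
  ca <- simulate_cohort(cfg, 3, seed = 1)
  cb <- simulate_cohort(cfg, 3, seed = 1)
  expect_identical(ca, cb)
})

test_that("too-short durations are rejected", {
  cfg <- sim_config(seed = 1, max_duration_ms = 0.4, dt_ms = 1)
  expect_error(simulate_trace(cfg, seed = 1), "sampling interval")
})

test_that("staircase generator honours plateau lengths and step count", {
  cfg <- fixed_step_config()
  s <- simulate_staircase(25, cfg, plateau_samples = 8:12, seed = 3)
  expect_equal(nrow(s$truth$steps), 25)
  gaps <- diff(s$truth$steps$step_index)
  expect_true(all(gaps >= 8 & gaps <= 12))
  s10 <- simulate_staircase(5, cfg, plateau_samples = 10, seed = 4)
  expect_true(all(diff(s10$truth$steps$step_index) == 10))
})

test_that("config validation catches invariant violations", {
  expect_error(sim_config(seed = 1, p_back = 1.5), "p_back")
  expect_error(sim_config(seed = 1, dt_ms = 0), "sampling")
  expect_error(sim_config(seed = 1, state_means_ms = c(
    retrograde = -1, anterograde = 400, pause = 150, reversal = 15)),
    "positive")
  w <- matrix(0.4, 4, 4); diag(w) <- 0
  expect_error(sim_config(seed = 1, transition_weights = w), "sum to 1")
})

test_that("rendered kymograph lines have the configured slope", {
  ln <- data.frame(t0_ms = 0, x0_um = 0.5, speed_um_s = 1, intensity = 7)
  sk <- simulate_kymograph(ln, 40, 60, dt_ms = 100, dx_um = 0.1,
                           noise_level = 0)
  img <- sk$kymograph$intensity
  rows <- which(rowSums(img) > 0)
  # intensity-weighted column centre per row follows x = x0 + v t
  centre <- vapply(rows, function(r) {
    sum(img[r, ] * seq_len(ncol(img))) / sum(img[r, ])
  }, numeric(1))
  t_s <- (rows - 1) * 0.1
  fitline <- lm(centre ~ t_s)
  expect_close(coef(fitline)[2] * 0.1, 1.0, 0.02)  # um/s
  expect_equal(sum(rowSums(img) > 0), length(rows))
})

test_that("empty line set yields pure noise at the requested mean", {
  sk <- simulate_kymograph(NULL, 50, 50, noise_level = 2, seed = 8)
  expect_close(mean(sk$kymograph$intensity), 2, 3 * 2 / sqrt(2500))
  expect_equal(nrow(sk$lines), 0)
})

test_that("out-of-bounds lines are clipped with a warning", {
  ln <- data.frame(t0_ms = 0, x0_um = 3.5, speed_um_s = 1, intensity = 5)
  expect_warning(
    sk <- simulate_kymograph(ln, 80, 40, dt_ms = 100, dx_um = 0.1,
                             noise_level = 0),
    "clipped")
  expect_lte(sk$lines$x1_um, 3.9 + 1e-9)
})

test_that("antiparallel truth lines round-trip through line_speed", {
  ln <- data.frame(t0_ms = c(0, 0), x0_um = c(0.5, 3.5),
                   speed_um_s = c(1, -1), intensity = c(5, 5))
  sk <- simulate_kymograph(ln, 30, 45, dt_ms = 100, dx_um = 0.1,
                           noise_level = 0)
  for (i in 1:2) {
    ls <- line_speed(sk$lines$t0_ms[i], sk$lines$x0_um[i],
                     sk$lines$t1_ms[i], sk$lines$x1_um[i])
    expect_close(ls$speed_um_s, 1, 1e-9)
  }
  expect_equal(line_speed(sk$lines$t0_ms[2], sk$lines$x0_um[2],
                          sk$lines$t1_ms[2], sk$lines$x1_um[2])$direction,
               "retrograde")
})

test_that("truncated-normal location solver hits the target mean", {
  mu <- truncnorm_mu_for_mean(8.7, 3.8, 4)
  x <- motorsteps:::rtruncnorm_lower(2e5, mu, 3.8, 4)
  expect_close(mean(x), 8.7, 0.05)
  expect_error(truncnorm_mu_for_mean(3, 1, 4), "exceed")
})
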