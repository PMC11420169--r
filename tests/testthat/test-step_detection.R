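test_that("a noiseless staircase is recovered exactly", {
  f <- fit_steps(noiseless_staircase())
  expect_equal(f$n_steps, 2)
  expect_equal(f$steps$step_index, c(21, 41))
  f <- decompose_steps(f)
  # retrograde along -x, so retrograde-positive on-axis sizes are +8
  expect_equal(f$steps$s_on_nm, c(8, 8), tolerance = 1e-12)
  expect_equal(f$steps$s_off_nm, c(0, 0), tolerance = 1e-12)
  expect_lt(f$rss, 1e-20)
})

test_that("an all-constant trace yields zero steps, not an error", {
  tr <- localization_trace("flat", 0:19, rep(1, 20), rep(2, 20))
  f <- fit_steps(tr)
  expect_equal(f$n_steps, 0)
  expect_equal(nrow(f$plateaus), 1)
})

test_that("false-positive rate on constant noisy traces is at most 5%", {
  hits <- vapply(1:60, function(i) {
    fit_steps(constant_trace(8000 + i))$n_steps > 0
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("short traces are rejected", {
  tr <- localization_trace("tiny", 0:3, rnorm(4), rnorm(4))
  expect_error(fit_steps(tr, min_plateau_points = 3), "min_plateau_points")
})

test_that("fixed-count fits match the dynamic-programming optimum", {
  cfg <- fixed_step_config()
  for (i in 1:20) {
    s <- simulate_staircase(9, cfg, plateau_samples = 10, seed = i)
    f <- fit_steps(s$trace, n_steps = 9)
    dp <- optimal_changepoints(s$trace$x_nm, s$trace$y_nm, 9, 3)
    expect_lte(max(abs(sort(f$steps$step_index) - dp$changepoints)), 2)
  }
})

test_that("optimal_changepoints agrees with exhaustive enumeration", {
  set.seed(31)
  x <- c(rnorm(4), rnorm(4, 6), rnorm(4, -3))
  y <- rnorm(12)
  # brute force over all 2-change-point placements with >=2-sample plateaus
  sse_of <- function(c1, c2) {
    segs <- list(1:(c1 - 1), c1:(c2 - 1), c2:12)
    sum(vapply(segs, function(ix) {
      sum((x[ix] - mean(x[ix]))^2) + sum((y[ix] - mean(y[ix]))^2)
    }, numeric(1)))
  }
  best <- Inf; best_cp <- NULL
  for (c1 in 3:9) for (c2 in (c1 + 2):11) {
    v <- sse_of(c1, c2)
    if (v < best) { best <- v; best_cp <- c(c1, c2) }
  }
  dp <- optimal_changepoints(x, y, 2, min_plateau_points = 2)
  expect_equal(dp$changepoints, best_cp)
  expect_equal(dp$sse, best, tolerance = 1e-10)
})

test_that("detection is invariant under translation and rotation", {
  cfg <- fixed_step_config()
  s <- simulate_staircase(8, cfg, plateau_samples = 10, seed = 21)
  tr <- s$trace
  th <- 0.6
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y + 120,
                             y = sin(th) * x + cos(th) * y - 44)
  r <- rot(tr$x_nm, tr$y_nm)
  tr2 <- localization_trace("rot", tr$t_ms, r$x, r$y,
                            metadata = list(retro_dir = c(cos(th + pi),
                                                          sin(th + pi))))
  f1 <- fit_steps(tr, n_steps = 8)
  f2 <- fit_steps(tr2, n_steps = 8)
  expect_equal(f1$steps$step_index, f2$steps$step_index)
  expect_equal(f1$steps$size_nm, f2$steps$size_nm, tolerance = 1e-9)
  expect_equal(f1$steps$tau_ms, f2$steps$tau_ms)
  expect_equal(f1$steps$sigma_step_nm, f2$steps$sigma_step_nm,
               tolerance = 1e-9)
})

test_that("recall and precision exceed 0.85 on well-sampled 8 nm staircases", {
  cfg <- fixed_step_config()
  n_true <- n_det <- n_match <- 0
  for (i in 1:10) {
    s <- simulate_staircase(40, cfg, plateau_samples = 8:14, seed = 60 + i)
    f <- fit_steps(s$trace)
    ti <- s$truth$steps$step_index
    di <- f$steps$step_index
    n_true <- n_true + length(ti)
    n_det <- n_det + length(di)
    n_match <- n_match + sum(vapply(di, function(d) any(abs(ti - d) <= 2),
                                    logical(1)))
  }
  expect_gte(n_match / n_true, 0.85)
  expect_gte(n_match / n_det, 0.85)
})

test_that("interior dwell times equal true plateau durations when indices are exact", {
  f <- fit_steps(noiseless_staircase())
  expect_equal(f$steps$tau_ms, c(20, 20))
  expect_equal(f$steps$tau_censored, c(TRUE, FALSE))
  expect_equal(dwell_times(f), 20)
  expect_equal(dwell_times(f, drop_censored = FALSE), c(20, 20))
})

test_that("motion axis estimation matches geometry", {
  # collinear centroids along +x, declared retrograde +x
  tr <- localization_trace("ax", 0:59, rep(c(0, 8, 16), each = 20),
                           rep(0, 60), metadata = list(retro_dir = c(1, 0)))
  f <- fit_steps(tr)
  ax <- estimate_motion_axis(f)
  expect_equal(dim(ax), c(2, 2))
  expect_equal(ax, matrix(c(1, 1, 0, 0), 2), tolerance = 1e-9)

  # 45 degree line
  tr45 <- localization_trace("d45", 0:59, rep(c(0, 8, 16), each = 20) / sqrt(2),
                             rep(c(0, 8, 16), each = 20) / sqrt(2),
                             metadata = list(retro_dir = c(1, 1) / sqrt(2)))
  ax45 <- estimate_motion_axis(fit_steps(tr45))
  expect_equal(ax45[1, ], c(sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-9)

  expect_error(estimate_motion_axis(
    fit_steps(localization_trace("f", 0:19, rep(0, 20), rep(0, 20)))),
    ">= 2 plateaus")
})

test_that("per-step axes follow a curved track within 10 degrees", {
  # two straight sections meeting at 30 degrees, noiseless 8 nm steps
  n_per <- 8
  ang2 <- 30 * pi / 180
  d1 <- matrix(rep(c(8, 0), n_per), ncol = 2, byrow = TRUE)
  d2 <- matrix(rep(8 * c(cos(ang2), sin(ang2)), n_per), ncol = 2,
               byrow = TRUE)
  cent <- rbind(c(0, 0), apply(rbind(d1, d2), 2, cumsum))
  x <- rep(cent[, 1], each = 10)
  y <- rep(cent[, 2], each = 10)
  tr <- localization_trace("curve", seq_along(x) - 1, x, y,
                           metadata = list(retro_dir = c(1, 0)))
  f <- fit_steps(tr)
  expect_equal(f$n_steps, 2 * n_per)
  ax <- estimate_motion_axis(f, window_steps = 5)
  ang <- atan2(ax[, 2], ax[, 1])
  true_ang <- c(rep(0, n_per), rep(ang2, n_per))
  # windows straddling the bend average the two directions
  interior <- c(1:(n_per - 3), (n_per + 4):(2 * n_per))
  expect_true(all(abs(ang[interior] - true_ang[interior]) < 10 * pi / 180))
})

test_that("on/off-axis decomposition preserves magnitudes and rotation algebra", {
  f <- synthetic_step_fit(c(10, 20, 30), c(8, 6, 8))
  f$steps$dx_nm <- c(8, 0, 5.656854)
  f$steps$dy_nm <- c(0, 6, 5.656854)
  f$steps$size_nm <- sqrt(f$steps$dx_nm^2 + f$steps$dy_nm^2)
  axes <- matrix(c(1, 0,
                   1, 0,
                   sqrt(2) / 2, sqrt(2) / 2), 3, 2, byrow = TRUE)
  g <- decompose_steps(f, axes = axes)
  expect_equal(g$steps$s_on_nm, c(8, 0, 8), tolerance = 1e-6)
  expect_equal(g$steps$s_off_nm, c(0, 6, 0), tolerance = 1e-6)
  expect_equal(sqrt(g$steps$s_on_nm^2 + g$steps$s_off_nm^2),
               g$steps$size_nm, tolerance = 1e-9)
})

test_that("localization precision is recovered and rotation invariant", {
  f0 <- fit_steps(noiseless_staircase())
  p0 <- estimate_localization_precision(noiseless_staircase(), f0)
  expect_equal(p0$median_nm, 0)
  expect_equal(p0$mad_nm, 0)

  cfg <- fixed_step_config(sigma = 3.5)
  s <- simulate_staircase(10, cfg, plateau_samples = 40, seed = 77)
  f <- fit_steps(s$trace)
  pr <- estimate_localization_precision(s$trace, f)
  expect_close(pr$median_nm, 3.5, 0.35)

  th <- 1.1
  tr2 <- localization_trace("rot", s$trace$t_ms,
                            cos(th) * s$trace$x_nm - sin(th) * s$trace$y_nm,
                            sin(th) * s$trace$x_nm + cos(th) * s$trace$y_nm)
  f2 <- fit_steps(tr2, n_steps = f$n_steps)
  pr2 <- estimate_localization_precision(tr2, f2)
  expect_equal(pr2$median_nm, pr$median_nm, tolerance = 1e-6)
})

test_that("step uncertainties follow the pooled-sd closed form", {
  # two 10-point plateaus with residuals of known pooled sd
  resid <- rep(c(1, -1), 5) * 3.5 * sqrt(9 / 10)  # sample sd exactly 3.5*sqrt(...)
  x <- c(rep(0, 10) + resid, rep(20, 10) + resid)
  tr <- localization_trace("unc", 0:19, x, rep(0, 20))
  f <- fit_steps(tr, n_steps = 1)
  # pooled over both coordinates: y residuals are 0, halving the variance
  s_pool <- sqrt(sum((x[1:10] - mean(x[1:10]))^2 +
                     (x[11:20] - mean(x[11:20]))^2) / (2 * 10 + 2 * 10 - 4))
  expect_equal(f$steps$sigma_step_nm, s_pool * sqrt(1 / 10 + 1 / 10),
               tolerance = 1e-9)
  expect_equal(step_uncertainties(tr, f), f$steps$sigma_step_nm)
  # noiseless: zero uncertainty
  f0 <- fit_steps(noiseless_staircase())
  expect_equal(step_uncertainties(noiseless_staircase(), f0), c(0, 0))
})

test_that("median step uncertainty lands in the expected 1-3 nm range", {
  cfg <- sim_config(seed = 5)
  s <- simulate_staircase(30, cfg, plateau_samples = 8:12, seed = 13)
  f <- fit_steps(s$trace)
  med <- median(f$steps$sigma_step_nm, na.rm = TRUE)
  expect_gt(med, 1)
  expect_lt(med, 3)
})
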