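# classification unit tests run on hand-built step fits (perfect-detector
# stand-ins), so they exercise the rules, not the detector

test_that("a monotone retrograde staircase is one segment with no events", {
  f <- synthetic_step_fit(seq(10, 100, by = 10), rep(8, 10))
  seg <- classify_motion(f)
  cls <- seg$segments$class
  expect_equal(sum(cls == "retrograde"), 1)
  expect_false(any(cls %in% c("pause", "reversal")))
})

test_that("a long stationary gap between same-direction runs is a pause", {
  t <- c(seq(10, 50, by = 10), seq(250, 290, by = 10))
  f <- synthetic_step_fit(t, rep(8, 10), t_end = 300)
  seg <- classify_motion(f)
  cls <- seg$segments$class
  expect_equal(cls[cls != "unclassified"], c("retrograde", "pause",
                                             "retrograde"))
  pause <- seg$segments[seg$segments$class == "pause", ]
  expect_equal(pause$t_start_ms, 50)
  expect_equal(pause$t_end_ms, 250)
  expect_equal(pause$duration_ms, 200)
})

test_that("a direction flip produces a reversal lasting about one dwell", {
  t <- c(seq(10, 50, by = 10), seq(60, 100, by = 10))
  f <- synthetic_step_fit(t, c(rep(8, 5), rep(-8, 5)), t_end = 110)
  seg <- classify_motion(f)
  cls <- seg$segments$class
  expect_equal(cls[cls != "unclassified"],
               c("retrograde", "reversal", "anterograde"))
  rev <- seg$segments[seg$segments$class == "reversal", ]
  expect_equal(rev$duration_ms, 10)   # one step dwell
})

test_that("sub-threshold runs and short gaps are not segmented as events", {
  # two same-direction runs separated by only one dwell: merged
  t <- seq(10, 100, by = 10)
  f <- synthetic_step_fit(t, rep(8, 10))
  rules <- segmentation_rules(min_event_duration_ms = 15)
  seg <- classify_motion(f, rules)
  expect_equal(sum(seg$segments$class == "retrograde"), 1)
  # a 2-step excursion does not qualify as processive
  f2 <- synthetic_step_fit(c(10, 20), c(8, 8))
  seg2 <- classify_motion(f2)
  expect_equal(seg2$segments$class, "unclassified")
  expect_match(seg2$diagnostic, "no processive segment")
})

test_that("classification requires decomposed steps", {
  f <- synthetic_step_fit(c(10, 20, 30, 40), rep(8, 4))
  f$steps$s_on_nm <- NA_real_
  expect_error(classify_motion(f), "decompose_steps")
})

test_that("segment speeds follow the arithmetic and summary conventions", {
  # sustained 8 nm per 8 ms: exactly 1 um/s
  t <- seq(8, 80, by = 8)
  f <- synthetic_step_fit(t, rep(8, 10), t_end = 88)
  seg <- classify_motion(f)
  sp <- segment_speeds(seg)
  expect_equal(sp$median_um_s[sp$direction == "retrograde"], 1.0)

  segs <- list(
    synthetic_segmentation("retrograde", 100),
    synthetic_segmentation("retrograde", 100),
    synthetic_segmentation("retrograde", 100))
  segs[[1]]$segments$speed_um_s <- 1
  segs[[2]]$segments$speed_um_s <- 1
  segs[[3]]$segments$speed_um_s <- 3
  sp2 <- segment_speeds(segs)
  r <- sp2[sp2$direction == "retrograde", ]
  expect_equal(r$median_um_s, 1)
  expect_equal(r$mad_um_s, 0)
  expect_equal(r$n, 3)
})

test_that("trace categories are non-exclusive fractions over processive traces", {
  segs <- list(
    synthetic_segmentation(c("retrograde", "reversal", "anterograde"),
                           c(100, 10, 100)),
    synthetic_segmentation(c("retrograde", "pause", "retrograde"),
                           c(100, 80, 100)),
    synthetic_segmentation("retrograde", 300))
  ct <- trace_categories(segs)
  expect_equal(ct$contains_reversal, 1 / 3)
  expect_equal(ct$contains_pause, 1 / 3)
  expect_equal(ct$uninterrupted, 1 / 3)
  expect_equal(ct$n_traces, 3)

  all_clean <- list(synthetic_segmentation("retrograde", 300),
                    synthetic_segmentation("anterograde", 300))
  ct2 <- trace_categories(all_clean)
  expect_equal(ct2$contains_reversal, 0)
  expect_equal(ct2$uninterrupted, 1)
  # traces without processive movement are excluded from the denominator
  with_dud <- c(segs, list(synthetic_segmentation("unclassified", 100)))
  expect_equal(trace_categories(with_dud)$n_traces, 3)
})

test_that("event durations summarise per class with a pause/reversal ratio", {
  segs <- list(
    synthetic_segmentation(c("retrograde", "pause", "retrograde"),
                           c(50, 100, 50)),
    synthetic_segmentation(c("retrograde", "reversal", "anterograde"),
                           c(50, 10, 50)))
  ed <- event_durations(segs)
  expect_equal(ed$stats$median_ms[ed$stats$class == "pause"], 100)
  expect_equal(ed$stats$median_ms[ed$stats$class == "reversal"], 10)
  expect_equal(ed$pause_reversal_ratio, 10)

  only_pause <- list(synthetic_segmentation(
    c("retrograde", "pause", "retrograde"), c(50, 100, 50)))
  expect_message(ed2 <- event_durations(only_pause), "no events")
  expect_true(is.na(ed2$pause_reversal_ratio))
})

test_that("event durations of exponential events recover ln2 times the mean", {
  set.seed(99)
  n <- 4000
  durs <- rexp(n, 1 / 150)
  segs <- lapply(durs, function(d) {
    synthetic_segmentation(c("retrograde", "pause", "retrograde"),
                           c(100, d, 100))
  })
  ed <- event_durations(segs)
  med <- ed$stats$median_ms[ed$stats$class == "pause"]
  se <- 1.2533 * (150 / sqrt(n))  # asymptotic SE of an exponential median
  expect_close(med, log(2) * 150, 3 * se)
})

test_that("intra-event stepping detection counts adjacent opposite pairs", {
  # no steps inside events -> 0
  f <- synthetic_step_fit(c(seq(10, 50, by = 10), seq(250, 290, by = 10)),
                          rep(8, 10), t_end = 300)
  seg <- classify_motion(f)
  r0 <- detect_intra_event_stepping(f, seg)
  expect_equal(r0$fraction, 0)
  expect_equal(r0$n_events, 1)

  # inject a +8/-8 adjacent pair well inside the pause
  f2 <- synthetic_step_fit(
    c(seq(10, 50, by = 10), 160, 175, seq(250, 290, by = 10)),
    c(rep(8, 5), 8, -8, rep(8, 5)), t_end = 300)
  seg2 <- classify_motion(f2)
  r2 <- detect_intra_event_stepping(f2, seg2)
  expect_equal(r2$fraction, 1)

  # ten events, one with a pair -> 0.1
  fits <- list(); segl <- list()
  for (i in 1:10) {
    if (i == 1) {
      fi <- f2
    } else {
      fi <- f
    }
    fits[[i]] <- fi
    segl[[i]] <- classify_motion(fi)
  }
  r10 <- detect_intra_event_stepping(fits, segl)
  expect_equal(r10$fraction, 0.1)
  expect_equal(r10$n_events, 10)
})

test_that("tug-of-war events are recovered near the configured incidence", {
  # perfect-detector stand-ins built from generator ground truth
  p_tug <- 0.3
  cfg <- sim_config(seed = 71, p_tug = p_tug, max_duration_ms = 2500)
  n_events <- 0; n_hit <- 0
  for (i in 1:40) {
    sim <- simulate_trace(cfg, seed = 700 + i)
    st <- sim$truth$steps
    if (nrow(st) < 4) next
    f <- synthetic_step_fit(st$t_ms, st$s_on_nm,
                            t_end = sim$truth$duration_ms)
    seg <- classify_motion(f)
    r <- detect_intra_event_stepping(f, seg)
    n_events <- n_events + r$n_events
    n_hit <- n_hit + r$n_with_stepping
  }
  expect_gt(n_events, 30)
  ci <- qnorm(0.995) * sqrt(p_tug * (1 - p_tug) / n_events)
  expect_close(n_hit / n_events, p_tug, ci + 0.1)
})

test_that("segmentation is invariant under time shifts and direction relabel", {
  t <- c(seq(10, 50, by = 10), seq(250, 290, by = 10))
  f <- synthetic_step_fit(t, rep(8, 10), t_end = 300)
  seg <- classify_motion(f)
  f2 <- f
  f2$steps$t_ms <- f2$steps$t_ms + 500
  f2$t_ms <- f2$t_ms + 500
  seg2 <- classify_motion(f2)
  expect_equal(seg2$segments$t_start_ms - 500, seg$segments$t_start_ms)
  expect_equal(seg2$segments$class, seg$segments$class)

  # flipping every on-axis sign swaps the processive classes, same boundaries
  f3 <- f
  f3$steps$s_on_nm <- -f3$steps$s_on_nm
  seg3 <- classify_motion(f3)
  swap <- c(retrograde = "anterograde", anterograde = "retrograde",
            pause = "pause", reversal = "reversal",
            unclassified = "unclassified")
  expect_equal(unname(swap[seg$segments$class]), seg3$segments$class)
  expect_equal(seg3$segments$t_start_ms, seg$segments$t_start_ms)
})

test_that("segment boundaries match generator state changes on clean traces", {
  cfg <- sim_config(seed = 41, sigma_loc_nm = 0, p_tug = 0,
                    off_axis_sd_nm = 0, p_off_jump = 0,
                    state_means_ms = c(retrograde = 400, anterograde = 400,
                                       pause = 200, reversal = 15),
                    max_duration_ms = 2000)
  checked <- 0
  for (i in 1:12) {
    sim <- simulate_trace(cfg, seed = 300 + i)
    st <- sim$truth$steps
    if (nrow(st) < 8) next
    f <- synthetic_step_fit(st$t_ms, st$s_on_nm,
                            t_end = sim$truth$duration_ms)
    seg <- classify_motion(f)
    pauses <- seg$segments[seg$segments$class == "pause", ]
    truth_pauses <- sim$truth$states[sim$truth$states$state == "pause", ]
    med_dwell <- median(diff(st$t_ms))
    for (j in seq_len(nrow(pauses))) {
      near <- abs(truth_pauses$t_start_ms - pauses$t_start_ms[j]) <
        3 * med_dwell
      if (nrow(truth_pauses) > 0 && any(near)) checked <- checked + 1
    }
  }
  expect_gt(checked, 3)
})
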