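#' Segmentation rules
#'
#' Thresholds for classifying a fitted trace into processive runs, pauses
#' and direction reversals. Defaults: a processive run needs at least 3
#' same-direction on-axis steps and 20 nm net displacement; a gap between
#' same-direction runs is a pause when its internal speed stays below
#' 0.1 um/s and it lasts at least `min_event_duration_ms` (default: the
#' median detected dwell time, i.e. one step dwell) — shorter or faster
#' same-direction gaps are merged into the flanking movement. Gaps between
#' opposite-direction runs are reversals.
#'
#' @param min_steps_processive minimum steps per processive run.
#' @param min_net_displacement_nm minimum absolute net on-axis displacement
#'   of a processive run (nm).
#' @param pause_max_speed_um_s maximum internal speed of a pause (um/s).
#' @param min_event_duration_ms minimum duration of a same-direction gap to
#'   count as a pause; `NULL` = one median dwell of the fitted trace.
#' @param run_break_dwell_mult a run of same-direction steps is split where
#'   the interval to the previous step exceeds this multiple of the median
#'   dwell (default 10): stepping that stops for much longer than the
#'   renewal process predicts marks a candidate pause. For an exponential
#'   dwell distribution a spurious break occurs in ~0.1% of steps; shorter
#'   stationary intervals are fundamentally indistinguishable from a long
#'   dwell and stay inside the run.
#' @return List of class `"segmentation_rules"`.
#' @export
segmentation_rules <- function(min_steps_processive = 3,
                               min_net_displacement_nm = 20,
                               pause_max_speed_um_s = 0.1,
                               min_event_duration_ms = NULL,
                               run_break_dwell_mult = 10) {
  structure(list(min_steps_processive = min_steps_processive,
                 min_net_displacement_nm = min_net_displacement_nm,
                 pause_max_speed_um_s = pause_max_speed_um_s,
                 min_event_duration_ms = min_event_duration_ms,
                 run_break_dwell_mult = run_break_dwell_mult),
            class = "segmentation_rules")
}

#' Classify a fitted trace into runs, pauses and reversals
#'
#' Finds maximal runs of consecutive same-direction on-axis steps meeting
#' the rules' step-count and net-displacement thresholds; these become
#' retrograde/anterograde segments (on-axis sign convention: retrograde
#' positive). The gap between two processive runs of the same direction is a
#' pause, between opposite directions a reversal. Events are delimited by
#' the last step of the preceding run and the first step of the following
#' run, so an event's duration is exactly the inter-run interval.
#' Same-direction gaps shorter than `min_event_duration_ms` or with internal
#' speed above `pause_max_speed_um_s` are merged into the flanking movement.
#' Leading/trailing spans without processive movement are labelled
#' `unclassified` and excluded from event statistics.
#'
#' @param stepfit a [fit_steps()] result with `s_on_nm` filled (see
#'   [decompose_steps()]).
#' @param rules a [segmentation_rules()].
#' @return Object of class `"motion_segmentation"`: a data.frame `segments`
#'   with class, start/end time (ms), net on-axis displacement (nm), duration
#'   (ms) and speed (um/s, processive classes only), plus the rules used and
#'   a diagnostic when no processive movement was found.
#' @export
classify_motion <- function(stepfit, rules = segmentation_rules()) {
  stopifnot(inherits(stepfit, "step_fit"))
  st <- stepfit$steps
  if (nrow(st) > 0 && all(is.na(st$s_on_nm))) {
    stopf("steps are not decomposed; run decompose_steps() first")
  }
  t_first <- stepfit$t_ms[1]
  t_last <- stepfit$t_ms[length(stepfit$t_ms)]
  med_dwell <- if (nrow(st) > 0) stats::median(st$tau_ms) else Inf
  min_event <- rules$min_event_duration_ms %||% med_dwell

  runs <- find_runs(st, rules)
  merged <- TRUE
  while (merged && nrow(runs) > 1) {
    merged <- FALSE
    for (r in seq_len(nrow(runs) - 1L)) {
      if (runs$dir[r] != runs$dir[r + 1L]) next
      gap_t0 <- st$t_ms[runs$last[r]]
      gap_t1 <- st$t_ms[runs$first[r + 1L]]
      inside <- st$t_ms > gap_t0 & st$t_ms < gap_t1
      gap_disp <- sum(st$s_on_nm[inside])
      gap_speed <- abs(gap_disp) / (gap_t1 - gap_t0)  # nm/ms == um/s
      if ((gap_t1 - gap_t0) < min_event || gap_speed > rules$pause_max_speed_um_s) {
        runs$last[r] <- runs$last[r + 1L]
        runs <- runs[-(r + 1L), , drop = FALSE]
        merged <- TRUE
        break
      }
    }
  }

  segs <- list()
  add_seg <- function(class, t0, t1, disp, speed = NA_real_) {
    segs[[length(segs) + 1L]] <<- data.frame(
      class = class, t_start_ms = t0, t_end_ms = t1,
      net_disp_nm = disp, duration_ms = t1 - t0, speed_um_s = speed)
  }
  if (nrow(runs) == 0) {
    seg_df <- data.frame(class = "unclassified", t_start_ms = t_first,
                         t_end_ms = t_last, net_disp_nm = sum(st$s_on_nm),
                         duration_ms = t_last - t_first,
                         speed_um_s = NA_real_)
    return(structure(list(trace_id = stepfit$trace_id, segments = seg_df,
                          rules = rules,
                          diagnostic = "no processive segment found"),
                     class = "motion_segmentation"))
  }
  for (r in seq_len(nrow(runs))) {
    t0 <- st$t_ms[runs$first[r]]
    t1 <- st$t_ms[runs$last[r]]
    if (r == 1 && t_first < t0) {
      add_seg("unclassified", t_first, t0,
              sum(st$s_on_nm[st$t_ms <= t0]))
    }
    if (r > 1) {
      p0 <- st$t_ms[runs$last[r - 1L]]
      inside <- st$t_ms > p0 & st$t_ms < t0
      cls <- if (runs$dir[r - 1L] == runs$dir[r]) "pause" else "reversal"
      add_seg(cls, p0, t0, sum(st$s_on_nm[inside]))
    }
    run_steps <- st$t_ms > t0 & st$t_ms <= t1  # position change across run
    disp <- sum(st$s_on_nm[run_steps])
    add_seg(if (runs$dir[r] > 0) "retrograde" else "anterograde",
            t0, t1, disp, abs(disp) / (t1 - t0))
  }
  tN <- st$t_ms[runs$last[nrow(runs)]]
  if (t_last > tN) {
    add_seg("unclassified", tN, t_last, sum(st$s_on_nm[st$t_ms > tN]))
  }
  structure(list(trace_id = stepfit$trace_id,
                 segments = do.call(rbind, segs),
                 rules = rules, diagnostic = NULL),
            class = "motion_segmentation")
}

# maximal same-sign runs of on-axis steps, additionally split where the
# interval since the previous step exceeds run_break_dwell_mult median
# dwells (a long stationary stretch), then filtered by the processivity
# rules
find_runs <- function(st, rules) {
  empty <- data.frame(first = integer(0), last = integer(0), dir = numeric(0))
  if (nrow(st) == 0) return(empty)
  sgn <- sign(st$s_on_nm)
  gap <- c(0, diff(st$t_ms))
  med_dwell <- stats::median(st$tau_ms)
  break_gap <- rules$run_break_dwell_mult * med_dwell
  new_run <- c(TRUE, sgn[-1] != sgn[-length(sgn)]) | gap > break_gap
  run_id <- cumsum(new_run)
  first <- which(new_run)
  last <- c(first[-1] - 1L, length(sgn))
  keep <- (last - first + 1L) >= rules$min_steps_processive &
    sgn[first] != 0
  disp <- vapply(seq_along(first), function(i) {
    sum(st$s_on_nm[first[i]:last[i]])
  }, numeric(1))
  keep <- keep & abs(disp) >= rules$min_net_displacement_nm
  data.frame(first = first[keep], last = last[keep], dir = sgn[first][keep])
}

#' @export
print.motion_segmentation <- function(x, ...) {
  tb <- table(x$segments$class)
  cat(sprintf("<motion_segmentation '%s': %s>\n", x$trace_id,
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

as_segmentation_list <- function(x) {
  if (inherits(x, "motion_segmentation")) list(x) else x
}

#' Segment speed summaries per direction
#'
#' Median +/- raw MAD of the speeds of processive segments, per direction.
#'
#' @param segmentations a `motion_segmentation` or list of them.
#' @return data.frame with direction, n, median and MAD of speed (um/s).
#' @export
segment_speeds <- function(segmentations) {
  segs <- do.call(rbind, lapply(as_segmentation_list(segmentations),
                                function(s) s$segments))
  out <- lapply(c("retrograde", "anterograde"), function(d) {
    v <- segs$speed_um_s[segs$class == d]
    data.frame(direction = d, n = length(v),
               median_um_s = if (length(v)) stats::median(v) else NA_real_,
               mad_um_s = if (length(v)) mad_raw(v) else NA_real_)
  })
  do.call(rbind, out)
}

#' Trace-level category fractions
#'
#' Fractions of traces containing at least one reversal, at least one pause,
#' and neither ("uninterrupted"). Categories overlap, so the three fractions
#' need not sum to 1. Only traces with at least one processive segment are
#' counted.
#'
#' @param segmentations list of `motion_segmentation` objects.
#' @return Named list `contains_reversal`, `contains_pause`, `uninterrupted`,
#'   `n_traces` (the denominator).
#' @export
trace_categories <- function(segmentations) {
  segl <- as_segmentation_list(segmentations)
  has_proc <- vapply(segl, function(s) {
    any(s$segments$class %in% c("retrograde", "anterograde"))
  }, logical(1))
  segl <- segl[has_proc]
  if (length(segl) == 0) {
    return(list(contains_reversal = NA_real_, contains_pause = NA_real_,
                uninterrupted = NA_real_, n_traces = 0L))
  }
  rev <- vapply(segl, function(s) any(s$segments$class == "reversal"),
                logical(1))
  pse <- vapply(segl, function(s) any(s$segments$class == "pause"),
                logical(1))
  list(contains_reversal = mean(rev), contains_pause = mean(pse),
       uninterrupted = mean(!rev & !pse), n_traces = length(segl))
}

#' Event duration statistics
#'
#' Median +/- raw MAD of pause and reversal durations, and the ratio of the
#' pause median to the reversal median.
#'
#' @param segmentations a `motion_segmentation` or list of them.
#' @return List with per-class data.frame `stats` and
#'   `pause_reversal_ratio` (NA with a message when a class is absent).
#' @export
event_durations <- function(segmentations) {
  segs <- do.call(rbind, lapply(as_segmentation_list(segmentations),
                                function(s) s$segments))
  stats_df <- do.call(rbind, lapply(c("pause", "reversal"), function(cl) {
    d <- segs$duration_ms[segs$class == cl]
    data.frame(class = cl, n = length(d),
               median_ms = if (length(d)) stats::median(d) else NA_real_,
               mad_ms = if (length(d)) mad_raw(d) else NA_real_)
  }))
  ratio <- stats_df$median_ms[1] / stats_df$median_ms[2]
  if (any(stats_df$n == 0)) {
    message("event_durations: a class has no events; ratio is NA")
    ratio <- NA_real_
  }
  list(stats = stats_df, pause_reversal_ratio = ratio)
}

#' Fraction of events containing tug-of-war-like stepping
#'
#' An event (pause or reversal) counts when its interior contains two
#' *consecutive* on-axis steps of opposite sign, each of magnitude at least
#' `min_step_nm` — discrete forward-and-backward stepping inside an
#' interruption, the signature of a brief mechanical competition between
#' opposing motors. Requiring the pair to be adjacent suppresses incidental
#' combinations of unrelated sub-processive steps.
#'
#' @param stepfit `step_fit` (or list) matching the segmentation(s).
#' @param segmentation `motion_segmentation` (or list).
#' @param min_step_nm minimum on-axis magnitude counted (default 4 nm).
#' @return List with `fraction` (NA when no events), `n_events`,
#'   `n_with_stepping`.
#' @export
detect_intra_event_stepping <- function(stepfit, segmentation,
                                        min_step_nm = 4) {
  fits <- if (inherits(stepfit, "step_fit")) list(stepfit) else stepfit
  segl <- as_segmentation_list(segmentation)
  if (length(fits) != length(segl)) {
    stopf("stepfit and segmentation lists differ in length")
  }
  n_events <- 0L
  n_hit <- 0L
  for (i in seq_along(fits)) {
    st <- fits[[i]]$steps
    ev <- segl[[i]]$segments
    ev <- ev[ev$class %in% c("pause", "reversal"), , drop = FALSE]
    for (j in seq_len(nrow(ev))) {
      n_events <- n_events + 1L
      inside <- st$t_ms > ev$t_start_ms[j] & st$t_ms < ev$t_end_ms[j]
      s <- st$s_on_nm[inside]
      if (length(s) >= 2) {
        pair <- abs(s[-1]) >= min_step_nm &
          abs(s[-length(s)]) >= min_step_nm &
          sign(s[-1]) * sign(s[-length(s)]) < 0
        if (any(pair)) n_hit <- n_hit + 1L
      }
    }
  }
  list(fraction = if (n_events > 0) n_hit / n_events else NA_real_,
       n_events = n_events, n_with_stepping = n_hit)
}
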