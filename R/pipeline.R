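#' Pipeline configuration
#'
#' Bundles the simulator configuration with the analysis settings of the
#' end-to-end chain (simulate -> fit steps -> decompose -> segment ->
#' Markov chains -> dwell-time inference -> report). All thresholds live
#' here with frozen defaults: the 6 nm "large" and 25 nm "track-change"
#' off-axis cuts, the 3 ms dwell truncation bound, the segmentation rules
#' and the Markov discretization step.
#'
#' @param seed integer seed; fans out deterministically to per-stage child
#'   seeds.
#' @param n_traces number of traces to simulate.
#' @param sim named list of overrides passed to [sim_config()].
#' @param min_plateau_points,acceptance_threshold step-detection settings
#'   (see [fit_steps()]).
#' @param window_steps axis-estimation window (see [estimate_motion_axis()]).
#' @param rules a [segmentation_rules()].
#' @param markov_dt_ms Markov discretization step (ms).
#' @param tau_min_ms dwell-time truncation bound (ms); fits are also run
#'   untruncated (tau_min = 0) for comparison.
#' @param dwell_models candidate dwell models to fit and compare.
#' @param off_large_nm,off_jump_nm off-axis magnitude thresholds (nm) for
#'   the reported "large" and "track-change" fractions.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed,
                            n_traces = 50,
                            sim = list(),
                            min_plateau_points = 3,
                            acceptance_threshold = 2.0,
                            window_steps = 5,
                            rules = segmentation_rules(),
                            markov_dt_ms = 10,
                            tau_min_ms = 3,
                            dwell_models = c("exp1", "erlang2", "hypoexp2"),
                            off_large_nm = 6,
                            off_jump_nm = 25) {
  if (missing(seed) || !is_number(seed)) stopf("pipeline_config: seed is mandatory")
  if (!is_count(n_traces)) stopf("n_traces must be a positive integer")
  sim_cfg <- do.call(sim_config, c(sim, list(seed = seed)))
  structure(list(seed = seed, n_traces = n_traces, sim = sim_cfg,
                 min_plateau_points = min_plateau_points,
                 acceptance_threshold = acceptance_threshold,
                 window_steps = window_steps, rules = rules,
                 markov_dt_ms = markov_dt_ms, tau_min_ms = tau_min_ms,
                 dwell_models = dwell_models,
                 off_large_nm = off_large_nm, off_jump_nm = off_jump_nm),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Deterministic given the config seed: simulates the cohort, fits steps,
#' estimates axes and decomposes steps, segments every trace, estimates
#' both candidate Markov chains, fits the dwell-time models (truncated at
#' `tau_min_ms` and untruncated) with Akaike-weight comparison, and
#' assembles a run report. When `out_dir` is given, all intermediate
#' tables (traces, steps, segments) are written as CSV and the models and
#' report as JSON, plus a human-readable `summary.txt`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @return The run report (class `"run_report"`): config echo, per-stage
#'   counts, 1 nm-binned on/off-axis step histograms, dwell histogram,
#'   speed and event statistics, trace categories, Markov models and the
#'   dwell-model comparison tables.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set_seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  cohort <- simulate_cohort(config$sim, config$n_traces,
                            seed = stage_seeds[1])
  fits <- lapply(cohort$traces, function(tr) {
    f <- fit_steps(tr, config$min_plateau_points, config$acceptance_threshold)
    decompose_steps(f, window_steps = config$window_steps)
  })
  segs <- lapply(fits, classify_motion, rules = config$rules)

  step_tab <- steps_table(fits)
  seg_tab <- segments_table(segs)

  speeds <- segment_speeds(segs)
  categories <- trace_categories(segs)
  events <- event_durations(segs)
  intra <- detect_intra_event_stepping(fits, segs)

  markov <- list(
    regulated = try_markov(segs, "regulated", config$markov_dt_ms),
    tug_of_war = try_markov(segs, "tug_of_war", config$markov_dt_ms))

  taus <- dwell_times(fits)
  dwell <- lapply(c(truncated = config$tau_min_ms, untruncated = 0),
                  function(tmin) {
    fitl <- lapply(config$dwell_models, function(m)
      tryCatch(fit_dwell_model(taus, m, tau_min_ms = tmin),
               error = function(e) NULL))
    fitl <- Filter(Negate(is.null), fitl)
    list(fits = fitl,
         comparison = if (length(fitl) >= 2) compare_models(fitl) else NULL)
  })

  run_steps <- run_relative_steps(fits, segs)
  fwd <- run_steps$size[run_steps$forward]
  report <- structure(list(
    config = config,
    counts = list(
      n_traces = length(cohort$traces),
      n_steps = nrow(step_tab),
      n_segments = nrow(seg_tab),
      n_dwell_input = length(taus),
      n_dwell_used = if (length(dwell$truncated$fits) > 0)
        dwell$truncated$fits[[1]]$n_used else 0L,
      n_dwell_excluded = if (length(dwell$truncated$fits) > 0)
        dwell$truncated$fits[[1]]$n_excluded else 0L),
    step_stats = list(
      mean_forward_on_axis_nm = if (length(fwd)) mean(fwd) else NA_real_,
      backstep_fraction = if (nrow(run_steps) > 0)
        mean(!run_steps$forward) else NA_real_,
      frac_off_axis_large = if (nrow(step_tab) > 0)
        mean(abs(step_tab$s_off_nm) > config$off_large_nm, na.rm = TRUE)
        else NA_real_,
      frac_off_axis_jump = if (nrow(step_tab) > 0)
        mean(abs(step_tab$s_off_nm) > config$off_jump_nm, na.rm = TRUE)
        else NA_real_,
      median_sigma_step_nm = stats::median(step_tab$sigma_step_nm,
                                           na.rm = TRUE)),
    histograms = list(
      s_on = bin_histogram(step_tab$s_on_nm, 1),
      s_off = bin_histogram(step_tab$s_off_nm, 1),
      dwell = bin_histogram(taus, 1)),
    speeds = speeds,
    categories = categories,
    event_durations = events,
    intra_event_stepping = intra,
    markov = markov,
    dwell = dwell
  ), class = "run_report")

  if (!is.null(out_dir)) {
    write_report_artifacts(report, cohort, step_tab, seg_tab, out_dir)
  }
  report
}

try_markov <- function(segs, mechanism, dt_ms) {
  tryCatch(estimate_transitions(segs, mechanism, dt_ms),
           error = function(e) {
             message(sprintf("markov (%s): %s", mechanism, conditionMessage(e)))
             NULL
           })
}

# steps inside processive segments, signed relative to the run direction:
# "forward" means along the segment's direction of travel, so anterograde
# runs are not misread as strings of backsteps
run_relative_steps <- function(fits, segs) {
  rows <- lapply(seq_along(fits), function(i) {
    st <- fits[[i]]$steps
    sg <- segs[[i]]$segments
    sg <- sg[sg$class %in% c("retrograde", "anterograde"), , drop = FALSE]
    out <- NULL
    for (j in seq_len(nrow(sg))) {
      dir <- if (sg$class[j] == "retrograde") 1 else -1
      inside <- st$t_ms >= sg$t_start_ms[j] & st$t_ms <= sg$t_end_ms[j] &
        !is.na(st$s_on_nm)
      if (!any(inside)) next
      s <- st$s_on_nm[inside] * dir
      out <- rbind(out, data.frame(size = abs(s), forward = s > 0))
    }
    out
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(size = numeric(0), forward = logical(0)))
  }
  do.call(rbind, rows)
}

bin_histogram <- function(x, width) {
  x <- x[is.finite(x)]
  if (length(x) == 0) {
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0)))
  }
  lo <- floor(min(x) / width) * width
  hi <- ceiling(max(x) / width) * width
  if (hi <= lo) hi <- lo + width
  br <- seq(lo, hi, by = width)
  ct <- tabulate(findInterval(x, br, rightmost.closed = TRUE),
                 nbins = length(br) - 1L)
  data.frame(bin_lo = br[-length(br)], bin_hi = br[-1], count = ct)
}

#' Pooled step table of a list of step fits
#'
#' @param fits list of `step_fit` objects.
#' @return data.frame with one row per detected step
#'   (`trace_id, step_index, t_ms, s_on_nm, s_off_nm, tau_ms, sigma_step_nm`).
#' @export
steps_table <- function(fits) {
  fits <- if (inherits(fits, "step_fit")) list(fits) else fits
  rows <- lapply(fits, function(f) {
    if (nrow(f$steps) == 0) return(NULL)
    data.frame(trace_id = f$trace_id, f$steps)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(trace_id = character(0), step_index = integer(0),
                      t_ms = numeric(0), s_on_nm = numeric(0),
                      s_off_nm = numeric(0), tau_ms = numeric(0),
                      sigma_step_nm = numeric(0)))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab[, c("trace_id", "step_index", "t_ms", "s_on_nm", "s_off_nm",
          "tau_ms", "tau_censored", "sigma_step_nm")]
}

#' Pooled segment table of a list of segmentations
#'
#' @param segs list of `motion_segmentation` objects.
#' @return data.frame with one row per segment.
#' @export
segments_table <- function(segs) {
  segs <- as_segmentation_list(segs)
  tab <- do.call(rbind, lapply(segs, function(s)
    data.frame(trace_id = s$trace_id, s$segments)))
  rownames(tab) <- NULL
  tab
}

write_report_artifacts <- function(report, cohort, step_tab, seg_tab,
                                   out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_traces(cohort$traces, p("traces.csv"))
  data.table::fwrite(step_tab, p("steps.csv"))
  data.table::fwrite(seg_tab, p("segments.csv"))
  for (m in names(report$markov)) {
    if (!is.null(report$markov[[m]])) {
      write_markov_model(report$markov[[m]], p(sprintf("markov_%s.json", m)))
    }
  }
  for (d in names(report$dwell)) {
    if (length(report$dwell[[d]]$fits) > 0) {
      write_dwell_fits(report$dwell[[d]]$fits,
                       p(sprintf("dwell_%s.json", d)))
    }
  }
  jsonlite::write_json(report_payload(report), p("report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(utils::capture.output(print(report)), p("summary.txt"))
  invisible(out_dir)
}

report_payload <- function(report) {
  list(
    schema_version = 1L,
    seed = report$config$seed,
    counts = report$counts,
    step_stats = report$step_stats,
    histograms = report$histograms,
    speeds = report$speeds,
    categories = report$categories,
    event_durations = report$event_durations$stats,
    pause_reversal_ratio = report$event_durations$pause_reversal_ratio,
    intra_event_stepping = report$intra_event_stepping,
    markov = lapply(report$markov, function(m) if (is.null(m)) NULL else
      list(mechanism = m$mechanism, states = m$states, dt_ms = m$dt_ms,
           P = m$P, pi = as.numeric(m$pi))),
    dwell = lapply(report$dwell, function(d) d$comparison)
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("motorsteps run report (seed %s)\n", x$config$seed))
  cat(sprintf("  traces: %d | steps: %d | segments: %d\n",
              x$counts$n_traces, x$counts$n_steps, x$counts$n_segments))
  ss <- x$step_stats
  cat(sprintf("  mean forward on-axis step: %.2f nm | backstep fraction: %.3f\n",
              ss$mean_forward_on_axis_nm, ss$backstep_fraction))
  cat(sprintf("  off-axis > large threshold: %.3f | > jump threshold: %.4f | median sigma_step: %.2f nm\n",
              ss$frac_off_axis_large, ss$frac_off_axis_jump,
              ss$median_sigma_step_nm))
  for (i in seq_len(nrow(x$speeds))) {
    cat(sprintf("  %s speed: median %.2f um/s (MAD %.2f, n=%d)\n",
                x$speeds$direction[i], x$speeds$median_um_s[i],
                x$speeds$mad_um_s[i], x$speeds$n[i]))
  }
  ct <- x$categories
  cat(sprintf("  traces with reversal: %.1f%% | with pause: %.1f%% | uninterrupted: %.1f%% (n=%d)\n",
              100 * ct$contains_reversal, 100 * ct$contains_pause,
              100 * ct$uninterrupted, ct$n_traces))
  if (!is.na(x$event_durations$pause_reversal_ratio)) {
    cat(sprintf("  pause/reversal median duration ratio: %.1f\n",
                x$event_durations$pause_reversal_ratio))
  }
  cat(sprintf("  intra-event stepping: %.1f%% of %d events\n",
              100 * x$intra_event_stepping$fraction,
              x$intra_event_stepping$n_events))
  cat(sprintf("  dwell: n=%d used, %d excluded below %g ms\n",
              x$counts$n_dwell_used, x$counts$n_dwell_excluded,
              x$config$tau_min_ms))
  cmp <- x$dwell$truncated$comparison
  if (!is.null(cmp)) {
    cat("  dwell model comparison (truncated):\n")
    for (i in seq_len(nrow(cmp))) {
      cat(sprintf("    %-9s w(AIC)=%.3f rates=%s s^-1\n",
                  cmp$model_id[i], cmp$akaike_weight[i], cmp$rates[i]))
    }
  }
  invisible(x)
}
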