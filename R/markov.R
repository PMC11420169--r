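#' Estimate a discrete-time Markov chain from segmentations
#'
#' Builds one of the two candidate chains for the reversal mechanism of
#' bidirectional transport. The `regulated` chain distinguishes
#' direction-specific event states (`R`, `A`, `Pause_R_R`, `Pause_A_A`,
#' `Rev_R_A`, `Rev_A_R`); the `tug_of_war` chain pools all interruptions
#' into a single `Pause` state from which movement can resume in either
#' direction (`R`, `A`, `Pause`). Both occurrence and duration of segments
#' enter the estimate: each segment is discretized into
#' `round(duration / dt_ms)` dwell ticks in its state followed by one
#' transition tick into the next segment's state, and the pooled tick
#' transition counts are row-normalized.
#'
#' States never observed keep a flagged self-loop row (probability 1) rather
#' than pseudocounts, so the stationary distribution is not silently biased.
#'
#' @param segmentations a `motion_segmentation` or list of them
#'   (see [classify_motion()]); `unclassified` spans are skipped.
#' @param mechanism `"regulated"` or `"tug_of_war"`.
#' @param dt_ms discretization time step (default 10 ms, the order of the
#'   median step dwell).
#' @return Object of class `"markov_model"`: states, `dt_ms`,
#'   row-stochastic matrix `P`, stationary distribution `pi`, raw `counts`,
#'   and `unobserved` state flags.
#' @export
estimate_transitions <- function(segmentations,
                                 mechanism = c("regulated", "tug_of_war"),
                                 dt_ms = 10) {
  mechanism <- match.arg(mechanism)
  if (dt_ms <= 0) stopf("dt_ms must be > 0")
  segl <- as_segmentation_list(segmentations)
  if (length(segl) == 0) stopf("no segmentations given")
  states <- markov_states(mechanism)
  counts <- matrix(0, length(states), length(states),
                   dimnames = list(states, states))
  for (s in segl) {
    seq_states <- map_segment_states(s$segments, mechanism)
    if (is.null(seq_states) || nrow(seq_states) == 0) next
    if (dt_ms > min(seq_states$duration_ms)) {
      stopf("dt_ms = %g exceeds the shortest segment (%.3g ms); choose a smaller time step",
            dt_ms, min(seq_states$duration_ms))
    }
    m <- nrow(seq_states)
    ticks <- pmax(round(seq_states$duration_ms / dt_ms), 1)
    for (i in seq_len(m)) {
      st <- seq_states$state[i]
      if (i < m) {
        counts[st, st] <- counts[st, st] + ticks[i]
        counts[st, seq_states$state[i + 1L]] <-
          counts[st, seq_states$state[i + 1L]] + 1
      } else {
        counts[st, st] <- counts[st, st] + ticks[i] - 1
      }
    }
  }
  tot <- rowSums(counts)
  unobserved <- tot == 0
  P <- counts
  P[unobserved, ] <- 0
  P[cbind(which(unobserved), which(unobserved))] <- 1
  P[!unobserved, ] <- counts[!unobserved, , drop = FALSE] / tot[!unobserved]
  model <- structure(list(mechanism = mechanism, states = states,
                          dt_ms = dt_ms, P = P, pi = NULL, counts = counts,
                          unobserved = unobserved),
                     class = "markov_model")
  model$pi <- stationary_distribution(model)
  model
}

markov_states <- function(mechanism) {
  if (mechanism == "regulated") {
    c("R", "A", "Pause_R_R", "Pause_A_A", "Rev_R_A", "Rev_A_R")
  } else {
    c("R", "A", "Pause")
  }
}

# contiguous processive/event segments -> chain state labels
map_segment_states <- function(segments, mechanism) {
  seg <- segments[segments$class != "unclassified", , drop = FALSE]
  if (nrow(seg) == 0) return(NULL)
  lab <- character(nrow(seg))
  prev_dir <- NA_character_
  for (i in seq_len(nrow(seg))) {
    cl <- seg$class[i]
    if (cl == "retrograde") {
      lab[i] <- "R"; prev_dir <- "R"
    } else if (cl == "anterograde") {
      lab[i] <- "A"; prev_dir <- "A"
    } else if (mechanism == "tug_of_war") {
      lab[i] <- "Pause"
    } else if (cl == "pause") {
      lab[i] <- if (identical(prev_dir, "A")) "Pause_A_A" else "Pause_R_R"
    } else {
      lab[i] <- if (identical(prev_dir, "A")) "Rev_A_R" else "Rev_R_A"
    }
  }
  data.frame(state = lab, duration_ms = seg$duration_ms)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of `P` for eigenvalue 1, normalized to sum 1 and
#' polished by power iteration so that `pi %*% P == pi` to 1e-12. A
#' reducible chain (more than one closed communicating class) triggers a
#' warning and returns the average of the per-class stationary
#' distributions.
#'
#' For a fitted `markov_model`, closed classes consisting only of
#' never-observed states (their flagged self-loops) are excluded: they are
#' bookkeeping artifacts, not reachable dynamics.
#'
#' @param model a `markov_model` or a row-stochastic matrix.
#' @return Named numeric vector `pi`.
#' @export
stationary_distribution <- function(model) {
  unobserved <- NULL
  if (inherits(model, "markov_model")) {
    P <- model$P
    unobserved <- model$unobserved
  } else {
    P <- as.matrix(model)
  }
  n <- nrow(P)
  if (ncol(P) != n) stopf("P must be square")
  if (any(P < -1e-12) || any(abs(rowSums(P) - 1) > 1e-8)) {
    stopf("P must be row-stochastic")
  }
  closed <- closed_classes(P)
  if (!is.null(unobserved) && any(unobserved)) {
    real <- Filter(function(idx) !all(unobserved[idx]), closed)
    if (length(real) > 0) closed <- real
  }
  solve_class <- function(idx) {
    sub <- P[idx, idx, drop = FALSE]
    ev <- eigen(t(sub))
    w <- which.min(abs(ev$values - 1))
    v <- abs(Re(ev$vectors[, w]))
    v <- v / sum(v)
    for (it in seq_len(1000)) {      # polish the fixed point
      v2 <- as.numeric(v %*% sub)
      if (max(abs(v2 - v)) < 1e-15) { v <- v2; break }
      v <- v2
    }
    full <- numeric(n)
    full[idx] <- v
    full
  }
  if (length(closed) > 1) {
    warnf("reducible chain: %d closed classes; returning their average stationary distribution",
          length(closed))
  }
  pi <- Reduce(`+`, lapply(closed, solve_class)) / length(closed)
  names(pi) <- rownames(P)
  pi
}

# closed communicating classes via boolean reachability (small matrices)
closed_classes <- function(P) {
  n <- nrow(P)
  adj <- (P > 0) | diag(TRUE, n)
  reach <- adj
  for (i in seq_len(ceiling(log2(n)) + 1L)) {
    reach <- (reach %*% reach) > 0
  }
  comm <- reach & t(reach)
  classes <- unique(apply(comm, 1, function(r) which(r), simplify = FALSE))
  Filter(function(idx) {
    outside <- setdiff(which(apply(reach[idx, , drop = FALSE], 2, any)), idx)
    length(outside) == 0
  }, classes)
}

#' Pause versus reversal persistence
#'
#' How much more persistent pauses are than reversals in a
#' regulated-mechanism chain: the ratio of the mean per-tick escape
#' probability of the reversal states to that of the pause states,
#' `(1 - p_rev_self) / (1 - p_pause_self)`. A value of about 4 means a
#' reversal is four times more likely than a pause to end at any tick —
#' equivalently, four times less likely to persist. As the time step
#' shrinks this converges to the ratio of mean event durations.
#'
#' @param model a regulated `markov_model`.
#' @return Single number, or `NA` (with a message) when an event state was
#'   never observed.
#' @export
persistence_ratio <- function(model) {
  stopifnot(inherits(model, "markov_model"))
  if (model$mechanism != "regulated") {
    stopf("persistence_ratio is defined for the regulated mechanism")
  }
  pstates <- c("Pause_R_R", "Pause_A_A")
  rstates <- c("Rev_R_A", "Rev_A_R")
  pobs <- pstates[!model$unobserved[pstates]]
  robs <- rstates[!model$unobserved[rstates]]
  if (length(pobs) == 0 || length(robs) == 0) {
    message("persistence_ratio: unobserved event state; returning NA")
    return(NA_real_)
  }
  escape <- 1 - diag(model$P)
  mean(escape[robs]) / mean(escape[pobs])
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("<markov_model %s: dt=%g ms, states %s>\n", x$mechanism,
              x$dt_ms, paste(x$states, collapse = ", ")))
  cat("pi:", paste(sprintf("%s=%.3f", x$states, x$pi), collapse = " "), "\n")
  invisible(x)
}

#' Serialize a Markov model to JSON
#'
#' @param model a `markov_model`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_markov_model <- function(model, path) {
  stopifnot(inherits(model, "markov_model"))
  jsonlite::write_json(list(
    schema_version = 1L,
    mechanism = model$mechanism,
    states = model$states,
    dt_ms = model$dt_ms,
    P = model$P,       # row-major matrix
    pi = as.numeric(model$pi),
    counts = model$counts,
    unobserved = as.logical(model$unobserved)
  ), path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
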