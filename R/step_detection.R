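#' Bias-free change-point step detection on 2D localization traces
#'
#' Fits a piecewise-constant staircase to a trace with no prior on step
#' number or size. Change points are placed by exact penalized least
#' squares (PELT dynamic programming: global minimum of residual sum of
#' squares plus a per-change penalty expressed in units of the trace's own
#' noise variance, estimated robustly from median absolute successive
#' differences). Detection runs in two passes:
#' \enumerate{
#'   \item a 2D pass on the raw coordinates (summed x and y residuals, no
#'     axis assumption), which fixes the coarse staircase and, through the
#'     plateau centroids, the local direction of motion;
#'   \item a refined pass on the axis-projected 1D signal, where on-axis
#'     steps stand out of the noise by a factor sqrt(2) better than in 2D.
#'     Change points found only by the 2D pass (purely lateral
#'     displacements, e.g. track changes) are kept alongside.
#' }
#' The union is polished by coordinate-descent position refinement and by
#' backward elimination of steps that are not significant against their
#' own uncertainty (`prune_z`). Finally a Kerssemakers-style counter-fit
#' acceptance criterion is applied to the whole fit: the ratio of the SSE
#' of a counter fit (change points at the midpoints of the fitted
#' plateaus) to the SSE of the fit must exceed `acceptance_threshold`,
#' otherwise the trace is declared step-free. A constant noisy trace
#' therefore yields zero steps.
#'
#' The first pass is deliberately axis-free so that axis estimation and
#' step finding are not circular; the paper-style characterisation of the
#' detector ("no prior assumptions about step number or size") holds: both
#' penalties and the elimination floor scale with the measured noise, not
#' with an absolute step size.
#'
#' @param trace a [localization_trace()].
#' @param min_plateau_points minimum samples per plateau (default 3).
#' @param acceptance_threshold final counter-fit ratio gate (default 1.25,
#'   frozen from the false-positive tuning run in
#'   `scripts/tune_threshold.R`: on 200 constant traces with 3.5 nm noise
#'   at most 5% of seeds yield any step).
#' @param prune_z significance floor for retained steps (default 2.5):
#'   a step survives when its on-axis displacement exceeds `prune_z` times
#'   its uncertainty, or its full 2D magnitude exceeds `prune_z + 2` times
#'   (so large lateral jumps are never discarded). `NULL` disables
#'   elimination.
#' @param penalty_2d,penalty_1d PELT per-change-point penalties for the two
#'   passes, in units of the summed two-coordinate noise variance and the
#'   projected one-coordinate noise variance respectively (defaults 5 and
#'   6.5, frozen with the tuning run).
#' @param n_steps if given, skip selection entirely and return the fit with
#'   exactly `n_steps` greedily-placed steps (used by the oracle tests).
#' @return An object of class `"step_fit"`: plateau table (index intervals
#'   tiling the trace, centroids, durations), step table (change index,
#'   time, displacement vector, magnitude, dwell time `tau_ms` of the
#'   preceding plateau, `sigma_step_nm`, and `s_on_nm`/`s_off_nm` once
#'   decomposed), residual sum of squares, and selection diagnostics.
#'   The dwell time of the first step is left-boundary censored
#'   (`tau_censored = TRUE`); see [dwell_times()].
#' @seealso [optimal_changepoints()] for the exact fixed-k dynamic
#'   programming reference, [decompose_steps()], [dwell_times()].
#' @export
fit_steps <- function(trace, min_plateau_points = 3,
                      acceptance_threshold = 1.25,
                      prune_z = 2.5,
                      penalty_2d = 5, penalty_1d = 6.5,
                      n_steps = NULL) {
  stopifnot(inherits(trace, "localization_trace"))
  minp <- as.integer(min_plateau_points)
  if (minp < 1L) stopf("min_plateau_points must be >= 1")
  x <- trace$x_nm; y <- trace$y_nm; n <- length(x)
  if (n < 2L * minp) {
    stopf("trace '%s' has %d points; need >= 2 * min_plateau_points = %d",
          trace$trace_id, n, 2L * minp)
  }

  if (!is.null(n_steps)) {
    gr <- greedy_changepoints(x, y, minp, as.integer(n_steps), stop_gain = 0)
    if (n_steps > length(gr$cps)) {
      stopf("only %d candidate steps available, %d requested",
            length(gr$cps), n_steps)
    }
    cps <- sort(gr$cps[seq_len(n_steps)])
    cps <- refine_changepoints(x, y, cps, minp)
    cps <- move_changepoints(x, y, cps, minp)
    cps <- window_polish(x, y, cps, minp)
    return(build_step_fit(trace, cps,
                          list(threshold = NA_real_, forced = TRUE), minp))
  }

  # absolute penalty floor so exactly noiseless staircases (estimated noise
  # zero) are not shattered into zero-gain micro-plateaus
  ss0 <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
  floor_beta <- 1e-9 * (ss0 + 1)
  sigma2_2d <- noise_sd(x)^2 + noise_sd(y)^2
  cps1 <- pelt_changepoints(x, y, max(penalty_2d * sigma2_2d, floor_beta),
                            minp)

  # axis-projected second pass: direction per stage-1 plateau from windowed
  # PCA of the centroids; falls back to the global principal direction when
  # the first pass found nothing
  u <- project_on_motion_axis(x, y, cps1)
  zero <- rep(0, n)
  cps2 <- pelt_changepoints(u, zero,
                            max(penalty_1d * noise_sd(u)^2, floor_beta),
                            minp)
  lateral <- cps1[vapply(cps1, function(c) all(abs(cps2 - c) >= minp),
                         logical(1))]
  cps <- sort(unique(c(cps2, lateral)))

  cps <- refine_changepoints(x, y, cps, minp)
  if (!is.null(prune_z)) {
    cps <- eliminate_changepoints(x, y, cps, minp, prune_z)
  }
  cps <- move_changepoints(x, y, cps, minp)
  cps <- window_polish(x, y, cps, minp)
  S <- counterfit_ratio(x, y, cps)
  if (!(is.na(S) || S > acceptance_threshold)) cps <- integer(0)
  build_step_fit(trace, cps,
                 list(S = S, threshold = acceptance_threshold,
                      prune_z = prune_z, penalty_2d = penalty_2d,
                      penalty_1d = penalty_1d, forced = FALSE),
                 minp)
}

# exact penalized least-squares change points (PELT): minimises
# sum of segment SSEs + beta * (#changes), segments >= minp samples
pelt_changepoints <- function(x, y, beta, minp) {
  n <- length(x)
  seg_cost <- make_seg_cost(x, y)
  F <- rep(Inf, n + 1L)
  F[1] <- -beta
  cp_prev <- rep(NA_integer_, n + 1L)
  R <- 0L                              # candidate previous-change positions
  for (t in seq_len(n)) {
    usable <- R[t - R >= minp]
    waiting <- R[t - R < minp]
    if (length(usable) == 0) {
      R <- c(R, t)
      next
    }
    cost <- seg_cost(usable + 1L, rep(t, length(usable)))
    vals <- F[usable + 1L] + cost + beta
    w <- which.min(vals)
    F[t + 1L] <- vals[w]
    cp_prev[t + 1L] <- usable[w]
    keep <- F[usable + 1L] + cost <= F[t + 1L]
    R <- c(usable[keep], waiting, t)
  }
  cps <- integer(0)
  t <- n
  while (t > 0) {
    s <- cp_prev[t + 1L]
    if (is.na(s) || s == 0L) break
    cps <- c(s + 1L, cps)
    t <- s
  }
  cps
}

# project positions onto the overall direction of motion implied by a
# coarse plateau segmentation (PCA of the plateau centroids; the raw
# positions when the coarse pass found nothing). A single global axis is
# used on purpose: a per-plateau axis applied to absolute positions would
# inject |r| * d(angle) discontinuities at plateau boundaries.
project_on_motion_axis <- function(x, y, cps) {
  n <- length(x)
  starts <- c(1L, cps)
  ends <- c(starts[-1] - 1L, n)
  P <- length(starts)
  cent <- cbind(
    vapply(seq_len(P), function(p) mean(x[starts[p]:ends[p]]), numeric(1)),
    vapply(seq_len(P), function(p) mean(y[starts[p]:ends[p]]), numeric(1)))
  a <- principal_direction(cent)
  if (is.null(a)) a <- principal_direction(cbind(x, y))
  if (is.null(a)) a <- c(1, 0)
  x * a[1] + y * a[2]
}

# Kerssemakers counter-fit quality of one fit: SSE with change points at
# the plateau midpoints over the SSE of the fit itself
counterfit_ratio <- function(x, y, cps) {
  if (length(cps) == 0) return(NA_real_)
  n <- length(x)
  seg_cost <- make_seg_cost(x, y)
  starts <- sort(c(1L, cps))
  ends <- c(starts[-1] - 1L, n)
  fit <- sum(seg_cost(starts, ends))
  mids <- integer(0)
  for (p in seq_along(starts)) {
    if (ends[p] > starts[p]) {
      mids <- c(mids, floor((starts[p] + ends[p]) / 2) + 1L)
    }
  }
  cstarts <- sort(unique(c(1L, mids)))
  cends <- c(cstarts[-1] - 1L, n)
  counter <- sum(seg_cost(cstarts, cends))
  if (fit <= .Machine$double.eps * n) {
    if (counter <= .Machine$double.eps * n) 1 else Inf
  } else {
    counter / fit
  }
}

# robust noise sd of a piecewise-constant + Gaussian signal: successive
# differences are N(0, 2 sigma^2) away from the (sparse) steps
noise_sd <- function(v) {
  d <- diff(v)
  stats::median(abs(d)) / (0.6744898 * sqrt(2))
}

# O(1) segment SSE via zero-prefixed cumulative sums; vectorised over i, j
make_seg_cost <- function(x, y) {
  cx <- c(0, cumsum(x)); cx2 <- c(0, cumsum(x^2))
  cy <- c(0, cumsum(y)); cy2 <- c(0, cumsum(y^2))
  function(i, j) {
    ni <- j - i + 1
    sx <- cx[j + 1L] - cx[i]
    sy <- cy[j + 1L] - cy[i]
    sx2 <- cx2[j + 1L] - cx2[i]
    sy2 <- cy2[j + 1L] - cy2[i]
    pmax(sx2 - sx^2 / ni, 0) + pmax(sy2 - sy^2 / ni, 0)
  }
}

# greedy top-down placement of candidate change points, jointly over x and y.
# A change point c means the new plateau starts at index c. Stops when the
# best available gain drops to stop_gain (the caller's noise floor).
greedy_changepoints <- function(x, y, minp, max_steps, stop_gain = 0) {
  n <- length(x)
  seg_cost <- make_seg_cost(x, y)
  best_split <- function(i, j) {
    cand <- seq.int(i + minp, j - minp + 1L)
    if (length(cand) == 0 || cand[1] > cand[length(cand)]) return(NULL)
    gain <- seg_cost(i, j) - seg_cost(rep(i, length(cand)), cand - 1L) -
      seg_cost(cand, rep(j, length(cand)))
    w <- which.max(gain)            # ties -> smallest index
    list(c = cand[w], gain = gain[w])
  }
  plateaus <- list(list(i = 1L, j = n, split = best_split(1L, n)))
  cps <- integer(0)
  sse <- numeric(0)
  sse0 <- seg_cost(1L, n)
  floor_gain <- max(stop_gain, .Machine$double.eps * (sse0 + 1))
  cur <- sse0
  while (length(cps) < max_steps) {
    gains <- vapply(plateaus, function(p) {
      if (is.null(p$split)) -Inf else p$split$gain
    }, numeric(1))
    b <- which.max(gains)
    if (!is.finite(gains[b]) || gains[b] <= floor_gain) break
    p <- plateaus[[b]]
    c <- p$split$c
    cps <- c(cps, c)
    cur <- cur - p$split$gain
    sse <- c(sse, cur)
    plateaus[[b]] <- list(i = p$i, j = c - 1L,
                          split = best_split(p$i, c - 1L))
    plateaus[[length(plateaus) + 1L]] <- list(i = c, j = p$j,
                                              split = best_split(c, p$j))
  }
  list(cps = cps, sse = sse, sse0 = sse0, seg_cost = seg_cost, n = n)
}

# Kerssemakers-style quality curve: S(j) = SSE of the counter fit (change
# points at the midpoints of the j-step fit's plateaus) over SSE of the fit
counterfit_curve <- function(x, y, gr) {
  n <- gr$n
  vapply(seq_along(gr$cps), function(j) {
    starts <- sort(c(1L, gr$cps[seq_len(j)]))
    ends <- c(starts[-1] - 1L, n)
    mids <- integer(0)
    for (p in seq_along(starts)) {
      if (ends[p] > starts[p]) {
        mids <- c(mids, floor((starts[p] + ends[p]) / 2) + 1L)
      }
    }
    cstarts <- sort(unique(c(1L, mids)))
    cends <- c(cstarts[-1] - 1L, n)
    counter <- sum(gr$seg_cost(cstarts, cends))
    fit <- gr$sse[j]
    if (fit <= .Machine$double.eps * n) {
      if (counter <= .Machine$double.eps * n) 1 else Inf
    } else {
      counter / fit
    }
  }, numeric(1))
}

# coordinate-descent position refinement: each change point is re-placed at
# the least-squares optimum between its neighbours, sweeping until stable.
# Removes the residual edges that greedy placement can leave 1-2 samples off
# a true transition.
refine_changepoints <- function(x, y, cps, minp) {
  if (length(cps) == 0) return(cps)
  n <- length(x)
  seg_cost <- make_seg_cost(x, y)
  for (sweep in seq_len(20)) {
    moved <- FALSE
    bounds <- c(1L, sort(cps), n + 1L)
    for (k in seq_along(cps)) {
      new_c <- replace_cp(seg_cost, bounds[k], bounds[k + 1L],
                          bounds[k + 2L] - 1L, minp)
      if (new_c != bounds[k + 1L]) {
        bounds[k + 1L] <- new_c
        moved <- TRUE
      }
    }
    cps <- bounds[c(-1L, -length(bounds))]
    if (!moved) break
  }
  sort(cps)
}

# windowed exact polish: re-solves each run of `width` consecutive change
# points exactly (fixed-count dynamic programming on the spanned samples,
# outer boundaries held). Turns the near-tie local optima that single-point
# moves cannot fix into the global least-squares arrangement.
window_polish <- function(x, y, cps, minp, width = 6L) {
  if (length(cps) <= 1) return(cps)
  n <- length(x)
  for (sweep in 1:2) {
    changed <- FALSE
    k <- 1L
    while (k <= length(cps) - 1L) {
      hi <- min(length(cps), k + width - 1L)
      bounds <- c(1L, cps, n + 1L)
      sl <- bounds[k]                 # start of plateau before window
      er <- bounds[hi + 2L] - 1L      # end of plateau after window
      sub <- optimal_changepoints(x[sl:er], y[sl:er], hi - k + 1L, minp)
      new_cps <- sub$changepoints + sl - 1L
      if (!identical(new_cps, cps[k:hi])) {
        cps[k:hi] <- new_cps
        cps <- sort(cps)
        changed <- TRUE
      }
      k <- k + max(1L, width %/% 2L)
    }
    if (!changed) break
  }
  cps
}

# stronger local search at fixed step count: repeatedly remove one change
# point and re-insert it at the globally best position given the others,
# until no move lowers the SSE. Escapes the wrong-plateau local optima that
# within-neighbour refinement cannot fix.
move_changepoints <- function(x, y, cps, minp) {
  if (length(cps) < 1) return(cps)
  n <- length(x)
  seg_cost <- make_seg_cost(x, y)
  total_sse <- function(cc) {
    starts <- c(1L, cc)
    sum(seg_cost(starts, c(starts[-1] - 1L, n)))
  }
  cur <- total_sse(cps)
  for (sweep in seq_len(10)) {
    improved <- FALSE
    for (k in seq_along(cps)) {
      rest <- cps[-k]
      bounds <- c(1L, rest, n + 1L)
      base <- sum(seg_cost(bounds[-length(bounds)], bounds[-1] - 1L))
      best_val <- Inf
      best_cp <- NA_integer_
      for (p in seq_len(length(bounds) - 1L)) {
        sl <- bounds[p]
        er <- bounds[p + 1L] - 1L
        if (er - sl + 1L < 2L * minp) next
        cand <- seq.int(sl + minp, er - minp + 1L)
        gain <- seg_cost(sl, er) -
          seg_cost(rep(sl, length(cand)), cand - 1L) -
          seg_cost(cand, rep(er, length(cand)))
        w <- which.max(gain)
        val <- base - gain[w]
        if (val < best_val) {
          best_val <- val
          best_cp <- cand[w]
        }
      }
      if (!is.na(best_cp) && best_val < cur - 1e-9 * (cur + 1)) {
        cps <- sort(c(rest, best_cp))
        cur <- best_val
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  cps
}

# optimal position for one change point between fixed neighbours
replace_cp <- function(seg_cost, sl, cur, er, minp) {
  cand <- seq.int(sl + minp, er - minp + 1L)
  if (length(cand) == 0 || cand[1] > cand[length(cand)]) return(cur)
  tot <- seg_cost(rep(sl, length(cand)), cand - 1L) +
    seg_cost(cand, rep(er, length(cand)))
  cand[which.min(tot)]
}

# backward elimination: repeatedly drop the least significant step,
# re-placing the two neighbouring change points after each removal. A step
# is significant when its displacement projected on the local direction of
# motion exceeds prune_z uncertainties (one-coordinate test), or when its
# full 2D magnitude exceeds prune_z + 2 uncertainties (so genuine large
# lateral jumps, e.g. track changes, are never discarded). The 1D test is
# what suppresses short noise plateaus whose apparent displacement is
# mostly perpendicular to the motion.
eliminate_changepoints <- function(x, y, cps, minp, prune_z) {
  n <- length(x)
  seg_cost <- make_seg_cost(x, y)
  repeat {
    if (length(cps) == 0) return(cps)
    starts <- c(1L, cps)
    ends <- c(starts[-1] - 1L, n)
    npts <- ends - starts + 1L
    mx <- vapply(seq_along(starts), function(p)
      mean(x[starts[p]:ends[p]]), numeric(1))
    my <- vapply(seq_along(starts), function(p)
      mean(y[starts[p]:ends[p]]), numeric(1))
    sse <- vapply(seq_along(starts), function(p) {
      ix <- starts[p]:ends[p]
      sum((x[ix] - mx[p])^2) + sum((y[ix] - my[p])^2)
    }, numeric(1))
    P <- length(starts)
    k <- seq_len(P - 1L)
    dxs <- diff(mx); dys <- diff(my)
    size <- sqrt(dxs^2 + dys^2)
    dof <- 2 * (npts[k] + npts[k + 1L]) - 4
    s_pool <- sqrt((sse[k] + sse[k + 1L]) / pmax(dof, 1))
    sigma <- s_pool * sqrt(1 / npts[k] + 1 / npts[k + 1L])
    cent <- cbind(mx, my)
    s_on_abs <- vapply(k, function(i) {
      lo <- max(1L, i - 2L); hi <- min(P, i + 3L)
      u <- principal_direction(cent[lo:hi, , drop = FALSE])
      if (is.null(u)) return(size[i])
      abs(dxs[i] * u[1] + dys[i] * u[2])
    }, numeric(1))
    z_on <- ifelse(sigma > 0, s_on_abs / sigma, Inf)
    z_2d <- ifelse(sigma > 0, size / sigma, Inf)
    keep <- z_on >= prune_z | z_2d >= prune_z + 2
    if (all(keep)) return(cps)
    drop <- which.min(pmax(z_on, z_2d - 2))
    cps <- cps[-drop]
    # local re-refinement of the neighbours of the removed change point
    bounds <- c(1L, cps, n + 1L)
    for (j in intersect(c(drop - 1L, drop), seq_along(cps))) {
      bounds[j + 1L] <- replace_cp(seg_cost, bounds[j], bounds[j + 1L],
                                   bounds[j + 2L] - 1L, minp)
    }
    cps <- sort(bounds[c(-1L, -length(bounds))])
  }
}

build_step_fit <- function(trace, starts_new, selection, minp) {
  n <- length(trace$t_ms)
  starts <- c(1L, starts_new)
  ends <- c(starts[-1] - 1L, n)
  P <- length(starts)
  cx <- vapply(seq_len(P), function(p) mean(trace$x_nm[starts[p]:ends[p]]),
               numeric(1))
  cy <- vapply(seq_len(P), function(p) mean(trace$y_nm[starts[p]:ends[p]]),
               numeric(1))
  npts <- ends - starts + 1L
  sse_p <- vapply(seq_len(P), function(p) {
    ix <- starts[p]:ends[p]
    sum((trace$x_nm[ix] - cx[p])^2) + sum((trace$y_nm[ix] - cy[p])^2)
  }, numeric(1))
  plateaus <- data.frame(
    start = starts, end = ends, n = npts,
    t_start_ms = trace$t_ms[starts], t_end_ms = trace$t_ms[ends],
    cx_nm = cx, cy_nm = cy, sse = sse_p)
  if (P > 1) {
    k <- seq_len(P - 1)
    dx <- diff(cx); dy <- diff(cy)
    tau <- trace$t_ms[starts[-1]] - trace$t_ms[starts[-P]]
    pool_n <- 2 * (npts[k] + npts[k + 1]) - 4
    s_pool <- ifelse(pool_n > 0,
                     sqrt((sse_p[k] + sse_p[k + 1]) / pmax(pool_n, 1)),
                     NA_real_)
    sigma <- s_pool * sqrt(1 / npts[k] + 1 / npts[k + 1])
    sigma[npts[k] < 2 | npts[k + 1] < 2] <- NA_real_
    steps <- data.frame(
      step_index = starts[-1],
      t_ms = trace$t_ms[starts[-1]],
      dx_nm = dx, dy_nm = dy,
      size_nm = sqrt(dx^2 + dy^2),
      tau_ms = tau,
      tau_censored = c(TRUE, rep(FALSE, P - 2)),
      sigma_step_nm = sigma,
      s_on_nm = NA_real_, s_off_nm = NA_real_)
  } else {
    steps <- data.frame(
      step_index = integer(0), t_ms = numeric(0), dx_nm = numeric(0),
      dy_nm = numeric(0), size_nm = numeric(0), tau_ms = numeric(0),
      tau_censored = logical(0), sigma_step_nm = numeric(0),
      s_on_nm = numeric(0), s_off_nm = numeric(0))
  }
  structure(list(
    trace_id = trace$trace_id,
    t_ms = trace$t_ms, x_nm = trace$x_nm, y_nm = trace$y_nm,
    plateaus = plateaus, steps = steps,
    rss = sum(sse_p), n_steps = P - 1L,
    min_plateau_points = minp,
    selection = selection,
    metadata = trace$metadata,
    axes = NULL
  ), class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("<step_fit '%s': %d points, %d steps, rss %.1f nm^2>\n",
              x$trace_id, length(x$t_ms), x$n_steps, x$rss))
  invisible(x)
}

#' Exact least-squares change points by dynamic programming
#'
#' Reference solver used to validate the greedy detector: computes the
#' global minimum of the summed squared residuals over both coordinates for
#' a piecewise-constant fit with exactly `n_changes` change points. Runs in
#' O(k n^2); intended for traces of at most a few hundred points.
#'
#' @param x,y coordinate vectors.
#' @param n_changes number of change points (>= 0).
#' @param min_plateau_points minimum samples per plateau.
#' @return List with `changepoints` (indices where new plateaus start,
#'   sorted) and `sse` (the optimal residual).
#' @export
optimal_changepoints <- function(x, y, n_changes, min_plateau_points = 1) {
  n <- length(x)
  minp <- as.integer(min_plateau_points)
  k <- as.integer(n_changes)
  if (length(y) != n) stopf("x and y lengths differ")
  if (k < 0) stopf("n_changes must be >= 0")
  if ((k + 1L) * minp > n) stopf("too many change points for trace length")
  seg_cost <- make_seg_cost(x, y)
  # dp[r, j]: best SSE for x[1..j] with r-1 changes; arg[r, j]: last start
  dp <- matrix(Inf, k + 1L, n)
  arg <- matrix(NA_integer_, k + 1L, n)
  ok0 <- seq.int(minp, n)
  dp[1, ok0] <- seg_cost(rep(1L, length(ok0)), ok0)
  if (k > 0) {
    for (r in seq_len(k)) {
      for (j in seq.int((r + 1L) * minp, n)) {
        cc <- seq.int(r * minp + 1L, j - minp + 1L)
        tot <- dp[r, cc - 1L] + seg_cost(cc, rep(j, length(cc)))
        w <- which.min(tot)
        dp[r + 1L, j] <- tot[w]
        arg[r + 1L, j] <- cc[w]
      }
    }
  }
  cps <- integer(0)
  j <- n
  for (r in seq.int(k + 1L, 2L, length.out = k)) {
    c <- arg[r, j]
    cps <- c(c, cps)
    j <- c - 1L
  }
  list(changepoints = cps, sse = dp[k + 1L, n])
}

#' Dwell times between successive detected steps
#'
#' The dwell time of a step is the duration of the plateau preceding it.
#' The first plateau starts at an unknown offset into its true dwell, so the
#' first step's dwell is left-boundary censored and dropped by default.
#'
#' @param stepfit a [fit_steps()] result, or a list of them.
#' @param drop_censored drop the first (censored) dwell per trace.
#' @return Numeric vector of dwell times in ms.
#' @export
dwell_times <- function(stepfit, drop_censored = TRUE) {
  fits <- if (inherits(stepfit, "step_fit")) list(stepfit) else stepfit
  unlist(lapply(fits, function(f) {
    s <- f$steps
    if (nrow(s) == 0) return(numeric(0))
    if (drop_censored) s <- s[!s$tau_censored, , drop = FALSE]
    s$tau_ms
  }), use.names = FALSE)
}
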