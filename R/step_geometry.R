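#' Per-step motion-axis estimation
#'
#' Estimates the local direction of motion for every detected step as the
#' principal direction of the plateau centroids inside a window of
#' `window_steps` steps centred on the step (windows shrink at the trace
#' ends). Axes are unit vectors oriented so that they point in the
#' retrograde direction: along `metadata$retro_dir` when the trace declares
#' it, otherwise along the trace's net displacement (majority direction).
#'
#' @param stepfit a [fit_steps()] result with at least 2 plateaus.
#' @param window_steps window width in steps (default 5).
#' @return Numeric matrix (n_steps x 2) of unit axis vectors.
#' @export
estimate_motion_axis <- function(stepfit, window_steps = 5) {
  stopifnot(inherits(stepfit, "step_fit"))
  P <- nrow(stepfit$plateaus)
  if (P < 2) stopf("axis estimation needs >= 2 plateaus (one step)")
  cent <- cbind(stepfit$plateaus$cx_nm, stepfit$plateaus$cy_nm)
  ref <- stepfit$metadata$retro_dir
  if (is.null(ref)) ref <- cent[P, ] - cent[1, ]
  if (sum(ref^2) == 0) ref <- c(1, 0)
  half <- max(1L, floor(window_steps / 2))
  global_dir <- principal_direction(cent)
  axes <- matrix(NA_real_, P - 1L, 2)
  for (i in seq_len(P - 1L)) {
    lo <- max(1L, i - half)
    hi <- min(P, i + 1L + half)
    u <- principal_direction(cent[lo:hi, , drop = FALSE])
    if (is.null(u)) u <- global_dir
    if (is.null(u)) u <- c(1, 0)  # fully degenerate trace
    axes[i, ] <- orient_axis(u, ref)
  }
  axes
}

# first principal component of a set of 2D points; NULL when degenerate
principal_direction <- function(pts) {
  if (nrow(pts) < 2) return(NULL)
  d <- sweep(pts, 2, colMeans(pts))
  cv <- crossprod(d) / nrow(pts)
  if (sum(diag(cv)) <= .Machine$double.eps) return(NULL)
  ev <- eigen(cv, symmetric = TRUE)
  u <- ev$vectors[, 1]
  u / sqrt(sum(u^2))
}

orient_axis <- function(u, ref) {
  s <- sum(u * ref)
  if (s < 0) u <- -u
  if (s == 0) {               # deterministic tie-break
    if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
  }
  u
}

#' Decompose detected steps into on-axis and off-axis components
#'
#' Projects each step displacement vector onto its local motion axis:
#' `s_on = step . axis` (retrograde positive) and `s_off = step . axis_perp`
#' with `axis_perp` the axis rotated by +90 degrees. Magnitude is preserved:
#' `sqrt(s_on^2 + s_off^2)` equals the step size.
#'
#' @param stepfit a [fit_steps()] result.
#' @param axes per-step axis matrix from [estimate_motion_axis()]; computed
#'   with defaults when omitted.
#' @param window_steps passed to [estimate_motion_axis()] when `axes` is
#'   missing.
#' @return The `step_fit` with `s_on_nm`, `s_off_nm` filled and the axes
#'   stored in `$axes`.
#' @export
decompose_steps <- function(stepfit, axes = NULL, window_steps = 5) {
  stopifnot(inherits(stepfit, "step_fit"))
  if (stepfit$n_steps == 0) {
    stepfit$axes <- matrix(numeric(0), 0, 2)
    return(stepfit)
  }
  if (is.null(axes)) axes <- estimate_motion_axis(stepfit, window_steps)
  if (!is.matrix(axes) || nrow(axes) != stepfit$n_steps || ncol(axes) != 2) {
    stopf("axes must be a %d x 2 matrix", stepfit$n_steps)
  }
  dx <- stepfit$steps$dx_nm; dy <- stepfit$steps$dy_nm
  stepfit$steps$s_on_nm <- dx * axes[, 1] + dy * axes[, 2]
  stepfit$steps$s_off_nm <- -dx * axes[, 2] + dy * axes[, 1]
  stepfit$axes <- axes
  stepfit
}

#' Localization precision from plateau residuals
#'
#' For every plateau with at least `min_points` samples, the precision is
#' the pooled standard deviation of the x and y residuals about the plateau
#' centroid. Returns the median +/- raw MAD across plateaus, the summary
#' convention used for instrument precision.
#'
#' @param trace the [localization_trace()] that was fitted.
#' @param stepfit its [fit_steps()] result.
#' @param min_points minimum plateau size considered (default 3).
#' @return List with `median_nm`, `mad_nm`, `per_plateau_nm`.
#' @export
estimate_localization_precision <- function(trace, stepfit, min_points = 3) {
  stopifnot(inherits(stepfit, "step_fit"))
  pl <- stepfit$plateaus
  keep <- pl$n >= min_points
  if (!any(keep)) stopf("no plateau with >= %d points", min_points)
  prec <- sqrt(pl$sse[keep] / (2 * pl$n[keep] - 2))
  list(median_nm = stats::median(prec), mad_nm = mad_raw(prec),
       per_plateau_nm = prec)
}

#' Per-step size uncertainties
#'
#' Standard error of a step size between plateaus with n1 and n2 points:
#' `sigma_step = s * sqrt(1/n1 + 1/n2)` with `s` the residual standard
#' deviation pooled over both coordinates of both plateaus. Steps adjacent
#' to a single-point plateau get `NA` (reported and counted).
#'
#' @param trace the fitted [localization_trace()] (unused beyond interface
#'   symmetry; residuals come from the fit).
#' @param stepfit a [fit_steps()] result.
#' @return Numeric vector of per-step uncertainties (nm).
#' @export
step_uncertainties <- function(trace, stepfit) {
  stopifnot(inherits(stepfit, "step_fit"))
  sigma <- stepfit$steps$sigma_step_nm
  n_missing <- sum(is.na(sigma))
  if (n_missing > 0) {
    message(sprintf("step_uncertainties: %d step(s) adjacent to a <2-point plateau; reported as NA",
                    n_missing))
  }
  sigma
}
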