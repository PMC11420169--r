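#' Kymograph container
#'
#' A time-versus-position intensity image: rows are time (one frame per
#' `dt_ms`), columns are position along the axon (one pixel per `dx_um`)
#' with the soma toward low column index. Under this convention a particle
#' moving retrograde (toward the soma) traces a line of negative slope.
#'
#' @param intensity numeric matrix, finite and non-negative.
#' @param dt_ms time per row (ms).
#' @param dx_um distance per column (um).
#' @return Object of class `"kymograph"`.
#' @export
kymograph <- function(intensity, dt_ms, dx_um) {
  intensity <- as.matrix(intensity)
  if (any(!is.finite(intensity))) stopf("kymograph intensities must be finite")
  if (any(intensity < 0)) stopf("kymograph intensities must be non-negative")
  if (dt_ms <= 0 || dx_um <= 0) stopf("pixel sizes must be > 0")
  structure(list(intensity = intensity, dt_ms = dt_ms, dx_um = dx_um),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph %d x %d px (%g ms/px, %g um/px)>\n",
              nrow(x$intensity), ncol(x$intensity), x$dt_ms, x$dx_um))
  invisible(x)
}

#' Directional Fourier filtering of a kymograph
#'
#' Separates movement directions in frequency space: the 2D Fourier
#' transform of a line of constant speed concentrates along a line through
#' the origin whose quadrant is set by the slope sign, so zeroing the two
#' quadrants of the opposite sign and inverse-transforming keeps only one
#' direction of motion. The axial component (DC plus the zero-frequency and
#' Nyquist rows/columns, i.e. static and purely-temporal structure) is
#' retained in both outputs, which makes the decomposition exactly
#' complementary:
#' `retrograde + anterograde - axial = original` to machine precision
#' (see [axial_component()]). The filter is linear.
#'
#' @param kymo a [kymograph()] of size at least 4 x 4.
#' @param direction `"retrograde"` (negative slope) or `"anterograde"`.
#' @return A filtered `kymograph` (real part of the inverse transform;
#'   small negative ringing values are kept in the `intensity` matrix,
#'   which for filtered output is allowed to be signed).
#' @export
directional_filter <- function(kymo, direction = c("retrograde", "anterograde")) {
  stopifnot(inherits(kymo, "kymograph"))
  direction <- match.arg(direction)
  img <- kymo$intensity
  if (nrow(img) < 4 || ncol(img) < 4) stopf("kymograph must be >= 4 x 4")
  F <- fft(img)
  mask <- quadrant_mask(nrow(img), ncol(img),
                        same_sign = (direction == "retrograde"))
  out <- Re(fft(F * mask, inverse = TRUE)) / length(img)
  res <- kymo
  res$intensity <- out
  res
}

#' Axial (non-directional) component of a kymograph
#'
#' The part of the image carried by the zero-frequency and Nyquist rows and
#' columns of the 2D spectrum: static background and structure with no
#' resolvable slope. This component is included in both directional
#' outputs, so `directional_filter(k, "retrograde")$intensity +
#' directional_filter(k, "anterograde")$intensity - axial_component(k)`
#' reproduces the original image.
#'
#' @param kymo a [kymograph()].
#' @return Numeric matrix.
#' @export
axial_component <- function(kymo) {
  stopifnot(inherits(kymo, "kymograph"))
  img <- kymo$intensity
  F <- fft(img)
  ax <- axial_mask(nrow(img), ncol(img))
  Re(fft(F * ax, inverse = TRUE)) / length(img)
}

# signed frequency index for an FFT dimension of size n
signed_freq <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k <= n / 2, k, k - n)
}

axial_mask <- function(nr, nc) {
  ft <- signed_freq(nr); fx <- signed_freq(nc)
  ax_t <- ft == 0 | (nr %% 2 == 0 & ft == nr / 2)
  ax_x <- fx == 0 | (nc %% 2 == 0 & fx == nc / 2)
  outer(ax_t, ax_x, `|`) * 1
}

quadrant_mask <- function(nr, nc, same_sign) {
  ft <- signed_freq(nr); fx <- signed_freq(nc)
  sgn <- outer(sign(ft), sign(fx))
  m <- if (same_sign) (sgn > 0) else (sgn < 0)
  (m | axial_mask(nr, nc) > 0) * 1
}

#' Speed and direction of a kymograph line
#'
#' Converts the endpoints of a traced line to a speed with a direction
#' label. Endpoints are in physical units (ms, um), e.g. from a line
#' annotation table; pixel coordinates convert via the kymograph's pixel
#' sizes before calling.
#'
#' @param t0_ms,x0_um,t1_ms,x1_um endpoints (time ms, position um).
#' @return List with `speed_um_s` (non-negative) and `direction`
#'   (`"retrograde"`, `"anterograde"` or `"stationary"`).
#' @examples
#' line_speed(0, 0, 10000, 10) # 1 um/s anterograde
#' @export
line_speed <- function(t0_ms, x0_um, t1_ms, x1_um) {
  if (t1_ms == t0_ms) stopf("line has zero time extent")
  slope <- (x1_um - x0_um) / ((t1_ms - t0_ms) / 1000)
  list(speed_um_s = abs(slope),
       direction = if (slope < 0) "retrograde"
                   else if (slope > 0) "anterograde" else "stationary")
}

#' Read/write kymographs as plain-text matrices
#'
#' Plain-text serialization: the first line is a JSON header with the pixel
#' sizes and dimensions, followed by one CSV row of intensities per time
#' frame. (A TIFF route is intentionally not provided: the toolchain is
#' text-only and no TIFF codec is assumed.)
#'
#' @param kymo a [kymograph()].
#' @param path file path.
#' @return `write_kymograph`: `path` invisibly; `read_kymograph`: a
#'   [kymograph()].
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  hdr <- jsonlite::toJSON(list(schema_version = 1L, dt_ms = kymo$dt_ms,
                               dx_um = kymo$dx_um,
                               n_time = nrow(kymo$intensity),
                               n_pos = ncol(kymo$intensity)),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  utils::write.table(kymo$intensity, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  mat <- as.matrix(utils::read.table(text = lines[-1], sep = ","))
  dimnames(mat) <- NULL
  if (nrow(mat) != hdr$n_time || ncol(mat) != hdr$n_pos) {
    stopf("%s: matrix dimensions do not match header", path)
  }
  kymograph(mat, hdr$dt_ms, hdr$dx_um)
}
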