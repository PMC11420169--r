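#' Localization trace container
#'
#' A `localization_trace` holds the time-ordered 2D positions of a single
#' tracked fluorophore in the lab frame, plus optional per-point precision
#' and acquisition metadata. This is the raw input of every analysis stage.
#'
#' @param trace_id single string identifying the trace.
#' @param t_ms numeric timestamps in ms, strictly increasing.
#' @param x_nm,y_nm numeric coordinates in nm, finite.
#' @param sigma_nm optional per-point localization precision (nm).
#' @param metadata named list; recognised entries are `label_site` (one of
#'   `"DHC"`, `"DIC"`, `"unknown"`), `dt_ms` (acquisition interval) and
#'   `retro_dir` (lab-frame unit vector of the retrograde direction, used to
#'   orient on-axis signs when present).
#'
#' @return An object of class `"localization_trace"`.
#' @export
localization_trace <- function(trace_id, t_ms, x_nm, y_nm, sigma_nm = NULL,
                               metadata = list()) {
  trace_id <- as.character(trace_id)
  if (length(trace_id) != 1L || is.na(trace_id) || !nzchar(trace_id)) {
    stopf("trace_id must be a single non-empty string")
  }
  n <- length(t_ms)
  if (n < 2L) stopf("trace '%s': needs >= 2 points, got %d", trace_id, n)
  if (length(x_nm) != n || length(y_nm) != n) {
    stopf("trace '%s': t/x/y lengths differ", trace_id)
  }
  if (any(!is.finite(t_ms)) || any(!is.finite(x_nm)) || any(!is.finite(y_nm))) {
    stopf("trace '%s': non-finite coordinate or timestamp", trace_id)
  }
  if (any(diff(t_ms) <= 0)) {
    stopf("trace '%s': timestamps must be strictly increasing", trace_id)
  }
  if (!is.null(sigma_nm) && length(sigma_nm) != n) {
    stopf("trace '%s': sigma_nm length mismatch", trace_id)
  }
  md <- metadata %||% list()
  md$label_site <- md$label_site %||% "unknown"
  structure(list(trace_id = trace_id, t_ms = as.numeric(t_ms),
                 x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm),
                 sigma_nm = sigma_nm, metadata = md),
            class = "localization_trace")
}

#' @export
print.localization_trace <- function(x, ...) {
  cat(sprintf("<localization_trace '%s': %d points, %.1f ms, site %s>\n",
              x$trace_id, length(x$t_ms), diff(range(x$t_ms)),
              x$metadata$label_site))
  invisible(x)
}

#' @export
length.localization_trace <- function(x) length(x$t_ms)

#' Read localization traces from delimited text
#'
#' Expects a comma-separated file with header columns
#' `trace_id,t_ms,x_nm,y_nm` and optionally `sigma_nm`. Rows are grouped by
#' exact `trace_id` string match and sorted by time within each trace;
#' duplicated timestamps within a trace are a parse error.
#'
#' @param path file to read.
#' @return A named list of [localization_trace()] objects, in order of first
#'   appearance in the file.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- data.table::fread(path, colClasses = list(character = "trace_id"),
                          showProgress = FALSE)
  required <- c("trace_id", "t_ms", "x_nm", "y_nm")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols) > 0) {
    stopf("%s: missing column(s) %s", path,
          paste(missing_cols, collapse = ", "))
  }
  if (nrow(dt) == 0) return(structure(list(), names = character(0)))
  for (col in c("t_ms", "x_nm", "y_nm")) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stopf("%s: non-numeric value in column '%s' at data row %d",
            path, col, if (is.na(bad)) 1L else bad)
    }
  }
  ids <- unique(dt$trace_id)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    sub <- dt[dt$trace_id == id, ]
    ord <- order(sub$t_ms)
    sub <- sub[ord, ]
    dup <- which(diff(sub$t_ms) == 0)
    if (length(dup) > 0) {
      stopf("%s: duplicated timestamp t_ms=%g for trace_id '%s' (row %d)",
            path, sub$t_ms[dup[1] + 1L], id, dup[1] + 1L)
    }
    sig <- if ("sigma_nm" %in% names(sub)) sub$sigma_nm else NULL
    out[[id]] <- localization_trace(id, sub$t_ms, sub$x_nm, sub$y_nm,
                                    sigma_nm = sig)
  }
  out
}

#' Write localization traces to delimited text
#'
#' Inverse of [read_traces()]: emits one `trace_id,t_ms,x_nm,y_nm[,sigma_nm]`
#' row per localization, traces in the order given, points in time order.
#' An empty input writes a header-only file.
#'
#' @param traces a [localization_trace()] or list of them.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "localization_trace")) traces <- list(traces)
  has_sigma <- any(vapply(traces, function(tr) !is.null(tr$sigma_nm),
                          logical(1)))
  rows <- lapply(traces, function(tr) {
    d <- data.table::data.table(trace_id = tr$trace_id, t_ms = tr$t_ms,
                                x_nm = tr$x_nm, y_nm = tr$y_nm)
    if (has_sigma) d$sigma_nm <- tr$sigma_nm %||% rep(NA_real_, length(tr$t_ms))
    d
  })
  empty <- data.table::data.table(trace_id = character(0), t_ms = numeric(0),
                                  x_nm = numeric(0), y_nm = numeric(0))
  if (has_sigma) empty$sigma_nm <- numeric(0)
  dt <- if (length(rows) > 0) data.table::rbindlist(rows) else empty
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a JSON run-configuration file
#'
#' Keys mirror the arguments of [sim_config()] and [pipeline_config()];
#' unknown keys are an error so that typos do not silently fall back to
#' defaults. A `seed` entry is mandatory.
#'
#' @param path JSON file.
#' @param constructor which config to build: `"pipeline"` or `"sim"`.
#' @return A validated config object.
#' @export
read_config <- function(path, constructor = c("pipeline", "sim")) {
  constructor <- match.arg(constructor)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(vals$seed)) stopf("%s: config must set a seed", path)
  fn <- if (constructor == "pipeline") pipeline_config else sim_config
  known <- names(formals(fn))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stopf("%s: unknown config key(s): %s", path,
          paste(unknown, collapse = ", "))
  }
  do.call(fn, vals)
}
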