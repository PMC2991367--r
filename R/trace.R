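#' Whole-cell current trace
#'
#' Container for a single uniformly sampled voltage-clamp current recording.
#' Sample `i` (1-based) is assigned the time `(i - 1) / sampling_rate * 1000`
#' milliseconds, so the first sample sits at t = 0 ms.
#'
#' @param samples numeric vector of current values (pA); must be finite.
#' @param sampling_rate sampling frequency in Hz (default 10000).
#' @param laser_onset photostimulation onset time in ms, or `NULL` when the
#'   trace was recorded without a stimulus (spontaneous activity, simulation).
#' @param site optional integer vector `c(row, col)` locating the trace on a
#'   photostimulation grid.
#' @param polarity `"inward"` for raw EPSC-sign data, `"inverted"` once
#'   [invert_polarity()] has been applied (IPSC workflow).
#' @return An object of class `psc_trace`.
#' @seealso [invert_polarity()], [read_trace()], [detect_events()]
#' @export
psc_trace <- function(samples, sampling_rate = 10000, laser_onset = NULL,
                      site = NULL, polarity = c("inward", "inverted")) {
  polarity <- match.arg(polarity)
  samples <- as.numeric(samples)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("'sampling_rate' must be a single positive number (Hz)")
  }
  if (length(samples) && any(!is.finite(samples))) {
    stop("all trace samples must be finite")
  }
  if (!is.null(laser_onset)) {
    laser_onset <- as.numeric(laser_onset)
    stopifnot(length(laser_onset) == 1, is.finite(laser_onset))
    if (laser_onset < 0 || laser_onset > trace_duration_ms(samples, sampling_rate)) {
      stop("'laser_onset' must lie within the trace extent")
    }
  }
  if (!is.null(site)) {
    site <- as.integer(site)
    stopifnot(length(site) == 2)
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         laser_onset = laser_onset, site = site, polarity = polarity),
    class = "psc_trace")
}

trace_duration_ms <- function(samples, sampling_rate) {
  (length(samples) - 1) / sampling_rate * 1000
}

#' @export
print.psc_trace <- function(x, ...) {
  cat(sprintf("<psc_trace> %d samples @ %g Hz (%.1f ms), polarity %s\n",
              length(x$samples), x$sampling_rate,
              trace_duration_ms(x$samples, x$sampling_rate), x$polarity))
  if (!is.null(x$laser_onset)) cat(sprintf("  laser onset: %.2f ms\n", x$laser_onset))
  if (!is.null(x$site)) cat(sprintf("  site: (%d, %d)\n", x$site[1], x$site[2]))
  invisible(x)
}

#' @export
length.psc_trace <- function(x) length(x$samples)

# sample index (1-based) -> time in ms
idx_to_ms <- function(i, sampling_rate) (i - 1) / sampling_rate * 1000

# time in ms -> nearest sample index (clamped to [1, n] when n given)
ms_to_idx <- function(t, sampling_rate, n = NULL) {
  i <- round(t * sampling_rate / 1000) + 1
  if (!is.null(n)) i <- pmin(pmax(i, 1L), n)
  as.integer(i)
}

#' Invert trace polarity for IPSC analysis
#'
#' Outward (positive-going) IPSCs are turned into inward, EPSC-like
#' deflections by negating the samples; the detection pipeline is then used
#' unchanged. Applying the inversion twice restores the original trace.
#'
#' @param trace a [psc_trace()].
#' @return The trace with samples negated and the polarity flag toggled.
#' @export
invert_polarity <- function(trace) {
  stopifnot(inherits(trace, "psc_trace"))
  trace$samples <- -trace$samples
  trace$polarity <- if (trace$polarity == "inward") "inverted" else "inward"
  trace
}

#' Read a single-column trace file
#'
#' The plain-text trace format is one current value (pA) per line, preceded
#' by comment headers of the form `# sampling_rate_hz=10000` and, optionally,
#' `# laser_onset_ms=100`.
#'
#' @param path file path.
#' @return A [psc_trace()].
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta <- parse_trace_headers(lines, path)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  samples <- suppressWarnings(as.numeric(body))
  if (any(is.na(samples))) {
    bad <- which(is.na(samples))[1]
    stop(sprintf("%s: non-numeric sample value in data line %d", path, bad))
  }
  psc_trace(samples, sampling_rate = meta$sampling_rate,
            laser_onset = meta$laser_onset)
}

parse_trace_headers <- function(lines, path) {
  hdr <- grep("^\\s*#", lines, value = TRUE)
  get <- function(key) {
    pat <- paste0("^\\s*#\\s*", key, "\\s*=\\s*(.+)\\s*$")
    hit <- grep(pat, hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    val <- suppressWarnings(as.numeric(sub(pat, "\\1", hit[1])))
    if (is.na(val)) {
      lineno <- grep(pat, lines)[1]
      stop(sprintf("%s: line %d: header '%s' is not numeric", path, lineno, key))
    }
    val
  }
  sr <- get("sampling_rate_hz")
  if (is.null(sr)) stop(sprintf("%s: missing required header 'sampling_rate_hz'", path))
  list(sampling_rate = sr, laser_onset = get("laser_onset_ms"))
}

#' Write a single-column trace file
#'
#' @param trace a [psc_trace()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "psc_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz=%.10g", trace$sampling_rate), con)
  if (!is.null(trace$laser_onset)) {
    writeLines(sprintf("# laser_onset_ms=%.10g", trace$laser_onset), con)
  }
  writeLines(format(trace$samples, digits = 15, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

#' Read a multi-trace container file
#'
#' The container format is a tab-separated matrix (one row per trace, one
#' column per sample) preceded by the same `#key=value` headers as
#' [read_trace()]. An optional sidecar JSON file maps 1-based trace indices
#' to grid positions: `{"1": [1, 1], "2": [1, 2], ...}`.
#'
#' @param path container file path.
#' @param layout optional path of a JSON sidecar assigning `(row, col)` grid
#'   sites to trace indices.
#' @return A list of [psc_trace()] objects.
#' @export
read_traces <- function(path, layout = NULL) {
  lines <- readLines(path)
  meta <- parse_trace_headers(lines, path)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rows <- strsplit(body, "\t", fixed = TRUE)
  lens <- lengths(rows)
  if (length(unique(lens)) > 1) {
    stop(sprintf("%s: inconsistent trace lengths (%s)", path,
                 paste(unique(lens), collapse = ", ")))
  }
  sites <- NULL
  if (!is.null(layout)) {
    lay <- jsonlite::read_json(layout, simplifyVector = TRUE)
    sites <- lay
  }
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    samples <- suppressWarnings(as.numeric(rows[[i]]))
    if (any(is.na(samples))) stop(sprintf("%s: non-numeric value in trace %d", path, i))
    site <- if (!is.null(sites)) sites[[as.character(i)]] else NULL
    out[[i]] <- psc_trace(samples, sampling_rate = meta$sampling_rate,
                          laser_onset = meta$laser_onset, site = site)
  }
  out
}

#' Write a multi-trace container file
#'
#' All traces must share sampling rate and laser onset; per-trace sites are
#' written to a JSON sidecar when `layout` is given.
#'
#' @param traces list of [psc_trace()] objects of equal length.
#' @param path destination path.
#' @param layout optional path for the JSON site sidecar.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, layout = NULL) {
  stopifnot(length(traces) >= 1, all(vapply(traces, inherits, TRUE, "psc_trace")))
  sr <- unique(vapply(traces, function(x) x$sampling_rate, 0))
  if (length(sr) != 1) stop("all traces must share one sampling rate")
  los <- unique(vapply(traces, function(x) {
    if (is.null(x$laser_onset)) NA_real_ else x$laser_onset
  }, 0))
  if (length(los) != 1) stop("all traces must share one laser onset")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz=%.10g", sr), con)
  if (!is.na(los)) writeLines(sprintf("# laser_onset_ms=%.10g", los), con)
  for (tr in traces) {
    writeLines(paste(format(tr$samples, digits = 15, trim = TRUE,
                            scientific = FALSE), collapse = "\t"), con)
  }
  if (!is.null(layout)) {
    sites <- list()
    for (i in seq_along(traces)) {
      if (!is.null(traces[[i]]$site)) sites[[as.character(i)]] <- traces[[i]]$site
    }
    jsonlite::write_json(sites, layout, auto_unbox = FALSE)
  }
  invisible(path)
}
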