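#' Baseline-subtracted mean input amplitude for one stimulation site
#'
#' The site's input amplitude is the mean current carried by detected events
#' in the response analysis window -- the sum of their summed-input
#' contributions (pA.ms) divided by the window length (ms) -- minus the same
#' statistic computed on the pre-stimulus (spontaneous) portion of the same
#' trace, so sites whose evoked activity equals their spontaneous activity
#' map to 0 pA.
#'
#' @param events data frame of detected events for this site (needs columns
#'   `summed_input_pAms` and `latency_ms`).
#' @param window `c(start, end)` of the analysis window, ms after laser
#'   onset.
#' @param spont_events events detected in the pre-stimulus portion (their
#'   latencies are negative); `NULL` for none.
#' @param spont_duration length of the pre-stimulus portion, ms; defaults to
#'   the analysis-window length.
#' @return Mean input amplitude, pA.
#' @export
site_input_amplitude <- function(events, window, spont_events = NULL,
                                 spont_duration = NULL) {
  stopifnot(length(window) == 2, window[2] > window[1])
  wlen <- window[2] - window[1]
  if (is.null(spont_duration)) spont_duration <- wlen
  evoked <- 0
  if (!is.null(events) && nrow(events)) {
    inw <- events$latency_ms >= window[1] & events$latency_ms < window[2]
    evoked <- sum(events$summed_input_pAms[inw]) / wlen
  }
  spont <- 0
  if (!is.null(spont_events) && nrow(spont_events)) {
    spont <- sum(spont_events$summed_input_pAms) / spont_duration
  }
  evoked - spont
}

#' Build the three photostimulation map layers
#'
#' Aggregates detected events per stimulation site into the three map layers
#' of a circuit-mapping experiment: baseline-subtracted mean input amplitude
#' (pA), in-window event count, and first-event latency (ms; `NA` where no
#' event occurred). Events with negative latency are treated as pre-stimulus
#' (spontaneous) activity and feed the baseline of the amplitude layer.
#'
#' @param events data frame of detected events across sites, with columns
#'   `row`, `col`, `latency_ms`, `summed_input_pAms`.
#' @param grid `c(rows, cols)` map dimensions (default 16 x 16).
#' @param window analysis window `c(start, end)`, ms after laser onset
#'   (default 10-150 ms, i.e. from the end of the direct-response window).
#' @param spont_duration pre-stimulus duration per trace, ms; defaults to
#'   the window length.
#' @return List of three matrices: `input_amplitude_pA`, `event_count`,
#'   `first_latency_ms`.
#' @export
build_maps <- function(events, grid = c(16, 16), window = c(10, 150),
                       spont_duration = NULL) {
  stopifnot(is.data.frame(events),
            all(c("row", "col", "latency_ms", "summed_input_pAms") %in%
                  names(events)))
  if (nrow(events) &&
      (max(events$row) > grid[1] || max(events$col) > grid[2] ||
       min(events$row) < 1 || min(events$col) < 1)) {
    stop("event site indices fall outside the grid layout")
  }
  amp <- matrix(0, grid[1], grid[2])
  cnt <- matrix(0L, grid[1], grid[2])
  lat <- matrix(NA_real_, grid[1], grid[2])
  for (r in seq_len(grid[1])) {
    for (c in seq_len(grid[2])) {
      here <- events[events$row == r & events$col == c, , drop = FALSE]
      evoked <- here[here$latency_ms >= window[1] &
                       here$latency_ms < window[2], , drop = FALSE]
      spont <- here[here$latency_ms < 0, , drop = FALSE]
      amp[r, c] <- site_input_amplitude(evoked, window, spont, spont_duration)
      cnt[r, c] <- nrow(evoked)
      if (nrow(evoked)) lat[r, c] <- min(evoked$latency_ms)
    }
  }
  list(input_amplitude_pA = amp, event_count = cnt, first_latency_ms = lat)
}

#' Group-level summary of event parameters across cells
#'
#' Per-cell statistics -- median event peak amplitude, median rise time,
#' median first-event latency per site, and mean event frequency across
#' responsive sites (in-window count over window duration) -- are averaged
#' across the cells of a group and reported as mean +/- standard error.
#' Pooled-event medians (all cells' events pooled before taking the median)
#' are available as an alternative convention.
#'
#' @param cells list of per-cell event data frames, each with columns
#'   `peak_amplitude_pA`, `rise_time_ms`, `latency_ms` and a site identifier
#'   column `site` (any format with one value per site).
#' @param window_duration_ms duration of the per-site analysis window, ms.
#' @param statistic `"per_cell"` (default): medians per cell, then mean/SE
#'   across cells; `"pooled"`: medians over all pooled events, SE `NA`.
#' @return Data frame with columns `measure`, `mean`, `se`.
#' @export
summarize_by_cell <- function(cells, window_duration_ms,
                              statistic = c("per_cell", "pooled")) {
  statistic <- match.arg(statistic)
  if (!length(cells)) stop("empty cell group")
  per_cell <- lapply(cells, function(ev) {
    stopifnot(all(c("peak_amplitude_pA", "rise_time_ms", "latency_ms",
                    "site") %in% names(ev)))
    first_lat <- tapply(ev$latency_ms, ev$site, min)
    freq <- tapply(ev$latency_ms, ev$site, length) /
      (window_duration_ms / 1000)
    c(amplitude = stats::median(ev$peak_amplitude_pA),
      rise_time = stats::median(ev$rise_time_ms),
      frequency = mean(freq),
      first_latency = stats::median(first_lat))
  })
  tab <- do.call(rbind, per_cell)
  if (statistic == "pooled") {
    all_ev <- do.call(rbind, cells)
    first_lat <- unlist(lapply(cells, function(ev) tapply(ev$latency_ms, ev$site, min)))
    vals <- c(amplitude = stats::median(all_ev$peak_amplitude_pA),
              rise_time = stats::median(all_ev$rise_time_ms),
              frequency = mean(tab[, "frequency"]),
              first_latency = stats::median(first_lat))
    return(data.frame(measure = names(vals), mean = unname(vals),
                      se = NA_real_))
  }
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  data.frame(measure = colnames(tab),
             mean = colMeans(tab),
             se = apply(tab, 2, se),
             row.names = NULL)
}
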