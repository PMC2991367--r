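#' Match detected events against simulated ground truth
#'
#' Greedy one-to-one nearest matching: among all truth/detection pairs with
#' an absolute arrival-time difference within the tolerance (1.5 ms, well
#' below the ~11 ms average test-template duration), pairs are accepted in
#' order of increasing |difference| (ties toward the earlier truth event),
#' each truth and each detection used at most once. Unmatched truths are
#' omissions; unmatched detections are false alarms. The rule is symmetric:
#' swapping the two lists exchanges omissions and false alarms.
#'
#' @param truth_times sorted true arrival times (ms).
#' @param detected_times sorted estimated arrival times (ms).
#' @param tolerance maximal |estimated - true| for a correct detection (ms).
#' @return An object of class `psc_match`: counts `n_true`, `n_detected`,
#'   `n_correct`, `n_omissions`, `n_false_alarms` and a data frame `matched`
#'   with columns `truth`, `detected`, `error` (estimated - true, ms).
#' @export
match_events <- function(truth_times, detected_times, tolerance = 1.5) {
  truth_times <- as.numeric(truth_times)
  detected_times <- as.numeric(detected_times)
  nt <- length(truth_times)
  nd <- length(detected_times)
  pairs <- NULL
  if (nt && nd) {
    d <- abs(outer(detected_times, truth_times, `-`))
    hit <- which(d <= tolerance, arr.ind = TRUE)
    if (nrow(hit)) {
      pairs <- data.frame(det = hit[, 1], tru = hit[, 2],
                          dist = d[hit])
      pairs <- pairs[order(pairs$dist, truth_times[pairs$tru],
                           detected_times[pairs$det]), , drop = FALSE]
    }
  }
  used_t <- logical(nt)
  used_d <- logical(nd)
  m_t <- integer(0); m_d <- integer(0)
  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$det[r]; j <- pairs$tru[r]
      if (!used_d[i] && !used_t[j]) {
        used_d[i] <- TRUE; used_t[j] <- TRUE
        m_d <- c(m_d, i); m_t <- c(m_t, j)
      }
    }
  }
  n_correct <- length(m_t)
  structure(
    list(n_true = nt, n_detected = nd, n_correct = n_correct,
         n_omissions = nt - n_correct, n_false_alarms = nd - n_correct,
         matched = data.frame(truth = truth_times[m_t],
                              detected = detected_times[m_d],
                              error = detected_times[m_d] - truth_times[m_t])),
    class = "psc_match")
}

#' @export
print.psc_match <- function(x, ...) {
  cat(sprintf("<psc_match> %d true, %d detected: %d correct, %d omissions, %d false alarms\n",
              x$n_true, x$n_detected, x$n_correct, x$n_omissions,
              x$n_false_alarms))
  invisible(x)
}

#' Score a trial set at one detection threshold
#'
#' Runs detection on every trial and matches the detected peak times against
#' the trial's true arrival times.
#'
#' @param trials list from [simulate_trials()].
#' @param bank a [build_bank()] result.
#' @param k detection-threshold multiplier.
#' @param config base [detection_config()]; its `k` is overridden.
#' @param tolerance matching tolerance (ms).
#' @return List of [match_events()] results, one per trial.
#' @export
evaluate_trials <- function(trials, bank, k, config = detection_config(),
                            tolerance = 1.5) {
  config$k <- k
  lapply(trials, function(tr) {
    ev <- detect_events(tr$trace, bank, config)
    match_events(tr$truth$arrival_times, ev$t_p_ms, tolerance)
  })
}

# trial-wise averaged Pcd/Pfa from a list of psc_match results
trial_rates <- function(matches, pfa_denominator = c("detected", "true")) {
  pfa_denominator <- match.arg(pfa_denominator)
  pcd <- vapply(matches, function(m) {
    if (m$n_true == 0) NA_real_ else m$n_correct / m$n_true
  }, 0)
  pfa <- vapply(matches, function(m) {
    den <- if (pfa_denominator == "detected") m$n_detected else m$n_true
    if (den == 0) 0 else m$n_false_alarms / den
  }, 0)
  c(pcd = mean(pcd, na.rm = TRUE), pfa = mean(pfa))
}

#' ROC curves over SNR and detection-threshold grids
#'
#' For each SNR a fixed, seeded trial set is generated once; detection is
#' then run at every threshold multiplier `k` of the grid (the paper-style
#' grid runs from -2 to +3 in steps of 1 sigma). Per-trial correct-detection
#' and false-alarm rates are averaged across trials into one (Pfa, Pcd)
#' point per (snr, k).
#'
#' @param spec a [simulation_spec()]; `snr` is overridden per grid value,
#'   and per-SNR seeds are derived from `spec$seed`.
#' @param bank a [build_bank()] result.
#' @param library,noise template and noise libraries.
#' @param snrs SNR grid (default `c(3, 6, 9)`).
#' @param k_grid threshold-multiplier grid (default `-2:3`).
#' @param config base [detection_config()].
#' @param pfa_denominator `"detected"` (default: false alarms over detected
#'   events) or `"true"` (over true events).
#' @param tolerance matching tolerance (ms).
#' @return Data frame with columns `snr`, `k`, `pcd`, `pfa`.
#' @export
roc_curve <- function(spec, bank, library, noise, snrs = c(3, 6, 9),
                      k_grid = -2:3, config = detection_config(),
                      pfa_denominator = c("detected", "true"),
                      tolerance = 1.5) {
  pfa_denominator <- match.arg(pfa_denominator)
  rows <- list()
  for (si in seq_along(snrs)) {
    sp <- spec
    sp$snr <- snrs[si]
    sp$seed <- (spec$seed + 7919L * si) %% .Machine$integer.max
    trials <- simulate_trials(sp, library, noise)
    for (k in k_grid) {
      matches <- evaluate_trials(trials, bank, k, config, tolerance)
      r <- trial_rates(matches, pfa_denominator)
      rows[[length(rows) + 1L]] <- data.frame(
        snr = snrs[si], k = k, pcd = r["pcd"], pfa = r["pfa"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Arrival-time error statistics of correct detections
#'
#' Pools the signed errors (estimated - true arrival time) of all correctly
#' matched events across trials and reports their mean and sample SD.
#'
#' @param matches list of [match_events()] results, or a single one.
#' @return List with `mean`, `sd` (ms) and `n` (correct detections pooled).
#' @export
arrival_error_stats <- function(matches) {
  if (inherits(matches, "psc_match")) matches <- list(matches)
  errors <- unlist(lapply(matches, function(m) m$matched$error))
  if (!length(errors)) stop("no correct detections to summarize")
  list(mean = mean(errors),
       sd = if (length(errors) > 1) stats::sd(errors) else 0,
       n = length(errors))
}
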