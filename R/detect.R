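#' Detection-stage configuration
#'
#' Collects the tunable parameters of the detection stage. The detection
#' threshold is `mu_cmax + k * sigma_cmax`; `k` is typically chosen between
#' -1.5 and -1 (default -1.2). The outlier threshold guarding against direct
#' uncaging responses is `mu_cmax + outlier_multiplier * sigma_cmax`
#' (default multiplier +4). `w_d` is the direct-response window after laser
#' onset in which no synaptic event can occur (default 10 ms); `w_o` is the
#' wider window in which convolution traces are checked against the outlier
#' threshold (default 30 ms).
#'
#' @param k detection-threshold multiplier of `sigma_cmax` (default -1.2).
#' @param outlier_multiplier outlier-threshold multiplier (default 4).
#' @param w_d direct-response window, ms after laser onset (default 10).
#' @param w_o outlier-check window, ms after laser onset (default 30).
#' @param amplitude_cutoff event amplitude gate in pA; `NULL` (default) uses
#'   the bank's `mean_spont_amplitude`.
#' @param highpass_cutoff high-pass corner frequency, Hz (default 10).
#' @param highpass_order Butterworth order (default 5).
#' @param lead_window_multiplier,trail_window_multiplier how many SDs of the
#'   leading/trailing part extend the onset and offset search windows
#'   `L_on = mean_lead + m * sd_lead`, `L_off = mean_trail + m * sd_trail`
#'   (default 1 each).
#' @param landscape_smooth_ms width (ms) of the zero-phase moving average
#'   applied to the filtered trace before peaks, onsets and offsets are
#'   located (default 1.5 ms). Local extrema are defined as strict sign
#'   changes of the first difference, so they must be sought at the event
#'   timescale, not the sample timescale; the symmetric kernel leaves
#'   occurrence times unshifted, and all amplitudes are still measured on
#'   the raw trace. Set to 0 to disable.
#' @return An object of class `psc_detection_config`.
#' @export
detection_config <- function(k = -1.2, outlier_multiplier = 4,
                             w_d = 10, w_o = 30,
                             amplitude_cutoff = NULL,
                             highpass_cutoff = 10, highpass_order = 5,
                             lead_window_multiplier = 1,
                             trail_window_multiplier = 1,
                             landscape_smooth_ms = 1.5) {
  if (w_d < 0 || w_o < w_d) stop("need w_o >= w_d >= 0")
  if (!is.null(amplitude_cutoff) && amplitude_cutoff < 0) {
    stop("'amplitude_cutoff' must be >= 0")
  }
  if (highpass_cutoff <= 0) stop("'highpass_cutoff' must be positive")
  structure(
    list(k = k, outlier_multiplier = outlier_multiplier, w_d = w_d, w_o = w_o,
         amplitude_cutoff = amplitude_cutoff,
         highpass_cutoff = highpass_cutoff, highpass_order = highpass_order,
         lead_window_multiplier = lead_window_multiplier,
         trail_window_multiplier = trail_window_multiplier,
         landscape_smooth_ms = landscape_smooth_ms),
    class = "psc_detection_config")
}

#' Zero-phase Butterworth high-pass filter
#'
#' Forward-and-reverse (zero-phase) application of a 5th-order IIR
#' Butterworth high-pass filter (>10 Hz by default). This removes the DC
#' level and attenuates the slow direct uncaging response while leaving
#' event occurrence times unshifted, so peaks located on the filtered trace
#' are valid times on the raw trace.
#'
#' @param trace a [psc_trace()].
#' @param config a [detection_config()] supplying cutoff and order.
#' @return The trace with filtered samples.
#' @export
highpass_zero_phase <- function(trace, config = detection_config()) {
  stopifnot(inherits(trace, "psc_trace"))
  n <- length(trace$samples)
  if (n <= 3 * config$highpass_order) {
    stop(sprintf("trace of %d samples too short for stable order-%d zero-phase filtering",
                 n, config$highpass_order))
  }
  bf <- signal::butter(config$highpass_order,
                       config$highpass_cutoff / (trace$sampling_rate / 2),
                       type = "high")
  x <- trace$samples
  # remove the mean and odd-reflect both ends before the forward-reverse
  # pass: an IIR filter started from zero state otherwise injects a long
  # edge transient (time constant ~1/cutoff) whenever the trace has a DC
  # level or ends off baseline
  mu <- mean(x)
  x <- x - mu
  n_pad <- min(n - 1L, 3L * round(trace$sampling_rate / config$highpass_cutoff))
  pre <- 2 * x[1] - x[(n_pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - n_pad)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, x, post)))
  trace$samples <- y[(n_pad + 1):(n_pad + n)]
  trace
}

#' Detection threshold from bank statistics
#'
#' @param bank a [build_bank()] result.
#' @param k multiplier of `sigma_cmax`.
#' @return `mu_cmax + k * sigma_cmax` (pA).
#' @export
detection_threshold <- function(bank, k = -1.2) {
  stopifnot(inherits(bank, "psc_bank"))
  bank$mu_cmax + k * bank$sigma_cmax
}

#' Convolve a filtered trace with every filter in the bank
#'
#' Each convolution trace is advanced by the shift recorded for its template
#' in the training stage, so convolution maxima align with candidate event
#' peaks. Samples shifted in from beyond the trace are zero.
#'
#' @param filtered a high-pass filtered [psc_trace()].
#' @param bank a [build_bank()] result.
#' @return Numeric matrix, `length(filtered)` rows by `n_filters` columns.
#' @export
convolve_bank <- function(filtered, bank) {
  stopifnot(inherits(filtered, "psc_trace"), inherits(bank, "psc_bank"))
  if (bank$n_filters < 1) stop("empty filter bank")
  x <- filtered$samples
  n <- length(x)
  out <- matrix(0, nrow = n, ncol = bank$n_filters)
  for (f in seq_len(bank$n_filters)) {
    tmpl <- bank$templates[[f]]
    cv <- conv_full(x, tmpl$template_samples)
    idx <- seq_len(n) + tmpl$shift_samples
    ok <- idx >= 1 & idx <= length(cv)
    out[ok, f] <- cv[idx[ok]]
  }
  out
}

#' Suprathreshold segments and center-of-mass occurrence candidates
#'
#' For each aligned convolution trace, the maximal runs of consecutive
#' samples exceeding the detection threshold form the suprathreshold
#' segments; the convolution-amplitude-weighted mean time of each run is its
#' occurrence-time candidate `t_cm`.
#'
#' @param conv matrix from [convolve_bank()].
#' @param threshold detection threshold (pA).
#' @param sampling_rate Hz.
#' @return Data frame with columns `t_cm` (ms), `filter`, `start_ms`,
#'   `end_ms` (run extent) and `peak_conv` (run maximum, pA).
#' @export
suprathreshold_candidates <- function(conv, threshold, sampling_rate = 10000) {
  stopifnot(is.matrix(conv), is.finite(threshold))
  res <- list()
  for (f in seq_len(ncol(conv))) {
    above <- conv[, f] > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      idx <- starts[j]:ends[j]
      w <- conv[idx, f]
      t <- idx_to_ms(idx, sampling_rate)
      res[[length(res) + 1L]] <- data.frame(
        t_cm = sum(w * t) / sum(w), filter = f,
        start_ms = t[1], end_ms = t[length(t)], peak_conv = max(w))
    }
  }
  if (!length(res)) {
    return(data.frame(t_cm = numeric(0), filter = integer(0),
                      start_ms = numeric(0), end_ms = numeric(0),
                      peak_conv = numeric(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$t_cm), , drop = FALSE]
}

#' Outlier threshold from bank statistics
#'
#' @inheritParams detection_threshold
#' @param multiplier multiplier of `sigma_cmax` (default 4).
#' @return `mu_cmax + multiplier * sigma_cmax` (pA).
#' @export
outlier_threshold <- function(bank, multiplier = 4) {
  detection_threshold(bank, multiplier)
}

#' Dismiss candidates caught by the direct-response and outlier windows
#'
#' Candidates with `t_cm` inside the direct-response window
#' `[laser, laser + w_d)` are dismissed outright: synaptic events cannot
#' occur there. Candidates inside `[laser + w_d, laser + w_o)` are dismissed
#' when any aligned convolution trace exceeds the outlier threshold within
#' their suprathreshold run (large direct responses), or when the run's
#' leading edge traces back into the direct-response window (small direct
#' responses that stay below the outlier threshold). Without a laser onset
#' all candidates pass.
#'
#' @param candidates data frame from [suprathreshold_candidates()].
#' @param conv matrix from [convolve_bank()].
#' @param laser_onset ms, or `NULL`.
#' @param config a [detection_config()].
#' @param bank a [build_bank()] result.
#' @return The eligible subset of `candidates`.
#' @export
gate_windows <- function(candidates, conv, laser_onset, config, bank) {
  if (is.null(laser_onset) || !nrow(candidates)) return(candidates)
  fs <- bank$sampling_rate
  out_thr <- outlier_threshold(bank, config$outlier_multiplier)
  keep <- rep(TRUE, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    tcm <- candidates$t_cm[i]
    if (tcm >= laser_onset && tcm < laser_onset + config$w_d) {
      keep[i] <- FALSE
      next
    }
    if (tcm >= laser_onset + config$w_d) {
      # small direct responses: leading edge traced back into W_d
      if (candidates$start_ms[i] >= laser_onset &&
          candidates$start_ms[i] < laser_onset + config$w_d) {
        keep[i] <- FALSE
        next
      }
      if (tcm < laser_onset + config$w_o) {
        i1 <- ms_to_idx(candidates$start_ms[i], fs, nrow(conv))
        i2 <- ms_to_idx(candidates$end_ms[i], fs, nrow(conv))
        if (max(conv[i1:i2, , drop = FALSE]) > out_thr) keep[i] <- FALSE
      }
    }
  }
  candidates[keep, , drop = FALSE]
}

# cluster occurrence candidates from different filters that refer to the same
# event (t_cm values within mean_lead ms of each other, i.e. cluster
# diameter bounded by mean_lead so that candidates straddling two nearby
# events are not chained together); each cluster is resolved to the
# peak_conv-weighted mean t_cm
merge_candidates <- function(candidates, bank) {
  if (!nrow(candidates)) return(numeric(0))
  o <- order(candidates$t_cm)
  t_cm <- candidates$t_cm[o]
  w <- candidates$peak_conv[o]
  cluster <- integer(length(t_cm))
  anchor <- t_cm[1]
  cl <- 1L
  for (i in seq_along(t_cm)) {
    if (t_cm[i] - anchor > bank$mean_lead) {
      cl <- cl + 1L
      anchor <- t_cm[i]
    }
    cluster[i] <- cl
  }
  as.numeric(tapply(seq_along(t_cm), cluster, function(ii) {
    sum(t_cm[ii] * w[ii]) / sum(w[ii])
  }))
}

# like merge_candidates, but also report each cluster's pooled run extent
merge_candidates_ext <- function(candidates, bank) {
  t_cms <- merge_candidates(candidates, bank)
  if (!length(t_cms)) {
    return(data.frame(t_cm = numeric(0), start_ms = numeric(0),
                      end_ms = numeric(0)))
  }
  start_ms <- end_ms <- numeric(length(t_cms))
  for (i in seq_along(t_cms)) {
    lo <- if (i == 1) -Inf else (t_cms[i - 1] + t_cms[i]) / 2
    hi <- if (i == length(t_cms)) Inf else (t_cms[i] + t_cms[i + 1]) / 2
    member <- candidates$t_cm > lo & candidates$t_cm <= hi
    if (!any(member)) member <- which.min(abs(candidates$t_cm - t_cms[i]))
    start_ms[i] <- min(candidates$start_ms[member])
    end_ms[i] <- max(candidates$end_ms[member])
  }
  data.frame(t_cm = t_cms, start_ms = start_ms, end_ms = end_ms)
}

# strict-sign-change local extrema of a numeric vector; plateaus resolve to
# their first sample; returns indices
local_extrema <- function(x, what = c("min", "max")) {
  what <- match.arg(what)
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  # carry the previous non-zero slope across plateaus
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- integer(0)
  for (i in seq_len(n - 2)) {
    if (s[i] == 0) next
    if (what == "min" && s[i] < 0 && s[i + 1] > 0) idx <- c(idx, i + 1L)
    if (what == "max" && s[i] > 0 && s[i + 1] < 0) idx <- c(idx, i + 1L)
  }
  idx
}

# zero-phase moving average of odd width w (samples); ends keep the input
smooth_ma <- function(x, w) {
  w <- as.integer(w)
  if (w < 3 || length(x) < w) return(x)
  if (w %% 2 == 0) w <- w + 1L
  y <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  y[is.na(y)] <- x[is.na(y)]
  y
}

# fractional trough position: vertex of the least-squares parabola fitted
# over +-h samples around a structurally identified minimum. Unlike the
# bare argmin -- which noise drags toward the flatter (decay) flank of an
# asymmetric trough -- the vertex weighs both flanks, so its noise error is
# zero-mean to first order; the deterministic shift the waveform asymmetry
# induces is calibrated out per bank (landscape_displacement)
trough_vertex <- function(x, p, h) {
  i1 <- max(1L, p - h)
  i2 <- min(length(x), p + h)
  if (i2 - i1 < 4) return(as.numeric(p))
  t <- (i1:i2) - p
  co <- qr.coef(qr(cbind(1, t, t * t)), x[i1:i2])
  if (anyNA(co) || !is.finite(co[3]) || co[3] <= 0) return(as.numeric(p))
  v <- p - co[2] / (2 * co[3])
  min(max(v, p - h), p + h)
}

# bank-mean displacement (samples, fractional) of the peak-timing
# estimator -- landscape minimum plus parabola vertex -- measured on the
# clean training segments, exactly as the training stage calibrates the
# convolution shift; subtracted from located peak times
landscape_displacement <- function(bank, config, fs) {
  w <- round(config$landscape_smooth_ms * fs / 1000)
  if (w < 3) return(0)
  segs <- lapply(bank$templates, `[[`, "segment_samples")
  if (any(vapply(segs, is.null, TRUE))) return(0)
  h <- max(3L, round(0.8 * w))
  d <- vapply(segs, function(s) {
    ls <- smooth_ma(s, w)
    p <- which.min(ls)
    trough_vertex(ls, p, h) - which.min(s)
  }, 0)
  mean(d)
}

# the extrema landscape: the filtered trace smoothed so local extrema live
# at the event timescale; width 0 disables
landscape_trace <- function(filtered, config, scale = 1) {
  w <- round(scale * config$landscape_smooth_ms *
               filtered$sampling_rate / 1000)
  if (w >= 3) filtered$samples <- smooth_ma(filtered$samples, w)
  filtered
}

#' Locate the event peak near an occurrence-time candidate
#'
#' Searches `[t_cm - L, t_cm + T]` (bank mean lead/trail) of the filtered
#' trace for local negative peaks. A single peak is taken directly. Multiple
#' peaks are scored on three equally weighted criteria, each normalized to
#' 0-100: (1) the number of aligned convolution traces exceeding the
#' detection threshold at the peak time, over `n_filters`; (2) the peak
#' amplitude, relative to the largest candidate peak; (3) the magnitude of
#' the second derivative at the peak (after 3-point smoothing), relative to
#' the largest across candidates, which favors sharp peaks over flat
#' inflections. The highest average score wins; ties go to the earlier peak.
#'
#' @param filtered high-pass filtered [psc_trace()].
#' @param t_cm occurrence-time candidate (ms).
#' @param bank a [build_bank()] result.
#' @param conv matrix from [convolve_bank()].
#' @param threshold detection threshold (pA).
#' @param t_max upper bound (ms) on the search window, exclusive. Candidates
#'   are processed from earlier to later and each occurrence candidate marks
#'   its own event's vicinity, so a peak search never reaches into the next
#'   pending candidate's territory; without this bound a large later event
#'   inside `[t_cm, t_cm + T]` would capture the earlier candidate's search.
#' @return Peak sample index, or `NA` if the window holds no negative peak.
#' @export
locate_peak <- function(filtered, t_cm, bank, conv, threshold, t_max = Inf) {
  x <- filtered$samples
  fs <- filtered$sampling_rate
  n <- length(x)
  i1 <- ms_to_idx(t_cm - bank$mean_lead, fs, n)
  i2 <- ms_to_idx(min(t_cm + bank$mean_trail, t_max), fs, n)
  if (is.finite(t_max)) i2 <- max(i1, i2 - 1L)
  if (i2 - i1 < 2) return(NA_integer_)
  win <- x[i1:i2]
  peaks <- local_extrema(win, "min") + i1 - 1L
  if (!length(peaks)) return(NA_integer_)
  if (length(peaks) == 1) return(peaks)
  scores <- score_peaks(x, peaks, conv, threshold, bank$n_filters,
                        d2_stencil = round(fs / 1000))
  peaks[which.max(scores)]
}

#' Three-criterion peak scores
#'
#' Normalizes and averages the raw criteria used to choose among competing
#' negative peaks near one occurrence-time candidate: (1) the number of
#' aligned convolution traces above the detection threshold at the peak,
#' normalized by the bank size to 0-100; (2) the peak amplitude and (3) the
#' second-derivative magnitude at the peak, each normalized to 100 at the
#' largest value across the competing peaks. The three scores are weighted
#' equally.
#'
#' @param conv_counts integer vector, criterion-1 raw counts per peak.
#' @param amplitudes numeric vector, criterion-2 raw peak amplitudes.
#' @param curvatures numeric vector, criterion-3 raw second-derivative
#'   magnitudes.
#' @param n_filters number of filters in the bank.
#' @return Data frame with the normalized scores `c1`, `c2`, `c3` and their
#'   equally weighted `average`, one row per peak.
#' @export
peak_scores <- function(conv_counts, amplitudes, curvatures, n_filters) {
  stopifnot(length(conv_counts) == length(amplitudes),
            length(amplitudes) == length(curvatures), n_filters >= 1)
  c1 <- conv_counts / n_filters * 100
  c2 <- if (max(amplitudes) > 0) amplitudes / max(amplitudes) * 100
        else rep(100, length(amplitudes))
  c3 <- if (max(curvatures) > 0) curvatures / max(curvatures) * 100
        else rep(100, length(curvatures))
  data.frame(c1 = c1, c2 = c2, c3 = c3, average = (c1 + c2 + c3) / 3)
}

# three-criterion averaged score (0-100) for candidate peaks; the second
# derivative is a central second difference over a stencil of about one
# rise time (d2_stencil samples), so curvature is measured at the event
# timescale rather than the sample timescale
score_peaks <- function(x, peaks, conv, threshold, n_filters,
                        d2_stencil = 10L) {
  counts <- vapply(peaks, function(p) sum(conv[p, ] > threshold), 0)
  amp <- pmax(-x[peaks], 0)
  h <- max(1L, as.integer(d2_stencil))
  d2 <- vapply(peaks, function(p) {
    if (p - h < 1 || p + h > length(x)) return(0)
    abs(x[p - h] - 2 * x[p] + x[p + h])
  }, 0)
  peak_scores(counts, amp, d2, n_filters)$average
}

#' Locate event onset and offset, splitting overlapping events
#'
#' The onset is the largest local maximum of the filtered trace on
#' `[t_p - L_on, t_p]` (the local supremum at the window edge if no maximum
#' exists). The offset is searched on `[t_p, t_p + L_off]`: with no local
#' maxima it is the local supremum of the window; otherwise each local
#' maximum `p_b` followed by a local minimum (a potential next event peak)
#' is subjected to an amplitude test on the raw trace -- if
#' `value(p_b) - value(minimum)` exceeds the amplitude cutoff, `p_b` is this
#' event's offset and simultaneously the next event's onset, and the
#' minimum is handed on as the next event's peak (overlap split). When two
#' boundary maxima compete, the one with the higher value is kept. If no
#' split is found, the offset is whichever of the last boundary maximum or
#' the window end has the higher value.
#'
#' @param filtered the trace on which extrema are located (in the standard
#'   pipeline the smoothed landscape of the high-pass filtered trace).
#' @param raw the trace on which the overlap amplitude test is evaluated
#'   (the pipeline passes the landscape here too, so the split decision is
#'   not driven by single-sample noise; reported event amplitudes are
#'   always measured on the raw trace afterwards).
#' @param t_p_idx peak sample index.
#' @param bank a [build_bank()] result.
#' @param config a [detection_config()].
#' @param amplitude_cutoff pA; the overlap amplitude test.
#' @param onset_idx optional pre-assigned onset (a split from the previous
#'   event hands its boundary over as this event's onset).
#' @return List with `onset_idx`, `offset_idx`, and `split_peak_idx`
#'   (`NA` when no overlapping event was found).
#' @export
locate_onset_offset <- function(filtered, raw, t_p_idx, bank, config,
                                amplitude_cutoff, onset_idx = NA) {
  x <- filtered$samples
  v <- raw$samples
  fs <- filtered$sampling_rate
  n <- length(x)
  l_on <- bank$mean_lead + config$lead_window_multiplier * bank$sd_lead
  l_off <- bank$mean_trail + config$trail_window_multiplier * bank$sd_trail

  if (is.na(onset_idx)) {
    a1 <- ms_to_idx(idx_to_ms(t_p_idx, fs) - l_on, fs, n)
    win <- x[a1:t_p_idx]
    mx <- local_extrema(win, "max") + a1 - 1L
    onset_idx <- if (length(mx)) mx[which.max(x[mx])] else (a1:t_p_idx)[which.max(win)]
  }

  b2 <- ms_to_idx(idx_to_ms(t_p_idx, fs) + l_off, fs, n)
  if (b2 <= t_p_idx + 1) {
    return(list(onset_idx = onset_idx, offset_idx = min(t_p_idx + 1L, n),
                split_peak_idx = NA_integer_))
  }
  win <- x[t_p_idx:b2]
  maxima <- local_extrema(win, "max") + t_p_idx - 1L
  minima <- local_extrema(win, "min") + t_p_idx - 1L
  if (!length(maxima)) {
    offset_idx <- (t_p_idx:b2)[which.max(win)]
    return(list(onset_idx = onset_idx, offset_idx = offset_idx,
                split_peak_idx = NA_integer_))
  }
  ext <- sort(c(maxima, minima))
  cur_max <- NA_integer_
  for (e in ext) {
    if (e %in% maxima) {
      if (is.na(cur_max) || x[e] > x[cur_max]) cur_max <- e
    } else if (!is.na(cur_max)) {
      if (v[cur_max] - v[e] > amplitude_cutoff) {
        return(list(onset_idx = onset_idx, offset_idx = cur_max,
                    split_peak_idx = e))
      }
    }
  }
  offset_idx <- if (!is.na(cur_max) && x[cur_max] >= x[b2]) cur_max else b2
  list(onset_idx = onset_idx, offset_idx = offset_idx,
       split_peak_idx = NA_integer_)
}

#' Event amplitude gate
#'
#' An event is kept only if its peak amplitude, `value(onset) - value(peak)`
#' on the raw trace, exceeds the cutoff. The cutoff is normally based on the
#' mean amplitude of spontaneous events assessed at training, and rejects
#' baseline fluctuations and "event-like" notches on direct responses.
#'
#' @param raw raw [psc_trace()].
#' @param onset_idx,t_p_idx sample indices.
#' @param cutoff pA.
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
amplitude_gate <- function(raw, onset_idx, t_p_idx, cutoff) {
  (raw$samples[onset_idx] - raw$samples[t_p_idx]) > cutoff
}

#' Measure a localized event
#'
#' Measures, on the raw trace: peak amplitude `value(onset) - value(peak)`
#' (pA); rise time `t_p - onset` (ms); summed input, defined as twice the
#' absolute trapezoidal integral of the baseline-referenced current from
#' onset to peak (pA.ms) -- the trailing limb is excluded because it may be
#' skewed by the direct response; and latency `t_p - laser_onset` (ms, `NA`
#' without a laser).
#'
#' @param raw raw [psc_trace()].
#' @param onset_idx,t_p_idx,offset_idx sample indices.
#' @return One-row data frame of event measurements.
#' @export
measure_event <- function(raw, onset_idx, t_p_idx, offset_idx) {
  v <- raw$samples
  fs <- raw$sampling_rate
  dt_ms <- 1000 / fs
  seg <- v[onset_idx:t_p_idx] - v[onset_idx]
  integral <- if (length(seg) > 1) {
    sum((seg[-1] + seg[-length(seg)]) / 2) * dt_ms
  } else 0
  t_p <- idx_to_ms(t_p_idx, fs)
  data.frame(
    t_p_ms = t_p,
    onset_ms = idx_to_ms(onset_idx, fs),
    offset_ms = idx_to_ms(offset_idx, fs),
    peak_amplitude_pA = v[onset_idx] - v[t_p_idx],
    rise_time_ms = (t_p_idx - onset_idx) * dt_ms,
    summed_input_pAms = 2 * abs(integral),
    latency_ms = if (is.null(raw$laser_onset)) NA_real_ else t_p - raw$laser_onset)
}

#' Detect and measure synaptic events in a trace
#'
#' The full detection stage: zero-phase high-pass filtering, convolution
#' with every filter in the bank, thresholding of the aligned convolution
#' traces into suprathreshold segments, center-of-mass occurrence
#' candidates, direct-response/outlier gating, candidate merging across
#' filters, peak localization (with three-criterion scoring when several
#' negative peaks compete), onset/offset localization with overlap
#' splitting, the amplitude gate, and event measurement. Candidates are
#' processed from earlier to later; a split hands its boundary to the next
#' event as onset exactly once. For IPSC data apply [invert_polarity()]
#' first (or `ipsc = TRUE`).
#'
#' @param trace a [psc_trace()].
#' @param bank a [build_bank()] result.
#' @param config a [detection_config()].
#' @param ipsc if `TRUE`, the trace polarity is inverted before detection.
#' @return Data frame of chronologically ordered events with columns
#'   `t_p_ms`, `onset_ms`, `offset_ms`, `peak_amplitude_pA`, `rise_time_ms`,
#'   `summed_input_pAms`, `latency_ms`, `flags`.
#' @export
detect_events <- function(trace, bank, config = detection_config(),
                          ipsc = FALSE) {
  stopifnot(inherits(trace, "psc_trace"), inherits(bank, "psc_bank"))
  empty <- data.frame(t_p_ms = numeric(0), onset_ms = numeric(0),
                      offset_ms = numeric(0), peak_amplitude_pA = numeric(0),
                      rise_time_ms = numeric(0), summed_input_pAms = numeric(0),
                      latency_ms = numeric(0), flags = character(0))
  if (!length(trace$samples)) return(empty)
  if (ipsc) trace <- invert_polarity(trace)
  cutoff <- if (is.null(config$amplitude_cutoff)) bank$mean_spont_amplitude
            else config$amplitude_cutoff
  fs <- trace$sampling_rate
  filtered <- highpass_zero_phase(trace, config)
  land <- landscape_trace(filtered, config)
  # peak times are refined to the calibrated parabola vertex of the
  # landscape trough (see trough_vertex / landscape_displacement)
  w_land <- round(config$landscape_smooth_ms * fs / 1000)
  vertex_h <- max(3L, round(0.8 * w_land))
  land_shift <- landscape_displacement(bank, config, fs)
  conv <- convolve_bank(filtered, bank)
  thr <- detection_threshold(bank, config$k)
  cands <- suprathreshold_candidates(conv, thr, fs)
  cands <- gate_windows(cands, conv, trace$laser_onset, config, bank)
  clusters <- merge_candidates_ext(cands, bank)
  if (!nrow(clusters)) return(empty)

  # work queue of (peak index, pre-assigned onset index); t_cm candidates
  # enter with the onset unassigned, split continuations with it assigned.
  # Candidates whose t_cm falls inside an already-localized event's
  # [onset, offset] refer to that same event and are consumed: overlapping
  # events within one suprathreshold segment are recovered through the
  # splitting cascade, which localizes each event exactly once.
  t_cms <- clusters$t_cm
  # a search never reaches into the next candidate's vicinity: the next
  # event's peak is expected within mean_lead of its own t_cm
  nxt <- c(t_cms[-1] - bank$mean_lead, Inf)
  queue <- lapply(seq_along(t_cms), function(i) {
    list(t_cm = t_cms[i], t_max = nxt[i], t_p = NA, onset = NA)
  })
  events <- list()
  seen_tp <- integer(0)
  peak_idx <- integer(0)  # accepted event peaks, for the residue pass
  claimed <- NULL  # matrix of (onset_idx, offset_idx) already assigned
  residue_passes <- rep(0L, nrow(clusters))
  repeat {
    while (length(queue)) {
      item <- queue[[1]]
      queue <- queue[-1]
      t_p <- item$t_p
      if (is.na(t_p)) {
        tc_idx <- ms_to_idx(item$t_cm, fs, length(trace$samples))
        if (!is.null(claimed) &&
            any(tc_idx >= claimed[, 1] & tc_idx <= claimed[, 2])) next
        t_p <- locate_peak(land, item$t_cm, bank, conv, thr,
                           t_max = item$t_max)
        if (is.na(t_p)) next
      }
      if (w_land >= 3) {
        t_p <- max(2L, as.integer(round(
          trough_vertex(land$samples, t_p, vertex_h) - land_shift)))
      }
      if (t_p %in% seen_tp) next
      seen_tp <- c(seen_tp, t_p)
      loc <- locate_onset_offset(land, land, t_p, bank, config, cutoff,
                                 onset_idx = item$onset)
      # a split-off next event must itself be backed by suprathreshold
      # convolution support at its peak, like every other candidate
      if (!is.na(loc$split_peak_idx) &&
          any(conv[loc$split_peak_idx, ] > thr)) {
        queue <- c(list(list(t_cm = NA, t_p = loc$split_peak_idx,
                             onset = loc$offset_idx)), queue)
      }
      claimed <- rbind(claimed, c(loc$onset_idx, loc$offset_idx))
      if (!amplitude_gate(trace, loc$onset_idx, t_p, cutoff)) next
      peak_idx <- c(peak_idx, t_p)
      ev <- measure_event(trace, loc$onset_idx, t_p, loc$offset_idx)
      ev$flags <- event_flags(trace$laser_onset, loc$onset_idx, t_p, fs, config)
      events[[length(events) + 1L]] <- ev
    }
    # residue pass: events pulled off-center by a larger neighbor sharing
    # their suprathreshold segment leave two kinds of evidence behind.
    # First, an aligned convolution trace peaks where an event peaks (the
    # matched-filter principle), so a suprathreshold local maximum of the
    # filter-wise maximum convolution farther than a mean lead from every
    # localized peak, outside every claimed [onset, offset], marks a missed
    # event. Second, an aligned run rises at an event onset, so a run whose
    # leading edge starts more than a mean lead before the earliest claimed
    # onset inside it still holds an earlier event even when the overlap is
    # too heavy for a separate convolution maximum. Either finding
    # re-enters the queue with a candidate confined to its vicinity.
    found <- FALSE
    n_tr <- length(trace$samples)
    for (ci in seq_len(nrow(clusters))) {
      if (residue_passes[ci] >= 4L) next
      i1 <- ms_to_idx(clusters$start_ms[ci], fs, n_tr)
      i2 <- ms_to_idx(clusters$end_ms[ci], fs, n_tr)
      if (i2 - i1 < 3) next
      in_direct <- function(t_ms) {
        !is.null(trace$laser_onset) && t_ms >= trace$laser_onset &&
          t_ms < trace$laser_onset + config$w_d
      }
      enq <- function(t_cm, t_max) {
        residue_passes[ci] <<- residue_passes[ci] + 1L
        queue <<- c(queue, list(list(t_cm = t_cm, t_max = t_max,
                                     t_p = NA, onset = NA)))
        found <<- TRUE
      }
      # unexplained convolution maxima
      mt <- apply(conv[i1:i2, , drop = FALSE], 1, max)
      cm <- local_extrema(mt, "max") + i1 - 1L
      cm <- cm[mt[cm - i1 + 1L] > thr]
      hit <- FALSE
      for (p in cm) {
        tpc <- idx_to_ms(p, fs)
        if (length(peak_idx) &&
            min(abs(idx_to_ms(peak_idx, fs) - tpc)) <= bank$mean_lead) next
        if (!is.null(claimed) &&
            any(p >= claimed[, 1] & p <= claimed[, 2])) next
        if (in_direct(tpc)) next
        enq(tpc, tpc + bank$mean_lead)
        hit <- TRUE
        break
      }
      if (hit) next
      # unexplained leading stretch of the run
      s_ms <- clusters$start_ms[ci]
      if (is.null(claimed) || in_direct(s_ms)) next
      onset_in <- claimed[claimed[, 2] >= i1 & claimed[, 1] <= i2, 1]
      if (!length(onset_in)) next
      o_min_ms <- idx_to_ms(min(onset_in), fs)
      if (o_min_ms - s_ms > bank$mean_lead) enq(s_ms + bank$mean_lead, o_min_ms)
    }
    if (!found) break
  }
  if (!length(events)) return(empty)
  out <- do.call(rbind, events)
  out <- out[order(out$t_p_ms), , drop = FALSE]
  out <- out[!duplicated(out$t_p_ms), , drop = FALSE]
  rownames(out) <- NULL
  out
}

event_flags <- function(laser_onset, onset_idx, t_p_idx, fs, config) {
  if (is.null(laser_onset)) return("")
  fl <- character(0)
  onset_ms <- idx_to_ms(onset_idx, fs)
  t_p <- idx_to_ms(t_p_idx, fs)
  if (onset_ms < laser_onset + config$w_d && t_p >= laser_onset + config$w_d) {
    fl <- c(fl, "overriding_direct")
  }
  if (t_p >= laser_onset + config$w_d && t_p < laser_onset + config$w_o) {
    fl <- c(fl, "near_outlier_window")
  }
  paste(fl, collapse = ";")
}
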