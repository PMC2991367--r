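#' Mark a training event on a trace
#'
#' A marked event is the user's annotation of one clean, non-superimposed
#' synaptic event: the onset sample (where the current starts falling sharply
#' from baseline), the offset sample (return to baseline) and the negative
#' peak in between. When `peak_index` is omitted it is located as the minimum
#' sample on `[onset_index, offset_index]`.
#'
#' @param onset_index,offset_index 1-based sample indices, inclusive.
#' @param peak_index optional 1-based index of the negative extremum.
#' @return An object of class `psc_mark`.
#' @export
psc_mark <- function(onset_index, offset_index, peak_index = NULL) {
  onset_index <- as.integer(onset_index)
  offset_index <- as.integer(offset_index)
  if (onset_index >= offset_index) {
    stop("'onset_index' must be strictly less than 'offset_index'")
  }
  if (!is.null(peak_index)) {
    peak_index <- as.integer(peak_index)
    if (peak_index <= onset_index || peak_index >= offset_index) {
      stop("'peak_index' must lie strictly inside (onset_index, offset_index)")
    }
  }
  structure(list(onset_index = onset_index, offset_index = offset_index,
                 peak_index = peak_index), class = "psc_mark")
}

# full (zero-padded) linear convolution, all lags; length n + m - 1
conv_full <- function(x, h) {
  stats::convolve(x, rev(h), type = "open")
}

#' Extract a baseline-anchored event segment
#'
#' Returns the samples on `[onset_index, offset_index]` (inclusive) with the
#' onset value subtracted, so the segment starts at 0 pA. A warning is issued
#' when onset and offset are not at a similar baseline level, which usually
#' indicates noise contamination or a superimposed direct response; such
#' events should not be used for training.
#'
#' @param trace a [psc_trace()].
#' @param mark a [psc_mark()].
#' @param baseline_tol maximal tolerated |offset - onset| baseline difference,
#'   as a fraction of the segment's peak-to-trough range (default 0.25).
#' @return Numeric vector, the anchored segment (pA).
#' @export
extract_segment <- function(trace, mark, baseline_tol = 0.25) {
  stopifnot(inherits(trace, "psc_trace"), inherits(mark, "psc_mark"))
  n <- length(trace$samples)
  if (mark$onset_index < 1 || mark$offset_index > n) {
    stop(sprintf("mark [%d, %d] out of trace bounds [1, %d]",
                 mark$onset_index, mark$offset_index, n))
  }
  seg <- trace$samples[mark$onset_index:mark$offset_index]
  rng <- diff(range(seg))
  if (rng > 0 && abs(seg[length(seg)] - seg[1]) > baseline_tol * rng) {
    warning(sprintf(
      "onset and offset are not at a similar baseline level (|diff| = %.3g pA, range %.3g pA); consider a different training event",
      abs(seg[length(seg)] - seg[1]), rng))
  }
  seg - seg[1]
}

#' Fit a polynomial matched-filter template to an event segment
#'
#' Least-squares polynomial fit (default order 8) of the event waveform on a
#' time axis rescaled to `[-1, 1]` for numerical conditioning. The fitted
#' waveform, evaluated back at the original sample times, is divided by its
#' L1 norm so that event detectability does not depend on the training
#' event's amplitude. Higher orders are allowed but risk overfitting.
#'
#' @param segment numeric waveform (pA), typically from [extract_segment()].
#' @param order polynomial order (default 8).
#' @param sampling_rate Hz (default 10000).
#' @return An object of class `psc_template` with elements `coefficients`
#'   (length `order + 1`, ascending powers of the scaled time axis),
#'   `template_samples` (L1 norm 1), `segment_samples` (the anchored input
#'   segment, kept for timing calibrations), `order` and `sampling_rate`. Waveform
#'   statistics (`lead`, `trail`, `amplitude`, `c_max`, `shift`) are filled
#'   by [template_statistics()].
#' @export
fit_template <- function(segment, order = 8, sampling_rate = 10000) {
  segment <- as.numeric(segment)
  m <- length(segment)
  if (m < order + 2) {
    stop(sprintf("segment length %d too short for an order-%d fit (need >= %d)",
                 m, order, order + 2))
  }
  if (sum(abs(segment)) == 0) stop("degenerate all-zero segment: L1 norm is 0")
  x <- seq(-1, 1, length.out = m)
  X <- outer(x, 0:order, `^`)
  fit <- stats::lm.fit(X, segment)
  fitted <- drop(X %*% fit$coefficients)
  l1 <- sum(abs(fitted))
  if (l1 == 0) stop("degenerate fit: fitted waveform has L1 norm 0")
  structure(
    list(coefficients = unname(fit$coefficients),
         template_samples = fitted / l1,
         segment_samples = segment,
         order = order,
         sampling_rate = sampling_rate,
         duration = (m - 1) / sampling_rate * 1000,
         lead = NULL, trail = NULL, amplitude = NULL,
         c_max = NULL, shift = NULL, shift_samples = NULL),
    class = "psc_template")
}

#' @export
print.psc_template <- function(x, ...) {
  cat(sprintf("<psc_template> order %d, %.1f ms @ %g Hz\n",
              x$order, x$duration, x$sampling_rate))
  if (!is.null(x$c_max)) {
    cat(sprintf("  lead %.2f ms, trail %.2f ms, amplitude %.2f pA, c_max %.3f pA, shift %.2f ms\n",
                x$lead, x$trail, x$amplitude, x$c_max, x$shift))
  }
  invisible(x)
}

#' Compute per-template waveform and convolution statistics
#'
#' Fills the statistics the detection stage needs: the leading part
#' `lead = t(peak) - t(onset)` and trailing part `trail = t(offset) - t(peak)`
#' in ms, the event amplitude `value(onset) - value(peak)` in pA, the maximum
#' `c_max` of the convolution of the raw (baseline-anchored, unfiltered)
#' marked segment with its own template, and the time `shift` between the
#' convolution maximum and the event peak. The shift is later used to align
#' convolution traces so their peaks coincide with candidate event peaks.
#'
#' @param trace a [psc_trace()].
#' @param mark a [psc_mark()]; a missing `peak_index` is located as the
#'   segment minimum.
#' @param model a fitted [fit_template()] result.
#' @return The template with `lead`, `trail`, `amplitude`, `c_max`, `shift`
#'   (ms) and `shift_samples` filled.
#' @export
template_statistics <- function(trace, mark, model) {
  stopifnot(inherits(trace, "psc_trace"), inherits(mark, "psc_mark"),
            inherits(model, "psc_template"))
  raw <- trace$samples[mark$onset_index:mark$offset_index]
  peak_local <- if (!is.null(mark$peak_index)) {
    mark$peak_index - mark$onset_index + 1L
  } else {
    which.min(raw)
  }
  if (peak_local <= 1 || peak_local >= length(raw)) {
    stop("event peak must lie strictly inside the marked segment")
  }
  fs <- trace$sampling_rate
  amplitude <- raw[1] - raw[peak_local]
  if (amplitude <= 0) {
    stop("non-inward event: amplitude value(onset) - value(peak) must be positive")
  }
  seg <- raw - raw[1]
  cv <- conv_full(seg, model$template_samples)
  i_max <- which.max(cv)
  model$lead <- (peak_local - 1) / fs * 1000
  model$trail <- (length(raw) - peak_local) / fs * 1000
  model$amplitude <- amplitude
  model$c_max <- cv[i_max]
  model$shift_samples <- as.integer(i_max - peak_local)
  model$shift <- model$shift_samples / fs * 1000
  model
}

#' Train one template from a marked event
#'
#' Convenience wrapper: [extract_segment()], [fit_template()] and
#' [template_statistics()] in sequence.
#'
#' @inheritParams extract_segment
#' @inheritParams fit_template
#' @return A fully populated [fit_template()] result.
#' @export
train_template <- function(trace, mark, order = 8, baseline_tol = 0.25) {
  seg <- extract_segment(trace, mark, baseline_tol = baseline_tol)
  model <- fit_template(seg, order = order, sampling_rate = trace$sampling_rate)
  template_statistics(trace, mark, model)
}

#' Build a filter bank from trained templates
#'
#' Pools the per-template statistics that set the detection thresholds and
#' search windows: mean/SD of `c_max` (detection and outlier thresholds),
#' mean/SD of the leading and trailing parts (peak and onset/offset search
#' windows) and the mean training-event amplitude (default basis of the
#' amplitude gate). Sample standard deviations (n - 1 denominator) are used;
#' a single-template bank has all SDs equal to 0. At least 10 templates are
#' recommended so the pooled statistics are estimated reliably.
#'
#' @param templates list of populated [psc_template] objects.
#' @param spont_amplitude optional mean spontaneous-event amplitude (pA) to
#'   use as the amplitude-gate basis instead of the mean training amplitude.
#' @return An object of class `psc_bank`.
#' @export
build_bank <- function(templates, spont_amplitude = NULL) {
  if (!length(templates)) stop("cannot build a bank from an empty template list")
  stopifnot(all(vapply(templates, inherits, TRUE, "psc_template")))
  if (any(vapply(templates, function(t) is.null(t$c_max), TRUE))) {
    stop("all templates must carry statistics; run template_statistics() first")
  }
  if (length(templates) < 10) {
    warning(sprintf("bank has %d templates; a minimum of 10 is recommended",
                    length(templates)))
  }
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  cmax <- vapply(templates, `[[`, 0, "c_max")
  lead <- vapply(templates, `[[`, 0, "lead")
  trail <- vapply(templates, `[[`, 0, "trail")
  amp <- vapply(templates, `[[`, 0, "amplitude")
  structure(
    list(templates = templates,
         n_filters = length(templates),
         mu_cmax = mean(cmax), sigma_cmax = sd0(cmax),
         mean_lead = mean(lead), sd_lead = sd0(lead),
         mean_trail = mean(trail), sd_trail = sd0(trail),
         mean_spont_amplitude = if (is.null(spont_amplitude)) mean(amp)
                                else as.numeric(spont_amplitude),
         sampling_rate = templates[[1]]$sampling_rate),
    class = "psc_bank")
}

#' @export
print.psc_bank <- function(x, ...) {
  cat(sprintf("<psc_bank> %d matched filters @ %g Hz\n", x$n_filters, x$sampling_rate))
  cat(sprintf("  c_max: %.2f +/- %.2f pA\n", x$mu_cmax, x$sigma_cmax))
  cat(sprintf("  lead:  %.2f +/- %.2f ms; trail: %.2f +/- %.2f ms\n",
              x$mean_lead, x$sd_lead, x$mean_trail, x$sd_trail))
  cat(sprintf("  amplitude gate basis: %.2f pA\n", x$mean_spont_amplitude))
  invisible(x)
}

#' Train a filter bank from traces and a mark table
#'
#' @param traces list of [psc_trace()] objects.
#' @param marks data frame with columns `trace_index`, `onset_index`,
#'   `offset_index` and optionally `peak_index` (1-based samples).
#' @inheritParams fit_template
#' @inheritParams build_bank
#' @return A [build_bank()] result.
#' @export
train_bank <- function(traces, marks, order = 8, spont_amplitude = NULL) {
  stopifnot(is.data.frame(marks),
            all(c("trace_index", "onset_index", "offset_index") %in% names(marks)))
  templates <- lapply(seq_len(nrow(marks)), function(i) {
    pk <- if ("peak_index" %in% names(marks)) marks$peak_index[i] else NULL
    if (!is.null(pk) && is.na(pk)) pk <- NULL
    mk <- psc_mark(marks$onset_index[i], marks$offset_index[i], pk)
    train_template(traces[[marks$trace_index[i]]], mk, order = order)
  })
  build_bank(templates, spont_amplitude = spont_amplitude)
}

BANK_SCHEMA_VERSION <- 1L

#' Persist a filter bank as JSON
#'
#' The bank is fully serialized (polynomial coefficients, sampled templates,
#' per-template and pooled statistics), so templates trained on one
#' experiment can be reused for detection in other similar experiments.
#'
#' @param bank a [build_bank()] result.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_bank <- function(bank, path) {
  stopifnot(inherits(bank, "psc_bank"))
  payload <- list(
    schema_version = BANK_SCHEMA_VERSION,
    sampling_rate = bank$sampling_rate,
    n_filters = bank$n_filters,
    mu_cmax = bank$mu_cmax, sigma_cmax = bank$sigma_cmax,
    mean_lead = bank$mean_lead, sd_lead = bank$sd_lead,
    mean_trail = bank$mean_trail, sd_trail = bank$sd_trail,
    mean_spont_amplitude = bank$mean_spont_amplitude,
    templates = lapply(bank$templates, function(t) {
      list(coefficients = t$coefficients,
           template_samples = t$template_samples,
           segment_samples = t$segment_samples,
           order = t$order, sampling_rate = t$sampling_rate,
           duration = t$duration, lead = t$lead, trail = t$trail,
           amplitude = t$amplitude, c_max = t$c_max,
           shift = t$shift, shift_samples = t$shift_samples)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a filter bank from JSON
#'
#' @param path file written by [write_bank()].
#' @return A `psc_bank`.
#' @export
read_bank <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(p$schema_version) || p$schema_version > BANK_SCHEMA_VERSION) {
    stop(sprintf("unsupported bank schema version in %s", path))
  }
  templates <- lapply(p$templates, function(t) {
    structure(
      list(coefficients = as.numeric(t$coefficients),
           template_samples = as.numeric(t$template_samples),
           segment_samples = as.numeric(t$segment_samples),
           order = as.integer(t$order), sampling_rate = t$sampling_rate,
           duration = t$duration, lead = t$lead, trail = t$trail,
           amplitude = t$amplitude, c_max = t$c_max,
           shift = t$shift, shift_samples = as.integer(t$shift_samples)),
      class = "psc_template")
  })
  structure(
    list(templates = templates, n_filters = as.integer(p$n_filters),
         mu_cmax = p$mu_cmax, sigma_cmax = p$sigma_cmax,
         mean_lead = p$mean_lead, sd_lead = p$sd_lead,
         mean_trail = p$mean_trail, sd_trail = p$sd_trail,
         mean_spont_amplitude = p$mean_spont_amplitude,
         sampling_rate = p$sampling_rate),
    class = "psc_bank")
}
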