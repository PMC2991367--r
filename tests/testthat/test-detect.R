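test_that("zero-phase high-pass rejects DC and preserves band frequencies", {
  cfg <- detection_config()
  expect_equal(highpass_zero_phase(psc_trace(numeric(500), 10000), cfg)$samples,
               numeric(500))
  const <- highpass_zero_phase(psc_trace(rep(100, 5000), 10000), cfg)
  expect_lt(max(abs(const$samples[500:4500])), 1e-6)

  # 200 Hz unit sinusoid: output amplitude equals |H(f)|^2 of the 5th-order
  # Butterworth high-pass (forward + reverse application squares the gain)
  fs <- 10000; f0 <- 200
  t <- seq(0, 1, by = 1 / fs)
  y <- highpass_zero_phase(psc_trace(sin(2 * pi * f0 * t), fs), cfg)$samples
  gain <- max(abs(y[2000:8000]))
  h2 <- 1 / (1 + (10 / f0)^(2 * 5))  # analytic squared magnitude at f0
  expect_equal(gain, h2, tolerance = 0.01)

  expect_error(highpass_zero_phase(psc_trace(rnorm(10), 10000), cfg), "short")
})

test_that("filtering is zero-phase: no lag against a band-limited pulse", {
  fs <- 10000
  x <- numeric(4000)
  x[1800:1999] <- -sin(seq(0, pi, length.out = 200))  # 25 Hz half-cycle pulse
  y <- highpass_zero_phase(psc_trace(x, fs))$samples
  cc <- ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("bank convolution is linear, aligned and superposes", {
  sim <- fix_sim()
  bank <- sim$bank
  n <- 3000
  zero <- convolve_bank(psc_trace(numeric(n), 10000), bank)
  expect_equal(zero, matrix(0, n, bank$n_filters))

  # input equal to a template scaled by a: the aligned convolution trace of
  # that template peaks at the template peak position with the brute-force
  # value of a * max(conv(template_waveform, template))
  tpl <- bank$templates[[3]]
  w <- sim$lib$waveforms[[3]] * 0.6
  x <- numeric(n)
  at <- 1200
  x[at + seq_along(w) - 1] <- w
  conv <- convolve_bank(psc_trace(x, 10000), bank)
  oracle <- max(pscdetect:::conv_full(w, tpl$template_samples))
  peak_pos <- which.max(conv[, 3])
  expect_equal(max(conv[, 3]), oracle, tolerance = 1e-9)
  expect_equal(peak_pos, at + sim$lib$peak_index[3] - 1, tolerance = 2)

  # superposition: two copies 50 ms apart give two equal peaks 50 ms apart
  x2 <- x
  x2[at + 500 + seq_along(w) - 1] <- x2[at + 500 + seq_along(w) - 1] + w
  conv2 <- convolve_bank(psc_trace(x2, 10000), bank)
  expect_equal(conv2[, 3], conv[, 3] + c(numeric(500), conv[1:(n - 500), 3]),
               tolerance = 1e-9)
})

test_that("detection and outlier thresholds follow the bank statistics", {
  sim <- fix_sim()
  b <- sim$bank
  expect_equal(detection_threshold(b, -1.2), b$mu_cmax - 1.2 * b$sigma_cmax)
  expect_equal(outlier_threshold(b, 4), b$mu_cmax + 4 * b$sigma_cmax)
  b0 <- b; b0$sigma_cmax <- 0
  expect_equal(detection_threshold(b0, -1.5), b0$mu_cmax)
  expect_equal(detection_threshold(b0, 3), b0$mu_cmax)
})

test_that("suprathreshold runs yield amplitude-weighted centers of mass", {
  conv <- matrix(0, 30, 1)
  conv[11:13, 1] <- c(2, 4, 2)  # times 1.0, 1.1, 1.2 ms at 10 kHz
  cands <- suprathreshold_candidates(conv, 1, 10000)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$t_cm, (2 * 1.0 + 4 * 1.1 + 2 * 1.2) / 8)

  expect_equal(nrow(suprathreshold_candidates(conv, 10, 10000)), 0)

  # symmetric unimodal run: center of mass at the central sample
  conv2 <- matrix(0, 50, 1)
  conv2[20:28, 1] <- c(1, 2, 3, 4, 5, 4, 3, 2, 1)
  c2 <- suprathreshold_candidates(conv2, 0.5, 10000)
  expect_equal(c2$t_cm, pscdetect:::idx_to_ms(24, 10000))
})

test_that("window gating dismisses direct responses and outliers", {
  sim <- fix_sim()
  bank <- sim$bank
  cfg <- detection_config()
  conv <- matrix(0, 3000, bank$n_filters)
  mk_cand <- function(t_cm, start, end, peak) {
    data.frame(t_cm = t_cm, filter = 1, start_ms = start, end_ms = end,
               peak_conv = peak)
  }
  laser <- 100
  # candidate 5 ms after onset: inside W_d, dismissed
  expect_equal(nrow(gate_windows(mk_cand(105, 103, 108, 1), conv, laser,
                                 cfg, bank)), 0)
  # candidate at 20 ms whose run exceeds the outlier threshold: dismissed
  out_thr <- outlier_threshold(bank, 4)
  conv_hot <- conv
  conv_hot[1180:1220, 2] <- out_thr * 1.05
  expect_equal(nrow(gate_windows(mk_cand(120, 118, 122, out_thr * 1.05),
                                 conv_hot, laser, cfg, bank)), 0)
  # candidate at 50 ms, modest convolution: retained
  expect_equal(nrow(gate_windows(mk_cand(150, 148, 152, out_thr / 2), conv,
                                 laser, cfg, bank)), 1)
  # small direct response: leading edge of the run inside W_d
  expect_equal(nrow(gate_windows(mk_cand(112, 106, 114, out_thr / 2), conv,
                                 laser, cfg, bank)), 0)
  # without a laser everything passes
  expect_equal(nrow(gate_windows(mk_cand(105, 103, 108, 1), conv, NULL,
                                 cfg, bank)), 1)
})

test_that("a single negative peak in the window is taken directly", {
  sim <- fix_sim()
  fx <- fix_event_trace(at_ms = 150, amp = 1, n = 3000)
  cfg <- detection_config()
  land <- pscdetect:::landscape_trace(
    highpass_zero_phase(fx$trace, cfg), cfg)
  conv <- convolve_bank(land, sim$bank)
  tp <- locate_peak(land, 150, sim$bank, conv, -Inf)
  expect_lt(abs(pscdetect:::idx_to_ms(tp, 10000) - 150), 1)
  # no negative peak: flat trace
  flat <- psc_trace(numeric(3000), 10000)
  expect_true(is.na(locate_peak(flat, 150, sim$bank,
                                matrix(0, 3000, sim$bank$n_filters), 1)))
})

test_that("offset search takes the supremum when the decay is monotone", {
  sim <- fix_sim()
  cfg <- detection_config(landscape_smooth_ms = 0)
  fx <- fix_event_trace(at_ms = 100, amp = 40, n = 2500)
  f <- fx$trace  # clean trace: extrema well defined without smoothing
  loc <- locate_onset_offset(f, f, fx$peak, sim$bank, cfg,
                             amplitude_cutoff = 10)
  expect_true(is.na(loc$split_peak_idx))
  expect_gt(loc$offset_idx, fx$peak)
  # supremum of a monotone rise back toward baseline is the window end
  l_off <- sim$bank$mean_trail + sim$bank$sd_trail
  expect_equal(pscdetect:::idx_to_ms(loc$offset_idx, 10000),
               pscdetect:::idx_to_ms(fx$peak, 10000) + l_off,
               tolerance = 0.3)
})

test_that("overlapping events split at the boundary; weak rebounds do not", {
  sim <- fix_sim()
  cfg <- detection_config(landscape_smooth_ms = 0)
  fs <- 10000
  mk_pair <- function(amp2) {
    fx1 <- fix_event_trace(at_ms = 100, amp = 40, n = 2500)
    fx2 <- fix_event_trace(at_ms = 108, amp = amp2, n = 2500)
    psc_trace(fx1$trace$samples + fx2$trace$samples, fs)
  }
  fx1 <- fix_event_trace(at_ms = 100, amp = 40, n = 2500)
  # strong second event: rebound exceeds the cutoff, split returned
  tr <- mk_pair(40)
  loc <- locate_onset_offset(tr, tr, fx1$peak, sim$bank, cfg,
                             amplitude_cutoff = 10)
  expect_false(is.na(loc$split_peak_idx))
  expect_equal(pscdetect:::idx_to_ms(loc$split_peak_idx, fs), 108,
               tolerance = 1)
  expect_lt(loc$offset_idx, loc$split_peak_idx)  # boundary before next peak

  # attenuated second event: rebound below cutoff, no split
  tr2 <- mk_pair(4)
  loc2 <- locate_onset_offset(tr2, tr2, fx1$peak, sim$bank, cfg,
                              amplitude_cutoff = 10)
  expect_true(is.na(loc2$split_peak_idx))
})

test_that("the amplitude gate compares onset-to-peak depth with the cutoff", {
  tr <- psc_trace(c(0, 5, -30, 0), 10000)
  expect_true(amplitude_gate(tr, 2, 3, 20))   # 35 pA > 20
  expect_false(amplitude_gate(tr, 1, 1, 0.1)) # 0 amplitude drops
  expect_true(amplitude_gate(tr, 2, 3, 0))    # cutoff 0 keeps positives
})

test_that("event measurements follow their definitions on a linear ramp", {
  fs <- 10000
  ramp <- c(rep(0, 100), seq(0, -30, length.out = 31), rep(-30, 100))
  tr <- psc_trace(ramp, fs, laser_onset = 2)
  ev <- measure_event(tr, 101, 131, 200)
  expect_equal(ev$peak_amplitude_pA, 30)
  expect_equal(ev$rise_time_ms, 3)
  expect_equal(ev$summed_input_pAms, 2 * (0.5 * 30 * 3), tolerance = 0.05)
  expect_equal(ev$latency_ms, ev$t_p_ms - 2)

  flat <- measure_event(psc_trace(numeric(300), fs), 100, 130, 200)
  expect_equal(flat$peak_amplitude_pA, 0)
  expect_equal(flat$summed_input_pAms, 0)
})

test_that("detection returns nothing on subthreshold noise and an empty trace", {
  sim <- fix_sim()
  set.seed(1)
  tiny <- psc_trace(rnorm(2150) * 1e-4, 10000)
  expect_equal(nrow(detect_events(tiny, sim$bank)), 0)
  expect_equal(nrow(detect_events(psc_trace(numeric(0), 10000), sim$bank)), 0)
})

test_that("a single planted event is localized within the matching tolerance", {
  sim <- fix_sim()
  set.seed(5)
  tr <- compose_trial(100, sim$lib, sim$noise, snr = 9)$trace
  ev <- detect_events(tr, sim$bank, detection_config(k = -1))
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$t_p_ms - 100), 1.5)
  expect_lt(ev$onset_ms, ev$t_p_ms)
  expect_lte(ev$t_p_ms, ev$offset_ms)
})

test_that("two events inside one suprathreshold segment are both identified", {
  sim <- fix_sim()
  set.seed(8)
  tr <- compose_trial(c(100, 108), sim$lib, sim$noise, snr = 9)$trace
  ev <- detect_events(tr, sim$bank, detection_config(k = -1))
  m <- match_events(c(100, 108), ev$t_p_ms)
  expect_equal(m$n_correct, 2)
})

test_that("detection is invariant to a DC offset and ordered without duplicates", {
  sim <- fix_sim()
  set.seed(9)
  trial <- compose_trial(c(60, 150), sim$lib, sim$noise, snr = 9)
  cfg <- detection_config(k = -1)
  a <- detect_events(trial$trace, sim$bank, cfg)
  shifted <- psc_trace(trial$trace$samples - 250, 10000)
  b <- detect_events(shifted, sim$bank, cfg)
  expect_equal(a$t_p_ms, b$t_p_ms)
  expect_equal(a$peak_amplitude_pA, b$peak_amplitude_pA, tolerance = 1e-6)
  expect_false(is.unsorted(a$t_p_ms, strictly = TRUE))
  expect_true(all(a$onset_ms < a$t_p_ms & a$t_p_ms <= a$offset_ms))
})

test_that("EPSC and IPSC detection are polarity-symmetric", {
  sim <- fix_sim()
  set.seed(10)
  trial <- compose_trial(c(70, 130), sim$lib, sim$noise, snr = 9)
  cfg <- detection_config(k = -1)
  inward <- detect_events(trial$trace, sim$bank, cfg)
  outward <- psc_trace(-trial$trace$samples, 10000)
  via_ipsc <- detect_events(outward, sim$bank, cfg, ipsc = TRUE)
  expect_equal(inward, via_ipsc)
})

test_that("lowering the threshold never shrinks suprathreshold runs", {
  sim <- fix_sim()
  set.seed(12)
  tr <- compose_trial(c(50, 120, 180), sim$lib, sim$noise, snr = 6)$trace
  f <- highpass_zero_phase(tr, detection_config())
  conv <- convolve_bank(f, sim$bank)
  hi <- suprathreshold_candidates(conv, detection_threshold(sim$bank, 0), 10000)
  lo <- suprathreshold_candidates(conv, detection_threshold(sim$bank, -2), 10000)
  # every high-threshold run is contained in some low-threshold run
  for (r in seq_len(nrow(hi))) {
    covering <- lo$filter == hi$filter[r] & lo$start_ms <= hi$start_ms[r] &
      lo$end_ms >= hi$end_ms[r]
    expect_true(any(covering))
  }
})

test_that("direct-response gating suppresses events near the laser onset", {
  sim <- fix_sim()
  set.seed(13)
  # event 5 ms after laser onset is dismissed; one at 60 ms survives
  trial <- compose_trial(c(105, 160), sim$lib, sim$noise, snr = 9)
  tr <- trial$trace
  tr$laser_onset <- 100
  ev <- detect_events(tr, sim$bank, detection_config(k = -1))
  expect_true(all(abs(ev$t_p_ms - 105) > 1.5))
  expect_true(any(abs(ev$t_p_ms - 160) <= 1.5))
  expect_true(all(ev$latency_ms == ev$t_p_ms - 100))
})
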