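test_that("extract_segment anchors at the onset value and checks bounds", {
  flat <- psc_trace(rep(42, 100), 10000)
  seg <- extract_segment(flat, psc_mark(10, 30))
  expect_equal(seg, rep(0, 21))

  expect_error(psc_mark(30, 30))
  expect_error(psc_mark(31, 30))
  expect_error(extract_segment(flat, psc_mark(90, 120)), "bounds")

  fx <- fix_event_trace(at_ms = 100, amp = 40)
  seg <- extract_segment(fx$trace, psc_mark(fx$onset, fx$offset))
  expect_equal(seg, fx$waveform)
})

test_that("a baseline mismatch between onset and offset warns", {
  x <- c(rep(0, 50), seq(0, -30, length.out = 50), rep(-30, 50))
  tr <- psc_trace(x, 10000)
  expect_warning(extract_segment(tr, psc_mark(40, 140)), "baseline")
})

test_that("fit_template reproduces an exact polynomial and normalizes to L1 = 1", {
  x <- seq(-1, 1, length.out = 200)
  seg <- 3 - 2 * x + 0.5 * x^3 - x^8
  tm <- fit_template(seg)
  expect_equal(tm$template_samples, seg / sum(abs(seg)), tolerance = 1e-8)
  expect_equal(sum(abs(tm$template_samples)), 1, tolerance = 1e-9)
  expect_length(tm$coefficients, 9)
})

test_that("fit residuals shrink with order up to the default on a real shape", {
  fx <- fix_event_trace(amp = 30, tau_r = 1, tau_d = 5)
  seg <- fx$waveform
  # independent oracle: direct least squares via qr at each order
  rss <- vapply(2:8, function(ord) {
    x <- seq(-1, 1, length.out = length(seg))
    X <- outer(x, 0:ord, `^`)
    sum(qr.resid(qr(X), seg)^2)
  }, 0)
  expect_true(all(diff(rss) < 0))
  tm <- fit_template(seg, order = 8, sampling_rate = 10000)
  fitted8 <- tm$template_samples
  x <- seq(-1, 1, length.out = length(seg))
  X <- outer(x, 0:8, `^`)
  oracle8 <- drop(X %*% qr.coef(qr(X), seg))
  expect_equal(fitted8, oracle8 / sum(abs(oracle8)), tolerance = 1e-6)
})

test_that("fit_template is scale invariant and rejects degenerate input", {
  fx <- fix_event_trace(amp = 20)
  a <- fit_template(fx$waveform)$template_samples
  b <- fit_template(7.3 * fx$waveform)$template_samples
  expect_equal(a, b, tolerance = 1e-9)
  expect_error(fit_template(numeric(5)), "short")
  expect_error(fit_template(numeric(20)), "L1")
})

test_that("template statistics measure lead, trail, amplitude and shift", {
  # symmetric triangular event: lead equals trail
  x <- c(rep(0, 50), seq(0, -10, length.out = 21)[-21],
         seq(-10, 0, length.out = 21), rep(0, 50))
  tr <- psc_trace(x, 10000)
  mk <- psc_mark(51, 91, 71)
  tm <- template_statistics(tr, mk, fit_template(x[51:91]))
  expect_equal(tm$lead, tm$trail)
  expect_equal(tm$amplitude, 10)

  # the paper-scale asymmetric case: onset 4.4 ms before, offset 10.2 after
  fs <- 10000
  lead_n <- 44; trail_n <- 102
  y <- c(rep(0, 10), seq(0, -30, length.out = lead_n + 1)[-(lead_n + 1)],
         seq(-30, 0, length.out = trail_n + 1), rep(0, 10))
  tr2 <- psc_trace(y, fs)
  mk2 <- psc_mark(11, 11 + lead_n + trail_n, 11 + lead_n)
  tm2 <- template_statistics(tr2, mk2,
                             fit_template(y[11:(11 + lead_n + trail_n)]))
  expect_equal(tm2$lead, 4.4)
  expect_equal(tm2$trail, 10.2)

  # outward event is rejected in EPSC polarity
  expect_error(template_statistics(psc_trace(-y, fs), mk2,
                                   fit_template(y[11:(11 + lead_n + trail_n)])),
               "non-inward")
})

test_that("c_max equals a brute-force convolution maximum on a toy segment", {
  seg <- c(0, -2, -4, -2, 0)
  tr <- psc_trace(seg, 10000)
  tm <- fit_template(seg, order = 2)
  tm2 <- template_statistics(tr, psc_mark(1, 5, 3), tm)
  h <- tm$template_samples
  # oracle: explicit full-convolution loop over all lags
  n <- length(seg); m <- length(h)
  cv <- numeric(n + m - 1)
  for (k in seq_along(cv)) {
    for (i in seq_len(n)) {
      j <- k - i + 1
      if (j >= 1 && j <= m) cv[k] <- cv[k] + seg[i] * h[j]
    }
  }
  expect_equal(tm2$c_max, max(cv), tolerance = 1e-12)
  expect_equal(tm2$shift_samples, which.max(cv) - 3L)
})

test_that("bank statistics pool template values with sample SDs", {
  fx <- fix_event_trace(amp = 30)
  base <- train_template(fx$trace, psc_mark(fx$onset, fx$offset))
  mk <- function(cmax, lead, trail, amp) {
    t <- base
    t$c_max <- cmax; t$lead <- lead; t$trail <- trail; t$amplitude <- amp
    t
  }
  b <- suppressWarnings(build_bank(list(mk(10, 4, 10, 30), mk(20, 5, 11, 40),
                                        mk(30, 6, 12, 50))))
  expect_equal(b$mu_cmax, 20)
  expect_equal(b$sigma_cmax, sd(c(10, 20, 30)))  # n-1 denominator
  expect_equal(b$mean_lead, 5)
  expect_equal(b$mean_spont_amplitude, 40)

  single <- suppressWarnings(build_bank(list(mk(10, 4, 10, 30))))
  expect_equal(single$sigma_cmax, 0)
  expect_error(build_bank(list()), "empty")
  expect_warning(build_bank(list(mk(10, 4, 10, 30), mk(20, 5, 11, 40))),
                 "recommended")
})

test_that("banks serialize to JSON and reload losslessly", {
  sim <- fix_sim()
  f <- withr::local_tempfile(fileext = ".json")
  write_bank(sim$bank, f)
  back <- read_bank(f)
  expect_equal(back$n_filters, sim$bank$n_filters)
  expect_equal(back$mu_cmax, sim$bank$mu_cmax, tolerance = 1e-12)
  expect_equal(back$sigma_cmax, sim$bank$sigma_cmax, tolerance = 1e-12)
  for (i in seq_len(back$n_filters)) {
    expect_equal(back$templates[[i]]$template_samples,
                 sim$bank$templates[[i]]$template_samples, tolerance = 1e-12)
    expect_identical(back$templates[[i]]$shift_samples,
                     sim$bank$templates[[i]]$shift_samples)
  }
})

test_that("every stored template has unit L1 norm", {
  sim <- fix_sim()
  for (t in sim$bank$templates) {
    expect_equal(sum(abs(t$template_samples)), 1, tolerance = 1e-9)
    expect_gt(t$lead, 0)
    expect_gt(t$trail, 0)
    expect_equal(t$duration, t$lead + t$trail, tolerance = 0.1)
  }
})
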