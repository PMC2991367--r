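# shared fixtures, all generated in code at test time

# a clean double-exponential inward event embedded in a flat trace
fix_event_trace <- function(at_ms = 100, amp = 50, tau_r = 0.8, tau_d = 4,
                            n = 3000, fs = 10000, laser_onset = NULL) {
  de <- pscdetect:::double_exp_epsc(tau_r, tau_d, fs)
  x <- numeric(n)
  start <- round(at_ms * fs / 1000) - de$peak_index + 1L
  idx <- start + seq_along(de$waveform) - 1L
  ok <- idx >= 1 & idx <= n
  x[idx[ok]] <- amp * de$waveform[seq_along(de$waveform)[ok]]
  list(trace = psc_trace(x, fs, laser_onset = laser_onset),
       onset = start, peak = start + de$peak_index - 1L,
       offset = start + length(de$waveform) - 1L,
       waveform = amp * de$waveform)
}

# small seeded synthetic bank + libraries shared by detection tests
fix_sim <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(42)
    lib <- synth_template_library(10)
    bank <- train_bank_from_library(lib)
    set.seed(99)
    noise <- synth_noise_library(8)
    cache <<- list(lib = lib, bank = bank, noise = noise)
    cache
  }
})
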