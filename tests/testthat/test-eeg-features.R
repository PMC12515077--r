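test_that("band-pass keeps in-band tones and rejects drift", {
  fs <- 250
  t <- seq(0, 40, by = 1 / fs)
  tone <- sin(2 * pi * 10 * t)
  drift <- sin(2 * pi * 0.05 * t)
  rec <- eeg_recording(rbind(tone, drift), c("tone", "drift"), fs)
  out <- bandpass_filter(rec, 0.2, 40)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  amp_tone <- max(abs(out$data["tone", mid]))
  expect_gt(amp_tone, 0.95)
  expect_lt(amp_tone, 1.05)
  expect_lt(max(abs(out$data["drift", mid])), 0.1)
  expect_error(bandpass_filter(rec, 0.2, 200), "Nyquist")
})

test_that("filter magnitude response matches an FFT transfer-function oracle", {
  fs <- 250
  set.seed(42)
  x <- rnorm(fs * 60)
  rec <- eeg_recording(rbind(x), "ch1", fs)
  y <- bandpass_filter(rec, 0.2, 40)$data[1, ]
  # oracle: ratio of smoothed periodograms approximates |H|^2
  px <- Mod(fft(x))^2
  py <- Mod(fft(y))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  band <- function(lo, hi) which(f >= lo & f <= hi)
  gain_mid <- sqrt(sum(py[band(5, 20)]) / sum(px[band(5, 20)]))
  gain_high <- sqrt(sum(py[band(60, 100)]) / sum(px[band(60, 100)]))
  expect_gt(gain_mid, 0.9)
  expect_lt(gain_high, 0.15)
})

test_that("epochs are half-open windows with identical sample counts", {
  p <- tiny_paradigm(seed = 2)
  rec <- simulate_eeg(p, seed = 1)
  tr <- segment_trials(rec, p)
  expect_equal(dim(tr$epochs), c(nrow(p$trials), 2, (2 + 3 + 1) * 250))
  # 3 s trial at 250 Hz -> 6 s epoch -> 1500 samples
  expect_equal(dim(tr$epochs)[3], 1500)

  # epoching is exact: epochs reproduce the original samples
  starts <- floor((tr$meta$onset - 2) * 250) + 1
  for (i in c(1, nrow(tr$meta))) {
    expect_identical(tr$epochs[i, , ],
                     unname(rec$data[, starts[i]:(starts[i] + 1499)]))
  }
})

test_that("segmenting an empty paradigm or out-of-bounds trial behaves", {
  p <- tiny_paradigm(seed = 2)
  rec <- simulate_eeg(p, seed = 1)
  p_empty <- p
  p_empty$trials <- p$trials[0, ]
  expect_equal(nrow(segment_trials(rec, p_empty)$meta), 0)

  p_bad <- p
  p_bad$trials$onset[1] <- 1        # 2 s pre-window exceeds the recording
  expect_error(segment_trials(rec, p_bad), "trial 1")
})

test_that("trial rejection uses a strict threshold on channel SD", {
  # all-zero epochs are kept
  ts0 <- manual_trial_set(rep(0, 1500))
  expect_true(reject_bad_trials(ts0)$meta$good)
  # SD 150 is rejected
  set.seed(1)
  x <- rnorm(1500)
  ts1 <- manual_trial_set((x - mean(x)) / sd(x) * 150)
  expect_false(reject_bad_trials(ts1)$meta$good)
  # SD exactly 100 (exact in floating point for {-100, 0, 100}) is kept
  ts2 <- manual_trial_set(c(-100, 0, 100))
  expect_identical(sd(c(-100, 0, 100)), 100)
  expect_true(reject_bad_trials(ts2)$meta$good)
  # flag order preserved
  p <- tiny_paradigm(seed = 5)
  rec <- simulate_eeg(p, seed = 2)
  tr <- segment_trials(rec, p)
  tr$epochs[3, 1, ] <- tr$epochs[3, 1, ] * 1000
  out <- reject_bad_trials(tr)
  expect_false(out$meta$good[3])
  expect_true(all(out$meta$good[-3]))
})

test_that("Morlet power peaks at the tone frequency and scales quadratically", {
  fs <- 250
  t <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  freqs <- seq(1, 40, by = 0.5)
  tfr <- morlet_tfr(rbind(x), sfreq_hz = fs, freqs = freqs)
  # FFT oracle: the spectral peak of the signal itself
  spec <- Mod(fft(x))^2
  f_axis <- (seq_along(x) - 1) * fs / length(x)
  f_peak <- f_axis[which.max(spec[f_axis <= fs / 2])]
  mean_p <- vapply(seq_along(freqs), function(fi) {
    mean(tfr$power[1, fi, tfr$valid[fi, ]])
  }, numeric(1))
  expect_equal(freqs[which.max(mean_p)], freqs[which.min(abs(freqs - f_peak))])
  expect_equal(freqs[which.max(mean_p)], 10)

  tfr2 <- morlet_tfr(rbind(2 * x), sfreq_hz = fs, freqs = freqs)
  expect_equal(tfr2$power, 4 * tfr$power, tolerance = 1e-10)

  tfr0 <- morlet_tfr(rbind(0 * x), sfreq_hz = fs, freqs = freqs)
  expect_true(all(tfr0$power == 0))

  expect_error(morlet_tfr(rbind(x), sfreq_hz = 60), "Nyquist")
})

test_that("ERD formula is the percentage change relative to baseline", {
  tfr <- list(power = array(1, dim = c(1, 3, 10)),
              valid = matrix(TRUE, 3, 10), freqs = c(8, 8.5, 9),
              times = seq(0, 0.9, 0.1), sfreq_hz = 10, channel_names = "C3")
  class(tfr) <- "tfr"
  R <- matrix(c(1, 2, 0.5), 1, 3)
  erd <- compute_erd(tfr, R)
  expect_equal(erd$values[1, 1, ], rep(0, 10))     # P = R
  expect_equal(erd$values[1, 2, ], rep(-50, 10))   # P = R/2
  expect_equal(erd$values[1, 3, ], rep(100, 10))   # P = 2R
  expect_error(compute_erd(tfr, matrix(c(1, 0, 1), 1, 3)), "positive")
})

test_that("trial alpha ERD averages the band and window correctly", {
  freqs <- seq(8, 13.5, by = 0.5)
  nt <- 61
  times <- seq(-2, 4, length.out = nt)
  vals <- array(-20, dim = c(1, length(freqs), nt))
  erd <- structure(list(values = vals,
                        valid = matrix(TRUE, length(freqs), nt),
                        freqs = freqs, times = times, channel_names = "C3"),
                   class = "erd_map")
  expect_equal(unname(trial_alpha_erd(erd, c(8, 13.5), c(0.5, 3))), -20)

  # the high-alpha band picks exactly the 7 bins 10.5, 11, ..., 13.5
  vals2 <- vals
  vals2[1, freqs >= 10.5, ] <- -40
  erd2 <- erd
  erd2$values <- vals2
  expect_equal(unname(trial_alpha_erd(erd2, c(10.5, 13.5), c(0.5, 3))), -40)
  expect_equal(sum(freqs >= 10.5 & freqs <= 13.5), 7)
  expect_equal((13.5 - 8) / 0.5 + 1, 12)

  expect_error(trial_alpha_erd(erd, c(50, 60), c(0.5, 3)), "band")
  expect_error(trial_alpha_erd(erd, c(8, 13.5), c(10, 11)), "empty")
})

test_that("ERD is invariant to rescaling the raw signal", {
  p <- tiny_paradigm(seed = 8)
  rec <- simulate_eeg(p, seed = 4)
  tr1 <- segment_trials(rec, p)
  rec2 <- rec
  rec2$data <- rec$data * 3.7
  tr2 <- segment_trials(rec2, p)
  t1 <- erd_summary(tr1)
  t2 <- erd_summary(tr2)
  expect_equal(t1$erd_percent, t2$erd_percent, tolerance = 1e-9)
})

test_that("uniformly lower power in the window strictly lowers trial ERD", {
  freqs <- seq(8, 13.5, by = 0.5)
  nt <- 61
  times <- seq(-2, 4, length.out = nt)
  base <- array(rexp(length(freqs) * nt) + 1, dim = c(1, length(freqs), nt))
  erd_a <- structure(list(values = base,
                          valid = matrix(TRUE, length(freqs), nt),
                          freqs = freqs, times = times,
                          channel_names = "C3"), class = "erd_map")
  erd_b <- erd_a
  win <- times >= 0.5 & times <= 3
  erd_b$values[1, , win] <- erd_b$values[1, , win] - 5
  expect_lt(trial_alpha_erd(erd_b, c(8, 13.5), c(0.5, 3)),
            trial_alpha_erd(erd_a, c(8, 13.5), c(0.5, 3)))
})
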