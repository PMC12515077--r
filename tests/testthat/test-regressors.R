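test_that("continuous band power is flat for a stationary tone and quadratic in amplitude", {
  fs <- 250
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  rec <- eeg_recording(rbind(C3 = x, C4 = x), c("C3", "C4"), fs)
  pw <- continuous_band_power(rec)
  v <- pw$C3$values
  mid <- seq(round(length(v) * 0.1), round(length(v) * 0.9))
  expect_lt(sd(v[mid]) / mean(v[mid]), 0.05)

  # amplitude step x2 -> power step x4
  x2 <- x
  half <- length(t) %/% 2
  x2[(half + 1):length(t)] <- 2 * x2[(half + 1):length(t)]
  rec2 <- eeg_recording(rbind(C3 = x2, C4 = x2), c("C3", "C4"), fs)
  v2 <- continuous_band_power(rec2)$C3$values
  pre <- mean(v2[seq(fs * 5, half - fs * 2)])
  post <- mean(v2[seq(half + fs * 2, length(t) - fs * 5)])
  expect_equal(post / pre, 4, tolerance = 0.05)

  # band average is the unweighted mean of the 12 alpha bins
  tfr <- morlet_tfr(rbind(x), sfreq_hz = fs, freqs = seq(8, 13.5, 0.5))
  expect_equal(length(tfr$freqs), 12)
  manual <- colMeans(tfr$power[1, , , drop = TRUE])
  ok <- colSums(!tfr$valid) == 0
  expect_equal(pw$C3$values[ok][1:100],
               manual[ok][1:100], tolerance = 1e-9)

  expect_error(continuous_band_power(rec, electrodes = c("C3", "Cz")), "Cz")
})

test_that("bad-trial imputation replaces segments with same-condition means", {
  p <- tiny_paradigm(seed = 3)
  fs <- 100
  n <- round(p$run_length_s * fs)
  # constant series: imputation of identical good segments is identity-like
  vals <- rep(5, n)
  series <- power_series(vals, fs, "C3")

  # craft a trial set over this paradigm's trials
  meta <- dplyr::mutate(p$trials, trial = dplyr::row_number(), good = TRUE)
  ts <- structure(list(epochs = array(0, c(nrow(meta), 1, 10)),
                       meta = tibble::tibble(trial = meta$trial,
                                             run = meta$run,
                                             condition = meta$condition,
                                             onset = meta$onset,
                                             duration = meta$duration,
                                             good = TRUE),
                       channel_names = "C3", sfreq_hz = fs,
                       pre_s = 2, post_s = 1), class = "trial_set")

  expect_identical(impute_bad_trials(series, ts)$values, series$values)

  # two good segments at 1 and 3 -> bad segment becomes 2
  cond <- ts$meta$condition[1]
  idx <- which(ts$meta$condition == cond)[1:3]
  seg <- function(k) {
    i0 <- floor(ts$meta$onset[k] * fs) + 1
    i0:(i0 + round(ts$meta$duration[k] * fs) - 1)
  }
  idx <- which(ts$meta$condition == cond)      # all 4 trials of `cond`
  vals2 <- rep(0, n)
  vals2[seg(idx[1])] <- 1
  vals2[seg(idx[2])] <- 3
  vals2[seg(idx[3])] <- 99
  ts$meta$good[idx[3:4]] <- FALSE              # only trials 1 and 2 are good
  out <- impute_bad_trials(power_series(vals2, fs, "C3"), ts)
  expect_equal(unique(out$values[seg(idx[3])]), 2)
  expect_equal(unique(out$values[seg(idx[4])]), 2)
  # good segments untouched
  expect_equal(unique(out$values[seg(idx[1])]), 1)

  # no good trials of a condition -> warning, unchanged
  ts$meta$good[ts$meta$condition == cond] <- FALSE
  expect_warning(out2 <- impute_bad_trials(power_series(vals2, fs, "C3"), ts),
                 "no good trials")
  expect_equal(out2$values[seg(idx[3])],
               vals2[seg(idx[3])])
})

test_that("condition masks partition the run exactly", {
  p <- tiny_paradigm(seed = 9, bpc = 2)
  fs <- 250
  set.seed(1)
  series <- power_series(rexp(round(p$run_length_s * fs)), fs, "C3")
  me <- condition_mask(series, p, "ME")
  mi <- condition_mask(series, p, "MI")
  rest <- condition_mask(series, p, "REST")
  expect_identical(me$values + mi$values + rest$values, series$values)

  # a 22 s block at 250 Hz retains 5500 samples
  b <- dplyr::filter(p$blocks, condition == "ME_LH")[1, ]
  i0 <- floor(b$onset * fs) + 1
  expect_equal(sum(me$values[i0:(i0 + 5499)] != 0), 5500)

  # a series that is zero during rest gives an all-zero REST regressor
  z <- series
  for (i in seq_len(nrow(p$blocks))) {
    if (p$blocks$type[i] == "rest") {
      ii <- (floor(p$blocks$onset[i] * fs) + 1):
        floor((p$blocks$onset[i] + p$blocks$duration[i]) * fs)
      z$values[ii] <- 0
    }
  }
  expect_true(all(condition_mask(z, p, "REST")$values == 0))
})

test_that("canonical HRF has the expected double-gamma shape", {
  dt <- 0.01
  h <- canonical_hrf(dt)
  tt <- seq(0, 32, by = dt)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  # dense-grid oracle: direct evaluation of the double-gamma difference
  dense <- dgamma(tt, shape = 6, scale = 1) -
    dgamma(tt, shape = 16, scale = 1) / 6
  expect_equal(h, dense / max(dense), tolerance = 1e-12)
  expect_lt(abs(tt[which.max(h)] - 5), 0.5)
  # exactly one sign change after the peak
  after <- h[which.max(h):length(h)]
  expect_equal(sum(diff(sign(after[after != 0])) != 0), 1)
})

test_that("make_regressor handles impulses, nulls, and drift removal", {
  fs <- 100
  n_vol <- 150
  n <- n_vol * 2 * fs
  zero <- power_series(rep(0, n), fs, "C3")
  expect_true(all(make_regressor(zero, n_vol) == 0))

  # impulse -> the HRF sampled at the TR grid (point sampling, centered)
  imp <- power_series(c(1, rep(0, n - 1)), fs, "C3")
  col <- make_regressor(imp, n_vol, highpass_cutoff_s = Inf,
                        downsample = "point")
  hrf <- canonical_hrf(1 / fs) / fs
  expected <- rep(0, n_vol)
  at <- seq_len(n_vol) * 2 * fs - 2 * fs + 1
  expected[at <= length(hrf)] <- hrf[at[at <= length(hrf)]]
  expect_equal(col, expected - mean(expected), tolerance = 1e-9)

  # a 300 s cosine is removed by the 128 s high-pass
  tt <- (seq_len(n) - 1) / fs
  slow <- power_series(10 + cos(2 * pi * tt / 300), fs, "C3")
  col2 <- make_regressor(slow, n_vol)
  cos_tr <- cos(2 * pi * (seq_len(n_vol) - 1) * 2 / 300)
  expect_lt(abs(cor(col2, cos_tr)), 0.05)

  expect_error(make_regressor(power_series(rep(1, 10), fs, "C3"), n_vol),
               "shorter")
})

test_that("regressor construction is linear and shift-covariant", {
  fs <- 100
  n_vol <- 100
  n <- n_vol * 2 * fs
  set.seed(2)
  x <- power_series(rexp(n), fs, "C3")
  y <- power_series(rexp(n), fs, "C3")
  combo <- power_series(2 * x$values - 0.5 * y$values, fs, "C3")
  expect_equal(make_regressor(combo, n_vol),
               2 * make_regressor(x, n_vol) - 0.5 * make_regressor(y, n_vol),
               tolerance = 1e-9)

  # delaying by one TR shifts the column by one row (no high-pass)
  spt <- 2 * fs
  shifted <- power_series(c(rep(0, spt), x$values[1:(n - spt)]), fs, "C3")
  a <- make_regressor(x, n_vol, highpass_cutoff_s = Inf)
  b <- make_regressor(shifted, n_vol, highpass_cutoff_s = Inf)
  expect_equal(b[2:n_vol] - mean(b[2:n_vol]),
               (a[1:(n_vol - 1)] - mean(a[1:(n_vol - 1)])), tolerance = 1e-6)
})

test_that("design assembly lays out shared, per-scan and intercept columns", {
  set.seed(3)
  reg <- matrix(rnorm(400 * 6), 400, 6,
                dimnames = list(NULL, c("C3-ME", "C3-MI", "C3-REST",
                                        "C4-ME", "C4-MI", "C4-REST")))
  mot <- matrix(rnorm(400 * 6), 400, 6)
  d1 <- assemble_design(reg, motion = mot)
  expect_equal(dim(d1$X), c(400, 6 + 6 + 1))

  d2 <- assemble_design(list(reg, reg + rnorm(length(reg))),
                        motion = list(mot, mot))
  expect_equal(nrow(d2$X), 800)
  expect_equal(sum(grepl("intercept", colnames(d2$X))), 2)
  expect_equal(d2$scans$first_row, c(1L, 401L))

  dup <- cbind(reg, `C3-ME2` = reg[, "C3-ME"])
  expect_error(assemble_design(dup), "collinear")
})
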