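#' Zero-phase band-pass filter an EEG recording
#'
#' Cascaded Butterworth high-pass and low-pass sections applied
#' forward-backward (zero phase). The defaults reproduce the 0.2-40 Hz band
#' used before time-frequency analysis.
#'
#' @param rec An [eeg_recording()].
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < sfreq/2`.
#' @param order Butterworth order per section (doubled by the
#'   forward-backward pass).
#' @return A filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low_hz = 0.2, high_hz = 40, order = 2) {
  nyq <- rec$sfreq_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("band must satisfy 0 < low_hz < high_hz < Nyquist (", nyq, " Hz)",
         call. = FALSE)
  }
  hp <- signal::butter(order, low_hz / nyq, type = "high")
  lp <- signal::butter(order + 2, high_hz / nyq, type = "low")
  out <- t(apply(rec$data, 1, function(x) {
    signal::filtfilt(lp, signal::filtfilt(hp, x))
  }))
  eeg_recording(out, rec$channel_names, rec$sfreq_hz, rec$t0_s)
}

#' Segment a recording into trial epochs
#'
#' Epochs span from `pre_s` before trial onset to `post_s` after trial end,
#' as half-open sample windows (`[start, end)`, sample index
#' `floor(t * rate)`), so every epoch of equal trial duration has an
#' identical sample count.
#'
#' @param rec An [eeg_recording()].
#' @param paradigm A [generate_paradigm()] object.
#' @param run Run whose trials are epoched.
#' @param pre_s Seconds before trial onset (default 2).
#' @param post_s Seconds after trial end (default 1).
#' @return A `trial_set`: epochs array (trial x channel x sample), a `meta`
#'   tibble (trial, run, condition, onset, duration, good), channel names,
#'   sampling rate and the epoch window.
#' @export
segment_trials <- function(rec, paradigm, run = 1, pre_s = 2, post_s = 1) {
  trials <- dplyr::filter(paradigm$trials, .data$run == !!run)
  fs <- rec$sfreq_hz
  n <- ncol(rec$data)
  if (nrow(trials) == 0) {
    return(structure(list(
      epochs = array(numeric(0), dim = c(0, nrow(rec$data), 0)),
      meta = tibble::tibble(trial = integer(), run = integer(),
                            condition = character(), onset = numeric(),
                            duration = numeric(), good = logical()),
      channel_names = rec$channel_names, sfreq_hz = fs,
      pre_s = pre_s, post_s = post_s), class = "trial_set"))
  }
  durs <- unique(trials$duration)
  if (length(durs) != 1) stop("trials must share one duration", call. = FALSE)
  n_samp <- as.integer(round((pre_s + durs + post_s) * fs))

  starts <- floor((trials$onset - pre_s - rec$t0_s) * fs) + 1L
  bad_bounds <- which(starts < 1L | starts + n_samp - 1L > n)
  if (length(bad_bounds) > 0) {
    stop("epoch for trial ", bad_bounds[1], " (onset ",
         trials$onset[bad_bounds[1]], " s) exceeds the recording bounds",
         call. = FALSE)
  }
  epochs <- array(NA_real_, dim = c(nrow(trials), nrow(rec$data), n_samp))
  for (i in seq_len(nrow(trials))) {
    epochs[i, , ] <- rec$data[, starts[i]:(starts[i] + n_samp - 1L),
                              drop = FALSE]
  }
  structure(list(
    epochs = epochs,
    meta = tibble::tibble(trial = seq_len(nrow(trials)), run = trials$run,
                          condition = trials$condition, onset = trials$onset,
                          duration = trials$duration, good = TRUE),
    channel_names = rec$channel_names, sfreq_hz = fs,
    pre_s = pre_s, post_s = post_s), class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat("<trial_set> ", nrow(x$meta), " trial(s), ",
      sum(x$meta$good), " good; epoch [-", x$pre_s, ", duration + ",
      x$post_s, "] s @ ", x$sfreq_hz, " Hz\n", sep = "")
  invisible(x)
}

#' Flag noisy trials by within-epoch standard deviation
#'
#' A trial is flagged bad when any channel's sample standard deviation over
#' the epoch strictly exceeds the threshold (a trial sitting exactly at the
#' threshold is kept).
#'
#' @param trials A `trial_set`.
#' @param sd_threshold_uv Rejection threshold in microvolts (default 100).
#' @return The `trial_set` with updated `meta$good`; order preserved.
#' @export
reject_bad_trials <- function(trials, sd_threshold_uv = 100) {
  if (nrow(trials$meta) == 0) return(trials)
  sds <- apply(trials$epochs, c(1, 2), stats::sd)
  trials$meta$good <- apply(sds, 1, function(s) all(s <= sd_threshold_uv))
  trials
}

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves each channel with complex Morlet wavelets (fixed number of
#' cycles per frequency, unit-energy normalization) and returns squared
#' magnitudes. Samples within half the wavelet support of either edge are
#' marked invalid per frequency.
#'
#' @param x Numeric matrix (channels x samples), vector, or
#'   [eeg_recording()].
#' @param sfreq_hz Sampling rate (ignored when `x` is a recording).
#' @param freqs Analysis frequencies in Hz (default 1-40 in 0.5 Hz steps).
#' @param n_cycles Wavelet width in cycles (default 7).
#' @param t0_s Time of the first sample (seconds), used for the time axis.
#' @return A `tfr` object: `power` array (channel x frequency x time, in
#'   microvolts squared), logical `valid` (frequency x time), `freqs`,
#'   `times`, `sfreq_hz`, `channel_names`.
#' @export
morlet_tfr <- function(x, sfreq_hz = NULL, freqs = seq(1, 40, by = 0.5),
                       n_cycles = 7, t0_s = 0) {
  if (inherits(x, "eeg_recording")) {
    sfreq_hz <- x$sfreq_hz
    t0_s <- x$t0_s
    channel_names <- x$channel_names
    x <- x$data
  } else {
    x <- rbind(x)
    channel_names <- rownames(x)
    if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(x)))
  }
  if (is.null(sfreq_hz)) stop("`sfreq_hz` required for matrix input", call. = FALSE)
  if (max(freqs) * 2 >= sfreq_hz) {
    stop("max(freqs) must be below the Nyquist frequency", call. = FALSE)
  }
  n <- ncol(x)
  n_ch <- nrow(x)
  power <- array(NA_real_, dim = c(n_ch, length(freqs), n))
  valid <- matrix(TRUE, length(freqs), n)

  wavelets <- purrr::map(freqs, function(f) {
    sigma_t <- n_cycles / (2 * pi * f)
    half <- ceiling(5 * sigma_t * sfreq_hz)
    tw <- (-half:half) / sfreq_hz
    w <- exp(2i * pi * f * tw) * exp(-tw^2 / (2 * sigma_t^2))
    list(w = w / sqrt(sum(Mod(w)^2)), half = half)
  })
  m_max <- max(vapply(wavelets, function(w) length(w$w), integer(1)))
  nfft <- stats::nextn(n + m_max - 1L, c(2, 3, 5))
  # one forward FFT per channel, shared across frequencies
  xf <- lapply(seq_len(n_ch),
               function(ci) stats::fft(c(x[ci, ], rep(0, nfft - n))))
  for (fi in seq_along(freqs)) {
    w <- wavelets[[fi]]$w
    half <- wavelets[[fi]]$half
    wf <- stats::fft(c(w, rep(0, nfft - length(w))))
    for (ci in seq_len(n_ch)) {
      full <- stats::fft(xf[[ci]] * wf, inverse = TRUE) / nfft
      power[ci, fi, ] <- Mod(full[(half + 1L):(half + n)])^2
    }
    edge <- min(half, n)
    if (edge > 0) valid[fi, c(seq_len(edge), (n - edge + 1L):n)] <- FALSE
  }
  structure(list(power = power, valid = valid, freqs = freqs,
                 times = t0_s + (seq_len(n) - 1L) / sfreq_hz,
                 sfreq_hz = sfreq_hz, channel_names = channel_names),
            class = "tfr")
}

# centered ("same") complex convolution via FFT
conv_same <- function(x, w) {
  n <- length(x)
  m <- length(w)              # odd by construction
  half <- (m - 1L) %/% 2L
  nfft <- stats::nextn(n + m - 1L, c(2, 3, 5))
  full <- stats::fft(stats::fft(c(x, rep(0, nfft - n))) *
                       stats::fft(c(w, rep(0, nfft - m))), inverse = TRUE) / nfft
  full[(half + 1L):(half + n)]
}

#' @export
print.tfr <- function(x, ...) {
  cat("<tfr> ", dim(x$power)[1], " channel(s) x ", length(x$freqs),
      " frequencies (", min(x$freqs), "-", max(x$freqs), " Hz) x ",
      length(x$times), " samples\n", sep = "")
  invisible(x)
}

#' Baseline spectrum of a time-frequency map
#'
#' Mean power per channel and frequency over a time window, using valid
#' samples only. The default window is the 1 s to 0.1 s interval preceding
#' trial onset (time 0 of an epoch time axis).
#'
#' @param tfr A [morlet_tfr()] object with a trial-relative time axis.
#' @param window Two-element numeric, window in seconds (closed).
#' @return A matrix R (channel x frequency), microvolts squared.
#' @export
baseline_spectrum <- function(tfr, window = c(-1, -0.1)) {
  ti <- which(tfr$times >= window[1] & tfr$times <= window[2])
  if (length(ti) == 0) stop("baseline window is empty", call. = FALSE)
  R <- matrix(NA_real_, dim(tfr$power)[1], length(tfr$freqs),
              dimnames = list(tfr$channel_names, NULL))
  for (fi in seq_along(tfr$freqs)) {
    use <- ti[tfr$valid[fi, ti]]
    if (length(use) > 0) R[, fi] <- rowMeans(tfr$power[, fi, use, drop = FALSE],
                                             dims = 2)
  }
  R
}

#' Event-related (de)synchronization map
#'
#' Percentage power change relative to a baseline spectrum:
#' `ERD(t, f, c) = (P(t, f, c) - R(f, c)) / R(f, c) * 100`.
#' Invalid time-frequency samples stay invalid.
#'
#' @param tfr A [morlet_tfr()] object.
#' @param baseline Matrix from [baseline_spectrum()] (channel x frequency).
#' @return An `erd_map`: `values` (channel x frequency x time, percent),
#'   plus the axes of `tfr`.
#' @export
compute_erd <- function(tfr, baseline) {
  stopifnot(all(dim(baseline) == dim(tfr$power)[1:2]))
  analyzed <- !is.na(baseline)
  if (any(baseline[analyzed] <= 0)) {
    stop("baseline power must be positive at analyzed frequencies",
         call. = FALSE)
  }
  vals <- sweep(sweep(tfr$power, c(1, 2), baseline, "-"),
                c(1, 2), baseline, "/") * 100
  structure(list(values = vals, valid = tfr$valid, freqs = tfr$freqs,
                 times = tfr$times, channel_names = tfr$channel_names),
            class = "erd_map")
}

#' Trial-level alpha-band ERD
#'
#' Unweighted mean of an ERD map over the frequency bins inside `band_hz`
#' (inclusive) and the valid time samples inside `window_s` (closed). The
#' default window runs from 0.5 s after trial onset to the trial end.
#'
#' @param erd An [compute_erd()] map with a trial-relative time axis.
#' @param band_hz Frequency band, inclusive (default alpha, 8-13.5 Hz).
#' @param window_s Averaging window in seconds.
#' @return Named numeric: mean ERD (percent) per channel.
#' @export
trial_alpha_erd <- function(erd, band_hz = c(8, 13.5), window_s = c(0.5, 3)) {
  fi <- which(erd$freqs >= band_hz[1] & erd$freqs <= band_hz[2])
  if (length(fi) == 0) stop("band outside the frequency axis", call. = FALSE)
  ti <- which(erd$times >= window_s[1] & erd$times <= window_s[2])
  if (length(ti) == 0) stop("empty averaging window", call. = FALSE)
  out <- vapply(seq_along(erd$channel_names), function(ci) {
    acc <- c()
    for (f in fi) {
      use <- ti[erd$valid[f, ti]]
      acc <- c(acc, erd$values[ci, f, use])
    }
    if (length(acc) == 0) NA_real_ else mean(acc)
  }, numeric(1))
  names(out) <- erd$channel_names
  out
}

#' Per-trial alpha ERD table for a trial set
#'
#' Runs the full single-trial pipeline — Morlet decomposition, per-trial
#' pre-trial baseline, ERD map, band/window average — and returns a tidy
#' table. Bad trials are carried with `good = FALSE` so downstream averages
#' can exclude them.
#'
#' @param trials A `trial_set` (after [reject_bad_trials()] if rejection is
#'   wanted).
#' @param freqs Analysis frequencies (defaults to the alpha band bins; use
#'   `seq(1, 40, 0.5)` for the full map).
#' @param band_hz Band for the trial average.
#' @param baseline_window_s Pre-trial baseline window (seconds re onset).
#' @param n_cycles Morlet cycles.
#' @param baseline `"per_trial"` (default) computes each trial's baseline
#'   spectrum from its own pre-trial window; `"average"` pools the baseline
#'   spectrum across all good trials first.
#' @return A tibble: trial, condition, channel, erd_percent, good.
#' @export
erd_summary <- function(trials, freqs = seq(8, 13.5, by = 0.5),
                        band_hz = c(8, 13.5),
                        baseline_window_s = c(-1, -0.1), n_cycles = 7,
                        baseline = c("per_trial", "average")) {
  baseline <- match.arg(baseline)
  n_tr <- nrow(trials$meta)
  n_ch <- length(trials$channel_names)
  if (n_tr == 0) {
    return(tibble::tibble(trial = integer(), condition = character(),
                          channel = character(), erd_percent = numeric(),
                          good = logical()))
  }
  # one decomposition over all stacked epochs (epochs share their length)
  stacked <- matrix(aperm(trials$epochs, c(3, 2, 1)),
                    nrow = n_tr * n_ch, byrow = TRUE)
  all_tfr <- morlet_tfr(stacked, sfreq_hz = trials$sfreq_hz, freqs = freqs,
                        n_cycles = n_cycles, t0_s = -trials$pre_s)
  R_pool <- NULL
  if (baseline == "average") {
    Rs <- purrr::map(which(trials$meta$good), function(i) {
      rows <- (i - 1L) * n_ch + seq_len(n_ch)
      tfr <- all_tfr
      tfr$power <- all_tfr$power[rows, , , drop = FALSE]
      tfr$channel_names <- trials$channel_names
      baseline_spectrum(tfr, baseline_window_s)
    })
    R_pool <- Reduce(`+`, Rs) / length(Rs)
  }
  purrr::map(seq_len(n_tr), function(i) {
    rows <- (i - 1L) * n_ch + seq_len(n_ch)
    tfr <- all_tfr
    tfr$power <- all_tfr$power[rows, , , drop = FALSE]
    tfr$channel_names <- trials$channel_names
    R <- if (is.null(R_pool)) baseline_spectrum(tfr, baseline_window_s)
    else R_pool
    erd <- compute_erd(tfr, R)
    vals <- trial_alpha_erd(erd, band_hz = band_hz,
                            window_s = c(0.5, trials$meta$duration[i]))
    tibble::tibble(trial = i, condition = trials$meta$condition[i],
                   channel = names(vals), erd_percent = unname(vals),
                   good = trials$meta$good[i])
  }) |> purrr::list_rbind()
}
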