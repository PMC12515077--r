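#' Simulate C3/C4 EEG with condition-dependent alpha desynchronization
#'
#' Generates a two-channel (C3, C4) recording for one run of a paradigm. Each
#' channel carries a 10 Hz (by default) alpha carrier whose amplitude envelope
#' encodes event-related desynchronization (ERD): during task trials the
#' hand-contralateral channel's band power drops by `erd_percent` of that
#' condition relative to the immediately preceding baseline, and the
#' ipsilateral channel by `ipsilateral_fraction` of that. Instruction and
#' inter-trial periods carry the block's modulation at half depth, so the
#' pre-trial baseline window sits on the block-level envelope and the
#' trial-versus-baseline power change equals the planted ERD. Broadband 1/f
#' background noise is added.
#'
#' Right-hand conditions modulate C3 (left sensorimotor cortex), left-hand
#' conditions modulate C4.
#'
#' @param paradigm A [generate_paradigm()] object.
#' @param erd_percent Named numeric: planted contralateral ERD (percent,
#'   usually negative) per task condition. Defaults use imagery values around
#'   -16 to -19 % and deeper execution ERD.
#' @param alpha_hz Carrier frequency (Hz). Values outside 8-13.5 warn.
#' @param sampling_rate_hz Sampling rate; must be at least 100 Hz.
#' @param amplitude_uv Resting alpha carrier amplitude (microvolts).
#' @param noise_sd_uv Standard deviation of the 1/f background noise.
#' @param ipsilateral_fraction Fraction of the contralateral ERD applied to
#'   the ipsilateral channel (0 disables ipsilateral modulation).
#' @param run Which run of the paradigm to synthesize.
#' @param seed Optional integer seed.
#' @return An [eeg_recording()] with channels C3 and C4.
#' @examples
#' p <- generate_paradigm(blocks_per_condition = 1, seed = 1)
#' rec <- simulate_eeg(p, seed = 1)
#' @export
simulate_eeg <- function(paradigm,
                         erd_percent = c(ME_LH = -25, ME_RH = -25,
                                         MI_LH = -18.58, MI_RH = -16.18),
                         alpha_hz = 10, sampling_rate_hz = 250,
                         amplitude_uv = 10, noise_sd_uv = 2,
                         ipsilateral_fraction = 0.4, run = 1, seed = NULL) {
  if (sampling_rate_hz < 100) {
    stop("`sampling_rate_hz` must be >= 100 Hz (2 x 40 Hz with margin)",
         call. = FALSE)
  }
  if (any(erd_percent <= -100)) {
    stop("`erd_percent` values must be > -100", call. = FALSE)
  }
  if (alpha_hz < 8 || alpha_hz > 13.5) {
    warning("`alpha_hz` outside the 8-13.5 Hz alpha band", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  fs <- sampling_rate_hz
  n <- as.integer(round(paradigm$run_length_s * fs))
  blocks <- dplyr::filter(paradigm$blocks, .data$run == !!run,
                          .data$type == "task")
  trials <- dplyr::filter(paradigm$trials, .data$run == !!run)

  # envelope per channel: start at resting amplitude
  env <- list(C3 = rep(amplitude_uv, n), C4 = rep(amplitude_uv, n))
  contra_of <- function(cond) if (grepl("RH$", cond)) "C3" else "C4"

  idx_of <- function(onset, end) {
    i0 <- floor(onset * fs) + 1L
    i1 <- floor(end * fs)          # half-open [onset, end)
    seq.int(max(i0, 1L), min(i1, n))
  }

  for (b in seq_len(nrow(blocks))) {
    cond <- blocks$condition[b]
    e <- unname(erd_percent[[cond]])
    for (ch in c("C3", "C4")) {
      e_eff <- if (ch == contra_of(cond)) e else e * ipsilateral_fraction
      base_fac <- sqrt(1 + e_eff / 200)   # instruction + ITI at half depth
      ii <- idx_of(blocks$onset[b], blocks$onset[b] + blocks$duration[b])
      env[[ch]][ii] <- amplitude_uv * base_fac
      tr <- trials[trials$onset >= blocks$onset[b] &
                     trials$onset < blocks$onset[b] + blocks$duration[b], ]
      trial_fac <- base_fac * sqrt(1 + e_eff / 100)
      for (k in seq_len(nrow(tr))) {
        jj <- idx_of(tr$onset[k], tr$onset[k] + tr$duration[k])
        env[[ch]][jj] <- amplitude_uv * trial_fac
      }
    }
  }

  t <- (seq_len(n) - 1L) / fs
  dat <- rbind(
    C3 = env$C3 * sin(2 * pi * alpha_hz * t + stats::runif(1, 0, 2 * pi)),
    C4 = env$C4 * sin(2 * pi * alpha_hz * t + stats::runif(1, 0, 2 * pi))
  )
  if (noise_sd_uv > 0) {
    dat <- dat + rbind(pink_noise(n, noise_sd_uv), pink_noise(n, noise_sd_uv))
  }
  eeg_recording(dat, c("C3", "C4"), fs, t0_s = 0)
}

# 1/f-amplitude noise via spectral shaping of white noise
pink_noise <- function(n, sd) {
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)                       # symmetric two-sided frequency
  f[1] <- 1                                 # avoid division by zero at DC
  xf <- xf / sqrt(f)
  xf[1] <- 0
  y <- Re(stats::fft(xf, inverse = TRUE)) / n
  y * sd / stats::sd(y)
}
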