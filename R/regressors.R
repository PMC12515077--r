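#' Construct a power-series object
#'
#' A continuous band-averaged power time course for one electrode, at the
#' EEG sampling rate.
#'
#' @param values Non-negative numeric vector (microvolts squared).
#' @param sfreq_hz Sampling rate.
#' @param electrode Electrode label.
#' @param t0_s Time of the first sample relative to run start.
#' @return A `power_series` object.
#' @export
power_series <- function(values, sfreq_hz, electrode = "C3", t0_s = 0) {
  stopifnot(is.numeric(values), sfreq_hz > 0)
  structure(list(values = as.numeric(values), sfreq_hz = sfreq_hz,
                 electrode = electrode, t0_s = t0_s),
            class = "power_series")
}

#' @export
print.power_series <- function(x, ...) {
  cat("<power_series> ", x$electrode, ": ", length(x$values), " samples @ ",
      x$sfreq_hz, " Hz\n", sep = "")
  invisible(x)
}

#' Continuous band-averaged alpha power at selected electrodes
#'
#' Morlet decomposition of the whole continuous recording (same estimator as
#' the trial analysis), averaged over the frequency bins inside `band_hz`
#' (inclusive, 0.5 Hz grid). Edge samples that fall inside the wavelet
#' support are filled with the nearest valid value so the series covers the
#' full run.
#'
#' @param rec An [eeg_recording()].
#' @param electrodes Channels to extract (default C3 and C4).
#' @param band_hz Band in Hz, inclusive (default alpha, 8-13.5).
#' @param n_cycles Morlet cycles.
#' @return Named list of [power_series()] objects, one per electrode.
#' @export
continuous_band_power <- function(rec, electrodes = c("C3", "C4"),
                                  band_hz = c(8, 13.5), n_cycles = 7) {
  missing <- setdiff(electrodes, rec$channel_names)
  if (length(missing) > 0) {
    stop("electrode(s) not in the recording: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  freqs <- seq(band_hz[1], band_hz[2], by = 0.5)
  sub <- rec$data[electrodes, , drop = FALSE]
  tfr <- morlet_tfr(sub, sfreq_hz = rec$sfreq_hz, freqs = freqs,
                    n_cycles = n_cycles, t0_s = rec$t0_s)
  out <- purrr::map(seq_along(electrodes), function(ci) {
    band <- colMeans(tfr$power[ci, , , drop = TRUE])
    # fill edge-invalid samples with nearest valid value (widest wavelet
    # dominates the invalid margin)
    ok <- colSums(!tfr$valid) == 0
    if (!all(ok)) {
      first <- which(ok)[1]
      last <- rev(which(ok))[1]
      band[seq_len(first - 1)] <- band[first]
      if (last < length(band)) band[(last + 1):length(band)] <- band[last]
    }
    power_series(band, rec$sfreq_hz, electrodes[ci], rec$t0_s)
  })
  names(out) <- electrodes
  out
}

#' Impute bad-trial segments in a continuous power series
#'
#' Replaces the series over each bad trial's span with the pointwise mean of
#' the same-condition good trials' segments (aligned to trial onset). When a
#' condition has no good trial, its bad segments are left unchanged with a
#' warning.
#'
#' @param series A [power_series()].
#' @param trials A `trial_set` with rejection flags set.
#' @param run Run the series belongs to (matches `trials$meta$run`).
#' @return The imputed `power_series`.
#' @export
impute_bad_trials <- function(series, trials, run = 1) {
  meta <- trials$meta[trials$meta$run == run, ]
  if (nrow(meta) == 0 || all(meta$good)) return(series)
  fs <- series$sfreq_hz
  vals <- series$values
  seg_idx <- function(onset, duration) {
    i0 <- floor((onset - series$t0_s) * fs) + 1L
    i0:(i0 + as.integer(round(duration * fs)) - 1L)
  }
  for (cond in unique(meta$condition[!meta$good])) {
    bad <- meta[meta$condition == cond & !meta$good, ]
    good <- meta[meta$condition == cond & meta$good, ]
    if (nrow(good) == 0) {
      warning("no good trials of condition ", cond,
              "; segments left unimputed", call. = FALSE)
      next
    }
    segs <- vapply(seq_len(nrow(good)),
                   function(i) vals[seg_idx(good$onset[i], good$duration[i])],
                   numeric(as.integer(round(bad$duration[1] * fs))))
    avg <- rowMeans(segs)
    for (i in seq_len(nrow(bad))) {
      vals[seg_idx(bad$onset[i], bad$duration[i])] <- avg
    }
  }
  power_series(vals, fs, series$electrode, series$t0_s)
}

#' Mask a power series to one experimental condition
#'
#' Sets the series to zero outside the blocks of the requested condition
#' group. Masks are block-wide (instruction, trials and inter-trial
#' intervals all belong to the block's condition): `"ME"` is the union of
#' both hands' execution blocks, `"MI"` both imagery blocks, `"REST"` the
#' rest blocks (including any trailing pad). The three masked series
#' partition the original sample-by-sample.
#'
#' @param series A [power_series()].
#' @param paradigm The paradigm the series was recorded under.
#' @param condition `"ME"`, `"MI"` or `"REST"`.
#' @param run Run index.
#' @return The masked `power_series`.
#' @export
condition_mask <- function(series, paradigm, condition, run = 1) {
  iv <- condition_intervals(paradigm, condition, run = run)
  fs <- series$sfreq_hz
  n <- length(series$values)
  keep <- rep(FALSE, n)
  for (i in seq_len(nrow(iv))) {
    i0 <- floor((iv$onset[i] - series$t0_s) * fs) + 1L
    i1 <- floor((iv$end[i] - series$t0_s) * fs)    # half-open [onset, end)
    keep[max(i0, 1L):min(i1, n)] <- TRUE
  }
  out <- series$values
  out[!keep] <- 0
  power_series(out, fs, series$electrode, series$t0_s)
}

#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = g(t; 6, 1) - g(t; 16, 1) / 6` with gamma probability densities
#' `g`, sampled on `[0, kernel_length_s]` at `dt_s` and scaled to a peak of
#' one. The kernel peaks near 5 s with a late undershoot — the canonical
#' shape used by SPM-style analyses.
#'
#' @param dt_s Sampling interval of the kernel in seconds.
#' @param peak_delay_s,undershoot_delay_s Gamma shape parameters (seconds,
#'   with unit dispersion these equal the means).
#' @param peak_dispersion_s,undershoot_dispersion_s Gamma scale parameters.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @param kernel_length_s Kernel support in seconds.
#' @return Numeric kernel sampled at `dt_s`, peak scaled to 1.
#' @examples
#' h <- canonical_hrf(0.1)
#' plot(seq(0, 32, 0.1), h, type = "l")
#' @export
canonical_hrf <- function(dt_s, peak_delay_s = 6, undershoot_delay_s = 16,
                          peak_dispersion_s = 1, undershoot_dispersion_s = 1,
                          ratio = 6, kernel_length_s = 32) {
  stopifnot(dt_s > 0, kernel_length_s >= undershoot_delay_s)
  t <- seq(0, kernel_length_s, by = dt_s)
  h <- stats::dgamma(t, shape = peak_delay_s, scale = peak_dispersion_s) -
    stats::dgamma(t, shape = undershoot_delay_s,
                  scale = undershoot_dispersion_s) / ratio
  h / max(h)
}

# causal convolution with kernel + within-TR block average to the TR grid
hrf_convolve_downsample <- function(values, sfreq_hz, hrf, tr_s, n_vol,
                                    downsample = c("average", "point")) {
  downsample <- match.arg(downsample)
  n <- length(values)
  m <- length(hrf)
  nfft <- stats::nextn(n + m - 1L, c(2, 3, 5))
  conv <- Re(stats::fft(stats::fft(c(values, rep(0, nfft - n))) *
                          stats::fft(c(hrf, rep(0, nfft - m))),
                        inverse = TRUE)) / nfft
  conv <- conv[seq_len(n)] / sfreq_hz        # causal; dt-scaled (units uV^2 s)
  spt <- as.integer(round(tr_s * sfreq_hz))  # samples per TR
  if (n < n_vol * spt) stop("series shorter than the run", call. = FALSE)
  if (downsample == "average") {
    vapply(seq_len(n_vol),
           function(v) mean(conv[((v - 1L) * spt + 1L):(v * spt)]),
           numeric(1))
  } else {
    conv[((seq_len(n_vol) - 1L) * spt) + 1L]
  }
}

#' Discrete-cosine high-pass basis
#'
#' DCT basis functions whose periods exceed `cutoff_s`, excluding the
#' constant term — the set an SPM-style 128 s high-pass removes.
#'
#' @param n_vol Number of volumes.
#' @param tr_s Repetition time.
#' @param cutoff_s High-pass cutoff in seconds.
#' @return Matrix with `n_vol` rows (possibly zero columns).
#' @export
dct_highpass_basis <- function(n_vol, tr_s, cutoff_s = 128) {
  k_max <- floor(2 * n_vol * tr_s / cutoff_s)
  if (k_max < 1) return(matrix(numeric(0), n_vol, 0))
  t <- seq_len(n_vol) - 1L
  sapply(seq_len(k_max), function(k) {
    cos(pi * k * (2 * t + 1) / (2 * n_vol))
  })
}

#' Build one EEG-informed regressor column
#'
#' Causal convolution of a (condition-masked) power series with the
#' canonical HRF, resampling to the TR grid (within-TR block average by
#' default, point sampling optionally), removal of slow drifts by
#' residualizing against a discrete-cosine basis with periods above the
#' cutoff, and mean-centering.
#'
#' @param masked A [power_series()] (typically from [condition_mask()]).
#' @param n_vol Number of volumes in the run.
#' @param hrf HRF kernel sampled at the EEG rate; built with
#'   [canonical_hrf()] when `NULL`.
#' @param tr_s Repetition time (default 2 s).
#' @param highpass_cutoff_s High-pass cutoff (default 128 s; `Inf` disables).
#' @param downsample `"average"` or `"point"`.
#' @return Numeric column of length `n_vol`, mean-centered.
#' @export
make_regressor <- function(masked, n_vol, hrf = NULL, tr_s = 2,
                           highpass_cutoff_s = 128,
                           downsample = c("average", "point")) {
  if (is.null(hrf)) hrf <- canonical_hrf(1 / masked$sfreq_hz)
  col <- hrf_convolve_downsample(masked$values, masked$sfreq_hz, hrf, tr_s,
                                 n_vol, downsample = match.arg(downsample))
  if (is.finite(highpass_cutoff_s)) {
    K <- dct_highpass_basis(n_vol, tr_s, highpass_cutoff_s)
    if (ncol(K) > 0) col <- stats::lm.fit(cbind(1, K), col)$residuals
  }
  col - mean(col)
}

#' Build the six EEG-informed regressors for one scan
#'
#' Convenience wrapper: masks each electrode's continuous alpha power by the
#' three condition groups and converts each masked series to a TR-rate
#' column, yielding the labeled columns C3-ME, C3-MI, C3-REST, C4-ME,
#' C4-MI, C4-REST.
#'
#' @param power Named list of [power_series()] (C3, C4), e.g. from
#'   [continuous_band_power()].
#' @param paradigm The paradigm.
#' @param run Run index.
#' @param ... Passed to [make_regressor()].
#' @return Matrix `n_vol` x 6 with column labels.
#' @export
eeg_regressor_set <- function(power, paradigm, run = 1, ...) {
  n_vol <- n_volumes(paradigm)
  cols <- list()
  for (el in c("C3", "C4")) {
    for (cond in c("ME", "MI", "REST")) {
      masked <- condition_mask(power[[el]], paradigm, cond, run = run)
      cols[[paste0(el, "-", cond)]] <- make_regressor(masked, n_vol, ...)
    }
  }
  do.call(cbind, cols)
}

#' Assemble a (possibly multi-scan) design matrix
#'
#' EEG regressors occupy shared labeled columns across scans; motion
#' parameters and intercepts enter block-diagonally per scan, giving the
#' fixed-effects layout used for group analysis. The assembled matrix is
#' checked for full column rank.
#'
#' @param regressors List (one per scan) of labeled regressor matrices with
#'   identical column names, or a single matrix.
#' @param motion List (one per scan) of motion-parameter matrices
#'   (volumes x 6), or `NULL` to omit motion columns.
#' @return A `design_matrix`: the numeric matrix `X` with column labels, a
#'   `scans` tibble of per-scan row ranges, and the label groups.
#' @export
assemble_design <- function(regressors, motion = NULL) {
  if (is.matrix(regressors)) regressors <- list(regressors)
  n_scans <- length(regressors)
  if (!is.null(motion) && is.matrix(motion)) motion <- list(motion)
  if (!is.null(motion) && length(motion) != n_scans) {
    stop("need one motion matrix per scan", call. = FALSE)
  }
  labels <- colnames(regressors[[1]])
  rows <- vapply(regressors, nrow, integer(1))
  if (!is.null(motion)) {
    mrows <- vapply(motion, nrow, integer(1))
    if (any(mrows != rows)) stop("motion rows must match regressor rows",
                                 call. = FALSE)
  }
  total <- sum(rows)
  n_mot <- if (is.null(motion)) 0L else ncol(motion[[1]])
  X <- matrix(0, total, length(labels) + n_scans * n_mot + n_scans)
  cn <- c(labels,
          if (n_mot > 0) paste0("motion", seq_len(n_mot), "_scan",
                                rep(seq_len(n_scans), each = n_mot)),
          paste0("intercept_scan", seq_len(n_scans)))
  colnames(X) <- cn
  offs <- cumsum(c(0, rows))
  for (s in seq_len(n_scans)) {
    rr <- (offs[s] + 1):offs[s + 1]
    X[rr, seq_along(labels)] <- regressors[[s]][, labels, drop = FALSE]
    if (n_mot > 0) {
      cc <- length(labels) + (s - 1) * n_mot + seq_len(n_mot)
      X[rr, cc] <- as.matrix(motion[[s]])
    }
    X[rr, length(labels) + n_scans * n_mot + s] <- 1
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- cn[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  structure(list(
    X = X,
    scans = tibble::tibble(scan = seq_len(n_scans),
                           first_row = offs[-length(offs)] + 1L,
                           last_row = offs[-1]),
    eeg_labels = labels), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$X), " rows x ", ncol(x$X), " columns, ",
      nrow(x$scans), " scan(s)\n", sep = "")
  cat("  shared columns:", paste(x$eeg_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Write a design matrix as TSV plus a scan-range sidecar
#' @param design A `design_matrix`.
#' @param path Output stem; writes `<path>.tsv` and `<path>_scans.tsv`.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(tibble::as_tibble(design$X), paste0(path, ".tsv"))
  readr::write_tsv(design$scans, paste0(path, "_scans.tsv"))
  invisible(path)
}
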