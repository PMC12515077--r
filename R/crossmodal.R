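#' Mean t statistic inside a region of interest
#'
#' Mean of the map's t values over the ROI voxels that individually pass
#' the one-sided voxel threshold. Returns `NA` (with a message) when no ROI
#' voxel passes.
#'
#' @param map A [stat_map()].
#' @param roi Logical array/vector on the same grid.
#' @param p_voxel One-sided voxel threshold (default 0.001).
#' @return Mean t (scalar), or `NA` if no voxel passes.
#' @export
roi_mean_t <- function(map, roi, p_voxel = 0.001) {
  if (length(roi) != length(map$t)) stop("roi grid mismatch", call. = FALSE)
  p <- stats::pt(map$t, df = map$df, lower.tail = FALSE)
  use <- as.vector(roi) & !is.na(p) & p < p_voxel
  if (!any(use)) {
    message("no ROI voxel passes p < ", p_voxel, "; mean t undefined")
    return(NA_real_)
  }
  mean(map$t[use])
}

#' Linear regression of ROI-mean BOLD t on contralateral ERD
#'
#' Ordinary least squares of the per-sample ROI-mean t statistic on the
#' contralateral high-alpha ERD, with the Pearson correlation and its
#' two-sided p value from the exact t transform with n - 2 degrees of
#' freedom. The physiological expectation is a negative relationship:
#' deeper alpha desynchronization with stronger BOLD activation.
#'
#' @param samples Tibble with columns `erd_percent` (contralateral
#'   high-alpha ERD) and `roi_mean_t`; other columns (subject, task) are
#'   carried along.
#' @return An `erd_bold_fit` with slope, intercept, r, p, n; supports
#'   [generics::tidy()], [generics::glance()] and `autoplot()`.
#' @export
erd_bold_regression <- function(samples) {
  x <- samples$erd_percent
  y <- samples$roi_mean_t
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite samples", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in the ERD predictor",
                              call. = FALSE)
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  structure(list(slope = slope, intercept = intercept, r = r, p_value = p,
                 n = n, samples = samples[keep, ]),
            class = "erd_bold_fit")
}

#' @export
print.erd_bold_fit <- function(x, ...) {
  cat("<erd_bold_fit> n = ", x$n, ": t = ", signif(x$intercept, 4), " + ",
      signif(x$slope, 4), " x ERD;  r = ", round(x$r, 3), ", p = ",
      signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Assemble cross-modal coupling samples for a cohort
#'
#' Pairs each subject's contralateral high-alpha ERD with the ROI-mean t of
#' the matching first-level map: C3 and the left sensorimotor ROI for
#' right-hand imagery, C4 and the right sensorimotor ROI for left-hand
#' imagery. Both imagery tasks' samples are pooled.
#'
#' @param erd Tibble with columns subject, task (`MI_RH`/`MI_LH`),
#'   erd_percent (high-alpha, contralateral channel).
#' @param roi_t Tibble with columns subject, task, roi_mean_t.
#' @return Tibble of coupling samples.
#' @export
coupling_samples <- function(erd, roi_t) {
  dplyr::inner_join(erd, roi_t, by = c("subject", "task"))
}
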