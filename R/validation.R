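#' Overlap of two binarized activation maps
#'
#' Counts TP (voxels active in both maps), FP (active in `A` only) and FN
#' (active in `B` only), treating `A` as the evaluated map (e.g. the
#' EEG-informed result) and `B` as the reference (e.g. the block-design
#' result), and reports Dice `2TP/(2TP+FP+FN)`, precision `TP/(TP+FP)` and
#' recall `TP/(TP+FN)`. Metrics with an empty denominator are reported as
#' `NA`, never as zero. An optional region of interest restricts both maps
#' before counting.
#'
#' @param A,B Logical arrays/vectors of identical dimensions.
#' @param roi Optional logical mask intersected with both maps first.
#' @return An `overlap_report` tibble row: tp, fp, fn, dice, precision,
#'   recall.
#' @examples
#' a <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
#' b <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
#' overlap(a, b)
#' @export
overlap <- function(A, B, roi = NULL) {
  if (!identical(dim(A), dim(B)) || length(A) != length(B)) {
    stop("maps must share one grid", call. = FALSE)
  }
  if (!is.null(roi)) {
    if (length(roi) != length(A)) stop("roi grid mismatch", call. = FALSE)
    A <- A & roi
    B <- B & roi
  }
  tp <- sum(A & B)
  fp <- sum(A & !B)
  fn <- sum(!A & B)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    dice = safe(2 * tp, 2 * tp + fp + fn),
    precision = safe(tp, tp + fp),
    recall = safe(tp, tp + fn))
  class(out) <- c("overlap_report", class(out))
  out
}

#' Precision-based subject screen
#'
#' For each subject, computes the precision of the two lateralized imagery
#' contrast maps against their contralateral sensorimotor regions of
#' interest, averages the two, and keeps subjects whose mean precision
#' strictly exceeds the threshold (15 % by default).
#'
#' @param subject_maps Named list (one element per subject) of lists with
#'   binarized maps `MI_RH` and `MI_LH` (thresholded at the voxel level).
#' @param roi_by_contrast List with ROIs `MI_RH` (left sensorimotor, for
#'   right-hand imagery) and `MI_LH` (right sensorimotor).
#' @param threshold_percent Retention threshold (strict `>`).
#' @return Tibble: subject, precision_rh, precision_lh, mean_precision
#'   (all percent), kept.
#' @export
subject_precision_screen <- function(subject_maps, roi_by_contrast,
                                     threshold_percent = 15) {
  purrr::imap(subject_maps, function(maps, subject) {
    for (ct in c("MI_RH", "MI_LH")) {
      if (is.null(maps[[ct]])) {
        stop("subject ", subject, " is missing contrast ", ct, call. = FALSE)
      }
    }
    prec <- vapply(c("MI_RH", "MI_LH"), function(ct) {
      roi <- roi_by_contrast[[ct]]
      tp <- sum(maps[[ct]] & roi)
      tot <- sum(maps[[ct]])
      if (tot == 0) NA_real_ else 100 * tp / tot
    }, numeric(1))
    m <- mean(prec)
    tibble::tibble(subject = subject, precision_rh = prec[["MI_RH"]],
                   precision_lh = prec[["MI_LH"]], mean_precision = m,
                   kept = !is.na(m) && m > threshold_percent)
  }) |> purrr::list_rbind()
}

#' Framewise displacement from motion parameters
#'
#' Power-style framewise displacement: the sum of absolute backward
#' differences of the three translations (mm) plus the three rotations
#' converted to arc length on a 50 mm sphere. The first volume's FD is 0 by
#' convention.
#'
#' @param motion Tibble/matrix of 6 motion parameters per volume
#'   (translations mm, then rotations rad).
#' @param sphere_radius_mm Rotation-to-displacement radius (default 50).
#' @return Tibble: volume, fd (mm).
#' @export
framewise_displacement <- function(motion, sphere_radius_mm = 50) {
  m <- as.matrix(motion)
  if (nrow(m) < 2) stop("need at least two volumes", call. = FALSE)
  d <- abs(diff(m))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            sphere_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  tibble::tibble(volume = seq_len(nrow(m)), fd = fd)
}

#' Motion-based subject exclusion
#'
#' Flags subjects whose mean framewise displacement exceeds the group mean
#' by more than `n_sd` group standard deviations.
#'
#' @param mean_fd Numeric vector of per-subject mean FD (mm).
#' @param n_sd Number of group SDs above the mean (default 3).
#' @return Tibble: subject, mean_fd, excluded, plus the group mean and SD
#'   as attributes.
#' @export
fd_exclusions <- function(mean_fd, n_sd = 3) {
  gm <- mean(mean_fd)
  gs <- stats::sd(mean_fd)
  out <- tibble::tibble(subject = seq_along(mean_fd), mean_fd = mean_fd,
                        excluded = mean_fd > gm + n_sd * gs)
  attr(out, "group_mean") <- gm
  attr(out, "group_sd") <- gs
  out
}

#' Write an overlap report as a key-value summary file
#' @param report An `overlap_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap <- function(report, path) {
  lines <- c(
    paste0("tp\t", report$tp),
    paste0("fp\t", report$fp),
    paste0("fn\t", report$fn),
    paste0("dice\t", formatC(report$dice, format = "f", digits = 4)),
    paste0("precision\t", formatC(report$precision, format = "f", digits = 4)),
    paste0("recall\t", formatC(report$recall, format = "f", digits = 4)))
  writeLines(lines, path)
  invisible(path)
}
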