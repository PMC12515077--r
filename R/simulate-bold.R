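#' Ground truth for the synthetic BOLD forward model
#'
#' Describes where and how strongly alpha power couples to the hemodynamic
#' signal. Each coupled mask pairs an electrode (C3 or C4) with a condition
#' group (ME or MI); voxels inside the mask receive
#' `weight x (condition-masked, HRF-convolved, TR-sampled alpha power)` on
#' top of baseline, noise and drift. Negative weights encode the
#' physiological expectation that alpha desynchronization accompanies a BOLD
#' increase.
#'
#' Defaults use a 20 x 20 x 12 grid of 2 mm voxels with disjoint
#' left-hemisphere blobs for C3 masks and mirrored right-hemisphere blobs
#' for C4 masks. The amplitude scales are chosen so that, with the default
#' EEG simulator, a coupled voxel's task response is roughly 1.5 % of
#' baseline and the noise roughly 0.5 % - typical of a strongly responding
#' sensorimotor voxel.
#'
#' @param grid_dims Integer 3-vector of voxel counts.
#' @param voxel_size_mm Isotropic voxel size.
#' @param coupled_masks Named list of logical 3D arrays; names like
#'   `"C3-ME"`. C3 and C4 masks must be disjoint.
#' @param coupling_weight Named numeric, one signed weight per mask (a.u.).
#' @param ar1_phi AR(1) coefficient of the noise, in (-1, 1).
#' @param noise_sd Marginal noise standard deviation (a.u.).
#' @param drift_amp Amplitude scale of the slow cosine drift (a.u.).
#' @param motion_amp Scale of the simulated head-motion random walk (mm).
#' @param motion_gain Gain of the motion-correlated nuisance added to every
#'   voxel (a.u. per mm).
#' @param baseline Baseline signal level (a.u.).
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(grid_dims = c(20, 20, 12), voxel_size_mm = 2,
                         coupled_masks = default_coupled_masks(grid_dims),
                         coupling_weight = c("C3-ME" = -0.5, "C4-ME" = -0.5,
                                             "C3-MI" = -0.5, "C4-MI" = -0.5),
                         ar1_phi = 0.3, noise_sd = 150, drift_amp = 300,
                         motion_amp = 0.1, motion_gain = 20,
                         baseline = 32000) {
  stopifnot(length(grid_dims) == 3, abs(ar1_phi) < 1)
  for (nm in names(coupled_masks)) {
    stopifnot(all(dim(coupled_masks[[nm]]) == grid_dims))
  }
  c3 <- Reduce(`|`, coupled_masks[startsWith(names(coupled_masks), "C3")])
  c4 <- Reduce(`|`, coupled_masks[startsWith(names(coupled_masks), "C4")])
  if (!is.null(c3) && !is.null(c4) && any(c3 & c4)) {
    stop("C3 and C4 coupled masks must be disjoint", call. = FALSE)
  }
  structure(list(grid_dims = grid_dims, voxel_size_mm = voxel_size_mm,
                 coupled_masks = coupled_masks,
                 coupling_weight = coupling_weight, ar1_phi = ar1_phi,
                 noise_sd = noise_sd, drift_amp = drift_amp,
                 motion_amp = motion_amp, motion_gain = motion_gain,
                 baseline = baseline),
            class = "ground_truth")
}

#' Default coupled masks: lateralized blobs
#'
#' Left-hemisphere (low x) blobs couple to C3, mirrored right-hemisphere
#' blobs to C4; execution and imagery blobs sit in different axial slabs.
#' @param grid_dims Grid dimensions.
#' @return Named list of logical arrays.
#' @export
default_coupled_masks <- function(grid_dims = c(20, 20, 12)) {
  blob <- function(xr, yr, zr) {
    m <- array(FALSE, grid_dims)
    m[xr, yr, zr] <- TRUE
    m
  }
  nx <- grid_dims[1]
  list(
    "C3-ME" = blob(4:8, 8:13, 5:8),
    "C4-ME" = blob((nx - 7):(nx - 3), 8:13, 5:8),
    "C3-MI" = blob(4:8, 8:13, 9:11),
    "C4-MI" = blob((nx - 7):(nx - 3), 8:13, 9:11)
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> grid ", paste(x$grid_dims, collapse = "x"), " @ ",
      x$voxel_size_mm, " mm\n", sep = "")
  for (nm in names(x$coupled_masks)) {
    cat("  ", nm, ": ", sum(x$coupled_masks[[nm]]), " voxels, weight ",
        x$coupling_weight[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Simulate a BOLD run with planted neurovascular coupling
#'
#' Voxels inside each coupled mask receive the electrode's
#' condition-masked, HRF-convolved, TR-resampled alpha power scaled by that
#' mask's coupling weight; every voxel receives AR(1) noise, slow cosine
#' drift (periods of 200 s and above) and a small motion-correlated
#' nuisance. Head motion itself is a smoothed random walk in six parameters.
#'
#' @param paradigm A [generate_paradigm()] object.
#' @param alpha_power Named list of [power_series()] for C3 and C4 (e.g.
#'   from [continuous_band_power()]).
#' @param truth A [ground_truth()].
#' @param run Run index.
#' @param seed Optional integer seed.
#' @return List with `bold` (a `bold4d`) and `motion` (tibble, one row per
#'   volume: trans_x/y/z in mm, rot_x/y/z in rad).
#' @export
simulate_bold <- function(paradigm, alpha_power, truth = ground_truth(),
                          run = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_vol <- n_volumes(paradigm)
  tr <- paradigm$tr_s
  dims <- truth$grid_dims
  n_vox <- prod(dims)

  for (el in names(alpha_power)) {
    expected <- as.integer(round(paradigm$run_length_s *
                                   alpha_power[[el]]$sfreq_hz))
    if (length(alpha_power[[el]]$values) != expected) {
      stop("alpha power series for ", el, " does not cover the run",
           call. = FALSE)
    }
  }

  # motion: smoothed random walks
  rw <- function(scale) {
    x <- cumsum(stats::rnorm(n_vol))
    x <- stats::filter(x, rep(1 / 9, 9), sides = 2)
    x[is.na(x)] <- 0
    x <- x - x[1]
    as.numeric(x) * scale / max(stats::sd(x), 1e-12)
  }
  motion <- tibble::tibble(
    trans_x = rw(truth$motion_amp), trans_y = rw(truth$motion_amp),
    trans_z = rw(truth$motion_amp), rot_x = rw(truth$motion_amp / 50),
    rot_y = rw(truth$motion_amp / 50), rot_z = rw(truth$motion_amp / 50))

  # noise + drift + motion nuisance, volumes x voxels
  innov_sd <- truth$noise_sd * sqrt(1 - truth$ar1_phi^2)
  eps <- matrix(stats::rnorm(n_vol * n_vox, sd = innov_sd), n_vol, n_vox)
  if (truth$ar1_phi != 0) {
    for (t in 2:n_vol) {
      eps[t, ] <- eps[t, ] + truth$ar1_phi * eps[t - 1, ]
    }
  }
  tt <- (seq_len(n_vol) - 1) * tr
  if (truth$drift_amp > 0) {
    periods <- stats::runif(3 * n_vox, 200, 800)
    phases <- stats::runif(3 * n_vox, 0, 2 * pi)
    amps <- stats::runif(3 * n_vox, 0.5, 1) * truth$drift_amp / sqrt(3)
    drift <- matrix(0, n_vol, n_vox)
    for (j in 1:3) {
      idx <- ((j - 1) * n_vox + 1):(j * n_vox)
      drift <- drift +
        sweep(cos(outer(tt, 2 * pi / periods[idx]) +
                    matrix(phases[idx], n_vol, n_vox, byrow = TRUE)),
              2, amps[idx], "*")
    }
    eps <- eps + drift
  }
  eps <- eps + truth$motion_gain *
    (motion$trans_x - mean(motion$trans_x))

  # planted coupling
  for (nm in names(truth$coupled_masks)) {
    el <- sub("-.*$", "", nm)
    cond <- sub("^.*-", "", nm)
    if (!el %in% names(alpha_power)) next
    masked <- condition_mask(alpha_power[[el]], paradigm, cond, run = run)
    reg <- hrf_convolve_downsample(
      masked$values, masked$sfreq_hz,
      canonical_hrf(1 / masked$sfreq_hz), tr, n_vol)
    vox <- which(as.vector(truth$coupled_masks[[nm]]))
    eps[, vox] <- eps[, vox] + truth$coupling_weight[[nm]] * reg
  }

  data <- array(truth$baseline + t(eps), dim = c(dims, n_vol))
  list(bold = bold4d(data, tr_s = tr, voxel_size_mm = truth$voxel_size_mm),
       motion = motion)
}

#' Construct a 4D BOLD object
#'
#' @param data 4D numeric array (x, y, z, volume).
#' @param tr_s Repetition time in seconds.
#' @param voxel_size_mm Isotropic voxel size.
#' @param affine Optional 4x4 voxel-to-mm (RAS) affine; defaults to a
#'   scaled identity centered at the grid origin.
#' @return A `bold4d` object.
#' @export
bold4d <- function(data, tr_s = 2, voxel_size_mm = 2, affine = NULL) {
  stopifnot(length(dim(data)) == 4)
  if (!all(is.finite(data))) stop("BOLD data must be finite", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size_mm, 3), 1))
  }
  structure(list(data = data, tr_s = tr_s, voxel_size_mm = voxel_size_mm,
                 affine = affine, grid_dims = dim(data)[1:3],
                 n_volumes = dim(data)[4]),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  cat("<bold4d> ", paste(x$grid_dims, collapse = "x"), " voxels @ ",
      x$voxel_size_mm, " mm, ", x$n_volumes, " volumes (TR ", x$tr_s,
      " s)\n", sep = "")
  invisible(x)
}

#' Flatten a 4D BOLD object to a volumes-by-voxels matrix
#' @param bold A `bold4d`.
#' @return Numeric matrix, volumes x voxels (voxels in array order).
#' @export
bold_matrix <- function(bold) {
  t(matrix(bold$data, prod(bold$grid_dims), bold$n_volumes))
}

#' Separable 3D Gaussian smoothing
#'
#' Smooths a volume with a separable Gaussian of the given full width at
#' half maximum, with reflective edge handling. `fwhm_mm = 0` returns the
#' input unchanged.
#'
#' @param volume 3D numeric array.
#' @param fwhm_mm Full width at half maximum in mm (default 4).
#' @param voxel_size_mm Voxel size in mm.
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_smooth <- function(volume, fwhm_mm = 4, voxel_size_mm = 2) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(volume)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  radius <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-radius:radius, sd = sigma)
  k <- k / sum(k)
  out <- volume
  for (axis in 1:3) {
    out <- apply(out, setdiff(1:3, axis), conv_reflect, k = k)
    # apply() puts the convolved axis first; restore order
    out <- aperm(out, order(c(axis, setdiff(1:3, axis))))
  }
  out
}

# 1D convolution with reflected (mirror) padding
conv_reflect <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- length(x)
  pad_l <- x[pmin(pmax(r:1, 1L), n)]
  pad_r <- x[pmin(pmax(n:(n - r + 1L), 1L), n)]
  xp <- c(pad_l, x, pad_r)
  as.numeric(stats::filter(xp, k, sides = 2))[(r + 1L):(r + n)]
}

#' Write a BOLD volume or map as NIfTI-1
#' @param x A `bold4d`, or a 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 affine for bare arrays.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, affine = NULL) {
  if (inherits(x, "bold4d")) {
    img <- RNifti::asNifti(x$data)
    img <- RNifti::`sform<-`(img, structure(x$affine, code = 2L))
    RNifti::pixdim(img) <- c(rep(x$voxel_size_mm, 3), x$tr_s)
  } else {
    img <- RNifti::asNifti(x)
    if (!is.null(affine)) img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write motion parameters as 6-column whitespace text
#' @param motion Tibble/data frame with 6 columns (translations mm,
#'   rotations rad), one row per volume.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(as.data.frame(motion), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read motion parameters from 6-column whitespace text
#' @param path Input path.
#' @return Tibble with trans_x/y/z, rot_x/y/z.
#' @export
read_motion <- function(path) {
  m <- utils::read.table(path)
  names(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  tibble::as_tibble(m)
}
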