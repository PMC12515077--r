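#' Fit a mass-univariate GLM
#'
#' Ordinary least squares of every voxel's time series on a shared design
#' matrix, assuming independent homoscedastic errors (no prewhitening by
#' default; see `prewhiten`). Estimation uses a QR decomposition.
#'
#' @param Y Numeric matrix, volumes x voxels (e.g. from [bold_matrix()]),
#'   or a `bold4d`.
#' @param design A [assemble_design()] object or bare numeric matrix.
#' @param prewhiten If `TRUE`, apply one Cochrane-Orcutt AR(1) prewhitening
#'   pass (a single pooled lag-1 coefficient estimated from the OLS
#'   residuals) before the final fit. Default `FALSE`.
#' @param grid_dims,affine Grid metadata carried through to maps; filled
#'   automatically when `Y` is a `bold4d`.
#' @return A `glm_fit`: `betas` (columns x voxels), `sigma2`, `df`,
#'   `xtx_inv`, column `labels`, grid metadata.
#' @export
fit_glm <- function(Y, design, prewhiten = FALSE, grid_dims = NULL,
                    affine = NULL) {
  if (inherits(Y, "bold4d")) {
    grid_dims <- Y$grid_dims
    if (is.null(affine)) affine <- Y$affine
    Y <- bold_matrix(Y)
  }
  X <- if (inherits(design, "design_matrix")) design$X else design
  if (nrow(Y) != nrow(X)) {
    stop("rows of Y (", nrow(Y), ") must match rows of the design (",
         nrow(X), ")", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)

  if (prewhiten) {
    res <- qr.resid(qrX, Y)
    num <- sum(res[-1, ] * res[-nrow(res), ])
    den <- sum(res[-nrow(res), ]^2)
    rho <- num / den
    W <- function(M) M[-1, , drop = FALSE] - rho * M[-nrow(M), , drop = FALSE]
    X <- W(X)
    Y <- W(Y)
    qrX <- qr(X)
  }

  betas <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  df <- nrow(Y) - qrX$rank
  sigma2 <- colSums(res^2) / df
  # residuals that are pure floating-point noise count as zero variance so
  # degenerate voxels surface as invalid rather than as huge t values
  sigma2[sigma2 <= colMeans(Y^2) * 1e-20] <- 0
  piv <- qrX$pivot
  xtx_inv <- matrix(NA_real_, ncol(X), ncol(X))
  xtx_inv[piv, piv] <- chol2inv(qr.R(qrX))
  labels <- colnames(X)
  structure(list(betas = betas, sigma2 = sigma2, df = df, xtx_inv = xtx_inv,
                 labels = labels, grid_dims = grid_dims, affine = affine),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("<glm_fit> ", length(x$labels), " columns x ", length(x$sigma2),
      " voxels, df = ", x$df, "\n", sep = "")
  invisible(x)
}

#' Build a contrast vector over labeled design columns
#'
#' @param labels Design column labels (or a `glm_fit`/`design_matrix`).
#' @param plus,minus Labels receiving weight +1 and -1.
#' @param weights Alternatively, a named numeric of weights.
#' @return Named numeric vector over all columns.
#' @export
contrast_vector <- function(labels, plus = character(), minus = character(),
                            weights = NULL) {
  if (inherits(labels, "glm_fit")) labels <- labels$labels
  if (inherits(labels, "design_matrix")) labels <- colnames(labels$X)
  cv <- stats::setNames(rep(0, length(labels)), labels)
  if (!is.null(weights)) {
    bad <- setdiff(names(weights), labels)
    if (length(bad) > 0) stop("unknown columns: ",
                              paste(bad, collapse = ", "), call. = FALSE)
    cv[names(weights)] <- weights
  }
  cv[plus] <- 1
  cv[minus] <- -1
  if (all(cv == 0)) stop("contrast has no nonzero weight", call. = FALSE)
  cv
}

#' Lateralized alpha-coupling contrast
#'
#' Maps the contrast names used for EEG-informed analysis to weights:
#' `"C3<C4-ME"` puts +1 on `C4-ME` and -1 on `C3-ME`, so positive t marks
#' voxels whose BOLD covaries more negatively with C3 alpha power than with
#' C4 alpha power (i.e. regions under C3 engaged by right-hand tasks).
#'
#' @param fit A `glm_fit` (or label vector).
#' @param name One of `"C3<C4-ME"`, `"C4<C3-ME"`, `"C3<C4-MI"`,
#'   `"C4<C3-MI"`.
#' @return A [stat_map()] of the contrast.
#' @export
lateral_contrast <- function(fit, name) {
  stopifnot(name %in% c("C3<C4-ME", "C4<C3-ME", "C3<C4-MI", "C4<C3-MI"))
  cond <- sub("^.*-", "", name)
  lesser <- sub("<.*$", "", name)          # electrode hypothesized more negative
  greater <- sub("-.*$", "", sub("^.*<", "", name))
  cv <- contrast_vector(fit, plus = paste0(greater, "-", cond),
                        minus = paste0(lesser, "-", cond))
  t_contrast(fit, cv)
}

#' Voxelwise t-contrast map
#'
#' `t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)` per voxel. Voxels with a zero
#' denominator (e.g. zero residual variance) are returned as `NA`.
#'
#' @param fit A [fit_glm()] result.
#' @param contrast Named or plain numeric vector conformable with the
#'   design columns.
#' @return A `stat_map` with the per-voxel t values and `df`.
#' @export
t_contrast <- function(fit, contrast) {
  if (!is.null(names(contrast))) {
    cv <- stats::setNames(rep(0, length(fit$labels)), fit$labels)
    cv[names(contrast)] <- contrast
    contrast <- cv
  }
  if (length(contrast) != nrow(fit$betas)) {
    stop("contrast not conformable with the design", call. = FALSE)
  }
  num <- drop(crossprod(contrast, fit$betas))
  cvar <- drop(t(contrast) %*% fit$xtx_inv %*% contrast)
  den <- sqrt(fit$sigma2 * cvar)
  t <- num / den
  t[den == 0] <- NA_real_
  stat_map(t, df = fit$df, grid_dims = fit$grid_dims, affine = fit$affine)
}

#' Construct a statistical map
#'
#' @param t Numeric vector (or 3D array) of t values.
#' @param df Residual degrees of freedom.
#' @param grid_dims Voxel grid dimensions (inferred from an array input).
#' @param affine Optional 4x4 voxel-to-mm affine.
#' @return A `stat_map` object.
#' @export
stat_map <- function(t, df, grid_dims = NULL, affine = NULL) {
  if (is.array(t) && length(dim(t)) == 3) {
    grid_dims <- dim(t)
    t <- as.vector(t)
  }
  structure(list(t = as.numeric(t), df = df, grid_dims = grid_dims,
                 affine = affine), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> ", length(x$t), " voxels, df = ", round(x$df, 1),
      ", t range [", round(min(x$t, na.rm = TRUE), 2), ", ",
      round(max(x$t, na.rm = TRUE), 2), "]\n", sep = "")
  invisible(x)
}

#' Volume view of a stat map
#' @param map A `stat_map` with grid metadata.
#' @return 3D array of t values.
#' @export
map_volume <- function(map) {
  stopifnot(!is.null(map$grid_dims))
  array(map$t, dim = map$grid_dims)
}

#' Block (boxcar) design matrix for conventional fMRI analysis
#'
#' One boxcar per task condition over its block intervals, convolved with
#' the canonical HRF on a fine grid, resampled to the TR grid, DCT
#' high-pass filtered and mean-centered; motion parameters and an intercept
#' are appended.
#'
#' @param paradigm A [generate_paradigm()] object.
#' @param motion Optional motion tibble/matrix (volumes x 6).
#' @param run Run index.
#' @param tr_s Repetition time (defaults to the paradigm's).
#' @param highpass_cutoff_s High-pass cutoff (128 s).
#' @param dt_s Internal sampling step for the boxcar convolution.
#' @return A `design_matrix` with condition columns ME_LH, ME_RH, MI_LH,
#'   MI_RH.
#' @export
block_design <- function(paradigm, motion = NULL, run = 1, tr_s = NULL,
                         highpass_cutoff_s = 128, dt_s = 0.1) {
  if (is.null(tr_s)) tr_s <- paradigm$tr_s
  n_vol <- n_volumes(paradigm)
  fs <- 1 / dt_s
  n <- as.integer(round(paradigm$run_length_s * fs))
  blocks <- dplyr::filter(paradigm$blocks, .data$run == !!run,
                          .data$type == "task")
  hrf <- canonical_hrf(dt_s)
  cols <- purrr::map(c("ME_LH", "ME_RH", "MI_LH", "MI_RH"), function(cond) {
    box <- rep(0, n)
    b <- blocks[blocks$condition == cond, ]
    for (i in seq_len(nrow(b))) {
      i0 <- floor(b$onset[i] * fs) + 1L
      i1 <- floor((b$onset[i] + b$duration[i]) * fs)
      box[i0:min(i1, n)] <- 1
    }
    col <- hrf_convolve_downsample(box, fs, hrf, tr_s, n_vol)
    if (is.finite(highpass_cutoff_s)) {
      K <- dct_highpass_basis(n_vol, tr_s, highpass_cutoff_s)
      if (ncol(K) > 0) col <- stats::lm.fit(cbind(1, K), col)$residuals
    }
    col - mean(col)
  })
  reg <- do.call(cbind, cols)
  colnames(reg) <- c("ME_LH", "ME_RH", "MI_LH", "MI_RH")
  assemble_design(reg, motion = if (is.null(motion)) NULL else as.matrix(motion))
}

#' Second-level (random-effects) model with covariates
#'
#' Per-voxel OLS of subject contrast values on an intercept plus
#' mean-centered covariates; the returned map is the t statistic of the
#' intercept, i.e. the covariate-adjusted group mean effect.
#'
#' @param contrast_maps List of per-subject `stat_map`s (or numeric
#'   vectors), identical grids.
#' @param covariates Data frame with one row per subject (e.g. age, sex,
#'   handedness). Factors/characters are converted to numeric codes.
#' @return A `stat_map` of the group-mean t with `df = n - 1 - n_covariates`.
#' @export
second_level <- function(contrast_maps, covariates = NULL) {
  vals <- vapply(contrast_maps,
                 function(m) if (inherits(m, "stat_map")) m$t else as.numeric(m),
                 numeric(length(if (inherits(contrast_maps[[1]], "stat_map"))
                   contrast_maps[[1]]$t else contrast_maps[[1]])))
  Y <- t(vals)                               # subjects x voxels
  n <- nrow(Y)
  if (is.null(covariates)) {
    X <- matrix(1, n, 1)
  } else {
    C <- as.matrix(data.frame(lapply(covariates, function(col) {
      if (is.numeric(col)) col else as.numeric(as.factor(col))
    })))
    C <- scale(C, center = TRUE, scale = FALSE)
    if (any(apply(C, 2, stats::sd) == 0)) {
      stop("degenerate (constant) covariate", call. = FALSE)
    }
    X <- cbind(1, C)
  }
  if (n < ncol(X) + 2) {
    stop("need more subjects than model columns (at least ", ncol(X) + 2,
         ")", call. = FALSE)
  }
  fit <- fit_glm(Y, X)
  cv <- c(1, rep(0, ncol(X) - 1))
  map <- t_contrast(fit, cv)
  g <- contrast_maps[[1]]
  if (inherits(g, "stat_map")) {
    map$grid_dims <- g$grid_dims
    map$affine <- g$affine
  }
  map
}

#' Threshold a stat map and extract clusters
#'
#' Voxels pass when their one-sided p value is below `p_voxel`; connected
#' components (18-connectivity by default) smaller than `extent_k` voxels
#' are removed. The cluster table is sorted by peak t, descending.
#'
#' @param map A `stat_map` with grid metadata.
#' @param p_voxel One-sided voxel threshold (default 0.001).
#' @param extent_k Minimum cluster extent in voxels (default 10).
#' @param connectivity 6, 18 or 26.
#' @return List with `binary` (logical 3D array) and `clusters` (tibble:
#'   cluster, size, peak_t, peak x/y/z voxel indices (1-based) and mm
#'   coordinates).
#' @export
threshold_and_cluster <- function(map, p_voxel = 0.001, extent_k = 10,
                                  connectivity = 18) {
  stopifnot(!is.null(map$grid_dims))
  dims <- map$grid_dims
  p <- stats::pt(map$t, df = map$df, lower.tail = FALSE)
  pass <- array(!is.na(p) & p < p_voxel, dim = dims)
  lab <- label_components(pass, connectivity = connectivity)
  keep_ids <- which(tabulate(lab[lab > 0]) >= extent_k)
  binary <- array(lab %in% keep_ids & lab > 0, dim = dims)
  tvol <- array(map$t, dim = dims)
  clusters <- purrr::map(keep_ids, function(id) {
    vox <- which(lab == id)
    peak <- vox[which.max(tvol[vox])]
    ijk <- arrayInd(peak, dims)
    mm <- if (is.null(map$affine)) rep(NA_real_, 3)
    else drop(map$affine %*% c(ijk - 1L, 1))[1:3]
    tibble::tibble(size = length(vox), peak_t = tvol[peak],
                   x = ijk[1], y = ijk[2], z = ijk[3],
                   x_mm = mm[1], y_mm = mm[2], z_mm = mm[3])
  }) |> purrr::list_rbind()
  if (nrow(clusters) > 0) {
    clusters <- dplyr::arrange(clusters, dplyr::desc(.data$peak_t))
    clusters <- dplyr::mutate(clusters, cluster = dplyr::row_number(),
                              .before = 1)
  } else {
    clusters <- tibble::tibble(cluster = integer(), size = integer(),
                               peak_t = numeric(), x = integer(),
                               y = integer(), z = integer(), x_mm = numeric(),
                               y_mm = numeric(), z_mm = numeric())
  }
  list(binary = binary, clusters = clusters)
}

# connected-component labeling on a logical 3D array
label_components <- function(mask, connectivity = 18) {
  stopifnot(connectivity %in% c(6, 18, 26))
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(offs))
  offs <- offs[nz > 0 & nz <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  lab <- array(0L, dims)
  nextlab <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] > 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ijk <- arrayInd(cur, dims)
      nb <- sweep(offs, 2, as.integer(ijk), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] +
        (nb[, 3] - 1L) * dims[1] * dims[2]
      new <- lin[mask[lin] & lab[lin] == 0L]
      lab[new] <- nextlab
      queue <- c(queue, new)
    }
  }
  lab
}

#' Permutation-based cluster-mass family-wise error correction
#'
#' A nonparametric alternative to random-field cluster correction at the
#' group level: subject contrast maps are sign-flipped (exchangeable under
#' the null of no group effect), the one-sample t map is rebuilt for each
#' flip, and the maximal suprathreshold cluster mass (sum of t over a
#' cluster) forms the null distribution. Observed clusters whose mass
#' exceeds the `1 - alpha` quantile survive.
#'
#' @param contrast_maps List of per-subject `stat_map`s (or numeric
#'   vectors) on one grid.
#' @param grid_dims Grid dimensions (taken from the first `stat_map` when
#'   available).
#' @param p_voxel Cluster-forming one-sided voxel threshold.
#' @param alpha Family-wise error level.
#' @param n_perm Number of sign-flip permutations.
#' @param connectivity Cluster connectivity (18 by default).
#' @param seed Optional seed for the flips.
#' @return List: `binary` (surviving-voxel array), `clusters` (tibble with
#'   mass and corrected p), `null_mass` (permutation distribution).
#' @export
cluster_fwe_permutation <- function(contrast_maps, grid_dims = NULL,
                                    p_voxel = 0.001, alpha = 0.05,
                                    n_perm = 500, connectivity = 18,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(contrast_maps[[1]], "stat_map") && is.null(grid_dims)) {
    grid_dims <- contrast_maps[[1]]$grid_dims
  }
  stopifnot(!is.null(grid_dims))
  Y <- t(vapply(contrast_maps,
                function(m) if (inherits(m, "stat_map")) m$t else
                  as.numeric(m),
                numeric(prod(grid_dims))))
  n <- nrow(Y)
  df <- n - 1
  t_thr <- stats::qt(p_voxel, df = df, lower.tail = FALSE)
  one_sample_t <- function(M) {
    mu <- colMeans(M)
    se <- sqrt(apply(M, 2, stats::var) / n)
    mu / se
  }
  mass_of <- function(tv) {
    pass <- array(!is.na(tv) & tv > t_thr, grid_dims)
    if (!any(pass)) return(list(max = 0, lab = NULL, tv = tv))
    lab <- label_components(pass, connectivity)
    masses <- vapply(seq_len(max(lab)),
                     function(id) sum(tv[lab == id]), numeric(1))
    list(max = max(masses), lab = lab, masses = masses, tv = tv)
  }
  obs <- mass_of(one_sample_t(Y))
  null_mass <- vapply(seq_len(n_perm), function(b) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    mass_of(one_sample_t(Y * flips))$max
  }, numeric(1))
  crit <- stats::quantile(null_mass, 1 - alpha, names = FALSE)
  binary <- array(FALSE, grid_dims)
  clusters <- tibble::tibble(cluster = integer(), size = integer(),
                             mass = numeric(), p_fwe = numeric())
  if (!is.null(obs$lab)) {
    keep <- which(obs$masses > crit)
    for (id in seq_along(obs$masses)) {
      p_fwe <- (1 + sum(null_mass >= obs$masses[id])) / (1 + n_perm)
      clusters <- dplyr::bind_rows(clusters, tibble::tibble(
        cluster = id, size = sum(obs$lab == id),
        mass = obs$masses[id], p_fwe = p_fwe))
    }
    binary[obs$lab %in% keep] <- TRUE
    clusters <- dplyr::arrange(clusters, .data$p_fwe)
  }
  list(binary = binary, clusters = clusters, null_mass = null_mass)
}

#' Write a cluster table as tab-separated text
#' @param clusters Cluster tibble from [threshold_and_cluster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  readr::write_tsv(clusters, path)
  invisible(path)
}
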