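test_that("OLS closed forms hold: orthonormal designs and exact recovery", {
  set.seed(1)
  X <- qr.Q(qr(matrix(rnorm(60 * 4), 60, 4)))
  colnames(X) <- paste0("c", 1:4)
  Y <- matrix(rnorm(60 * 5), 60, 5)
  fit <- fit_glm(Y, X)
  expect_equal(fit$betas, crossprod(X, Y), tolerance = 1e-10)

  beta_true <- matrix(rnorm(4 * 5), 4, 5)
  fit2 <- fit_glm(X %*% beta_true, X)
  expect_equal(unname(fit2$betas), beta_true, tolerance = 1e-8)
  expect_lt(max(fit2$sigma2), 1e-16)

  expect_error(fit_glm(Y[1:30, ], X), "match")
  expect_error(fit_glm(Y, cbind(X, X[, 1])), "rank")
})

test_that("betas, sigma2 and t match a per-voxel lm() oracle", {
  set.seed(7)
  X <- cbind(1, matrix(rnorm(50 * 7), 50, 7))
  colnames(X) <- paste0("c", 0:7)
  Y <- matrix(rnorm(50 * 20), 50, 20)
  fit <- fit_glm(Y, X)
  cv <- c(0, 1, -1, rep(0, 5))
  tm <- t_contrast(fit, cv)
  for (v in c(1, 7, 20)) {
    ref <- lm(Y[, v] ~ X - 1)
    expect_equal(unname(fit$betas[, v]), unname(coef(ref)), tolerance = 1e-8)
    expect_equal(fit$sigma2[v], summary(ref)$sigma^2, tolerance = 1e-8)
    sm <- summary(ref)
    se <- sqrt(drop(t(cv) %*% vcov(ref) %*% cv))
    expect_equal(tm$t[v], drop(cv %*% coef(ref)) / se, tolerance = 1e-8)
  }
})

test_that("contrast maps negate exactly when the contrast flips", {
  set.seed(2)
  X <- cbind(1, matrix(rnorm(40 * 3), 40, 3))
  colnames(X) <- c("i", "C3-ME", "C4-ME", "m")
  Y <- matrix(rnorm(40 * 10), 40, 10)
  fit <- fit_glm(Y, X)
  a <- t_contrast(fit, contrast_vector(fit, plus = "C4-ME", minus = "C3-ME"))
  b <- t_contrast(fit, contrast_vector(fit, plus = "C3-ME", minus = "C4-ME"))
  expect_equal(a$t, -b$t, tolerance = 1e-12)

  # single-column contrast equals the hand formula
  cv <- contrast_vector(fit, plus = "C4-ME")
  tm <- t_contrast(fit, cv)
  xtx_inv <- solve(crossprod(X))
  hand <- fit$betas["C4-ME", ] /
    sqrt(fit$sigma2 * xtx_inv["C4-ME", "C4-ME"])
  expect_equal(tm$t, unname(hand), tolerance = 1e-10)

  # zero-variance voxel (exact linear combination of the design) yields an
  # invalid (NA) t rather than a huge finite one
  Yc <- cbind(Y, X %*% c(1, 2, 0, 0))
  fitc <- fit_glm(Yc, X)
  expect_true(is.na(t_contrast(fitc, cv)$t[11]))
})

test_that("a planted coupled voxel is detected in most seeds", {
  # weight -0.5 coupling to the C3-ME alpha regressor, AR(1) noise,
  # 400 volumes; detection via the lateralized contrast
  set.seed(99)
  p <- generate_paradigm(1, 5, run_length_s = 800, seed = 42)
  fs <- 100
  rec <- simulate_eeg(p, sampling_rate_hz = fs, seed = 42)
  pw <- continuous_band_power(rec)
  reg <- eeg_regressor_set(pw, p)
  X <- assemble_design(reg)$X
  n_vol <- nrow(X)
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    innov <- rnorm(n_vol, sd = 100 * sqrt(1 - 0.3^2))
    noise <- as.numeric(stats::filter(innov, 0.3, method = "recursive"))
    y <- cbind(-0.5 * X[, "C3-ME"] + noise)
    fit <- fit_glm(y, X)
    tm <- t_contrast(fit, contrast_vector(fit, plus = "C4-ME",
                                          minus = "C3-ME"))
    abs(tm$t[1]) > 3.1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("block designs give boxcars with HRF lag and disjoint support", {
  p <- tiny_paradigm(seed = 12)
  d <- block_design(p, highpass_cutoff_s = Inf)
  b <- dplyr::filter(p$blocks, condition == "ME_RH")
  col <- d$X[, "ME_RH"]
  peak_t <- (which.max(col) - 1) * 2
  # dense-grid oracle: direct convolution of the boxcar with the HRF
  dt <- 0.01
  tt <- seq(0, p$run_length_s - dt, by = dt)
  box <- as.numeric(tt >= b$onset[1] & tt < b$onset[1] + 22)
  h <- canonical_hrf(dt)
  dense <- convolve(box, rev(h), type = "open")[seq_along(tt)]
  oracle_peak <- tt[which.max(dense)]
  expect_lte(abs(peak_t - oracle_peak), 3)
  # and the hemodynamic peak lags the block onset
  expect_gte(peak_t - b$onset[1], 4)

  # raw boxcars are disjoint: rebuild at fine rate and check inner product
  fs <- 10
  box <- function(cond) {
    bb <- dplyr::filter(p$blocks, condition == cond)
    v <- rep(0, p$run_length_s * fs)
    for (i in seq_len(nrow(bb))) {
      v[(bb$onset[i] * fs + 1):((bb$onset[i] + bb$duration[i]) * fs)] <- 1
    }
    v
  }
  expect_equal(sum(box("ME_RH") * box("ME_LH")), 0)

  # planted right-hand activation appears with a positive t
  set.seed(5)
  resp <- d$X[, "ME_RH"]
  Y <- cbind(2 * resp + rnorm(length(resp), sd = 0.5))
  fit <- fit_glm(Y, block_design(p))
  tm <- t_contrast(fit, contrast_vector(fit, plus = "ME_RH",
                                        minus = "ME_LH"))
  expect_gt(tm$t[1], 3)
})

test_that("second-level model adjusts for covariates correctly", {
  set.seed(11)
  n_sub <- 12
  maps <- lapply(1:n_sub, function(i) rnorm(30, mean = 1))
  covs <- data.frame(age = rnorm(n_sub, 25, 2),
                     sex = sample(c("F", "M"), n_sub, TRUE),
                     handedness = rnorm(n_sub))
  m <- second_level(maps, covs)
  expect_equal(m$df, n_sub - 4)

  # identical maps: zero residual variance -> flagged invalid
  same <- lapply(1:n_sub, function(i) rep(2, 5))
  expect_true(all(is.na(second_level(same)$t)))

  # covariate orthogonal to the effect: t equals the plain one-sample t
  cov_orth <- data.frame(x = scale(seq_len(n_sub), scale = FALSE))
  Yv <- vapply(maps, identity, numeric(30))
  m2 <- second_level(maps, cov_orth)
  # oracle: the intercept t of a per-voxel lm with the centered covariate
  for (v in c(1, 30)) {
    ref <- lm(t(Yv)[, v] ~ cov_orth$x)
    expect_equal(m2$t[v], summary(ref)$coefficients[1, "t value"],
                 tolerance = 1e-8)
  }

  expect_error(second_level(maps, data.frame(k = rep(1, n_sub))),
               "degenerate")
  expect_error(second_level(maps[1:2]), "more subjects")
})

test_that("group mean recovery at d = 1 over repeated small cohorts", {
  means <- vapply(1:100, function(s) {
    set.seed(s)
    maps <- lapply(1:10, function(i) rnorm(5, mean = 1))
    Y <- t(vapply(maps, identity, numeric(5)))
    mean(colMeans(Y))
  }, numeric(1))
  expect_lt(abs(mean(means) - 1), 0.2)
})

test_that("thresholding and clustering follow the extent and connectivity rules", {
  dims <- c(8, 8, 4)
  tvol <- array(0, dims)
  m0 <- stat_map(tvol, df = 100)
  out0 <- threshold_and_cluster(m0, extent_k = 1)
  expect_equal(sum(out0$binary), 0)
  expect_equal(nrow(out0$clusters), 0)

  # a 4-voxel blob survives k = 4 but not k = 5
  tvol[2:5, 3, 2] <- 10
  m <- stat_map(tvol, df = 100)
  expect_equal(sum(threshold_and_cluster(m, extent_k = 4)$binary), 4)
  expect_equal(sum(threshold_and_cluster(m, extent_k = 5)$binary), 0)

  # edge-touching blobs merge under 18- but not 6-connectivity
  tvol2 <- array(0, dims)
  tvol2[2:3, 2:3, 2] <- 8          # blob A
  tvol2[4, 4, 2] <- 8              # touches (3,3,2) by an edge
  m2 <- stat_map(tvol2, df = 100)
  c18 <- threshold_and_cluster(m2, extent_k = 1, connectivity = 18)
  c6 <- threshold_and_cluster(m2, extent_k = 1, connectivity = 6)
  expect_equal(nrow(c18$clusters), 1)
  expect_equal(nrow(c6$clusters), 2)

  # table is sorted by peak t
  tvol3 <- array(0, dims)
  tvol3[1:2, 1, 1] <- 5
  tvol3[6:7, 6, 3] <- 9
  m3 <- stat_map(tvol3, df = 100,
                 affine = diag(c(2, 2, 2, 1)))
  tab <- threshold_and_cluster(m3, extent_k = 1)$clusters
  expect_equal(tab$peak_t, c(9, 5))
  expect_equal(tab$x_mm[1], (6 - 1) * 2)
})

test_that("concatenating two identical-truth scans shrinks the standard error by sqrt(2)", {
  set.seed(21)
  reg <- matrix(rnorm(200 * 2), 200, 2,
                dimnames = list(NULL, c("C3-ME", "C4-ME")))
  ratio <- vapply(1:30, function(s) {
    set.seed(s)
    se_of <- function(n_scans) {
      d <- assemble_design(rep(list(reg), n_scans))
      y <- matrix(rnorm(200 * n_scans), ncol = 1)
      fit <- fit_glm(y, d)
      cv <- contrast_vector(fit, plus = "C4-ME", minus = "C3-ME")
      cvfull <- setNames(rep(0, length(fit$labels)), fit$labels)
      cvfull[names(cv)] <- cv
      sqrt(fit$sigma2 * drop(t(cvfull) %*% fit$xtx_inv %*% cvfull))
    }
    se_of(1) / se_of(2)
  }, numeric(1))
  expect_lt(abs(mean(ratio) - sqrt(2)), 0.1 * sqrt(2))
})

test_that("permutation cluster FWE separates real effects from noise", {
  set.seed(55)
  dims <- c(8, 8, 4)
  effect <- array(0, dims)
  effect[3:5, 3:5, 2:3] <- 1.5
  maps <- lapply(1:12, function(i) {
    stat_map(array(rnorm(prod(dims), sd = 1), dims) + effect, df = 100)
  })
  out <- cluster_fwe_permutation(maps, p_voxel = 0.01, n_perm = 200,
                                 seed = 9)
  expect_true(any(out$binary[3:5, 3:5, 2:3]))
  # surviving voxels are mostly inside the planted region
  expect_gte(sum(out$binary & effect > 0) / max(sum(out$binary), 1), 0.8)
  expect_true(all(out$clusters$p_fwe >= 1 / 201))

  # pure noise rarely survives
  null_maps <- lapply(1:12, function(i) {
    stat_map(array(rnorm(prod(dims)), dims), df = 100)
  })
  out0 <- cluster_fwe_permutation(null_maps, p_voxel = 0.01, n_perm = 200,
                                  seed = 10)
  expect_lte(sum(out0$binary), 10)
})

test_that("AR(1) prewhitening reduces t inflation under autocorrelated noise", {
  # inflation requires a temporally smooth regressor; use an AR(0.9) one
  set.seed(66)
  n <- 300
  x_smooth <- as.numeric(stats::filter(rnorm(n), 0.9, method = "recursive"))
  X <- cbind(1, x_smooth)
  colnames(X) <- c("i", "x")
  rates <- vapply(c(FALSE, TRUE), function(pw) {
    exceed <- vapply(1:200, function(s) {
      set.seed(s)
      e <- as.numeric(stats::filter(rnorm(n), 0.5, method = "recursive"))
      fit <- fit_glm(cbind(e), X, prewhiten = pw)
      tm <- t_contrast(fit, c(0, 1))
      abs(tm$t) > qt(0.975, fit$df)
    }, logical(1))
    mean(exceed)
  }, numeric(1))
  expect_gt(rates[1], 0.09)      # OLS inflated under phi = 0.5
  expect_lt(rates[2], rates[1])  # prewhitening reduces the inflation
  expect_lt(rates[2], 0.09)
})
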