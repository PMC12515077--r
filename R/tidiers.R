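#' @exportS3Method generics::tidy
tidy.stat_map <- function(x, ...) {
  if (is.null(x$grid_dims)) {
    return(tibble::tibble(voxel = seq_along(x$t), t = x$t))
  }
  tvals <- x$t
  ijk <- arrayInd(seq_along(tvals), x$grid_dims)
  tibble::tibble(voxel = seq_along(tvals), x = ijk[, 1], y = ijk[, 2],
                 z = ijk[, 3], t = tvals)
}

#' @exportS3Method generics::glance
glance.stat_map <- function(x, ...) {
  tibble::tibble(n_voxels = length(x$t), df = x$df,
                 t_max = max(x$t, na.rm = TRUE),
                 t_min = min(x$t, na.rm = TRUE))
}

#' @exportS3Method generics::tidy
tidy.glm_fit <- function(x, ...) {
  tibble::tibble(
    term = rep(x$labels, times = ncol(x$betas)),
    voxel = rep(seq_len(ncol(x$betas)), each = length(x$labels)),
    estimate = as.vector(x$betas))
}

#' @exportS3Method generics::glance
glance.glm_fit <- function(x, ...) {
  tibble::tibble(n_terms = length(x$labels), n_voxels = length(x$sigma2),
                 df = x$df, mean_sigma2 = mean(x$sigma2))
}

#' @exportS3Method generics::tidy
tidy.erd_bold_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "erd_percent"),
                 estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.erd_bold_fit <- function(x, ...) {
  tibble::tibble(r = x$r, p_value = x$p_value, n = x$n,
                 slope = x$slope, intercept = x$intercept)
}

#' @exportS3Method generics::tidy
tidy.paradigm <- function(x, ...) {
  dplyr::mutate(x$blocks, .keep = "all")
}
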