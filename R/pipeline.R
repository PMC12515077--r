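#' Simulate one synthetic subject (paradigm, EEG, BOLD, motion)
#'
#' One run per subject: randomized paradigm, two-channel EEG with planted
#' contralateral alpha desynchronization, continuous alpha-band power, and
#' a BOLD run with planted neurovascular coupling. Trial rejection and
#' bad-trial imputation of the continuous power are applied so the returned
#' power series are ready for regressor construction.
#'
#' @param seed Integer seed for this subject (derive per-subject seeds as
#'   master seed + subject index).
#' @param blocks_per_condition Task blocks per condition.
#' @param run_length_s Optional run length (padded with trailing rest).
#' @param truth A [ground_truth()].
#' @param erd_percent,alpha_hz,sampling_rate_hz,noise_sd_uv,ipsilateral_fraction
#'   Passed to [simulate_eeg()].
#' @param band_hz Alpha band for the continuous power.
#' @return List: paradigm, rec, trials, power (imputed), bold, motion.
#' @export
simulate_subject <- function(seed, blocks_per_condition = 5,
                             run_length_s = 800, truth = ground_truth(),
                             erd_percent = c(ME_LH = -25, ME_RH = -25,
                                             MI_LH = -18.58, MI_RH = -16.18),
                             alpha_hz = 10, sampling_rate_hz = 250,
                             noise_sd_uv = 2, ipsilateral_fraction = 0.4,
                             band_hz = c(8, 13.5)) {
  paradigm <- generate_paradigm(n_runs = 1,
                                blocks_per_condition = blocks_per_condition,
                                run_length_s = run_length_s, seed = seed)
  rec <- simulate_eeg(paradigm, erd_percent = erd_percent,
                      alpha_hz = alpha_hz,
                      sampling_rate_hz = sampling_rate_hz,
                      noise_sd_uv = noise_sd_uv,
                      ipsilateral_fraction = ipsilateral_fraction,
                      seed = seed + 10000L)
  trials <- reject_bad_trials(segment_trials(rec, paradigm))
  power <- continuous_band_power(rec, band_hz = band_hz)
  power <- purrr::map(power, impute_bad_trials, trials = trials)
  sim <- simulate_bold(paradigm, power, truth = truth,
                       seed = seed + 20000L)
  list(paradigm = paradigm, rec = rec, trials = trials, power = power,
       bold = sim$bold, motion = sim$motion)
}

#' Fixed-effects EEG-informed group GLM
#'
#' Builds the six alpha-power regressors per subject, assembles the
#' fixed-effects design (shared EEG columns, per-scan motion and
#' intercepts) and fits the concatenated mass-univariate GLM.
#'
#' @param subjects List of [simulate_subject()] outputs (or lists with
#'   `power`, `paradigm`, `bold`, `motion`).
#' @param prewhiten Passed to [fit_glm()].
#' @return A `glm_fit` carrying the grid metadata of the first subject.
#' @export
eeg_informed_fit <- function(subjects, prewhiten = FALSE) {
  regs <- purrr::map(subjects,
                     function(s) eeg_regressor_set(s$power, s$paradigm))
  design <- assemble_design(regs, motion = purrr::map(subjects,
                                                      ~ as.matrix(.x$motion)))
  Y <- do.call(rbind, purrr::map(subjects, ~ bold_matrix(.x$bold)))
  fit_glm(Y, design, prewhiten = prewhiten,
          grid_dims = subjects[[1]]$bold$grid_dims,
          affine = subjects[[1]]$bold$affine)
}

#' Fixed-effects block-design group GLM
#'
#' Conventional boxcar analysis over the same scans: per-condition
#' HRF-convolved block regressors as shared columns, per-scan motion and
#' intercepts.
#'
#' @inheritParams eeg_informed_fit
#' @return A `glm_fit`.
#' @export
block_group_fit <- function(subjects, prewhiten = FALSE) {
  regs <- purrr::map(subjects, function(s) {
    d <- block_design(s$paradigm)
    d$X[, c("ME_LH", "ME_RH", "MI_LH", "MI_RH"), drop = FALSE]
  })
  design <- assemble_design(regs, motion = purrr::map(subjects,
                                                      ~ as.matrix(.x$motion)))
  Y <- do.call(rbind, purrr::map(subjects, ~ bold_matrix(.x$bold)))
  fit_glm(Y, design, prewhiten = prewhiten,
          grid_dims = subjects[[1]]$bold$grid_dims,
          affine = subjects[[1]]$bold$affine)
}

#' Simulate a cross-modal coupling cohort
#'
#' Generates subjects whose neurovascular coupling strength varies: a
#' per-subject factor scales both the planted contralateral imagery ERD
#' depth and the BOLD coupling weight, emulating between-subject
#' differences in sensorimotor engagement. Each subject contributes one
#' coupling sample for one imagery task (alternating right/left hand): the
#' measured contralateral high-alpha trial ERD paired with the ROI-mean t
#' of that task's first-level block response, tested in its modeled
#' (negative-going) direction. Deeper alpha desynchronization therefore
#' accompanies a stronger task-locked hemodynamic response, and the
#' cohort-level Pearson r is negative. Small grids and short runs keep a
#' cohort cheap enough for Monte-Carlo use.
#'
#' @param n_subjects Number of coupling samples (one task per subject).
#' @param seed Master seed; per-subject seeds are `seed * 1000 + subject`.
#' @param erd_base Contralateral imagery ERD (percent) at coupling factor 1.
#' @param weight_base BOLD coupling weight at coupling factor 1.
#' @param high_alpha_hz Band for the ERD samples (10.5-13.5 Hz).
#' @return Tibble of coupling samples (subject, task, erd_percent,
#'   roi_mean_t).
#' @export
simulate_coupling_cohort <- function(n_subjects = 17, seed = 1,
                                     erd_base = -40, weight_base = -0.5,
                                     high_alpha_hz = c(10.5, 13.5)) {
  grid <- c(8, 8, 4)
  masks <- list(
    "C3-MI" = array(FALSE, grid), "C4-MI" = array(FALSE, grid))
  masks[["C3-MI"]][2:4, 3:6, 2:3] <- TRUE
  masks[["C4-MI"]][5:7, 3:6, 2:3] <- TRUE
  set.seed(seed)
  factors <- stats::runif(n_subjects, 0.2, 1)
  purrr::map(seq_len(n_subjects), function(i) {
    task <- if (i %% 2 == 1) "MI_RH" else "MI_LH"
    a <- factors[i]
    truth <- ground_truth(
      grid_dims = grid, coupled_masks = masks,
      coupling_weight = c("C3-MI" = weight_base * a,
                          "C4-MI" = weight_base * a),
      noise_sd = 150, drift_amp = 150)
    erd <- erd_base * a
    sub <- simulate_subject(
      seed = seed * 1000L + i, blocks_per_condition = 1,
      run_length_s = NULL, truth = truth,
      erd_percent = c(ME_LH = -10, ME_RH = -10, MI_LH = erd, MI_RH = erd),
      sampling_rate_hz = 100, noise_sd_uv = 1)
    # measured contralateral high-alpha ERD for this subject's task
    contra <- if (task == "MI_RH") "C3" else "C4"
    tab <- erd_summary(sub$trials,
                       freqs = seq(high_alpha_hz[1], high_alpha_hz[2], 0.5),
                       band_hz = high_alpha_hz)
    erd_meas <- tab |>
      dplyr::filter(.data$good, .data$condition == task,
                    .data$channel == contra) |>
      dplyr::summarise(m = mean(.data$erd_percent)) |>
      dplyr::pull("m")
    # first-level task response (its modeled direction) in the
    # contralateral sensorimotor ROI
    fit <- fit_glm(sub$bold, block_design(sub$paradigm,
                                          motion = sub$motion))
    cv <- contrast_vector(fit, weights = stats::setNames(-1, task))
    roi <- if (task == "MI_RH") masks[["C3-MI"]] else masks[["C4-MI"]]
    t_roi <- suppressMessages(roi_mean_t(t_contrast(fit, cv), roi))
    tibble::tibble(subject = i, task = task, erd_percent = erd_meas,
                   roi_mean_t = t_roi)
  }) |> purrr::list_rbind()
}

#' Default pipeline configuration
#'
#' Collects every tunable the pipeline uses, with the package defaults:
#' alpha band 8-13.5 Hz, high-alpha 10.5-13.5 Hz, TR 2 s, 128 s high-pass,
#' voxel p threshold 0.001, cluster extent 10, 15 % precision screen.
#'
#' @param ... Overrides for any default field.
#' @return A named list (class `pipeline_config`).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_subjects = 3, blocks_per_condition = 2, run_length_s = NULL,
    alpha_band_hz = c(8, 13.5), high_alpha_band_hz = c(10.5, 13.5),
    tr_s = 2, highpass_s = 128, p_voxel = 0.001, extent_k = 10,
    precision_screen_percent = 15, sd_threshold_uv = 100,
    sampling_rate_hz = 250, seed = 1, prewhiten = FALSE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config field(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic EEG-informed fMRI pipeline
#'
#' Simulates a cohort, fits both the EEG-informed and the conventional
#' block-design fixed-effects GLMs, thresholds the four lateralized
#' contrasts of each, quantifies their overlap, and runs the cross-modal
#' ERD-vs-BOLD regression. When `out_dir` is given, maps (NIfTI), events,
#' motion, design matrices, cluster tables, overlap reports and a log of
#' the configuration are written there.
#'
#' @param config A [pipeline_config()].
#' @param truth A [ground_truth()] shared by the cohort.
#' @param out_dir Optional output directory.
#' @return List: `subjects`, `eeg_fit`, `block_fit`, `eeg_maps`,
#'   `block_maps` (thresholded binaries + cluster tables), `overlap`
#'   (tibble per contrast pair), `crossmodal` (an `erd_bold_fit` or `NULL`).
#' @export
run_pipeline <- function(config = pipeline_config(), truth = ground_truth(),
                         out_dir = NULL) {
  subjects <- purrr::map(seq_len(config$n_subjects), function(i) {
    simulate_subject(seed = config$seed + i,
                     blocks_per_condition = config$blocks_per_condition,
                     run_length_s = config$run_length_s, truth = truth,
                     sampling_rate_hz = config$sampling_rate_hz,
                     band_hz = config$alpha_band_hz)
  })

  eeg_fit <- eeg_informed_fit(subjects, prewhiten = config$prewhiten)
  block_fit <- block_group_fit(subjects, prewhiten = config$prewhiten)

  contrast_pairs <- tibble::tribble(
    ~eeg, ~block_plus, ~block_minus,
    "C3<C4-ME", "ME_RH", "ME_LH",
    "C4<C3-ME", "ME_LH", "ME_RH",
    "C3<C4-MI", "MI_RH", "MI_LH",
    "C4<C3-MI", "MI_LH", "MI_RH")

  eeg_maps <- list()
  block_maps <- list()
  reports <- list()
  for (i in seq_len(nrow(contrast_pairs))) {
    nm <- contrast_pairs$eeg[i]
    em <- lateral_contrast(eeg_fit, nm)
    bm <- t_contrast(block_fit, contrast_vector(
      block_fit, plus = contrast_pairs$block_plus[i],
      minus = contrast_pairs$block_minus[i]))
    eeg_maps[[nm]] <- c(list(map = em),
                        threshold_and_cluster(em, config$p_voxel,
                                              config$extent_k))
    block_maps[[nm]] <- c(list(map = bm),
                          threshold_and_cluster(bm, config$p_voxel,
                                                config$extent_k))
    rep <- overlap(eeg_maps[[nm]]$binary, block_maps[[nm]]$binary)
    rep$contrast <- nm
    reports[[nm]] <- rep
  }
  overlap_tbl <- purrr::list_rbind(reports)

  # cross-modal: per-subject first-level imagery contrasts vs trial ERD
  samples <- purrr::imap(subjects, function(s, i) {
    fit <- fit_glm(s$bold, block_design(s$paradigm, motion = s$motion))
    tab <- erd_summary(
      s$trials, freqs = seq(config$high_alpha_band_hz[1],
                            config$high_alpha_band_hz[2], 0.5),
      band_hz = config$high_alpha_band_hz)
    purrr::map(c("MI_RH", "MI_LH"), function(task) {
      contra <- if (task == "MI_RH") "C3" else "C4"
      roi_name <- if (task == "MI_RH") "C3-MI" else "C4-MI"
      if (!roi_name %in% names(truth$coupled_masks)) return(NULL)
      cv <- contrast_vector(fit, plus = task,
                            minus = setdiff(c("MI_RH", "MI_LH"), task))
      tv <- suppressMessages(
        roi_mean_t(t_contrast(fit, cv), truth$coupled_masks[[roi_name]],
                   p_voxel = config$p_voxel))
      erd <- tab |>
        dplyr::filter(.data$good, .data$condition == task,
                      .data$channel == contra) |>
        dplyr::summarise(m = mean(.data$erd_percent)) |>
        dplyr::pull("m")
      tibble::tibble(subject = i, task = task, erd_percent = erd,
                     roi_mean_t = tv)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  crossmodal <- tryCatch(erd_bold_regression(samples), error = function(e) NULL)

  result <- list(subjects = subjects, eeg_fit = eeg_fit,
                 block_fit = block_fit, eeg_maps = eeg_maps,
                 block_maps = block_maps, overlap = overlap_tbl,
                 crossmodal = crossmodal, samples = samples,
                 config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(eeg_maps)) {
      safe <- gsub("[<>]", "_", nm)
      write_nifti(array(eeg_maps[[nm]]$map$t, truth$grid_dims),
                  file.path(out_dir, paste0("eeg_", safe, "_t.nii.gz")),
                  affine = subjects[[1]]$bold$affine)
      write_nifti(array(as.numeric(eeg_maps[[nm]]$binary), truth$grid_dims),
                  file.path(out_dir, paste0("eeg_", safe, "_bin.nii.gz")),
                  affine = subjects[[1]]$bold$affine)
      write_nifti(array(block_maps[[nm]]$map$t, truth$grid_dims),
                  file.path(out_dir, paste0("block_", safe, "_t.nii.gz")),
                  affine = subjects[[1]]$bold$affine)
      write_clusters(eeg_maps[[nm]]$clusters,
                     file.path(out_dir, paste0("eeg_", safe, "_clusters.tsv")))
    }
    readr::write_tsv(overlap_tbl, file.path(out_dir, "overlap.tsv"))
    readr::write_tsv(samples, file.path(out_dir, "crossmodal_samples.tsv"))
    for (i in seq_along(subjects)) {
      write_events(subjects[[i]]$paradigm,
                   file.path(out_dir, sprintf("sub-%02d_events.tsv", i)))
      write_motion(subjects[[i]]$motion,
                   file.path(out_dir, sprintf("sub-%02d_motion.txt", i)))
    }
    cfg_lines <- vapply(names(unclass(config)), function(k) {
      paste0(k, ": ", paste(config[[k]], collapse = " "))
    }, character(1))
    chars <- utf8ToInt(paste(cfg_lines, collapse = "|"))
    hash <- sprintf("%08x", sum(chars * seq_along(chars)) %% 2^31)
    writeLines(c(paste0("config_hash: ", hash),
                 paste0("seed: ", config$seed), cfg_lines),
               file.path(out_dir, "pipeline_log.txt"))
  }
  result
}
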