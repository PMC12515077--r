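# shared fixtures, built in code

tiny_paradigm <- function(seed = 1, bpc = 1) {
  generate_paradigm(n_runs = 1, blocks_per_condition = bpc, seed = seed)
}

# a hand-built trial_set with one trial, one channel
manual_trial_set <- function(samples, sfreq = 250, condition = "ME_RH") {
  structure(list(
    epochs = array(samples, dim = c(1, 1, length(samples))),
    meta = tibble::tibble(trial = 1L, run = 1L, condition = condition,
                          onset = 10, duration = 3, good = TRUE),
    channel_names = "C3", sfreq_hz = sfreq, pre_s = 2, post_s = 1),
    class = "trial_set")
}

# small ground truth for fast BOLD tests
tiny_truth <- function(coupling_weight = c("C3-ME" = -0.5, "C4-ME" = -0.5),
                       ...) {
  grid <- c(6, 6, 4)
  masks <- list("C3-ME" = array(FALSE, grid), "C4-ME" = array(FALSE, grid))
  masks[["C3-ME"]][2:3, 2:4, 2:3] <- TRUE
  masks[["C4-ME"]][4:5, 2:4, 2:3] <- TRUE
  ground_truth(grid_dims = grid, coupled_masks = masks,
               coupling_weight = coupling_weight, ...)
}

# constant-amplitude power series covering a paradigm run
flat_power <- function(paradigm, value = 1, sfreq = 250, electrode = "C3") {
  n <- round(paradigm$run_length_s * sfreq)
  power_series(rep(value, n), sfreq, electrode)
}
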