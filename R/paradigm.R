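#' Generate a randomized block/trial motor paradigm
#'
#' Builds the alternating task/rest block structure used throughout the
#' package: each task block lasts 22 s (2 s written instruction, then four
#' 3 s trials each followed by a 2 s inter-trial interval) and each rest
#' block lasts 16 s. Task blocks draw on four conditions (left/right hand
#' motor execution `ME_LH`/`ME_RH` and motor imagery `MI_LH`/`MI_RH`); the
#' block order is randomized per run under the constraint that execution
#' blocks for a hand always precede the imagery blocks for the same hand.
#' Runs start and end with a rest block, and a trailing rest pad rounds the
#' run length up to a multiple of the TR (or up to `run_length_s` if given).
#'
#' @param n_runs Number of runs to generate.
#' @param blocks_per_condition Task blocks per condition per run.
#' @param tr_s fMRI repetition time in seconds (default 2).
#' @param run_length_s Optional target run length in seconds; the trailing
#'   rest block is extended to reach it. Must be a multiple of `tr_s` and at
#'   least the natural run length.
#' @param seed Optional integer seed for the block randomization.
#'
#' @return A `paradigm` object: a list with tibbles `blocks` (run, onset,
#'   duration, condition, type), `trials` and `instructions`, plus
#'   `run_length_s`, `tr_s`, `n_runs`.
#' @examples
#' p <- generate_paradigm(n_runs = 1, blocks_per_condition = 2, seed = 1)
#' dplyr::count(p$blocks, condition)
#' @export
generate_paradigm <- function(n_runs = 1, blocks_per_condition = 2, tr_s = 2,
                              run_length_s = NULL, seed = NULL) {
  if (n_runs < 1 || blocks_per_condition < 1) {
    stop("`n_runs` and `blocks_per_condition` must be >= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  task_conditions <- c("ME_LH", "ME_RH", "MI_LH", "MI_RH")
  task_dur <- 22
  rest_dur <- 16

  runs <- purrr::map(seq_len(n_runs), function(run) {
    seq_cond <- sample(rep(task_conditions, blocks_per_condition))
    # execution precedes imagery for the same hand: within each hand's slots,
    # place the ME blocks first
    for (hand in c("LH", "RH")) {
      idx <- which(seq_cond %in% paste0(c("ME_", "MI_"), hand))
      seq_cond[idx] <- rep(paste0(c("ME_", "MI_"), hand),
                           each = blocks_per_condition)
    }
    n_task <- length(seq_cond)

    onset <- 0
    blocks <- vector("list", 2 * n_task + 1)
    k <- 0
    for (i in seq_len(n_task)) {
      k <- k + 1
      blocks[[k]] <- tibble::tibble(onset = onset, duration = rest_dur,
                                    condition = "REST", type = "rest")
      onset <- onset + rest_dur
      k <- k + 1
      blocks[[k]] <- tibble::tibble(onset = onset, duration = task_dur,
                                    condition = seq_cond[i], type = "task")
      onset <- onset + task_dur
    }
    blocks[[2 * n_task + 1]] <- tibble::tibble(
      onset = onset, duration = rest_dur, condition = "REST", type = "rest")
    onset <- onset + rest_dur

    blocks <- dplyr::bind_rows(blocks)
    natural_len <- onset
    len <- ceiling(natural_len / tr_s) * tr_s
    if (!is.null(run_length_s)) {
      if (run_length_s < len) {
        stop("`run_length_s` shorter than the natural run length (",
             natural_len, " s)", call. = FALSE)
      }
      if (abs(run_length_s / tr_s - round(run_length_s / tr_s)) > 1e-9) {
        stop("`run_length_s` must be a multiple of `tr_s`", call. = FALSE)
      }
      len <- run_length_s
    }
    # trailing rest absorbs the pad
    pad <- len - natural_len
    blocks$duration[nrow(blocks)] <- blocks$duration[nrow(blocks)] + pad

    task_blocks <- dplyr::filter(blocks, .data$type == "task")
    instructions <- tibble::tibble(
      onset = task_blocks$onset, duration = 2,
      condition = task_blocks$condition)
    trials <- tidyr::expand_grid(
      block_onset = task_blocks$onset,
      slot = 0:3
    ) |>
      dplyr::mutate(
        onset = .data$block_onset + 2 + .data$slot * 5,
        duration = 3,
        condition = rep(task_blocks$condition, each = 4)
      ) |>
      dplyr::select("onset", "duration", "condition")

    list(blocks = dplyr::mutate(blocks, run = run, .before = 1),
         trials = dplyr::mutate(trials, run = run, .before = 1),
         instructions = dplyr::mutate(instructions, run = run, .before = 1),
         run_length_s = len)
  })

  lens <- purrr::map_dbl(runs, "run_length_s")
  if (length(unique(lens)) > 1) {
    # equalize: pad every run's final rest to the longest run
    target <- max(lens)
    runs <- purrr::map(runs, function(r) {
      pad <- target - r$run_length_s
      r$blocks$duration[nrow(r$blocks)] <- r$blocks$duration[nrow(r$blocks)] + pad
      r$run_length_s <- target
      r
    })
    lens <- rep(target, n_runs)
  }

  structure(
    list(
      blocks = purrr::list_rbind(purrr::map(runs, "blocks")),
      trials = purrr::list_rbind(purrr::map(runs, "trials")),
      instructions = purrr::list_rbind(purrr::map(runs, "instructions")),
      run_length_s = lens[1],
      tr_s = tr_s,
      n_runs = n_runs
    ),
    class = "paradigm"
  )
}

#' @export
print.paradigm <- function(x, ...) {
  cat("<paradigm> ", x$n_runs, " run(s) of ", x$run_length_s, " s (TR ",
      x$tr_s, " s, ", x$run_length_s / x$tr_s, " volumes/run)\n", sep = "")
  cat("  task blocks per run:\n")
  print(dplyr::count(dplyr::filter(x$blocks, .data$type == "task",
                                   .data$run == 1), .data$condition))
  invisible(x)
}

#' Number of volumes per run implied by a paradigm
#' @param paradigm A `paradigm` object.
#' @return Integer volume count per run.
#' @export
n_volumes <- function(paradigm) {
  as.integer(round(paradigm$run_length_s / paradigm$tr_s))
}

#' Convert a paradigm to a BIDS-style events table
#'
#' @param paradigm A `paradigm` object.
#' @param run Run to extract.
#' @param what `"trials"` (default) or `"blocks"`.
#' @return A tibble with `onset`, `duration`, `trial_type` (seconds, 0-based
#'   from run start).
#' @export
as_events <- function(paradigm, run = 1, what = c("trials", "blocks")) {
  what <- match.arg(what)
  src <- dplyr::filter(paradigm[[what]], .data$run == !!run)
  tibble::tibble(onset = src$onset, duration = src$duration,
                 trial_type = src$condition)
}

#' Write a BIDS-style events.tsv
#' @param paradigm A `paradigm` object.
#' @param path Output path.
#' @param run Run to write.
#' @return `path`, invisibly.
#' @export
write_events <- function(paradigm, path, run = 1) {
  readr::write_tsv(as_events(paradigm, run = run), path)
  invisible(path)
}

# intervals (onset, end) of one masked condition group, one run.
# condition_group in {"ME", "MI", "REST"}; block-wide (instruction + ITIs).
condition_intervals <- function(paradigm, condition_group, run = 1) {
  stopifnot(condition_group %in% c("ME", "MI", "REST"))
  b <- dplyr::filter(paradigm$blocks, .data$run == !!run)
  keep <- if (condition_group == "REST") {
    b$condition == "REST"
  } else {
    startsWith(b$condition, condition_group)
  }
  b <- b[keep, ]
  tibble::tibble(onset = b$onset, end = b$onset + b$duration)
}
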