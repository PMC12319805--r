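# Block paradigms for the three task conditions.

#' Build a block-design task paradigm
#'
#' Active and passive conditions use 12 task blocks of 15 s alternating with
#' 13 rest periods of 15 s (rest first), 375 s in total. The tendon-vibration
#' condition uses 18 blocks of 10 s alternating strictly between agonist and
#' antagonist tendons, separated by rests jittered uniformly between 10 and
#' 15 s (drawn with `seed`).
#'
#' @param condition One of `"active"`, `"passive"`, `"vibration"`.
#' @param tr Repetition time in seconds (default 2.5).
#' @param seed Integer seed for the vibration jitter; ignored otherwise.
#' @param pad_volumes Extra volumes appended beyond the paradigm-derived
#'   count (some acquisitions record a few trailing volumes; the paradigm
#'   itself does not determine them, so they default to 0).
#' @param jitter_range Rest-duration bounds in seconds for vibration
#'   (default `c(10, 15)`).
#' @return A `paradigm` object: list with `condition`, `tr`, `n_volumes`,
#'   `blocks` (data.frame onset/duration/trial_type) and `total_duration`.
#' @export
make_paradigm <- function(condition, tr = 2.5, seed = NULL, pad_volumes = 0L,
                          jitter_range = c(10, 15)) {
  if (!condition %in% c("active", "passive", "vibration"))
    stopf("unknown condition '%s'", condition)
  if (condition %in% c("active", "passive")) {
    onsets <- 15 + (0:11) * 30     # rest 15 s, then task/rest pairs of 15 s
    blocks <- data.frame(onset = onsets, duration = 15,
                         trial_type = "task", stringsAsFactors = FALSE)
    total <- 25 * 15               # 12 task + 13 rest periods of 15 s = 375 s
  } else {
    rests <- with_seed(seed, stats::runif(18, jitter_range[1], jitter_range[2]))
    onsets <- cumsum(rests + c(0, rep(10, 17)))
    blocks <- data.frame(onset = onsets, duration = 10,
                         trial_type = rep(c("agonist", "antagonist"), 9),
                         stringsAsFactors = FALSE)
    total <- onsets[18] + 10 + 10  # trailing 10 s rest after the last block
  }
  n_volumes <- as.integer(ceiling(total / tr)) + as.integer(pad_volumes)
  structure(list(condition = condition, tr = tr, n_volumes = n_volumes,
                 blocks = blocks, total_duration = total),
            class = "paradigm")
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf("paradigm '%s': %d blocks, %d volumes at TR %.2g s (%.0f s)\n",
              x$condition, nrow(x$blocks), x$n_volumes, x$tr, x$total_duration))
  invisible(x)
}

#' Sample a paradigm's boxcar at volume times
#'
#' @param paradigm A `paradigm`.
#' @param trial_type Restrict to one trial type (default: all blocks).
#' @param dt Oversampling step in seconds for the fine-grained boxcar.
#' @return List with `fine` (fine-grid 0/1 vector), `dt`, and `volumes`
#'   (boxcar sampled at acquisition times `0, tr, 2 tr, ...`).
#' @export
paradigm_boxcar <- function(paradigm, trial_type = NULL, dt = 0.1) {
  stopifnot(inherits(paradigm, "paradigm"))
  blocks <- paradigm$blocks
  if (!is.null(trial_type)) blocks <- blocks[blocks$trial_type %in% trial_type, ]
  t_end <- paradigm$n_volumes * paradigm$tr
  tt <- seq(0, t_end, by = dt)
  box <- numeric(length(tt))
  for (i in seq_len(nrow(blocks)))
    box[tt >= blocks$onset[i] & tt < blocks$onset[i] + blocks$duration[i]] <- 1
  vol_t <- (seq_len(paradigm$n_volumes) - 1) * paradigm$tr
  list(fine = box, dt = dt, time = tt,
       volumes = box[round(vol_t / dt) + 1])
}

#' Write / read BIDS-style events files
#'
#' @param paradigm A `paradigm` (for writing).
#' @param path File path of the tab-separated events file with columns
#'   onset, duration, trial_type.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns the events data.frame.
#' @export
write_events_tsv <- function(paradigm, path) {
  stopifnot(inherits(paradigm, "paradigm"))
  utils::write.table(paradigm$blocks, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev)))
    stopf("events file must have columns %s", paste(need, collapse = ", "))
  ev
}
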