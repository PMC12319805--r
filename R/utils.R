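#' @keywords internal
"_PACKAGE"

# Rostrocaudal level names, rostral -> caudal. z increases rostrally (RAS+),
# so L1 occupies the highest slices of any labelled volume.
LEVEL_NAMES <- c("L1", "L2", "L3", "L4", "L5", "S1", "S2")

# Nerve roots whose entry zones delimit the levels: one root rostral of L1 and
# one caudal of S2 are needed to form the flanking midpoints.
ROOT_NAMES <- c("T12", LEVEL_NAMES, "S3")

#' Spinal level names handled by the pipeline
#'
#' The lumbosacral levels L1--S2 in rostral-to-caudal order. All level-indexed
#' results (level maps, segmental distributions, projectome entries) use this
#' ordering.
#'
#' @return Character vector of length 7.
#' @export
level_names <- function() LEVEL_NAMES

#' @rdname level_names
#' @return `root_names()`: the nerve roots T12--S3 whose entry zones flank the
#'   levels, rostral to caudal (length 9).
#' @export
root_names <- function() ROOT_NAMES

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Index of a level name in rostral->caudal order; errors on unknown names.
level_index <- function(level) {
  i <- match(level, LEVEL_NAMES)
  if (anyNA(i)) stopf("unknown spinal level(s): %s",
                      paste(level[is.na(i)], collapse = ", "))
  i
}

as_mask <- function(x, name = "mask") {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    m <- x != 0
    attributes(m) <- attributes(x)
    storage.mode(m) <- "logical"
    dim(m) <- dim(x)
    return(m)
  }
  stopf("%s must be a logical or numeric array", name)
}

check_same_dim <- function(a, b, what = "volumes") {
  if (!identical(dim(a)[seq_len(3)], dim(b)[seq_len(3)]))
    stopf("grid mismatch between %s: %s vs %s", what,
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

# Run code under a private RNG stream so generators are pure functions of
# their seed and never disturb the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Student t -> standard normal z by matched cumulative probability, with
# log-scale tails so |t| ~ 40 does not saturate to +/-Inf prematurely.
t_to_z <- function(t, df) {
  z <- numeric(length(t))
  neg <- !is.na(t) & t < 0
  pos <- !is.na(t) & t >= 0
  z[neg] <- stats::qnorm(stats::pt(t[neg], df, log.p = TRUE), log.p = TRUE)
  z[pos] <- -stats::qnorm(stats::pt(-t[pos], df, log.p = TRUE), log.p = TRUE)
  z[is.na(t)] <- NA_real_
  z
}
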