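# Haemodynamic basis and design-matrix construction.

#' Canonical double-gamma haemodynamic response function
#'
#' SPM-style difference of gammas: a response peaking at `peak_delay` seconds
#' minus an undershoot peaking at `undershoot_delay`, scaled by
#' `1/undershoot_ratio`.
#'
#' @param t Time in seconds (vector).
#' @param peak_delay,undershoot_delay Gamma peak delays (s).
#' @param peak_disp,undershoot_disp Gamma dispersions (s).
#' @param undershoot_ratio Peak-to-undershoot amplitude ratio.
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             peak_disp = 1, undershoot_disp = 1,
                             undershoot_ratio = 6) {
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                  scale = undershoot_disp) / undershoot_ratio
  h[t < 0] <- 0
  h
}

# Convolve a fine-grid boxcar with a kernel and sample at volume times.
convolve_sample <- function(box, kernel, dt, n_volumes, tr) {
  conv <- stats::convolve(box, rev(kernel), type = "open")[seq_along(box)] * dt
  vol_t <- (seq_len(n_volumes) - 1) * tr
  conv[round(vol_t / dt) + 1]
}

#' Task regressor: paradigm boxcar convolved with the canonical HRF
#'
#' Peak-normalized so a planted percent-signal-change amplitude multiplies a
#' regressor with maximum 1.
#'
#' @param paradigm A `paradigm`.
#' @param trial_type Restrict to one trial type (default all blocks).
#' @param hrf_delay Peak delay passed to [hrf_double_gamma()].
#' @param dt Oversampling step (s).
#' @return Numeric vector of length `paradigm$n_volumes`.
#' @export
task_regressor <- function(paradigm, trial_type = NULL, hrf_delay = 6, dt = 0.1) {
  bx <- paradigm_boxcar(paradigm, trial_type = trial_type, dt = dt)
  tk <- seq(0, 32, by = dt)
  h <- hrf_double_gamma(tk, peak_delay = hrf_delay)
  r <- convolve_sample(bx$fine, h, dt, paradigm$n_volumes, paradigm$tr)
  m <- max(abs(r))
  if (m > 0) r / m else r
}

hrf_basis_fine <- function(dt = 0.1, span = 32) {
  tk <- seq(0, span, by = dt)
  h1 <- hrf_double_gamma(tk)
  # Temporal derivative: finite difference in onset time.
  h2 <- (hrf_double_gamma(tk + dt) - h1) / dt
  # Dispersion derivative: finite difference in peak dispersion.
  dd <- 0.01
  h3 <- (hrf_double_gamma(tk, peak_disp = 1 + dd) - h1) / dd
  cbind(h1, h2, h3)
}

#' Build a first-level design matrix
#'
#' The task boxcar is convolved with a three-function basis (canonical
#' double-gamma plus its temporal and dispersion derivatives); the second and
#' third columns are then orthogonalized against the first. Polynomial drift
#' terms, nuisance tables (CSF components, motion parameters), outlier
#' one-hot regressors and an intercept are appended. All columns except the
#' intercept are mean-centered.
#'
#' @param paradigm A `paradigm`.
#' @param trial_type Restrict the task boxcar to one trial type.
#' @param nuisance Optional numeric matrix/data.frame of nuisance time
#'   courses (n_volumes rows), e.g. from [acompcor()].
#' @param motion Optional n_volumes x 6 motion-parameter matrix to include
#'   (used for the tendon-vibration condition).
#' @param outlier_volumes Integer volume indices to scrub with one-hot
#'   regressors.
#' @param drift_order Polynomial drift order (default 2; 0 disables).
#' @return A `design_matrix`: list with `X` (named numeric matrix),
#'   `task_cols` (indices of the 3 basis columns) and `contrast` (the
#'   canonical-basis contrast vector).
#' @export
build_design <- function(paradigm, trial_type = NULL, nuisance = NULL,
                         motion = NULL, outlier_volumes = integer(0),
                         drift_order = 2) {
  stopifnot(inherits(paradigm, "paradigm"))
  n <- paradigm$n_volumes
  if (nrow(paradigm$blocks) &&
      max(paradigm$blocks$onset + paradigm$blocks$duration) > n * paradigm$tr)
    stopf("paradigm blocks extend beyond the run duration")
  dt <- 0.1
  bx <- paradigm_boxcar(paradigm, trial_type = trial_type, dt = dt)
  basis <- hrf_basis_fine(dt = dt)
  has_task <- any(bx$fine > 0)
  task <- NULL
  if (has_task) {
    task <- sapply(seq_len(3), function(k)
      convolve_sample(bx$fine, basis[, k], dt, n, paradigm$tr))
    colnames(task) <- c("task_hrf", "task_tderiv", "task_dderiv")
    # Peak-normalize against the canonical column so its coefficient reads
    # in units of the response amplitude (percent signal change x baseline).
    pk <- max(abs(task[, 1]))
    if (pk > 0) task <- task / pk
    task <- scale(task, center = TRUE, scale = FALSE)
    # Orthogonalize derivatives against the canonical column.
    for (k in 2:3) {
      b1 <- task[, 1]
      task[, k] <- task[, k] - b1 * sum(task[, k] * b1) / sum(b1 * b1)
    }
  }
  cols <- list(task)
  if (drift_order > 0) {
    dr <- stats::poly(seq_len(n), degree = drift_order)
    colnames(dr) <- paste0("drift", seq_len(drift_order))
    cols <- c(cols, list(dr))
  }
  if (!is.null(nuisance)) {
    nu <- as.matrix(nuisance)
    if (nrow(nu) != n) stopf("nuisance table has %d rows, expected %d", nrow(nu), n)
    if (is.null(colnames(nu))) colnames(nu) <- paste0("nuis", seq_len(ncol(nu)))
    cols <- c(cols, list(scale(nu, center = TRUE, scale = FALSE)))
  }
  if (!is.null(motion)) {
    mo <- as.matrix(motion)
    if (nrow(mo) != n) stopf("motion table has %d rows, expected %d", nrow(mo), n)
    colnames(mo) <- paste0("motion_", seq_len(ncol(mo)))
    cols <- c(cols, list(scale(mo, center = TRUE, scale = FALSE)))
  }
  if (length(outlier_volumes)) {
    oh <- outlier_regressors(n, outlier_volumes)
    cols <- c(cols, list(scale(oh, center = TRUE, scale = FALSE)))
  }
  X <- do.call(cbind, c(Filter(Negate(is.null), cols),
                        list(intercept = rep(1, n))))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  task_cols <- if (has_task) 1:3 else integer(0)
  contrast <- numeric(ncol(X))
  if (has_task) contrast[1] <- 1
  structure(list(X = X, task_cols = task_cols, contrast = contrast,
                 tr = paradigm$tr),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d volumes x %d regressors (%s)\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

#' One-hot outlier (scrubbing) regressors
#'
#' @param n_volumes Run length.
#' @param outlier_volumes Integer volume indices (1-based).
#' @return n_volumes x k 0/1 matrix, one column per flagged volume.
#' @export
outlier_regressors <- function(n_volumes, outlier_volumes) {
  outlier_volumes <- sort(unique(as.integer(outlier_volumes)))
  if (any(outlier_volumes < 1 | outlier_volumes > n_volumes))
    stopf("outlier volume indices outside 1..%d", n_volumes)
  oh <- matrix(0, n_volumes, length(outlier_volumes))
  for (i in seq_along(outlier_volumes)) oh[outlier_volumes[i], i] <- 1
  colnames(oh) <- paste0("outlier_v", outlier_volumes)
  oh
}

#' CSF component-based nuisance regressors (aCompCor)
#'
#' Extracts the first principal components of the CSF signal from unsmoothed
#' data: the voxel-by-time CSF matrix is mean-centered per voxel and its
#' leading left singular time courses returned, variance-ranked, unit-norm
#' and mean-centered.
#'
#' @param bold 4D array.
#' @param csf_mask Logical 3D array (nonempty).
#' @param n_components Number of components (default 5).
#' @return n_volumes x n_components matrix with columns `csf_pc1..k`.
#' @export
acompcor <- function(bold, csf_mask, n_components = 5) {
  csf_mask <- as_mask(csf_mask, "csf_mask")
  dims <- dim(bold)
  if (length(dims) != 4L) stopf("bold must be a 4D array")
  check_same_dim(bold, csf_mask, "bold and csf mask")
  idx <- which(csf_mask)
  if (length(idx) < 2) stopf("CSF mask too small (%d voxels)", length(idx))
  nt <- dims[4]
  M <- matrix(bold, prod(dims[1:3]), nt)[idx, , drop = FALSE]  # voxels x time
  M <- t(M)                                  # time x voxels
  M <- scale(M, center = TRUE, scale = FALSE)
  sv <- svd(M, nu = min(nt, ncol(M)), nv = 0)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (n_components > rank)
    stopf("requested %d components but CSF signal has rank %d", n_components, rank)
  comps <- sv$u[, seq_len(n_components), drop = FALSE]
  comps <- scale(comps, center = TRUE, scale = FALSE)
  comps <- sweep(comps, 2, sqrt(colSums(comps^2)), "/")
  colnames(comps) <- paste0("csf_pc", seq_len(n_components))
  comps
}
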