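# Motion and signal-quality metrics with the run-exclusion and volume
# scrubbing rules.

#' Framewise displacement from realignment parameters
#'
#' FD between consecutive volumes is the sum of absolute backward
#' differences of the translations; when 3D rotations are present and
#' `include_rotations` is TRUE they are converted to arc lengths at
#' `rotation_radius_mm` and added. With per-slice traces (the slice-wise
#' realignment stage), FD is averaged over slices first, then over time for
#' the run mean.
#'
#' @param trace Either an n_volumes x p matrix (p = 3 translations in mm, or
#'   6 with rotations in degrees appended) or a list of such matrices, one
#'   per slice.
#' @param rotation_radius_mm Radius for rotation-to-mm conversion
#'   (default 50).
#' @param include_rotations Include rotation columns when present.
#' @return List with `fd_series` (length n_volumes - 1, slice-averaged) and
#'   `mean_fd`.
#' @export
framewise_displacement <- function(trace, rotation_radius_mm = 50,
                                   include_rotations = TRUE) {
  traces <- if (is.list(trace)) trace else list(trace)
  traces <- lapply(traces, as.matrix)
  n <- nrow(traces[[1]])
  if (n < 2) stopf("framewise displacement needs at least 2 volumes")
  per_slice <- lapply(traces, function(m) {
    if (nrow(m) != n) stopf("all slice traces must have the same length")
    if (any(!is.finite(m))) stopf("motion trace contains non-finite values")
    d <- abs(diff(m))
    fd <- rowSums(d[, 1:min(3, ncol(m)), drop = FALSE])
    if (include_rotations && ncol(m) >= 6)
      fd <- fd + rowSums(d[, 4:6, drop = FALSE] * pi / 180 * rotation_radius_mm)
    fd
  })
  fd_series <- Reduce(`+`, per_slice) / length(per_slice)
  list(fd_series = fd_series, mean_fd = mean(fd_series))
}

#' Partition runs into kept and excluded by mean framewise displacement
#'
#' A run is kept iff its mean FD is strictly less than the threshold
#' (a run at exactly the threshold is excluded).
#'
#' @param mean_fds Numeric vector of run mean-FD values (or a list of QC
#'   reports with `mean_fd` fields).
#' @param fd_threshold Exclusion threshold in mm (default 0.5).
#' @return List with logical `kept`, and `kept_idx` / `excluded_idx`.
#' @export
exclude_runs <- function(mean_fds, fd_threshold = 0.5) {
  stopifnot(fd_threshold > 0)
  if (is.list(mean_fds)) mean_fds <- vapply(mean_fds, `[[`, 0, "mean_fd")
  kept <- mean_fds < fd_threshold
  list(kept = kept, kept_idx = which(kept), excluded_idx = which(!kept))
}

#' DVARS: RMS intensity change between consecutive volumes within a mask
#'
#' @param bold 4D array.
#' @param mask Logical 3D array (nonempty), normally the cord mask on
#'   unsmoothed motion-corrected data.
#' @return Numeric vector of length n_volumes - 1.
#' @export
dvars <- function(bold, mask) {
  mask <- as_mask(mask)
  dims <- dim(bold)
  if (length(dims) != 4L || dims[4] < 2) stopf("bold must be 4D with >= 2 volumes")
  check_same_dim(bold, mask, "bold and mask")
  idx <- which(mask)
  if (!length(idx)) stopf("mask is empty")
  M <- matrix(bold, prod(dims[1:3]), dims[4])[idx, , drop = FALSE]
  d <- M[, -1, drop = FALSE] - M[, -dims[4], drop = FALSE]
  sqrt(colMeans(d^2))
}

#' Flag outlier volumes from a DVARS series by the boxplot rule
#'
#' A frame is an outlier when its DVARS exceeds Q3 + 1.5 IQR (strictly),
#' with quartiles computed by linear interpolation between order statistics
#' (type-7 quantiles).
#'
#' @param dvars_series Numeric vector (length >= 4).
#' @return Integer indices t into the series (1..n_volumes - 1); element t
#'   compares volumes t and t+1, so the volume to scrub is t + 1 (the
#'   mapping used by [qc_report()] when building one-hot regressors).
#' @export
scrub_outliers <- function(dvars_series) {
  if (length(dvars_series) < 4) stopf("DVARS series too short to estimate quartiles")
  q <- stats::quantile(dvars_series, c(0.25, 0.75), type = 7, names = FALSE)
  cutoff <- q[2] + 1.5 * (q[2] - q[1])
  which(dvars_series > cutoff)
}

#' Temporal signal-to-noise ratio
#'
#' Per-voxel temporal mean divided by temporal standard deviation (sample
#' sd, n - 1 denominator). Zero-variance voxels are reported as `Inf` in the
#' map and excluded from the mask mean.
#'
#' @param bold 4D array (>= 3 volumes).
#' @param mask Logical 3D array over which the mean is taken.
#' @return List with `tsnr_map` (3D array) and `mean_tsnr`.
#' @export
tsnr <- function(bold, mask) {
  mask <- as_mask(mask)
  dims <- dim(bold)
  if (length(dims) != 4L || dims[4] < 3) stopf("tSNR needs at least 3 volumes")
  check_same_dim(bold, mask, "bold and mask")
  M <- matrix(bold, prod(dims[1:3]), dims[4])
  mu <- rowMeans(M)
  sd_v <- sqrt(rowSums((M - mu)^2) / (dims[4] - 1))
  tmap <- ifelse(sd_v > 0, mu / sd_v, Inf)
  dim(tmap) <- dims[1:3]
  vals <- tmap[mask]
  list(tsnr_map = tmap, mean_tsnr = mean(vals[is.finite(vals)]))
}

#' Full QC report for one run
#'
#' @param bold 4D array (unsmoothed, motion-corrected).
#' @param trace Motion trace (see [framewise_displacement()]).
#' @param cord_mask Logical 3D cord mask.
#' @param fd_threshold Run-exclusion threshold in mm.
#' @return A `qc_report`: `mean_fd`, `fd_series`, `dvars_series`,
#'   `outlier_volumes` (volume indices to scrub, i.e. flagged transition + 1),
#'   `tsnr_mean`, `excluded`, `reason`.
#' @export
qc_report <- function(bold, trace, cord_mask, fd_threshold = 0.5) {
  fd <- framewise_displacement(trace)
  dv <- dvars(bold, cord_mask)
  out <- scrub_outliers(dv) + 1L
  ts <- tsnr(bold, cord_mask)
  excluded <- !(fd$mean_fd < fd_threshold)
  structure(list(mean_fd = fd$mean_fd, fd_series = fd$fd_series,
                 dvars_series = dv, outlier_volumes = out,
                 tsnr_mean = ts$mean_tsnr, excluded = excluded,
                 reason = if (excluded)
                   sprintf("mean FD %.3f mm >= %.2f mm", fd$mean_fd, fd_threshold)
                 else NA_character_),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: mean FD %.3f mm, %d outlier volume(s), tSNR %.2f%s\n",
              x$mean_fd, length(x$outlier_volumes), x$tsnr_mean,
              if (x$excluded) sprintf(" [EXCLUDED: %s]", x$reason) else ""))
  invisible(x)
}
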