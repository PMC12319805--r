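# Synthetic 4D BOLD runs with planted activation, drift, noise and motion.

#' Describe the ground truth of a simulated run
#'
#' @param clusters List of planted clusters; each a list with `muscle`,
#'   `level`, `quadrant` (e.g. "right-ventral"), `amplitude` (percent signal
#'   change, > 0) and `voxels` (n x 3 integer matrix of voxel coordinates).
#' @param noise_sd Gaussian noise standard deviation (signal units).
#' @param drift Polynomial drift coefficients (constant first), evaluated on
#'   time normalized to \[0, 1\] and added globally.
#' @param motion_spikes data.frame with `volume` and `magnitude_mm` columns
#'   (may be empty).
#' @param csf_signal Optional low-rank time course injected into CSF voxels
#'   with random weights, emulating structured physiological noise for
#'   aCompCor testing.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(clusters = list(), noise_sd = 1,
                         drift = c(0, 0, 0),
                         motion_spikes = NULL, csf_signal = NULL) {
  for (cl in clusters) {
    stopifnot(is.numeric(cl$amplitude), cl$amplitude > 0, is.matrix(cl$voxels))
  }
  if (is.null(motion_spikes))
    motion_spikes <- data.frame(volume = integer(), magnitude_mm = numeric())
  structure(list(clusters = clusters, noise_sd = noise_sd, drift = drift,
                 motion_spikes = motion_spikes, csf_signal = csf_signal),
            class = "ground_truth")
}

#' Simulate a 4D BOLD run with known ground truth
#'
#' Signal model: at planted voxels the time series is
#' `baseline * (1 + amplitude/100 * x(t))` where `x(t)` is the paradigm
#' boxcar convolved with the canonical double-gamma haemodynamic response
#' (peak-normalized, so `amplitude` is percent signal change); a global
#' polynomial drift and white Gaussian noise are added everywhere inside the
#' cord and CSF masks. The motion-parameter trace carries small jitter plus
#' the requested spikes. Identical seeds give identical output.
#'
#' @param geometry A `cord_geometry`.
#' @param paradigm A `paradigm`.
#' @param truth A `ground_truth`.
#' @param seed Integer seed.
#' @param baseline Baseline signal level (default 100).
#' @param motion_jitter_sd SD of the background motion jitter (mm / deg).
#' @param hrf_delay Peak delay of the simulated HRF in seconds (default 6,
#'   matching the GLM's first basis; vary it for mismatch experiments).
#' @return List with `bold` (4D array), `motion` (n_volumes x 6 matrix:
#'   3 translations mm, 3 rotations deg), and `truth`.
#' @export
simulate_run <- function(geometry, paradigm, truth, seed = NULL,
                         baseline = 100, motion_jitter_sd = 0.01,
                         hrf_delay = 6) {
  stopifnot(inherits(geometry, "cord_geometry"), inherits(paradigm, "paradigm"),
            inherits(truth, "ground_truth"))
  dims <- geometry$grid_shape
  nt <- paradigm$n_volumes
  for (cl in truth$clusters) {
    inside <- geometry$cord_mask[cl$voxels]
    if (!all(inside)) {
      bad <- cl$voxels[!inside, , drop = FALSE]
      stopf("planted cluster for %s has %d voxel(s) outside the cord mask, e.g. (%s)",
            cl$muscle %||% "?", nrow(bad), paste(bad[1, ], collapse = ", "))
    }
  }

  reg <- task_regressor(paradigm, hrf_delay = hrf_delay)
  t01 <- if (nt > 1) (seq_len(nt) - 1) / (nt - 1) else 0
  drift_t <- numeric(nt)
  for (k in seq_along(truth$drift)) drift_t <- drift_t + truth$drift[k] * t01^(k - 1)

  tissue <- geometry$cord_mask | geometry$csf_mask
  with_seed(seed, {
    bold <- array(0, c(dims, nt))
    slab <- prod(dims)
    tissue_idx <- which(tissue)
    n_tis <- length(tissue_idx)
    # Tissue voxel-by-time block in one draw.
    M <- baseline +
      matrix(stats::rnorm(n_tis * nt, sd = truth$noise_sd), n_tis, nt) +
      matrix(drift_t, n_tis, nt, byrow = TRUE)
    if (!is.null(truth$csf_signal)) {
      csf_idx <- which(geometry$csf_mask)
      csf_w <- stats::rnorm(length(csf_idx))
      M[match(csf_idx, tissue_idx), ] <- M[match(csf_idx, tissue_idx), ] +
        outer(csf_w, truth$csf_signal[seq_len(nt)])
    }
    for (cl in truth$clusters) {
      cl_flat <- cl$voxels[, 1] + (cl$voxels[, 2] - 1L) * dims[1] +
        (cl$voxels[, 3] - 1L) * dims[1] * dims[2]
      rows <- match(cl_flat, tissue_idx)
      M[rows, ] <- M[rows, ] + outer(rep(baseline * cl$amplitude / 100,
                                         length(rows)), reg)
    }
    bold[rep(tissue_idx, nt) + rep((seq_len(nt) - 1L) * slab, each = n_tis)] <- M
    motion <- matrix(stats::rnorm(nt * 6, sd = motion_jitter_sd), nt, 6,
                     dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))
    if (nrow(truth$motion_spikes))
      motion[truth$motion_spikes$volume, "tx"] <-
        motion[truth$motion_spikes$volume, "tx"] + truth$motion_spikes$magnitude_mm
    list(bold = bold, motion = motion, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pick a planted-cluster voxel set inside one level and hemicord quadrant
#'
#' Convenience for building ground truths: selects up to `n_voxels` cord
#' voxels inside the requested level and quadrant, clustered around the
#' quadrant's centroid slice.
#'
#' @param geometry A `cord_geometry`.
#' @param level Level name (L1..S2), using the geometry's true bounds.
#' @param quadrant String `"left"`/`"right"` and/or `"dorsal"`/`"ventral"`,
#'   hyphen-separated (e.g. `"right-ventral"`).
#' @param n_voxels Target cluster size.
#' @return n x 3 integer matrix of voxel coordinates.
#' @export
plant_cluster_voxels <- function(geometry, level, quadrant, n_voxels = 12) {
  stopifnot(inherits(geometry, "cord_geometry"))
  part <- hemicord_partition(geometry$cord_mask, geometry$centerline)
  sel <- array(TRUE, geometry$grid_shape)
  for (q in strsplit(quadrant, "-")[[1]]) {
    if (!q %in% names(part)[1:4]) stopf("unknown quadrant part '%s'", q)
    sel <- sel & part[[q]]
  }
  lvl <- array(FALSE, geometry$grid_shape)
  sl <- geometry$level_slices[[level]]
  if (is.null(sl)) stopf("unknown level '%s'", level)
  lvl[, , sl] <- TRUE
  cand <- which(sel & lvl & geometry$cord_mask)
  if (!length(cand)) stopf("no cord voxels in %s %s", level, quadrant)
  coords <- arrayInd(cand, geometry$grid_shape)
  # Prefer a compact blob: order by distance to the candidate centroid.
  ctr <- colMeans(coords)
  d <- sqrt(rowSums((sweep(coords, 2, ctr))^2))
  coords[order(d)[seq_len(min(n_voxels, nrow(coords)))], , drop = FALSE]
}

#' Generate probabilistic level maps across synthetic subjects
#'
#' Emulates an across-subject probabilistic atlas: each synthetic subject's
#' level boundaries are the geometry's true boundaries jittered by a uniform
#' integer number of slices, and the probability of a level at a voxel is the
#' across-subject frequency of that label.
#'
#' @param geometry A `cord_geometry`.
#' @param n_subjects Number of synthetic subjects (>= 1).
#' @param boundary_jitter_slices Maximum absolute slice jitter applied to
#'   each internal level boundary (0 reproduces the true bounds exactly).
#' @param seed Integer seed.
#' @return A probabilistic `level_map`.
#' @export
make_probabilistic_levels <- function(geometry, n_subjects = 10,
                                      boundary_jitter_slices = 0, seed = NULL) {
  stopifnot(inherits(geometry, "cord_geometry"), n_subjects >= 1)
  nz <- geometry$grid_shape[3]
  ext <- vapply(geometry$level_slices, length, 1L)
  tops <- vapply(geometry$level_slices, max, 1L)
  # Internal boundaries: top slice of each level except L1's top and S2's
  # bottom, expressed as "last slice of the caudal neighbour".
  true_tops <- tops  # per-level top slice index
  counts <- lapply(LEVEL_NAMES, function(nm) array(0L, geometry$grid_shape))
  names(counts) <- LEVEL_NAMES
  with_seed(seed, {
    for (s in seq_len(n_subjects)) {
      tops_s <- true_tops
      if (boundary_jitter_slices > 0 && length(LEVEL_NAMES) > 1) {
        j <- sample(seq.int(-boundary_jitter_slices, boundary_jitter_slices),
                    length(LEVEL_NAMES) - 1, replace = TRUE)
        tops_s[-1] <- true_tops[-1] + j
        # Keep boundaries strictly ordered with >= 1 slice per level.
        for (i in 2:length(tops_s))
          tops_s[i] <- min(tops_s[i], tops_s[i - 1] - 1L)
        tops_s <- pmax(tops_s, rev(seq_along(tops_s)))
      }
      bottom_s <- c(tops_s[-1] + 1L, max(1L, min(geometry$level_slices[[length(LEVEL_NAMES)]])))
      for (i in seq_along(LEVEL_NAMES)) {
        sl <- seq.int(bottom_s[i], tops_s[i])
        counts[[i]][, , sl] <- counts[[i]][, , sl] + 1L
      }
    }
  })
  levels <- lapply(counts, function(cnt) {
    p <- cnt / n_subjects
    p[!geometry$cord_mask] <- 0
    p
  })
  new_level_map(levels, kind = "probabilistic", grid_shape = geometry$grid_shape,
                voxel_size = geometry$voxel_size)
}
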