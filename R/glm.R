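# Voxelwise GLM estimation, fixed-effects combination and thresholding.

new_effect_map <- function(cope, varcope, dof, analysis_level, provenance = NULL) {
  structure(list(cope = cope, varcope = varcope, dof = dof,
                 analysis_level = analysis_level, provenance = provenance),
            class = "effect_map")
}

#' @export
print.effect_map <- function(x, ...) {
  cat(sprintf("effect_map (level %d): %s grid, dof %d\n", x$analysis_level,
              paste(dim(x$cope), collapse = "x"), x$dof))
  invisible(x)
}

new_stat_map <- function(z, threshold_spec, corrected, analysis_level,
                         active_mask, mask = NULL) {
  structure(list(z = z, threshold_spec = threshold_spec, corrected = corrected,
                 analysis_level = analysis_level, active_mask = active_mask,
                 mask = mask),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("stat_map (level %d%s): %d active voxels at Z > %.2f\n",
              x$analysis_level, if (x$corrected) ", cluster-corrected" else "",
              sum(x$active_mask), x$threshold_spec$z_threshold))
  invisible(x)
}

#' Threshold specification
#'
#' @param z_threshold Voxelwise Z threshold (> 0), default 2.3.
#' @param correction `"none"` or `"cluster"`.
#' @param cluster_p Cluster-level alpha in (0, 1) when `correction` is
#'   `"cluster"` (default 0.05).
#' @return A `threshold_spec` list.
#' @export
threshold_spec <- function(z_threshold = 2.3, correction = c("none", "cluster"),
                           cluster_p = if (match.arg(correction) == "cluster") 0.05 else NULL) {
  correction <- match.arg(correction)
  stopifnot(z_threshold > 0)
  if (correction == "cluster") {
    if (is.null(cluster_p) || cluster_p <= 0 || cluster_p >= 1)
      stopf("cluster_p must be in (0, 1) for cluster correction")
  }
  structure(list(z_threshold = z_threshold, correction = correction,
                 cluster_p = cluster_p), class = "threshold_spec")
}

#' First-level GLM for a single run
#'
#' Ordinary least squares per voxel inside the mask, with the contrast on
#' the canonical haemodynamic basis column. The t statistic is converted to
#' a Z score by matched cumulative probabilities. Voxels outside the mask
#' are zero.
#'
#' @param bold 4D array (x, y, z, t).
#' @param design A `design_matrix` from [build_design()].
#' @param mask Logical 3D array of voxels to fit.
#' @return List with `effect` (an `effect_map`, analysis level 1) and `z`
#'   (3D Z-score array).
#' @export
first_level <- function(bold, design, mask) {
  stopifnot(inherits(design, "design_matrix"))
  mask <- as_mask(mask)
  dims <- dim(bold)
  if (length(dims) != 4L) stopf("bold must be a 4D array")
  check_same_dim(bold, mask, "bold and mask")
  X <- design$X
  if (nrow(X) != dims[4])
    stopf("design has %d rows but the run has %d volumes", nrow(X), dims[4])
  dof <- nrow(X) - qr(X)$rank
  if (dof <= 0) stopf("no residual degrees of freedom (n = %d, p = %d)",
                      nrow(X), ncol(X))
  idx <- which(mask)
  Y <- matrix(bold, prod(dims[1:3]), dims[4])[idx, , drop = FALSE]
  Y <- t(Y)                                    # time x voxels
  fit <- stats::lm.fit(X, Y)
  beta <- fit$coefficients
  res <- fit$residuals
  sigma2 <- colSums(res^2) / dof
  XtX_inv <- chol2inv(qr.R(qr(X)))
  cvec <- design$contrast
  cXc <- drop(t(cvec) %*% XtX_inv %*% cvec)
  cope_v <- drop(t(cvec) %*% beta)
  var_v <- sigma2 * cXc
  t_v <- cope_v / sqrt(var_v)
  z_v <- t_to_z(t_v, dof)

  cope <- varcope <- z <- array(0, dims[1:3])
  cope[idx] <- cope_v
  varcope[idx] <- var_v
  z[idx] <- z_v
  list(effect = new_effect_map(cope, varcope, dof, analysis_level = 1L),
       z = z)
}

#' Fixed-effects combination of effect maps
#'
#' Effects are combined by summation: `cope = sum(cope_i)`,
#' `varcope = sum(varcope_i)`, `z = cope / sqrt(varcope)` (equal-weight
#' fixed-effects convention, appropriate when the input maps share one
#' acquisition protocol). The analysis level is incremented.
#'
#' @param effects List of `effect_map` objects on one grid.
#' @param mask Optional logical array restricting the combined Z map.
#' @return List with `effect` (combined `effect_map`) and `z`.
#' @export
fixed_effects <- function(effects, mask = NULL) {
  if (inherits(effects, "effect_map")) effects <- list(effects)
  stopifnot(length(effects) >= 1, all(vapply(effects, inherits, TRUE, "effect_map")))
  d0 <- dim(effects[[1]]$cope)
  for (e in effects) check_same_dim(e$cope, effects[[1]]$cope, "effect maps")
  cope <- Reduce(`+`, lapply(effects, `[[`, "cope"))
  varcope <- Reduce(`+`, lapply(effects, `[[`, "varcope"))
  z <- array(0, d0)
  ok <- varcope > 0
  if (!is.null(mask)) ok <- ok & as_mask(mask)
  z[ok] <- cope[ok] / sqrt(varcope[ok])
  lvl <- max(vapply(effects, `[[`, 1L, "analysis_level")) + 1L
  dof <- sum(vapply(effects, `[[`, 1L, "dof"))
  list(effect = new_effect_map(cope, varcope, dof, analysis_level = lvl),
       z = z)
}

# Cluster sizes of z > thr, 26-connected.
cluster_sizes <- function(z, thr, mask = NULL) {
  supra <- z > thr
  if (!is.null(mask)) supra <- supra & as_mask(mask)
  lab <- label_components(supra, 26)
  if (!any(supra)) return(list(lab = lab, sizes = integer(0)))
  list(lab = lab, sizes = tabulate(lab[lab > 0L]))
}

#' Threshold a Z map, optionally with permutation cluster correction
#'
#' Uncorrected: active voxels are those with `z > z_threshold` (strict).
#' Cluster correction: clusters are formed at the voxelwise threshold and
#' their sizes compared with a max-cluster-size null distribution obtained
#' by sign-flipping the run-level effect maps (a permutation stand-in for
#' random-field cluster inference); clusters with p >= `cluster_p` are
#' removed.
#'
#' @param z 3D Z array (or the list returned by [first_level()] /
#'   [fixed_effects()], whose `z` is used).
#' @param spec A `threshold_spec`.
#' @param mask Optional logical analysis mask.
#' @param run_effects For cluster correction: the list of run-level
#'   `effect_map`s whose fixed-effects combination produced `z`.
#' @param n_perm Number of sign-flip permutations (default 1000). When the
#'   full set of 2^k sign patterns for k runs is no larger than `n_perm`,
#'   all patterns are enumerated and the cluster p-values are exact.
#' @param seed Seed for the permutation draws.
#' @param analysis_level Recorded analysis level (default 1).
#' @return A `stat_map`.
#' @export
threshold_map <- function(z, spec = threshold_spec(), mask = NULL,
                          run_effects = NULL, n_perm = 1000, seed = NULL,
                          analysis_level = 1L) {
  if (is.list(z) && !is.null(z$z)) {
    if (!is.null(z$effect)) analysis_level <- z$effect$analysis_level
    z <- z$z
  }
  stopifnot(inherits(spec, "threshold_spec"))
  thr <- spec$z_threshold
  if (spec$correction == "none") {
    active <- z > thr
    if (!is.null(mask)) active <- active & as_mask(mask)
    return(new_stat_map(z, spec, corrected = FALSE,
                        analysis_level = analysis_level,
                        active_mask = active, mask = mask))
  }
  if (is.null(run_effects) || !length(run_effects))
    stopf("cluster correction needs the run-level effect maps for permutation")
  obs <- cluster_sizes(z, thr, mask)
  active <- array(FALSE, dim(z))
  if (length(obs$sizes)) {
    copes <- lapply(run_effects, `[[`, "cope")
    varsum <- Reduce(`+`, lapply(run_effects, `[[`, "varcope"))
    sdsum <- sqrt(varsum)
    ok <- varsum > 0
    if (!is.null(mask)) ok <- ok & as_mask(mask)
    k <- length(copes)
    max_cluster_for <- function(s) {
      num <- Reduce(`+`, Map(function(cm, si) cm * si, copes, as.list(s)))
      zp <- array(0, dim(z))
      zp[ok] <- num[ok] / sdsum[ok]
      cs <- cluster_sizes(zp, thr, mask)$sizes
      if (length(cs)) max(cs) else 0L
    }
    if (2^k <= n_perm) {
      # Few runs: enumerate every sign pattern for an exact null.
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
      max_null <- apply(signs, 1, max_cluster_for)
      pvals <- vapply(obs$sizes, function(sz)
        sum(max_null >= sz) / nrow(signs), numeric(1))
    } else {
      max_null <- with_seed(seed, {
        vapply(seq_len(n_perm), function(p)
          max_cluster_for(sample(c(-1, 1), k, replace = TRUE)), numeric(1))
      })
      pvals <- vapply(obs$sizes, function(sz)
        (1 + sum(max_null >= sz)) / (n_perm + 1), numeric(1))
    }
    keep <- which(pvals < spec$cluster_p)
    active <- obs$lab %in% keep
    dim(active) <- dim(z)
  }
  new_stat_map(z, spec, corrected = TRUE, analysis_level = analysis_level,
               active_mask = active, mask = mask)
}

# Separable Gaussian smoothing kernels with edge renormalization.
gauss_kernel <- function(fwhm_mm, voxel_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k / sum(k)
}

convolve_1d_renorm <- function(x, k) {
  n <- length(x); half <- (length(k) - 1L) / 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- seq.int(max(1L, i - half), min(n, i + half))
    w <- k[j - i + half + 1L]
    out[i] <- sum(x[j] * w) / sum(w)
  }
  out
}

#' Anisotropic cord-aligned Gaussian smoothing
#'
#' Applies in-plane smoothing per axial slice and 1D smoothing along the
#' cord's rostrocaudal axis. The longitudinal pass follows the centerline:
#' slices are shifted (to the nearest voxel) so the centerline is aligned,
#' smoothed along z, and shifted back, which realizes a kernel oriented
#' along the cord rather than along the scanner z-axis.
#'
#' @param bold 3D or 4D array.
#' @param geometry A `cord_geometry` (for voxel sizes and centerline).
#' @param fwhm_mm 3-vector of FWHM in mm, default `c(2, 2, 6)`.
#' @return Smoothed array of the same shape.
#' @export
smooth_cord <- function(bold, geometry, fwhm_mm = c(2, 2, 6)) {
  stopifnot(inherits(geometry, "cord_geometry"))
  dims <- dim(bold)
  is4d <- length(dims) == 4L
  if (!is4d) { bold <- array(bold, c(dims, 1L)); dims <- dim(bold) }
  kx <- gauss_kernel(fwhm_mm[1], geometry$voxel_size[1])
  ky <- gauss_kernel(fwhm_mm[2], geometry$voxel_size[2])
  kz <- gauss_kernel(fwhm_mm[3], geometry$voxel_size[3])
  cl <- geometry$centerline
  shift_x <- round(cl[, 1] - cl[1, 1])
  shift_y <- round(cl[, 2] - cl[1, 2])
  out <- array(0, dims)
  for (t in seq_len(dims[4])) {
    vol <- bold[, , , t]
    # In-plane separable smoothing.
    for (z in seq_len(dims[3])) {
      sl <- vol[, , z]
      if (length(kx) > 1) sl <- apply(sl, 2, convolve_1d_renorm, k = kx)
      if (length(ky) > 1) sl <- t(apply(sl, 1, convolve_1d_renorm, k = ky))
      vol[, , z] <- sl
    }
    # Longitudinal smoothing along the centerline: each output voxel
    # averages voxels of neighbouring slices displaced by the centerline
    # offset between the slices, with kernel weights renormalized over the
    # samples that fall inside the grid.
    if (length(kz) > 1) {
      half <- (length(kz) - 1L) / 2L
      ones <- matrix(1, dims[1], dims[2])
      sm <- array(0, dims[1:3])
      den <- array(0, dims[1:3])
      for (o in seq.int(-half, half)) {
        w <- kz[o + half + 1L]
        for (z in seq_len(dims[3])) {
          zs <- z + o
          if (zs < 1 || zs > dims[3]) next
          dx <- shift_x[z] - shift_x[zs]
          dy <- shift_y[z] - shift_y[zs]
          sm[, , z] <- sm[, , z] + w * shift_2d(vol[, , zs], dx, dy)
          den[, , z] <- den[, , z] + w * shift_2d(ones, dx, dy)
        }
      }
      vol <- ifelse(den > 0, sm / den, 0)
      dim(vol) <- dims[1:3]
    }
    out[, , , t] <- vol
  }
  if (is4d) out else out[, , , 1]
}

shift_2d <- function(m, dx, dy) {
  if (dx == 0 && dy == 0) return(m)
  out <- matrix(0, nrow(m), ncol(m))
  xs <- seq_len(nrow(m)); ys <- seq_len(ncol(m))
  xs_src <- xs - dx; ys_src <- ys - dy
  okx <- xs_src >= 1 & xs_src <= nrow(m)
  oky <- ys_src >= 1 & ys_src <= ncol(m)
  out[xs[okx], ys[oky]] <- m[xs_src[okx], ys_src[oky]]
  out
}
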