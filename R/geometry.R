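# Synthetic cord geometry: a tubular cord mask with an optional CSF ring,
# a (possibly meandering) centerline, and ground-truth level boundaries.

#' Generate a synthetic spinal cord geometry
#'
#' Builds a reduced-FOV axial grid containing a roughly cylindrical spinal
#' cord, an optional surrounding CSF ring, a per-slice centerline and
#' ground-truth rostrocaudal level boundaries for L1--S2. The grid is RAS+:
#' x increases to the right, y anteriorly (ventral), z rostrally, so L1
#' occupies the top slices.
#'
#' @param grid_shape Integer vector of 3 voxel counts, default `c(48, 48, 32)`.
#' @param voxel_size Numeric vector of 3 voxel sizes in mm, default
#'   `c(1.1, 1.1, 3)` (the acquisition this simulator emulates).
#' @param cord_radius_mm Cord radius in mm (default 4).
#' @param csf_thickness_mm Thickness of the CSF ring around the cord in mm;
#'   0 disables the ring.
#' @param level_extents Integer vector of 7 slice counts for L1..S2 (rostral
#'   to caudal). Defaults to an even split of the z extent. Must sum to at
#'   most `grid_shape[3]`.
#' @param meander_sd Standard deviation (voxels) of the smooth in-plane
#'   centerline meander; 0 gives a straight cord.
#' @param seed Integer seed for the meander; the geometry is a pure function
#'   of its arguments and seed.
#' @return A `cord_geometry` object: list with `grid_shape`, `voxel_size`,
#'   `cord_mask`, `csf_mask`, `centerline` (nz x 2 matrix of in-plane voxel
#'   coordinates), and `level_slices` (named list mapping L1..S2 to 1-based
#'   slice index vectors, rostral levels at larger z).
#' @export
make_cord_geometry <- function(grid_shape = c(48L, 48L, 32L),
                               voxel_size = c(1.1, 1.1, 3),
                               cord_radius_mm = 4,
                               csf_thickness_mm = 1.5,
                               level_extents = NULL,
                               meander_sd = 0,
                               seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0),
            length(voxel_size) == 3L, all(voxel_size > 0),
            cord_radius_mm > 0, csf_thickness_mm >= 0)
  nz <- grid_shape[3]
  if (is.null(level_extents)) {
    base <- nz %/% length(LEVEL_NAMES)
    extra <- nz %% length(LEVEL_NAMES)
    level_extents <- rep(base, length(LEVEL_NAMES)) +
      c(rep(1L, extra), rep(0L, length(LEVEL_NAMES) - extra))
  }
  level_extents <- as.integer(level_extents)
  if (length(level_extents) != length(LEVEL_NAMES) || any(level_extents <= 0))
    stopf("level_extents must give %d positive slice counts for %s",
          length(LEVEL_NAMES), paste(range(LEVEL_NAMES), collapse = ".."))
  if (sum(level_extents) > nz)
    stopf("level extents sum to %d slices but the grid has only %d",
          sum(level_extents), nz)

  cx0 <- (grid_shape[1] + 1) / 2
  cy0 <- (grid_shape[2] + 1) / 2
  centerline <- cbind(x = rep(cx0, nz), y = rep(cy0, nz))
  if (meander_sd > 0) {
    centerline <- with_seed(seed, {
      wiggle <- function() {
        w <- cumsum(stats::rnorm(nz, sd = meander_sd / max(1, sqrt(nz))))
        # Moving-average smoothing bounds the curvature between slices.
        k <- 5L
        pad <- c(rep(w[1], k), w, rep(w[nz], k))
        sm <- stats::filter(pad, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
        as.numeric(sm[(k + 1):(k + nz)])
      }
      cbind(x = cx0 + wiggle(), y = cy0 + wiggle())
    })
  }

  xs <- seq_len(grid_shape[1]); ys <- seq_len(grid_shape[2])
  cord_mask <- array(FALSE, grid_shape)
  csf_mask <- array(FALSE, grid_shape)
  r2 <- cord_radius_mm^2
  ro2 <- (cord_radius_mm + csf_thickness_mm)^2
  for (z in seq_len(nz)) {
    dx2 <- ((xs - centerline[z, 1]) * voxel_size[1])^2
    dy2 <- ((ys - centerline[z, 2]) * voxel_size[2])^2
    d2 <- outer(dx2, dy2, `+`)
    cord_mask[, , z] <- d2 <= r2
    if (csf_thickness_mm > 0) csf_mask[, , z] <- d2 > r2 & d2 <= ro2
  }

  # Rostral (L1) levels take the top slices; any slices left over below S2
  # remain unlabelled (outside the L1-S2 field of view).
  level_slices <- vector("list", length(LEVEL_NAMES))
  names(level_slices) <- LEVEL_NAMES
  top <- nz
  for (i in seq_along(LEVEL_NAMES)) {
    level_slices[[i]] <- seq.int(top - level_extents[i] + 1L, top)
    top <- top - level_extents[i]
  }

  structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size,
         cord_radius_mm = cord_radius_mm,
         cord_mask = cord_mask, csf_mask = csf_mask,
         centerline = centerline, level_slices = level_slices),
    class = "cord_geometry")
}

#' @export
print.cord_geometry <- function(x, ...) {
  cat(sprintf("cord_geometry: %s grid at %s mm, %d cord voxels, %d CSF voxels\n",
              paste(x$grid_shape, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              sum(x$cord_mask), sum(x$csf_mask)))
  ext <- vapply(x$level_slices, length, 1L)
  cat("  levels (slices):", paste(sprintf("%s=%d", names(ext), ext), collapse = " "), "\n")
  invisible(x)
}

#' Ground-truth level map of a synthetic geometry
#'
#' @param geometry A `cord_geometry`.
#' @return A binary `level_map` matching the generator's true level bounds.
#' @export
true_level_map <- function(geometry) {
  stopifnot(inherits(geometry, "cord_geometry"))
  levels <- lapply(geometry$level_slices, function(sl) {
    m <- array(FALSE, geometry$grid_shape)
    m[, , sl] <- geometry$cord_mask[, , sl]
    m
  })
  new_level_map(levels, kind = "binary", grid_shape = geometry$grid_shape,
                voxel_size = geometry$voxel_size)
}

#' Split a cord mask into left/right and dorsal/ventral hemicords
#'
#' Each slice is divided at the centerline: voxels with x greater than the
#' centerline x lie in the right hemicord (RAS+), voxels with y greater than
#' the centerline y lie ventrally (anterior). A voxel exactly on the dividing
#' line is assigned to the right (left/right split) and to the ventral
#' (dorsal/ventral split); the tie rule is fixed so counts are reproducible.
#'
#' @param cord_mask Logical 3D array.
#' @param centerline nz x 2 matrix of per-slice in-plane centerline
#'   coordinates (voxel units), as in [make_cord_geometry()].
#' @return A `hemicord_partition`: list of logical masks `left`, `right`,
#'   `dorsal`, `ventral`, each pair partitioning `cord_mask`.
#' @export
hemicord_partition <- function(cord_mask, centerline) {
  cord_mask <- as_mask(cord_mask, "cord_mask")
  dims <- dim(cord_mask)
  if (length(dims) != 3L) stopf("cord_mask must be a 3D array")
  if (!any(cord_mask)) stopf("cord_mask is empty")
  centerline <- as.matrix(centerline)
  if (nrow(centerline) != dims[3] || ncol(centerline) < 2)
    stopf("centerline must have one (x, y) row per slice")
  occupied <- which(apply(cord_mask, 3, any))
  if (any(!is.finite(centerline[occupied, ])))
    stopf("centerline undefined for slices intersecting the cord mask")

  left <- right <- dorsal <- ventral <- array(FALSE, dims)
  xs <- seq_len(dims[1]); ys <- seq_len(dims[2])
  for (z in occupied) {
    sl <- cord_mask[, , z]
    is_right <- matrix(xs >= centerline[z, 1], dims[1], dims[2])
    is_ventral <- matrix(rep(ys >= centerline[z, 2], each = dims[1]), dims[1], dims[2])
    right[, , z] <- sl & is_right
    left[, , z] <- sl & !is_right
    ventral[, , z] <- sl & is_ventral
    dorsal[, , z] <- sl & !is_ventral
  }
  structure(list(left = left, right = right, dorsal = dorsal, ventral = ventral,
                 centerline = centerline),
            class = "hemicord_partition")
}

#' @export
print.hemicord_partition <- function(x, ...) {
  cat(sprintf("hemicord_partition: left %d | right %d ; dorsal %d | ventral %d voxels\n",
              sum(x$left), sum(x$right), sum(x$dorsal), sum(x$ventral)))
  invisible(x)
}
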