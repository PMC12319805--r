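# Spinal-level maps: delimitation from root entry zones, the
# probabilistic-to-binary contiguous map algorithm, and level-map containers.

new_level_map <- function(levels, kind, grid_shape, voxel_size = NULL) {
  stopifnot(kind %in% c("probabilistic", "binary"),
            is.list(levels), identical(names(levels), LEVEL_NAMES) ||
              all(names(levels) %in% LEVEL_NAMES))
  structure(list(kind = kind, levels = levels,
                 grid_shape = as.integer(grid_shape), voxel_size = voxel_size),
            class = "level_map")
}

#' @export
print.level_map <- function(x, ...) {
  cat(sprintf("level_map (%s): %d levels on a %s grid\n", x$kind,
              length(x$levels), paste(x$grid_shape, collapse = "x")))
  if (x$kind == "binary") {
    n <- vapply(x$levels, sum, 0)
    cat("  voxels:", paste(sprintf("%s=%d", names(n), as.integer(n)), collapse = " "), "\n")
  }
  invisible(x)
}

# z-slices occupied by each level of a binary map.
level_slice_sets <- function(map) {
  lapply(map$levels, function(v) which(apply(v, 3, any)))
}

#' Delimit spinal levels from root entry zone annotations
#'
#' Each level's rostrocaudal span runs between the midpoints of its root
#' entry zone (REZ) and the two flanking REZs: level Lk spans the half-open
#' interval (mid(REZ_k, REZ_caudal), mid(REZ_rostral, REZ_k)] along z, with z
#' decreasing caudally. All nine roots T12..S3 must be annotated so that
#' L1 and S2 have flanking midpoints.
#'
#' @param rez A named numeric vector or list with entries for all of
#'   [root_names()], giving each root's z-coordinate, or a list with fields
#'   `entries` (that vector) and `unit` ("mm", the default, or "slice") and,
#'   for slice units, `slice_thickness_mm` used to convert to mm.
#' @return A data.frame with one row per level L1..S2: `level`,
#'   `caudal_mm` (exclusive), `rostral_mm` (inclusive), `length_mm`.
#' @export
levels_from_rez <- function(rez) {
  unit <- "mm"; thick <- NULL
  if (is.list(rez) && !is.null(rez$entries)) {
    unit <- if (is.null(rez$unit)) "mm" else rez$unit
    thick <- rez$slice_thickness_mm
    rez <- rez$entries
  }
  rez <- unlist(rez)
  missing_roots <- setdiff(ROOT_NAMES, names(rez))
  if (length(missing_roots))
    stopf("missing root entry zone(s): %s", paste(missing_roots, collapse = ", "))
  z <- as.numeric(rez[ROOT_NAMES])
  if (unit == "slice") {
    if (is.null(thick)) stopf("slice-unit REZ annotations need slice_thickness_mm")
    z <- z * thick
  } else if (unit != "mm") {
    stopf("unknown REZ unit '%s' (use 'mm' or 'slice')", unit)
  }
  if (any(diff(z) >= 0))
    stopf("REZ z-coordinates must strictly decrease caudally (T12 rostral-most)")
  mids <- (z[-1] + z[-length(z)]) / 2   # midpoint between consecutive roots
  data.frame(level = LEVEL_NAMES,
             caudal_mm = mids[-1],        # exclusive lower bound
             rostral_mm = mids[-length(mids)],  # inclusive upper bound
             length_mm = mids[-length(mids)] - mids[-1],
             stringsAsFactors = FALSE)
}

#' Convert probabilistic level maps into contiguous binary level maps
#'
#' Reproduces the probabilistic-to-binary adaptation used for rostrocaudal
#' analyses: each level's probability map is binarized (default threshold
#' 0.6), its largest 26-connected component kept, holes filled in 3D, and the
#' component dilated in-plane (x, y only) to the full cord extent of its
#' slices. Then, between adjacent levels, any z-overlap is divided equally
#' along z, and any z-gap is filled and divided equally between the two
#' levels; when a count is odd the extra slice goes to the more rostral
#' level. The result is a set of pairwise-disjoint, z-contiguous binary
#' levels filling the in-plane cord extent.
#'
#' @param prob A probabilistic `level_map` (values in \[0, 1\]).
#' @param threshold Binarization threshold in (0, 1); voxels with probability
#'   `>= threshold` survive. Default 0.6.
#' @param cord_mask Logical 3D array delimiting the cord.
#' @param on_empty What to do when a level has no voxel above threshold:
#'   `"error"` (default) or `"drop"` (warn and omit the level).
#' @return A binary `level_map`.
#' @export
binarize_prob_levels <- function(prob, threshold = 0.6, cord_mask,
                                 on_empty = c("error", "drop")) {
  on_empty <- match.arg(on_empty)
  stopifnot(inherits(prob, "level_map"))
  if (prob$kind != "probabilistic")
    stopf("binarize_prob_levels expects a probabilistic level_map")
  if (!(threshold > 0 && threshold < 1)) stopf("threshold must be in (0, 1)")
  cord_mask <- as_mask(cord_mask, "cord_mask")
  check_same_dim(prob$levels[[1]], cord_mask, "level map and cord mask")

  # Stage 1: per-level cleanup down to a set of whole cord slices.
  slice_sets <- list()
  for (nm in names(prob$levels)) {
    p <- prob$levels[[nm]]
    if (any(p < -1e-12 | p > 1 + 1e-12)) stopf("probabilities for %s outside [0, 1]", nm)
    bin <- (p >= threshold) & cord_mask
    if (!any(bin)) {
      if (on_empty == "error")
        stopf("level %s has no voxels at or above threshold %.2f", nm, threshold)
      warning(sprintf("dropping level %s: nothing above threshold", nm))
      next
    }
    comp <- largest_component(bin, connectivity = 26)
    comp <- fill_holes_3d(comp)
    # In-plane dilation to the cord extent turns the level into whole slices.
    slice_sets[[nm]] <- which(apply(comp, 3, any))
  }
  if (!length(slice_sets)) stopf("no levels survived binarization")

  # Stage 2: resolve z-overlaps and z-gaps between ADJACENT surviving levels.
  nms <- names(slice_sets)  # rostral -> caudal order inherited from input
  # Non-adjacent overlap violates rostrocaudal order.
  for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      if (j > i + 1 && length(intersect(slice_sets[[i]], slice_sets[[j]])))
        stopf("non-adjacent levels %s and %s overlap in z", nms[i], nms[j])
    }
  }
  for (i in seq_len(length(nms) - 1)) {
    r <- nms[i]; c <- nms[i + 1]
    ov <- sort(intersect(slice_sets[[r]], slice_sets[[c]]), decreasing = TRUE)
    if (length(ov)) {
      n_r <- ceiling(length(ov) / 2)  # odd slice to the more rostral level
      to_r <- ov[seq_len(n_r)]
      to_c <- setdiff(ov, to_r)
      slice_sets[[r]] <- setdiff(slice_sets[[r]], to_c)
      slice_sets[[c]] <- setdiff(slice_sets[[c]], to_r)
    } else {
      lo_r <- min(slice_sets[[r]]); hi_c <- max(slice_sets[[c]])
      if (lo_r > hi_c + 1L) {
        gap <- sort(seq.int(hi_c + 1L, lo_r - 1L), decreasing = TRUE)
        n_r <- ceiling(length(gap) / 2)
        slice_sets[[r]] <- c(slice_sets[[r]], gap[seq_len(n_r)])
        slice_sets[[c]] <- c(slice_sets[[c]], gap[-seq_len(n_r)])
      }
    }
  }

  levels <- lapply(slice_sets, function(sl) {
    m <- array(FALSE, dim(cord_mask))
    m[, , sort(sl)] <- cord_mask[, , sort(sl)]
    m
  })
  out <- new_level_map(levels, kind = "binary", grid_shape = dim(cord_mask),
                       voxel_size = prob$voxel_size)
  validate_binary_level_map(out)
  out
}

validate_binary_level_map <- function(map) {
  sets <- level_slice_sets(map)
  for (nm in names(sets)) {
    sl <- sets[[nm]]
    if (length(sl) && !identical(sort(sl), seq.int(min(sl), max(sl))))
      stopf("level %s is not z-contiguous", nm)
  }
  total <- Reduce(`+`, lapply(map$levels, function(v) v * 1L))
  if (any(total > 1L)) stopf("binary level maps overlap")
  # Rostral levels must sit at larger z than caudal ones.
  occ <- Filter(length, sets)
  if (length(occ) > 1) {
    mins <- vapply(occ, min, 0L); maxs <- vapply(occ, max, 0L)
    for (i in seq_len(length(occ) - 1))
      if (mins[i] <= maxs[i + 1])
        stopf("levels %s and %s violate rostrocaudal order",
              names(occ)[i], names(occ)[i + 1])
  }
  invisible(map)
}

#' Combine binary levels into a continuous L1--S2 mask with hemicord sub-masks
#'
#' @param map A binary `level_map`.
#' @param partition Optional `hemicord_partition` on the same grid; when
#'   given, per-level-by-hemicord sub-masks are returned.
#' @return List with `union` (logical array, z-contiguous), `per_level`
#'   (the input level masks), and, with a partition, `per_level_hemicord`
#'   (nested list level -> left/right/dorsal/ventral logical arrays).
#' @export
combine_levels <- function(map, partition = NULL) {
  stopifnot(inherits(map, "level_map"))
  if (map$kind != "binary") stopf("combine_levels expects a binary level_map")
  validate_binary_level_map(map)
  union <- Reduce(`|`, map$levels)
  occ <- which(apply(union, 3, any))
  if (length(occ) && !identical(occ, seq.int(min(occ), max(occ))))
    stopf("combined level mask has empty slices between levels")
  out <- list(union = union, per_level = map$levels)
  if (!is.null(partition)) {
    stopifnot(inherits(partition, "hemicord_partition"))
    out$per_level_hemicord <- lapply(map$levels, function(lv)
      list(left = lv & partition$left, right = lv & partition$right,
           dorsal = lv & partition$dorsal, ventral = lv & partition$ventral))
  }
  out
}
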