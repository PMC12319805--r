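# 3D morphology primitives on logical arrays. Volumes in this pipeline are
# small (reduced-FOV cord acquisitions, ~48x48x32 voxels), so breadth-first
# labelling over flattened indices in plain R is fast enough.

neighbor_offsets <- function(dims, connectivity = 26) {
  nx <- dims[1]; ny <- dims[2]
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ]
  if (connectivity == 6) {
    d <- d[abs(d$dx) + abs(d$dy) + abs(d$dz) == 1, ]
  } else if (connectivity == 18) {
    d <- d[abs(d$dx) + abs(d$dy) + abs(d$dz) <= 2, ]
  } else if (connectivity != 26) {
    stopf("connectivity must be 6, 18 or 26")
  }
  list(delta = as.matrix(d), flat = d$dx + d$dy * nx + d$dz * nx * ny)
}

#' Label connected components of a 3D mask
#'
#' Components are defined with 26-connectivity by default (voxels sharing a
#' face, edge or corner), the convention used throughout the pipeline for
#' activation clusters and level maps.
#'
#' @param mask Logical (or 0/1 numeric) 3D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of the same shape: 0 for background, 1..k component
#'   labels ordered by decreasing size.
#' @export
label_components <- function(mask, connectivity = 26) {
  mask <- as_mask(mask)
  dims <- dim(mask)
  if (length(dims) != 3L) stopf("mask must be a 3D array")
  lab <- array(0L, dims)
  idx_all <- which(mask)
  if (length(idx_all) == 0L) return(lab)
  off <- neighbor_offsets(dims, connectivity)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  # Precompute coordinates to guard against wrap-around at array edges.
  coord <- arrayInd(seq_len(prod(dims)), dims)
  n_off <- length(off$flat)
  cur <- 0L
  sizes <- integer(0)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    frontier <- start
    count <- 1L
    while (length(frontier)) {
      # Expand the whole frontier at once; bounds-check via coordinates so
      # flat-index arithmetic cannot wrap across slice edges.
      fc <- coord[frontier, , drop = FALSE]
      cand <- rep(frontier, each = n_off) + rep(off$flat, times = length(frontier))
      cx <- rep(fc[, 1], each = n_off) + rep(off$delta[, 1], times = length(frontier))
      cy <- rep(fc[, 2], each = n_off) + rep(off$delta[, 2], times = length(frontier))
      cz <- rep(fc[, 3], each = n_off) + rep(off$delta[, 3], times = length(frontier))
      ok <- cx >= 1 & cx <= nx & cy >= 1 & cy <= ny & cz >= 1 & cz <= nz
      cand <- unique(cand[ok])
      cand <- cand[mask[cand] & lab[cand] == 0L]
      lab[cand] <- cur
      count <- count + length(cand)
      frontier <- cand
    }
    sizes <- c(sizes, count)
  }
  # Relabel so component 1 is the largest (stable for ties).
  ord <- order(-sizes)
  remap <- integer(cur)
  remap[ord] <- seq_len(cur)
  nz_idx <- lab != 0L
  lab[nz_idx] <- remap[lab[nz_idx]]
  lab
}

#' Keep the largest connected component of a mask
#' @inheritParams label_components
#' @return Logical array with only the largest component retained.
#' @export
largest_component <- function(mask, connectivity = 26) {
  lab <- label_components(mask, connectivity)
  lab == 1L
}

#' Fill holes of a 3D mask
#'
#' A hole is any background region not connected to the array border.
#' Background connectivity is 6 (the complement convention for 26-connected
#' foreground).
#'
#' @inheritParams label_components
#' @return Logical array with interior cavities filled.
#' @export
fill_holes_3d <- function(mask) {
  mask <- as_mask(mask)
  dims <- dim(mask)
  # Pad with a background shell so all outside air is one component.
  pad <- array(FALSE, dims + 2L)
  pad[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- mask
  bg <- !pad
  lab <- label_components(bg, connectivity = 6)
  outside_label <- lab[1, 1, 1]
  filled <- pad | (bg & lab != outside_label)
  filled[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)]
}
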