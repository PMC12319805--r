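# Decision-tree construction of personalized projectomes from a ladder of
# stat maps.

#' One entry of a muscle's map set
#'
#' @param statmap A thresholded `stat_map`.
#' @param muscle Muscle name.
#' @return A `map_set_entry` carrying the map plus its priority metadata
#'   (analysis level, corrected flag, z threshold, cluster p).
#' @export
map_set_entry <- function(statmap, muscle) {
  stopifnot(inherits(statmap, "stat_map"))
  structure(list(statmap = statmap, muscle = muscle,
                 analysis_level = statmap$analysis_level,
                 corrected = isTRUE(statmap$corrected),
                 z_threshold = statmap$threshold_spec$z_threshold,
                 cluster_p = statmap$threshold_spec$cluster_p),
            class = "map_set_entry")
}

#' Order a muscle's maps by decision-tree priority
#'
#' Priority: higher analysis level first; corrected before uncorrected;
#' stricter (higher) Z threshold first; stricter (lower) cluster-defining
#' p first; stable for ties.
#'
#' @param entries List of `map_set_entry` objects.
#' @return The same list, priority-ordered.
#' @export
build_map_set <- function(entries) {
  stopifnot(length(entries) >= 1,
            all(vapply(entries, inherits, TRUE, "map_set_entry")))
  lvl <- vapply(entries, `[[`, 1L, "analysis_level")
  corr <- vapply(entries, function(e) as.integer(e$corrected), 1L)
  zt <- vapply(entries, `[[`, 0, "z_threshold")
  cp <- vapply(entries, function(e) e$cluster_p %||% Inf, 0)
  entries[order(-lvl, -corr, -zt, cp)]  # order() is stable
}

#' Extract connected components of an active map with projectome metadata
#'
#' Components are 26-connected. The center of gravity is the unweighted
#' voxel centroid by default (`weighted = TRUE` uses Z-weighted centroids
#' for sensitivity analyses); its spinal level is read from the level map at
#' the nearest voxel (`"outside"` when unlabelled). Hemicord tallies come
#' from the partition.
#'
#' @param statmap A thresholded `stat_map`.
#' @param level_map Binary `level_map`.
#' @param partition A `hemicord_partition`.
#' @param weighted Use Z-weighted centroids.
#' @return List of `component` objects: `voxels`, `size`,
#'   `center_of_gravity`, `level_at_cog`, `n_left`/`n_right`/`n_dorsal`/
#'   `n_ventral`, `lr_index`, `dv_index`.
#' @export
extract_components <- function(statmap, level_map, partition, weighted = FALSE) {
  stopifnot(inherits(statmap, "stat_map"))
  if (is.null(statmap$active_mask)) stopf("stat map has not been thresholded")
  stopifnot(inherits(level_map, "level_map"), level_map$kind == "binary",
            inherits(partition, "hemicord_partition"))
  lab <- label_components(statmap$active_mask, 26)
  k <- max(lab)
  if (k == 0L) return(list())
  # Integer-coded level lookup volume.
  level_code <- array(0L, dim(statmap$active_mask))
  for (i in seq_along(level_map$levels))
    level_code[level_map$levels[[i]]] <- i
  lapply(seq_len(k), function(ci) {
    idx <- which(lab == ci)
    vox <- arrayInd(idx, dim(lab))
    w <- if (weighted) pmax(statmap$z[idx], 0) else rep(1, length(idx))
    if (sum(w) == 0) w <- rep(1, length(idx))
    cog <- colSums(vox * w) / sum(w)
    nearest <- pmin(pmax(round(cog), 1L), dim(lab))
    code <- level_code[nearest[1], nearest[2], nearest[3]]
    if (code == 0L) {
      # Nearest labelled voxel of the component, if the rounded CoG itself
      # falls on an unlabelled voxel.
      codes <- level_code[idx]
      if (any(codes > 0L)) {
        labelled <- vox[codes > 0L, , drop = FALSE]
        d <- rowSums(sweep(labelled, 2, cog)^2)
        code <- codes[codes > 0L][which.min(d)]
      }
    }
    nl <- sum(partition$left[idx]); nr <- sum(partition$right[idx])
    nd <- sum(partition$dorsal[idx]); nv <- sum(partition$ventral[idx])
    structure(list(voxels = vox, size = length(idx), center_of_gravity = cog,
                   level_at_cog = if (code > 0L) names(level_map$levels)[code] else "outside",
                   n_left = nl, n_right = nr, n_dorsal = nd, n_ventral = nv,
                   lr_index = if (nl + nr > 0) (nl - nr) / (nl + nr) else NA_real_,
                   dv_index = if (nd + nv > 0) (nd - nv) / (nd + nv) else NA_real_),
              class = "component")
  })
}

#' Decide whether a component is a candidate for a muscle
#'
#' Kept iff its center-of-gravity level lies within the muscle's expected
#' innervation range (inclusive).
#'
#' @param component A `component`.
#' @param muscle Muscle name present in `expected`.
#' @param expected data.frame from [expected_ranges()].
#' @return List `kept` (logical) and `reason` (`NA` when kept).
#' @export
evaluate_candidate <- function(component, muscle, expected) {
  row <- expected[expected$muscle == muscle, ]
  if (nrow(row) != 1) stopf("no expected range for muscle '%s'", muscle)
  lvl <- component$level_at_cog
  if (identical(lvl, "outside"))
    return(list(kept = FALSE, reason = "center of gravity outside L1-S2"))
  li <- level_index(lvl)
  if (li >= level_index(row$rostral) && li <= level_index(row$caudal))
    list(kept = TRUE, reason = NA_character_)
  else
    list(kept = FALSE,
         reason = sprintf("center of gravity in %s, outside expected %s-%s",
                          lvl, row$rostral, row$caudal))
}

#' Classify a component as motor, sensory or mixed, with its side
#'
#' Uses the component's DV index: strongly ventral (`dv < -margin`) implies
#' a motor pool, strongly dorsal (`dv > margin`) a sensory pool, otherwise
#' mixed. Side is left when the LR index is positive, right otherwise (ties
#' go right, matching the partition tie rule).
#'
#' @param component A `component`.
#' @param margin Purity margin on |DV| (default 0.2).
#' @return List `pool` (`"motor"`, `"sensory"`, `"mixed"`) and `side`.
#' @export
classify_pool <- function(component, margin = 0.2) {
  dv <- component$dv_index
  pool <- if (is.na(dv)) "mixed"
  else if (dv < -margin) "motor"
  else if (dv > margin) "sensory"
  else "mixed"
  side <- if (!is.na(component$lr_index) && component$lr_index > 0) "left" else "right"
  list(pool = pool, side = side)
}

#' Build a personalized projectome from per-muscle map sets
#'
#' For each muscle, iterates its maps in decision-tree priority order; the
#' first map yielding at least one kept candidate determines the assignment
#' (the largest kept component within that map; equal sizes resolve to the
#' more caudal center of gravity). Confidence is `"high"` iff the selected
#' map is third-level corrected, `"standard"` otherwise. Muscles with no
#' kept candidate anywhere are reported as not estimable.
#'
#' @param map_sets Named list (by muscle) of lists of `map_set_entry`.
#' @param level_map Binary `level_map`.
#' @param partition A `hemicord_partition`.
#' @param expected data.frame from [expected_ranges()].
#' @param margin Motor/sensory purity margin.
#' @param weighted Use Z-weighted centers of gravity.
#' @return A `projectome`: data.frame with one row per muscle (`muscle`,
#'   `estimable`, `level`, `side`, `pool`, `confidence`, `source_level`,
#'   `source_corrected`, `component_size`).
#' @export
build_projectome <- function(map_sets, level_map, partition, expected,
                             margin = 0.2, weighted = FALSE) {
  rows <- lapply(names(map_sets), function(muscle) {
    entries <- build_map_set(map_sets[[muscle]])
    for (entry in entries) {
      comps <- extract_components(entry$statmap, level_map, partition,
                                  weighted = weighted)
      kept <- Filter(function(cp) evaluate_candidate(cp, muscle, expected)$kept,
                     comps)
      if (!length(kept)) next
      sizes <- vapply(kept, `[[`, 0, "size")
      best <- kept[sizes == max(sizes)]
      if (length(best) > 1) {
        # Equal sizes: the more caudal center of gravity (smaller z) wins.
        zc <- vapply(best, function(cp) cp$center_of_gravity[3], 0)
        best <- best[order(zc)]
      }
      cp <- best[[1]]
      cls <- classify_pool(cp, margin = margin)
      return(data.frame(
        muscle = muscle, estimable = TRUE, level = cp$level_at_cog,
        side = cls$side, pool = cls$pool,
        confidence = if (entry$analysis_level >= 3 && entry$corrected) "high" else "standard",
        source_level = entry$analysis_level, source_corrected = entry$corrected,
        component_size = cp$size, stringsAsFactors = FALSE))
    }
    data.frame(muscle = muscle, estimable = FALSE, level = NA_character_,
               side = NA_character_, pool = NA_character_,
               confidence = NA_character_, source_level = NA_integer_,
               source_corrected = NA, component_size = NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("projectome", class(out))
  out
}

#' @export
print.projectome <- function(x, ...) {
  cat(sprintf("projectome: %d/%d muscles estimable\n",
              sum(x$estimable), nrow(x)))
  NextMethod()
}
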