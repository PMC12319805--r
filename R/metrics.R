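# Laterality indices, size-corrected segmental distributions and group
# aggregation.

#' Left-right and dorsal-ventral laterality indices
#'
#' Counts active voxels in the four hemicords (restricted to `region`) and
#' forms `lr = (n_left - n_right) / (n_left + n_right)` and
#' `dv = (n_dorsal - n_ventral) / (n_dorsal + n_ventral)`. +1 on the DV
#' index means all active voxels are dorsal; +1 on the LR index, all left;
#' -1 all ventral / all right. Indices are `NA` (missing, not zero) when
#' there are no active voxels in the region.
#'
#' @param active Logical 3D active-voxel mask, or a `stat_map` whose
#'   `active_mask` is used.
#' @param partition A `hemicord_partition`.
#' @param region Optional logical 3D mask ("full" cord or one level's mask);
#'   default no restriction. Must be nonempty.
#' @return A `laterality_result`: counts `n_left`, `n_right`, `n_dorsal`,
#'   `n_ventral` and indices `lr_index`, `dv_index`.
#' @export
laterality_indices <- function(active, partition, region = NULL) {
  if (inherits(active, "stat_map")) active <- active$active_mask
  active <- as_mask(active, "active")
  stopifnot(inherits(partition, "hemicord_partition"))
  check_same_dim(active, partition$left, "active mask and partition")
  if (!is.null(region)) {
    region <- as_mask(region, "region")
    if (!any(region)) stopf("region mask is empty")
    active <- active & region
  }
  n_left <- sum(active & partition$left)
  n_right <- sum(active & partition$right)
  n_dorsal <- sum(active & partition$dorsal)
  n_ventral <- sum(active & partition$ventral)
  lr <- if (n_left + n_right > 0) (n_left - n_right) / (n_left + n_right) else NA_real_
  dv <- if (n_dorsal + n_ventral > 0) (n_dorsal - n_ventral) / (n_dorsal + n_ventral) else NA_real_
  structure(list(n_left = n_left, n_right = n_right,
                 n_dorsal = n_dorsal, n_ventral = n_ventral,
                 lr_index = lr, dv_index = dv),
            class = "laterality_result")
}

#' @export
print.laterality_result <- function(x, ...) {
  cat(sprintf("laterality: LR %+.3f (L %d / R %d), DV %+.3f (D %d / V %d)\n",
              x$lr_index, x$n_left, x$n_right, x$dv_index, x$n_dorsal, x$n_ventral))
  invisible(x)
}

#' Per-level laterality indices
#'
#' @inheritParams laterality_indices
#' @param level_map Binary `level_map` providing the per-level region masks.
#' @return data.frame with one row per level: counts and indices.
#' @export
laterality_by_level <- function(active, partition, level_map) {
  stopifnot(inherits(level_map, "level_map"), level_map$kind == "binary")
  rows <- lapply(names(level_map$levels), function(nm) {
    lv <- level_map$levels[[nm]]
    if (!any(lv)) return(NULL)
    r <- laterality_indices(active, partition, region = lv)
    data.frame(level = nm, n_left = r$n_left, n_right = r$n_right,
               n_dorsal = r$n_dorsal, n_ventral = r$n_ventral,
               lr_index = r$lr_index, dv_index = r$dv_index,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Size-corrected segmental distribution of active voxels
#'
#' Counts active voxels per level, labels a level "active" when it holds
#' strictly more than `active_fraction_threshold` of all active voxels (raw
#' counts), then applies a size correction: each level's count is divided by
#' its relative volume (level voxel count over the mean level voxel count)
#' so that rostrocaudal profiles are not driven by segment size. The
#' corrected counts are normalized to sum to 1.
#'
#' @param active Logical 3D mask or `stat_map`.
#' @param level_map Binary `level_map`.
#' @param active_fraction_threshold Fraction of all active voxels a level
#'   must exceed to be labeled active (default 0.30).
#' @return A `segmental_distribution`: `raw_counts`, `level_volumes`,
#'   `correction_factors`, `corrected_counts`, `normalized` (sums to 1 when
#'   any voxel is active, `NA` otherwise), `active_levels`.
#' @export
segmental_distribution <- function(active, level_map,
                                   active_fraction_threshold = 0.30) {
  if (inherits(active, "stat_map")) active <- active$active_mask
  active <- as_mask(active, "active")
  stopifnot(inherits(level_map, "level_map"))
  if (level_map$kind != "binary") stopf("segmental_distribution needs a binary level_map")
  check_same_dim(active, level_map$levels[[1]], "active mask and level map")
  nms <- names(level_map$levels)
  raw <- vapply(level_map$levels, function(lv) sum(active & lv), 0)
  vol <- vapply(level_map$levels, sum, 0)
  if (all(vol == 0)) stopf("level map is empty")
  factors <- vol / mean(vol[vol > 0])
  corrected <- ifelse(factors > 0, raw / factors, 0)
  total_raw <- sum(raw)
  normalized <- if (sum(corrected) > 0) corrected / sum(corrected) else
    rep(NA_real_, length(nms))
  active_levels <- if (total_raw > 0)
    nms[raw / total_raw > active_fraction_threshold] else character(0)
  structure(list(levels = nms, raw_counts = stats::setNames(raw, nms),
                 level_volumes = stats::setNames(vol, nms),
                 correction_factors = stats::setNames(factors, nms),
                 corrected_counts = stats::setNames(corrected, nms),
                 normalized = stats::setNames(normalized, nms),
                 active_levels = active_levels,
                 threshold = active_fraction_threshold),
            class = "segmental_distribution")
}

#' @export
print.segmental_distribution <- function(x, ...) {
  cat("segmental_distribution (normalized):\n")
  print(round(x$normalized, 3))
  cat("  active levels:",
      if (length(x$active_levels)) paste(x$active_levels, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Group segmental distribution
#'
#' Sums each participant's size-corrected counts over their active levels,
#' accumulates across participants, and normalizes to sum 1 — the
#' histogram-like group representation of activity along the cord.
#'
#' @param distributions List of `segmental_distribution` objects with the
#'   same level set.
#' @return A `segmental_distribution`-like object at the group level.
#' @export
group_distribution <- function(distributions) {
  stopifnot(length(distributions) >= 1,
            all(vapply(distributions, inherits, TRUE, "segmental_distribution")))
  nms <- distributions[[1]]$levels
  acc <- stats::setNames(numeric(length(nms)), nms)
  for (d in distributions) {
    if (!identical(d$levels, nms)) stopf("distributions have different level sets")
    contrib <- d$corrected_counts
    contrib[!(nms %in% d$active_levels)] <- 0
    acc <- acc + contrib
  }
  normalized <- if (sum(acc) > 0) acc / sum(acc) else rep(NA_real_, length(nms))
  structure(list(levels = nms, corrected_counts = acc,
                 normalized = stats::setNames(normalized, nms),
                 n_participants = length(distributions)),
            class = c("group_distribution", "segmental_distribution"))
}

#' Fraction of normalized activity within an expected innervation range
#'
#' @param distribution A `segmental_distribution` (or named normalized
#'   vector over [level_names()]).
#' @param range Length-2 character vector `c(rostral, caudal)` or one row of
#'   [expected_ranges()].
#' @return Sum of normalized fractions over levels within the range
#'   (inclusive), on \[0, 1\].
#' @export
compare_to_expected <- function(distribution, range) {
  normalized <- if (inherits(distribution, "segmental_distribution"))
    distribution$normalized else distribution
  if (is.data.frame(range)) range <- c(range$rostral[1], range$caudal[1])
  ri <- level_index(range)
  if (ri[1] > ri[2]) stopf("range rostral level must not be caudal of its caudal level")
  in_range <- level_index(names(normalized)) >= ri[1] &
    level_index(names(normalized)) <= ri[2]
  sum(normalized[in_range], na.rm = FALSE)
}

#' Expected innervation ranges per muscle
#'
#' Rostral-to-caudal spinal-level ranges within which each muscle's
#' innervation is expected from intraoperative nerve-root stimulation
#' literature: TA L4--S1, Gas L4--S2, Qd L1--L4, Il L1--L4, BF L5--S2,
#' GMax L5--S2. The table ships as editable JSON
#' (`system.file("extdata", "expected_ranges.json", package = "lumbomap")`)
#' and users may substitute their own.
#'
#' @param path Optional path to a JSON file mapping muscle ->
#'   `[rostral, caudal]`.
#' @return data.frame with columns `muscle`, `rostral`, `caudal`.
#' @export
expected_ranges <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "expected_ranges.json", package = "lumbomap")
  tab <- jsonlite::fromJSON(path)
  df <- data.frame(muscle = names(tab),
                   rostral = vapply(tab, `[`, "", 1),
                   caudal = vapply(tab, `[`, "", 2),
                   stringsAsFactors = FALSE, row.names = NULL)
  bad <- level_index(df$rostral) > level_index(df$caudal)
  if (any(bad)) stopf("invalid range for %s", paste(df$muscle[bad], collapse = ", "))
  df
}

#' One-sided t-tests with Benjamini-Hochberg correction
#'
#' Utility for cohort summaries of laterality indices: per group, a
#' one-sample one-sided t-test against 0, with FDR correction across groups.
#'
#' @param values Named list of numeric vectors (e.g. LR indices per level).
#' @param alternative `"less"` or `"greater"`.
#' @return data.frame with `group`, `n`, `mean`, `se`, `p`, `p_adj`.
#' @export
laterality_tests <- function(values, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  rows <- lapply(names(values), function(nm) {
    x <- values[[nm]][is.finite(values[[nm]])]
    if (length(x) < 2)
      return(data.frame(group = nm, n = length(x), mean = mean(x),
                        se = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    tt <- stats::t.test(x, mu = 0, alternative = alternative)
    data.frame(group = nm, n = length(x), mean = mean(x),
               se = stats::sd(x) / sqrt(length(x)), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
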