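# Minimal stat-map constructor for decision-tree tests.
fake_statmap <- function(g, active, level = 2L, corrected = FALSE,
                         z_threshold = 2.3, cluster_p = NULL, z = NULL) {
  if (is.null(z)) {
    z <- array(0, g$grid_shape)
    z[active] <- z_threshold + 1
  }
  spec <- threshold_spec(z_threshold,
                         if (corrected) "cluster" else "none",
                         cluster_p = if (corrected) (cluster_p %||% 0.05))
  lumbomap:::new_stat_map(z, spec, corrected = corrected,
                          analysis_level = level, active_mask = active)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("map sets are ordered by level, correction, then strictness", {
  g <- small_geometry()
  act <- array(FALSE, g$grid_shape)
  e <- list(
    map_set_entry(fake_statmap(g, act, level = 2L, corrected = FALSE), "TA"),
    map_set_entry(fake_statmap(g, act, level = 3L, corrected = TRUE), "TA"),
    map_set_entry(fake_statmap(g, act, level = 2L, corrected = TRUE), "TA"),
    map_set_entry(fake_statmap(g, act, level = 3L, corrected = FALSE), "TA"))
  ord <- build_map_set(e)
  key <- vapply(ord, function(x) sprintf("%d%s", x$analysis_level,
                                         if (x$corrected) "c" else "u"), "")
  expect_identical(key, c("3c", "3u", "2c", "2u"))

  # Stricter Z threshold first among same level/correction.
  e2 <- list(map_set_entry(fake_statmap(g, act, 2L, TRUE, z_threshold = 2.3), "TA"),
             map_set_entry(fake_statmap(g, act, 2L, TRUE, z_threshold = 3.1), "TA"))
  ord2 <- build_map_set(e2)
  expect_equal(vapply(ord2, `[[`, 0, "z_threshold"), c(3.1, 2.3))

  # Ties preserve input order (stability).
  e3 <- list(e2[[1]], map_set_entry(fake_statmap(g, act, 2L, TRUE, 2.3), "TA"))
  e3[[1]]$tag <- "first"; e3[[2]]$tag <- "second"
  ord3 <- build_map_set(e3)
  expect_identical(ord3[[1]]$tag, "first")
})

test_that("components carry centroid, level and hemicord metadata", {
  g <- small_geometry()
  lmap <- true_level_map(g)
  part <- hemicord_partition(g$cord_mask, g$centerline)

  # Single-voxel blob: CoG is that voxel.
  act <- array(FALSE, g$grid_shape)
  vx <- which(lmap$levels$L4 & part$right, arr.ind = TRUE)[1, ]
  act[vx[1], vx[2], vx[3]] <- TRUE
  comps <- extract_components(fake_statmap(g, act), lmap, part)
  expect_length(comps, 1)
  expect_equal(unname(comps[[1]]$center_of_gravity), as.numeric(vx))
  expect_identical(comps[[1]]$level_at_cog, "L4")

  # Two well-separated blobs are two components.
  act2 <- act
  vx2 <- which(lmap$levels$S1 & part$left, arr.ind = TRUE)[1, ]
  act2[vx2[1], vx2[2], vx2[3]] <- TRUE
  expect_length(extract_components(fake_statmap(g, act2), lmap, part), 2)

  # An L-shaped blob spanning two levels: CoG level follows voxel balance.
  # L4 spans slices 13..16, L5 spans 9..12; put 5 voxels at z=13 (L4) and
  # 2 voxels at z=12 (L5) in one 26-connected column.
  act3 <- array(FALSE, g$grid_shape)
  col <- which(g$cord_mask[, , 13], arr.ind = TRUE)[1:5, ]
  act3[cbind(col, 13)] <- TRUE
  act3[col[1, 1], col[1, 2], 12] <- TRUE
  act3[col[2, 1], col[2, 2], 12] <- TRUE
  comps3 <- extract_components(fake_statmap(g, act3), lmap, part)
  expect_length(comps3, 1)
  # Mean z = (5*13 + 2*12)/7 = 12.71 -> rounds to 13 -> L4.
  expect_identical(comps3[[1]]$level_at_cog, "L4")

  expect_error(extract_components(
    structure(list(z = NULL, active_mask = NULL), class = "stat_map"),
    lmap, part), "threshold")
})

test_that("candidates are kept only inside the expected innervation range", {
  g <- small_geometry()
  lmap <- true_level_map(g)
  part <- hemicord_partition(g$cord_mask, g$centerline)
  exp_tab <- expected_ranges()
  mk_comp <- function(level) {
    act <- array(FALSE, g$grid_shape)
    act[which(lmap$levels[[level]])[1:5]] <- TRUE
    extract_components(fake_statmap(g, act), lmap, part)[[1]]
  }
  expect_true(evaluate_candidate(mk_comp("L4"), "TA", exp_tab)$kept)
  res <- evaluate_candidate(mk_comp("L1"), "TA", exp_tab)
  expect_false(res$kept)
  expect_match(res$reason, "L1")
  expect_true(evaluate_candidate(mk_comp("S2"), "Gas", exp_tab)$kept)
  expect_error(evaluate_candidate(mk_comp("L4"), "Soleus", exp_tab), "Soleus")
})

test_that("pool classification uses the DV margin and side tie rule", {
  g <- small_geometry()
  lmap <- true_level_map(g)
  part <- hemicord_partition(g$cord_mask, g$centerline)
  comp_from <- function(mask) {
    act <- array(FALSE, g$grid_shape); act[mask] <- TRUE
    extract_components(fake_statmap(g, act), lmap, part)[[1]]
  }
  ventral <- comp_from(which(part$ventral & lmap$levels$L4 & part$right))
  expect_identical(classify_pool(ventral)$pool, "motor")
  dorsal <- comp_from(which(part$dorsal & lmap$levels$L4 & part$right))
  expect_identical(classify_pool(dorsal)$pool, "sensory")
  # Within-margin DV -> mixed.
  mixed <- list(dv_index = 0.1, lr_index = 0)
  expect_identical(classify_pool(mixed, margin = 0.2)$pool, "mixed")
  expect_identical(classify_pool(mixed, margin = 0.2)$side, "right")
  expect_identical(classify_pool(list(dv_index = 0, lr_index = 0.3))$side, "left")
})

test_that("the decision tree assigns by priority with fallback", {
  g <- small_geometry()
  lmap <- true_level_map(g)
  part <- hemicord_partition(g$cord_mask, g$centerline)
  exp_tab <- expected_ranges()

  in_range <- array(FALSE, g$grid_shape)
  in_range[which(lmap$levels$L4 & part$right & part$ventral)[1:8]] <- TRUE
  elsewhere <- array(FALSE, g$grid_shape)
  elsewhere[which(lmap$levels$L2 & part$left)[1:8]] <- TRUE

  # Third-level corrected map with an in-range component wins: high
  # confidence, and lower-priority maps cannot change the result.
  sets <- list(TA = list(
    map_set_entry(fake_statmap(g, elsewhere, 2L, FALSE), "TA"),
    map_set_entry(fake_statmap(g, in_range, 3L, TRUE), "TA")))
  pj <- build_projectome(sets, lmap, part, exp_tab)
  expect_true(pj$estimable)
  expect_identical(pj$level, "L4")
  expect_identical(pj$side, "right")
  expect_identical(pj$pool, "motor")
  expect_identical(pj$confidence, "high")
  expect_identical(pj$source_level, 3L)

  # Priority soundness: an out-of-range third-level map falls through to a
  # second-level uncorrected in-range component at standard confidence.
  sets2 <- list(TA = list(
    map_set_entry(fake_statmap(g, in_range, 2L, FALSE), "TA"),
    map_set_entry(fake_statmap(g, elsewhere, 3L, TRUE), "TA")))
  pj2 <- build_projectome(sets2, lmap, part, exp_tab)
  expect_true(pj2$estimable)
  expect_identical(pj2$confidence, "standard")
  expect_identical(pj2$source_level, 2L)

  # All maps empty: the muscle is not estimable, not an error.
  empty <- array(FALSE, g$grid_shape)
  pj3 <- build_projectome(list(TA = list(
    map_set_entry(fake_statmap(g, empty, 3L, TRUE), "TA"))),
    lmap, part, exp_tab)
  expect_false(pj3$estimable)
  expect_true(is.na(pj3$level))

  # Largest kept component wins within one map.
  both <- array(FALSE, g$grid_shape)
  small_vox <- which(lmap$levels$L4 & part$left)[1:3]
  big_vox <- which(lmap$levels$L5 & part$right)[1:12]
  both[small_vox] <- TRUE; both[big_vox] <- TRUE
  pj4 <- build_projectome(list(TA = list(
    map_set_entry(fake_statmap(g, both, 2L, FALSE), "TA"))),
    lmap, part, exp_tab)
  expect_identical(pj4$level, "L5")
  expect_identical(pj4$side, "right")
  expect_equal(pj4$component_size, 12L)
})
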