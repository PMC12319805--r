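make_active <- function(g, voxels) {
  m <- array(FALSE, g$grid_shape)
  m[voxels] <- TRUE
  m
}

test_that("laterality indices match their defining ratios", {
  g <- small_geometry()
  part <- hemicord_partition(g$cord_mask, g$centerline)

  # All-dorsal activation: DV = +1; all-ventral: -1.
  expect_equal(laterality_indices(part$dorsal, part)$dv_index, 1)
  expect_equal(laterality_indices(part$ventral, part)$dv_index, -1)
  expect_equal(laterality_indices(part$left, part)$lr_index, 1)
  expect_equal(laterality_indices(part$right, part)$lr_index, -1)

  # Balanced activation: LR = 0.
  li <- laterality_indices(g$cord_mask, part)
  expect_equal(li$lr_index, 0)
  expect_equal(li$dv_index, 0)

  # n_left 3, n_right 7 -> lr = -0.4.
  lv <- which(part$left); rv <- which(part$right)
  act <- array(FALSE, g$grid_shape)
  act[lv[1:3]] <- TRUE
  act[rv[1:7]] <- TRUE
  li2 <- laterality_indices(act, part)
  expect_equal(li2$n_left, 3L)
  expect_equal(li2$n_right, 7L)
  expect_equal(li2$lr_index, -0.4)

  # Empty activation -> indices missing, not zero.
  li3 <- laterality_indices(array(FALSE, g$grid_shape), part)
  expect_true(is.na(li3$lr_index) && is.na(li3$dv_index))
  expect_error(laterality_indices(act, part, region = array(FALSE, g$grid_shape)),
               "empty")
})

test_that("mirror reflection negates the laterality indices exactly", {
  g <- small_geometry()
  part <- hemicord_partition(g$cord_mask, g$centerline)
  set.seed(77)
  for (rep in 1:5) {
    act <- array(FALSE, g$grid_shape)
    act[sample(which(g$cord_mask), 40)] <- TRUE
    li <- laterality_indices(act, part)
    # Reflect about the centerline plane x = cx: x' = 2 cx - x. With the
    # centerline on a half-integer, the lattice maps onto itself and the
    # tie column is empty, so the reflection is exact.
    vox <- which(act, arr.ind = TRUE)
    vox_lr <- vox
    vox_lr[, 1] <- round(2 * g$centerline[1, 1] - vox[, 1])
    act_lr <- array(FALSE, g$grid_shape)
    act_lr[vox_lr] <- TRUE
    expect_equal(laterality_indices(act_lr, part)$lr_index, -li$lr_index)
    vox_dv <- vox
    vox_dv[, 2] <- round(2 * g$centerline[1, 2] - vox[, 2])
    act_dv <- array(FALSE, g$grid_shape)
    act_dv[vox_dv] <- TRUE
    expect_equal(laterality_indices(act_dv, part)$dv_index, -li$dv_index)
  }
})

test_that("per-level laterality restricts counts to each level", {
  g <- small_geometry()
  part <- hemicord_partition(g$cord_mask, g$centerline)
  lmap <- true_level_map(g)
  act <- lmap$levels$L4 & part$right
  tab <- laterality_by_level(act, part, lmap)
  expect_equal(tab$lr_index[tab$level == "L4"], -1)
  expect_true(all(is.na(tab$lr_index[tab$level != "L4"])))
})

test_that("segmental distribution applies the size correction and 30% rule", {
  g <- small_geometry()
  lmap <- true_level_map(g)

  # All activity in L4 with equal-volume levels: normalized mass 1 at L4.
  d1 <- segmental_distribution(lmap$levels$L4, lmap)
  expect_equal(unname(d1$normalized["L4"]), 1)
  expect_equal(sum(d1$normalized), 1)
  expect_identical(d1$active_levels, "L4")

  # Raw shares 40/35/25% across three levels: the >30% rule keeps two.
  act <- array(FALSE, g$grid_shape)
  act[which(lmap$levels$L4)[1:40]] <- TRUE
  act[which(lmap$levels$L5)[1:35]] <- TRUE
  act[which(lmap$levels$S1)[1:25]] <- TRUE
  d2 <- segmental_distribution(act, lmap)
  expect_identical(d2$active_levels, c("L4", "L5"))

  # Hand-checked size correction: volumes {100, 50}, raw {10, 10} ->
  # factors {4/3, 2/3} about the mean 75 -> corrected {7.5, 15} ->
  # normalized {1/3, 2/3}.
  two <- lumbomap:::new_level_map(
    list(L2 = make_active(g, which(g$cord_mask)[1:100]),
         L3 = make_active(g, which(g$cord_mask)[101:150])),
    kind = "binary", grid_shape = g$grid_shape)
  act2 <- make_active(g, c(which(two$levels$L2)[1:10], which(two$levels$L3)[1:10]))
  d3 <- segmental_distribution(act2, two)
  expect_equal(unname(d3$correction_factors), c(4 / 3, 2 / 3))
  expect_equal(unname(d3$normalized), c(1 / 3, 2 / 3))

  # Empty activation: distribution missing, no active levels.
  d4 <- segmental_distribution(array(FALSE, g$grid_shape), lmap)
  expect_true(all(is.na(d4$normalized)))
  expect_length(d4$active_levels, 0)
})

test_that("uniform whole-cord activation yields a flat normalized histogram", {
  g <- make_cord_geometry(grid_shape = c(32, 32, 28),
                          level_extents = c(6, 5, 4, 4, 3, 3, 3))
  lmap <- true_level_map(g)
  d <- segmental_distribution(g$cord_mask, lmap)
  expect_lt(max(abs(d$normalized - 1 / 7)), 1e-9)
})

test_that("group distribution sums corrected active-level counts", {
  g <- small_geometry()
  lmap <- true_level_map(g)
  dA <- segmental_distribution(lmap$levels$L4, lmap)
  dB <- segmental_distribution(lmap$levels$L5, lmap)

  # One participant: the group equals its own normalized distribution.
  g1 <- group_distribution(list(dA))
  expect_equal(g1$normalized, dA$normalized)

  # Two identical participants: shape unchanged.
  g2 <- group_distribution(list(dA, dA))
  expect_equal(g2$normalized, dA$normalized)

  # L4-only and L5-only participants with equal corrected mass: 50/50.
  g3 <- group_distribution(list(dA, dB))
  expect_equal(unname(g3$normalized[c("L4", "L5")]), c(0.5, 0.5))
  expect_equal(sum(g3$normalized), 1)
})

test_that("expected-range overlap sums in-range normalized mass", {
  norm <- setNames(rep(0, 7), level_names())
  norm[c("L3", "L4", "S2")] <- c(0.2, 0.5, 0.3)
  expect_equal(compare_to_expected(norm, c("L4", "S1")), 0.5)
  norm_all_in <- setNames(c(0, 0, 0, 0.6, 0.4, 0, 0), level_names())
  expect_equal(compare_to_expected(norm_all_in, c("L4", "S2")), 1.0)
  expect_equal(compare_to_expected(norm_all_in, c("L1", "L2")), 0.0)
  tab <- expected_ranges()
  expect_setequal(tab$muscle, c("TA", "Gas", "Qd", "Il", "BF", "GMax"))
  expect_equal(compare_to_expected(norm, tab[tab$muscle == "TA", ]), 0.5)
})

test_that("laterality group tests return BH-adjusted one-sided p-values", {
  set.seed(5)
  vals <- list(full = rnorm(12, -0.4, 0.2), L4 = rnorm(12, -0.3, 0.2),
               L1 = rnorm(12, 0, 0.2))
  out <- laterality_tests(vals, alternative = "less")
  expect_equal(out$group, c("full", "L4", "L1"))
  expect_true(all(out$p_adj >= out$p - 1e-12))
  expect_lt(out$p[1], 0.01)
})
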