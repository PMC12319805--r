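# Shared synthetic fixtures, built in code at test time.

# Compact geometry for fast GLM runs: ~32x32x28 grid, 7 levels of 4 slices.
small_geometry <- function(meander_sd = 0, seed = NULL) {
  make_cord_geometry(grid_shape = c(32, 32, 28), voxel_size = c(1.1, 1.1, 3),
                     cord_radius_mm = 4, csf_thickness_mm = 1.5,
                     level_extents = rep(4L, 7), meander_sd = meander_sd,
                     seed = seed)
}

# A planted-cluster ground truth in one level/quadrant.
planted_truth <- function(geometry, level = "L4", quadrant = "right-ventral",
                          amplitude = 3, n_voxels = 12, noise_sd = 1,
                          drift = c(0, 0, 0), ...) {
  vox <- plant_cluster_voxels(geometry, level, quadrant, n_voxels)
  ground_truth(clusters = list(list(muscle = "TA", level = level,
                                    quadrant = quadrant,
                                    amplitude = amplitude, voxels = vox)),
               noise_sd = noise_sd, drift = drift, ...)
}

# Hand-built probabilistic level map from slice intervals (probability 1
# inside each level's slices, 0 elsewhere), for binarization tests.
prob_map_from_slices <- function(geometry, slice_sets) {
  levels <- lapply(level_names(), function(nm) {
    p <- array(0, geometry$grid_shape)
    sl <- slice_sets[[nm]]
    if (!is.null(sl)) p[, , sl] <- geometry$cord_mask[, , sl] * 1
    p
  })
  names(levels) <- level_names()
  lumbomap:::new_level_map(levels, kind = "probabilistic",
                           grid_shape = geometry$grid_shape,
                           voxel_size = geometry$voxel_size)
}
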