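# Shared fixtures, computed once per test run.

PH_SPEC <- phantom_spec()
PH <- make_phantom(PH_SPEC)
INPUT_FINE <- synth_input(fine = TRUE)
WATER_SCHED <- standard_schedule("water")
FDDNP_SCHED <- standard_schedule("fddnp")
KIN_GRID <- seq(0, 10, by = 0.01)

# gamma-variate reference curve on a fine grid out to the FDDNP horizon,
# generated from the reference region's own one-tissue parameters
make_ref_curve <- function(t_max = 65) {
  grid <- seq(0, t_max, by = 0.01)
  cb <- approx(INPUT_FINE$time_min, INPUT_FINE$value, xout = grid,
               yleft = 0, rule = 2)$y
  ct <- neuropet:::one_tissue_on_grid(list(K1 = 0.30, k2 = 0.12, Vb = 0.04),
                                      cb, 0.01)
  tissue_curve(grid, ct)
}
REF_CURVE <- make_ref_curve()

# one-region label volume with n voxels for voxel-wise recovery checks
flat_labels <- function(n = 500, name = "R") {
  shape <- c(n %/% 20, 20)
  label_volume(array(1L, shape), volume_geometry(shape),
               data.frame(id = 1, name = name))
}

landmark_error <- function(field, landmarks) {
  uv <- neuropet:::sample_field(field, list(landmarks$x_def, landmarks$y_def))
  sqrt((landmarks$x_def + uv[[1]] - landmarks$x_src)^2 +
         (landmarks$y_def + uv[[2]] - landmarks$y_src)^2)
}

mean_mag <- function(field) mean(neuropet:::field_magnitude(field))
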