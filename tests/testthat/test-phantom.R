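test_that("phantom construction is deterministic with populated regions", {
  sp <- phantom_spec(noise_percent = 4, seed = 5)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$labels$data, b$labels$data)
  expect_identical(a$structural, b$structural)
  ids <- unique(as.integer(a$labels$data))
  expect_true(all(1:15 %in% ids))  # 14 reporting regions + ventricle
  for (id in 1:15) expect_gt(sum(a$labels$data == id), 0)

  # at zero noise the structural histogram shows the declared intensities
  clean <- make_phantom(phantom_spec(noise_percent = 0))
  for (nm in c("FRT", "SWM", "VENT")) {
    id <- which(names(phantom_spec()$regions) == nm)
    vals <- clean$structural[clean$labels$data == id]
    target <- phantom_spec()$regions[[nm]]$intensity
    expect_lt(max(abs(vals / target - 1)), 0.1)  # within the bias field
  }
})

test_that("gamma-variate input peaks at t0 + alpha beta and scales linearly", {
  grid <- seq(0, 5, by = 0.001)
  bc <- synth_input(alpha = 2, beta_min = 0.2, t0_min = 0.25,
                    recirc_fraction = 0, times_min = grid)
  expect_equal(grid[which.max(bc$value)], 0.65, tolerance = 2e-3)
  expect_true(all(bc$value[grid <= 0.25] == 0))
  bc2 <- synth_input(A = 600, alpha = 2, beta_min = 0.2, t0_min = 0.25,
                     recirc_fraction = 0, times_min = grid)
  expect_equal(bc2$value, 2 * bc$value)
  expect_error(synth_input(alpha = -1), "invalid")
})

test_that("input degradation delays, smears and conserves area", {
  true <- synth_input(fine = TRUE)
  ident <- degrade_input(true, 0, 0, 0)
  expect_equal(ident$value, true$value, tolerance = 1e-12)

  sm <- degrade_input(true, 0, 8, 0)
  expect_lt(max(sm$value), max(true$value))            # peak drops
  expect_gt(which.max(sm$value), which.max(true$value)) # and arrives later
  dt <- diff(true$time_min[1:2])
  area <- function(v) sum(v) * dt
  expect_lt(abs(area(sm$value) / area(true$value) - 1), 0.005)

  # seeded noise is reproducible
  n1 <- degrade_input(true, 2, 3, 5, seed = 4)
  n2 <- degrade_input(true, 2, 3, 5, seed = 4)
  expect_identical(n1$value, n2$value)
})

test_that("simulated dynamics broadcast the model curves exactly at zero noise", {
  dyn <- simulate_dynamic(PH$labels, PH_SPEC, "water", INPUT_FINE,
                          noise_percent = 0)
  curves <- attr(dyn, "region_curves")
  ids <- neuropet:::region_ids(PH_SPEC)
  for (nm in c("FRT", "SWM", "CGM")) {
    sel <- which(PH$labels$data == ids[[nm]])[1]
    vox <- vapply(seq_len(26), function(f) dyn$data[, , f][sel], 1)
    expect_equal(vox, curves[[nm]], tolerance = 1e-12)
  }
  dyn2 <- simulate_dynamic(PH$labels, PH_SPEC, "water", INPUT_FINE,
                           noise_percent = 3, seed = 9)
  dyn3 <- simulate_dynamic(PH$labels, PH_SPEC, "water", INPUT_FINE,
                           noise_percent = 3, seed = 9)
  expect_identical(dyn2$data, dyn3$data)

  # fddnp: reference region equals its own one-tissue curve
  fd <- simulate_dynamic(PH$labels, PH_SPEC, "fddnp", INPUT_FINE,
                         noise_percent = 0)
  crv <- attr(fd, "region_curves")
  grid <- seq(0, 65, by = 0.01)
  cbg <- approx(INPUT_FINE$time_min, INPUT_FINE$value, xout = grid,
                yleft = 0, rule = 2)$y
  refc <- neuropet:::one_tissue_on_grid(PH_SPEC$regions$CGM$fddnp_ref, cbg, 0.01)
  expect_equal(crv$CGM, frame_average(refc, grid, FDDNP_SCHED)$value,
               tolerance = 1e-10)
})

test_that("generated deformations respect amplitude and invertibility", {
  g <- volume_geometry(c(128, 128))
  expect_true(all(make_deformation(g, 0)$disp == 0))
  f <- make_deformation(g, 8, 12, seed = 3)
  mx <- max(neuropet:::field_magnitude(f))
  expect_gte(mx, 7.5)
  expect_lte(mx, 8.0)
  expect_gt(min(jacobian_determinant(f)), 0)
  expect_equal(nrow(attr(f, "landmarks")), 25)
  # determinism
  expect_identical(f$disp, make_deformation(g, 8, 12, seed = 3)$disp)
})

test_that("lesion insertion touches only the ellipsoid and reports its mask", {
  vol <- PH$structural
  les <- insert_lesion(vol, c(50, 90), c(6, 5), 240)
  expect_equal(les$volume[les$mask == 0], vol[les$mask == 0])
  expect_true(all(les$volume[les$mask == 1] == 240))
  # counting oracle: direct enumeration of the ellipse inequality
  co <- neuropet:::grid_coords(dim(vol))
  inside <- ((co[[1]] - 50) / 6)^2 + ((co[[2]] - 90) / 5)^2 <= 1
  expect_equal(sum(les$mask), sum(inside))
  # equal-to-background intensity: image unchanged, mask still returned
  flat <- array(10, c(32, 32))
  l2 <- insert_lesion(flat, c(16, 16), c(4, 4), 10)
  expect_equal(l2$volume, flat)
  expect_gt(sum(l2$mask), 0)
  expect_error(insert_lesion(flat, c(2, 2), c(4, 4), 5), "outside")
})
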