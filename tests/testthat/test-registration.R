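test_that("mutual information behaves at its limits", {
  set.seed(7)
  a <- matrix(runif(128 * 128), 128)
  expect_gt(mutual_information(a, a), 3)          # self-MI ~ marginal entropy
  expect_equal(mutual_information(matrix(1, 32, 32), matrix(rnorm(1024), 32)), 0)
  b <- matrix(runif(128 * 128), 128)
  expect_lt(mutual_information(a, b), 0.1)        # independence, up to sampling bias
  expect_error(mutual_information(a, matrix(1, 2, 2)), "shape")
})

test_that("rigid registration recovers identity, shifts and rotations", {
  I <- PH$structural
  rt0 <- rigid_register(I, I)
  expect_lt(max(abs(rt0$translation)), 0.1)
  expect_lt(abs(rt0$angles_deg), 0.1)

  tr <- rigid_transform(0, c(3, -2))
  mov <- warp_image(I, invert_transform(tr), geometry = PH$geometry)
  rt <- rigid_register(mov, I)
  expect_lt(max(abs(rt$translation - c(3, -2))), 0.5)

  rr <- rigid_transform(5, c(0, 0))
  mov2 <- warp_image(I, invert_transform(rr), geometry = PH$geometry)
  rt2 <- rigid_register(mov2, I)
  expect_lt(abs(rt2$angles_deg - 5), 0.5)
})

test_that("local cross-correlation scores, invariances and exact gradient", {
  set.seed(3)
  S <- matrix(rnorm(256), 16)
  T <- matrix(rnorm(256), 16)
  r <- 3
  # rho = 1 against itself and under affine intensity maps
  self <- local_cc(S, S, radius = r)
  expect_true(all(abs(self$rho - 1) < 1e-9))
  aff <- local_cc(S, 2 * S + 3, radius = r)
  expect_true(all(abs(aff$rho - 1) < 1e-9))

  cc <- local_cc(S, T, radius = r)
  num <- matrix(0, 16, 16)
  h <- 1e-6
  for (i in 1:16) for (j in 1:16) {
    Sp <- S; Sp[i, j] <- S[i, j] + h
    Sm <- S; Sm[i, j] <- S[i, j] - h
    num[i, j] <- (local_cc(Sp, T, radius = r)$score -
                    local_cc(Sm, T, radius = r)$score) / (2 * h)
  }
  expect_lt(max(abs(num - cc$grad_scalar)) / max(abs(num)), 1e-3)
  expect_error(local_cc(S, T, radius = 10), "window")
})

test_that("cost-function masking zeroes, inpaints and extends constants", {
  g <- volume_geometry(c(32, 32))
  msk <- array(0, c(32, 32)); msk[14:18, 14:18] <- 1
  disp <- array(0, c(32, 32, 2))
  disp[, , 1] <- 1.25; disp[, , 2] <- -0.5
  f <- deformation_field(disp, g)
  out <- apply_cost_mask(f, msk, sweeps = 200)
  # harmonic extension of a constant is the constant
  expect_lt(max(abs(out$disp[, , 1] - 1.25)), 1e-3)
  expect_lt(max(abs(out$disp[, , 2] + 0.5)), 1e-3)
  # empty mask is the identity operation
  expect_equal(apply_cost_mask(f, array(0, c(32, 32)))$disp, f$disp)
  expect_error(apply_cost_mask(f, array(1, c(32, 32))), "whole image")
})

test_that("field inversion satisfies its fixed-point contract", {
  g <- volume_geometry(c(64, 64))
  expect_true(all(invert_field(neuropet:::zero_field(g))$disp == 0))
  const <- deformation_field(array(rep(c(2, -1), each = 64 * 64),
                                   c(64, 64, 2)), g)
  inv <- invert_field(const)
  # interior voxels of a constant field invert to the negated constant
  expect_lt(max(abs(inv$disp[10:54, 10:54, 1] + 2)), 1e-6)
  expect_lt(max(abs(inv$disp[10:54, 10:54, 2] - 1)), 1e-6)

  f <- make_deformation(g, 5, 10, seed = 2)
  fi <- invert_field(f)
  comp <- neuropet:::compose_disp(f, fi)
  expect_lt(mean_mag(comp), 0.05)
})

test_that("transform chains compose into a single equivalent field", {
  g <- volume_geometry(c(64, 64))
  f <- make_deformation(g, 4, 10, seed = 6)
  chain_id <- compose_chain(list(f, invert_field(f)))
  expect_lt(mean_mag(chain_id), 0.05)

  rt <- rigid_transform(10, c(2, 1))
  single <- compose_chain(list(rt), g)
  expect_lt(max(abs(single$disp - neuropet:::rigid_to_field(rt, g)$disp)), 1e-6)

  # one interpolation beats two: compare both against the exact warp
  r1 <- rigid_transform(7, c(1.3, -0.8))
  r2 <- rigid_transform(-4, c(-0.6, 2.1))
  I <- PH$structural
  g2 <- PH$geometry
  seq_warp <- warp_image(warp_image(I, r1, geometry = g2), r2, geometry = g2)
  comp_warp <- warp_image(I, compose_chain(list(r1, r2), g2))
  exact <- local({  # analytic composite rigid map
    f1 <- neuropet:::rigid_to_field(r1, g2)
    f2 <- neuropet:::rigid_to_field(r2, g2)
    warp_image(I, neuropet:::compose_disp(f1, f2))
  })
  expect_lte(mean(abs(comp_warp - exact)), mean(abs(seq_warp - exact)))
})

test_that("warping preserves identity, labels and integer shifts", {
  I <- PH$structural
  g <- PH$geometry
  expect_equal(warp_image(I, neuropet:::zero_field(g)), I)
  lab <- PH$labels$data
  warped <- warp_image(lab, make_deformation(g, 4, 10, seed = 8), "nearest")
  expect_true(all(unique(as.integer(warped)) %in% unique(as.integer(lab))))
  # exact integer shift under linear interpolation
  sh <- deformation_field(array(rep(c(1, 0), each = prod(g$shape)),
                                c(g$shape, 2)), g)
  out <- warp_image(I, sh)
  expect_equal(out[1:127, ], I[2:128, ])
  expect_error(warp_image(I, sh$disp), "not a transform")
})

test_that("jacobian determinant matches closed forms", {
  g <- volume_geometry(c(32, 32))
  expect_equal(jacobian_determinant(neuropet:::zero_field(g)),
               array(1, c(32, 32)))
  co <- neuropet:::grid_coords(c(32, 32))
  s <- 1.15
  disp <- array(0, c(32, 32, 2))
  disp[, , 1] <- (s - 1) * (co[[1]] - 1)
  disp[, , 2] <- (s - 1) * (co[[2]] - 1)
  expect_equal(jacobian_determinant(deformation_field(disp, g)),
               array(s^2, c(32, 32)), tolerance = 1e-12)
})

test_that("3-D fields invert and warp consistently", {
  g <- volume_geometry(c(24, 24, 24))
  f <- make_deformation(g, 2.5, 6, seed = 9)
  expect_gt(min(jacobian_determinant(f)), 0)
  fi <- invert_field(f)
  expect_lt(mean_mag(neuropet:::compose_disp(f, fi)), 0.05)
  vol <- array(rnorm(24^3), c(24, 24, 24))
  expect_equal(warp_image(vol, neuropet:::zero_field(g)), vol)
})
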