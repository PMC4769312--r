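test_that("one-tissue curve matches closed forms for constant input", {
  cb <- blood_curve(c(0, 5, 10), rep(10, 3))
  expect_equal(one_tissue_tac(list(K1 = 0, k2 = 0.3, Vb = 0), cb, c(1, 2, 5)),
               rep(0, 3))
  # k2 = 0: pure accumulation K1*c*t
  expect_equal(one_tissue_tac(list(K1 = 0.5, k2 = 0, Vb = 0), cb, 2), 10,
               tolerance = 1e-9)
  # saturation (K1 c / k2)(1 - exp(-k2 t))
  expect_equal(one_tissue_tac(list(K1 = 0.5, k2 = 0.25, Vb = 0), cb, 4),
               (0.5 * 10 / 0.25) * (1 - exp(-1)), tolerance = 1e-7)
  expect_error(one_tissue_tac(list(K1 = 1, k2 = 1, Vb = 0), cb, 11), "outside")
})

test_that("convolution solution agrees with a stiff ODE oracle", {
  cbf <- function(t) approx(INPUT_FINE$time_min, INPUT_FINE$value,
                            xout = t, yleft = 0, rule = 2)$y
  set.seed(11)
  for (rep in 1:4) {
    K1 <- runif(1, 0.1, 0.8); k2 <- runif(1, 0.05, 1.2); Vb <- runif(1, 0, 0.1)
    ts <- seq(0.5, 9.5, by = 0.5)
    ours <- one_tissue_tac(list(K1 = K1, k2 = k2, Vb = Vb), INPUT_FINE, ts)
    sol <- deSolve::lsoda(c(C = 0), c(0, ts),
                          function(t, y, p) list(K1 * cbf(t) - k2 * y),
                          rtol = 1e-10, atol = 1e-10)
    oracle <- sol[-1, "C"] + Vb * cbf(ts)
    expect_lt(max(abs(ours - oracle)) / max(oracle), 1e-6)
  }
})

test_that("frame averaging reproduces constants, linear ramps and quadrature", {
  sched <- frame_schedule(c(0, 30, 60), c(30, 30, 60))
  grid <- seq(0, 2, by = 0.01)
  fa <- frame_average(rep(7, length(grid)), grid, sched)
  expect_equal(fa$value, rep(7, 3))
  expect_equal(fa$weight, sched$duration_s / 60)
  # linear a*t averages to a*(t1+t2)/2
  a <- 3.2
  fa2 <- frame_average(a * grid, grid, sched)
  expect_equal(fa2$value, a * c(0.25, 0.75, 1.5), tolerance = 1e-9)
  # smooth curve vs an independent trapezoid quadrature oracle at the same step
  f <- sin(2 * grid) + 2
  ora <- vapply(seq_len(3), function(i) {
    t0 <- sched$start_s[i] / 60; t1 <- t0 + sched$duration_s[i] / 60
    tt <- seq(t0, t1, by = 0.01)
    ft <- sin(2 * tt) + 2
    sum((ft[-1] + ft[-length(ft)]) / 2 * 0.01) / (t1 - t0)
  }, 1)
  expect_lt(max(abs(frame_average(f, grid, sched)$value - ora)), 1e-6)
  expect_error(frame_average(f[1:50], grid[1:50], sched), "cover")
})

test_that("one-tissue fitting recovers parameters and degenerate limits", {
  truth <- list(K1 = 0.4, k2 = 0.5, Vb = 0.03)
  ct <- one_tissue_tac(truth, INPUT_FINE, KIN_GRID)
  tac <- frame_average(ct, KIN_GRID, WATER_SCHED)
  fit <- fit_one_tissue(tac, INPUT_FINE, WATER_SCHED)
  for (nm in names(truth))
    expect_lt(abs(fit$params[[nm]] / truth[[nm]] - 1), 0.005)

  zero <- tissue_curve(frame_mid_times(WATER_SCHED),
                       rep(0, 26), WATER_SCHED$duration_s / 60)
  fz <- fit_one_tissue(zero, INPUT_FINE, WATER_SCHED)
  expect_equal(fz$params$K1, 0)
  expect_equal(fz$wrss, 0)

  # vascular-only signal: K1 ~ 0, Vb recovered
  cbg <- neuropet:::blood_on_grid(INPUT_FINE, KIN_GRID)
  vb_tac <- frame_average(0.05 * cbg, KIN_GRID, WATER_SCHED)
  fv <- fit_one_tissue(vb_tac, INPUT_FINE, WATER_SCHED)
  expect_lt(abs(fv$params$Vb - 0.05), 1e-3)
  expect_lt(fv$params$K1, 1e-4)
})

test_that("fitting is scale-equivariant in the joint input/tissue scale", {
  truth <- list(K1 = 0.3, k2 = 0.4, Vb = 0.05)
  ct <- one_tissue_tac(truth, INPUT_FINE, KIN_GRID)
  tac <- frame_average(ct, KIN_GRID, WATER_SCHED)
  f1 <- fit_one_tissue(tac, INPUT_FINE, WATER_SCHED)
  c <- 3.7
  input2 <- blood_curve(INPUT_FINE$time_min, c * INPUT_FINE$value)
  tac2 <- tissue_curve(tac$time_min, c * tac$value, tac$weight)
  f2 <- fit_one_tissue(tac2, input2, WATER_SCHED)
  expect_equal(f2$params$K1, f1$params$K1, tolerance = 1e-3)
  expect_equal(f2$params$k2, f1$params$k2, tolerance = 1e-3)
  expect_equal(f2$params$Vb, f1$params$Vb, tolerance = 1e-3)
})

test_that("delay/dispersion search inverts a known degradation", {
  ct <- one_tissue_tac(list(K1 = 0.2805, k2 = 0.31, Vb = 0.04),
                       INPUT_FINE, KIN_GRID)
  wb <- frame_average(ct, KIN_GRID, WATER_SCHED)

  res <- correct_delay_dispersion(degrade_input(INPUT_FINE, 6, 5), wb, WATER_SCHED)
  expect_equal(res$dd$delta_t_s, 6, tolerance = 0.26)
  expect_equal(res$dd$tau_s, 5, tolerance = 0.51)

  res0 <- correct_delay_dispersion(degrade_input(INPUT_FINE, 0, 0), wb, WATER_SCHED)
  expect_equal(res0$dd$delta_t_s, 0, tolerance = 1e-9)
  expect_equal(res0$dd$tau_s, 0, tolerance = 1e-9)

  # shifting the measured curve shifts the recovered delay equally
  for (s in c(2, -3)) {
    rs <- correct_delay_dispersion(degrade_input(INPUT_FINE, 6 + s, 5),
                                   wb, WATER_SCHED)
    expect_equal(rs$dd$delta_t_s - res$dd$delta_t_s, s, tolerance = 0.26)
  }

  flat <- tissue_curve(wb$time_min, rep(1, 26), wb$weight)
  expect_error(correct_delay_dispersion(degrade_input(INPUT_FINE, 0, 0),
                                        flat, WATER_SCHED), "flat")
})

test_that("linearized parametric fit matches NLS on noiseless data, ridge helps under noise", {
  lv <- flat_labels(500)
  sp <- PH_SPEC
  sp$regions <- list(R = list(type = "x", intensity = 1,
                              water = list(K1 = 0.2805, k2 = 0.31, Vb = 0.04)))
  noiseless <- simulate_dynamic(lv, sp, "water", INPUT_FINE, noise_percent = 0)
  m0 <- ridge_parametric_fit(noiseless, INPUT_FINE, lv$data > 0, h = 0)
  nls <- fit_one_tissue(region_tac(noiseless, lv, 1), INPUT_FINE, WATER_SCHED)
  expect_lt(abs(m0$K1$data[1, 1] / nls$params$K1 - 1), 0.01)

  noisy <- simulate_dynamic(lv, sp, "water", INPUT_FINE, noise_percent = 5,
                            seed = 42)
  ridge <- ridge_parametric_fit(noisy, INPUT_FINE, lv$data > 0)
  ols <- ridge_parametric_fit(noisy, INPUT_FINE, lv$data > 0, h = 0)
  rmse <- function(m, tv) sqrt(mean((m$data - tv)^2, na.rm = TRUE))
  expect_lt(rmse(ridge$K1, 0.2805), rmse(ols$K1, 0.2805))
  expect_lt(rmse(ridge$k2, 0.31), rmse(ols$k2, 0.31))
  expect_lt(rmse(ridge$Vb, 0.04), rmse(ols$Vb, 0.04))

  # all-zero dynamic gives all-zero maps
  zero_dyn <- dynamic_image(array(0, c(dim(lv$data), 26)), lv$geometry,
                            WATER_SCHED)
  mz <- ridge_parametric_fit(zero_dyn, INPUT_FINE, lv$data > 0)
  expect_true(all(mz$K1$data == 0))
  expect_error(ridge_parametric_fit(noisy, INPUT_FINE, lv$data > 5), "empty")
})

test_that("flow conversion and reference normalization are plain arithmetic", {
  g <- volume_geometry(c(2, 2))
  k1 <- parametric_map("K1", array(0.2805, c(2, 2)), "1/min", g)
  expect_equal(unname(flow_map(k1)$data[1, 1]), 33.0, tolerance = 1e-12)
  expect_equal(unname(flow_map(parametric_map("K1", array(0.2, c(2, 2)),
                                              "1/min", g), 1)$data[1, 1]), 20.0)
  expect_true(all(flow_map(parametric_map("K1", array(0, c(2, 2)), "1/min", g))$data == 0))
  expect_error(flow_map(k1, 0), "positive")

  m <- parametric_map("CBF", array(40, c(2, 2)), "mL/100g/min", g)
  expect_equal(unname(normalize_map(m, 38.4)$data[1, 1]), 40 / 38.4)
  expect_equal(unname(normalize_map(m, 40)$data[1, 1]), 1)
  expect_error(normalize_map(m, 0), "positive")
  expect_match(normalize_map(m, 40)$name, "_norm")
})
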