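test_that("dynamic image round-trips through NIfTI + timing sidecar", {
  dir <- withr::local_tempdir()
  sched <- frame_schedule(c(0, 10, 20), rep(10, 3))
  img <- dynamic_image(array(rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3)),
                       volume_geometry(c(2, 2, 2), c(2, 2, 2.5)), sched)
  save_dynamic_image(img, file.path(dir, "d.nii.gz"), file.path(dir, "d.tsv"))
  back <- load_dynamic_image(file.path(dir, "d.nii.gz"), file.path(dir, "d.tsv"))
  expect_equal(back$data, img$data, tolerance = 1e-6)
  expect_equal(back$schedule$start_s, sched$start_s)
  expect_equal(back$schedule$duration_s, sched$duration_s)

  # frame-count mismatch between image and sidecar is an error
  bad <- frame_schedule(c(0, 10, 20, 30), rep(10, 4))
  utils::write.table(data.frame(frame_start_s = bad$start_s,
                                frame_duration_s = bad$duration_s),
                     file.path(dir, "bad.tsv"), sep = "\t", row.names = FALSE)
  expect_error(load_dynamic_image(file.path(dir, "d.nii.gz"),
                                  file.path(dir, "bad.tsv")), "frames")
})

test_that("acquisition protocols have the documented frame counts and spans", {
  w <- standard_schedule("water")
  expect_length(w, 26)
  expect_equal(max(w$start_s + w$duration_s), 600)
  f <- standard_schedule("fddnp")
  expect_length(f, 20)
  expect_equal(max(f$start_s + f$duration_s), 65 * 60)
  expect_true(all(diff(frame_mid_times(w)) > 0))
  expect_equal(arterial_sample_times_s()[1:3], c(0, 12, 24))
  expect_length(arterial_sample_times_s(), 15)
})

test_that("frame schedules reject overlap and bad durations", {
  expect_error(frame_schedule(c(0, 4), c(5, 5)), "overlap")
  expect_error(frame_schedule(0, 0), "positive")
  expect_error(frame_schedule(c(10, 0), c(5, 5)), "non-decreasing")
})

test_that("blood curves round-trip and reject degenerate input", {
  dir <- withr::local_tempdir()
  bc <- blood_curve(arterial_sample_times_s() / 60,
                    pmax(0, sin(seq_len(15))) * 100)
  save_blood_curve(bc, file.path(dir, "b.tsv"))
  back <- load_blood_curve(file.path(dir, "b.tsv"))
  expect_equal(back$time_min, bc$time_min, tolerance = 1e-12)
  expect_equal(back$value, bc$value, tolerance = 1e-12)
  expect_equal(max(back$time_min), 10)  # sampling reaches 600 s

  expect_error(blood_curve(c(0, 1), c(1, 2)), "3 samples")
  expect_error(blood_curve(c(0, 1, 1), c(1, 2, 3)), "increasing")
  expect_error(blood_curve(c(0, 1, 2), c(1, -2, 3)), "negative")
})

test_that("integrate_frames is a duration-weighted integral and linear", {
  g <- volume_geometry(c(4, 4))
  sched <- frame_schedule(c(0, 30), c(30, 30))
  mk <- function(v1, v2) dynamic_image(
    array(rep(c(v1, v2), each = 16), c(4, 4, 2)), g, sched)
  s <- integrate_frames(mk(2, 4), 0, 1)
  expect_equal(unname(s[1, 1]), 3.0)  # 2*0.5 + 4*0.5 kBq.min/mL

  # window containing no mid-times errors
  expect_error(integrate_frames(mk(1, 1), 5, 6), "no frame")
  expect_error(integrate_frames(mk(1, 1), 2, 1), "empty")

  # linearity in the image
  X <- dynamic_image(array(rnorm(32), c(4, 4, 2)), g, sched)
  Y <- dynamic_image(array(rnorm(32), c(4, 4, 2)), g, sched)
  aXbY <- dynamic_image(2 * X$data + 3 * Y$data, g, sched)
  expect_equal(integrate_frames(aXbY, 0, 1),
               2 * integrate_frames(X, 0, 1) + 3 * integrate_frames(Y, 0, 1))

  # constant-1 dynamic on the 0-6 min FDDNP window integrates to 6
  fd <- standard_schedule("fddnp")
  ones <- dynamic_image(array(1, c(2, 2, length(fd))), volume_geometry(c(2, 2)), fd)
  expect_equal(unname(integrate_frames(ones, 0, 6)[1, 1]), 6.0)
})

test_that("volumes round-trip bit-exactly for labels and closely for floats", {
  dir <- withr::local_tempdir()
  g <- volume_geometry(c(5, 6, 4), c(1, 1.5, 2))
  lab <- array(sample(0:3, 120, TRUE), c(5, 6, 4))
  save_volume(lab, g, file.path(dir, "lab.nii.gz"))
  expect_identical(array(as.integer(load_volume(file.path(dir, "lab.nii.gz"))$data),
                         dim(lab)), lab)
  fl <- array(rnorm(120), c(5, 6, 4))
  save_volume(fl, g, file.path(dir, "f.nii.gz"))
  expect_lt(max(abs(load_volume(file.path(dir, "f.nii.gz"))$data - fl)), 1e-6)
  expect_error(save_volume(fl, volume_geometry(c(4, 4, 4)), file.path(dir, "x.nii")),
               "shape")
})
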