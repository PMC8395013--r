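# Phantom simulator: seeded determinism, geometry, artifact field, dataset
# assembly.

test_that("degenerate spec yields a two-valued image and seeded determinism holds", {
  spec <- simple_spec(n_bone_structures = 0L, texture_sigma_hu = 0,
                      gas_cavity_probability = 0)
  img1 <- generate_phantom(spec, seed = 42)
  img2 <- generate_phantom(spec, seed = 42)
  expect_identical(img1$pixels, img2$pixels)
  vals <- sort(unique(as.numeric(img1$pixels)))
  expect_length(vals, 2L)
  expect_equal(vals[1], -1000)
  expect_true(vals[2] >= -100 && vals[2] <= 100)
  img3 <- generate_phantom(spec, seed = 43)
  expect_false(identical(img1$pixels, img3$pixels))
})

test_that("rasterized body area matches the analytic ellipse area within 2%", {
  spec <- phantom_spec(image_size = 256L, body_axes = c(60, 40),
                       n_bone_structures = 0L, texture_sigma_hu = 0,
                       gas_cavity_probability = 0)
  img <- generate_phantom(spec, seed = 1)
  n_body <- sum(attr(img, "body_mask"))
  expect_lt(abs(n_body - pi * 60 * 40) / (pi * 60 * 40), 0.02)
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(image_size = 64L, body_axes = c(40, 30)),
               "does not fit")
  expect_error(phantom_spec(bone_hu_range = c(-50, 10)), "bone HU")
  expect_error(artifact_model(fov_radius_fraction = 0), "fov_radius_fraction")
  expect_error(artifact_model(noise_sigma = -1), "noise_sigma")
})

test_that("identity artifact model reproduces the CT exactly", {
  spec <- simple_spec()
  ct <- generate_phantom(spec, seed = 7)
  cbct <- apply_cbct_artifacts(ct, attr(ct, "body_mask"), artifact_model(),
                               seed = 9)
  expect_equal(cbct$pixels, ct$pixels)
})

test_that("gain/offset and radial cupping act as specified inside the body", {
  px <- disk_image(64L, radius = 20, value = 100)
  body <- px > -1000
  ct <- hu_image(px)
  # gain 1.1, offset 20: body pixel at 100 HU -> 130 HU
  m <- artifact_model(gain = 1.1, offset = 20)
  out <- apply_cbct_artifacts(ct, body, m, seed = 1)
  expect_equal(unique(out$pixels[body]), 130)
  expect_equal(out$pixels[!body], px[!body])
  # cupping A = 50: bias -50 at the centroid, -> 0 at r = R
  m2 <- artifact_model(cupping_amplitude = 50)
  out2 <- apply_cbct_artifacts(ct, body, m2, seed = 1)
  bias <- out2$pixels - px
  center <- c(32.5, 32.5)
  expect_equal(bias[32, 32], -50, tolerance = 0.01)
  # near the rim (r close to R = 20 for a disk) the bias tends to 0
  expect_gt(bias[32, 52], -5)
})

test_that("offset increments move within-body MAE by exactly the increment", {
  spec <- simple_spec(texture_sigma_hu = 10)
  ct <- generate_phantom(spec, seed = 3)
  body <- attr(ct, "body_mask")
  maes <- vapply(c(10, 25, 40), function(off) {
    cbct <- apply_cbct_artifacts(ct, body, artifact_model(offset = off),
                                 seed = 1)
    compute_mae_hu(ct, cbct, body)
  }, numeric(1))
  expect_equal(maes, c(10, 25, 40), tolerance = 1e-10)
})

test_that("cupping leaves a concave-up mid-row CBCT-minus-CT profile", {
  spec <- phantom_spec(image_size = 128L, body_axes = c(50, 40),
                       n_bone_structures = 0L, texture_sigma_hu = 0,
                       gas_cavity_probability = 0)
  ct <- generate_phantom(spec, seed = 2)
  body <- attr(ct, "body_mask")
  cbct <- apply_cbct_artifacts(ct, body, artifact_model(cupping_amplitude = 80),
                               seed = 1)
  mid <- 64L
  prof <- (cbct$pixels - ct$pixels)[mid, body[mid, ]]
  d2 <- diff(prof, differences = 2)
  expect_true(all(d2 > -1e-8))
  expect_lt(prof[which.min(abs(seq_along(prof) - length(prof) / 2))],
            min(prof[1], prof[length(prof)]))
})

test_that("fov truncation and isocenter shift behave geometrically", {
  spec <- simple_spec()
  ct <- generate_phantom(spec, seed = 4)
  body <- attr(ct, "body_mask")
  m <- artifact_model(fov_radius_fraction = 0.5)
  out <- apply_cbct_artifacts(ct, body, m, seed = 1)
  n <- nrow(out$pixels)
  ictr <- (n + 1) / 2
  rr <- sqrt(outer((seq_len(n) - ictr)^2, (seq_len(n) - ictr)^2, "+"))
  expect_true(all(out$pixels[rr > 0.5 * n / 2] == -1000))
  # pure shift: centroid moves by the offset
  m2 <- artifact_model(isocenter_offset = c(5, -3))
  out2 <- apply_cbct_artifacts(ct, body, m2, seed = 1)
  c_ct <- colMeans(which(ct$pixels > -1000, arr.ind = TRUE))
  c_cb <- colMeans(which(out2$pixels > -1000, arr.ind = TRUE))
  expect_equal(unname(c_cb - c_ct), c(-3, 5), tolerance = 0.3)
})

test_that("every emitted pixel respects the HU clip range", {
  ds <- generate_dataset(3, 2, model_ranges = list(
    gain = c(1.3, 1.5), offset = c(150, 300), noise_sigma = c(40, 80),
    cupping_amplitude = c(100, 200)), image_size = 32L, seed = 13)
  for (p in ds) {
    expect_true(all(p$ct$pixels >= -1024 & p$ct$pixels <= 3200))
    expect_true(all(p$cbct$pixels >= -1024 & p$cbct$pixels <= 3200))
  }
})

test_that("generate_dataset counts, reproducibility, and identity null model", {
  ds <- generate_dataset(4, 10, image_size = 32L, seed = 21)
  expect_length(ds, 40L)
  expect_length(unique(vapply(ds, function(p) p$subject_id, character(1))), 4L)
  ds2 <- generate_dataset(4, 10, image_size = 32L, seed = 21)
  expect_identical(lapply(ds, function(p) p$cbct$pixels),
                   lapply(ds2, function(p) p$cbct$pixels))
  # identity model ranges -> cbct equals ct everywhere
  for (p in ds) expect_equal(compute_mae_hu(p$ct, p$cbct), 0)
  expect_error(generate_dataset(2, 2, model_ranges = list(gain = c(2, 1))),
               "empty range")
})

test_that("cavity mismatch re-draws gas independently of the CT", {
  spec <- simple_spec(size = 96L, axes = c(34, 26), gas_cavity_probability = 1,
                      texture_sigma_hu = 0)
  ct <- generate_phantom(spec, seed = 8)
  body <- attr(ct, "body_mask")
  expect_true(any(attr(ct, "cavity_mask")))
  out <- apply_cbct_artifacts(ct, body, artifact_model(cavity_mismatch = TRUE),
                              seed = 31)
  ct_gas <- body & ct$pixels <= -300
  cb_gas <- body & out$pixels <= -300
  expect_true(any(cb_gas))
  expect_false(identical(which(ct_gas), which(cb_gas)))
})
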