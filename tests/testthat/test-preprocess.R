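# Pre-processing: Otsu body masking, masking, alignment, normalization,
# resampling, coherent augmentation.

test_that("body mask recovers a disk, drops debris, and fills holes", {
  disk <- disk_image(64L, radius = 18, value = 0)
  m <- compute_body_mask(disk)[[1]]
  # slightly eroded disk: inside the disk, and nearly its full area
  expect_true(all(disk[m] == 0))
  expect_gt(sum(m), 0.85 * sum(disk == 0))

  # a detached 5-pixel blob must not survive the largest-component filter
  debris <- disk
  debris[2:3, 2:4] <- 0
  m2 <- compute_body_mask(debris)[[1]]
  expect_true(all(!m2[1:6, 1:6]))

  # an interior air hole is inside the mask after fill-holes
  holed <- disk
  holed[30:34, 30:34] <- -1000
  m3 <- compute_body_mask(holed)[[1]]
  expect_true(all(m3[31:33, 31:33]))

  expect_error(compute_body_mask(matrix(0, 8, 8)), "degenerate histogram")
})

test_that("mask threshold is volume-wide and ignores structures outside the main component", {
  base <- disk_image(64L, radius = 18, value = 50)
  with_couch <- base
  with_couch[60:62, 10:54] <- 150  # couch-like bar
  m_plain <- compute_body_mask(base)[[1]]
  m_couch <- compute_body_mask(with_couch)[[1]]
  expect_identical(m_plain, m_couch)
  masked <- apply_mask(with_couch, m_couch)
  expect_true(all(masked$pixels[60:62, 10:54] == -1000))
})

test_that("apply_mask leaves inside pixels and sets outside to air", {
  img <- disk_image(32L, radius = 10, value = 80)
  full <- matrix(TRUE, 32, 32)
  expect_identical(apply_mask(img, full)$pixels, img)
  one <- matrix(FALSE, 32, 32); one[16, 16] <- TRUE
  out <- apply_mask(img, one)
  expect_equal(sum(out$pixels != -1000), 1L)
  expect_equal(out$pixels[16, 16], img[16, 16])
  expect_error(apply_mask(img, matrix(TRUE, 8, 8)), "shape mismatch")
})

test_that("align_pair inverts the simulated isocenter shift", {
  expect_identical(
    align_pair(hu_image(disk_image(32L)), hu_image(disk_image(32L)),
               c(0, 0))$cbct$pixels,
    disk_image(32L))

  spec <- simple_spec()
  ct <- generate_phantom(spec, seed = 12)
  body <- attr(ct, "body_mask")
  cbct <- apply_cbct_artifacts(ct, body, artifact_model(
    isocenter_offset = c(3, 0)), seed = 1)
  pair <- align_pair(cbct, ct, c(3, 0))
  c_ct <- colMeans(which(ct$pixels > -1000, arr.ind = TRUE))
  c_cb <- colMeans(which(pair$cbct$pixels > -1000, arr.ind = TRUE))
  expect_true(all(abs(c_ct - c_cb) <= 1))

  # full-width shift leaves pure air
  w <- ncol(ct$pixels)
  gone <- align_pair(ct, ct, c(w, 0))
  expect_true(all(gone$cbct$pixels == -1000))
  expect_error(align_pair(ct, ct, c(NA, 0)), "non-finite")
})

test_that("normalize/denormalize implement the documented linear map", {
  expect_equal(normalize_hu(matrix(-1024))[1], 0)
  expect_equal(normalize_hu(matrix(3200))[1], 1)
  expect_equal(normalize_hu(matrix(1088))[1], 0.5)
  expect_equal(normalize_hu(matrix(5000))[1], 1)  # clipped
  x <- matrix(seq(-1024, 3200, length.out = 100), 10)
  expect_equal(denormalize_hu(normalize_hu(x)), x, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(diff(normalize_hu(matrix(seq(-2000, 5000, by = 10)))) >= 0))
  expect_error(denormalize_hu(matrix(1.5)), "outside")
})

test_that("resampling preserves constants, identity, and geometry bookkeeping", {
  const <- hu_image(matrix(120, 64, 64), pixel_spacing = c(1, 1))
  small <- resample_slice(const, 32L)
  expect_equal(dim(small$pixels), c(32L, 32L))
  expect_equal(unique(round(as.numeric(small$pixels), 6)), 120)
  expect_equal(small$pixel_spacing, c(2, 2))
  same <- resample_slice(const, 64L)
  expect_identical(same$pixels, const$pixels)
  expect_error(resample_slice(const, 1L), "target_size")
})

test_that("augmentation group has 8 distinct elements and preserves pair correspondence", {
  spec <- simple_spec()
  ct <- generate_phantom(spec, seed = 3)
  body <- attr(ct, "body_mask")
  cbct <- apply_cbct_artifacts(ct, body, artifact_model(offset = 30), seed = 2)
  pair <- structure(list(ct = ct, cbct = cbct, subject_id = "S1",
                         isocenter_offset = c(0, 0), seed = 3L),
                    class = "paired_slice")
  # identity and involution
  expect_identical(augment_pair(pair, 0L, FALSE)$ct$pixels, ct$pixels)
  expect_identical(augment_pair(augment_pair(pair, 2L, FALSE), 2L,
                                FALSE)$ct$pixels, ct$pixels)
  # 8 distinct configurations
  outs <- list()
  for (k in 0:3) for (f in c(FALSE, TRUE))
    outs[[length(outs) + 1]] <- augment_pair(pair, k, f)$ct$pixels
  expect_length(unique(lapply(outs, identity)), 8L)
  # marker-pixel correspondence: the same transform hits both images
  mk <- pair
  mk$ct$pixels[10, 20] <- 3000
  mk$cbct$pixels[10, 20] <- 3000
  for (k in 0:3) for (f in c(FALSE, TRUE)) {
    tr <- augment_pair(mk, k, f)
    expect_identical(which(tr$ct$pixels == 3000),
                     which(tr$cbct$pixels == 3000))
  }
  expect_error(augment_pair(structure(list(
    ct = hu_image(matrix(0, 4, 6)), cbct = hu_image(matrix(0, 4, 6))),
    class = "paired_slice"), 1L, FALSE), "square")
})

test_that("masking and normalizing commute", {
  spec <- simple_spec()
  ct <- generate_phantom(spec, seed = 6)
  mask <- compute_body_mask(ct)[[1]]
  a <- normalize_hu(apply_mask(ct, mask))
  b <- normalize_hu(ct)
  b[!mask] <- normalize_hu(matrix(-1000))[1]
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-12)
})
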