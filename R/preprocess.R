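# Pre-processing pipeline: body masking (Otsu + largest component + fill
# holes + erosion), pair alignment from isocenter offsets, HU clipping and
# [0,1] normalization, bilinear resampling, and coherent pair augmentation.

NORM_RANGE <- HU_MAX - HU_MIN  # 4224

#' Compute per-slice body masks for a volume
#'
#' The threshold is chosen once by Otsu's criterion on the whole volume's
#' histogram. Per slice, the largest connected foreground component is kept
#' (removing couches and detached debris), interior holes are filled, and the
#' boundary halo is trimmed by a single 3x3 erosion.
#'
#' @param volume A list of [hu_image()] objects / matrices, a single matrix,
#'   or a 3D array (slices along the third dimension).
#' @param erode_iter Number of 3x3 erosion passes (default 1).
#' @return A list of logical matrices, one per slice (a single matrix input
#'   yields a list of length 1).
#' @export
compute_body_mask <- function(volume, erode_iter = 1L) {
  slices <- volume_slices(volume)
  if (length(slices) == 0L) stop("empty volume")
  all_px <- unlist(lapply(slices, identity), use.names = FALSE)
  if (max(all_px) - min(all_px) < 1e-8)
    stop("degenerate histogram: volume is constant, no Otsu threshold exists")
  scaled <- (clip_hu(all_px) - HU_MIN) / NORM_RANGE
  thr_scaled <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1),
                              levels = 256)
  thr <- thr_scaled * NORM_RANGE + HU_MIN

  kern <- EBImage::makeBrush(3, shape = "box")
  lapply(slices, function(px) {
    bw <- EBImage::Image(px > thr)
    lab <- EBImage::bwlabel(bw)
    labs <- as.integer(lab)
    labs <- labs[labs > 0L]
    if (length(labs) == 0L) stop("no foreground above the Otsu threshold")
    keep <- as.integer(names(which.max(table(labs))))
    comp <- EBImage::Image(matrix(as.integer(lab) == keep, nrow(px), ncol(px)))
    comp <- EBImage::fillHull(comp)
    for (i in seq_len(erode_iter)) comp <- EBImage::erode(comp, kern)
    matrix(as.logical(comp), nrow(px), ncol(px))
  })
}

volume_slices <- function(volume) {
  if (inherits(volume, "hu_image")) return(list(volume$pixels))
  if (is.matrix(volume)) return(list(volume))
  if (is.array(volume) && length(dim(volume)) == 3L)
    return(lapply(seq_len(dim(volume)[3]), function(i) volume[, , i]))
  lapply(volume, function(s) if (inherits(s, "hu_image")) s$pixels else s)
}

#' Apply a body mask to an image
#'
#' Pixels outside the mask are set to air (-1000 HU by default); pixels inside
#' are unchanged.
#'
#' @param image A [hu_image()] or matrix.
#' @param mask Logical matrix of the same shape.
#' @param background Fill value for masked-out pixels.
#' @return A [hu_image()].
#' @export
apply_mask <- function(image, mask, background = HU_AIR) {
  image <- as_hu_image(image)
  if (!all(dim(image$pixels) == dim(mask))) stop("image/mask shape mismatch")
  px <- image$pixels
  px[!mask] <- background
  hu_image(px, image$pixel_spacing, image$slice_thickness)
}

#' Rigidly align a CBCT slice to its CT using the isocenter offset
#'
#' The CBCT is translated by `-isocenter_offset` (mm converted to integer
#' pixels through the pixel spacing); vacated pixels are filled with air. No
#' interpolation or rotation is applied.
#'
#' @param cbct,ct [hu_image()] objects with identical pixel spacing.
#' @param isocenter_offset Numeric (dx, dy) in mm (dx = column, dy = row).
#' @param subject_id Optional identifier carried into the result.
#' @return A `paired_slice` with the aligned CBCT and untouched CT.
#' @export
align_pair <- function(cbct, ct, isocenter_offset, subject_id = NA_character_) {
  cbct <- as_hu_image(cbct); ct <- as_hu_image(ct)
  if (!isTRUE(all.equal(cbct$pixel_spacing, ct$pixel_spacing)))
    stop("pixel spacing mismatch between ct and cbct")
  if (any(!is.finite(isocenter_offset))) stop("non-finite isocenter offset")
  shift_px <- round(isocenter_offset / cbct$pixel_spacing)
  aligned <- shift_image(cbct$pixels, -shift_px, fill = HU_AIR)
  structure(list(ct = ct,
                 cbct = hu_image(aligned, cbct$pixel_spacing,
                                 cbct$slice_thickness),
                 subject_id = subject_id,
                 isocenter_offset = c(0, 0),
                 seed = NA_integer_),
            class = "paired_slice")
}

#' Normalize HU to the unit interval
#'
#' `y = (clip(x, -1024, 3200) + 1024) / 4224`, so -1024 maps to 0 and 3200 to
#' 1. [denormalize_hu()] inverts the map on `[0, 1]`.
#'
#' @param image A [hu_image()], matrix, or numeric array of HU values.
#' @return Object of the same shape with values in `[0, 1]` and attribute
#'   `"clip_range"` recording the provenance.
#' @export
normalize_hu <- function(image) {
  px <- if (inherits(image, "hu_image")) image$pixels else image
  y <- (clip_hu(px) - HU_MIN) / NORM_RANGE
  attr(y, "clip_range") <- c(HU_MIN, HU_MAX)
  y
}

#' @rdname normalize_hu
#' @param normalized Numeric values in `[0, 1]`.
#' @export
denormalize_hu <- function(normalized) {
  x <- if (inherits(normalized, "hu_image")) normalized$pixels else normalized
  if (min(x) < -1e-9 || max(x) > 1 + 1e-9)
    stop("denormalize input outside [0, 1]")
  x * NORM_RANGE + HU_MIN
}

#' Bilinearly resample a slice to a square target size
#'
#' @param image A [hu_image()] or matrix.
#' @param target_size Output pixels per side (>= 2).
#' @return A [hu_image()] with rescaled pixel spacing.
#' @export
resample_slice <- function(image, target_size = 256L) {
  if (target_size < 2L) stop("target_size must be >= 2")
  image <- as_hu_image(image)
  d <- dim(image$pixels)
  if (all(d == target_size)) return(image)
  out <- EBImage::resize(EBImage::Image(image$pixels), w = target_size,
                         h = target_size, filter = "bilinear")
  hu_image(matrix(as.numeric(out), target_size, target_size),
           image$pixel_spacing * d / target_size,
           image$slice_thickness)
}

rot90_mat <- function(px, k) {
  k <- k %% 4L
  for (i in seq_len(k)) px <- t(px)[rev(seq_len(ncol(px))), , drop = FALSE]
  px
}

flip_h_mat <- function(px) px[, rev(seq_len(ncol(px))), drop = FALSE]

#' Coherently augment a CT/CBCT pair
#'
#' Rotates both images by `rotation_k` quarter turns and optionally flips them
#' horizontally, applying the identical transform to CT and CBCT (and to any
#' attached masks) so pixel-wise correspondence is preserved. The eight
#' `(rotation_k, flip)` combinations form the full augmentation group.
#'
#' @param pair A `paired_slice`.
#' @param rotation_k Integer in `{0, 1, 2, 3}`: quarter turns
#'   (counter-clockwise).
#' @param flip Logical: horizontal flip applied after the rotation.
#' @return The transformed `paired_slice`.
#' @export
augment_pair <- function(pair, rotation_k = 0L, flip = FALSE) {
  stopifnot(inherits(pair, "paired_slice"))
  if (nrow(pair$ct$pixels) != ncol(pair$ct$pixels))
    stop("augmentation requires square images")
  tf <- function(px) {
    px <- rot90_mat(px, rotation_k)
    if (flip) px <- flip_h_mat(px)
    px
  }
  out <- pair
  out$ct$pixels <- tf(pair$ct$pixels)
  out$cbct$pixels <- tf(pair$cbct$pixels)
  for (a in c("body_mask", "cavity_mask")) {
    m <- attr(pair, a)
    if (!is.null(m) && is.matrix(m)) attr(out, a) <- tf(m)
  }
  out
}

# Simple rotation helper used internally (k counter-clockwise quarter turns).
# Implemented via transpose + row reversal; exactly involutive for k = 2.
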