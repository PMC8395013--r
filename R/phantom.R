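# Seeded pelvic-like digital phantom and parametric CBCT degradation model.
# HU conventions: air -1000, soft tissue around 0, trabecular/cortical bone
# 700-1200; everything is clipped to the working range [-1024, 3200].

HU_MIN <- -1024
HU_MAX <- 3200
HU_AIR <- -1000

clip_hu <- function(x) pmin(pmax(x, HU_MIN), HU_MAX)

#' 2D image in Hounsfield units
#'
#' Lightweight container pairing a pixel matrix with its geometry.
#'
#' @param pixels Numeric matrix of HU values.
#' @param pixel_spacing Length-2 numeric, mm per pixel along (x, y).
#' @param slice_thickness Slice thickness in mm.
#' @return An object of class `hu_image`.
#' @export
hu_image <- function(pixels, pixel_spacing = c(1, 1), slice_thickness = 3) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)),
            length(pixel_spacing) == 2L, all(pixel_spacing > 0))
  structure(list(pixels = pixels, pixel_spacing = as.numeric(pixel_spacing),
                 slice_thickness = as.numeric(slice_thickness)),
            class = "hu_image")
}

#' @export
print.hu_image <- function(x, ...) {
  cat(sprintf("<hu_image %dx%d px, %.2fx%.2f mm, slice %.2f mm, HU [%d, %d]>\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing[1],
              x$pixel_spacing[2], x$slice_thickness,
              round(min(x$pixels)), round(max(x$pixels))))
  invisible(x)
}

as_hu_image <- function(x, spacing = c(1, 1), thickness = 3) {
  if (inherits(x, "hu_image")) x else hu_image(x, spacing, thickness)
}

#' Specification of a synthetic pelvic slice
#'
#' Parameters of the anatomy model: an elliptical soft-tissue body on an air
#' background, with high-density bone structures and optional gas cavities.
#'
#' @param image_size Pixels per side (square image).
#' @param body_axes Semi-axes of the elliptical body, in pixels.
#' @param n_bone_structures Number of elliptical bone structures.
#' @param bone_hu_range HU interval for bone structures.
#' @param soft_tissue_hu_range HU interval for the body soft tissue.
#' @param gas_cavity_probability Probability that a slice carries a gas cavity.
#' @param gas_hu HU value of gas cavities (air, about -1000).
#' @param background_hu HU value outside the body (air).
#' @param texture_sigma_hu Standard deviation (HU) of the within-tissue
#'   Gaussian texture.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256L,
                         body_axes = c(96, 72),
                         n_bone_structures = 4L,
                         bone_hu_range = c(700, 1200),
                         soft_tissue_hu_range = c(-100, 100),
                         gas_cavity_probability = 0.3,
                         gas_hu = -1000,
                         background_hu = -1000,
                         texture_sigma_hu = 20) {
  spec <- structure(list(image_size = as.integer(image_size),
                         body_axes = as.numeric(body_axes),
                         n_bone_structures = as.integer(n_bone_structures),
                         bone_hu_range = as.numeric(bone_hu_range),
                         soft_tissue_hu_range = as.numeric(soft_tissue_hu_range),
                         gas_cavity_probability = gas_cavity_probability,
                         gas_hu = gas_hu,
                         background_hu = background_hu,
                         texture_sigma_hu = texture_sigma_hu),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(2 * spec$body_axes >= spec$image_size))
    stop("invalid phantom spec: body ellipse does not fit inside the image")
  if (min(spec$bone_hu_range) <= max(spec$soft_tissue_hu_range))
    stop("invalid phantom spec: bone HU must exceed soft-tissue HU")
  if (spec$gas_hu >= min(spec$soft_tissue_hu_range))
    stop("invalid phantom spec: gas HU must lie below soft-tissue HU")
  if (spec$gas_cavity_probability < 0 || spec$gas_cavity_probability > 1)
    stop("invalid phantom spec: gas_cavity_probability outside [0,1]")
  if (spec$texture_sigma_hu < 0)
    stop("invalid phantom spec: texture_sigma_hu must be >= 0")
  invisible(spec)
}

#' Parametric CBCT degradation operator
#'
#' Describes how a CT slice is corrupted into a CBCT-like slice: a linear HU
#' miscalibration (gain/offset), a low-frequency cupping depression toward the
#' body centre, beam-hardening brightening at the periphery, additive Gaussian
#' noise, field-of-view truncation, an optional anatomical mismatch of gas
#' cavities, and a rigid isocenter shift.
#'
#' @param gain Multiplicative HU miscalibration (1 = calibrated).
#' @param offset Additive HU shift.
#' @param cupping_amplitude HU depression at the body centre (A >= 0 cups).
#' @param hardening_amplitude HU brightening at the body periphery.
#' @param hardening_power Exponent of the radial rise of the hardening term.
#' @param noise_sigma Standard deviation (HU) of additive Gaussian noise.
#' @param fov_radius_fraction Fraction of the image half-width outside which
#'   content is truncated to background; must lie in (0, 1].
#' @param cavity_mismatch If `TRUE`, gas cavities are re-drawn independently of
#'   the CT (emulating day-to-day rectal gas changes).
#' @param isocenter_offset Integer (dx, dy) pixel shift applied to the CBCT.
#' @return An object of class `artifact_model`.
#' @export
artifact_model <- function(gain = 1, offset = 0,
                           cupping_amplitude = 0, hardening_amplitude = 0,
                           hardening_power = 6, noise_sigma = 0,
                           fov_radius_fraction = 1, cavity_mismatch = FALSE,
                           isocenter_offset = c(0, 0)) {
  if (fov_radius_fraction <= 0 || fov_radius_fraction > 1)
    stop("fov_radius_fraction must lie in (0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(gain = gain, offset = offset,
                 cupping_amplitude = cupping_amplitude,
                 hardening_amplitude = hardening_amplitude,
                 hardening_power = hardening_power,
                 noise_sigma = noise_sigma,
                 fov_radius_fraction = fov_radius_fraction,
                 cavity_mismatch = isTRUE(cavity_mismatch),
                 isocenter_offset = as.integer(round(isocenter_offset))),
            class = "artifact_model")
}

# Rasterize an ellipse on the pixel-centre grid.
ellipse_mask <- function(n_row, n_col, center, axes, angle = 0) {
  r <- matrix(seq_len(n_row), n_row, n_col) - center[1]
  cc <- matrix(seq_len(n_col), n_row, n_col, byrow = TRUE) - center[2]
  ca <- cos(angle); sa <- sin(angle)
  u <- ca * r + sa * cc
  v <- -sa * r + ca * cc
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

# Bone structures and gas cavities are sampled inside a shrunken copy of the
# body ellipse so they never cross the body boundary.
sample_inside_body <- function(center, axes, margin_frac) {
  repeat {
    u <- stats::runif(1, -1, 1); v <- stats::runif(1, -1, 1)
    if (u^2 + v^2 <= 1) break
  }
  center + c(u * axes[1], v * axes[2]) * (1 - margin_frac)
}

#' Generate a synthetic CT slice
#'
#' Deterministic function of `(spec, seed)`: renders an elliptical soft-tissue
#' body on an air background, places `n_bone_structures` elliptical bone
#' structures inside the body, optionally carves a gas cavity in the lower
#' body half (rectal gas), and adds Gaussian within-tissue texture. All values
#' are clipped to `[-1024, 3200]`.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @return A [hu_image()] with attribute `"body_mask"` (logical matrix) and
#'   `"cavity_mask"`.
#' @export
generate_phantom <- function(spec, seed = 1L) {
  validate_phantom_spec(spec)
  n <- spec$image_size
  with_seed(seed, {
    ctr <- c((n + 1) / 2, (n + 1) / 2)
    body <- ellipse_mask(n, n, ctr, spec$body_axes)
    img <- matrix(spec$background_hu, n, n)
    soft <- stats::runif(1, spec$soft_tissue_hu_range[1],
                         spec$soft_tissue_hu_range[2])
    img[body] <- soft
    if (spec$n_bone_structures > 0) {
      for (i in seq_len(spec$n_bone_structures)) {
        c_i <- sample_inside_body(ctr, spec$body_axes, margin_frac = 0.3)
        ax <- stats::runif(2, 0.06, 0.14) * mean(spec$body_axes)
        ang <- stats::runif(1, 0, pi)
        hu <- stats::runif(1, spec$bone_hu_range[1], spec$bone_hu_range[2])
        bone <- ellipse_mask(n, n, c_i, ax, ang) & body
        img[bone] <- hu
      }
    }
    cavity <- matrix(FALSE, n, n)
    if (stats::runif(1) < spec$gas_cavity_probability) {
      cavity <- draw_cavity(n, ctr, spec$body_axes, body)
      img[cavity] <- spec$gas_hu
    }
    if (spec$texture_sigma_hu > 0) {
      tex <- matrix(stats::rnorm(n * n, 0, spec$texture_sigma_hu), n, n)
      img[body] <- img[body] + tex[body]
    }
    out <- hu_image(clip_hu(img))
    attr(out, "body_mask") <- body
    attr(out, "cavity_mask") <- cavity
    out
  })
}

# A cavity is an ellipse in the lower half of the body (posterior rectum
# region), capped at ~6% of the body area (well under the 15% design bound).
draw_cavity <- function(n, ctr, body_axes, body) {
  c_i <- ctr + c(stats::runif(1, 0.25, 0.55) * body_axes[1],
                 stats::runif(1, -0.25, 0.25) * body_axes[2])
  ax <- stats::runif(2, 0.08, 0.16) * mean(body_axes)
  ellipse_mask(n, n, c_i, ax, stats::runif(1, 0, pi)) & body
}

# Body centroid and effective radius (mean of the principal semi-axes derived
# from the mask's second moments; for a perfect ellipse these equal the true
# semi-axes).
mask_geometry <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty body mask")
  ctr <- colMeans(idx)
  cov <- stats::cov(idx)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  semi_axes <- 2 * sqrt(pmax(ev, 0))
  list(centroid = ctr, R = mean(semi_axes))
}

#' Degrade a CT slice into a CBCT-like slice
#'
#' Applies, inside the body, the radial degradation field
#' `CBCT = gain * CT + offset - A * (1 - (r/R)^2) + B * (r/R)^p + noise`,
#' where `r` is the distance from the body centroid and `R` the body's
#' effective radius. Pixels beyond `fov_radius_fraction` of the image
#' half-width are truncated to background; with `cavity_mismatch` the gas
#' cavities are re-drawn under an independent sub-seed; the result is shifted
#' by `isocenter_offset` and clipped to `[-1024, 3200]`.
#'
#' @param ct A [hu_image()] or numeric matrix.
#' @param body_mask Logical matrix of the body region, same shape as `ct`.
#' @param model An [artifact_model()].
#' @param seed Integer seed driving noise and cavity re-draws.
#' @return A [hu_image()] of the degraded slice.
#' @export
apply_cbct_artifacts <- function(ct, body_mask, model, seed = 1L) {
  ct <- as_hu_image(ct)
  px <- ct$pixels
  if (!all(dim(px) == dim(body_mask))) stop("ct and body_mask shape mismatch")
  n_row <- nrow(px); n_col <- ncol(px)

  with_seed(seed, {
    if (model$cavity_mismatch) px <- redraw_cavities(px, body_mask)

    geo <- mask_geometry(body_mask)
    rr <- matrix(seq_len(n_row), n_row, n_col) - geo$centroid[1]
    cc <- matrix(seq_len(n_col), n_row, n_col, byrow = TRUE) - geo$centroid[2]
    rho <- sqrt(rr^2 + cc^2) / geo$R

    out <- px
    inside <- body_mask
    bias <- model$gain * px[inside] + model$offset -
      model$cupping_amplitude * (1 - pmin(rho[inside], 1)^2) +
      model$hardening_amplitude * pmin(rho[inside], 1)^model$hardening_power
    if (model$noise_sigma > 0)
      bias <- bias + stats::rnorm(sum(inside), 0, model$noise_sigma)
    out[inside] <- bias

    if (model$fov_radius_fraction < 1) {
      ictr <- c((n_row + 1) / 2, (n_col + 1) / 2)
      ir <- sqrt((matrix(seq_len(n_row), n_row, n_col) - ictr[1])^2 +
                 (matrix(seq_len(n_col), n_row, n_col, byrow = TRUE) - ictr[2])^2)
      out[ir > model$fov_radius_fraction * (min(n_row, n_col) / 2)] <- HU_AIR
    }

    out <- shift_image(out, model$isocenter_offset, fill = HU_AIR)
    hu_image(clip_hu(out), ct$pixel_spacing, ct$slice_thickness)
  })
}

# Replace gas already present inside the body with soft tissue, then carve a
# fresh cavity: count preserved (0 or 1), position and shape re-sampled.
redraw_cavities <- function(px, body_mask) {
  gas <- body_mask & (px <= -300)
  had_gas <- any(gas)
  if (had_gas) {
    fill_hu <- stats::median(px[body_mask & !gas])
    px[gas] <- fill_hu
    geo <- mask_geometry(body_mask)
    axes <- mask_geometry(body_mask)$R * c(1, 1)  # isotropic fallback
    cav <- draw_cavity(nrow(px), geo$centroid, c(geo$R, geo$R), body_mask)
    px[cav] <- HU_AIR
  }
  px
}

# Integer-pixel translation; vacated pixels take `fill`.
# offset = (dx, dy) = (column shift, row shift).
shift_image <- function(px, offset, fill = HU_AIR) {
  dx <- as.integer(round(offset[1])); dy <- as.integer(round(offset[2]))
  if (dx == 0L && dy == 0L) return(px)
  n_row <- nrow(px); n_col <- ncol(px)
  out <- matrix(fill, n_row, n_col)
  src_r <- seq_len(n_row) - dy
  src_c <- seq_len(n_col) - dx
  ok_r <- src_r >= 1L & src_r <= n_row
  ok_c <- src_c >= 1L & src_c <= n_col
  out[which(ok_r), which(ok_c)] <- px[src_r[ok_r], src_c[ok_c]]
  out
}

#' Generate a paired synthetic CT/CBCT dataset
#'
#' Draws one phantom spec and one artifact model per subject from the given
#' parameter ranges (intra-subject consistency), then renders
#' `slices_per_subject` paired slices per subject. Fully reproducible from
#' `seed`; slice-level sub-seeds are derived from (seed, subject, slice) so the
#' content of early subjects does not depend on the dataset size.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param slices_per_subject Slices per subject.
#' @param spec_ranges Named list of `c(lo, hi)` intervals overriding
#'   [phantom_spec()] defaults (e.g. `list(body_axes_x = c(80, 100))`).
#'   Recognised names: `body_axes_x`, `body_axes_y`, `soft_tissue_center`,
#'   `texture_sigma_hu`, `gas_cavity_probability`.
#' @param model_ranges Named list of `c(lo, hi)` intervals for
#'   [artifact_model()] fields (`gain`, `offset`, `cupping_amplitude`,
#'   `hardening_amplitude`, `noise_sigma`, `isocenter_dx`, `isocenter_dy`),
#'   plus scalars `fov_radius_fraction`, `cavity_mismatch_probability`.
#' @param image_size Pixels per side of every slice.
#' @param seed Integer master seed.
#' @return A list of `paired_slice` objects, each with fields `ct`, `cbct`,
#'   `subject_id`, `isocenter_offset`, `seed`, and attributes `"body_mask"`,
#'   `"cavity_mask"`.
#' @export
generate_dataset <- function(n_subjects, slices_per_subject,
                             spec_ranges = list(), model_ranges = list(),
                             image_size = 256L, seed = 1L) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  check_ranges <- function(rg) {
    for (nm in names(rg)) {
      v <- rg[[nm]]
      if (length(v) == 2L && is.numeric(v) && v[2] < v[1])
        stop("invalid config: empty range for '", nm, "'")
    }
  }
  check_ranges(spec_ranges); check_ranges(model_ranges)

  runif_range <- function(rg, nm, default) {
    v <- rg[[nm]]
    if (is.null(v)) default
    else if (length(v) == 1L) v
    else stats::runif(1, v[1], v[2])
  }

  dataset <- vector("list", n_subjects * slices_per_subject)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    subj_seed <- sub_seed(seed, s, 0L)
    subj <- with_seed(subj_seed, {
      ax <- c(runif_range(spec_ranges, "body_axes_x", image_size * 0.375),
              runif_range(spec_ranges, "body_axes_y", image_size * 0.28))
      st_c <- runif_range(spec_ranges, "soft_tissue_center", 0)
      spec <- phantom_spec(
        image_size = image_size, body_axes = ax,
        soft_tissue_hu_range = st_c + c(-100, 100),
        gas_cavity_probability =
          runif_range(spec_ranges, "gas_cavity_probability", 0.3),
        texture_sigma_hu = runif_range(spec_ranges, "texture_sigma_hu", 20))
      model <- artifact_model(
        gain = runif_range(model_ranges, "gain", 1),
        offset = runif_range(model_ranges, "offset", 0),
        cupping_amplitude = runif_range(model_ranges, "cupping_amplitude", 0),
        hardening_amplitude =
          runif_range(model_ranges, "hardening_amplitude", 0),
        noise_sigma = runif_range(model_ranges, "noise_sigma", 0),
        fov_radius_fraction =
          runif_range(model_ranges, "fov_radius_fraction", 1),
        cavity_mismatch = stats::runif(1) <
          (model_ranges$cavity_mismatch_probability %||% 0),
        isocenter_offset = c(
          round(runif_range(model_ranges, "isocenter_dx", 0)),
          round(runif_range(model_ranges, "isocenter_dy", 0))))
      list(spec = spec, model = model)
    })
    for (j in seq_len(slices_per_subject)) {
      sl_seed <- sub_seed(seed, s, j)
      ct <- generate_phantom(subj$spec, seed = sl_seed)
      body <- attr(ct, "body_mask")
      cbct <- apply_cbct_artifacts(ct, body, subj$model,
                                   seed = sub_seed(seed, s, j + 100000L))
      k <- k + 1L
      ps <- structure(list(ct = ct, cbct = cbct,
                           subject_id = sprintf("S%03d", s),
                           isocenter_offset = subj$model$isocenter_offset,
                           seed = sl_seed),
                      class = "paired_slice")
      attr(ps, "body_mask") <- body
      attr(ps, "cavity_mask") <- attr(ct, "cavity_mask")
      attr(ps, "artifact_model") <- subj$model
      dataset[[k]] <- ps
    }
  }
  dataset
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed from (seed, subject, slice); linear-congruential mix
# kept below 2^31.
sub_seed <- function(seed, subject, slice) {
  x <- (as.double(seed) %% 2147483647) * 2654435 + subject * 97561 + slice * 7919
  as.integer(x %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
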