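# Volume I/O (NIfTI), PNG previews, manifests, and weight checkpoints.

#' Read a volume from a NIfTI file
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A list of [hu_image()] slices (axial, third dimension).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (is.null(pd) || length(pd) < 2 || any(pd[1:2] <= 0)) {
    warning("missing or invalid geometry in ", path,
            "; defaulting to 1x1 mm pixels, 3 mm slices")
    pd <- c(1, 1, 3)
  }
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  # single-slice files legitimately drop the third dimension
  thickness <- if (length(pd) >= 3 && pd[3] > 0) pd[3] else 3
  lapply(seq_len(dim(arr)[3]), function(i)
    hu_image(arr[, , i], pixel_spacing = pd[1:2], slice_thickness = thickness))
}

#' Write a volume to a NIfTI file (16-bit signed integers)
#'
#' @param volume A list of [hu_image()] slices, a matrix, or a 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  slices <- volume_slices(volume)
  spacing <- if (inherits(volume, "hu_image")) volume$pixel_spacing
    else if (is.list(volume) && inherits(volume[[1]], "hu_image"))
      volume[[1]]$pixel_spacing else c(1, 1)
  thickness <- if (inherits(volume, "hu_image")) volume$slice_thickness
    else if (is.list(volume) && inherits(volume[[1]], "hu_image"))
      volume[[1]]$slice_thickness else 3
  arr <- array(0L, dim = c(dim(slices[[1]]), length(slices)))
  for (i in seq_along(slices)) arr[, , i] <- as.integer(round(slices[[i]]))
  hdr <- RNifti::niftiHeader(list(pixdim = c(-1, spacing, thickness,
                                             rep(0, 4))))
  img <- RNifti::asNifti(arr, hdr, datatype = "int16")
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Write an 8-bit PNG preview of a slice
#'
#' HU are windowed to `[-1024, 3200]` (the working range) unless a narrower
#' window is given.
#'
#' @param image A [hu_image()] or matrix.
#' @param path Output `.png` path.
#' @param window `c(lo, hi)` HU display window.
#' @return `path`, invisibly.
#' @export
write_preview <- function(image, path, window = c(HU_MIN, HU_MAX)) {
  px <- if (inherits(image, "hu_image")) image$pixels else image
  z <- (pmin(pmax(px, window[1]), window[2]) - window[1]) / diff(window)
  grDevices::png(path, width = ncol(z), height = nrow(z))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(t(z)[, rev(seq_len(nrow(z)))], col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, useRaster = TRUE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}

#' Save / load network weights
#'
#' Weights are serialized with a sidecar JSON recording the configuration and
#' the trainable-parameter count, so checkpoints are self-describing.
#'
#' @param model A generator or discriminator.
#' @param path Output `.rds` path (sidecar written as `<path>.json`).
#' @return `path`, invisibly.
#' @export
save_weights <- function(model, path) {
  saveRDS(get_weights(model), path)
  sidecar <- list(class = class(model)[1],
                  parameters = count_trainable_parameters(model),
                  config = unclass(model$config))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_weights
#' @param path Path written by [save_weights()].
#' @export
load_weights <- function(model, path) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  set_weights(model, readRDS(path))
  model$initialized <- TRUE
  invisible(model)
}

# Write a dataset of paired slices to disk: per-pair NIfTI files, optional
# previews, and a manifest CSV.
write_dataset <- function(dataset, out_dir, previews = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset), function(i) {
    p <- dataset[[i]]
    base <- sprintf("%s_slice%03d", p$subject_id, i)
    ct_path <- file.path(out_dir, paste0(base, "_ct.nii.gz"))
    cbct_path <- file.path(out_dir, paste0(base, "_cbct.nii.gz"))
    write_volume(p$ct, ct_path)
    write_volume(p$cbct, cbct_path)
    if (previews) {
      write_preview(p$ct, file.path(out_dir, paste0(base, "_ct.png")),
                    window = c(-1000, 1000))
      write_preview(p$cbct, file.path(out_dir, paste0(base, "_cbct.png")),
                    window = c(-1000, 1000))
    }
    am <- attr(p, "artifact_model")
    data.frame(subject_id = p$subject_id, slice = i,
               ct_path = ct_path, cbct_path = cbct_path,
               isocenter_dx = p$isocenter_offset[1],
               isocenter_dy = p$isocenter_offset[2],
               seed = p$seed,
               gain = am$gain %||% NA, offset = am$offset %||% NA,
               cupping_amplitude = am$cupping_amplitude %||% NA,
               hardening_amplitude = am$hardening_amplitude %||% NA,
               noise_sigma = am$noise_sigma %||% NA,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# Read a dataset back from a manifest directory.
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    ct <- read_volume(r$ct_path)[[1]]
    cbct <- read_volume(r$cbct_path)[[1]]
    ps <- structure(list(ct = ct, cbct = cbct, subject_id = r$subject_id,
                         isocenter_offset = c(r$isocenter_dx, r$isocenter_dy),
                         seed = r$seed),
                    class = "paired_slice")
    attr(ps, "body_mask") <- compute_body_mask(ct)[[1]]
    ps
  })
}
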