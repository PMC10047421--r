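#' CT display window
#'
#' A width/level pair in Hounsfield units defining the linear HU-to-display
#' mapping: `lower = level - width/2` maps to 0, `upper = level + width/2`
#' to 1, hard-clipped outside. The bone window used throughout is width
#' 1000 / level 600, which keeps rib cortex near the top of the range while
#' preserving surrounding soft tissue.
#'
#' @param width Window width in HU, > 0.
#' @param level Window level (centre) in HU.
#' @return An object of class `window_spec` with fields `width`, `level`,
#'   `lower`, `upper`.
#' @export
window_spec <- function(width = 1000, level = 600) {
  if (!is.finite(width) || !is.finite(level) || width <= 0) {
    stop("window width must be a positive finite HU value")
  }
  structure(list(width = width, level = level,
                 lower = level - width / 2, upper = level + width / 2),
            class = "window_spec")
}

#' Apply a display window to an HU image
#'
#' `clip((hu - (level - width/2)) / width, 0, 1)`, elementwise; monotone
#' non-decreasing in HU and idempotent composed with itself on the \[0, 1\]
#' scale (via the identity window).
#'
#' @param hu_image Numeric array of HU values (any shape); must be finite.
#' @param spec A [window_spec()].
#' @return Array of intensities in \[0, 1\], shape preserved.
#' @export
apply_window <- function(hu_image, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  if (!all(is.finite(hu_image))) {
    stop("hu_image contains non-finite values (NaN/Inf); clean the volume first")
  }
  out <- pmin(pmax((hu_image - spec$lower) / spec$width, 0), 1)
  dim(out) <- dim(hu_image)
  out
}

#' Extract and filter axial training slices from a volume
#'
#' Each axial slice of the mask volume is binarized (any positive label is
#' lesion) and kept iff it has at least `min_annotated_pixels` foreground
#' pixels -- small-area slices carry too little signal to train on. Kept
#' slices are windowed to \[0, 1\].
#'
#' @param volume 3D array of HU values.
#' @param mask_volume Congruent 3D array of lesion labels (any positive
#'   value is foreground).
#' @param spec A [window_spec()].
#' @param min_annotated_pixels Minimum lesion pixel count to retain a slice
#'   (default 100).
#' @param volume_id Identifier recorded on each extracted sample.
#' @return List of [slice_sample()] objects (possibly empty).
#' @export
extract_slices <- function(volume, mask_volume, spec = window_spec(),
                           min_annotated_pixels = 100L,
                           volume_id = "volume") {
  if (!identical(dim(volume), dim(mask_volume))) {
    stop("volume and mask_volume dimensions differ")
  }
  stopifnot(length(dim(volume)) == 3L, min_annotated_pixels >= 0)
  out <- list()
  for (k in seq_len(dim(volume)[3])) {
    m <- (mask_volume[, , k] > 0) + 0L
    if (sum(m) < min_annotated_pixels) next
    img <- apply_window(volume[, , k], spec)
    out[[length(out) + 1L]] <- slice_sample(img, m, volume_id,
                                            slice_index = k - 1L)
  }
  out
}

.sample_base <- function(s) sprintf("%s_s%04d", s$volume_id, s$slice_index)

#' Persist slices plus a tabular manifest
#'
#' Writes each image/mask pair as a lossless raster and a CSV manifest with
#' columns `volume_id`, `slice_index`, `n_lesion_pixels`, `image_path`,
#' `mask_path` (paths relative to `dir`). Format `"rds"` (default) is
#' bit-exact for floating-point images; `"png"` (8-bit, requires the `png`
#' package) is lossless for binary masks but quantizes images.
#'
#' @param samples List of [slice_sample()] objects.
#' @param dir Destination directory (created if needed).
#' @param format `"rds"` or `"png"`.
#' @return The number of records written.
#' @export
write_manifest <- function(samples, dir, format = c("rds", "png")) {
  format <- match.arg(format)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create manifest directory: ", dir)
  }
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    stopifnot(inherits(s, "slice_sample"))
    base <- .sample_base(s)
    ipath <- paste0(base, "_img.", format)
    mpath <- paste0(base, "_mask.", format)
    if (format == "rds") {
      saveRDS(s$image, file.path(dir, ipath))
      saveRDS(s$mask, file.path(dir, mpath))
    } else {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop("the 'png' package is required for format = 'png'")
      }
      png::writePNG(s$image, file.path(dir, ipath))
      png::writePNG(s$mask, file.path(dir, mpath))
    }
    rows[[i]] <- data.frame(volume_id = s$volume_id,
                            slice_index = s$slice_index,
                            n_lesion_pixels = sum(s$mask),
                            image_path = ipath, mask_path = mpath)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(volume_id = character(0), slice_index = integer(0),
               n_lesion_pixels = integer(0), image_path = character(0),
               mask_path = character(0))
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  nrow(manifest)
}

#' Read a manifest CSV
#'
#' @param path Path to `manifest.csv` (or its directory).
#' @return The manifest data frame with attribute `"dir"` set to the
#'   directory holding the rasters.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  attr(m, "dir") <- dirname(path)
  m
}

#' Load slice samples listed in a manifest
#'
#' @param manifest Data frame from [read_manifest()], or a path.
#' @return List of [slice_sample()] objects.
#' @export
load_samples <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir <- attr(manifest, "dir")
  read_raster <- function(p) {
    fp <- file.path(dir, p)
    if (grepl("\\.rds$", p)) readRDS(fp) else {
      a <- png::readPNG(fp)
      if (length(dim(a)) == 3L) a <- a[, , 1]
      a
    }
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_raster(manifest$image_path[i])
    msk <- read_raster(manifest$mask_path[i])
    slice_sample(img, (msk > 0.5) + 0L, manifest$volume_id[i],
                 manifest$slice_index[i])
  })
}

#' Preprocess a NIfTI volume/mask pair into a slice manifest
#'
#' Reads the two volumes, windows and filters slices via
#' [extract_slices()], and persists them with [write_manifest()].
#'
#' @param image_path,mask_path Paths to congruent `.nii`/`.nii.gz` files.
#' @param out_dir Destination directory.
#' @param spec A [window_spec()].
#' @param min_annotated_pixels Slice filter threshold (see
#'   [extract_slices()]).
#' @param format Raster format for [write_manifest()].
#' @return Number of slices written.
#' @export
preprocess_volume <- function(image_path, mask_path, out_dir,
                              spec = window_spec(),
                              min_annotated_pixels = 100L,
                              format = "rds") {
  vol <- read_nifti(image_path)$data
  msk <- read_nifti(mask_path)$data
  vid <- sub("\\.nii(\\.gz)?$", "", basename(image_path))
  samples <- extract_slices(vol, msk, spec, min_annotated_pixels, vid)
  write_manifest(samples, out_dir, format = format)
}
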