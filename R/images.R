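#' Intensity images
#'
#' An `intensity_image` is a plain numeric matrix of non-negative intensities,
#' indexed `[x, y]` (EBImage convention), carrying the physical pixel size in
#' micrometres as an attribute. A `fish_stack` is the 3-D analogue (x, y, z)
#' used for FISH z-stacks, with z-step metadata.
#'
#' @param pixels numeric matrix (or 3-D array for stacks) of intensities,
#'   all values >= 0.
#' @param pixel_size_um physical pixel size in micrometres (> 0).
#' @return An `intensity_image` object.
#' @export
intensity_image <- function(pixels, pixel_size_um) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(dim(pixels) < 16))
    stop("image dimensions must both be >= 16 pixels")
  if (any(pixels < 0)) stop("intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  structure(pixels, pixel_size_um = pixel_size_um, class = c("intensity_image", "matrix"))
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d px, %.3f um/px, range [%.3g, %.3g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"), min(x), max(x)))
  invisible(x)
}

pixel_size <- function(img) {
  ps <- attr(img, "pixel_size_um")
  if (is.null(ps)) stop("image carries no pixel_size_um attribute")
  ps
}

as_plain_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "pixel_size_um") <- NULL
  m
}

#' Read a single-plane or multi-page TIFF image
#'
#' 8/16-bit integer TIFFs are mapped to non-negative reals (EBImage scales to
#' \[0, 1\]; values are kept on that scale). Multi-page files become a
#' `fish_stack`-style 3-D array.
#'
#' @param path path to a TIFF file.
#' @param pixel_size_um physical pixel size in micrometres.
#' @param z_step_um z spacing for multi-page stacks (ignored for single planes).
#' @return An `intensity_image` (single page) or a 3-D array with attributes
#'   `pixel_size_um` and `z_step_um` (multi-page).
#' @export
read_intensity_image <- function(path, pixel_size_um, z_step_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2) {
    intensity_image(dat, pixel_size_um)
  } else {
    structure(dat, pixel_size_um = pixel_size_um,
              z_step_um = if (is.null(z_step_um)) NA_real_ else z_step_um,
              class = "fish_stack_array")
  }
}

#' Write an intensity image, mask, or label matrix as TIFF
#'
#' Intensities are rescaled to the unit range expected by TIFF writers; masks
#' are written as 8-bit, labels and images as 16-bit.
#'
#' @param x matrix (image, binary mask, or integer labels) or 3-D array.
#' @param path output path.
#' @param kind one of `"image"`, `"mask"`, `"labels"`.
#' @return `path`, invisibly.
#' @export
write_intensity_image <- function(x, path, kind = c("image", "mask", "labels")) {
  kind <- match.arg(kind)
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m))
  scale <- switch(kind,
                  image = if (max(m) > 0) max(m) else 1,
                  mask = 1,
                  labels = 65535)
  bits <- if (kind == "mask") 8L else 16L
  EBImage::writeImage(EBImage::Image(m / scale), path, type = "tiff",
                      bits.per.sample = bits)
  invisible(path)
}
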