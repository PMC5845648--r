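#' Calibrated RGB brightfield slide image
#'
#' Container for one scanned, chromogen-stained section: an 8-bit-per-channel
#' RGB pixel grid plus the microns-per-pixel calibration that converts pixel
#' measurements into physical units. All downstream modules (stain
#' separation, tissue masking, signal quantification) consume this type.
#'
#' @param pixels numeric `H x W x 3` array with values in `[0, 255]`.
#' @param mpp microns per pixel, a single positive number.
#' @param slide_id character identifier for the section.
#' @param marker stained marker name, e.g. `"CD90"` or `"CD117"`.
#'
#' @return An object of class `rgb_slide` with elements `pixels`, `mpp`,
#'   `slide_id`, `marker`.
#' @export
#' @examples
#' px <- array(255, dim = c(4, 4, 3))
#' rgb_slide(px, mpp = 0.5, slide_id = "demo", marker = "CD90")
rgb_slide <- function(pixels, mpp, slide_id = "slide", marker = "") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("slide must have at least one pixel", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0)
    stop("`mpp` must be a single positive number", call. = FALSE)
  structure(
    list(pixels = pixels, mpp = as.numeric(mpp),
         slide_id = as.character(slide_id), marker = as.character(marker)),
    class = "rgb_slide")
}

#' @export
print.rgb_slide <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_slide> %s [%s]  %d x %d px @ %.3g um/px (%.2f x %.2f mm)\n",
              x$slide_id, x$marker, d[1], d[2], x$mpp,
              d[1] * x$mpp / 1000, d[2] * x$mpp / 1000))
  invisible(x)
}

#' @export
dim.rgb_slide <- function(x) dim(x$pixels)

#' Read an 8-bit RGB PNG as a calibrated slide
#'
#' The scanner's proprietary container is out of scope; slides are exchanged
#' as plain 8-bit RGB PNG with the spatial calibration supplied alongside
#' (it is not stored in PNG headers).
#'
#' @param path PNG file path.
#' @inheritParams rgb_slide
#' @return An [rgb_slide].
#' @export
read_slide_png <- function(path, mpp, slide_id = NULL, marker = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), dim = c(dim(img)[1:2], 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  px <- round(img * 255)
  if (is.null(slide_id)) slide_id <- sub("\\.png$", "", basename(path))
  rgb_slide(px, mpp = mpp, slide_id = slide_id, marker = marker)
}

#' Write a slide (or any image array/matrix) as PNG
#'
#' Matrices are written as single-channel images; values are expected on the
#' `[0, 255]` scale for integer-like input, otherwise they are rescaled to
#' the data range. Used for debug output of per-stain concentration maps and
#' for label images.
#'
#' @param x an [rgb_slide], an `H x W x 3` array on `[0, 255]`, or a matrix.
#' @param path output path.
#' @param rescale logical; rescale a numeric matrix to its data range.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path, rescale = FALSE) {
  if (inherits(x, "rgb_slide")) x <- x$pixels
  if (is.logical(x)) x <- matrix(as.numeric(x) * 255, nrow(x), ncol(x))
  if (rescale) {
    rng <- range(x)
    x <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) else x * 0
  } else {
    x <- x / 255
  }
  png::writePNG(pmin(pmax(x, 0), 1), target = path)
  invisible(path)
}
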