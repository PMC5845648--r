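#' Tissue mask for one section
#'
#' @param mask logical `H x W` matrix, `TRUE` on tissue.
#' @param mpp microns per pixel.
#' @return Object of class `tissue_mask` with elements `mask`,
#'   `tissue_area_px` (number of `TRUE` entries) and `mpp`.
#' @export
tissue_mask <- function(mask, mpp) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  structure(list(mask = mask, tissue_area_px = sum(mask),
                 mpp = as.numeric(mpp)),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %d x %d px, tissue %d px (%.3f mm^2)\n",
              nrow(x$mask), ncol(x$mask), x$tissue_area_px,
              tissue_area_mm2(x)))
  invisible(x)
}

#' Tissue area in square millimetres
#' @param tissue a [tissue_mask].
#' @return scalar area in mm^2 (`tissue_area_px * mpp^2 * 1e-6`).
#' @export
tissue_area_mm2 <- function(tissue) {
  tissue$tissue_area_px * tissue$mpp^2 * 1e-6
}

#' Otsu threshold of a numeric vector
#'
#' Maximises between-class variance over a 256-bin histogram of the data
#' range. Deterministic; used to split stained tissue from bright glass.
#'
#' @param x numeric values.
#' @param n_bins histogram resolution.
#' @return Threshold on the scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(
    as.integer((x - rng[1]) / diff(rng) * n_bins) + 1L, 1L), n_bins), n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  # between-class variance at each cut
  sb <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  mids[which.max(sb)]
}

#' Segment tissue foreground from bright background
#'
#' Stage one of the whole-slide rule set: pixels whose total stain uptake
#' (hematoxylin + chromogen OD) exceeds a data-driven threshold are tissue.
#' The threshold is Otsu's cut on the summed concentration image, floored
#' at `min_od` so a slide with no tissue at all yields an empty mask rather
#' than a noise split. Holes (e.g. vessel lumina) are filled and connected
#' components smaller than `min_tissue_fragment_um2` are dropped as debris.
#'
#' @param slide an [rgb_slide] (used for its `mpp`).
#' @param stain_maps `stain_maps` aligned with the slide.
#' @param min_od absolute OD floor for the foreground threshold.
#' @param min_tissue_fragment_um2 smallest fragment kept, in square microns.
#' @param fill_holes fill enclosed background before filtering.
#' @return A [tissue_mask] (pre edge-exclusion).
#' @export
segment_tissue <- function(slide, stain_maps, min_od = 0.05,
                           min_tissue_fragment_um2 = 500,
                           fill_holes = TRUE) {
  total <- stain_maps$hematoxylin + stain_maps$chromogen
  if (!identical(dim(total), dim(slide$pixels)[1:2]))
    stop("stain maps are not aligned with the slide", call. = FALSE)
  thr <- max(otsu_threshold(total), min_od)
  m <- total > thr
  if (!any(m)) return(tissue_mask(m, slide$mpp))
  if (fill_holes) m <- .fill_holes_cpp(m)
  min_px <- max(1L, as.integer(round(min_tissue_fragment_um2 / slide$mpp^2)))
  lab <- .cc_label_cpp(m, 8L)
  n <- attr(lab, "n_components")
  if (n > 0L) {
    sizes <- tabulate(lab[lab > 0L], n)
    keep <- which(sizes >= min_px)
    m <- matrix(lab %in% keep & lab > 0L, nrow(m), ncol(m))
  }
  tissue_mask(m, slide$mpp)
}

#' Exclude a border zone along the tissue edge
#'
#' Tissue along the section edge carries cutting and staining artifacts, so
#' a margin is removed before any measurement: the mask is eroded by a
#' discrete disc of radius `round(margin_um / mpp)` pixels. Every
#' downstream metric uses the post-exclusion area as its denominator.
#'
#' The `"square"` element (Chebyshev ball) exists for analytic tests where
#' the erosion of a rectangle has a closed form.
#'
#' @param tissue a [tissue_mask].
#' @param margin_um margin width in microns, `>= 0`.
#' @param element structuring element, `"disc"` (default) or `"square"`.
#' @return Eroded [tissue_mask]; always a subset of the input mask.
#' @export
exclude_edge <- function(tissue, margin_um, element = c("disc", "square")) {
  element <- match.arg(element)
  if (!is.numeric(margin_um) || length(margin_um) != 1L || is.na(margin_um) ||
      margin_um < 0)
    stop("parameter error: margin_um must be a single number >= 0",
         call. = FALSE)
  r <- as.integer(round(margin_um / tissue$mpp))
  if (r == 0L || tissue$tissue_area_px == 0L)
    return(tissue_mask(tissue$mask, tissue$mpp))
  m <- tissue$mask
  if (element == "disc") {
    d2 <- .edt_sq_cpp(m)          # squared distance to nearest background
    out <- m & (d2 > r * r)       # disc of radius r fits entirely inside
  } else {
    out <- .erode_square(m, r)
  }
  tissue_mask(out, tissue$mpp)
}

# erosion by a (2r+1) square via separable running minima
.erode_square <- function(m, r) {
  shrink_1d <- function(mat, r) {
    out <- mat
    for (k in seq_len(r)) {
      nr <- nrow(mat)
      up <- rbind(mat[-1, , drop = FALSE], FALSE)
      dn <- rbind(FALSE, mat[-nr, , drop = FALSE])
      mat <- mat & up & dn
    }
    mat
  }
  m <- shrink_1d(m, r)
  t(shrink_1d(t(m), r))
}

#' Write a tissue mask as PNG with a JSON sidecar
#'
#' @param tissue a [tissue_mask].
#' @param path output PNG path (0/255); a `.json` sidecar with
#'   `slide_id`, `tissue_area_px`, `tissue_area_mm2`, `margin_um` is written
#'   alongside.
#' @param slide_id,margin_um provenance recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_mask <- function(tissue, path, slide_id = "slide", margin_um = NA) {
  write_image_png(tissue$mask, path)
  side <- sub("\\.png$", ".json", path)
  jsonlite::write_json(
    list(slide_id = slide_id, tissue_area_px = tissue$tissue_area_px,
         tissue_area_mm2 = tissue_area_mm2(tissue), margin_um = margin_um),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
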