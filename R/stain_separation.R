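#' Stain basis for optical-density colour deconvolution
#'
#' Beer-Lambert absorbance adds linearly in optical density (OD), so an RGB
#' pixel of a two-stain chromogenic slide is modelled as
#' `OD = M %*% c`, where the columns of `M` are the unit OD vectors of the
#' hematoxylin counterstain, the AEC chromogen, and a residual direction
#' completing an orthogonal complement. Solving this 3x3 system per pixel
#' yields per-stain concentration maps.
#'
#' Defaults are the standard published brightfield vectors for this stain
#' pair: hematoxylin `(0.650, 0.704, 0.286)` and AEC `(0.274, 0.679, 0.680)`,
#' renormalised to unit length. The residual is the unit cross product of
#' the two, so it is orthogonal to both.
#'
#' @param hematoxylin,chromogen numeric length-3 OD vectors (any positive
#'   scale; they are renormalised).
#' @return An object of class `stain_basis`: list with unit vectors
#'   `hematoxylin`, `chromogen`, `residual` and the 3x3 matrix `M`.
#' @export
#' @examples
#' b <- stain_basis()
#' crossprod(b$residual, b$hematoxylin)  # ~0: orthogonal complement
stain_basis <- function(hematoxylin = c(0.650, 0.704, 0.286),
                        chromogen = c(0.274, 0.679, 0.680)) {
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n == 0) stop("stain vector must be nonzero", call. = FALSE)
    v / n
  }
  h <- unit(as.numeric(hematoxylin))
  a <- unit(as.numeric(chromogen))
  ang <- acos(pmin(1, abs(sum(h * a)))) * 180 / pi
  if (ang <= 1)
    stop("stain vectors are collinear (angle <= 1 degree): basis is singular",
         call. = FALSE)
  r <- unit(c(h[2] * a[3] - h[3] * a[2],
              h[3] * a[1] - h[1] * a[3],
              h[1] * a[2] - h[2] * a[1]))
  M <- cbind(hematoxylin = h, chromogen = a, residual = r)
  structure(list(hematoxylin = h, chromogen = a, residual = r, M = M),
            class = "stain_basis")
}

#' @export
print.stain_basis <- function(x, ...) {
  cat("<stain_basis>\n")
  print(round(x$M, 4))
  invisible(x)
}

#' Convert RGB intensities to optical density
#'
#' Per channel, `OD = -log10((I + 1) / (I0 + 1))` against the white
#' reference `I0`. The +1 offset keeps the result finite at intensity 0 on
#' 8-bit data; OD is 0 where a pixel equals the background and positive
#' where it is darker.
#'
#' @param slide an [rgb_slide] (or a bare `H x W x 3` array on `[0, 255]`).
#' @param background_intensity length-3 white reference, components in
#'   `(0, 255]`; see [estimate_background()].
#' @return `H x W x 3` numeric array of optical densities.
#' @export
rgb_to_od <- function(slide, background_intensity) {
  px <- if (inherits(slide, "rgb_slide")) slide$pixels else slide
  i0 <- as.numeric(background_intensity)
  if (length(i0) != 3L || anyNA(i0) || any(i0 <= 0) || any(i0 > 255))
    stop("background intensity must be a 3-vector in (0, 255]", call. = FALSE)
  od <- px
  for (ch in 1:3) od[, , ch] <- -log10((px[, , ch] + 1) / (i0[ch] + 1))
  od
}

#' Estimate the white reference of a brightfield slide
#'
#' The background (glass) of a brightfield scan is the brightest, most
#' common content outside the tissue. The white reference is taken as a
#' per-channel quantile of the pixels whose luminance exceeds a brightness
#' floor, which is robust even when tissue occupies most of the frame. The
#' floor does the work of rejecting tissue, so the default quantile is the
#' median of the remaining bright pixels: unlike an extreme quantile it is
#' unbiased under camera noise (a 99th percentile sits ~2.3 noise sd above
#' the true illumination).
#'
#' @param slide an [rgb_slide].
#' @param luminance_floor minimum Rec.601 luminance for a pixel to count as
#'   candidate background (default 200 of 255).
#' @param probs quantile used per channel (default 0.5).
#' @return Length-3 numeric white reference in `(0, 255]`.
#' @export
estimate_background <- function(slide, luminance_floor = 200, probs = 0.5) {
  px <- slide$pixels
  lum <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  keep <- lum > luminance_floor
  if (!any(keep))
    stop("calibration error: no pixel brighter than the luminance floor (",
         luminance_floor, ")", call. = FALSE)
  i0 <- vapply(1:3, function(ch) {
    v <- px[, , ch][keep]
    as.numeric(quantile(v, probs = probs, names = FALSE, type = 7))
  }, numeric(1))
  pmin(pmax(i0, 1e-6), 255)
}

#' Deconvolve an OD image into per-stain concentration maps
#'
#' Solves `OD = M %*% c` per pixel for the concentration triple `c`
#' (hematoxylin, chromogen, residual). Concentrations are physical
#' quantities, so negatives arising from noise are clipped to zero; the
#' unclipped solution is retained in the `preclip` attribute so the exact
#' round trip `M %*% c == OD` remains checkable.
#'
#' @param od_image `H x W x 3` optical-density array from [rgb_to_od()].
#' @param basis a [stain_basis()].
#' @param background_intensity optional length-3 white reference carried
#'   along for provenance.
#' @return Object of class `stain_maps`: list with `H x W` matrices
#'   `hematoxylin`, `chromogen`, `residual`, plus `background_intensity`
#'   and `basis`. Attribute `preclip` holds the unclipped `H x W x 3` array.
#' @export
deconvolve <- function(od_image, basis = stain_basis(),
                       background_intensity = c(255, 255, 255)) {
  if (!inherits(basis, "stain_basis"))
    stop("`basis` must be a stain_basis object", call. = FALSE)
  M <- basis$M
  if (abs(det(M)) < 1e-12)
    stop("basis error: stain matrix is singular", call. = FALSE)
  d <- dim(od_image)
  flat <- matrix(od_image, nrow = d[1] * d[2], ncol = 3)  # N x 3
  conc <- flat %*% t(solve(M))                            # N x 3, c = M^-1 od
  preclip <- array(conc, dim = d)
  clip <- pmax(conc, 0)
  out <- structure(
    list(hematoxylin = matrix(clip[, 1], d[1], d[2]),
         chromogen   = matrix(clip[, 2], d[1], d[2]),
         residual    = matrix(clip[, 3], d[1], d[2]),
         background_intensity = as.numeric(background_intensity),
         basis = basis),
    class = "stain_maps")
  attr(out, "preclip") <- preclip
  out
}

#' @export
print.stain_maps <- function(x, ...) {
  cat(sprintf("<stain_maps> %d x %d px; chromogen OD range [%.3f, %.3f]\n",
              nrow(x$chromogen), ncol(x$chromogen),
              min(x$chromogen), max(x$chromogen)))
  invisible(x)
}

#' One-call stain separation for a slide
#'
#' Convenience composition: estimate the white reference, convert to OD,
#' deconvolve with the given basis.
#'
#' @inheritParams rgb_to_od
#' @inheritParams deconvolve
#' @return A `stain_maps` object.
#' @export
separate_stains <- function(slide, basis = stain_basis()) {
  i0 <- estimate_background(slide)
  od <- rgb_to_od(slide, i0)
  deconvolve(od, basis, background_intensity = i0)
}
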