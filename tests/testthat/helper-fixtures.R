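# Shared fixtures, all generated in code.

# a fast phantom for unit tests: 256 px @ 1 um/px, tissue disc r = 100 um
small_spec <- function(seed = 1L, ...) {
  defaults <- list(height_px = 256L, width_px = 256L, mpp = 1,
                   tissue_radius_um = 122, n_single_signals = 6L,
                   n_cluster_signals = 2L, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_spec, args)
}

# wrap bare matrices as a stain_maps object (for tests that bypass
# deconvolution and feed concentration maps directly)
make_stain_maps <- function(chromogen, hematoxylin = NULL) {
  if (is.null(hematoxylin))
    hematoxylin <- matrix(0, nrow(chromogen), ncol(chromogen))
  structure(list(hematoxylin = hematoxylin, chromogen = chromogen,
                 residual = matrix(0, nrow(chromogen), ncol(chromogen)),
                 background_intensity = c(255, 255, 255),
                 basis = stain_basis()),
            class = "stain_maps")
}

# an asymmetric lobed tissue blob (rotation-identifiable), as a tissue_mask
make_blob_mask <- function(nr = 200L, nc = 200L, mpp = 2) {
  x <- matrix((seq_len(nc) - 0.5) * mpp, nr, nc, byrow = TRUE)
  y <- matrix((seq_len(nr) - 0.5) * mpp, nr, nc)
  ctr <- c(nc, nr) * mpp / 2
  R <- 0.3 * nr * mpp
  m <- ((x - ctr[1])^2 + (y - ctr[2])^2 <= R^2) |
    ((x - ctr[1] - 0.7 * R)^2 + (y - ctr[2] - 0.2 * R)^2 <= (0.45 * R)^2) |
    ((x - ctr[1] + 0.55 * R)^2 + (y - ctr[2] - 0.5 * R)^2 <= (0.3 * R)^2)
  tissue_mask(m, mpp)
}

# uniform-colour slide
flat_slide <- function(rgb = c(255, 255, 255), n = 64L, mpp = 1) {
  px <- array(rep(rgb, each = n * n), dim = c(n, n, 3))
  rgb_slide(px, mpp = mpp, slide_id = "flat")
}
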