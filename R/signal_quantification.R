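#' Default signal-detection parameters
#'
#' Scales are set by the cardiomyocyte/interstitium geometry of myocardial
#' biopsies: a nominal single cell occupies ~150 um^2, so anything above
#' about two cell areas, or containing two distinct intensity peaks, is a
#' concatenation of signals rather than a single one.
#'
#' @param positivity_od chromogen OD at/above which a pixel is positive
#'   (fixed default 0.15 for reproducibility).
#' @param adaptive use a per-slide Otsu cut (restricted to tissue pixels
#'   with chromogen OD > 0.02) instead of the fixed threshold, mirroring a
#'   "relative intensity" judgement.
#' @param min_signal_area_um2 smallest detection kept.
#' @param concat_area_threshold_um2 area above which a component is
#'   classified as concatenated outright (~2 cells).
#' @param min_peak_separation_um minimum distance between two intensity
#'   maxima for them to count as distinct signals.
#' @param peak_rel_prominence secondary peaks below this fraction of the
#'   component maximum are ignored (noise guard).
#' @return Named list of parameters.
#' @export
signal_params <- function(positivity_od = 0.15, adaptive = FALSE,
                          min_signal_area_um2 = 20,
                          concat_area_threshold_um2 = 300,
                          min_peak_separation_um = 5,
                          peak_rel_prominence = 0.5) {
  list(positivity_od = positivity_od, adaptive = adaptive,
       min_signal_area_um2 = min_signal_area_um2,
       concat_area_threshold_um2 = concat_area_threshold_um2,
       min_peak_separation_um = min_peak_separation_um,
       peak_rel_prominence = peak_rel_prominence)
}

#' Detect chromogen-positive signals inside the tissue mask
#'
#' Thresholds the chromogen concentration map at the positivity cut,
#' intersects with the (post-exclusion) tissue mask, labels 8-connected
#' components and drops those below the minimum area. Deterministic for
#' fixed input and parameters.
#'
#' @param stain_maps `stain_maps` for the slide.
#' @param tissue [tissue_mask] (after [exclude_edge()]).
#' @param params list from [signal_params()].
#' @return `data.frame` of signal components: `component_id`, `area_px`,
#'   `centroid_row`, `centroid_col`, `mean_chromogen`, `n_peaks`,
#'   `signal_class` (`NA` until [split_single_concatenated()]).
#'   Attributes: `labels` (integer `H x W` label matrix), `mpp`,
#'   `threshold_od`.
#' @export
detect_signals <- function(stain_maps, tissue, params = signal_params()) {
  if (tissue$tissue_area_px == 0L)
    stop(errorCondition("no tissue: the tissue mask is empty",
                        class = "cpcquant_degenerate_error"))
  chrom <- stain_maps$chromogen
  thr <- params$positivity_od
  if (isTRUE(params$adaptive)) {
    cand <- chrom[tissue$mask & chrom > 0.02]
    if (length(cand) > 1L && diff(range(cand)) > 0)
      thr <- otsu_threshold(cand)
  }
  pos <- (chrom >= thr) & tissue$mask
  lab <- .cc_label_cpp(pos, 8L)
  n <- attr(lab, "n_components")
  min_px <- max(1L, as.integer(round(params$min_signal_area_um2 /
                                       tissue$mpp^2)))
  comps <- .component_table(lab, n, chrom, min_px)
  # relabel kept components 1..k in the label image
  keep_map <- integer(n)
  keep_map[comps$orig_label] <- seq_len(nrow(comps))
  lab_flat <- as.integer(lab)
  kept <- lab_flat > 0L
  lab_flat[kept] <- keep_map[lab_flat[kept]]
  lab <- matrix(lab_flat, nrow(chrom), ncol(chrom))
  comps$orig_label <- NULL
  structure(comps,
            labels = lab, mpp = tissue$mpp, threshold_od = thr)
}

.component_table <- function(lab, n, chrom, min_px) {
  empty <- data.frame(component_id = integer(), area_px = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      mean_chromogen = numeric(), n_peaks = integer(),
                      signal_class = character(), orig_label = integer(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  idx <- which(lab > 0L)
  l <- lab[idx]
  sizes <- tabulate(l, n)
  keep <- which(sizes >= min_px)
  if (length(keep) == 0L) return(empty)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  sum_r <- rowsum(as.numeric(rows), l)[, 1]
  sum_c <- rowsum(as.numeric(cols), l)[, 1]
  sum_v <- rowsum(chrom[idx], l)[, 1]
  labs_present <- as.integer(rownames(rowsum(as.numeric(rows), l)))
  ord <- match(keep, labs_present)
  data.frame(
    component_id = seq_along(keep),
    area_px = sizes[keep],
    centroid_row = sum_r[ord] / sizes[keep],
    centroid_col = sum_c[ord] / sizes[keep],
    mean_chromogen = sum_v[ord] / sizes[keep],
    n_peaks = NA_integer_,
    signal_class = NA_character_,
    orig_label = keep,
    stringsAsFactors = FALSE)
}

# 3x3 box smoothing (edge-replicated), applied `times` times
.box_smooth <- function(m, times = 2L) {
  pad <- function(x) rbind(x[1, , drop = FALSE], x, x[nrow(x), , drop = FALSE])
  for (k in seq_len(times)) {
    p <- pad(m)
    v <- (p[1:nrow(m), , drop = FALSE] + p[2:(nrow(m) + 1), , drop = FALSE] +
            p[3:(nrow(m) + 2), , drop = FALSE])
    p <- t(pad(t(v)))
    m <- (p[, 1:ncol(m), drop = FALSE] + p[, 2:(ncol(m) + 1), drop = FALSE] +
            p[, 3:(ncol(m) + 2), drop = FALSE]) / 9
  }
  m
}

# count intensity peaks of one component given its bounding-box crop
.count_peaks <- function(crop, inside, min_sep_px, rel_prominence) {
  sm <- .box_smooth(crop, 2L)
  sm[!inside] <- -Inf
  nr <- nrow(sm); nc <- ncol(sm)
  if (nr < 3L || nc < 3L) return(1L)
  ctr <- sm[2:(nr - 1), 2:(nc - 1)]
  is_max <- ctr > -Inf
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- sm[2:(nr - 1) + dr, 2:(nc - 1) + dc]
    is_max <- is_max & (ctr >= nb) & !(ctr == nb & (dr < 0 | (dr == 0 & dc < 0)))
  }
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(1L)
  vals <- ctr[is_max]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  keep_rc <- cand[1, , drop = FALSE]
  vmax <- vals[1]
  for (i in seq_len(nrow(cand))[-1]) {
    if (vals[i] < rel_prominence * vmax) break
    d2 <- (keep_rc[, 1] - cand[i, 1])^2 + (keep_rc[, 2] - cand[i, 2])^2
    if (all(d2 >= min_sep_px^2)) keep_rc <- rbind(keep_rc, cand[i, ])
  }
  nrow(keep_rc)
}

#' Classify detected signals as single or concatenated
#'
#' A component is "concatenated" if its area exceeds
#' `concat_area_threshold_um2` (it cannot be one cell), or if its chromogen
#' map holds two or more regional intensity maxima at least
#' `min_peak_separation_um` apart (several touching cells of ordinary
#' size). Everything else is a "single" signal. Each component receives
#' exactly one class.
#'
#' @param components output of [detect_signals()].
#' @param stain_maps the same `stain_maps` used for detection.
#' @param params list from [signal_params()].
#' @return The component table with `n_peaks` and `signal_class` filled in.
#' @export
split_single_concatenated <- function(components, stain_maps,
                                      params = signal_params()) {
  lab <- attr(components, "labels")
  mpp <- attr(components, "mpp")
  chrom <- stain_maps$chromogen
  concat_px <- params$concat_area_threshold_um2 / mpp^2
  sep_px <- max(1, params$min_peak_separation_um / mpp)
  n <- nrow(components)
  if (n == 0L) return(components)
  idx <- which(lab > 0L)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  l <- lab[idx]
  for (i in seq_len(n)) {
    sel <- l == i
    r0 <- range(rows[sel]); c0 <- range(cols[sel])
    # pad the crop by 1 px so border pixels have neighbours
    r1 <- max(1L, r0[1] - 1L); r2 <- min(nrow(lab), r0[2] + 1L)
    c1 <- max(1L, c0[1] - 1L); c2 <- min(ncol(lab), c0[2] + 1L)
    crop <- chrom[r1:r2, c1:c2, drop = FALSE]
    inside <- lab[r1:r2, c1:c2, drop = FALSE] == i
    npk <- .count_peaks(crop, inside, sep_px, params$peak_rel_prominence)
    components$n_peaks[i] <- npk
    components$signal_class[i] <-
      if (components$area_px[i] > concat_px || npk >= 2L)
        "concatenated" else "single"
  }
  components
}

#' Per-section slide metrics
#'
#' The whole-slide readouts: the relative number of signals (total count
#' divided by the tissue area in pixels), the relative area (signal pixels
#' divided by tissue pixels, a dimensionless fraction in `[0, 1]`), and the
#' physically calibrated density per mm^2. Concatenated signals count once.
#'
#' @param components component table (classes may be `NA`).
#' @param tissue the post-exclusion [tissue_mask] used for detection.
#' @param slide_id,marker metadata copied into the row.
#' @return Object of class `slide_metrics`: one-row `data.frame` with
#'   `slide_id`, `marker`, `total_signals`, `n_single`, `n_concatenated`,
#'   `relative_number`, `relative_area`, `signals_per_mm2`,
#'   `tissue_area_mm2`.
#' @export
slide_metrics <- function(components, tissue, slide_id = "slide",
                          marker = "") {
  if (tissue$tissue_area_px == 0L)
    stop(errorCondition("no tissue: tissue_area_px is zero",
                        class = "cpcquant_degenerate_error"))
  a <- tissue$tissue_area_px
  total <- nrow(components)
  sig_px <- sum(components$area_px)
  out <- data.frame(
    slide_id = slide_id, marker = marker,
    total_signals = total,
    n_single = sum(components$signal_class == "single", na.rm = TRUE),
    n_concatenated = sum(components$signal_class == "concatenated",
                         na.rm = TRUE),
    relative_number = total / a,
    relative_area = sig_px / a,
    signals_per_mm2 = total / (a * tissue$mpp^2 * 1e-6),
    tissue_area_mm2 = tissue_area_mm2(tissue),
    stringsAsFactors = FALSE)
  class(out) <- c("slide_metrics", class(out))
  out
}
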