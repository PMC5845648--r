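#' Phantom specification for synthetic slide generation
#'
#' Describes a geometric two-stain phantom: a contiguous tissue disc of
#' hematoxylin counterstain on bright glass, carrying chromogen-positive
#' signal discs (isolated singles and touching clusters) and optional
#' artifact blobs hugging the tissue edge. Geometry defaults emulate a 20x
#' whole-slide scan (0.5 um/px); signal scale defaults match the
#' single-cell assumptions of [signal_params()]. All randomness is fixed by
#' `seed`.
#'
#' @param height_px,width_px image size in pixels.
#' @param mpp microns per pixel.
#' @param tissue_radius_um radius of the tissue disc.
#' @param tissue_center_um `(x, y)` centre in microns (default image centre).
#' @param n_single_signals,n_cluster_signals number of isolated signals and
#'   of clusters (a cluster renders 2-3 touching cells but is one
#'   connected component, hence one ground-truth record).
#' @param cluster_size_range integer range of cells per cluster.
#' @param signal_radius_um radius of one cell signal (7 um ~ 150 um^2).
#' @param chromogen_od_level peak chromogen OD at a signal centre.
#' @param hematoxylin_od_level counterstain OD over tissue.
#' @param background_intensity length-3 white illumination on `[0, 255]`.
#' @param noise_sd additive Gaussian intensity noise (camera noise model;
#'   sd on the 0-255 scale, applied after Beer-Lambert rendering, clipped
#'   to `[0, 255]`).
#' @param edge_artifact_width_um width of the boundary band receiving
#'   chromogen-like artifact blobs (0 disables them).
#' @param n_edge_artifacts number of artifact blobs on the tissue edge.
#' @param seed integer seed fixing all randomness.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(height_px = 1024L, width_px = 1024L, mpp = 0.5,
                         tissue_radius_um = 220,
                         tissue_center_um = NULL,
                         n_single_signals = 30L, n_cluster_signals = 5L,
                         cluster_size_range = c(2L, 3L),
                         signal_radius_um = 7,
                         chromogen_od_level = 0.8,
                         hematoxylin_od_level = 0.4,
                         background_intensity = c(245, 243, 242),
                         noise_sd = 3, edge_artifact_width_um = 10,
                         n_edge_artifacts = 6L, seed = 1L) {
  if (is.null(tissue_center_um))
    tissue_center_um <- c(width_px, height_px) * mpp / 2
  spec <- list(height_px = as.integer(height_px),
               width_px = as.integer(width_px), mpp = mpp,
               tissue_radius_um = tissue_radius_um,
               tissue_center_um = tissue_center_um,
               n_single_signals = as.integer(n_single_signals),
               n_cluster_signals = as.integer(n_cluster_signals),
               cluster_size_range = as.integer(cluster_size_range),
               signal_radius_um = signal_radius_um,
               chromogen_od_level = chromogen_od_level,
               hematoxylin_od_level = hematoxylin_od_level,
               background_intensity = background_intensity,
               noise_sd = noise_sd,
               edge_artifact_width_um = edge_artifact_width_um,
               n_edge_artifacts = as.integer(n_edge_artifacts),
               seed = as.integer(seed))
  stopifnot(spec$height_px >= 1, spec$width_px >= 1, spec$mpp > 0,
            spec$n_single_signals >= 0, spec$n_cluster_signals >= 0,
            spec$chromogen_od_level >= 0, spec$hematoxylin_od_level >= 0,
            spec$noise_sd >= 0)
  structure(spec, class = "phantom_spec")
}

# pixel-centre coordinate grids in microns (x = column, y = row direction)
.coord_grid <- function(nr, nc, mpp) {
  list(x = matrix((seq_len(nc) - 0.5) * mpp, nr, nc, byrow = TRUE),
       y = matrix((seq_len(nr) - 0.5) * mpp, nr, nc))
}

# rejection-sample n points in a disc with pairwise min separation
.place_points <- function(n, center, radius, min_sep, max_tries = 4000L) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("placement error: could not place ", n, " signals after ",
           max_tries, " tries", call. = FALSE)
    u <- runif(1); th <- runif(1, 0, 2 * pi)
    p <- center + radius * sqrt(u) * c(cos(th), sin(th))
    if (nrow(pts) == 0L ||
        min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= min_sep^2)
      pts <- rbind(pts, p)
  }
  pts
}

# paint dome-profile chromogen discs; returns list(conc, mask)
# profile: level * (0.6 + 0.4 * exp(-d^2 / (2 (r/2)^2))) inside d <= r,
# combined across discs by max -- distinct cells keep distinct peaks while
# the positive area is exactly the painted union of discs. Work is confined
# to each disc's bounding box so large phantoms stay cheap.
.paint_signals <- function(conc, mpp, centers, r, level) {
  nr <- nrow(conc); nc <- ncol(conc)
  painted <- matrix(FALSE, nr, nc)
  sig2 <- (r / 2)^2
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    rows <- max(1L, floor((cy - r) / mpp)):min(nr, ceiling((cy + r) / mpp) + 1L)
    cols <- max(1L, floor((cx - r) / mpp)):min(nc, ceiling((cx + r) / mpp) + 1L)
    d2 <- outer(((rows - 0.5) * mpp - cy)^2, ((cols - 0.5) * mpp - cx)^2, `+`)
    inside <- d2 <= r^2
    prof <- level * (0.6 + 0.4 * exp(-d2 / (2 * sig2)))
    sub <- conc[rows, cols, drop = FALSE]
    sub[inside] <- pmax(sub[inside], prof[inside])
    conc[rows, cols] <- sub
    pm <- painted[rows, cols, drop = FALSE]
    painted[rows, cols] <- pm | inside
  }
  list(conc = conc, mask = painted)
}

#' Generate a synthetic slide with exact ground truth
#'
#' Renders per-pixel stain concentrations (counterstain over the tissue
#' disc, dome-profile chromogen over each signal disc), converts them to
#' RGB through the Beer-Lambert inverse `I = (I0 + 1) * 10^(-M c) - 1`, and
#' adds clipped Gaussian intensity noise. Identical spec (including seed)
#' gives bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @param basis [stain_basis()] used for rendering (the same default the
#'   analysis uses).
#' @return List with `slide` (an [rgb_slide]) and `truth`, a ground-truth
#'   record holding `tissue_mask` (logical matrix), `signal_mask`,
#'   `signals` (`data.frame`: `x_um`, `y_um`, `area_px`, `cluster_flag`),
#'   `n_signals`, `n_single`, `n_cluster`, `relative_area` (signal pixels /
#'   tissue pixels), `background_intensity`.
#' @export
generate_slide <- function(spec, basis = stain_basis()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nr <- spec$height_px; nc <- spec$width_px; mpp <- spec$mpp
  grid <- .coord_grid(nr, nc, mpp)
  ctr <- spec$tissue_center_um
  d2c <- (grid$x - ctr[1])^2 + (grid$y - ctr[2])^2
  tissue <- d2c <= spec$tissue_radius_um^2
  hema <- matrix(0, nr, nc)
  hema[tissue] <- spec$hematoxylin_od_level
  chrom <- matrix(0, nr, nc)

  r_sig <- spec$signal_radius_um
  # keep real signals clear of the edge-exclusion band (2x default margin)
  inner <- spec$tissue_radius_um - 40 - r_sig
  n_place <- spec$n_single_signals + spec$n_cluster_signals
  signals <- data.frame(x_um = numeric(0), y_um = numeric(0),
                        area_px = integer(0), cluster_flag = logical(0))
  signal_mask <- matrix(FALSE, nr, nc)
  if (n_place > 0L) {
    if (inner <= r_sig)
      stop("placement error: tissue disc too small for signals",
           call. = FALSE)
    min_sep <- 2 * r_sig + 18   # clusters spread ~10 um; keep components apart
    anchors <- .place_points(n_place, ctr, inner, min_sep)
    # snap anchors to pixel centres so a single signal's dome peak sits
    # exactly on a pixel (makes the noise-free Beer-Lambert round trip exact)
    anchors <- (floor(anchors / mpp) + 0.5) * mpp
    cluster_flag <- c(rep(FALSE, spec$n_single_signals),
                      rep(TRUE, spec$n_cluster_signals))
    for (i in seq_len(n_place)) {
      if (!cluster_flag[i]) {
        members <- anchors[i, , drop = FALSE]
      } else {
        s <- if (diff(spec$cluster_size_range) > 0)
          sample(spec$cluster_size_range[1]:spec$cluster_size_range[2], 1)
        else spec$cluster_size_range[1]
        th0 <- runif(1, 0, 2 * pi)
        # members on a circle so that pairwise distance ~ 10 um (touching)
        rad <- if (s == 2) 5 else 10 / sqrt(3)
        ang <- th0 + 2 * pi * (seq_len(s) - 1) / s
        members <- cbind(anchors[i, 1] + rad * cos(ang),
                         anchors[i, 2] + rad * sin(ang))
      }
      before <- signal_mask
      p <- .paint_signals(chrom, mpp, members, r_sig,
                          spec$chromogen_od_level)
      chrom <- p$conc
      signal_mask <- signal_mask | p$mask
      signals <- rbind(signals, data.frame(
        x_um = mean(members[, 1]), y_um = mean(members[, 2]),
        area_px = sum(p$mask & !before), cluster_flag = cluster_flag[i]))
    }
  }

  # chromogen-like artifacts hugging the tissue boundary (excluded by the
  # edge margin downstream, never part of ground-truth signals)
  if (spec$edge_artifact_width_um > 0 && spec$n_edge_artifacts > 0L) {
    band_r <- spec$tissue_radius_um - spec$edge_artifact_width_um / 2
    th <- runif(spec$n_edge_artifacts, 0, 2 * pi)
    art <- cbind(ctr[1] + band_r * cos(th), ctr[2] + band_r * sin(th))
    ra <- spec$edge_artifact_width_um / 2
    for (i in seq_len(nrow(art))) {
      cx <- art[i, 1]; cy <- art[i, 2]
      rows <- max(1L, floor((cy - ra) / mpp)):min(nr, ceiling((cy + ra) / mpp) + 1L)
      cols <- max(1L, floor((cx - ra) / mpp)):min(nc, ceiling((cx + ra) / mpp) + 1L)
      d2 <- outer(((rows - 0.5) * mpp - cy)^2, ((cols - 0.5) * mpp - cx)^2, `+`)
      inside <- d2 <= ra^2 & tissue[rows, cols, drop = FALSE]
      sub <- chrom[rows, cols, drop = FALSE]
      sub[inside] <- pmax(sub[inside], spec$chromogen_od_level)
      chrom[rows, cols] <- sub
    }
  }

  # Beer-Lambert rendering + camera noise
  M <- basis$M
  i0 <- spec$background_intensity
  px <- array(0, dim = c(nr, nc, 3))
  for (ch in 1:3) {
    od <- M[ch, 1] * hema + M[ch, 2] * chrom
    px[, , ch] <- (i0[ch] + 1) * 10^(-od) - 1
  }
  if (spec$noise_sd > 0)
    px <- px + array(rnorm(length(px), 0, spec$noise_sd), dim = dim(px))
  px <- pmin(pmax(px, 0), 255)

  slide <- rgb_slide(px, mpp = mpp,
                     slide_id = sprintf("phantom_seed%d", spec$seed),
                     marker = "synthetic")
  truth <- list(tissue_mask = tissue, signal_mask = signal_mask,
                signals = signals,
                n_signals = nrow(signals),
                n_single = sum(!signals$cluster_flag),
                n_cluster = sum(signals$cluster_flag),
                relative_area = sum(signal_mask) / max(1L, sum(tissue)),
                background_intensity = i0)
  list(slide = slide, truth = truth)
}

#' Generate a serial-section stack with known transforms and co-expression
#'
#' Emulates 2-3 adjacent serial sections of one block, each carrying a
#' different marker. A pool of well-separated cell positions is drawn in
#' the reference frame; a fraction `marker_overlap_fraction` of cells is
#' shared by all sections (with a small positional jitter, these are the
#' truly co-expressing cells) while the remainder is unique per section.
#' Section `k > 1` is the base geometry under a recorded small rigid
#' transform. Positions are separated by more than twice the default match
#' radius so matching is unambiguous up to registration error.
#'
#' @param n_sections number of sections / markers (2 or 3).
#' @param n_cells cells per section.
#' @param marker_overlap_fraction fraction in `[0, 1]` of cells present in
#'   every section.
#' @param rot_sd_deg,trans_sd_um sd of the random section rotation
#'   (clamped to +/-5 deg) and translation.
#' @param position_jitter_um per-section anatomical jitter of shared cells.
#' @param height_px,width_px,mpp,tissue_radius_um stack geometry (defaults
#'   give a 2.24 mm field of view that fully contains a 4 mm^2 analysis
#'   field and the tissue disc).
#' @param seed integer seed.
#' @return List with `sections` (each: `mask` a [tissue_mask], `cells` a
#'   [cell_set], `marker`), `true_transforms` (section -> reference frame,
#'   identity first), `true_coexpress_count`, and `mpp`.
#' @export
generate_serial_stack <- function(n_sections = 2L, n_cells = 40L,
                                  marker_overlap_fraction = 0.5,
                                  rot_sd_deg = 1.5, trans_sd_um = 15,
                                  position_jitter_um = 2,
                                  height_px = 560L, width_px = 560L,
                                  mpp = 4, tissue_radius_um = 900,
                                  seed = 1L) {
  if (n_sections < 2L)
    stop("parameter error: need at least 2 sections", call. = FALSE)
  if (marker_overlap_fraction < 0 || marker_overlap_fraction > 1)
    stop("parameter error: overlap fraction must be in [0, 1]",
         call. = FALSE)
  set.seed(seed)
  nr <- height_px; nc <- width_px
  ctr <- c(nc, nr) * mpp / 2
  markers <- c("CD90", "CD117", "CD105")[seq_len(n_sections)]

  n_shared <- round(marker_overlap_fraction * n_cells)
  n_unique <- n_cells - n_shared
  pool <- .place_points(n_shared + n_sections * n_unique, ctr,
                        tissue_radius_um - 60, min_sep = 35)
  shared <- pool[seq_len(n_shared), , drop = FALSE]
  uniq <- if (n_shared > 0L) pool[-seq_len(n_shared), , drop = FALSE] else pool

  # biopsy fragments are irregular; an asymmetric multi-lobed blob keeps
  # the rotation identifiable (a plain disc is rotationally symmetric and
  # cannot constrain the registration angle)
  grid <- .coord_grid(nr, nc, mpp)
  R <- tissue_radius_um
  lobes <- rbind(c(0, 0, R),
                 c(0.75 * R, 0.15 * R, 0.45 * R),
                 c(-0.6 * R, 0.45 * R, 0.35 * R))
  base_mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(lobes)))
    base_mask <- base_mask |
      ((grid$x - ctr[1] - lobes[i, 1])^2 +
         (grid$y - ctr[2] - lobes[i, 2])^2 <= lobes[i, 3]^2)

  sections <- vector("list", n_sections)
  true_tf <- vector("list", n_sections)
  for (s in seq_len(n_sections)) {
    # section-frame transform T_s: reference -> section s
    T_s <- if (s == 1L) rigid_transform(0, c(0, 0), ctr) else
      rigid_transform(max(-5, min(5, rnorm(1, 0, rot_sd_deg))),
                      rnorm(2, 0, trans_sd_um), ctr)
    own_unique <- uniq[seq_len(n_unique) + (s - 1L) * n_unique, ,
                       drop = FALSE]
    cells_ref <- rbind(shared, own_unique)
    if (nrow(cells_ref) > 0 && position_jitter_um > 0)
      cells_ref <- cells_ref +
        matrix(rnorm(2 * nrow(cells_ref), 0, position_jitter_um),
               ncol = 2)
    cells_s <- apply_rigid(T_s, cells_ref)
    mask_s <- if (s == 1L) base_mask else
      .transform_mask(base_mask, T_s, mpp)
    sections[[s]] <- list(mask = tissue_mask(mask_s, mpp),
                          cells = cell_set(cells_s,
                                           sprintf("section_%d", s),
                                           markers[s]),
                          marker = markers[s])
    true_tf[[s]] <- invert_rigid(T_s)  # section -> reference
  }
  list(sections = sections, true_transforms = true_tf,
       true_coexpress_count = n_shared, mpp = mpp)
}

#' Generate a synthetic cohort with known group effects
#'
#' Draws per-patient values of a ratio metric on the logit scale,
#' `Normal(baseline + effect_g, within_sd)`, and maps them through the
#' inverse logit into `(0, 1)` -- the statistical structure of the
#' reference cohort (logit-scale group shifts with within-group spread).
#' Defaults mirror that cohort: group sizes (3, 3, 10, 7), a healthy-like
#' baseline of -4 logits and a within-group sd of 1.3 logits.
#'
#' @param group_sizes named integer vector of patients per group.
#' @param baseline_logit_mean grand baseline on the logit scale.
#' @param group_effects additive logit-scale shift per group (same order
#'   as `group_sizes`).
#' @param within_sd within-group sd on the logit scale (`> 0`).
#' @param seed integer seed.
#' @param metric_name metric label for the generated rows.
#' @return A [cohort_table()] with one row per patient; attribute `truth`
#'   records the generating parameters.
#' @export
generate_cohort <- function(group_sizes = c(Healthy = 3, Myocarditis = 3,
                                            ICM = 10, DCM = 7),
                            baseline_logit_mean = -4,
                            group_effects = c(0, 0, 0, 0),
                            within_sd = 1.3, seed = 1L,
                            metric_name = "synthetic_relative_area") {
  if (any(group_sizes < 1L)) stop("group sizes must be >= 1", call. = FALSE)
  if (within_sd <= 0) stop("within_sd must be > 0", call. = FALSE)
  if (length(group_effects) != length(group_sizes))
    stop("one effect per group", call. = FALSE)
  set.seed(seed)
  groups <- rep(names(group_sizes), times = group_sizes)
  eff <- rep(group_effects, times = group_sizes)
  y <- rnorm(length(groups), baseline_logit_mean + eff, within_sd)
  df <- data.frame(
    patient_id = sprintf("SynthPatient %02d", seq_along(groups)),
    group = groups, biopsy_location = "synthetic",
    metric_name = metric_name,
    # clamp away from 0/1 so extreme draws survive double rounding
    value = pmin(pmax(inv_logit(y), 1e-12), 1 - 1e-12),
    stringsAsFactors = FALSE)
  out <- cohort_table(df)
  attr(out, "truth") <- list(baseline = baseline_logit_mean,
                             effects = group_effects,
                             within_sd = within_sd, seed = seed,
                             logit_values = y)
  out
}
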