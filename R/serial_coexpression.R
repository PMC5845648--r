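#' Cell centroid set from one stained serial section
#'
#' @param centroids numeric `n x 2` matrix of `(x, y)` positions in microns
#'   (x along columns, y along rows of the source image).
#' @param section_id,marker identifiers.
#' @return Object of class `cell_set`.
#' @export
cell_set <- function(centroids, section_id = "section", marker = "") {
  centroids <- matrix(as.numeric(centroids), ncol = 2)
  if (nrow(centroids) > 0 && !all(is.finite(centroids)))
    stop("cell coordinates must be finite", call. = FALSE)
  if (!nzchar(marker)) stop("marker must be nonempty", call. = FALSE)
  colnames(centroids) <- c("x_um", "y_um")
  structure(list(section_id = as.character(section_id),
                 marker = as.character(marker), centroids = centroids),
            class = "cell_set")
}

#' Read cell sets from CSV
#'
#' Expected columns: `section_id, marker, x_um, y_um`; one [cell_set] is
#' returned per `(section_id, marker)` combination, in file order.
#' @param path CSV path.
#' @return Named list of [cell_set] objects.
#' @export
read_cell_sets <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("section_id", "marker", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("format error: cell-set CSV needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  key <- paste(df$section_id, df$marker, sep = "/")
  lapply(split(df, factor(key, levels = unique(key))), function(d)
    cell_set(cbind(d$x_um, d$y_um), d$section_id[1], d$marker[1]))
}

#' Rigid transform between serial-section frames
#'
#' Maps a point `p` (microns, `(x, y)`) by
#' `q = R(theta) (p - c) + c + t` with rotation centre `c` (`center_um`,
#' typically the image centre) and translation `t`.
#'
#' @param rotation_deg rotation angle in degrees (counter-clockwise in the
#'   `(x, y)` frame).
#' @param translation_um length-2 translation `(dx, dy)` in microns.
#' @param center_um length-2 rotation centre in microns.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = 0, translation_um = c(0, 0),
                            center_um = c(0, 0)) {
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 translation_um = as.numeric(translation_um),
                 center_um = as.numeric(center_um)),
            class = "rigid_transform")
}

.rot_mat <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Apply a rigid transform to points
#' @param tf a [rigid_transform].
#' @param points `n x 2` matrix of `(x, y)` microns.
#' @return Transformed `n x 2` matrix.
#' @export
apply_rigid <- function(tf, points) {
  points <- matrix(as.numeric(points), ncol = 2)
  if (nrow(points) == 0) return(points)
  R <- .rot_mat(tf$rotation_deg)
  sweep(sweep(points, 2, tf$center_um) %*% t(R), 2,
        tf$center_um + tf$translation_um, `+`)
}

#' Invert / compose rigid transforms (same centre)
#' @param tf,a,b [rigid_transform] objects sharing `center_um`.
#' @return A [rigid_transform].
#' @export
invert_rigid <- function(tf) {
  R <- .rot_mat(-tf$rotation_deg)
  rigid_transform(-tf$rotation_deg,
                  as.numeric(-R %*% tf$translation_um), tf$center_um)
}

#' @rdname invert_rigid
#' @export
compose_rigid <- function(a, b) {
  # (a o b): apply b first, then a
  R <- .rot_mat(a$rotation_deg)
  rigid_transform(a$rotation_deg + b$rotation_deg,
                  as.numeric(R %*% b$translation_um) + a$translation_um,
                  a$center_um)
}

# resample a logical mask under a rigid transform (nearest neighbour);
# out(q) = in(T^-1 q), pixels mapped from outside the frame become FALSE
.transform_mask <- function(mask, tf, mpp) {
  nr <- nrow(mask); nc <- ncol(mask)
  inv <- invert_rigid(tf)
  xy <- cbind(rep((seq_len(nc) - 0.5) * mpp, each = nr),
              rep((seq_len(nr) - 0.5) * mpp, times = nc))
  src <- apply_rigid(inv, xy)
  sc <- as.integer(floor(src[, 1] / mpp) + 1L)
  sr <- as.integer(floor(src[, 2] / mpp) + 1L)
  ok <- sr >= 1L & sr <= nr & sc >= 1L & sc <= nc
  out <- rep(FALSE, nr * nc)
  out[ok] <- mask[cbind(sr[ok], sc[ok])]
  matrix(out, nr, nc)
}

# integer-pixel translation (dr, dc) aligning `mov` to `ref` by
# phase correlation; returns c(dr, dc)
.phase_correlate <- function(ref, mov) {
  nr <- nrow(ref); nc <- ncol(ref)
  Fr <- fft(matrix(as.numeric(ref), nr, nc))
  Fm <- fft(matrix(as.numeric(mov), nr, nc))
  cps <- Fr * Conj(Fm)
  cps <- cps / pmax(Mod(cps), 1e-12)
  r <- Re(fft(cps, inverse = TRUE)) / (nr * nc)
  peak <- arrayInd(which.max(r), dim(r))
  dr <- peak[1] - 1L; dc <- peak[2] - 1L
  if (dr > nr / 2) dr <- dr - nr
  if (dc > nc / 2) dc <- dc - nc
  c(dr, dc)
}

#' Register two serial-section tissue masks rigidly
#'
#' Serial sections of one block are nearly aligned, so an exhaustive coarse
#' rotation grid combined with phase-correlation translation at each angle
#' is both robust and deterministic. Candidates are scored by mask overlap
#' (intersection pixel count) and the best transform, mapping points of
#' `moving` into the frame of `reference`, is returned.
#'
#' @param reference,moving [tissue_mask] objects of equal size and `mpp`.
#' @param rot_range_deg half-width of the rotation search grid.
#' @param rot_step_deg grid step (also the angular resolution).
#' @return A [rigid_transform] with `score` attribute (fractional overlap
#'   of the moved mask with the reference).
#' @export
register_rigid <- function(reference, moving, rot_range_deg = 10,
                           rot_step_deg = 0.5) {
  if (reference$tissue_area_px == 0L || moving$tissue_area_px == 0L)
    stop(errorCondition("no tissue: registration needs nonempty masks",
                        class = "cpcquant_degenerate_error"))
  mpp <- reference$mpp
  ref <- reference$mask
  ctr <- c(ncol(ref), nrow(ref)) * mpp / 2
  best <- NULL; best_score <- -1
  angles <- seq(-rot_range_deg, rot_range_deg, by = rot_step_deg)
  for (th in angles) {
    tf_rot <- rigid_transform(th, c(0, 0), ctr)
    rot <- if (th == 0) moving$mask else .transform_mask(moving$mask, tf_rot, mpp)
    sh <- .phase_correlate(ref, rot)
    cand <- rigid_transform(th, c(sh[2], sh[1]) * mpp, ctr)
    moved <- .shift_mask(rot, sh[1], sh[2])
    score <- sum(ref & moved)
    if (score > best_score) { best_score <- score; best <- cand }
  }
  attr(best, "score") <- best_score / max(1L, sum(ref))
  best
}

.shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  sr <- seq_len(nr) - dr; sc <- seq_len(nc) - dc
  okr <- sr >= 1L & sr <= nr; okc <- sc >= 1L & sc <= nc
  out[okr, okc] <- m[sr[okr], sc[okc]]
  out
}

#' Representative analysis field
#'
#' An axis-aligned square window of the requested area. The published
#' procedure picks a field of "high histological quality" by eye; the
#' computable proxy here is the window with maximal tissue coverage, ties
#' broken by the smallest `(row, col)` origin.
#'
#' @param tissue a [tissue_mask].
#' @param field_area_mm2 requested field area (default 4 mm^2).
#' @return Object of class `field`: `origin_um` (`(x, y)` of the top-left
#'   corner), `width_um`, `height_um`, `area_mm2`, `coverage` (tissue
#'   fraction inside), and pixel bookkeeping `origin_px`, `width_px`.
#' @export
select_field <- function(tissue, field_area_mm2 = 4) {
  mpp <- tissue$mpp
  side_px <- as.integer(round(sqrt(field_area_mm2) * 1000 / mpp))
  nr <- nrow(tissue$mask); nc <- ncol(tissue$mask)
  if (side_px > nr || side_px > nc || side_px < 1L)
    stop("parameter error: image (", nr, " x ", nc,
         " px) cannot contain a field of ", field_area_mm2, " mm^2",
         call. = FALSE)
  # integral image: ii[r+1, c+1] = sum mask[1:r, 1:c]
  cum <- t(apply(apply(tissue$mask, 2, cumsum), 1, cumsum))
  ii <- rbind(0, cbind(0, cum))
  r_or <- seq_len(nr - side_px + 1L)
  c_or <- seq_len(nc - side_px + 1L)
  sums <- ii[r_or + side_px, c_or + side_px, drop = FALSE] -
    ii[r_or, c_or + side_px, drop = FALSE] -
    ii[r_or + side_px, c_or, drop = FALSE] + ii[r_or, c_or, drop = FALSE]
  mx <- max(sums)
  hit <- which(sums == mx, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
  origin_px <- c(row = unname(hit[1]), col = unname(hit[2]))
  side_um <- side_px * mpp
  structure(list(
    origin_um = c((origin_px["col"] - 1) * mpp, (origin_px["row"] - 1) * mpp),
    width_um = side_um, height_um = side_um,
    area_mm2 = side_um^2 * 1e-6,
    coverage = mx / side_px^2,
    origin_px = origin_px, width_px = side_px), class = "field")
}

.in_field <- function(points, field) {
  ox <- field$origin_um[1]; oy <- field$origin_um[2]
  points[, 1] >= ox & points[, 1] < ox + field$width_um &
    points[, 2] >= oy & points[, 2] < oy + field$height_um
}

#' Count cells co-expressing markers across serial sections
#'
#' Each marker lives on its own section, so a co-expressing cell appears as
#' one centroid per section at (nearly) the same anatomical position. After
#' mapping every cell set into the reference frame and clipping to the
#' analysis field, a cell is counted when a greedy mutual nearest-neighbour
#' chain links one centroid from every set with all pairwise distances
#' within `match_radius_um`; every centroid is used at most once. The count
#' is normalised by the field area to cells per mm^2.
#'
#' @param cellsets list of `k >= 2` [cell_set] objects; the first is the
#'   reference frame.
#' @param transforms list of [rigid_transform]s for the non-reference sets
#'   (length `k - 1`, or `k` with an identity first), mapping each set into
#'   the reference frame, e.g. from [register_rigid()].
#' @param field a [select_field()] window in the reference frame.
#' @param match_radius_um maximum matching distance (default 15, about one
#'   cell diameter).
#' @return Object of class `coexpression_result`: `matched_count`,
#'   `field_area_mm2`, `density_per_mm2`, `markers`, `n_in_field`.
#' @export
match_and_count <- function(cellsets, transforms = NULL, field,
                            match_radius_um = 15) {
  k <- length(cellsets)
  if (k < 2L)
    stop("parameter error: need at least 2 cell sets", call. = FALSE)
  if (!is.numeric(match_radius_um) || match_radius_um <= 0)
    stop("parameter error: match_radius_um must be > 0", call. = FALSE)
  if (is.null(transforms))
    transforms <- rep(list(rigid_transform()), k - 1L)
  if (length(transforms) == k - 1L)
    transforms <- c(list(rigid_transform()), transforms)
  if (length(transforms) != k)
    stop("parameter error: one transform per non-reference cell set",
         call. = FALSE)
  pts <- lapply(seq_len(k), function(i) {
    p <- apply_rigid(transforms[[i]], cellsets[[i]]$centroids)
    p[.in_field(p, field), , drop = FALSE]
  })
  n_in <- vapply(pts, nrow, integer(1))
  count <- if (any(n_in == 0L)) 0L else .greedy_match_count(pts, match_radius_um)
  structure(list(matched_count = count,
                 field_area_mm2 = field$area_mm2,
                 density_per_mm2 = count / field$area_mm2,
                 markers = vapply(cellsets, `[[`, "", "marker"),
                 n_in_field = n_in),
            class = "coexpression_result")
}

# greedy disjoint matching over candidate tuples sorted by total distance
.greedy_match_count <- function(pts, radius) {
  k <- length(pts)
  r2 <- radius^2
  # recursive candidate enumeration: one index per set, all pairwise <= radius
  cands <- list(); scores <- numeric(0)
  pick <- function(level, idx) {
    if (level > k) {
      d <- 0
      for (a in 1:(k - 1)) for (b in (a + 1):k)
        d <- d + sqrt(sum((pts[[a]][idx[a], ] - pts[[b]][idx[b], ])^2))
      cands[[length(cands) + 1L]] <<- idx
      scores[length(scores) + 1L] <<- d
      return(invisible())
    }
    for (j in seq_len(nrow(pts[[level]]))) {
      ok <- TRUE
      for (a in seq_len(level - 1L)) {
        if (sum((pts[[a]][idx[a], ] - pts[[level]][j, ])^2) > r2) {
          ok <- FALSE; break
        }
      }
      if (ok) pick(level + 1L, c(idx, j))
    }
  }
  pick(1L, integer(0))
  if (length(cands) == 0L) return(0L)
  ord <- order(scores, vapply(cands, paste, "", collapse = ","))
  used <- lapply(pts, function(p) rep(FALSE, nrow(p)))
  count <- 0L
  for (i in ord) {
    idx <- cands[[i]]
    if (any(mapply(function(u, j) u[j], used, idx))) next
    for (s in seq_len(k)) used[[s]][idx[s]] <- TRUE
    count <- count + 1L
  }
  count
}

#' Per-group mean and standard deviation of co-expression densities
#'
#' @param densities numeric vector of per-patient densities (cells/mm^2).
#' @param groups group label per density.
#' @return `data.frame` with `group`, `n`, `mean`, `sd` (sample, `n - 1`
#'   denominator; a single observation has `sd` 0).
#' @export
group_coexpression_summary <- function(densities, groups) {
  if (length(densities) == 0L || length(densities) != length(groups))
    stop("parameter error: densities and groups must be equal-length, n >= 1",
         call. = FALSE)
  groups <- as.character(groups)
  lev <- unique(groups)
  out <- do.call(rbind, lapply(lev, function(g) {
    v <- densities[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) sd(v) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
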