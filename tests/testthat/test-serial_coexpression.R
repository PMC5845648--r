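test_that("registering identical masks returns the identity", {
  tm <- make_blob_mask()
  tf <- register_rigid(tm, tm)
  expect_lte(abs(tf$rotation_deg), 0.25)
  expect_lte(max(abs(tf$translation_um)), tm$mpp)
  expect_error(register_rigid(tm, tissue_mask(matrix(FALSE, 10, 10), 2)),
               "no tissue", class = "cpcquant_degenerate_error")
})

test_that("known shifts and rotations are recovered", {
  tm <- make_blob_mask()
  ctr <- c(ncol(tm$mask), nrow(tm$mask)) * tm$mpp / 2
  # pure translation (30, -12) um
  t_true <- rigid_transform(0, c(30, -12), ctr)
  moved <- tissue_mask(cpcquant:::.transform_mask(tm$mask, t_true, tm$mpp),
                       tm$mpp)
  est <- register_rigid(tm, moved)
  comp <- compose_rigid(est, t_true)   # should be ~identity
  expect_lte(abs(comp$rotation_deg), 0.5)
  expect_lte(max(abs(comp$translation_um)), tm$mpp)  # within 1 px
  # pure rotation 5 degrees
  r_true <- rigid_transform(5, c(0, 0), ctr)
  rot <- tissue_mask(cpcquant:::.transform_mask(tm$mask, r_true, tm$mpp),
                     tm$mpp)
  est_r <- register_rigid(tm, rot)
  expect_lte(abs(est_r$rotation_deg + 5), 0.5)
})

test_that("rigid transforms compose and invert exactly", {
  set.seed(3)
  for (i in 1:10) {
    tf <- rigid_transform(runif(1, -30, 30), runif(2, -50, 50),
                          runif(2, 0, 100))
    p <- matrix(runif(10, 0, 500), ncol = 2)
    back <- apply_rigid(invert_rigid(tf), apply_rigid(tf, p))
    expect_lt(max(abs(back - p)), 1e-6)
  }
})

test_that("select_field maximises tissue coverage with stated tie-breaks", {
  # full tissue -> origin (0, 0)
  full <- tissue_mask(matrix(TRUE, 30, 30), 100)
  f <- select_field(full, 1)   # 1 mm^2 -> 10 px window
  expect_equal(unname(f$origin_um), c(0, 0))
  expect_equal(f$area_mm2, 1)
  expect_equal(f$coverage, 1)
  # empty mask -> origin (0, 0) by tie-break, coverage 0
  f0 <- select_field(tissue_mask(matrix(FALSE, 30, 30), 100), 1)
  expect_equal(unname(f0$origin_um), c(0, 0))
  expect_equal(f0$coverage, 0)
  # tissue in the lower-right quadrant: compare to an exhaustive scan
  m <- matrix(FALSE, 30, 30)
  m[16:30, 16:30] <- TRUE
  tm <- tissue_mask(m, 100)
  f <- select_field(tm, 1)
  side <- 10L
  best <- -1; best_rc <- NULL
  for (r in 1:(30 - side + 1)) for (cc in 1:(30 - side + 1)) {
    s <- sum(m[r:(r + side - 1), cc:(cc + side - 1)])
    if (s > best) { best <- s; best_rc <- c(r, cc) }
  }
  expect_equal(unname(f$origin_px), best_rc)
  expect_equal(f$coverage, best / side^2)
  expect_gte(f$origin_px[1], 16 - side + 1)
  # image smaller than field
  expect_error(select_field(tissue_mask(matrix(TRUE, 5, 5), 100), 4),
               "parameter")
})

test_that("match_and_count handles the arithmetic reference cases", {
  side <- sqrt(4) * 1000
  fld <- structure(list(origin_um = c(0, 0), width_um = side,
                        height_um = side, area_mm2 = 4, coverage = 1,
                        origin_px = c(1, 1), width_px = NA),
                   class = "field")
  empty <- cell_set(matrix(numeric(0), 0, 2), marker = "CD90")
  r <- match_and_count(list(empty, cell_set(matrix(numeric(0), 0, 2),
                                            marker = "CD117")),
                       NULL, fld, 10)
  expect_equal(c(r$matched_count, r$density_per_mm2), c(0, 0))
  # one pair 3 um apart in a 4 mm^2 field, radius 10 -> 1 cell, 0.25/mm^2
  a <- cell_set(cbind(1000, 1000), marker = "CD90")
  b <- cell_set(cbind(1003, 1000), marker = "CD117")
  r <- match_and_count(list(a, b), NULL, fld, 10)
  expect_equal(r$matched_count, 1L)
  expect_equal(r$density_per_mm2, 0.25)
  # 27 coincident pairs -> 6.75 per mm^2
  set.seed(8)
  pts <- cbind(runif(27, 100, 1900), runif(27, 100, 1900))
  r27 <- match_and_count(list(cell_set(pts, marker = "CD90"),
                              cell_set(pts, marker = "CD117")),
                         NULL, fld, 15)
  expect_equal(r27$matched_count, 27L)
  expect_equal(r27$density_per_mm2, 6.75)
  expect_error(match_and_count(list(a), NULL, fld, 10), "parameter")
  expect_error(match_and_count(list(a, b), NULL, fld, 0), "parameter")
})

test_that("matching is symmetric, radius-monotone and frame-invariant", {
  side <- 2000
  fld <- structure(list(origin_um = c(0, 0), width_um = side,
                        height_um = side, area_mm2 = 4, coverage = 1,
                        origin_px = c(1, 1), width_px = NA),
                   class = "field")
  set.seed(21)
  for (rep in 1:5) {
    p1 <- cbind(runif(15, 0, side), runif(15, 0, side))
    p2 <- cbind(runif(15, 0, side), runif(15, 0, side))
    s1 <- cell_set(p1, marker = "CD90"); s2 <- cell_set(p2, marker = "CD117")
    c12 <- match_and_count(list(s1, s2), NULL, fld, 120)$matched_count
    c21 <- match_and_count(list(s2, s1), NULL, fld, 120)$matched_count
    expect_equal(c12, c21)
    # monotone in radius
    counts <- vapply(c(20, 60, 120, 300), function(r)
      match_and_count(list(s1, s2), NULL, fld, r)$matched_count, integer(1))
    expect_true(all(diff(counts) >= 0))
    # common rigid motion of all inputs leaves the count unchanged
    tf <- rigid_transform(7, c(40, -25), c(side / 2, side / 2))
    s1m <- cell_set(apply_rigid(tf, p1), marker = "CD90")
    s2m <- cell_set(apply_rigid(tf, p2), marker = "CD117")
    inv <- invert_rigid(tf)
    cmoved <- match_and_count(list(s1m, s2m), list(inv, inv), fld,
                              120)$matched_count
    expect_equal(cmoved, c12)
  }
})

test_that("three-marker counts never exceed any pairwise count", {
  side <- 2000
  fld <- structure(list(origin_um = c(0, 0), width_um = side,
                        height_um = side, area_mm2 = 4, coverage = 1,
                        origin_px = c(1, 1), width_px = NA),
                   class = "field")
  set.seed(33)
  for (rep in 1:5) {
    sets <- lapply(c("CD90", "CD117", "CD105"), function(mk)
      cell_set(cbind(runif(12, 0, side), runif(12, 0, side)), marker = mk))
    c123 <- match_and_count(sets, NULL, fld, 250)$matched_count
    for (pair in list(1:2, c(1, 3), 2:3)) {
      cp <- match_and_count(sets[pair], NULL, fld, 250)$matched_count
      expect_lte(c123, cp)
    }
  }
})

test_that("greedy matching agrees with an exhaustive assignment oracle", {
  # brute-force maximum matching count for k = 2 by recursion
  max_match <- function(p1, p2, r) {
    ok <- outer(seq_len(nrow(p1)), seq_len(nrow(p2)), function(i, j)
      (p1[i, 1] - p2[j, 1])^2 + (p1[i, 2] - p2[j, 2])^2 <= r^2)
    rec <- function(i, used) {
      if (i > nrow(p1)) return(0L)
      best <- rec(i + 1L, used)             # leave i unmatched
      for (j in which(ok[i, ] & !used)) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
      best
    }
    rec(1L, rep(FALSE, nrow(p2)))
  }
  fld <- structure(list(origin_um = c(0, 0), width_um = 500,
                        height_um = 500, area_mm2 = 0.25, coverage = 1,
                        origin_px = c(1, 1), width_px = NA),
                   class = "field")
  set.seed(44)
  hits <- 0L; total <- 0L
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    p1 <- cbind(runif(n1, 0, 500), runif(n1, 0, 500))
    p2 <- cbind(runif(n2, 0, 500), runif(n2, 0, 500))
    greedy <- match_and_count(list(cell_set(p1, marker = "a"),
                                   cell_set(p2, marker = "b")),
                              NULL, fld, 80)$matched_count
    opt <- max_match(p1, p2, 80)
    expect_lte(greedy, opt)
    total <- total + 1L
    if (greedy == opt) hits <- hits + 1L
  }
  # greedy is near-optimal at these densities
  expect_gte(hits / total, 0.9)
})

test_that("group summaries use the sample standard deviation", {
  s <- group_coexpression_summary(c(1, 2, 2), rep("Myocarditis", 3))
  expect_equal(round(s$mean, 2), 1.67)
  expect_equal(round(s$sd, 2), 0.58)
  s2 <- group_coexpression_summary(c(5, 5, 5), rep("g", 3))
  expect_equal(c(s2$mean, s2$sd), c(5, 0))
  s3 <- group_coexpression_summary(c(0, 8), rep("g", 2))
  expect_equal(s3$mean, 4)
  expect_equal(round(s3$sd, 2), 5.66)
  s4 <- group_coexpression_summary(7, "g")      # n = 1 -> sd 0
  expect_equal(s4$sd, 0)
  expect_error(group_coexpression_summary(numeric(0), character(0)),
               "parameter")
})
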