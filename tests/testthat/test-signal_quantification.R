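test_that("zero chromogen yields no signals; empty tissue errors", {
  chrom <- matrix(0, 50, 50)
  maps <- make_stain_maps(chrom)
  tis <- tissue_mask(matrix(TRUE, 50, 50), 1)
  comps <- detect_signals(maps, tis)
  expect_equal(nrow(comps), 0L)
  empty <- tissue_mask(matrix(FALSE, 50, 50), 1)
  expect_error(detect_signals(maps, empty), "no tissue",
               class = "cpcquant_degenerate_error")
})

test_that("components below min_signal_area are excluded", {
  chrom <- matrix(0, 50, 50)
  chrom[10:12, 10:12] <- 0.5          # 9 px
  chrom[30:34, 30:33] <- 0.5          # 20 px
  maps <- make_stain_maps(chrom)
  tis <- tissue_mask(matrix(TRUE, 50, 50), 1)
  comps <- detect_signals(maps, tis, signal_params(min_signal_area_um2 = 20))
  expect_equal(nrow(comps), 1L)
  expect_equal(comps$area_px, 20L)
  # at 10 um^2 both survive
  comps2 <- detect_signals(maps, tis, signal_params(min_signal_area_um2 = 9))
  expect_equal(nrow(comps2), 2L)
})

test_that("phantom signal count is exact for well-separated signals", {
  g <- generate_slide(small_spec(seed = 9))
  m <- quantify_slide(g$slide, pipeline_config(mpp = 1))
  expect_equal(m$total_signals, g$truth$n_signals)
})

test_that("single/concatenated classification matches generator labels", {
  # the spec's reference composition: 20 singles, 5 pairs
  spec <- phantom_spec(height_px = 512L, width_px = 512L, mpp = 1,
                       tissue_radius_um = 220, n_single_signals = 20L,
                       n_cluster_signals = 5L,
                       cluster_size_range = c(2L, 2L), seed = 12)
  g <- generate_slide(spec)
  m <- quantify_slide(g$slide, pipeline_config(mpp = 1))
  comps <- attr(m, "components")
  expect_equal(nrow(comps), 25L)
  # match detections to truth records by nearest centroid
  truth <- g$truth$signals
  got_xy <- cbind(comps$centroid_col * 1, comps$centroid_row * 1)  # mpp = 1
  idx <- vapply(seq_len(nrow(truth)), function(i) {
    which.min((got_xy[, 1] - truth$x_um[i])^2 +
                (got_xy[, 2] - truth$y_um[i])^2)
  }, integer(1))
  pred_concat <- comps$signal_class[idx] == "concatenated"
  agreement <- mean(pred_concat == truth$cluster_flag)
  expect_gte(agreement, 0.9)
})

test_that("slide_metrics computes the defined ratios", {
  tis <- tissue_mask(matrix(TRUE, 100, 100), 1)   # 10,000 px
  comps <- data.frame(component_id = 1L, area_px = 500L,
                      centroid_row = 1, centroid_col = 1,
                      mean_chromogen = 0.5, n_peaks = 1L,
                      signal_class = "single", stringsAsFactors = FALSE)
  m <- slide_metrics(comps, tis)
  expect_equal(m$relative_area, 0.05)
  expect_equal(m$relative_number, 1e-4)
  # consistency: signals_per_mm2 = relative_number / (mpp^2 * 1e-6)
  expect_equal(m$signals_per_mm2, m$relative_number / (1^2 * 1e-6))
  # no components
  m0 <- slide_metrics(comps[0, ], tis)
  expect_equal(c(m0$total_signals, m0$relative_number, m0$relative_area),
               c(0, 0, 0))
  expect_error(slide_metrics(comps, tissue_mask(matrix(FALSE, 2, 2), 1)),
               "no tissue", class = "cpcquant_degenerate_error")
})

test_that("relative_area ignores mpp while signals_per_mm2 scales as 1/mpp^2", {
  comps <- data.frame(component_id = 1L, area_px = 500L,
                      centroid_row = 1, centroid_col = 1,
                      mean_chromogen = 0.5, n_peaks = 1L,
                      signal_class = "single", stringsAsFactors = FALSE)
  m1 <- slide_metrics(comps, tissue_mask(matrix(TRUE, 100, 100), 0.5))
  m2 <- slide_metrics(comps, tissue_mask(matrix(TRUE, 100, 100), 1.0))
  expect_equal(m1$relative_area, m2$relative_area)
  expect_equal(m1$relative_number, m2$relative_number)
  expect_equal(m1$signals_per_mm2 / m2$signals_per_mm2, (1.0 / 0.5)^2)
})

test_that("raising the positivity threshold shrinks the signal pixel set", {
  g <- generate_slide(small_spec(seed = 14))
  maps <- separate_stains(g$slide)
  tis <- exclude_edge(segment_tissue(g$slide, maps), 20)
  lab1 <- attr(detect_signals(maps, tis, signal_params(positivity_od = 0.15,
                                                       min_signal_area_um2 = 1)),
               "labels")
  # the dome profile floors at 0.6 x peak OD, so the higher cut must sit
  # above that floor to bite
  lab2 <- attr(detect_signals(maps, tis, signal_params(positivity_od = 0.6,
                                                       min_signal_area_um2 = 1)),
               "labels")
  expect_true(all(lab1[lab2 > 0] > 0))   # t2-positive pixels subset of t1
  expect_lt(sum(lab2 > 0), sum(lab1 > 0))
})

test_that("pure background outside tissue changes no metric", {
  g <- generate_slide(small_spec(seed = 15))
  maps <- separate_stains(g$slide)
  tis <- exclude_edge(segment_tissue(g$slide, maps), 20)
  comps <- split_single_concatenated(detect_signals(maps, tis), maps)
  m <- slide_metrics(comps, tis)
  # pad every map and the mask with background on two sides
  pad <- function(x, fill) rbind(cbind(x, matrix(fill, nrow(x), 30)),
                                 matrix(fill, 30, ncol(x) + 30))
  maps_p <- make_stain_maps(pad(maps$chromogen, 0), pad(maps$hematoxylin, 0))
  tis_p <- tissue_mask(pad(tis$mask, FALSE), tis$mpp)
  comps_p <- split_single_concatenated(detect_signals(maps_p, tis_p), maps_p)
  m_p <- slide_metrics(comps_p, tis_p)
  expect_equal(m_p$total_signals, m$total_signals)
  expect_equal(m_p$relative_area, m$relative_area)
  expect_equal(m_p$relative_number, m$relative_number)
})

test_that("per-class counts sum to the total", {
  g <- generate_slide(small_spec(seed = 16))
  m <- quantify_slide(g$slide, pipeline_config(mpp = 1))
  expect_equal(m$n_single + m$n_concatenated, m$total_signals)
})
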