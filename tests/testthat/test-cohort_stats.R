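test_that("logit is the natural-log odds with its stated properties", {
  expect_equal(logit(0.5), 0)
  expect_equal(logit(0.2) + logit(0.8), 0, tolerance = 1e-12)
  # high-precision evaluation: log(0.058857617 / 0.941142383) = -2.7719733
  expect_equal(round(logit(0.058857617), 4), -2.772)
  expect_equal(inv_logit(logit(0.37)), 0.37, tolerance = 1e-12)
  # strictly increasing
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(logit(p)) > 0))
  expect_error(logit(0), "domain")
  expect_error(logit(1), "domain")
  expect_error(logit(c(0.5, 1.2)), "domain")
})

test_that("the packaged cohort validates and summarises correctly", {
  tab <- table2_cohort()
  expect_s3_class(tab, "cohort_table")
  expect_equal(nrow(tab), 92L)
  expect_equal(length(unique(tab$patient_id)), 23L)
  s <- group_summary(tab, "cd117_relative_area", "raw")
  expect_equal(s$n, c(3L, 3L, 10L, 7L))
  expect_equal(s$mean[s$group == "Myocarditis"], 0.51312868,
               tolerance = 1e-8)
  s90 <- group_summary(tab, "cd90_relative_number", "raw")
  expect_equal(s90$mean[s90$group == "Healthy"], 0.00015239,
               tolerance = 1e-8)
  expect_error(group_summary(tab, "nope"), "parameter")
})

test_that("cohort_table rejects malformed input", {
  tab <- as.data.frame(table2_cohort())
  bad <- tab; bad$group[1] <- "Unknown"
  expect_error(cohort_table(bad), "group")
  dup <- rbind(tab, tab[1, ])
  expect_error(cohort_table(dup), "duplicate")
  oob <- tab; oob$value[oob$metric_name == "cd90_relative_area"][1] <- 1.2
  expect_error(cohort_table(oob), "ratio")
})

test_that("a single-observation group has sd 0", {
  df <- data.frame(patient_id = c("a", "b", "c"),
                   group = c("Healthy", "DCM", "DCM"),
                   biopsy_location = "x",
                   metric_name = "cd90_relative_area",
                   value = c(0.1, 0.2, 0.3))
  s <- group_summary(cohort_table(df), "cd90_relative_area")
  expect_equal(s$sd[s$group == "Healthy"], 0)
  expect_equal(s$n[s$group == "Healthy"], 1L)
})

test_that("anova_oneway reproduces hand-computed decompositions", {
  # groups {1,2,3} and {2,3,4}: SSB = 1.5, SSW = 4, F = 1.5, df (1, 4)
  a <- anova_oneway(c(1, 2, 3, 2, 3, 4), rep(c("g1", "g2"), each = 3))
  expect_equal(a$ss_between, 1.5)
  expect_equal(a$ss_within, 4)
  expect_equal(a$F, 1.5)
  expect_equal(c(a$df_between, a$df_within), c(1L, 4L))
  # identical group means with spread -> F exactly 0
  a0 <- anova_oneway(c(1, 3, 1, 3), rep(c("g1", "g2"), each = 2))
  expect_equal(a0$F, 0)
  expect_error(anova_oneway(c(1, 1, 1, 1), rep(c("a", "b"), each = 2)),
               "degenerate", class = "cpcquant_degenerate_error")
  expect_error(anova_oneway(1:3, rep("a", 3)), "parameter")
  # grand-mean identity: sum n_g * mean_g = N * grand mean
  set.seed(5)
  v <- rnorm(20); g <- sample(letters[1:4], 20, TRUE)
  g[1:4] <- letters[1:4]
  an <- anova_oneway(v, g)
  expect_equal(sum(an$group_n * an$group_means),
               length(v) * an$grand_mean)
})

test_that("anova matches the reference implementation on the fixture", {
  tab <- table2_cohort()
  for (metric in c("cd117_relative_area", "cd90_relative_area")) {
    d <- tab[tab$metric_name == metric, ]
    y <- logit(d$value)
    mine <- anova_oneway(y, d$group)
    ref <- anova(stats::lm(y ~ factor(d$group)))
    expect_equal(mine$F, ref$`F value`[1], tolerance = 1e-8)
    expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-8)
    expect_equal(c(mine$df_between, mine$df_within), ref$Df)
  }
})

test_that("the studentized-range integrator matches independent references", {
  # R's own implementation at the fixture's (k, df)
  for (q in c(0.5, 1.5, 3, 3.98, 4.91, 6))
    expect_equal(pstudrange(q, 4, 19), stats::ptukey(q, 4, 19),
                 tolerance = 1e-8)
  # published critical-value table entries (2 decimals):
  # q(k=4, df=19) = 3.98 and q(k=4, df=20) = 3.96
  expect_equal(round(qstudrange(0.95, 4, 19), 2), 3.98)
  expect_equal(round(qstudrange(0.95, 4, 20), 2), 3.96)
  expect_equal(qstudrange(0.95, 4, 19), stats::qtukey(0.95, 4, 19),
               tolerance = 1e-5)
  # normal-range limit
  expect_equal(pstudrange(3.5, 3, Inf), stats::ptukey(3.5, 3, Inf),
               tolerance = 1e-8)
})

test_that("tukey_kramer reproduces reference adjusted p-values", {
  tab <- table2_cohort()
  d <- tab[tab$metric_name == "cd117_relative_area", ]
  y <- logit(d$value)
  tk <- tukey_kramer(y, d$group)
  # reference: stats::TukeyHSD on the same model
  ref <- stats::TukeyHSD(stats::aov(y ~ factor(d$group)))[[1]]
  for (i in seq_len(nrow(tk))) {
    key1 <- paste0(tk$group_a[i], "-", tk$group_b[i])
    key2 <- paste0(tk$group_b[i], "-", tk$group_a[i])
    row <- if (key1 %in% rownames(ref)) ref[key1, ] else ref[key2, ]
    expect_equal(tk$adjusted_p[i], unname(row["p adj"]), tolerance = 1e-6)
  }
  # q = |diff| / SE identity
  expect_equal(tk$q_statistic, abs(tk$mean_diff) / tk$standard_error)
  # the three disease-vs-healthy comparisons are significant
  vs_healthy <- tk[tk$group_a == "Healthy" | tk$group_b == "Healthy", ]
  expect_equal(nrow(vs_healthy), 3L)
  expect_true(all(vs_healthy$adjusted_p < 0.05))
})

test_that("identical groups give q = 0 and adjusted p = 1", {
  tk <- tukey_kramer(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(tk$q_statistic, 0)
  expect_equal(tk$adjusted_p, 1)
  expect_false(tk$significant)
})

test_that("tukey_kramer protects relative to the unadjusted t-test", {
  tab <- table2_cohort()
  d <- tab[tab$metric_name == "cd117_relative_area", ]
  tk <- tukey_kramer(logit(d$value), d$group)
  an <- attr(tk, "anova")
  # unadjusted two-group p using the pooled MSW: t = q / sqrt(2)
  p_unadj <- 2 * stats::pt(-tk$q_statistic / sqrt(2), an$df_within)
  expect_true(all(tk$adjusted_p >= p_unadj - 1e-12))
})

test_that("F, q and significance are invariant under positive affine maps", {
  tab <- table2_cohort()
  d <- tab[tab$metric_name == "cd117_relative_area", ]
  y <- logit(d$value)
  base_a <- anova_oneway(y, d$group)
  base_t <- tukey_kramer(y, d$group)
  for (ab in list(c(2.5, -3), c(1 / log(10), 0), c(0.1, 100))) {
    y2 <- ab[1] * y + ab[2]
    a2 <- anova_oneway(y2, d$group)
    t2 <- tukey_kramer(y2, d$group)
    expect_equal(a2$F, base_a$F, tolerance = 1e-10)
    expect_equal(t2$q_statistic, base_t$q_statistic, tolerance = 1e-10)
    expect_identical(t2$significant, base_t$significant)
  }
})

test_that("analyze_cohort picks the analysis scale by metric type", {
  tab <- table2_cohort()
  rep_ratio <- analyze_cohort(tab, "cd90_relative_number")
  expect_equal(rep_ratio$scale, "logit")
  expect_s3_class(rep_ratio$anova, "anova_result")
  expect_equal(nrow(rep_ratio$tukey), 6L)
  expect_true(all(c("summary_raw", "summary_analysis") %in%
                    names(rep_ratio)))
  # counts are analysed raw (logit undefined at values >= 1)
  rep_count <- analyze_cohort(tab, "cd90_total_signals")
  expect_equal(rep_count$scale, "raw")
  expect_error(analyze_cohort(tab, "bogus"), "parameter")
})
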