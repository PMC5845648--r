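#' Logit transform
#'
#' `logit(p) = log(p / (1 - p))` with the natural logarithm. Per-section
#' relative numbers and areas are proportions in `(0, 1)` whose group
#' comparisons are best made on this scale. The base of the logarithm is a
#' positive rescaling and therefore cannot change any F statistic,
#' studentized range or significance call; natural log is fixed purely for
#' reproducibility.
#'
#' @param p numeric vector with all values strictly in `(0, 1)`.
#' @return `logit`: numeric vector of logits.
#' @export
#' @examples
#' logit(0.5)            # 0
#' logit(0.2) + logit(0.8)  # 0 by antisymmetry
logit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("domain error: logit needs 0 < p < 1", call. = FALSE)
  log(p / (1 - p))
}

#' @rdname logit
#' @param x numeric vector.
#' @return `inv_logit`: values in `(0, 1)`.
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Assemble and validate a cohort table
#'
#' Long-format per-patient metric table: one row per
#' `(patient_id, metric_name)`. Ratio metrics (relative number/area) must
#' lie strictly in `(0, 1)`; count metrics (`*_total_signals`) are
#' non-negative numbers. Group labels come from the fixed set Healthy,
#' Myocarditis, ICM, DCM.
#'
#' @param df `data.frame` with columns `patient_id`, `group`,
#'   `biopsy_location`, `metric_name`, `value`.
#' @return The validated `data.frame` with class `cohort_table` prepended.
#' @export
cohort_table <- function(df) {
  need <- c("patient_id", "group", "biopsy_location", "metric_name", "value")
  if (!all(need %in% names(df)))
    stop("format error: cohort table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$group), .group_levels)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df[c("patient_id", "metric_name")]))
    stop("duplicate (patient_id, metric_name) rows", call. = FALSE)
  ratio <- .is_ratio_metric(df$metric_name)
  v <- df$value
  if (any(!is.finite(v))) stop("values must be finite", call. = FALSE)
  if (any(ratio & (v <= 0 | v >= 1)))
    stop("ratio metrics must lie strictly in (0, 1)", call. = FALSE)
  if (any(!ratio & v < 0))
    stop("count metrics must be non-negative", call. = FALSE)
  class(df) <- c("cohort_table", setdiff(class(df), "cohort_table"))
  df
}

.is_ratio_metric <- function(metric_name) {
  grepl("relative|ratio|area_fraction", metric_name)
}

#' Read a cohort table from CSV
#' @param path CSV with the [cohort_table()] columns.
#' @return A `cohort_table`.
#' @export
read_cohort_csv <- function(path) {
  cohort_table(read.csv(path, stringsAsFactors = FALSE))
}

#' The packaged 23-patient reference cohort
#'
#' Per-patient whole-slide quantification results for the four metrics
#' (total CD90 signals, relative number and area of CD90, relative area of
#' CD117) across the four diagnosis groups (Healthy n = 3, Myocarditis
#' n = 3, ICM n = 10, DCM n = 7), copied verbatim at printed precision
#' from the published per-patient table.
#'
#' @return A `cohort_table` with 92 rows (23 patients x 4 metrics).
#' @export
table2_cohort <- function() {
  path <- system.file("extdata", "table2_cohort.csv", package = "cpcquant",
                      mustWork = TRUE)
  read_cohort_csv(path)
}

#' Per-group summaries of one metric
#'
#' @param table a [cohort_table()].
#' @param metric_name metric to summarise.
#' @param scale `"raw"` or `"logit"` (ratio metrics only).
#' @return `data.frame` with `group`, `n`, `mean`, `sd` (sample sd; 0 for a
#'   single observation) and `scale`; groups in fixed cohort order.
#' @export
group_summary <- function(table, metric_name, scale = c("raw", "logit")) {
  scale <- match.arg(scale)
  d <- table[table$metric_name == metric_name, ]
  if (nrow(d) == 0L)
    stop("parameter error: unknown metric '", metric_name, "'",
         call. = FALSE)
  v <- d$value
  if (scale == "logit") v <- logit(v)
  lev <- intersect(.group_levels, unique(d$group))
  out <- do.call(rbind, lapply(lev, function(g) {
    x <- v[d$group == g]
    data.frame(group = g, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) sd(x) else 0,
               scale = scale, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition: `F = MSB / MSW` with
#' `df_between = k - 1`, `df_within = N - k`, and the p-value from the
#' upper tail of the F distribution.
#'
#' @param values numeric observations.
#' @param groups group label per observation (`>= 2` groups, `N > k`).
#' @return Object of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p_value`, plus `ms_within`, `group_means`, `group_n`, `grand_mean`,
#'   `ss_between`, `ss_within`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  k <- length(lev)
  N <- length(values)
  if (k < 2L) stop("parameter error: need >= 2 groups", call. = FALSE)
  if (N <= k) stop("parameter error: need N > number of groups",
                   call. = FALSE)
  n_g <- vapply(lev, function(g) sum(groups == g), integer(1))
  m_g <- vapply(lev, function(g) mean(values[groups == g]), numeric(1))
  grand <- mean(values)
  ssb <- sum(n_g * (m_g - grand)^2)
  ssw <- sum((values - m_g[match(groups, lev)])^2)
  if (ssw == 0)
    stop(errorCondition(
      "degenerate-variance error: all within-group values identical",
      class = "cpcquant_degenerate_error"))
  dfb <- k - 1L
  dfw <- N - k
  f <- (ssb / dfb) / (ssw / dfw)
  structure(list(F = f, df_between = dfb, df_within = dfw,
                 p_value = pf(f, dfb, dfw, lower.tail = FALSE),
                 ms_within = ssw / dfw, group_means = m_g, group_n = n_g,
                 grand_mean = grand, ss_between = ssb, ss_within = ssw),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  invisible(x)
}

#' Tukey-Kramer all-pairs post-hoc comparisons
#'
#' For each group pair `(i, j)`:
#' `SE = sqrt(MSW / 2 * (1/n_i + 1/n_j))`, `q = |mean_i - mean_j| / SE`,
#' and the adjusted p-value is the upper tail of the studentized range
#' distribution with `(k, df_within)` (the Kramer form of `SE` makes the
#' procedure valid for unequal group sizes).
#'
#' @inheritParams anova_oneway
#' @param alpha familywise significance level (default 0.05).
#' @return `data.frame` of class `tukey_result`: `group_a`, `group_b`,
#'   `mean_diff` (`mean_a - mean_b`), `standard_error`, `q_statistic`,
#'   `adjusted_p`, `significant`.
#' @export
tukey_kramer <- function(values, groups, alpha = 0.05) {
  an <- anova_oneway(values, groups)
  lev <- names(an$group_means)
  k <- length(lev)
  pairs <- utils::combn(k, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    se <- sqrt(an$ms_within / 2 *
                 (1 / an$group_n[i] + 1 / an$group_n[j]))
    diff <- an$group_means[i] - an$group_means[j]
    q <- abs(diff) / se
    adj <- 1 - pstudrange(q, k, an$df_within)
    data.frame(group_a = lev[i], group_b = lev[j], mean_diff = diff,
               standard_error = se, q_statistic = q, adjusted_p = adj,
               significant = adj < alpha, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "anova") <- an
  class(out) <- c("tukey_result", class(out))
  out
}

#' Full cohort analysis of one metric
#'
#' The complete statistics layer for a metric: ratio metrics are
#' logit-transformed (counts are analysed raw, since proportions' logit
#' domain excludes values >= 1), then per-group summaries, one-way ANOVA
#' and Tukey-Kramer comparisons are computed on the analysis scale.
#'
#' @param table a [cohort_table()].
#' @param metric_name metric to analyse.
#' @param alpha significance level (default 0.05).
#' @return Object of class `stats_report`: list with `metric_name`,
#'   `scale` (`"logit"` or `"raw"`), `summary_raw`, `summary_analysis`,
#'   `anova`, `tukey`, `alpha`.
#' @export
analyze_cohort <- function(table, metric_name, alpha = 0.05) {
  d <- table[table$metric_name == metric_name, ]
  if (nrow(d) == 0L)
    stop("parameter error: unknown metric '", metric_name, "'",
         call. = FALSE)
  use_logit <- .is_ratio_metric(metric_name)
  scale <- if (use_logit) "logit" else "raw"
  v <- if (use_logit) logit(d$value) else d$value
  structure(list(
    metric_name = metric_name, scale = scale,
    summary_raw = group_summary(table, metric_name, "raw"),
    summary_analysis = group_summary(table, metric_name,
                                     if (use_logit) "logit" else "raw"),
    anova = anova_oneway(v, d$group),
    tukey = tukey_kramer(v, d$group, alpha = alpha),
    alpha = alpha), class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("== Cohort analysis:", x$metric_name, "(scale:", x$scale, ") ==\n")
  cat("\nGroup summaries (analysis scale):\n")
  print(x$summary_analysis, row.names = FALSE)
  cat("\n")
  print(x$anova)
  cat(sprintf("\nTukey-Kramer pairwise comparisons (alpha = %g):\n",
              x$alpha))
  t <- as.data.frame(x$tukey)
  t$mean_diff <- round(t$mean_diff, 4)
  t$standard_error <- round(t$standard_error, 4)
  t$q_statistic <- round(t$q_statistic, 4)
  t$adjusted_p <- signif(t$adjusted_p, 4)
  print(t, row.names = FALSE)
  invisible(x)
}
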