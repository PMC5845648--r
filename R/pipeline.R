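#' Pipeline configuration
#'
#' One flat configuration object covering every tunable of the image
#' pipeline, serialisable to and from a single YAML file. Precedence when
#' assembling: explicit arguments > config file > defaults.
#'
#' @param stain_hematoxylin,stain_chromogen length-3 OD vectors overriding
#'   the default stain basis.
#' @param positivity_od,adaptive_threshold,min_signal_area_um2,concat_area_threshold_um2,min_peak_separation_um
#'   signal-detection parameters, see [signal_params()].
#' @param min_od,min_tissue_fragment_um2 tissue segmentation parameters,
#'   see [segment_tissue()].
#' @param edge_margin_um edge-exclusion margin (microns).
#' @param mpp microns per pixel of the input slides.
#' @param match_radius_um co-expression matching radius.
#' @param field_area_mm2 analysis-field area for co-expression.
#' @param alpha significance level for the statistics layer.
#' @param seed integer seed recorded in provenance.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(stain_hematoxylin = c(0.650, 0.704, 0.286),
                            stain_chromogen = c(0.274, 0.679, 0.680),
                            positivity_od = 0.15,
                            adaptive_threshold = FALSE,
                            min_signal_area_um2 = 20,
                            concat_area_threshold_um2 = 300,
                            min_peak_separation_um = 5,
                            min_od = 0.05,
                            min_tissue_fragment_um2 = 500,
                            edge_margin_um = 20,
                            mpp = 0.5,
                            match_radius_um = 15,
                            field_area_mm2 = 4,
                            alpha = 0.05,
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$mpp > 0, cfg$edge_margin_um >= 0, cfg$alpha > 0,
            cfg$alpha < 1, cfg$positivity_od >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML, applying overrides
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments
#'   (missing keys fall back to defaults); `NULL` for pure defaults.
#' @param overrides named list applied on top (CLI > config > defaults).
#' @return A `pipeline_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("config file not found: ", path, call. = FALSE)
    vals <- yaml::read_yaml(path)
    unknown <- setdiff(names(vals), names(formals(pipeline_config)))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Stable hash of a configuration (provenance)
#' @param config a `pipeline_config`.
#' @return md5 string of the canonical YAML serialisation.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}

.log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Quantify one whole-slide image
#'
#' End-to-end composition of the image layer: stain separation ->
#' tissue masking (with edge exclusion) -> signal detection and
#' single/concatenated classification -> per-section metrics. Stages are
#' logged to stderr; errors are annotated with the slide id and stage.
#'
#' @param x an [rgb_slide], or a path to an 8-bit RGB PNG.
#' @param config a [pipeline_config()].
#' @param marker marker label when `x` is a path.
#' @param out_dir optional directory receiving per-slide outputs: the
#'   metrics CSV row, the per-component CSV, the tissue mask (PNG + JSON
#'   sidecar) and a 16-bit label PNG.
#' @param verbose log per-stage progress to stderr.
#' @return A [slide_metrics()] row; attributes `components` and `tissue`
#'   carry the intermediate objects.
#' @export
quantify_slide <- function(x, config = pipeline_config(), marker = "",
                           out_dir = NULL, verbose = FALSE) {
  slide <- if (inherits(x, "rgb_slide")) x else
    read_slide_png(x, mpp = config$mpp, marker = marker)
  stage <- "stain_separation"
  res <- tryCatch({
    t0 <- proc.time()[3]
    basis <- stain_basis(config$stain_hematoxylin, config$stain_chromogen)
    maps <- separate_stains(slide, basis)
    .log_stage(verbose, "[%s] stain_separation done (%.2fs)",
               slide$slide_id, proc.time()[3] - t0)

    stage <- "tissue_detection"
    tis <- segment_tissue(slide, maps, min_od = config$min_od,
                          min_tissue_fragment_um2 =
                            config$min_tissue_fragment_um2)
    tis <- exclude_edge(tis, config$edge_margin_um)
    if (tis$tissue_area_px == 0L)
      stop(errorCondition("no tissue: the tissue mask is empty",
                          class = "cpcquant_degenerate_error"))
    .log_stage(verbose, "[%s] tissue_detection done: %d px",
               slide$slide_id, tis$tissue_area_px)

    stage <- "signal_quantification"
    sp <- signal_params(
      positivity_od = config$positivity_od,
      adaptive = config$adaptive_threshold,
      min_signal_area_um2 = config$min_signal_area_um2,
      concat_area_threshold_um2 = config$concat_area_threshold_um2,
      min_peak_separation_um = config$min_peak_separation_um)
    comps <- detect_signals(maps, tis, sp)
    comps <- split_single_concatenated(comps, maps, sp)
    m <- slide_metrics(comps, tis, slide_id = slide$slide_id,
                       marker = if (nzchar(marker)) marker else
                         slide$marker)
    attr(m, "components") <- comps
    attr(m, "tissue") <- tis
    m
  }, error = function(e) {
    extra <- setdiff(class(e), c("simpleError", "error", "condition"))
    stop(errorCondition(
      sprintf("slide '%s', stage %s: %s", slide$slide_id, stage,
              conditionMessage(e)),
      class = c(extra, "cpcquant_pipeline_error")))
  })
  if (!is.null(out_dir)) .write_slide_outputs(res, out_dir, config)
  res
}

.write_slide_outputs <- function(metrics, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  id <- metrics$slide_id
  comps <- attr(metrics, "components")
  tis <- attr(metrics, "tissue")
  write.csv(as.data.frame(metrics)[, 1:9],
            file.path(out_dir, paste0(id, "_metrics.csv")),
            row.names = FALSE, quote = FALSE)
  write.csv(as.data.frame(comps),
            file.path(out_dir, paste0(id, "_components.csv")),
            row.names = FALSE, quote = FALSE)
  write_mask(tis, file.path(out_dir, paste0(id, "_mask.png")),
             slide_id = id, margin_um = config$edge_margin_um)
  lab <- attr(comps, "labels")
  png::writePNG(lab / 65535, file.path(out_dir, paste0(id, "_labels.png")))
  invisible(out_dir)
}

#' Run the cohort statistics on a metrics table
#'
#' @param input a [cohort_table()], a CSV path with its columns, or the
#'   fixture flag `"table2"` for the packaged 23-patient reference cohort.
#' @param metric_name metric to analyse, e.g. `"cd117_relative_area"`.
#' @param config a [pipeline_config()] (supplies `alpha` and provenance).
#' @param out_json,out_txt optional report outputs (JSON, plain text).
#' @return A `stats_report` (see [analyze_cohort()]) with a `provenance`
#'   attribute (config hash, seed, package version).
#' @export
run_cohort_analysis <- function(input, metric_name,
                                config = pipeline_config(),
                                out_json = NULL, out_txt = NULL) {
  tab <- if (inherits(input, "cohort_table")) input
  else if (identical(input, "table2")) table2_cohort()
  else read_cohort_csv(input)
  if (length(unique(tab$group[tab$metric_name == metric_name])) < 2L)
    stop("format error: need at least 2 groups for metric '", metric_name,
         "'", call. = FALSE)
  rep <- analyze_cohort(tab, metric_name, alpha = config$alpha)
  prov <- list(config_hash = config_hash(config), seed = config$seed,
               version = .cpcquant_version())
  attr(rep, "provenance") <- prov
  if (!is.null(out_json)) write_stats_json(rep, out_json)
  if (!is.null(out_txt)) {
    con <- file(out_txt, "w")
    sink(con); print(rep); sink()
    close(con)
  }
  rep
}

#' Serialise a stats report to JSON
#' @param report a `stats_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(report, path) {
  x <- list(
    metric_name = report$metric_name, scale = report$scale,
    alpha = report$alpha,
    summary_raw = report$summary_raw,
    summary_analysis = report$summary_analysis,
    anova = report$anova[c("F", "df_between", "df_within", "p_value")],
    tukey = as.data.frame(report$tukey),
    provenance = attr(report, "provenance"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
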