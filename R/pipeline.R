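#' Pipeline configuration
#'
#' Collects every analysis constant in one validated object. The defaults
#' are the study's printed values: 1.5 s apnea threshold, FDR < 0.05 with
#' signed fold change >= 1.2 in magnitude, significance at P <= 0.05,
#' ventilation windows of at least 10 s totalling at least 60 s from the
#' last 300 s of a condition, 600 s of pattern data, 20 ul calibration
#' injections at 3 Hz, and GREAT-default regulatory domains (5 kb up, 1 kb
#' down, 1 Mb maximum extension).
#'
#' @param apnea_threshold_s apnea threshold, seconds.
#' @param fdr_threshold,fc_threshold DE calling thresholds.
#' @param significance_p group-comparison significance level.
#' @param min_segment_s,min_total_s,tail_s,pattern_cap_s window policy
#'   parameters, seconds.
#' @param cal_volume_ul,cal_rate_hz calibration injection volume and rate.
#' @param basal_up,basal_down,max_ext regulatory-domain geometry, bp.
#' @param hi_frac,lo_frac,refractory_s breath-segmentation parameters.
#' @param drift_correction drift-correction mode for [integrate_flow()].
#' @param seed integer seed for any stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(apnea_threshold_s = 1.5, fdr_threshold = 0.05,
                            fc_threshold = 1.2, significance_p = 0.05,
                            min_segment_s = 10, min_total_s = 60,
                            tail_s = 300, pattern_cap_s = 600,
                            cal_volume_ul = 20, cal_rate_hz = 3,
                            basal_up = 5000, basal_down = 1000,
                            max_ext = 1e6, hi_frac = 0.5, lo_frac = 0.25,
                            refractory_s = 0.1,
                            drift_correction = "rolling_quantile",
                            seed = 1L) {
  for (nm in c("apnea_threshold_s", "fdr_threshold", "fc_threshold",
               "significance_p", "min_segment_s", "min_total_s", "tail_s",
               "pattern_cap_s", "cal_volume_ul", "cal_rate_hz", "basal_up",
               "basal_down", "max_ext", "hi_frac", "lo_frac",
               "refractory_s"))
    check_scalar_num(get(nm), nm, 0, strict_lower = TRUE)
  drift_correction <- match.arg(drift_correction,
                                c("rolling_quantile", "rolling_median",
                                  "linear", "none"))
  structure(list(apnea_threshold_s = apnea_threshold_s,
                 fdr_threshold = fdr_threshold,
                 fc_threshold = fc_threshold,
                 significance_p = significance_p,
                 min_segment_s = min_segment_s, min_total_s = min_total_s,
                 tail_s = tail_s, pattern_cap_s = pattern_cap_s,
                 cal_volume_ul = cal_volume_ul, cal_rate_hz = cal_rate_hz,
                 basal_up = basal_up, basal_down = basal_down,
                 max_ext = max_ext, hi_frac = hi_frac, lo_frac = lo_frac,
                 refractory_s = refractory_s,
                 drift_correction = drift_correction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML mapping whose keys are [pipeline_config()] arguments;
#' unknown keys are an error, missing keys take the defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(formals(pipeline_config)))
  if (length(unknown))
    stop_input("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline on a set of inputs
#'
#' Orchestrates the three analysis arms on whatever inputs are supplied:
#'
#' * `pleth`: a list of recordings, each
#'   `list(id =, trace =, cal_trace =)` with condition epochs on the trace.
#'   Every epoch is integrated, segmented, calibrated and summarised
#'   (ventilation + pattern statistics); epochs with insufficient
#'   artifact-free data are flagged rather than failing the run.
#' * `expr`: `list(a = list(values =, groups =), b = ...)`. Each study is
#'   quantile-normalized, tested for differential expression and
#'   thresholded; with both studies present, overlap and reciprocity
#'   statistics are computed on the shared deregulated genes.
#' * `chip`: `list(peaks =, genes =)`. Peaks are assigned to genes via
#'   regulatory domains; with both expression studies present, the
#'   three-way intersections (any-direction and reciprocal-only) are
#'   reported.
#'
#' @param config a [pipeline_config()].
#' @param inputs list with any of `pleth`, `expr`, `chip` as above.
#' @return List of class `pipeline_report` with sections `ventilation`,
#'   `pattern`, `de`, `overlap`, `triangulation`, `counts` and the `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(config = unclass(config), errors = character(0))
  counts <- list()

  if (!is.null(inputs$pleth)) {
    vent <- list(); patt <- list()
    for (rec in inputs$pleth) {
      cal <- calibrate(rec$cal_trace, config$cal_volume_ul)
      vol <- integrate_flow(rec$trace, config$drift_correction)
      series <- segment_breaths(vol, config$hi_frac, config$lo_frac,
                                config$refractory_s)
      for (lab in rec$trace$epochs$label) {
        key <- paste(rec$id, lab, sep = ".")
        wv <- select_windows(rec$trace, lab, "ventilation",
                             config$min_segment_s, config$min_total_s,
                             config$tail_s, config$pattern_cap_s)
        if (wv$insufficient) {
          report$errors <- c(report$errors, sprintf(
            "%s: insufficient ventilation windows (%.1f s)", key,
            wv$cumulative_s))
        } else {
          vent[[key]] <- ventilation_summary(series, cal, wv,
                                             condition = lab)
        }
        wp <- select_windows(rec$trace, lab, "pattern",
                             config$min_segment_s, config$min_total_s,
                             config$tail_s, config$pattern_cap_s)
        if (!wp$insufficient)
          patt[[key]] <- pattern_summary(series, wp,
                                         config$apnea_threshold_s)
      }
    }
    report$ventilation <- vent
    report$pattern <- patt
    counts$recordings <- length(inputs$pleth)
  }

  des <- list()
  if (!is.null(inputs$expr)) {
    for (nm in names(inputs$expr)) {
      st <- inputs$expr[[nm]]
      norm <- normalize_quantile(st$values)
      res <- de_test(norm, st$groups)
      sets <- threshold_filter(res, config$fdr_threshold,
                               config$fc_threshold)
      des[[nm]] <- list(records = res, sets = sets)
      counts[[paste0("genes_", nm)]] <- nrow(res)
      counts[[paste0("dereg_", nm)]] <- length(sets$up) + length(sets$down)
    }
    report$de <- lapply(des, function(d) list(
      n_up = length(d$sets$up), n_down = length(d$sets$down),
      up = d$sets$up, down = d$sets$down))
    if (all(c("a", "b") %in% names(des))) {
      universe <- intersect(rownames(inputs$expr$a$values),
                            rownames(inputs$expr$b$values))
      sa <- des$a$sets; sb <- des$b$sets
      ov <- overlap_test(intersect(c(sa$up, sa$down), universe),
                         intersect(c(sb$up, sb$down), universe), universe)
      rec <- classify_reciprocity(ov$overlap_genes, sa$directions,
                                  sb$directions)
      report$overlap <- list(
        overlap_size = ov$overlap_size, overlap_genes = ov$overlap_genes,
        p_hypergeometric = ov$p_hypergeometric,
        reciprocal = rec$reciprocal, concordant = rec$concordant,
        uu = rec$uu, dd = rec$dd, ud = rec$ud, du = rec$du,
        p_binomial = reciprocity_test(rec$reciprocal, rec$m))
    }
  }

  if (!is.null(inputs$chip)) {
    assoc <- assign_peaks(inputs$chip$peaks, inputs$chip$genes,
                          config$basal_up, config$basal_down,
                          config$max_ext)
    chip_genes <- sort(unique(assoc$gene_id))
    tri <- list(n_peaks = NROW(inputs$chip$peaks),
                n_associations = nrow(assoc),
                chip_genes = chip_genes)
    if (nrow(assoc))
      tri$tss_histogram <- tss_distance_histogram(assoc)
    if (all(c("a", "b") %in% names(des))) {
      tri$common_genes <- three_way_intersect(chip_genes, des$a$sets,
                                              des$b$sets)
      tri$reciprocal_targets <- three_way_intersect(chip_genes, des$a$sets,
                                                    des$b$sets,
                                                    require_reciprocal = TRUE)
    }
    report$triangulation <- tri
    counts$peaks <- NROW(inputs$chip$peaks)
    counts$peak_gene_associations <- nrow(assoc)
  }

  report$counts <- counts
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (!is.null(x$ventilation))
    cat(sprintf("  ventilation summaries: %d\n", length(x$ventilation)))
  if (!is.null(x$de))
    for (nm in names(x$de))
      cat(sprintf("  DE study %s: %d up, %d down\n", nm, x$de[[nm]]$n_up,
                  x$de[[nm]]$n_down))
  if (!is.null(x$overlap))
    cat(sprintf("  overlap %d (p=%.3g), reciprocal %d (p=%.3g)\n",
                x$overlap$overlap_size, x$overlap$p_hypergeometric,
                x$overlap$reciprocal, x$overlap$p_binomial))
  if (!is.null(x$triangulation)) {
    cat(sprintf("  peak-gene associations: %d\n",
                x$triangulation$n_associations))
    if (!is.null(x$triangulation$common_genes))
      cat(sprintf("  triangulated genes: %d (%d reciprocal)\n",
                  length(x$triangulation$common_genes),
                  length(x$triangulation$reciprocal_targets)))
  }
  if (length(x$errors)) cat("  flagged:", length(x$errors), "section(s)\n")
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Deterministic machine-readable output: no timestamps, stable key order,
#' so two runs with identical config and inputs produce identical bytes.
#'
#' @param report a `pipeline_report`.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(x) {
    if (is.data.frame(x)) return(as.data.frame(unclass(x)))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       dataframe = "columns")
  invisible(path)
}
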