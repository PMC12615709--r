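#' Run configuration for a paired stain study
#'
#' @param suppress_marker detect and mask embedded marker lines before
#'   computing metrics (see [preprocess()]).
#' @param params marker-suppression parameters ([preprocess_params()]).
#' @param output_dir directory for the CSV/JSON outputs; `NULL` skips writing.
#' @param seed integer seed recorded in the run report (the analysis itself is
#'   deterministic; the seed matters only when inputs are simulated).
#' @param verbose log per-stage progress to standard error.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(suppress_marker = TRUE, params = preprocess_params(),
                       output_dir = NULL, seed = 1L, verbose = FALSE) {
  structure(list(suppress_marker = suppress_marker, params = params,
                 output_dir = output_dir, seed = as.integer(seed),
                 verbose = verbose),
            class = "run_config")
}

#' Validate a study manifest
#'
#' Checks the pairing contract of a manifest (columns `organism`, `dye_role`,
#' `path`): every organism must appear exactly once per dye role, roles must
#' be `test` or `standard`, and every path must exist. Never raises; all
#' problems are returned together.
#'
#' @param manifest data frame with columns `organism`, `dye_role`, `path`.
#' @return character vector of violations; empty when the manifest is valid.
#' @export
validate_manifest <- function(manifest) {
  problems <- character(0)
  need <- c("organism", "dye_role", "path")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols) > 0L)
    return(sprintf("manifest lacks column '%s'", missing_cols))
  if (nrow(manifest) == 0L) return("manifest is empty")
  bad_role <- unique(manifest$dye_role[!manifest$dye_role %in% c("test", "standard")])
  for (r in bad_role)
    problems <- c(problems, sprintf("unknown dye_role '%s'", r))
  for (org in unique(manifest$organism)) {
    for (role in c("test", "standard")) {
      k <- sum(manifest$organism == org & manifest$dye_role == role)
      if (k == 0L)
        problems <- c(problems,
                      sprintf("organism '%s' lacks a '%s' image", org, role))
      else if (k > 1L)
        problems <- c(problems,
                      sprintf("organism '%s' has %d '%s' rows (need 1)", org, k, role))
    }
  }
  for (p in unique(manifest$path[!file.exists(manifest$path)]))
    problems <- c(problems, sprintf("image file does not exist: '%s'", p))
  problems
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run a full paired stain study
#'
#' Orchestrates the complete analysis: every image in the manifest is loaded,
#' preprocessed (optional marker suppression), and scored with the five
#' quality metrics; the per-image table is then paired by organism and
#' summarized per metric (means, mean difference, sd of differences, Cohen's
#' d, exact Wilcoxon signed-rank p). With `output_dir` set, the per-image
#' table, the summary table and a JSON run report (configuration, package
#' version, input digests) are written; reruns with identical inputs and
#' configuration produce byte-identical files.
#'
#' @param manifest data frame with columns `organism`, `dye_role`, `path`
#'   (PNG/TIFF images), or the path of such a CSV file.
#' @param config a [run_config()].
#' @return a list with `metrics` (per-image data frame: `organism`,
#'   `dye_role`, `path`, five metric columns) and `summary` (5-row per-metric
#'   data frame, see [summarize_study()]).
#' @export
run_study <- function(manifest, config = run_config()) {
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  problems <- validate_manifest(manifest)
  if (length(problems) > 0L)
    stop("invalid manifest:\n  ", paste(problems, collapse = "\n  "))
  log_stage(config$verbose, "run_study: %d images, marker suppression %s",
            nrow(manifest), if (config$suppress_marker) "on" else "off")
  metric_rows <- lapply(seq_len(nrow(manifest)), function(i) {
    path <- manifest$path[i]
    img <- tryCatch(read_gray_image(path),
                    error = function(e) stop("cannot load image '", path, "': ",
                                             conditionMessage(e), call. = FALSE))
    pre <- preprocess(img, config$suppress_marker, config$params)
    log_stage(config$verbose, "  %s/%s: %dx%d, %d line(s) masked",
              manifest$organism[i], manifest$dye_role[i],
              nrow(img), ncol(img), nrow(pre$lines))
    mv <- metric_vector(pre$image, pre$mask)
    cbind(data.frame(organism = manifest$organism[i],
                     dye_role = manifest$dye_role[i],
                     path = path, stringsAsFactors = FALSE),
          as.data.frame(as.list(mv)))
  })
  metrics <- do.call(rbind, metric_rows)
  summary <- summarize_study(metrics_table_to_records(metrics))
  log_stage(config$verbose, "run_study: summarized %d metrics over %d organisms",
            nrow(summary), length(unique(metrics$organism)))
  if (!is.null(config$output_dir))
    write_study_outputs(metrics, summary, manifest, config)
  list(metrics = metrics, summary = summary)
}

# fixed-precision formatting so reruns are byte-identical:
# metrics at 6 significant digits, p-values at 4 decimals
format_sig <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", trimws(formatC(x, digits = digits, format = "g")))
}

write_formatted_csv <- function(df, numeric_cols, path, p_cols = character(0)) {
  out <- df
  for (cn in numeric_cols)
    out[[cn]] <- format_sig(df[[cn]])
  for (cn in p_cols)
    out[[cn]] <- formatC(df[[cn]], digits = 4, format = "f")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write study outputs to disk
#'
#' Writes `metrics.csv` (per-image table), `summary.csv` (per-metric table)
#' and `run_report.json` (configuration, package version, md5 digests of the
#' input images) into `config$output_dir`.
#'
#' @param metrics,summary the two tables produced by [run_study()].
#' @param manifest the input manifest.
#' @param config the [run_config()] used.
#' @return the output directory, invisibly.
#' @export
write_study_outputs <- function(metrics, summary, manifest, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_formatted_csv(metrics, METRIC_NAMES,
                      file.path(config$output_dir, "metrics.csv"))
  write_formatted_csv(summary,
                      c("mean_test", "mean_standard", "mean_difference",
                        "sd_difference", "cohens_d"),
                      file.path(config$output_dir, "summary.csv"),
                      p_cols = "p_value")
  report <- list(
    package = "stainqual",
    version = as.character(packageVersion("stainqual")),
    config = list(suppress_marker = config$suppress_marker,
                  params = config$params, seed = config$seed),
    inputs = data.frame(path = manifest$path,
                        md5 = unname(tools::md5sum(manifest$path)),
                        stringsAsFactors = FALSE))
  jsonlite::write_json(report, file.path(config$output_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$output_dir)
}

#' Summarize a precomputed metric table
#'
#' The statistics-only entry point: takes a per-image metric table (the same
#' layout [run_study()] produces, or the packaged [stain_study_metrics()]
#' table) and computes the per-metric study summary without touching any
#' image. Running this on the metric table of a full [run_study()] pass
#' reproduces that run's summary exactly.
#'
#' @param df per-image metric data frame (columns `organism`, `dye_role`,
#'   five metrics), or the path of such a CSV file.
#' @return a 5-row per-metric summary data frame (see [summarize_study()]).
#' @export
#' @examples
#' compare_metrics(stain_study_metrics())
compare_metrics <- function(df) {
  if (is.character(df) && length(df) == 1L)
    df <- read.csv(df, stringsAsFactors = FALSE)
  summarize_study(metrics_table_to_records(df))
}
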