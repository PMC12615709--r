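#' One organism's paired stain record
#'
#' Couples the quality [metric_vector()] of the test-dye image with that of
#' the standard-dye image for one organism — one paired observation of the
#' dye-comparison design.
#'
#' @param organism organism label (unique within a study).
#' @param test,standard named numeric vectors with elements `sharpness`,
#'   `entropy`, `contrast`, `snr`, `edge_intensity` (as from
#'   [metric_vector()]).
#' @return an object of class `paired_stain_record`.
#' @export
paired_stain_record <- function(organism, test, standard) {
  for (v in list(test, standard)) {
    if (!is.numeric(v) || !all(METRIC_NAMES %in% names(v)) || anyNA(v[METRIC_NAMES]))
      stop("test and standard must be complete named metric vectors")
  }
  structure(list(organism = as.character(organism),
                 test = test[METRIC_NAMES], standard = standard[METRIC_NAMES]),
            class = "paired_stain_record")
}

#' Per-organism paired differences for one metric
#'
#' Returns `standard - test` for the named metric, in record order. The sign
#' convention makes a positive difference mean the standard dye scored higher.
#'
#' @param records list of [paired_stain_record()] objects.
#' @param metric one of `"sharpness"`, `"entropy"`, `"contrast"`, `"snr"`,
#'   `"edge_intensity"`.
#' @return numeric vector, one element per record.
#' @export
paired_differences <- function(records, metric) {
  metric <- match.arg(metric, METRIC_NAMES)
  if (length(records) < 1L) stop("need at least one record")
  vapply(records, function(r) {
    stopifnot(inherits(r, "paired_stain_record"))
    unname(r$standard[[metric]] - r$test[[metric]])
  }, numeric(1))
}

#' Exact null distribution of the signed-rank statistic
#'
#' Counts, over all `2^n` assignments of signs to the given (mid)ranks, how
#' many assignments yield each value of the positive-rank sum `W+`. Computed
#' by dynamic programming over the doubled-rank integers, which enumerates the
#' sign assignments exactly; midranks (half-integers) are supported.
#'
#' @param ranks numeric vector of ranks of the absolute differences (integer
#'   or half-integer midranks).
#' @return a data frame with columns `w` (attainable statistic values on the
#'   original half-integer scale) and `count` (number of sign assignments);
#'   counts sum to `2^length(ranks)`.
#' @seealso [wilcoxon_exact()]
#' @export
#' @examples
#' d <- signed_rank_null(1:6)
#' sum(d$count[d$w <= 8]) / 2^6  # 22/64
signed_rank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  if (any(abs(2 * ranks - r2) > 1e-8))
    stop("ranks must be integers or half-integer midranks")
  counts <- 1
  for (rr in r2) {
    grown <- c(counts, rep(0, rr))
    grown[(rr + 1):(rr + length(counts))] <-
      grown[(rr + 1):(rr + length(counts))] + counts
    counts <- grown
  }
  w2 <- seq_along(counts) - 1L
  keep <- counts > 0
  data.frame(w = w2[keep] / 2, count = counts[keep])
}

#' Exact two-sided Wilcoxon signed-rank test
#'
#' Small-sample exact test for paired differences. Zero differences are
#' dropped (the classical convention); the absolute values of the remaining
#' differences are ranked with midranks for ties; the two-sided p-value is
#' `P(T <= min(W+, W-)) + P(T >= max(W+, W-))` under the exact null obtained
#' from all `2^n` sign assignments of the observed rank multiset
#' ([signed_rank_null()]). No normal approximation and no continuity
#' correction are ever applied; for untied data this reduces to the
#' closed-form signed-rank distribution.
#'
#' @param diffs numeric vector of paired differences, `1 <= n <= 20` after
#'   removing zeros is required (the enumeration bound); an all-zero vector is
#'   an error (the test is undefined).
#' @return the exact two-sided p-value, in `(0, 1]`.
#' @export
#' @examples
#' wilcoxon_exact(c(3.21, -9.17, 40.29, 56.05, 1.56, -44.41))  # 0.6875
wilcoxon_exact <- function(diffs) {
  if (!is.numeric(diffs) || length(diffs) < 1L)
    stop("diffs must be a non-empty numeric vector")
  if (length(diffs) > 20L)
    stop("n > 20: exact enumeration not supported; use an approximate test")
  d <- diffs[diffs != 0]
  if (length(d) == 0L)
    stop("all differences are zero: signed-rank test undefined")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  null <- signed_rank_null(r)
  total <- 2^length(d)
  lo <- sum(null$count[null$w <= min(w_pos, w_neg) + 1e-9])
  hi <- sum(null$count[null$w >= max(w_pos, w_neg) - 1e-9])
  min(1, (lo + hi) / total)
}

#' Summary statistics for one metric's paired differences
#'
#' One column of the study summary: the per-dye means, the mean difference
#' (`mean_standard - mean_test`), the sample (n-1) standard deviation of the
#' differences, the paired Cohen's d (mean difference over the standard
#' deviation of the differences), and the exact two-sided signed-rank p-value.
#' When the differences have zero spread, Cohen's d is reported as `NA`
#' (undefined), not an error.
#'
#' @param diffs numeric vector of paired differences (standard minus test).
#' @param mean_test,mean_standard the per-dye means of the metric.
#' @param metric metric name carried into the output.
#' @return a one-row data frame with columns `metric`, `mean_test`,
#'   `mean_standard`, `mean_difference`, `sd_difference`, `cohens_d`,
#'   `p_value`.
#' @export
summarize_metric <- function(diffs, mean_test, mean_standard,
                             metric = "metric") {
  n <- length(diffs)
  sd_diff <- if (n >= 2L) sd(diffs) else NA_real_
  md <- mean(diffs)
  cohens_d <- if (!is.na(sd_diff) && sd_diff > 0) md / sd_diff else NA_real_
  data.frame(metric = metric,
             mean_test = mean_test,
             mean_standard = mean_standard,
             mean_difference = md,
             sd_difference = sd_diff,
             cohens_d = cohens_d,
             p_value = wilcoxon_exact(diffs),
             stringsAsFactors = FALSE)
}

#' Per-metric summary of a paired stain study
#'
#' Computes, for each of the five metrics in fixed order (sharpness, entropy,
#' contrast, snr, edge_intensity), the per-dye means, mean difference, sample
#' standard deviation of the differences, paired Cohen's d, and the exact
#' two-sided Wilcoxon signed-rank p-value.
#'
#' @param records list of [paired_stain_record()] objects (>= 2).
#' @return a 5-row data frame, one row per metric (see [summarize_metric()]).
#' @export
#' @examples
#' summarize_study(metrics_table_to_records(stain_study_metrics()))
summarize_study <- function(records) {
  if (length(records) < 2L) stop("need at least two paired records")
  out <- lapply(METRIC_NAMES, function(m) {
    diffs <- paired_differences(records, m)
    summarize_metric(diffs,
                     mean_test = mean(vapply(records, function(r)
                       unname(r$test[[m]]), numeric(1))),
                     mean_standard = mean(vapply(records, function(r)
                       unname(r$standard[[m]]), numeric(1))),
                     metric = m)
  })
  do.call(rbind, out)
}

#' Convert a per-image metric table to paired records
#'
#' @param df data frame with columns `organism`, `dye_role` (values `test`
#'   and `standard`) and the five metric columns — the layout written by
#'   [run_study()] and shipped in [stain_study_metrics()].
#' @return a list of [paired_stain_record()] objects, ordered by first
#'   appearance of each organism.
#' @export
metrics_table_to_records <- function(df) {
  need <- c("organism", "dye_role", METRIC_NAMES)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("metric table lacks columns: ", paste(missing_cols, collapse = ", "))
  organisms <- unique(df$organism)
  lapply(organisms, function(org) {
    rows <- df[df$organism == org, , drop = FALSE]
    for (role in c("test", "standard"))
      if (sum(rows$dye_role == role) != 1L)
        stop("organism '", org, "' must have exactly one '", role, "' row")
    as_vec <- function(role) {
      r <- rows[rows$dye_role == role, METRIC_NAMES]
      stats::setNames(as.numeric(r), METRIC_NAMES)
    }
    paired_stain_record(org, test = as_vec("test"),
                        standard = as_vec("standard"))
  })
}

#' Packaged beetroot-stain study metric table
#'
#' The per-organism image-quality metrics from the motivating comparison of an
#' aqueous beetroot (*Beta vulgaris*) extract against standard dyes (LPCB,
#' India ink) on six fungi: one `test` and one `standard` row per organism
#' with the five metric columns. One value (the standard-dye entropy of
#' *A. niger*) is typeset ambiguously in the original table and is fixed here
#' at 7, the value consistent with the published per-dye entropy mean of 7.0.
#'
#' @return a 12-row data frame with columns `organism`, `dye_role`,
#'   `sharpness`, `entropy`, `contrast`, `snr`, `edge_intensity`.
#' @export
stain_study_metrics <- function() {
  path <- system.file("extdata", "beetroot_stain_study.csv",
                      package = "stainqual", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
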