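#' ROC curve and AUC for scores against binary labels
#'
#' AUC is computed by the Mann-Whitney identity: the fraction of
#' (positive, negative) score pairs in which the positive outranks the
#' negative, with ties credited 0.5.  Curve points are obtained by
#' thresholding at every distinct score (plus the two trivial corners).
#'
#' @param scores numeric prediction scores.
#' @param labels logical (or 0/1) class labels, same length.
#' @return A list of class `roc_result`: `auc`, `n_pos`, `n_neg`,
#'   `curve` (data.frame of `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    parameter_error("scores and labels must have equal length")
  }
  if (anyNA(scores) || anyNA(labels)) {
    parameter_error("scores and labels must not contain NA")
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    parameter_error("AUC undefined: both classes must be present")
  }
  # Mann-Whitney U via midranks; midranks give exactly the 0.5 tie credit.
  rk <- rank(scores, ties.method = "average")
  u <- sum(rk[labels]) - n_pos * (n_pos + 1) / 2
  auc <- u / (n_pos * n_neg)

  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thresholds,
    fpr = vapply(thresholds, function(t) sum(!labels & scores >= t) / n_neg, 1),
    tpr = vapply(thresholds, function(t) sum(labels & scores >= t) / n_pos, 1)
  )
  structure(list(auc = auc, n_pos = n_pos, n_neg = n_neg, curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC %.4f (%d positive, %d negative)>\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Benchmark fingerprint scores against enrichment-derived labels
#'
#' The validation design: for each query, reference pathways are labeled
#' positive/negative by over-representation of the query's genes
#' (BH-adjusted p < `alpha`), the fingerprint's Z-scores are used as
#' prediction scores for those same references, and the agreement is
#' summarized as ROC/AUC.  Queries whose labels are single-class are
#' skipped with a warning.  The summary AUC is the unweighted mean over
#' evaluable queries.
#'
#' @param queries list of [gene_network()] queries.
#' @param refs a [reference_set()].
#' @param scorer similarity backend for the fingerprints.
#' @param universe background gene IDs for the enrichment labels.
#' @param config a [fp_config()].
#' @param seed master seed; query i scans with derived seed
#'   `seed + 100000 * i`.
#' @param use_raw use raw similarity instead of Z as the prediction
#'   score (ablation switch).
#' @param alpha enrichment label threshold.
#' @return A list of class `benchmark_result`: `per_query` (data.frame
#'   query, n_pos, n_neg, auc), `mean_auc`, `rocs` (list of
#'   [roc_auc()] results), `fingerprints`.
#' @export
benchmark_fingerprint_vs_enrichment <- function(queries, refs, scorer,
                                                universe,
                                                config = fp_config(),
                                                seed = 1L,
                                                use_raw = FALSE,
                                                alpha = config$alpha) {
  if (length(queries) == 0L) parameter_error("no queries supplied")
  rows <- list()
  rocs <- list()
  fps <- list()
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    labels <- label_references_by_enrichment(q, refs, universe, alpha = alpha)
    if (all(labels) || !any(labels)) {
      warning(sprintf(
        "query '%s' skipped: enrichment labels are single-class", q$id),
        call. = FALSE)
      next
    }
    fp <- fingerprint_scan(q, refs, scorer, config,
                           seed = derive_seed(seed, 100000 * i))
    fps[[q$id]] <- fp
    scores <- if (use_raw) fp$results$raw else fp$results$z
    scores[is.na(scores)] <- -Inf  # failed references rank last
    roc <- roc_auc(scores, labels[fp$results$reference])
    rocs[[q$id]] <- roc
    rows[[length(rows) + 1L]] <- data.frame(
      query = q$id, n_pos = roc$n_pos, n_neg = roc$n_neg, auc = roc$auc,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    parameter_error("no evaluable query: every query had single-class labels")
  }
  per_query <- do.call(rbind, rows)
  structure(list(per_query = per_query, mean_auc = mean(per_query$auc),
                 rocs = rocs, fingerprints = fps),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result: %d quer(ies), mean AUC %.4f>\n",
              nrow(x$per_query), x$mean_auc))
  print(x$per_query, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark report as TSV
#'
#' One row per evaluable query plus a trailing summary comment line with
#' the mean AUC.
#'
#' @param bench a [benchmark_fingerprint_vs_enrichment()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_tsv <- function(bench, path) {
  utils::write.table(bench$per_query, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat(sprintf("# mean_auc\t%.6f\n", bench$mean_auc),
      file = path, append = TRUE)
  invisible(path)
}
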