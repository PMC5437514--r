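#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` marked genes when `n` genes are sampled without
#' replacement from a universe of `N` genes of which `K` are marked.
#' Computed through the exact distribution function (log-space
#' internally), never a normal approximation.
#'
#' @param k observed overlap count.
#' @param K gene-set size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @return p in `(0, 1]`; `k = 0` gives exactly 1.
#' @export
hypergeometric_pvalue <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N) {
    parameter_error("require 0 <= k <= min(K, n) and K, n <= N")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sort ascending, take running minima of
#' `p_(j) * m / j` from the largest rank down, cap at 1, and return in
#' the input order.
#'
#' @param pvalues numeric vector with all values in `(0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (any(!is.finite(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    parameter_error("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis of a gene set against a collection
#'
#' For each named set in the collection, counts the overlap with the
#' query inside the universe and computes the upper-tail hypergeometric
#' p-value; BH adjustment is applied across all tested sets.  Query and
#' collection sets are intersected with the universe first, duplicates
#' dropped; sets with zero overlap are omitted from the result.
#'
#' @param query_genes character vector of query gene IDs.
#' @param collection named list of character vectors (gene sets).
#' @param universe character vector of background gene IDs.
#' @return Data.frame with columns `set`, `k` (overlap), `K` (set size),
#'   `n` (query size), `N` (universe size), `p`, `p_adj`, sorted by
#'   `p_adj` then `set`.
#' @export
enrich_gene_set <- function(query_genes, collection, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) parameter_error("universe is empty")
  query <- intersect(unique(query_genes), universe)
  n <- length(query)
  N <- length(universe)

  rows <- lapply(names(collection), function(id) {
    set <- intersect(unique(collection[[id]]), universe)
    k <- length(intersect(query, set))
    if (k == 0L) return(NULL)
    data.frame(set = id, k = k, K = length(set), n = n, N = N,
               p = hypergeometric_pvalue(k, length(set), n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p_adj, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GO term gene sets from an annotation map
#'
#' Builds one gene set per ontology term from the annotations, with
#' annotations propagated to ancestor terms (so a gene annotated to a
#' leaf is a member of every ancestor's set).
#'
#' @param annot an [annotation_map()].
#' @param ont an [ontology()].
#' @param min_size smallest set to keep.
#' @return Named list of character vectors.
#' @export
go_collection <- function(annot, ont, min_size = 2L) {
  sets <- list()
  for (g in names(annot$genes)) {
    covered <- unique(unlist(lapply(annot$genes[[g]], term_ancestors, ont = ont),
                             use.names = FALSE))
    for (t in covered) sets[[t]] <- c(sets[[t]], g)
  }
  sets <- lapply(sets, unique)
  sets[vapply(sets, length, 1L) >= min_size]
}

#' Label reference pathways by enrichment of the query's genes
#'
#' Treats each reference pathway's node set as a gene set, runs
#' over-representation analysis of the query's nodes against all of
#' them, and labels a reference positive when its BH-adjusted p-value is
#' below `alpha`.  References with zero overlap are negative.  These
#' labels are the ground truth of the ROC validation harness.
#'
#' @param q a [gene_network()] query.
#' @param refs a [reference_set()].
#' @param universe background gene IDs.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return Named logical vector over reference ids, in reference order.
#' @export
label_references_by_enrichment <- function(q, refs, universe, alpha = 0.05) {
  tab <- enrich_gene_set(q$nodes, reference_gene_sets(refs), universe)
  labels <- stats::setNames(rep(FALSE, length(refs$pathways)),
                            names(refs$pathways))
  if (nrow(tab) > 0L) {
    pos <- tab$set[tab$p_adj < alpha]
    labels[pos] <- TRUE
  }
  labels
}
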