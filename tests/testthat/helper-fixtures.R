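# Shared fixtures and independent oracles, all built in code.

# -- small ontology / annotation worlds --------------------------------

# root -> {proc, func}; proc -> {pa, pb}; func -> {fa}
toy_ontology <- function() {
  ontology(list(
    root = character(),
    proc = "root",
    func = "root",
    pa = "proc",
    pb = "proc",
    fa = "func"
  ))
}

# 10-gene universe with a clean split: g1..g5 on pa, g6..g10 on pb,
# g1 also on fa.
toy_annotations <- function(ont = toy_ontology()) {
  annotation_map(list(
    g1 = c("pa", "fa"), g2 = "pa", g3 = "pa", g4 = "pa", g5 = "pa",
    g6 = "pb", g7 = "pb", g8 = "pb", g9 = "pb", g10 = "pb"
  ), ont)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tiny_graphml <- function(nodes, edges, directed = FALSE) {
  # Minimal GraphML writer for fixtures (tests only).
  hdr <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    sprintf('<graph id="G" edgedefault="%s">',
            if (directed) "directed" else "undirected"))
  body <- c(
    sprintf('<node id="%s"/>', nodes),
    sprintf('<edge source="%s" target="%s"/>', edges[, 1], edges[, 2]))
  write_lines_tmp(c(hdr, body, "</graph>", "</graphml>"), ext = ".graphml")
}

# -- independent oracles -----------------------------------------------

# Exhaustive exemplar-set search: maximize sum of exemplar preferences
# plus each non-exemplar's best similarity to an exemplar.
exhaustive_best_net <- function(S) {
  n <- nrow(S)
  best <- -Inf
  best_set <- NULL
  for (mask in 1:(2^n - 1)) {
    ex <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    net <- sum(S[cbind(ex, ex)])
    for (i in setdiff(seq_len(n), ex)) {
      net <- net + max(S[i, ex])
    }
    if (net > best) {
      best <- net
      best_set <- ex
    }
  }
  list(net = best, exemplars = best_set)
}

# Exact hypergeometric upper tail by integer-binomial enumeration
# (exact in double precision for N <= 25).
hyper_tail_oracle <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Literal BH step-up: sort ascending, running min of p_(j) * m / j from
# the top rank down, cap at 1, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  if (m >= 2) {
    for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# AUC as the fraction of concordant positive-negative pairs, ties 0.5.
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Small shared synthetic universe for pipeline tests (cheap to build,
# cached per test run).
small_universe <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_synthetic_universe(
        universe_params(n_refs = 4L, node_range = c(8L, 10L),
                        pool_size = 60L),
        seed = 202
      )
    }
    cache
  }
})
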