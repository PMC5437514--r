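#' Local similarity score of one cluster
#'
#' A cluster that mixes query-side and reference-side nodes is scored by
#' the best-match average of the gene-gene similarities between its two
#' sides; a single-origin cluster scores 0, so non-overlapping structure
#' penalizes the network-level mean.
#'
#' @param members character vector of tagged node ids (`Q:`/`R:` prefixes).
#' @param sim a [similarity_matrix()].
#' @return A list of class `cluster_score` with fields `local` (number
#'   in `[0, 1]`) and `mixed` (logical).
#' @export
cluster_local_score <- function(members, sim) {
  origin <- substr(members, 1L, 1L)
  genes <- sub("^[QR]:", "", members)
  q_genes <- genes[origin == "Q"]
  r_genes <- genes[origin == "R"]
  mixed <- length(q_genes) > 0L && length(r_genes) > 0L
  local <- 0
  if (mixed) {
    m <- sim_block(sim, q_genes, r_genes)
    local <- (mean(apply(m, 1L, max)) + mean(apply(m, 2L, max))) / 2
  }
  structure(list(local = local, mixed = mixed), class = "cluster_score")
}

#' Raw similarity between two networks under a node mapping
#'
#' The raw network similarity is the unweighted mean of all clusters'
#' local scores — mixed and unmixed alike, so clusters private to one
#' network drag the score down.
#'
#' @param mapping a [node_mapping()].
#' @param sim a [similarity_matrix()].
#' @return A number in `[0, 1]`.
#' @export
raw_network_similarity <- function(mapping, sim) {
  if (length(mapping$clusters) == 0L) {
    parameter_error("node mapping has no clusters")
  }
  scores <- vapply(mapping$clusters,
                   function(cl) cluster_local_score(cl$members, sim)$local,
                   1)
  mean(scores)
}

#' Topology-preserving label randomization of a query network
#'
#' Produces an isomorphic copy of the query in which node labels are
#' replaced by a uniform sample (without replacement) from a gene pool.
#' This is the permutation null of the fingerprint: topology is held
#' fixed, so the null distribution isolates the attribute (annotation)
#' signal.
#'
#' @param q a [gene_network()].
#' @param gene_pool character vector of candidate labels, at least as
#'   large as the query's node set.
#' @param seed integer RNG seed.
#' @return A [gene_network()] isomorphic to `q`.
#' @export
randomize_query <- function(q, gene_pool, seed = 1L) {
  n <- n_nodes(q)
  if (length(gene_pool) < n) {
    parameter_error("gene pool smaller than the query's node count")
  }
  with_rng_seed(seed, {
    new_labels <- stats::setNames(sample(gene_pool, n), q$nodes)
    edges <- cbind(new_labels[q$edges[, 1L]], new_labels[q$edges[, 2L]])
    gene_network(paste0(q$id, "_perm"), edges,
                 nodes = as.character(new_labels),
                 metadata = list(randomized_from = q$id))
  })
}

#' Pairwise alignment of a query against one reference
#'
#' Runs the full node-mapping step for one network pair: builds the
#' similarity matrix over the union of both gene sets, merges the
#' networks, clusters with the configured algorithm, and scores every
#' cluster.  This is the unit of work behind both the standalone
#' alignment view and each fingerprint coordinate.
#'
#' @param q,r [gene_network()] objects.
#' @param scorer a [make_gene_scorer()] / [make_matrix_scorer()] backend.
#' @param config a [fp_config()] list.
#' @return A list of class `alignment` with fields `mapping`,
#'   `cluster_table` (data.frame: cluster, exemplar, members, local,
#'   mixed), `raw`, `merged`, `sim`.
#' @export
align_networks <- function(q, r, scorer, config = fp_config()) {
  union_genes <- sort(unique(c(q$nodes, r$nodes)))
  sim <- scorer$matrix(union_genes, union_genes)
  mg <- merge_networks(q, r, sim, tau = config$tau)

  mapping <- switch(
    config$algorithm,
    apcluster = {
      A <- build_affinity(mg, sim, w_topo = config$w_topo,
                          preference = config$preference)
      affinity_propagation(A, damping = config$damping,
                           max_iter = config$max_iter,
                           convergence_window = config$convergence_window)
    },
    greedy = greedy_align(q, r, sim, min_sim = config$min_sim),
    external = {
      if (is.null(config$external_cmd)) {
        config_error("algorithm 'external' requires an external_cmd template")
      }
      run_external_aligner(config$external_cmd, q, r)
    },
    config_error(sprintf("unknown algorithm: %s", config$algorithm))
  )

  scores <- lapply(mapping$clusters,
                   function(cl) cluster_local_score(cl$members, sim))
  tab <- data.frame(
    cluster = seq_along(mapping$clusters),
    exemplar = vapply(mapping$clusters, `[[`, "", "exemplar"),
    members = vapply(mapping$clusters,
                     function(cl) paste(sort(cl$members), collapse = ","), ""),
    local = vapply(scores, `[[`, 1, "local"),
    mixed = vapply(scores, `[[`, TRUE, "mixed"),
    stringsAsFactors = FALSE
  )
  structure(list(mapping = mapping, cluster_table = tab,
                 raw = mean(tab$local), merged = mg, sim = sim,
                 q_id = q$id, r_id = r$id),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment '%s' ~ '%s': %d cluster(s), raw similarity %.4f>\n",
              x$q_id, x$r_id, nrow(x$cluster_table), x$raw))
  invisible(x)
}

#' Permutation-normalized similarity against one reference
#'
#' Computes the raw query/reference similarity, then re-runs the
#' identical pipeline on `n_perm` label-randomized copies of the query to
#' obtain a null distribution, and reports `z = (raw - null mean) /
#' max(null sd, 1e-8)` clipped to `[-1000, 1000]`.  The null sd is the
#' sample (n-1) standard deviation.
#'
#' @param q a [gene_network()] query.
#' @param r a [gene_network()] reference pathway.
#' @param scorer similarity backend.
#' @param config a [fp_config()].
#' @param n_perm number of randomized copies (>= 2).
#' @param seed integer seed; permutation i uses derived seed `seed + i`.
#' @param gene_pool label pool for randomization; defaults to the
#'   scorer's annotation universe.
#' @return A list of class `similarity_result` with fields `reference`,
#'   `raw`, `null_mean`, `null_sd`, `z`, `n_perm`, `seed`.
#' @export
permutation_zscore <- function(q, r, scorer, config = fp_config(),
                               n_perm = config$n_perm, seed = 1L,
                               gene_pool = NULL) {
  if (n_perm < 2L) parameter_error("n_perm must be >= 2")
  gene_pool <- gene_pool %||% scorer$universe
  raw <- align_networks(q, r, scorer, config)$raw
  null_scores <- vapply(seq_len(n_perm), function(i) {
    qi <- tryCatch(
      randomize_query(q, gene_pool, seed = derive_seed(seed, i)),
      error = function(e) {
        nfp_error(sprintf("permutation %d: %s", i, conditionMessage(e)),
                  class(e)[[1L]])
      })
    align_networks(qi, r, scorer, config)$raw
  }, 1)
  null_mean <- mean(null_scores)
  null_sd <- stats::sd(null_scores)
  z <- (raw - null_mean) / max(null_sd, 1e-8)
  z <- max(-1000, min(1000, z))
  structure(list(reference = r$id, raw = raw, null_mean = null_mean,
                 null_sd = null_sd, z = z, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "similarity_result")
}

#' Scan a query against a reference set: the network fingerprint
#'
#' Computes one permutation-normalized similarity per reference pathway,
#' in the reference set's order (which defines the fingerprint's
#' coordinate order).  Reference i uses the derived seed
#' `seed + 1000 * i`, so results are identical however the scan is
#' scheduled.  A failure on one reference is recorded and flagged; the
#' scan continues.
#'
#' @param q a [gene_network()] query.
#' @param refs a [reference_set()].
#' @param scorer similarity backend.
#' @param config a [fp_config()].
#' @param seed master integer seed.
#' @param gene_pool label pool for the permutation null.
#' @param progress log per-reference progress to stderr.
#' @return An object of class `fingerprint`: fields `query_id`,
#'   `reference_set_id`, `results` (data.frame with columns reference,
#'   category, raw, null_mean, null_sd, z, n_perm, seed, error) and
#'   `config`.
#' @export
fingerprint_scan <- function(q, refs, scorer, config = fp_config(),
                             seed = 1L, gene_pool = NULL, progress = FALSE) {
  if (length(refs$pathways) == 0L) parameter_error("reference set is empty")
  rows <- vector("list", length(refs$pathways))
  for (i in seq_along(refs$pathways)) {
    r <- refs$pathways[[i]]
    if (isTRUE(progress)) {
      message(sprintf("[%d/%d] %s", i, length(refs$pathways), r$id))
    }
    res <- tryCatch(
      permutation_zscore(q, r, scorer, config, n_perm = config$n_perm,
                         seed = derive_seed(seed, 1000 * i),
                         gene_pool = gene_pool),
      error = function(e) e
    )
    rows[[i]] <- if (inherits(res, "error")) {
      data.frame(reference = r$id,
                 category = r$metadata$category %||% NA_character_,
                 raw = NA_real_, null_mean = NA_real_, null_sd = NA_real_,
                 z = NA_real_, n_perm = as.integer(config$n_perm),
                 seed = derive_seed(seed, 1000 * i),
                 error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(reference = res$reference,
                 category = r$metadata$category %||% NA_character_,
                 raw = res$raw, null_mean = res$null_mean,
                 null_sd = res$null_sd, z = res$z, n_perm = res$n_perm,
                 seed = res$seed, error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  }
  structure(list(query_id = q$id, reference_set_id = refs$id,
                 results = do.call(rbind, rows),
                 config = config_snapshot(config, seed)),
            class = "fingerprint")
}

config_snapshot <- function(config, seed) {
  snap <- config
  snap$seed <- as.integer(seed)
  snap$version <- as.character(utils::packageVersion("netfingerprint"))
  snap
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint of '%s' against '%s' (%d references)>\n",
              x$query_id, x$reference_set_id, nrow(x$results)))
  top <- x$results[order(-x$results$z), c("reference", "category", "raw", "z")]
  print(utils::head(top, 5L), row.names = FALSE)
  invisible(x)
}

#' Compare two fingerprints reference by reference
#'
#' @param f1,f2 [fingerprint_scan()] results over the same reference set
#'   (same id, same order).
#' @return Data.frame with columns reference, category, z1, z2, dz,
#'   ranked by `|dz|` descending.
#' @export
fingerprint_diff <- function(f1, f2) {
  if (!identical(f1$reference_set_id, f2$reference_set_id) ||
      !identical(f1$results$reference, f2$results$reference)) {
    parameter_error("fingerprints were computed against different reference sets")
  }
  out <- data.frame(
    reference = f1$results$reference,
    category = f1$results$category,
    z1 = f1$results$z,
    z2 = f2$results$z,
    dz = f1$results$z - f2$results$z,
    stringsAsFactors = FALSE
  )
  out[order(-abs(out$dz)), , drop = FALSE]
}

#' Write a fingerprint to JSON
#'
#' Full-record serialization (all null statistics and the resolved
#' configuration).  Serialization is canonical: two identical
#' fingerprints produce byte-identical files.
#'
#' @param fp a `fingerprint`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fingerprint_json <- function(fp, path) {
  obj <- list(
    query_id = fp$query_id,
    reference_set_id = fp$reference_set_id,
    config = fp$config,
    results = fp$results
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fingerprint back from JSON
#'
#' @param path JSON file written by [write_fingerprint_json()].
#' @return A `fingerprint` object.
#' @export
read_fingerprint_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  res <- as.data.frame(obj$results, stringsAsFactors = FALSE)
  if (!"error" %in% names(res)) res$error <- NA_character_
  structure(list(query_id = obj$query_id,
                 reference_set_id = obj$reference_set_id,
                 results = res, config = obj$config),
            class = "fingerprint")
}

#' Write a fingerprint as TSV
#'
#' Compact table form: reference id, category, raw score, Z-score.
#'
#' @param fp a `fingerprint`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fingerprint_tsv <- function(fp, path) {
  utils::write.table(
    fp$results[, c("reference", "category", "raw", "z")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
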