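#' Merge a query and a reference network into one tagged graph
#'
#' The merged graph is the disjoint union of both networks, with node ids
#' prefixed `Q:` / `R:` to record origin, plus cross-network edges
#' between every query/reference gene pair whose attribute similarity is
#' at least `tau`.  A gene present in both networks contributes two
#' tagged nodes (linked by a cross edge when its self-similarity clears
#' the threshold).
#'
#' @param q,r [gene_network()] objects (query, reference).
#' @param sim a [similarity_matrix()] covering query genes x reference
#'   genes (a union-by-union matrix also works).
#' @param tau cross-edge similarity threshold in `[0, 1]`.
#' @return An object of class `merged_graph` with fields `graph`
#'   (igraph), `nodes` (tagged ids), `origin` (named "Q"/"R" vector),
#'   `gene` (named tagged-id to gene-id vector), `q_id`, `r_id`.
#' @export
merge_networks <- function(q, r, sim, tau = 0.5) {
  q_tag <- paste0("Q:", q$nodes)
  r_tag <- paste0("R:", r$nodes)
  nodes <- c(q_tag, r_tag)
  origin <- stats::setNames(c(rep("Q", length(q_tag)), rep("R", length(r_tag))),
                            nodes)
  gene <- stats::setNames(c(q$nodes, r$nodes), nodes)

  within_q <- cbind(paste0("Q:", q$edges[, 1L]), paste0("Q:", q$edges[, 2L]))
  within_r <- cbind(paste0("R:", r$edges[, 1L]), paste0("R:", r$edges[, 2L]))

  block <- sim_block(sim, q$nodes, r$nodes)
  hits <- which(block >= tau, arr.ind = TRUE)
  cross <- if (nrow(hits) > 0L) {
    cbind(paste0("Q:", q$nodes[hits[, 1L]]), paste0("R:", r$nodes[hits[, 2L]]))
  } else {
    matrix(character(), ncol = 2L)
  }
  edges <- rbind(within_q, within_r, cross)
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = nodes))
  structure(list(graph = g, nodes = nodes, origin = origin, gene = gene,
                 n_cross = nrow(cross), q_id = q$id, r_id = r$id),
            class = "merged_graph")
}

#' @export
print.merged_graph <- function(x, ...) {
  cat(sprintf("<merged_graph '%s' ~ '%s': %d nodes, %d edges (%d cross)>\n",
              x$q_id, x$r_id, length(x$nodes), igraph::ecount(x$graph),
              x$n_cross))
  invisible(x)
}

#' Build the affinity matrix for node clustering
#'
#' The pairwise affinity blends merged-graph topology with attribute
#' similarity: `s(i,j) = w_topo * Jaccard(N(i), N(j)) + (1 - w_topo) *
#' attr(i,j)`, where `N()` is the neighborhood in the merged graph and
#' `attr` is the gene-gene similarity (for same-origin pairs the same
#' scorer's value when the matrix covers it, else 0).  Nodes with two
#' empty neighborhoods get Jaccard 0.  The diagonal holds the affinity
#' propagation preference; `"median"` uses the median off-diagonal
#' affinity, the common self-tuning default.
#'
#' @param mg a [merge_networks()] result.
#' @param sim a [similarity_matrix()].
#' @param w_topo topology weight in `[0, 1]`.
#' @param preference numeric diagonal value, or `"median"`.
#' @return A symmetric numeric matrix with tagged-node dimnames, class
#'   `affinity_matrix`.
#' @export
build_affinity <- function(mg, sim, w_topo = 0.5, preference = "median") {
  if (w_topo < 0 || w_topo > 1) parameter_error("w_topo must be in [0, 1]")
  n <- length(mg$nodes)
  adj <- as.matrix(igraph::as_adjacency_matrix(mg$graph, sparse = FALSE))
  adj <- adj[mg$nodes, mg$nodes, drop = FALSE]
  adj[adj > 1] <- 1

  inter <- adj %*% t(adj)
  deg <- rowSums(adj)
  uni <- outer(deg, deg, "+") - inter
  jac <- ifelse(uni > 0, inter / uni, 0)

  attr_m <- sim_block(sim, mg$gene, mg$gene)
  dimnames(attr_m) <- list(mg$nodes, mg$nodes)
  diag(attr_m) <- 0
  s <- w_topo * jac + (1 - w_topo) * attr_m

  diag_val <- if (identical(preference, "median")) {
    off <- s[upper.tri(s)]
    if (length(off) == 0L) 0 else stats::median(off)
  } else {
    as.numeric(preference)
  }
  diag(s) <- diag_val
  dimnames(s) <- list(mg$nodes, mg$nodes)
  structure(s, class = c("affinity_matrix", "matrix", "array"))
}

#' Node mapping: a partition of merged nodes into exemplar-led clusters
#'
#' @param clusters list of lists with fields `exemplar` (node id) and
#'   `members` (character vector containing the exemplar).
#' @param algorithm name of the producing algorithm.
#' @param parameters named list snapshot of the parameters used.
#' @return An object of class `node_mapping`.
#' @export
node_mapping <- function(clusters, algorithm, parameters = list()) {
  members <- unlist(lapply(clusters, `[[`, "members"), use.names = FALSE)
  if (anyDuplicated(members)) {
    data_error("node mapping clusters are not disjoint")
  }
  for (cl in clusters) {
    if (!cl$exemplar %in% cl$members) {
      data_error("cluster exemplar must be one of its members")
    }
  }
  structure(list(clusters = clusters, algorithm = algorithm,
                 parameters = parameters),
            class = "node_mapping")
}

#' @export
print.node_mapping <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), 1L)
  cat(sprintf("<node_mapping (%s): %d cluster(s), sizes %s>\n",
              x$algorithm, length(x$clusters),
              paste(sort(sizes, decreasing = TRUE), collapse = "/")))
  invisible(x)
}

mapping_nodes <- function(mapping) {
  unlist(lapply(mapping$clusters, `[[`, "members"), use.names = FALSE)
}

#' Affinity propagation clustering
#'
#' Standard affinity propagation message passing on a similarity matrix:
#' responsibilities `r(i,k) = s(i,k) - max_{k' != k}[a(i,k') + s(i,k')]`,
#' availabilities `a(i,k) = min(0, r(k,k) + sum_{i' not in {i,k}}
#' max(0, r(i',k)))` with `a(k,k) = sum_{i' != k} max(0, r(i',k))`, both
#' damped.  Exemplars are the nodes with `r(k,k) + a(k,k) > 0`; every
#' other node joins the exemplar of maximal similarity.  Iteration stops
#' when the exemplar set has been stable for `convergence_window`
#' consecutive sweeps, or at `max_iter` with a non-convergence warning.
#' The procedure contains no randomness: identical inputs give identical
#' mappings.
#'
#' @param A square numeric [build_affinity()] matrix (finite entries;
#'   diagonal = preference).
#' @param damping damping factor in `[0.5, 1)`.
#' @param max_iter maximum number of sweeps.
#' @param convergence_window sweeps of exemplar stability required.
#' @return A [node_mapping()] with algorithm `"apcluster"`.
#' @export
affinity_propagation <- function(A, damping = 0.9, max_iter = 1000L,
                                 convergence_window = 50L) {
  n <- nrow(A)
  if (is.null(n) || n == 0L) parameter_error("affinity matrix is empty")
  if (damping < 0.5 || damping >= 1) {
    parameter_error("damping must be in [0.5, 1)")
  }
  if (any(!is.finite(A))) parameter_error("affinity matrix must be finite")
  ids <- rownames(A) %||% as.character(seq_len(n))

  if (n == 1L) {
    return(node_mapping(
      list(list(exemplar = ids[[1L]], members = ids[[1L]])),
      "apcluster",
      list(damping = damping, max_iter = max_iter,
           convergence_window = convergence_window, converged = TRUE,
           iterations = 0L)))
  }

  S <- unclass(A)
  # Exactly tied similarities can lock the messages into a period-2
  # oscillation of the exemplar set.  Break ties with a tiny fixed
  # pseudo-noise pattern (no RNG involved, so runs stay deterministic);
  # its magnitude is far below any meaningful similarity difference.
  scale <- max(abs(S))
  if (scale == 0) scale <- 1
  idx <- seq_len(n)
  tie_break <- ((outer(idx * 73L, idx * 151L, "+") %% 1009L) / 1009) *
    (1e-9 * scale)
  S <- S + tie_break
  R <- matrix(0, n, n)
  Av <- matrix(0, n, n)
  stable <- 0L
  prev_ex <- rep(FALSE, n)
  converged <- FALSE
  it <- 0L
  seq_n <- seq_len(n)
  dind <- cbind(seq_n, seq_n)

  while (it < max_iter) {
    it <- it + 1L

    # Responsibilities: r(i,k) = s(i,k) - max_{k' != k} [a(i,k') + s(i,k')].
    AS <- Av + S
    m1i <- max.col(AS, ties.method = "first")
    i1 <- cbind(seq_n, m1i)
    max1 <- AS[i1]
    AS[i1] <- -Inf
    max2 <- AS[cbind(seq_n, max.col(AS, ties.method = "first"))]
    Rnew <- S - max1
    Rnew[i1] <- S[i1] - max2
    R <- damping * R + (1 - damping) * Rnew

    # Availabilities.
    Rp <- pmax(R, 0)
    Rp[dind] <- R[dind]
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    Anew[Anew > 0] <- 0
    Anew[dind] <- cs - R[dind]
    Av <- damping * Av + (1 - damping) * Anew

    ex <- (R[dind] + Av[dind]) > 0
    if (identical(ex, prev_ex) && any(ex)) {
      stable <- stable + 1L
      if (stable >= convergence_window) {
        converged <- TRUE
        break
      }
    } else {
      stable <- 0L
    }
    prev_ex <- ex
  }
  if (!converged) {
    warning(sprintf(
      "affinity propagation did not converge within %d iterations", max_iter),
      call. = FALSE)
  }

  ex <- which((diag(R) + diag(Av)) > 0)
  if (length(ex) == 0L) {
    # Degenerate outcome (all evidence negative): fall back to the single
    # strongest candidate so the mapping still partitions the node set.
    ex <- which.max(diag(R) + diag(Av))
  }

  assign_to <- integer(n)
  for (i in seq_len(n)) {
    if (i %in% ex) {
      assign_to[[i]] <- i
    } else {
      assign_to[[i]] <- ex[[which.max(S[i, ex])]]
    }
  }
  clusters <- lapply(ex, function(k) {
    list(exemplar = ids[[k]], members = ids[assign_to == k])
  })
  node_mapping(clusters, "apcluster",
               list(damping = damping, max_iter = max_iter,
                    convergence_window = convergence_window,
                    converged = converged, iterations = it))
}

# Net similarity of an exemplar set: sum of exemplar preferences plus
# each non-exemplar's best similarity to an exemplar.  Used by tests as
# the exhaustive-search objective and exposed for diagnostics.
#' Net similarity of a node mapping under an affinity matrix
#'
#' Sum of the exemplars' self-affinities (preferences) plus each
#' non-exemplar member's affinity to its cluster exemplar.  This is the
#' objective affinity propagation maximizes.
#'
#' @param mapping a [node_mapping()].
#' @param A the [build_affinity()] matrix the mapping was computed from.
#' @return A single number.
#' @export
mapping_net_similarity <- function(mapping, A) {
  total <- 0
  for (cl in mapping$clusters) {
    total <- total + A[cl$exemplar, cl$exemplar]
    for (m in setdiff(cl$members, cl$exemplar)) {
      total <- total + A[m, cl$exemplar]
    }
  }
  total
}

#' Greedy one-to-one aligner
#'
#' A lightweight alternative to clustering: repeatedly takes the
#' globally most similar unmatched query/reference gene pair (ties broken
#' lexicographically by query then reference gene id) and emits it as a
#' two-node cluster, until the best remaining similarity falls below
#' `min_sim`.  Unmatched nodes become singleton clusters.
#'
#' @param q,r [gene_network()] objects.
#' @param sim a [similarity_matrix()] covering query x reference genes.
#' @param min_sim matching threshold.
#' @return A [node_mapping()] with algorithm `"greedy"`.
#' @export
greedy_align <- function(q, r, sim, min_sim = 0.5) {
  qs <- sort(q$nodes)
  rs <- sort(r$nodes)
  m <- sim_block(sim, qs, rs)
  dimnames(m) <- list(qs, rs)

  clusters <- list()
  free_q <- rep(TRUE, length(qs))
  free_r <- rep(TRUE, length(rs))
  repeat {
    sub <- m
    sub[!free_q, ] <- -Inf
    sub[, !free_r] <- -Inf
    best <- max(sub)
    if (!is.finite(best) || best < min_sim) break
    hits <- which(sub == best, arr.ind = TRUE)
    # Lexicographic tie-break on (query gene, reference gene); rows and
    # columns are already sorted, so the minimal index pair wins.
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    i <- hits[1L, 1L]
    j <- hits[1L, 2L]
    qt <- paste0("Q:", qs[[i]])
    rt <- paste0("R:", rs[[j]])
    clusters[[length(clusters) + 1L]] <-
      list(exemplar = qt, members = c(qt, rt))
    free_q[[i]] <- FALSE
    free_r[[j]] <- FALSE
  }
  for (a in qs[free_q]) {
    t <- paste0("Q:", a)
    clusters[[length(clusters) + 1L]] <- list(exemplar = t, members = t)
  }
  for (b in rs[free_r]) {
    t <- paste0("R:", b)
    clusters[[length(clusters) + 1L]] <- list(exemplar = t, members = t)
  }
  node_mapping(clusters, "greedy", list(min_sim = min_sim))
}

#' Run an external alignment tool as the node-mapping step
#'
#' Adapter contract for third-party aligners: the command template gets
#' `{query}`, `{reference}` and `{output}` placeholders substituted with
#' temporary edge-list paths (exported with `Q:` / `R:` node-id prefixes)
#' and an output path.  The tool must write one cluster per line,
#' whitespace-separated prefixed node ids.  Nodes absent from the output
#' become singleton clusters.
#'
#' @param cmd_template shell command template with the three placeholders.
#' @param q,r [gene_network()] objects.
#' @return A [node_mapping()] with algorithm `"external"`.
#' @export
run_external_aligner <- function(cmd_template, q, r) {
  td <- tempfile("aligner")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qp <- file.path(td, "query.tsv")
  rp <- file.path(td, "reference.tsv")
  op <- file.path(td, "clusters.txt")

  q_tagged <- gene_network(q$id, cbind(paste0("Q:", q$edges[, 1L]),
                                       paste0("Q:", q$edges[, 2L])),
                           nodes = paste0("Q:", q$nodes))
  r_tagged <- gene_network(r$id, cbind(paste0("R:", r$edges[, 1L]),
                                       paste0("R:", r$edges[, 2L])),
                           nodes = paste0("R:", r$nodes))
  write_edge_list(q_tagged, qp)
  write_edge_list(r_tagged, rp)

  cmd <- cmd_template
  cmd <- gsub("{query}", qp, cmd, fixed = TRUE)
  cmd <- gsub("{reference}", rp, cmd, fixed = TRUE)
  cmd <- gsub("{output}", op, cmd, fixed = TRUE)

  res <- suppressWarnings(system(paste(cmd, "2>&1"), intern = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L) {
    external_error(sprintf("external aligner exited with status %d: %s",
                           status, paste(res, collapse = "\n")))
  }
  if (!file.exists(op)) {
    external_error("external aligner produced no output file")
  }

  all_nodes <- c(paste0("Q:", q$nodes), paste0("R:", r$nodes))
  lines <- readLines(op, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  clusters <- list()
  seen <- character()
  for (i in seq_along(lines)) {
    members <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(members) == 0L || !all(grepl("^[QR]:", members))) {
      format_error(sprintf("unparseable aligner output line %d: %s",
                           i, lines[[i]]))
    }
    members <- unique(members)
    unknown <- setdiff(members, all_nodes)
    if (length(unknown) > 0L) {
      format_error(sprintf("aligner output names unknown node(s): %s",
                           paste(unknown, collapse = ", ")))
    }
    clusters[[length(clusters) + 1L]] <-
      list(exemplar = members[[1L]], members = members)
    seen <- c(seen, members)
  }
  for (t in setdiff(all_nodes, seen)) {
    clusters[[length(clusters) + 1L]] <- list(exemplar = t, members = t)
  }
  node_mapping(clusters, "external", list(cmd_template = cmd_template))
}
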