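#' Construct an ontology DAG
#'
#' Holds a directed acyclic graph of terms linked by `is_a` edges
#' (child to parent).  Only `is_a` relations are modeled; `part_of` and
#' other relation types are ignored by the loaders.
#'
#' @param parents named list mapping each term ID to a character vector
#'   of its parent term IDs (empty vector for roots).
#' @return An object of class `ontology` with fields `terms`, `parents`,
#'   `children` and `roots`.
#' @export
ontology <- function(parents) {
  terms <- names(parents)
  if (is.null(terms) || anyDuplicated(terms)) {
    data_error("parents must be a uniquely named list of terms")
  }
  all_parents <- unique(unlist(parents, use.names = FALSE))
  dangling <- setdiff(all_parents, terms)
  if (length(dangling) > 0L) {
    data_error(sprintf("dangling parent term(s): %s",
                       paste(utils::head(dangling, 5L), collapse = ", ")))
  }
  check_acyclic(parents)
  roots <- terms[vapply(parents, length, 1L) == 0L]
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) {
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  structure(
    list(terms = terms, parents = parents, children = children,
         roots = roots, cache = new.env(parent = emptyenv())),
    class = "ontology"
  )
}

# Kahn's algorithm; on failure walk parent links to exhibit one cycle.
check_acyclic <- function(parents) {
  indeg <- vapply(parents, length, 1L)  # number of parents still unresolved
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  child_of <- list()
  for (t in names(parents)) {
    for (p in parents[[t]]) child_of[[p]] <- c(child_of[[p]], t)
  }
  while (length(queue) > 0L) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in child_of[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(parents)) {
    start <- names(indeg)[indeg > 0L][[1L]]
    path <- start
    cur <- start
    repeat {
      nxt <- intersect(parents[[cur]], names(indeg)[indeg > 0L])[[1L]]
      if (nxt %in% path) {
        cyc <- c(path[which(path == nxt):length(path)], nxt)
        data_error(sprintf("ontology contains a cycle: %s",
                           paste(cyc, collapse = " -> ")))
      }
      path <- c(path, nxt)
      cur <- nxt
    }
  }
  invisible(TRUE)
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology: %d terms, %d root(s)>\n",
              length(x$terms), length(x$roots)))
  invisible(x)
}

#' Load an ontology from OBO or child-parent TSV
#'
#' Accepts either a subset of the OBO flat-file format (`[Term]` stanzas
#' with `id`, `is_a` and `is_obsolete` tags; obsolete terms skipped) or a
#' two-column TSV of child/parent pairs.  A file is treated as OBO when
#' it contains a `[Term]` stanza header.
#'
#' @param path path to the ontology file.
#' @return An [ontology()].
#' @export
load_ontology <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^\\[Term\\]", lines))) {
    parse_obo(lines)
  } else {
    parse_parent_tsv(lines)
  }
}

parse_obo <- function(lines) {
  parents <- list()
  cur_id <- NULL
  cur_parents <- character()
  obsolete <- FALSE
  in_term <- FALSE
  flush <- function() {
    if (in_term && !is.null(cur_id) && !obsolete) {
      parents[[cur_id]] <<- unique(cur_parents)
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      in_term <- TRUE
      cur_id <- NULL
      cur_parents <- character()
      obsolete <- FALSE
    } else if (grepl("^\\[", ln)) {
      flush()
      in_term <- FALSE
    } else if (in_term && grepl("^id:", ln)) {
      cur_id <- trimws(sub("^id:", "", ln))
    } else if (in_term && grepl("^is_a:", ln)) {
      val <- trimws(sub("^is_a:", "", ln))
      val <- trimws(sub("!.*$", "", val))  # strip trailing name comment
      cur_parents <- c(cur_parents, val)
    } else if (in_term && grepl("^is_obsolete:\\s*true", ln)) {
      obsolete <- TRUE
    }
  }
  flush()
  if (length(parents) == 0L) format_error("no usable [Term] stanzas in OBO input")
  ontology(parents)
}

parse_parent_tsv <- function(lines) {
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) format_error("empty ontology TSV")
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad) > 0L) {
    format_error(sprintf("ontology TSV line %d lacks two columns",
                         which(keep)[bad[[1L]]]))
  }
  child <- vapply(toks, `[[`, "", 1L)
  parent <- vapply(toks, `[[`, "", 2L)
  terms <- unique(c(child, parent))
  parents <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) parents[[t]] <- character()
  for (i in seq_along(child)) {
    parents[[child[[i]]]] <- unique(c(parents[[child[[i]]]], parent[[i]]))
  }
  ontology(parents)
}

# Ancestors of a term including the term itself, memoized on the
# ontology's cache environment.
term_ancestors <- function(ont, term) {
  key <- paste0("anc:", term)
  hit <- ont$cache[[key]]
  if (!is.null(hit)) return(hit)
  if (!term %in% ont$terms) data_error(sprintf("unknown term: %s", term))
  anc <- term
  frontier <- ont$parents[[term]]
  while (length(frontier) > 0L) {
    anc <- union(anc, frontier)
    frontier <- setdiff(unique(unlist(ont$parents[frontier], use.names = FALSE)), anc)
  }
  ont$cache[[key]] <- anc
  anc
}

#' Construct a gene-to-term annotation map
#'
#' @param gene2terms named list mapping gene IDs to character vectors of
#'   term IDs.  Every term must exist in the ontology.
#' @param ont an [ontology()].
#' @return An object of class `annotation_map` with fields `genes`
#'   (the named list, deduplicated) and `universe` (genes with at least
#'   one annotation).
#' @export
annotation_map <- function(gene2terms, ont) {
  gene2terms <- lapply(gene2terms, function(ts) sort(unique(as.character(ts))))
  gene2terms <- gene2terms[vapply(gene2terms, length, 1L) > 0L]
  used <- unique(unlist(gene2terms, use.names = FALSE))
  unknown <- setdiff(used, ont$terms)
  if (length(unknown) > 0L) {
    data_error(sprintf("annotation uses term(s) absent from the ontology: %s",
                       paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  structure(list(genes = gene2terms, universe = sort(names(gene2terms)),
                 cache = new.env(parent = emptyenv())),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map: %d annotated genes>\n", length(x$universe)))
  invisible(x)
}

#' Read gene-term annotations from a two-column TSV
#'
#' @param path TSV/whitespace file with columns gene, term; `#` comments
#'   allowed.
#' @param ont an [ontology()] used to validate term IDs.
#' @return An [annotation_map()].
#' @export
read_annotations <- function(path, ont) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) format_error(sprintf("no annotations in %s", path))
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad) > 0L) {
    format_error(sprintf("annotation line %d lacks two columns",
                         which(keep)[bad[[1L]]]))
  }
  gene <- vapply(toks, `[[`, "", 1L)
  term <- vapply(toks, `[[`, "", 2L)
  annotation_map(split(term, gene), ont)
}

# Term -> number of universe genes annotated to the term or any
# descendant, computed by propagating each gene's direct annotations to
# all ancestors.  Returns a named integer over all ontology terms
# (zero where uncovered).
term_gene_counts <- function(annot, ont) {
  counts <- stats::setNames(integer(length(ont$terms)), ont$terms)
  for (g in names(annot$genes)) {
    covered <- unique(unlist(lapply(annot$genes[[g]], term_ancestors, ont = ont),
                             use.names = FALSE))
    counts[covered] <- counts[covered] + 1L
  }
  counts
}

#' Information content of an ontology term
#'
#' IC(t) = -ln( n(t) / N ), where n(t) is the number of universe genes
#' annotated to t or any of its descendants and N is the universe size.
#' Terms covering the whole universe (roots, typically) have IC 0.
#'
#' @param term a term ID present in the ontology.
#' @param annot an [annotation_map()]; the IC corpus is this map itself,
#'   with annotations propagated to ancestors before counting.
#' @param ont an [ontology()].
#' @return Non-negative IC in nats.
#' @export
term_ic <- function(term, annot, ont) {
  ic <- ic_values(annot, ont)
  if (!term %in% names(ic)) data_error(sprintf("unknown term: %s", term))
  v <- ic[[term]]
  if (is.na(v)) {
    data_error(sprintf("IC undefined for term '%s' (no annotated genes below it)", term))
  }
  v
}

# Full IC vector, memoized on the annotation map keyed by the ontology's
# cache environment identity (unique per ontology object per session).
ic_values <- function(annot, ont) {
  key <- paste0("ic:", format(ont$cache))
  hit <- annot$cache[[key]]
  if (!is.null(hit)) return(hit)
  if (length(annot$universe) == 0L) data_error("annotation universe is empty")
  counts <- term_gene_counts(annot, ont)
  ic <- ifelse(counts == 0L, NA_real_, -log(counts / length(annot$universe)))
  ic <- stats::setNames(as.numeric(ic), names(counts))
  annot$cache[[key]] <- ic
  ic
}

#' Lin semantic similarity between two terms
#'
#' sim(t1, t2) = 2 IC(MICA) / (IC(t1) + IC(t2)), where the MICA is the
#' common ancestor of t1 and t2 (each term counting as its own ancestor)
#' with maximal information content.  Defined as 0 when the terms share
#' no ancestor or when IC(t1) + IC(t2) = 0.
#'
#' @inheritParams term_ic
#' @param t1,t2 term IDs with defined IC.
#' @return Similarity in `[0, 1]`.
#' @export
lin_term_sim <- function(t1, t2, annot, ont) {
  ic <- ic_values(annot, ont)
  lin_from_ic(t1, t2, ic, ont)
}

lin_from_ic <- function(t1, t2, ic, ont) {
  ic1 <- ic[[t1]]
  ic2 <- ic[[t2]]
  if (is.na(ic1) || is.na(ic2)) {
    data_error(sprintf("IC undefined for term '%s'", if (is.na(ic1)) t1 else t2))
  }
  common <- intersect(term_ancestors(ont, t1), term_ancestors(ont, t2))
  if (length(common) == 0L || ic1 + ic2 == 0) return(0)
  mica_ic <- max(ic[common], na.rm = TRUE)
  if (!is.finite(mica_ic)) return(0)
  2 * mica_ic / (ic1 + ic2)
}

#' Gene-gene similarity by best-match averaging of Lin term similarity
#'
#' Computes the Lin similarity matrix between the two genes' direct
#' annotation term sets and returns the best-match average: the mean of
#' (average of row maxima, average of column maxima).  A gene with no
#' annotations scores 0 against everything, so unannotated genes stay in
#' the network with zero attribute signal rather than being dropped.
#'
#' @inheritParams term_ic
#' @param g1,g2 gene IDs.
#' @return Similarity in `[0, 1]`.
#' @export
gene_sim_bma <- function(g1, g2, annot, ont) {
  scorer <- make_gene_scorer(annot, ont)
  scorer$sim(g1, g2)
}

#' Build a memoized GO-based gene similarity scorer
#'
#' Precomputes IC values and caches gene-pair similarities so that
#' repeated scoring (for example across the permutations of a fingerprint
#' scan) never recomputes a pair.  The returned object is the pluggable
#' similarity backend used throughout the pipeline; `make_matrix_scorer()`
#' provides the precomputed-matrix alternative.
#'
#' @inheritParams term_ic
#' @return A list with functions `sim(g1, g2)` and
#'   `matrix(genes_a, genes_b)`, plus fields `provenance` ("go") and
#'   `universe`.
#' @export
make_gene_scorer <- function(annot, ont) {
  ic <- ic_values(annot, ont)
  pair_cache <- new.env(parent = emptyenv())
  term_cache <- new.env(parent = emptyenv())

  term_sim <- function(t1, t2) {
    key <- if (t1 <= t2) paste0(t1, "\r", t2) else paste0(t2, "\r", t1)
    hit <- term_cache[[key]]
    if (!is.null(hit)) return(hit)
    v <- lin_from_ic(t1, t2, ic, ont)
    term_cache[[key]] <- v
    v
  }

  sim <- function(g1, g2) {
    key <- if (g1 <= g2) paste0(g1, "\r", g2) else paste0(g2, "\r", g1)
    hit <- pair_cache[[key]]
    if (!is.null(hit)) return(hit)
    ts1 <- annot$genes[[g1]]
    ts2 <- annot$genes[[g2]]
    v <- if (is.null(ts1) || is.null(ts2)) {
      0
    } else {
      m <- matrix(0, length(ts1), length(ts2))
      for (i in seq_along(ts1)) {
        for (j in seq_along(ts2)) m[i, j] <- term_sim(ts1[[i]], ts2[[j]])
      }
      (mean(apply(m, 1L, max)) + mean(apply(m, 2L, max))) / 2
    }
    pair_cache[[key]] <- v
    v
  }

  mat <- function(genes_a, genes_b) {
    m <- matrix(0, length(genes_a), length(genes_b),
                dimnames = list(genes_a, genes_b))
    for (a in genes_a) for (b in genes_b) m[a, b] <- sim(a, b)
    similarity_matrix(m, provenance = "go")
  }

  list(sim = sim, matrix = mat, provenance = "go",
       universe = annot$universe)
}

#' Similarity matrix container
#'
#' A numeric matrix of gene-gene attribute similarities in `[0, 1]` with
#' row/column gene names and a provenance tag.
#'
#' @param m numeric matrix with dimnames.
#' @param provenance "go" or "precomputed".
#' @return The matrix with class `similarity_matrix`.
#' @export
similarity_matrix <- function(m, provenance = c("go", "precomputed")) {
  provenance <- match.arg(provenance)
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    data_error("similarity values must lie in [0, 1]")
  }
  structure(m, provenance = provenance,
            class = c("similarity_matrix", class(m)))
}

# Similarity lookup with a default for gene pairs the matrix does not
# cover (used for same-origin attribute similarity when only a
# query-by-reference matrix is available).
sim_lookup <- function(sim, a, b, default = 0) {
  ra <- rownames(sim)
  cb <- colnames(sim)
  if (a %in% ra && b %in% cb) return(sim[a, b])
  if (b %in% ra && a %in% cb) return(sim[b, a])
  default
}

# Block lookup: genes_a x genes_b values with `default` where the matrix
# has no coverage in either orientation.  Fast path when fully covered.
sim_block <- function(sim, genes_a, genes_b, default = 0) {
  ra <- rownames(sim)
  cb <- colnames(sim)
  m0 <- unclass(sim)
  if (all(genes_a %in% ra) && all(genes_b %in% cb)) {
    return(m0[genes_a, genes_b, drop = FALSE])
  }
  m <- matrix(default, length(genes_a), length(genes_b))
  in_a <- genes_a %in% ra
  in_b <- genes_b %in% cb
  if (any(in_a) && any(in_b)) {
    m[in_a, in_b] <- m0[genes_a[in_a], genes_b[in_b], drop = FALSE]
  }
  # Transposed coverage for any cell still at the default.
  t_a <- genes_a %in% cb
  t_b <- genes_b %in% ra
  if (any(t_a) && any(t_b)) {
    hole <- outer(!in_a, !in_b, "|") & outer(t_a, t_b, "&")
    if (any(hole)) {
      idx <- which(hole, arr.ind = TRUE)
      m[idx] <- m0[cbind(match(genes_b[idx[, 2L]], ra),
                         match(genes_a[idx[, 1L]], cb))]
    }
  }
  m
}

#' Compute a gene-gene similarity matrix from GO annotations
#'
#' @inheritParams term_ic
#' @param genes_a,genes_b character vectors of gene IDs (rows, columns).
#' @return A [similarity_matrix()] with provenance "go".
#' @export
build_similarity_matrix <- function(genes_a, genes_b, annot, ont) {
  make_gene_scorer(annot, ont)$matrix(genes_a, genes_b)
}

#' Load a precomputed gene-gene similarity matrix
#'
#' Reads a three-column TSV (gene_a, gene_b, value in `[0, 1]`); this is
#' the route for externally computed similarities such as sequence-based
#' scores.  Pairs absent from the file default to 0 with a single summary
#' warning.
#'
#' @param path TSV file path.
#' @param genes_a,genes_b gene IDs for the rows and columns.
#' @return A [similarity_matrix()] with provenance "precomputed".
#' @export
load_precomputed_matrix <- function(path, genes_a, genes_b) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  m <- matrix(0, length(genes_a), length(genes_b),
              dimnames = list(genes_a, genes_b))
  seen <- matrix(FALSE, length(genes_a), length(genes_b),
                 dimnames = list(genes_a, genes_b))
  for (i in which(keep)) {
    tk <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tk) < 3L) {
      format_error(sprintf("similarity TSV line %d lacks three columns", i))
    }
    v <- suppressWarnings(as.numeric(tk[[3L]]))
    if (is.na(v) || v < 0 || v > 1) {
      data_error(sprintf("similarity value out of [0, 1] on line %d: %s",
                         i, tk[[3L]]))
    }
    for (pair in list(c(tk[[1L]], tk[[2L]]), c(tk[[2L]], tk[[1L]]))) {
      if (pair[[1L]] %in% genes_a && pair[[2L]] %in% genes_b) {
        m[pair[[1L]], pair[[2L]]] <- v
        seen[pair[[1L]], pair[[2L]]] <- TRUE
      }
    }
  }
  n_missing <- sum(!seen)
  if (n_missing > 0L) {
    warning(sprintf("%d gene pair(s) missing from %s; defaulted to 0",
                    n_missing, path), call. = FALSE)
  }
  similarity_matrix(m, provenance = "precomputed")
}

#' Build a scorer around a precomputed similarity matrix
#'
#' @param sim a [similarity_matrix()].
#' @param universe optional gene universe for permutation pools.
#' @return A scorer object with the same surface as [make_gene_scorer()].
#' @export
make_matrix_scorer <- function(sim, universe = NULL) {
  universe <- universe %||% sort(unique(c(rownames(sim), colnames(sim))))
  list(
    sim = function(g1, g2) sim_lookup(sim, g1, g2, default = 0),
    matrix = function(genes_a, genes_b) {
      m <- matrix(0, length(genes_a), length(genes_b),
                  dimnames = list(genes_a, genes_b))
      for (a in genes_a) for (b in genes_b) m[a, b] <- sim_lookup(sim, a, b)
      similarity_matrix(m, provenance = "precomputed")
    },
    provenance = "precomputed",
    universe = universe
  )
}
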