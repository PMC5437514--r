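#' Construct a reference set of pathway networks
#'
#' An ordered, categorized collection of reference pathways.  The order
#' of pathways is significant: it defines the coordinate order of every
#' fingerprint computed against the set, and is never sorted implicitly.
#'
#' @param id set label.
#' @param pathways list of [gene_network()] objects; each should carry
#'   `metadata$source` and `metadata$category`.
#' @return An object of class `reference_set` with fields `id`,
#'   `pathways` (named by pathway id, manifest order) and `categories`
#'   (unique labels in order of first appearance).
#' @export
reference_set <- function(id, pathways) {
  ids <- vapply(pathways, function(p) p$id, "")
  if (anyDuplicated(ids)) {
    data_error(sprintf("duplicate pathway id(s): %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names(pathways) <- ids
  cats <- unique(vapply(pathways, function(p) p$metadata$category %||% "", ""))
  structure(list(id = as.character(id), pathways = pathways,
                 categories = cats[cats != ""]),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set '%s': %d pathway(s), %d categorie(s)>\n",
              x$id, length(x$pathways), length(x$categories)))
  invisible(x)
}

#' @export
length.reference_set <- function(x) length(x$pathways)

#' Load a reference set from a manifest
#'
#' The manifest is either a JSON array of `{id, category, source, path}`
#' records or a TSV with those four columns (header required).  Edge-list
#' paths are resolved relative to the manifest's directory; each file is
#' loaded through [read_edge_list()].  Manifest order is preserved.
#'
#' @param path manifest file path.
#' @param id set label; defaults to the manifest file name.
#' @return A [reference_set()].
#' @export
load_reference_manifest <- function(path, id = NULL) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  id <- id %||% tools::file_path_sans_ext(basename(path))
  dir <- dirname(path)
  entries <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = "character", comment.char = "#")
  }
  need <- c("id", "category", "source", "path")
  if (!all(need %in% names(entries))) {
    format_error(sprintf("manifest must provide columns: %s",
                         paste(need, collapse = ", ")))
  }
  if (anyDuplicated(entries$id)) {
    data_error(sprintf("duplicate pathway id '%s' in manifest",
                       entries$id[duplicated(entries$id)][[1L]]))
  }
  pathways <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    p <- entries$path[[i]]
    if (!file.exists(p)) p <- file.path(dir, entries$path[[i]])
    if (!file.exists(p)) {
      data_error(sprintf("edge-list file missing for pathway '%s': %s",
                         entries$id[[i]], entries$path[[i]]))
    }
    net <- read_edge_list(p, id = entries$id[[i]])
    net$metadata$source <- entries$source[[i]]
    net$metadata$category <- entries$category[[i]]
    pathways[[i]] <- net
  }
  reference_set(id, pathways)
}

#' Drop reference pathways below an edge-count threshold
#'
#' Very small pathways carry too little interaction structure to serve
#' as fingerprint coordinates; pathways with fewer than `min_edges` edges
#' are excluded (default 10).  Order of the survivors is preserved.
#'
#' @param set a [reference_set()].
#' @param min_edges minimum edge count to retain (inclusive).
#' @return The filtered [reference_set()].
#' @export
filter_small_pathways <- function(set, min_edges = 10L) {
  if (min_edges < 1L) parameter_error("min_edges must be a positive integer")
  keep <- vapply(set$pathways, function(p) n_edges(p) >= min_edges, TRUE)
  dropped <- names(set$pathways)[!keep]
  if (length(dropped) > 0L) {
    message(sprintf("excluded %d pathway(s) with < %d edges: %s",
                    length(dropped), min_edges, paste(dropped, collapse = ", ")))
  }
  if (!any(keep)) {
    warning("all pathways fell below the edge threshold; reference set is empty",
            call. = FALSE)
  }
  reference_set(set$id, set$pathways[keep])
}

#' Write a reference set as a directory of edge lists plus manifest
#'
#' @param set a [reference_set()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_reference_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in set$pathways) {
    write_edge_list(p, file.path(dir, paste0(p$id, ".tsv")))
  }
  entries <- data.frame(
    id = names(set$pathways),
    category = vapply(set$pathways, function(p) p$metadata$category %||% "", ""),
    source = vapply(set$pathways, function(p) p$metadata$source %||% "", ""),
    path = paste0(names(set$pathways), ".tsv"),
    stringsAsFactors = FALSE
  )
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = FALSE, digits = NA)
  invisible(manifest)
}

#' Reference pathways as gene sets
#'
#' @param set a [reference_set()].
#' @return Named list of character vectors (pathway id -> node set),
#'   usable as a collection for [enrich_gene_set()] or GMT export.
#' @export
reference_gene_sets <- function(set) {
  lapply(set$pathways, function(p) p$nodes)
}

#' Default parameters for the synthetic universe generator
#'
#' The defaults describe the benchmark scenario used throughout the
#' package's validation: 20 reference pathways of 10-15 nodes drawn from
#' a 300-gene pool, three high-specificity "theme" terms per pathway
#' assigned to its member genes with probability 0.8 (the annotation
#' coherence), and two uniformly drawn background terms per gene.
#'
#' @param n_refs number of reference pathways (>= 2).
#' @param node_range inclusive node-count range per pathway, within
#'   `[5, 200]`.
#' @param coherence probability that a pathway gene carries each of the
#'   pathway's theme terms.
#' @param pool_size total number of genes in the universe.
#' @param themes_per_ref theme terms owned by each pathway.
#' @param noise_terms_per_gene uniformly assigned background terms per gene.
#' @param mean_degree target mean degree of each pathway graph.
#' @return A named list of generation parameters.
#' @export
universe_params <- function(n_refs = 20L, node_range = c(10L, 15L),
                            coherence = 0.8, pool_size = 300L,
                            themes_per_ref = 3L, noise_terms_per_gene = 2L,
                            mean_degree = 3) {
  if (n_refs < 2L) parameter_error("n_refs must be >= 2")
  if (node_range[1L] < 5L || node_range[2L] > 200L || node_range[1L] > node_range[2L]) {
    parameter_error("pathway node range must lie within [5, 200]")
  }
  if (coherence < 0 || coherence > 1) parameter_error("coherence must be in [0, 1]")
  if (node_range[2L] > pool_size) {
    parameter_error("pathway size exceeds the gene pool")
  }
  list(n_refs = as.integer(n_refs), node_range = as.integer(node_range),
       coherence = coherence, pool_size = as.integer(pool_size),
       themes_per_ref = as.integer(themes_per_ref),
       noise_terms_per_gene = as.integer(noise_terms_per_gene),
       mean_degree = mean_degree)
}

#' Generate a synthetic universe for planted-module benchmarks
#'
#' Builds a complete, self-consistent test world: a layered single-root
#' `is_a` ontology; a pool of genes; a set of connected random reference
#' pathways; and coherent annotations in which each pathway owns a set of
#' specific leaf "theme" terms carried by its genes with probability
#' `coherence`, on top of uniform background annotation.  The generator
#' is fully deterministic given its parameters and seed.
#'
#' @param params a [universe_params()] list.
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_universe` with fields
#'   `ontology`, `annotations`, `references`, `theme_terms` (per-pathway
#'   list), `gene_pool`, `params` and `seed`.
#' @export
generate_synthetic_universe <- function(params = universe_params(), seed = 1L) {
  with_rng_seed(seed, {
    genes <- sprintf("g%04d", seq_len(params$pool_size))
    n_themes <- params$n_refs * params$themes_per_ref
    n_extra_leaves <- max(10L, ceiling(n_themes / 3))
    n_mid <- max(4L, ceiling((n_themes + n_extra_leaves) / 10))

    root <- "T:root"
    mids <- sprintf("T:mid%03d", seq_len(n_mid))
    leaves <- sprintf("T:leaf%03d", seq_len(n_themes + n_extra_leaves))
    parents <- c(
      stats::setNames(list(character()), root),
      stats::setNames(lapply(mids, function(m) root), mids),
      stats::setNames(lapply(leaves, function(l) sample(mids, 1L)), leaves)
    )
    ont <- ontology(parents)

    theme_terms <- split(
      leaves[seq_len(n_themes)],
      rep(seq_len(params$n_refs), each = params$themes_per_ref)
    )

    # Background annotation: every pool gene gets noise terms drawn
    # uniformly from the leaves.
    gene2terms <- stats::setNames(
      lapply(genes, function(g) sample(leaves, params$noise_terms_per_gene)),
      genes
    )

    cats <- c("signaling", "metabolism", "regulation", "immune")
    pathways <- vector("list", params$n_refs)
    for (r in seq_len(params$n_refs)) {
      n <- sample(seq(params$node_range[1L], params$node_range[2L]), 1L)
      members <- sample(genes, n)
      edges <- random_connected_edges(members, params$mean_degree,
                                      min_edges = 10L)
      net <- gene_network(sprintf("ref%02d", r), edges, nodes = members,
                          metadata = list(source = "synthetic",
                                          category = cats[(r - 1L) %% length(cats) + 1L]))
      pathways[[r]] <- net
      # Coherent theme annotation for this pathway's genes.
      for (g in members) {
        got <- theme_terms[[r]][stats::runif(params$themes_per_ref) < params$coherence |
                                  params$coherence >= 1]
        gene2terms[[g]] <- c(gene2terms[[g]], got)
      }
    }

    annot <- annotation_map(gene2terms, ont)
    refs <- reference_set("synthetic", pathways)
    structure(
      list(ontology = ont, annotations = annot, references = refs,
           theme_terms = stats::setNames(theme_terms, names(refs$pathways)),
           gene_pool = genes, params = params, seed = as.integer(seed)),
      class = "synthetic_universe"
    )
  })
}

#' @export
print.synthetic_universe <- function(x, ...) {
  cat(sprintf(
    "<synthetic_universe: %d genes, %d terms, %d reference pathway(s), seed %d>\n",
    length(x$gene_pool), length(x$ontology$terms),
    length(x$references$pathways), x$seed))
  invisible(x)
}

# Erdos-Renyi edges over `members` at the target mean degree, repaired to
# a single connected component and topped up to `min_edges` edges.
# Consumes RNG state; callers are responsible for seeding.
random_connected_edges <- function(members, mean_degree, min_edges = 10L) {
  n <- length(members)
  p <- min(1, mean_degree / (n - 1))
  pairs <- utils::combn(sort(members), 2L)
  pick <- stats::runif(ncol(pairs)) < p
  edges <- t(pairs[, pick, drop = FALSE])

  # Connectivity repair: link each extra component to the first.
  repeat {
    g <- igraph::graph_from_data_frame(
      as.data.frame(edges, stringsAsFactors = FALSE),
      directed = FALSE, vertices = data.frame(name = members))
    comp <- igraph::components(g)
    if (comp$no == 1L) break
    memb <- comp$membership
    a <- sample(names(memb)[memb == 1L], 1L)
    b <- sample(names(memb)[memb == 2L], 1L)
    edges <- rbind(edges, c(a, b))
  }
  # Top-up: add unused pairs until the edge-count floor is met.
  if (nrow(edges) < min_edges) {
    key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    all_key <- paste(pairs[1L, ], pairs[2L, ])
    avail <- which(!(all_key %in% key))
    need <- min_edges - nrow(edges)
    if (length(avail) < need) {
      parameter_error("pathway too small to reach the minimum edge count")
    }
    add <- avail[sample.int(length(avail), need)]
    edges <- rbind(edges, t(pairs[, add, drop = FALSE]))
  }
  edges
}

#' Plant a query network derived from one reference pathway
#'
#' Emulates a disease-module query with known ground truth: an induced
#' subgraph on a `retention` fraction of one reference pathway's nodes,
#' diluted with unrelated background genes and random noise edges, then
#' repaired to a single connected component.  The planted reference id is
#' recorded in the query's metadata.
#'
#' @param universe a [generate_synthetic_universe()] result.
#' @param ref_id id of the pathway to plant.
#' @param retention fraction of the reference's nodes to keep, in (0, 1].
#' @param noise_edges number of random extra edges to add.
#' @param n_background number of background pool genes to mix in.
#' @param seed integer RNG seed.
#' @return A [gene_network()] with `metadata$planted_ref = ref_id`.
#' @export
plant_query <- function(universe, ref_id, retention = 0.9, noise_edges = 5L,
                        n_background = 3L, seed = 1L) {
  if (!ref_id %in% names(universe$references$pathways)) {
    parameter_error(sprintf("unknown reference id: %s", ref_id))
  }
  if (retention <= 0 || retention > 1) {
    parameter_error("retention must be in (0, 1]")
  }
  ref <- universe$references$pathways[[ref_id]]
  with_rng_seed(seed, {
    n_keep <- round(retention * n_nodes(ref))
    if (n_keep < 2L) parameter_error("retention sample smaller than 2 nodes")
    kept <- if (n_keep == n_nodes(ref)) ref$nodes else sample(ref$nodes, n_keep)
    in_kept <- ref$edges[, 1L] %in% kept & ref$edges[, 2L] %in% kept
    edges <- ref$edges[in_kept, , drop = FALSE]

    bg_pool <- setdiff(universe$gene_pool, ref$nodes)
    background <- if (n_background > 0L) sample(bg_pool, n_background) else character()
    nodes <- c(kept, background)

    if (noise_edges > 0L && length(nodes) >= 2L) {
      pairs <- utils::combn(sort(nodes), 2L)
      key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
      avail <- which(!(paste(pairs[1L, ], pairs[2L, ]) %in% key))
      add <- avail[sample.int(length(avail), min(noise_edges, length(avail)))]
      edges <- rbind(edges, t(pairs[, add, drop = FALSE]))
    }

    # Connectivity repair, as for generated pathways.
    repeat {
      g <- igraph::graph_from_data_frame(
        as.data.frame(edges, stringsAsFactors = FALSE),
        directed = FALSE, vertices = data.frame(name = nodes))
      comp <- igraph::components(g)
      if (comp$no == 1L) break
      memb <- comp$membership
      a <- sample(names(memb)[memb == 1L], 1L)
      b <- sample(names(memb)[memb == 2L], 1L)
      edges <- rbind(edges, c(a, b))
    }

    gene_network(sprintf("query_%s_s%d", ref_id, as.integer(seed)), edges,
                 nodes = nodes,
                 metadata = list(planted_ref = ref_id,
                                 retention = as.character(retention)))
  })
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description column (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[[i]], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    tk <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(tk) < 3L) {
      format_error(sprintf("GMT line %d has fewer than 3 fields", i))
    }
    sets[[tk[[1L]]]] <- unique(tk[-(1:2)])
  }
  sets
}
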