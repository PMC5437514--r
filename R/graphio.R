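#' Construct a normalized gene network
#'
#' A `gene_network` is an undirected labeled graph over gene identifiers.
#' Gene IDs are case-sensitive opaque strings; the model carries no edge
#' direction or weight because neither the node-mapping nor the scoring
#' step uses them.  Construction normalizes the edge set: self-loops are
#' dropped (with a warning), duplicate edges are collapsed under
#' unordered-endpoint equality, endpoints within an edge and the edge rows
#' themselves are sorted lexicographically so that equal networks have
#' identical representations.
#'
#' @param id character label for the network.
#' @param edges two-column character matrix (or data.frame) of endpoint
#'   pairs; may have zero rows if `nodes` supplies at least two nodes.
#' @param nodes optional character vector of node IDs; isolated nodes
#'   (present here but in no edge) are kept.
#' @param metadata named list of free-form string metadata.
#' @return An object of class `gene_network` with fields `id`, `nodes`
#'   (sorted character vector), `edges` (n x 2 character matrix, canonical
#'   order) and `metadata`.
#' @export
gene_network <- function(id, edges, nodes = NULL, metadata = list()) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (!is.character(edges)) storage.mode(edges) <- "character"
  if (ncol(edges) < 2L) format_error("edges must have two columns")
  edges <- edges[, 1:2, drop = FALSE]

  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    warning(sprintf("%d self-loop(s) dropped in network '%s'", sum(loops), id),
            call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges) > 0L) {
    swap <- edges[, 1L] > edges[, 2L]
    tmp <- edges[swap, 1L]
    edges[swap, 1L] <- edges[swap, 2L]
    edges[swap, 2L] <- tmp
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  colnames(edges) <- c("from", "to")

  all_nodes <- sort(unique(c(as.character(edges), as.character(nodes %||% character()))))
  if (length(all_nodes) < 2L) {
    format_error(sprintf("network '%s' has fewer than 2 nodes after normalization", id))
  }
  structure(
    list(id = as.character(id), nodes = all_nodes, edges = edges,
         metadata = metadata),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network '%s': %d nodes, %d edges>\n",
              x$id, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

n_nodes <- function(net) length(net$nodes)
n_edges <- function(net) nrow(net$edges)

#' Read a gene network from a two-column edge list
#'
#' Parses a whitespace- or tab-separated edge list.  Lines starting with
#' `#` are comments.  A single header line is auto-detected and skipped
#' when neither of its first two tokens appears in any other line.  Only
#' the first two tokens of each line are used.  The result is normalized
#' as described in [gene_network()].
#'
#' @param path path to the edge-list file.
#' @param id network label; defaults to the file name without extension.
#' @param mapping optional two-column data.frame (old ID, new ID) applied
#'   to node labels at load time.
#' @return A [gene_network()].
#' @export
read_edge_list <- function(path, id = NULL, mapping = NULL) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  id <- id %||% tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) format_error(sprintf("no edges in %s", path))

  toks <- lapply(idx, function(i) {
    tk <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tk) < 2L) {
      format_error(sprintf("malformed line %d in %s (need two tokens)", i, path))
    }
    tk[1:2]
  })
  # Header detection: drop the first data line if its tokens occur in no
  # other edge (e.g. a "source\ttarget" header).
  if (length(toks) > 1L) {
    rest <- unique(unlist(toks[-1L]))
    if (!any(toks[[1L]] %in% rest)) toks <- toks[-1L]
  }
  edges <- do.call(rbind, toks)
  # "# node\t<id>" comment lines record isolated nodes (written by
  # write_edge_list) so round trips preserve the node set.
  isolated <- sub("^# node\t", "", grep("^# node\t", lines, value = TRUE))
  if (!is.null(mapping)) {
    edges <- apply_id_mapping(edges, mapping)
    if (length(isolated)) {
      isolated <- as.character(apply_id_mapping(matrix(isolated, ncol = 1), mapping))
    }
  }
  gene_network(id, edges, nodes = isolated)
}

apply_id_mapping <- function(edges, mapping) {
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- utils::read.table(mapping, header = FALSE, sep = "",
                                 colClasses = "character")
  }
  m <- stats::setNames(as.character(mapping[[2L]]), as.character(mapping[[1L]]))
  hit <- edges %in% names(m)
  edges[hit] <- m[edges[hit]]
  edges
}

#' Read a gene network from a GraphML file
#'
#' Parses GraphML through igraph.  Edge direction in the file is
#' discarded (the network model is undirected) and the usual
#' normalization applies.  Node identity defaults to the GraphML node id;
#' a string node attribute can override it as the gene label.
#'
#' @param path path to the GraphML file.
#' @param id network label; defaults to the file name without extension.
#' @param label_attr optional name of a node attribute to use as the gene
#'   label instead of the node id.
#' @param mapping optional two-column ID mapping, as in [read_edge_list()].
#' @return A [gene_network()].
#' @export
read_graphml <- function(path, id = NULL, label_attr = NULL, mapping = NULL) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  id <- id %||% tools::file_path_sans_ext(basename(path))
  g <- tryCatch(
    igraph::read_graph(path, format = "graphml"),
    error = function(e) format_error(sprintf("GraphML parse failure in %s: %s",
                                             path, conditionMessage(e)))
  )
  if (igraph::vcount(g) == 0L) format_error(sprintf("GraphML file %s has zero nodes", path))
  attrs <- igraph::vertex_attr_names(g)
  lab_name <- label_attr %||% (if ("name" %in% attrs) "name" else "id")
  if (!lab_name %in% attrs) {
    format_error(sprintf("node attribute '%s' not present in %s", lab_name, path))
  }
  labels <- as.character(igraph::vertex_attr(g, lab_name))
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- cbind(labels[el[, 1L]], labels[el[, 2L]])
  if (!is.null(mapping)) {
    edges <- apply_id_mapping(edges, mapping)
    labels <- as.character(apply_id_mapping(matrix(labels, ncol = 1), mapping))
  }
  gene_network(id, edges, nodes = labels)
}

#' Write a gene network as a canonical edge list
#'
#' Emits tab-separated edges with lexicographically sorted endpoints and
#' lines; isolated nodes are recorded in a trailing comment block so that
#' a write/read round trip preserves the exact node and edge sets.
#'
#' @param net a [gene_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  lines <- sprintf("%s\t%s", net$edges[, 1L], net$edges[, 2L])
  isolated <- setdiff(net$nodes, unique(as.character(net$edges)))
  if (length(isolated) > 0L) {
    lines <- c(lines, sprintf("# node\t%s", sort(isolated)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Check a network against the recommended size range
#'
#' Query networks in the 50-100 node / 100-1,000 edge range give the most
#' informative fingerprints; outside that range the method still runs, so
#' violations are advisory warnings, never errors.
#'
#' @param net a [gene_network()].
#' @param node_range,edge_range inclusive recommended ranges.
#' @return A list of class `validation_report` with fields `id`,
#'   `n_nodes`, `n_edges` and `warnings` (character vector, possibly
#'   empty).
#' @export
validate_network_size <- function(net, node_range = c(50L, 100L),
                                  edge_range = c(100L, 1000L)) {
  warns <- character()
  nv <- n_nodes(net)
  ne <- n_edges(net)
  if (nv < node_range[1L] || nv > node_range[2L]) {
    warns <- c(warns, sprintf(
      "node count %d outside recommended range [%d, %d]",
      nv, node_range[1L], node_range[2L]))
  }
  if (ne < edge_range[1L] || ne > edge_range[2L]) {
    warns <- c(warns, sprintf(
      "edge count %d outside recommended range [%d, %d]",
      ne, edge_range[1L], edge_range[2L]))
  }
  structure(list(id = net$id, n_nodes = nv, n_edges = ne, warnings = warns),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report '%s': %d nodes, %d edges, %d warning(s)>\n",
              x$id, x$n_nodes, x$n_edges, length(x$warnings)))
  for (w in x$warnings) cat(" -", w, "\n")
  invisible(x)
}

# igraph view of a gene_network (undirected, named vertices).
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}
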