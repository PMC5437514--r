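make_manifest <- function(dir, entries) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (e in entries) {
    if (!is.null(e$edges)) {
      net <- gene_network(e$id, e$edges)
      write_edge_list(net, file.path(dir, paste0(e$id, ".tsv")))
    }
  }
  df <- data.frame(
    id = vapply(entries, `[[`, "", "id"),
    category = "cat",
    source = "test",
    path = paste0(vapply(entries, `[[`, "", "id"), ".tsv"),
    stringsAsFactors = FALSE
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(df, mp)
  mp
}

path_edges <- function(n_edges, prefix) {
  # A star with n_edges edges, distinct gene names per pathway.
  cbind(paste0(prefix, "_hub"), paste0(prefix, "_", seq_len(n_edges)))
}

test_that("manifests load in order; duplicates and missing files error", {
  d <- tempfile("refs")
  mp <- make_manifest(d, list(
    list(id = "p1", edges = path_edges(3, "a")),
    list(id = "p2", edges = path_edges(4, "b")),
    list(id = "p3", edges = path_edges(5, "c"))
  ))
  set <- load_reference_manifest(mp)
  expect_equal(names(set$pathways), c("p1", "p2", "p3"))
  expect_equal(set$pathways$p2$metadata$source, "test")

  d2 <- tempfile("refs")
  mp2 <- make_manifest(d2, list(
    list(id = "p1", edges = path_edges(3, "a")),
    list(id = "p1", edges = path_edges(3, "a2"))
  ))
  expect_error(load_reference_manifest(mp2), "duplicate pathway id")

  d3 <- tempfile("refs")
  mp3 <- make_manifest(d3, list(
    list(id = "p1", edges = path_edges(3, "a")),
    list(id = "p2", edges = NULL)  # no file written
  ))
  expect_error(load_reference_manifest(mp3), "p2")
})

test_that("small pathways are excluded at the 10-edge boundary", {
  d <- tempfile("refs")
  mp <- make_manifest(d, list(
    list(id = "e9", edges = path_edges(9, "x")),
    list(id = "e10", edges = path_edges(10, "y")),
    list(id = "e11", edges = path_edges(11, "z"))
  ))
  set <- load_reference_manifest(mp)
  filtered <- suppressMessages(filter_small_pathways(set))
  expect_equal(names(filtered$pathways), c("e10", "e11"))

  # min_edges = 1 is the identity on loaded sets.
  expect_equal(names(filter_small_pathways(set, min_edges = 1L)$pathways),
               names(set$pathways))

  # Idempotence.
  twice <- suppressMessages(filter_small_pathways(filtered))
  expect_identical(names(twice$pathways), names(filtered$pathways))

  expect_warning(suppressMessages(filter_small_pathways(set, min_edges = 100L)),
                 "empty")
})

test_that("synthetic universes are reproducible and coherent", {
  params <- universe_params(n_refs = 3L, node_range = c(8L, 10L),
                            pool_size = 40L)
  u1 <- generate_synthetic_universe(params, seed = 7)
  u2 <- generate_synthetic_universe(params, seed = 7)
  # Byte-identical apart from session-specific cache environments.
  strip <- function(u) {
    u$ontology$cache <- NULL
    u$annotations$cache <- NULL
    u
  }
  expect_identical(serialize(strip(u1), NULL), serialize(strip(u2), NULL))
  u3 <- generate_synthetic_universe(params, seed = 8)
  expect_false(identical(strip(u1), strip(u3)))

  # Every generated pathway is connected with >= 10 edges.
  for (p in u1$references$pathways) {
    expect_gte(nrow(p$edges), 10L)
    g <- igraph::graph_from_data_frame(as.data.frame(p$edges),
                                       directed = FALSE,
                                       vertices = data.frame(name = p$nodes))
    expect_equal(igraph::components(g)$no, 1L)
  }

  # coherence = 1: every pathway gene carries all theme terms.
  uc <- generate_synthetic_universe(
    universe_params(n_refs = 2L, node_range = c(8L, 9L), pool_size = 30L,
                    coherence = 1), seed = 3)
  for (rid in names(uc$references$pathways)) {
    themes <- uc$theme_terms[[rid]]
    for (g in uc$references$pathways[[rid]]$nodes) {
      expect_true(all(themes %in% uc$annotations$genes[[g]]))
    }
  }
})

test_that("infeasible generator parameters error", {
  expect_error(universe_params(n_refs = 1L), "n_refs")
  expect_error(universe_params(node_range = c(2L, 10L)), "node range")
  expect_error(universe_params(node_range = c(10L, 50L), pool_size = 20L),
               "pool")
})

test_that("planted queries honor retention, seeds and repair", {
  uni <- small_universe()
  rid <- names(uni$references$pathways)[[1L]]
  ref <- uni$references$pathways[[rid]]

  # Identity planting.
  q <- plant_query(uni, rid, retention = 1, noise_edges = 0L,
                   n_background = 0L, seed = 5)
  expect_setequal(q$nodes, ref$nodes)
  expect_equal(q$metadata$planted_ref, rid)

  # Exact retention count before background.
  q <- plant_query(uni, rid, retention = 0.5, noise_edges = 0L,
                   n_background = 0L, seed = 5)
  expect_equal(sum(q$nodes %in% ref$nodes), round(0.5 * length(ref$nodes)))

  # Different seeds give different node samples (over 20 trials).
  samples <- vapply(1:20, function(s) {
    paste(sort(plant_query(uni, rid, retention = 0.5, noise_edges = 0L,
                           n_background = 0L, seed = s)$nodes),
          collapse = ",")
  }, "")
  expect_gt(length(unique(samples)), 1L)

  # Background genes come from outside the reference.
  q <- plant_query(uni, rid, retention = 0.9, noise_edges = 2L,
                   n_background = 5L, seed = 5)
  expect_equal(sum(!q$nodes %in% ref$nodes), 5L)

  expect_error(plant_query(uni, "nope", seed = 1), "unknown reference")
  expect_error(plant_query(uni, rid, retention = 0, seed = 1), "retention")
})

test_that("reference sets round-trip through a written directory", {
  uni <- small_universe()
  d <- tempfile("export")
  mp <- write_reference_set(uni$references, d)
  back <- load_reference_manifest(mp, id = uni$references$id)
  expect_equal(names(back$pathways), names(uni$references$pathways))
  for (rid in names(back$pathways)) {
    expect_identical(back$pathways[[rid]]$nodes,
                     uni$references$pathways[[rid]]$nodes)
    expect_identical(back$pathways[[rid]]$edges,
                     uni$references$pathways[[rid]]$edges)
  }
})

test_that("GMT files round-trip", {
  sets <- list(s1 = c("a", "b", "c"), s2 = c("d", "e"))
  p <- tempfile(fileext = ".gmt")
  write_gmt(sets, p)
  expect_equal(read_gmt(p), sets)
})
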