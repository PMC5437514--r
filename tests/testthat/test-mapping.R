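two_nets <- function() {
  q <- gene_network("q", rbind(c("a", "b")))
  r <- gene_network("r", rbind(c("x", "y")))
  list(q = q, r = r)
}

manual_sim <- function(values, genes_a, genes_b) {
  similarity_matrix(
    matrix(values, length(genes_a), length(genes_b), byrow = TRUE,
           dimnames = list(genes_a, genes_b)),
    provenance = "precomputed")
}

test_that("network merging adds cross edges exactly at the threshold", {
  w <- two_nets()
  sim <- manual_sim(c(0.9, 0.1, 0.1, 0.1), c("a", "b"), c("x", "y"))
  mg <- merge_networks(w$q, w$r, sim, tau = 0.5)
  expect_equal(mg$n_cross, 1L)
  expect_true(igraph::are_adjacent(mg$graph, "Q:a", "R:x"))
  expect_equal(unname(mg$origin[c("Q:a", "R:x")]), c("Q", "R"))

  mg0 <- merge_networks(w$q, w$r, sim, tau = 1)
  expect_equal(mg0$n_cross, 0L)

  # Reference = copy of query with identity similarity.
  r2 <- gene_network("r2", w$q$edges)
  id_sim <- manual_sim(c(1, 0, 0, 1), c("a", "b"), c("a", "b"))
  mg2 <- merge_networks(w$q, r2, id_sim, tau = 0.5)
  expect_equal(mg2$n_cross, 2L)
})

test_that("affinity blends Jaccard topology with attribute similarity", {
  w <- two_nets()
  sim <- manual_sim(c(0.9, 0.1, 0.1, 0.1), c("a", "b"), c("x", "y"))
  mg <- merge_networks(w$q, w$r, sim, tau = 0.5)

  # w_topo = 0: off-diagonal equals the attribute similarity exactly.
  A <- build_affinity(mg, sim, w_topo = 0, preference = 0)
  expect_equal(A["Q:a", "R:x"], 0.9)
  expect_equal(A["Q:a", "R:y"], 0.1)
  expect_equal(A["Q:a", "Q:b"], 0)  # same-origin pair not covered -> 0

  # Identical neighbor sets with zero attribute, w_topo = 1 -> s = 1.
  # Q:b and R:y both have exactly {Q:a} u {R:x}? Build a case:
  q <- gene_network("q", rbind(c("a", "b"), c("a", "c")))
  r <- gene_network("r", rbind(c("x", "y")))
  s2 <- manual_sim(rep(0, 6), c("a", "b", "c"), c("x", "y"))
  mg2 <- merge_networks(q, r, s2, tau = 0.5)  # no cross edges
  A2 <- build_affinity(mg2, s2, w_topo = 1, preference = 0)
  expect_equal(A2["Q:b", "Q:c"], 1)  # both neighbor exactly {Q:a}

  # Median preference over off-diagonal values {0.1, 0.9} -> 0.5.
  qq <- gene_network("qq", rbind(c("a", "b")))
  rr <- gene_network("rr", rbind(c("x", "y")))
  # Construct so the only nonzero off-diagonals are 0.1 and 0.9: use
  # w_topo = 0 and a 2x2 identity-free sim.
  s3 <- manual_sim(c(0.9, 0.9, 0.1, 0.1), c("a", "b"), c("x", "y"))
  mg3 <- merge_networks(qq, rr, s3, tau = 2)  # no cross edges, tau > 1
  A3 <- build_affinity(mg3, s3, w_topo = 0, preference = "median")
  off <- A3[upper.tri(A3)]
  expect_equal(unname(diag(A3)), rep(stats::median(off), 4))
})

test_that("affinity propagation solves the two-block worked example", {
  S <- matrix(0.1, 4, 4)
  S[1, 2] <- S[2, 1] <- 0.9
  S[3, 4] <- S[4, 3] <- 0.9
  diag(S) <- 0.5
  dimnames(S) <- list(letters[1:4], letters[1:4])

  # Independent oracle: exhaustive exemplar-set search.
  opt <- exhaustive_best_net(S)
  expect_equal(opt$net, 2.8, tolerance = 1e-9)
  expect_length(opt$exemplars, 2L)

  m <- affinity_propagation(S)
  expect_length(m$clusters, 2L)
  sizes <- sort(unname(vapply(m$clusters, function(cl) length(cl$members), 1L)))
  expect_equal(sizes, c(2L, 2L))
  members <- lapply(m$clusters, function(cl) sort(cl$members))
  expect_true(any(vapply(members, identical, TRUE, c("a", "b"))))
  expect_true(any(vapply(members, identical, TRUE, c("c", "d"))))
  expect_equal(mapping_net_similarity(m, S), opt$net, tolerance = 1e-6)
})

test_that("high preference makes every node its own exemplar", {
  set.seed(11)
  for (trial in 1:5) {
    n <- sample(3:8, 1)
    S <- matrix(stats::runif(n * n, 0, 0.5), n, n)
    S <- (S + t(S)) / 2
    diag(S) <- 0.9  # strictly above every off-diagonal
    dimnames(S) <- list(paste0("n", 1:n), paste0("n", 1:n))
    opt <- exhaustive_best_net(S)
    expect_length(opt$exemplars, n)  # oracle agrees singletons are optimal
    m <- affinity_propagation(S)
    expect_length(m$clusters, n)
  }
})

test_that("AP net similarity is near-optimal on block-structured matrices", {
  set.seed(23)
  for (trial in 1:8) {
    n <- sample(4:8, 1)
    k <- sample(2:3, 1)
    block <- sample(k, n, replace = TRUE)
    S <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      if (i != j) S[i, j] <- if (block[i] == block[j]) stats::runif(1, 0.7, 0.9)
                             else stats::runif(1, 0, 0.2)
    }
    S <- (S + t(S)) / 2
    diag(S) <- 0.3
    dimnames(S) <- list(paste0("n", 1:n), paste0("n", 1:n))
    opt <- exhaustive_best_net(S)
    m <- suppressWarnings(affinity_propagation(S))
    expect_gte(mapping_net_similarity(m, S), 0.95 * opt$net)
  }
})

test_that("AP handles degenerate sizes and is deterministic", {
  S1 <- matrix(0.5, 1, 1, dimnames = list("solo", "solo"))
  m <- affinity_propagation(S1)
  expect_length(m$clusters, 1L)
  expect_equal(m$clusters[[1]]$exemplar, "solo")

  S <- matrix(c(0.2, 0.8, 0.8, 0.2), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  m1 <- affinity_propagation(S)
  m2 <- affinity_propagation(S)
  expect_identical(m1$clusters, m2$clusters)

  expect_error(affinity_propagation(matrix(numeric(), 0, 0)), "empty")
  expect_error(affinity_propagation(matrix(c(0, NA, 0, 0), 2, 2)), "finite")
  expect_error(affinity_propagation(S, damping = 0.3), "damping")
})

test_that("every mapping algorithm partitions the merged node set", {
  uni <- small_universe()
  scorer <- make_gene_scorer(uni$annotations, uni$ontology)
  q <- plant_query(uni, names(uni$references$pathways)[[1L]],
                   retention = 0.9, seed = 3)
  for (alg in c("apcluster", "greedy")) {
    aln <- align_networks(q, uni$references$pathways[[2L]], scorer,
                          fp_config(algorithm = alg))
    tagged <- c(paste0("Q:", q$nodes),
                paste0("R:", uni$references$pathways[[2L]]$nodes))
    got <- unlist(lapply(aln$mapping$clusters, `[[`, "members"))
    if (alg == "apcluster") {
      expect_setequal(got, tagged)
    } else {
      expect_setequal(got, tagged)
    }
    expect_false(anyDuplicated(got) > 0)
  }
})

test_that("greedy alignment follows global best-first order with ties", {
  q <- gene_network("q", rbind(c("a1", "a2")))
  r <- gene_network("r", rbind(c("b1", "b2")))
  sim <- manual_sim(c(0.9, 0.2, 0.8, 0.7), c("a1", "a2"), c("b1", "b2"))
  m <- greedy_align(q, r, sim, min_sim = 0.5)
  pairs <- lapply(m$clusters[1:2], `[[`, "members")
  expect_equal(pairs[[1]], c("Q:a1", "R:b1"))
  expect_equal(pairs[[2]], c("Q:a2", "R:b2"))

  # Identity case: each gene pairs with its copy.
  r2 <- gene_network("r2", q$edges)
  id_sim <- manual_sim(c(1, 0, 0, 1), c("a1", "a2"), c("a1", "a2"))
  m2 <- greedy_align(q, r2, id_sim, min_sim = 0.5)
  two <- Filter(function(cl) length(cl$members) == 2L, m2$clusters)
  for (cl in two) {
    genes <- sub("^[QR]:", "", cl$members)
    expect_equal(genes[[1]], genes[[2]])
  }

  # All sims below threshold: singletons only.
  m3 <- greedy_align(q, r, sim, min_sim = 0.95)
  expect_true(all(vapply(m3$clusters, function(cl) length(cl$members), 1L) == 1L))
})

test_that("external aligner adapter parses clusters and completes singletons", {
  w <- two_nets()
  fixture <- tempfile(fileext = ".txt")
  writeLines(c("Q:a R:x", "Q:b R:y"), fixture)
  cmd <- sprintf("cp %s {output}", fixture)
  m <- run_external_aligner(cmd, w$q, w$r)
  expect_length(m$clusters, 2L)
  expect_equal(m$algorithm, "external")

  # Omitted node becomes a singleton.
  writeLines("Q:a R:x", fixture)
  m2 <- run_external_aligner(cmd, w$q, w$r)
  singles <- Filter(function(cl) length(cl$members) == 1L, m2$clusters)
  expect_setequal(unlist(lapply(singles, `[[`, "members")),
                  c("Q:b", "R:y"))

  expect_error(run_external_aligner("false # {output}", w$q, w$r),
               class = "nfp_external_error")
  writeLines("not-a-tagged-node", fixture)
  expect_error(run_external_aligner(cmd, w$q, w$r),
               class = "nfp_format_error")
})
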