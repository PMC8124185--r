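test_that("subnetwork induction filters nodes and edge scores exactly", {
  g <- graph_from_edges(data.frame(
    from = c("a", "a", "b", "c"), to = c("b", "c", "c", "d"),
    score = c(0.9, 0.3, 0.5, 0.8)))
  expect_warning(sub <- build_subnetwork(c("x", "y"), g), "intersect")
  expect_equal(igraph::vcount(sub), 0)

  sub0 <- build_subnetwork(c("a", "b", "c"), g, score_cut = 0)
  expect_equal(igraph::ecount(sub0), 3)  # plain induced subgraph

  sub <- build_subnetwork(c("a", "b", "c"), g, score_cut = 0.4)
  expect_equal(igraph::ecount(sub), 2)   # 0.3 edge dropped

  # brute-force double-loop oracle on a random scored graph
  set.seed(41)
  nodes <- sprintf("n%02d", 1:30)
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < 0.2
  edf <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                    score = runif(sum(keep)))
  g <- graph_from_edges(edf, nodes = nodes)
  gs <- sample(nodes, 12)
  cut <- 0.35
  oracle <- sum(edf$from %in% gs & edf$to %in% gs & edf$score > cut)
  expect_equal(igraph::ecount(build_subnetwork(gs, g, cut)), oracle)
})

test_that("MCL separates disconnected components and keeps singletons", {
  cl <- mcl_cluster(two_triangles(), inflation = 2)
  expect_identical(cl$n_clusters, 2L)
  expect_identical(unname(cl$membership[c("a", "b", "c")]), rep(1L, 3))
  expect_identical(unname(cl$membership[c("x", "y", "z")]), rep(2L, 3))
  expect_true(cl$converged)
  # idempotence: re-clustering each converged cluster leaves it whole
  for (cid in 1:2) {
    members <- names(cl$membership)[cl$membership == cid]
    sub <- igraph::induced_subgraph(two_triangles(), members)
    expect_identical(mcl_cluster(sub, inflation = 2)$n_clusters, 1L)
  }

  iso <- igraph::make_empty_graph(n = 1, directed = FALSE)
  igraph::V(iso)$name <- "solo"
  cl1 <- mcl_cluster(iso, inflation = 2)
  expect_identical(cl1$n_clusters, 1L)
})

test_that("MCL output is a partition of the node set", {
  set.seed(42)
  for (i in 1:5) {
    g <- igraph::sample_gnp(25, 0.15)
    igraph::V(g)$name <- sprintf("n%02d", 1:25)
    igraph::E(g)$score <- runif(igraph::ecount(g), 0.2, 1)
    cl <- mcl_cluster(g, inflation = 2)
    expect_setequal(names(cl$membership), igraph::V(g)$name)
    expect_true(all(cl$membership >= 1 & cl$membership <= cl$n_clusters))
    expect_identical(anyDuplicated(names(cl$membership)), 0L)
  }
})

test_that("column normalization keeps the transition matrix stochastic", {
  set.seed(43)
  M <- matrix(runif(64), 8, 8)^4
  M[M < 0.01] <- 0
  N <- duomics:::normalize_columns(M)
  expect_equal(colSums(N), rep(1, 8), tolerance = 1e-9)
  # all-zero column gets a unit self-entry
  M[, 3] <- 0
  N <- duomics:::normalize_columns(M)
  expect_equal(colSums(N), rep(1, 8), tolerance = 1e-9)
  expect_equal(N[3, 3], 1)
})

test_that("clique test checks all pairs", {
  g <- graph_from_edges(data.frame(
    from = c("a", "a", "b", "p", "q", "k1", "k1", "k1", "k2", "k2"),
    to = c("b", "c", "c", "q", "r", "k2", "k3", "k4", "k3", "k4"),
    score = 1))
  expect_true(is_clique(c("a", "b", "c"), g))          # triangle
  expect_false(is_clique(c("p", "q", "r"), g))         # path of 3
  expect_false(is_clique(c("k1", "k2", "k3", "k4"), g))  # K4 minus k3-k4
  expect_true(is_clique("a", g))
  expect_error(is_clique(c("a", "zz"), g), "absent")
})

test_that("clique refinement emits a lone clique unchanged and nothing from an edgeless graph", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  igraph::E(k5)$score <- 0.9
  out <- clique_refine(k5)
  expect_length(out, 1L)
  expect_true(out[[1]]$is_clique)
  expect_setequal(out[[1]]$nodes, letters[1:5])
  expect_equal(out[[1]]$inflation, 1.5)

  edgeless <- igraph::make_empty_graph(n = 6, directed = FALSE)
  igraph::V(edgeless)$name <- letters[1:6]
  expect_length(clique_refine(edgeless), 0L)
})

test_that("two planted 4-cliques joined by a bridge are both recovered", {
  k4a <- igraph::make_full_graph(4); igraph::V(k4a)$name <- paste0("a", 1:4)
  k4b <- igraph::make_full_graph(4); igraph::V(k4b)$name <- paste0("b", 1:4)
  g <- igraph::disjoint_union(k4a, k4b)
  g <- igraph::add_edges(g, c(which(igraph::V(g)$name == "a1"),
                              which(igraph::V(g)$name == "b1")))
  igraph::E(g)$score <- 0.8
  out <- clique_refine(g, c(1.5, 2, 4, 6))
  cliques <- lapply(Filter(function(x) x$is_clique, out), `[[`, "nodes")
  expect_true(any(vapply(cliques, setequal, logical(1), paste0("a", 1:4))))
  expect_true(any(vapply(cliques, setequal, logical(1), paste0("b", 1:4))))
  # every emitted clique passes is_clique exactly
  for (cl in cliques) expect_true(is_clique(cl, g))
})

test_that("first-neighbour expansion collects the adjacency union with classes", {
  # star: clique {hub, leaf1}; hub also adjacent to leaf2
  g <- graph_from_edges(data.frame(from = c("hub", "hub"),
                                   to = c("leaf1", "leaf2"), score = 1))
  sn <- expand_first_neighbours(c("hub", "leaf1"), g,
                                node_status = c(hub = "red"))
  expect_identical(sn$neighbours, "leaf2")
  expect_identical(unname(sn$node_classes["hub"]), "red")
  expect_identical(unname(sn$node_classes["leaf2"]), "background")

  # clique with no outside edges has no neighbours
  tri <- graph_from_edges(data.frame(from = c("a", "a", "b"),
                                     to = c("b", "c", "c"), score = 1))
  expect_length(expand_first_neighbours(c("a", "b", "c"), tri)$neighbours, 0L)

  expect_error(expand_first_neighbours(c("a", "nope"), tri), "nope")

  # adjacency-union oracle on a synthetic planted module with decoys
  set.seed(44)
  cfg <- synthetic_config(n_genes = 120, background_edge_prob = 0.03,
                          seed = 44)
  b <- generate_omics_dataset(cfg)
  net <- generate_background_network(cfg, b$truth)
  tr <- net$truth
  clique1 <- tr$gene_id[!is.na(tr$clique_id) & tr$clique_id == 1]
  sn <- expand_first_neighbours(clique1, net$network)
  adj <- igraph::as_data_frame(net$network, what = "edges")
  oracle <- setdiff(unique(c(adj$to[adj$from %in% clique1],
                             adj$from[adj$to %in% clique1])), clique1)
  expect_setequal(sn$neighbours, oracle)
})
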