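# Network deconstruction/reconstruction: scored subnetworks, Markov
# clustering (MCL), clique refinement and first-neighbour expansion.
#
# Graphs are igraph objects whose edges carry a `score` attribute in (0,1].

#' Build a scored induced subnetwork
#'
#' Induces the subgraph of `background` on the intersection of `gene_set`
#' with its nodes, keeping only edges whose score exceeds `score_cut`.
#' The default cut of 0.4 is the conventional "medium confidence" level for
#' functional-interaction scores.
#'
#' @param gene_set Character vector of node names.
#' @param background igraph graph with an edge attribute `score`.
#' @param score_cut Edges with score strictly above this are kept.
#' @return The induced igraph subgraph (possibly empty, with a warning).
#' @export
build_subnetwork <- function(gene_set, background, score_cut = 0.4) {
  stopifnot(igraph::is_igraph(background),
            is.numeric(score_cut), score_cut >= 0, score_cut < 1)
  keep <- intersect(gene_set, igraph::V(background)$name)
  if (!length(keep)) {
    warning("gene set does not intersect the background network")
    return(igraph::make_empty_graph(directed = FALSE))
  }
  g <- igraph::induced_subgraph(background, keep)
  if (igraph::ecount(g)) {
    sc <- igraph::E(g)$score
    if (is.null(sc)) sc <- rep(1, igraph::ecount(g))
    g <- igraph::delete_edges(g, which(!(sc > score_cut)))
  }
  g
}

# Column-normalize a non-negative matrix; all-zero columns get a 1 on the
# diagonal so the matrix stays column-stochastic.
normalize_columns <- function(M) {
  cs <- colSums(M)
  zero <- cs == 0
  if (any(zero)) {
    M[cbind(which(zero), which(zero))] <- 1
    cs[zero] <- 1
  }
  sweep(M, 2L, cs, `/`)
}

#' Markov clustering (MCL) of a scored graph
#'
#' Runs the Markov cluster algorithm on the scored adjacency matrix:
#' self-loops are added with weight equal to the node's maximum incident
#' edge score (1 for isolated nodes), columns are normalized to a
#' column-stochastic transition matrix, and expansion (matrix power) is
#' alternated with inflation (element-wise power followed by column
#' renormalization) and pruning of entries below `prune_threshold`, until
#' the matrix changes by less than `convergence_tol` or `max_iters` is
#' reached. Clusters are read from the attractor rows of the limit matrix;
#' a node attracted by several attractor systems is assigned to the one
#' containing the lexicographically smallest node name, so the output is a
#' deterministic partition.
#'
#' @param g igraph graph (edge attribute `score` optional; unscored edges
#'   count as 1).
#' @param inflation Inflation exponent, > 1 for non-trivial granularity.
#' @param expansion Integer expansion power (default 2).
#' @param prune_threshold Entries below this are zeroed each iteration.
#' @param max_iters Iteration cap; non-convergence is returned with a flag.
#' @param convergence_tol Maximum absolute change defining convergence.
#' @return A list with `membership` (named integer vector over nodes),
#'   `n_clusters`, `iterations` and `converged`.
#' @export
mcl_cluster <- function(g, inflation = 2, expansion = 2L,
                        prune_threshold = 1e-5, max_iters = 100L,
                        convergence_tol = 1e-8) {
  stopifnot(igraph::is_igraph(g), inflation > 1, expansion >= 2L)
  n <- igraph::vcount(g)
  if (n == 0L) stop("cannot cluster an empty graph")
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  if (igraph::ecount(g) && is.null(igraph::E(g)$score))
    igraph::E(g)$score <- 1
  A <- igraph::as_adjacency_matrix(g, attr = if (igraph::ecount(g)) "score" else NULL,
                                   sparse = FALSE)
  A <- (A + t(A)) / 2  # symmetrize defensively
  loop <- apply(A, 1L, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- normalize_columns(A)

  converged <- FALSE
  iter <- 0L
  while (iter < max_iters) {
    iter <- iter + 1L
    Mexp <- M
    for (k in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf[Minf < prune_threshold] <- 0
    Mnew <- normalize_columns(Minf)
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < convergence_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iters, " iterations")

  # attractor rows: any positive mass on their own column or elsewhere
  eps <- sqrt(.Machine$double.eps)
  support <- M > eps
  attractors <- which(rowSums(support) > 0L)
  membership <- integer(n)
  cluster_key <- rep(NA_character_, n)
  for (j in seq_len(n)) {
    rows <- attractors[support[attractors, j]]
    members <- if (length(rows)) rows else j
    cluster_key[j] <- min(nodes[members])
  }
  keys <- sort(unique(cluster_key))
  membership <- match(cluster_key, keys)
  names(membership) <- nodes
  list(membership = membership,
       n_clusters = length(keys),
       iterations = iter,
       converged = converged)
}

#' Test whether a node set is a clique
#'
#' @param node_set Character vector of node names (must exist in `g`).
#' @param g igraph graph.
#' @return `TRUE` iff every pair of nodes in the set is connected by an
#'   edge; singletons and connected pairs are cliques.
#' @export
is_clique <- function(node_set, g) {
  stopifnot(igraph::is_igraph(g))
  node_set <- unique(node_set)
  if (!all(node_set %in% igraph::V(g)$name))
    stop("node set contains nodes absent from the graph")
  k <- length(node_set)
  if (k <= 1L) return(TRUE)
  sub <- igraph::induced_subgraph(g, node_set)
  sub <- igraph::simplify(sub)
  igraph::ecount(sub) == choose(k, 2)
}

# Greedy deterministic extension of a clique to a maximal clique: nodes
# adjacent to every current member are added one at a time in name order.
expand_maximal_clique <- function(members, g) {
  repeat {
    nb <- lapply(members, function(x)
      igraph::V(g)$name[as.integer(igraph::neighbors(g, x))])
    common <- setdiff(Reduce(intersect, nb), members)
    if (!length(common)) break
    members <- sort(c(members, sort(common)[1L]))
  }
  members
}

# Peel a cluster down to a clique core: repeatedly drop the member with the
# lowest within-cluster score strength (ties by name) until the remainder
# is a clique. NULL when no core of at least min_size exists.
trim_to_clique_core <- function(nodes, g, min_size) {
  members <- sort(nodes)
  while (length(members) > min_size && !is_clique(members, g)) {
    sub <- igraph::induced_subgraph(g, members)
    st <- igraph::strength(sub, weights = igraph::E(sub)$score)
    weakest <- sort(names(st)[st == min(st)])[1L]
    members <- setdiff(members, weakest)
  }
  if (!is_clique(members, g) || length(members) < min_size) return(NULL)
  members
}

#' Deconstruct a graph into functional cliques by iterated MCL
#'
#' Progressively deconstructs a scored network into cliques ("clusters in
#' which every node is connected to every other node"). The graph is first
#' clustered with [mcl_cluster()] at the lowest inflation of the schedule.
#' Clusters that are cliques are emitted. A non-clique cluster is
#' re-clustered at the next inflation value; that split is accepted only
#' while it is productive, i.e. while it yields at least two parts of
#' viable size -- Markov clustering cannot detach a weakly-attached
#' satellite node from a clique at any inflation (a pendant's random walk
#' always returns to the clique), and past the cluster's natural
#' granularity higher inflation merely shatters it. When the sweep stops
#' being productive (or the schedule is exhausted), the cluster is either
#' emitted flagged non-clique (`trim = FALSE`, the raw behaviour) or, by
#' default, reduced to its clique core by deterministic peeling of the
#' weakest-connected member. Emitted cliques are extended to maximal
#' cliques when `trim = TRUE`, so a member separated by an earlier split is
#' recovered. Cliques smaller than `min_size` are discarded.
#'
#' @param g igraph graph with edge scores.
#' @param inflation_schedule Ascending inflation values (default
#'   `c(1.5, 2, 4, 6)`).
#' @param min_size Minimum clique size to report (default 3).
#' @param trim Trim stalled non-clique clusters to their clique core and
#'   maximalize emitted cliques (default `TRUE`).
#' @param ... Further arguments to [mcl_cluster()].
#' @return A list of records, each with `nodes`, `is_clique`, `inflation`
#'   (the schedule value at which the cluster was resolved) and `trimmed`.
#' @export
clique_refine <- function(g, inflation_schedule = c(1.5, 2, 4, 6),
                          min_size = 3L, trim = TRUE, ...) {
  stopifnot(igraph::is_igraph(g), length(inflation_schedule) >= 1L,
            !is.unsorted(inflation_schedule), min_size >= 1L)
  out <- list()
  schedule <- inflation_schedule

  emit <- function(nodes, infl, trimmed = FALSE) {
    nodes <- sort(nodes)
    if (trim) nodes <- expand_maximal_clique(nodes, g)
    out[[length(out) + 1L]] <<-
      list(nodes = nodes, is_clique = TRUE, inflation = infl,
           trimmed = trimmed)
  }
  finish <- function(nodes, infl) {
    if (trim) {
      core <- trim_to_clique_core(nodes, g, min_size)
      if (!is.null(core)) return(emit(core, infl, trimmed = TRUE))
    }
    out[[length(out) + 1L]] <<-
      list(nodes = sort(nodes), is_clique = FALSE, inflation = infl,
           trimmed = FALSE)
  }
  parts_of <- function(nodes, infl) {
    cl <- mcl_cluster(igraph::induced_subgraph(g, nodes),
                      inflation = infl, ...)
    unname(split(names(cl$membership), cl$membership))
  }
  handle_parts <- function(parts, level) {
    for (p in parts) {
      if (length(p) < min_size) next
      if (is_clique(p, g)) emit(p, schedule[level])
      else step(p, level + 1L)
    }
  }
  step <- function(nodes, level) {
    if (level > length(schedule))
      return(finish(nodes, schedule[length(schedule)]))
    parts <- parts_of(nodes, schedule[level])
    substantial <- sum(vapply(parts, length, integer(1L)) >= min_size)
    if (substantial >= 2L) handle_parts(parts, level)
    else if (substantial == 1L && length(parts) == 1L &&
             is_clique(parts[[1L]], g))
      emit(parts[[1L]], schedule[level])
    else if (level == 1L) handle_parts(parts, level)
    else finish(nodes, schedule[level - 1L])
  }

  if (igraph::vcount(g) >= min_size)
    handle_parts(parts_of(igraph::V(g)$name, schedule[1L]), 1L)
  out
}

#' Expand a clique to its first neighbours in a background network
#'
#' Reintroduces a clique into the full background network and collects the
#' union of its members' direct neighbours (excluding the clique itself),
#' together with the induced edge set over clique plus neighbours and a
#' display class per node (`red`/`grey`/`green`/`background`, see
#' [assign_groups()]).
#'
#' @param clique Character vector of clique node names; all must exist in
#'   the background network.
#' @param background igraph graph with edge scores.
#' @param node_status Optional named character vector mapping node names to
#'   display classes; unmapped nodes get `"background"`.
#' @return An object of class `"CliqueSubnetwork"`: a list with `clique`,
#'   `neighbours`, `edges` (data.frame `from`/`to`/`score`) and
#'   `node_classes` (named character vector over clique plus neighbours).
#' @export
expand_first_neighbours <- function(clique, background, node_status = NULL) {
  stopifnot(igraph::is_igraph(background), length(clique) >= 1L)
  missing <- setdiff(clique, igraph::V(background)$name)
  if (length(missing))
    stop("clique node(s) absent from background network: ",
         paste(missing, collapse = ", "))
  nb <- unique(unlist(lapply(
    igraph::adjacent_vertices(background, clique),
    function(v) igraph::V(background)$name[as.integer(v)])))
  neighbours <- sort(setdiff(nb, clique))
  all_nodes <- c(sort(unique(clique)), neighbours)
  sub <- igraph::induced_subgraph(background, all_nodes)
  edges <- igraph::as_data_frame(sub, what = "edges")
  if (!"score" %in% names(edges)) edges$score <- rep(1, nrow(edges))
  edges <- edges[, c("from", "to", "score"), drop = FALSE]
  classes <- rep("background", length(all_nodes))
  names(classes) <- all_nodes
  if (!is.null(node_status)) {
    hit <- intersect(all_nodes, names(node_status))
    classes[hit] <- unname(node_status[hit])
  }
  structure(list(clique = sort(unique(clique)),
                 neighbours = neighbours,
                 edges = edges,
                 node_classes = classes),
            class = "CliqueSubnetwork")
}

#' @export
print.CliqueSubnetwork <- function(x, ...) {
  cat(sprintf("CliqueSubnetwork: clique of %d, %d first neighbours, %d edges\n",
              length(x$clique), length(x$neighbours), nrow(x$edges)))
  cat("  clique:", paste(x$clique, collapse = ", "), "\n")
  invisible(x)
}
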