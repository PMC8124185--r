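# Right-sided hypergeometric term enrichment with Holm (Bonferroni
# step-down) correction and kappa-score term grouping.

#' Right tail of the hypergeometric distribution
#'
#' Probability of observing at least `k` annotated genes in a query of size
#' `n` drawn without replacement from a universe of `N` genes of which `K`
#' carry the annotation: \eqn{P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeom}(N, K, n)}.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K Term size.
#' @param n Query size.
#' @param N Universe size (K, n <= N).
#' @return The right-tail probability; exactly 1 when `k = 0`.
#' @export
hypergeom_right_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric counts")
  if (k == 0) return(1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Term over-representation analysis
#'
#' Right-sided hypergeometric test of each term against a query gene list,
#' with Bonferroni step-down (Holm) adjustment across the tested terms.
#' Terms with no overlap with the query are skipped before correction, so
#' the correction multiplicity is the number of terms actually tested.
#'
#' @param query_genes Character vector of query gene IDs (subset of
#'   `universe`).
#' @param terms Named list of character vectors (term ID -> gene IDs), as
#'   returned by [read_gmt()]. Genes outside the universe are ignored.
#' @param universe Character vector of background gene IDs.
#' @param alpha Significance level on the adjusted p-value.
#' @param p_adjust Adjustment method (default `"holm"`).
#' @return data.frame with one row per tested term: `term_id`, `k`, `K`,
#'   `n`, `N`, `p_raw`, `p_adj`, `significant`, sorted by `p_adj` then
#'   `p_raw`.
#' @export
enrich_terms <- function(query_genes, terms, universe, alpha = 0.05,
                         p_adjust = "holm") {
  stopifnot(is.list(terms), !is.null(names(terms)), length(universe) >= 1L)
  query_genes <- unique(query_genes)
  if (!length(query_genes)) stop("empty query gene list")
  extra <- setdiff(query_genes, universe)
  if (length(extra))
    stop("query genes outside the universe: ", paste(utils::head(extra, 3L),
                                                     collapse = ", "))
  universe <- unique(universe)
  N <- length(universe)
  n <- length(query_genes)
  rows <- lapply(names(terms), function(id) {
    tg <- intersect(unique(terms[[id]]), universe)
    K <- length(tg)
    k <- length(intersect(tg, query_genes))
    if (k == 0L || K == 0L) return(NULL)
    data.frame(term_id = id, k = k, K = K, n = n, N = N,
               p_raw = hypergeom_right_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_raw = numeric())
  out$p_adj <- if (nrow(out)) stats::p.adjust(out$p_raw, method = p_adjust)
               else numeric()
  out$significant <- out$p_adj <= alpha
  out <- out[order(out$p_adj, out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohen's kappa between two terms' gene memberships
#'
#' Agreement between the binary membership vectors of two terms over a gene
#' universe: \eqn{\kappa = (p_o - p_e) / (1 - p_e)}, where \eqn{p_o} is the
#' observed co-classification rate and \eqn{p_e} the rate expected if the
#' memberships were independent.
#'
#' @param term_a,term_b Character vectors of gene IDs (non-empty subsets of
#'   `universe`).
#' @param universe Character vector of background gene IDs.
#' @return Kappa in \[-1, 1\]; 1 for identical terms.
#' @export
kappa_score <- function(term_a, term_b, universe) {
  universe <- unique(universe)
  a <- universe %in% term_a
  b <- universe %in% term_b
  if (!any(a) || !any(b))
    stop("both terms must be non-empty subsets of the universe")
  N <- length(universe)
  po <- mean(a == b)
  pa <- mean(a); pb <- mean(b)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (pe >= 1) {
    if (identical(a, b)) return(1)
    stop("degenerate kappa: expected agreement is 1 for non-identical terms")
  }
  (po - pe) / (1 - pe)
}

#' Group redundant terms by kappa score
#'
#' Builds a term graph connecting pairs whose kappa score meets
#' `kappa_threshold` and takes connected components as term groups. Within
#' each group the leading term is the one with the smallest adjusted
#' p-value (ties broken by larger term size, then term ID).
#'
#' @param results Enrichment table from [enrich_terms()].
#' @param terms The term list used for the enrichment.
#' @param universe The gene universe used for the enrichment.
#' @param kappa_threshold Minimum kappa connecting two terms (default 0.4,
#'   the conventional cut for term-grouping).
#' @return `results` with `group_id` (integer) and `is_leading` columns.
#' @export
group_terms <- function(results, terms, universe, kappa_threshold = 0.4) {
  stopifnot(is.data.frame(results), "term_id" %in% names(results))
  ids <- results$term_id
  m <- length(ids)
  out <- results
  if (m == 0L) {
    out$group_id <- integer()
    out$is_leading <- logical()
    return(out)
  }
  edges <- NULL
  if (m >= 2L) {
    pairs <- utils::combn(m, 2L)
    kap <- apply(pairs, 2L, function(ij) {
      kappa_score(terms[[ids[ij[1L]]]], terms[[ids[ij[2L]]]], universe)
    })
    sel <- kap >= kappa_threshold
    if (any(sel)) edges <- pairs[, sel, drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, as.vector(edges))
  comp <- igraph::components(g)$membership
  out$group_id <- comp
  out$is_leading <- FALSE
  for (grp in unique(comp)) {
    idx <- which(comp == grp)
    ord <- idx[order(out$p_adj[idx], -out$K[idx], out$term_id[idx])]
    out$is_leading[ord[1L]] <- TRUE
  }
  out
}
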