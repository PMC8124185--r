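# Synthetic-data generators: every pipeline input with planted structure
# (differential expression groups, uORF carriers, network cliques, enriched
# annotation terms), fully reproducible from one seed.

#' Configuration of the synthetic dataset
#'
#' Collects the study-design parameters of the synthetic two-layer dataset.
#' Defaults emulate a microarray-plus-TMT screen: five replicates per arm,
#' protein coverage of roughly a third of the gene universe, a log2-scale
#' baseline with mean 8 and SD 2 (a typical microarray dynamic range), and
#' a 43% uORF-carrier frequency.
#'
#' @param n_genes Number of genes.
#' @param n_reps_per_condition Replicates per condition (default 5).
#' @param protein_coverage Fraction of genes quantified at the protein
#'   layer, in (0, 1] (default 0.37).
#' @param frac_group1,frac_group2,frac_group3 Planted fractions of
#'   concordance groups (up/up, up/unchanged, down/down); must sum to < 1,
#'   the remainder being null genes.
#' @param effect_log2fc_mean Planted effect size on the log2 scale
#'   (default 2).
#' @param noise_sd Replicate noise SD on the log2 scale (default 0.25).
#' @param baseline_log2_mean,baseline_log2_sd Baseline abundance
#'   distribution on the log2 scale (defaults 8 and 2).
#' @param uorf_carrier_freq Fraction of genes carrying at least one uORF
#'   (default 0.43).
#' @param utr_length 5'UTR length in nt (default 150).
#' @param n_clique_modules Number of planted network cliques (default 3).
#' @param clique_size_range Min/max clique size (default `c(4, 6)`).
#' @param background_edge_prob Bernoulli probability of a background edge
#'   between two non-clique-mate genes (default 0.01).
#' @param n_terms Number of annotation term sets (default 20).
#' @param term_size_range Min/max term size (default `c(20, 50)`).
#' @param seed Global seed; each generator derives its own child seed.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_genes,
                             n_reps_per_condition = 5L,
                             protein_coverage = 0.37,
                             frac_group1 = 0.02,
                             frac_group2 = 0.05,
                             frac_group3 = 0.03,
                             effect_log2fc_mean = 2,
                             noise_sd = 0.25,
                             baseline_log2_mean = 8,
                             baseline_log2_sd = 2,
                             uorf_carrier_freq = 0.43,
                             utr_length = 150L,
                             n_clique_modules = 3L,
                             clique_size_range = c(4L, 6L),
                             background_edge_prob = 0.01,
                             n_terms = 20L,
                             term_size_range = c(20L, 50L),
                             seed = 1L) {
  stopifnot(n_genes >= 1L, n_reps_per_condition >= 2L,
            noise_sd > 0, baseline_log2_sd > 0, utr_length >= 9L,
            n_clique_modules >= 0L, length(clique_size_range) == 2L,
            clique_size_range[1L] >= 3L,
            clique_size_range[1L] <= clique_size_range[2L],
            n_terms >= 1L, length(term_size_range) == 2L,
            term_size_range[1L] >= 1L,
            term_size_range[2L] <= n_genes)
  check_fraction(protein_coverage, "protein_coverage")
  for (nm in c("frac_group1", "frac_group2", "frac_group3"))
    check_fraction(get(nm), nm, allow_zero = TRUE)
  if (frac_group1 + frac_group2 + frac_group3 >= 1)
    stop("group fractions must sum to < 1 (the remainder is null genes)")
  check_fraction(uorf_carrier_freq, "uorf_carrier_freq", allow_zero = TRUE)
  check_fraction(background_edge_prob, "background_edge_prob",
                 allow_zero = TRUE)
  if (round(protein_coverage * n_genes) < 1)
    stop("protein_coverage x n_genes must be at least 1")
  structure(list(n_genes = as.integer(n_genes),
                 n_reps_per_condition = as.integer(n_reps_per_condition),
                 protein_coverage = protein_coverage,
                 frac_group1 = frac_group1,
                 frac_group2 = frac_group2,
                 frac_group3 = frac_group3,
                 effect_log2fc_mean = effect_log2fc_mean,
                 noise_sd = noise_sd,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 uorf_carrier_freq = uorf_carrier_freq,
                 utr_length = as.integer(utr_length),
                 n_clique_modules = as.integer(n_clique_modules),
                 clique_size_range = as.integer(clique_size_range),
                 background_edge_prob = background_edge_prob,
                 n_terms = as.integer(n_terms),
                 term_size_range = as.integer(term_size_range),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate the two-layer abundance matrices and the truth table
#'
#' Draws per-gene log2 baselines from a normal distribution, plants
#' direction-consistent effects for the three concordance groups (group 1
#' up at both layers, group 2 up at the transcript layer only, group 3 down
#' at both), adds replicate noise, and returns raw-scale (log-normal)
#' matrices. The protein layer covers `round(protein_coverage * n_genes)`
#' genes: every planted-group gene (the concordance-group definitions
#' presuppose a quantified protein) topped up with a random draw of null
#' genes; its baseline is the gene's
#' transcript baseline plus independent noise, so the two layers share
#' abundance structure without being copies.
#'
#' @param config A [synthetic_config()].
#' @return A list with `transcript` and `protein` ([expression_matrix()]s of
#'   raw abundances), `id_map` (transcript_id/protein_id/gene_id, protein
#'   `NA` for uncovered genes) and `truth` (data.frame `gene_id`, `group`,
#'   `de_transcript`, `de_protein`).
#' @export
generate_omics_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(child_seed(config$seed, 1L))
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  n1 <- round(config$frac_group1 * n)
  n2 <- round(config$frac_group2 * n)
  n3 <- round(config$frac_group3 * n)
  shuffled <- sample(genes)
  group <- rep("none", n)
  names(group) <- shuffled
  if (n1) group[seq_len(n1)] <- "1"
  if (n2) group[n1 + seq_len(n2)] <- "2"
  if (n3) group[n1 + n2 + seq_len(n3)] <- "3"
  group <- group[genes]  # back to canonical order

  de_tx <- c("1" = "up", "2" = "up", "3" = "down", "none" = "ns")[group]
  de_pr <- c("1" = "up", "2" = "ns", "3" = "down", "none" = "ns")[group]
  eff <- config$effect_log2fc_mean
  tx_effect <- c(up = eff, down = -eff, ns = 0)[de_tx]
  pr_effect <- c(up = eff, down = -eff, ns = 0)[de_pr]

  reps <- config$n_reps_per_condition
  samples <- c(paste0("control_", seq_len(reps)),
               paste0("treated_", seq_len(reps)))
  condition <- rep(c("control", "treated"), each = reps)
  treated <- condition == "treated"

  baseline <- stats::rnorm(n, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  tx_log2 <- matrix(baseline, n, 2L * reps) +
    outer(tx_effect, as.numeric(treated)) +
    matrix(stats::rnorm(n * 2L * reps, 0, config$noise_sd), n, 2L * reps)
  tx_ids <- paste0("tx_", genes)
  dimnames(tx_log2) <- list(tx_ids, samples)
  transcript <- expression_matrix(2^tx_log2, condition)

  # the protein layer must quantify every planted-group gene (the group
  # definitions presuppose a measured protein); coverage is topped up to
  # n_prot with a random draw from the null genes
  n_prot <- round(config$protein_coverage * n)
  grouped <- which(group != "none")
  if (length(grouped) > n_prot)
    stop("protein_coverage too small to quantify all planted-group genes; ",
         "need frac_group1+frac_group2+frac_group3 <= protein_coverage")
  covered <- sort(c(grouped,
                    sample(setdiff(seq_len(n), grouped),
                           n_prot - length(grouped))))
  pr_base <- baseline[covered] + stats::rnorm(n_prot, 0, 1)
  pr_log2 <- matrix(pr_base, n_prot, 2L * reps) +
    outer(pr_effect[covered], as.numeric(treated)) +
    matrix(stats::rnorm(n_prot * 2L * reps, 0, config$noise_sd),
           n_prot, 2L * reps)
  pr_ids <- paste0("pr_", genes[covered])
  dimnames(pr_log2) <- list(pr_ids, samples)
  protein <- expression_matrix(2^pr_log2, condition)

  de_pr_truth <- de_pr
  de_pr_truth[-covered] <- "unmeasured"
  id_map <- data.frame(transcript_id = tx_ids,
                       protein_id = NA_character_,
                       gene_id = genes, stringsAsFactors = FALSE)
  id_map$protein_id[covered] <- pr_ids
  truth <- data.frame(gene_id = genes,
                      group = unname(group),
                      de_transcript = unname(de_tx),
                      de_protein = unname(de_pr_truth),
                      stringsAsFactors = FALSE)
  list(transcript = transcript, protein = protein,
       id_map = id_map, truth = truth)
}

# Uniform integer draw from [lo, hi] that is safe when lo == hi (sample()
# would otherwise interpret a scalar as a range).
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n) else sample(seq(lo, hi), n,
                                                   replace = TRUE)
}

# Random sequence guaranteed to contain no "ATG": letters are drawn
# uniformly, then every occurrence of ATG has its G resampled from {A,C,T}
# until none remains (converges in a handful of passes).
random_aug_free <- function(len) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  for (pass in 1:100) {
    s <- paste(chars, collapse = "")
    hits <- gregexpr("ATG", s, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) return(s)
    chars[hits + 2L] <- sample(c("A", "C", "T"), length(hits), replace = TRUE)
  }
  stop("failed to construct an AUG-free sequence")  # practically unreachable
}

#' Generate 5'UTR sequences with a planted uORF-carrier frequency
#'
#' Builds one 5'UTR per gene. Each gene is independently flagged as a uORF
#' carrier with probability `uorf_carrier_freq`; carriers receive an
#' AUG-free background with an embedded AUG...stop cassette (AUG, 0-3
#' random non-stop codons, then a stop codon) at a random in-sequence
#' position, while non-carriers are AUG-free throughout and therefore
#' scanner-negative by construction.
#'
#' @param config A [synthetic_config()].
#' @param truth Truth table from [generate_omics_dataset()].
#' @return A list with `utrs` (named character vector keyed by transcript
#'   ID) and `truth` (input truth with `uorf_carrier` added).
#' @export
generate_utr_set <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"), is.data.frame(truth))
  set.seed(child_seed(config$seed, 2L))
  len <- config$utr_length
  max_cassette <- 3L + 3L * 3L + 3L  # AUG + up to 3 codons + stop
  if (len < max_cassette + 2L)
    stop("utr_length too short to embed a uORF cassette")
  b <- c("A", "C", "G", "T")
  non_stop <- setdiff(as.vector(outer(b, as.vector(outer(b, b, paste0)),
                                      paste0)), STOP_CODONS)
  carriers <- stats::runif(nrow(truth)) < config$uorf_carrier_freq
  utrs <- vapply(seq_len(nrow(truth)), function(i) {
    base <- random_aug_free(len)
    if (!carriers[i]) return(base)
    n_mid <- sample(0:3, 1L)
    cassette <- paste0("ATG",
                       paste(sample(non_stop, n_mid, replace = TRUE),
                             collapse = ""),
                       sample(STOP_CODONS, 1L))
    pos <- sample.int(len - nchar(cassette) + 1L, 1L)
    paste0(substr(base, 1L, pos - 1L), cassette,
           substr(base, pos + nchar(cassette), len))
  }, character(1L))
  names(utrs) <- paste0("tx_", truth$gene_id)
  truth$uorf_carrier <- carriers
  list(utrs = utrs, truth = truth)
}

#' Generate a background interaction network with planted cliques
#'
#' Creates a scored graph over all genes: `n_clique_modules` disjoint
#' complete subgraphs are planted (members drawn preferentially from
#' group-2 genes, the group whose network structure the downstream clique
#' analysis targets), with high edge scores, and every remaining gene pair
#' receives an edge independently with probability `background_edge_prob`
#' and a lower score. All scores lie in (0, 1].
#'
#' @param config A [synthetic_config()].
#' @param truth Truth table (used for group membership).
#' @return A list with `network` (igraph with edge attribute `score`) and
#'   `truth` (input truth with `clique_id` added, `NA` for non-members).
#' @export
generate_background_network <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"), is.data.frame(truth))
  set.seed(child_seed(config$seed, 3L))
  genes <- truth$gene_id
  n <- length(genes)
  sizes <- if (config$n_clique_modules)
    sample_range(config$clique_size_range[1L], config$clique_size_range[2L],
                 config$n_clique_modules) else integer()
  need <- sum(sizes)
  pool <- genes[truth$group == "2"]
  if (length(pool) < need)
    pool <- c(pool, sample(setdiff(genes, pool), need - length(pool)))
  members <- if (need) sample(pool, need) else character()
  clique_id <- rep(NA_integer_, n)
  names(clique_id) <- genes
  edges <- list()
  offset <- 0L
  for (m in seq_along(sizes)) {
    nodes <- members[offset + seq_len(sizes[m])]
    offset <- offset + sizes[m]
    clique_id[nodes] <- m
    pairs <- t(utils::combn(sort(nodes), 2L))
    edges[[length(edges) + 1L]] <-
      data.frame(from = pairs[, 1L], to = pairs[, 2L],
                 score = stats::runif(nrow(pairs), 0.6, 1),
                 stringsAsFactors = FALSE)
  }
  # background edges over pairs not inside one planted clique
  if (config$background_edge_prob > 0 && n >= 2L) {
    n_pairs <- choose(n, 2)
    m_bg <- stats::rbinom(1L, n_pairs, config$background_edge_prob)
    seen <- character()
    picked <- 0L
    bg_from <- bg_to <- character(m_bg)
    guard <- 0L
    while (picked < m_bg && guard < 50L) {
      guard <- guard + 1L
      k <- (m_bg - picked) * 2L
      i <- sample.int(n, k, replace = TRUE)
      j <- sample.int(n, k, replace = TRUE)
      ok <- i < j
      i <- i[ok]; j <- j[ok]
      key <- paste(i, j)
      fresh <- !duplicated(key) & !(key %in% seen)
      i <- i[fresh]; j <- j[fresh]; key <- key[fresh]
      same_clique <- !is.na(clique_id[i]) & !is.na(clique_id[j]) &
        clique_id[i] == clique_id[j]
      same_clique[is.na(same_clique)] <- FALSE
      i <- i[!same_clique]; j <- j[!same_clique]; key <- key[!same_clique]
      take <- seq_len(min(length(i), m_bg - picked))
      bg_from[picked + take] <- genes[i[take]]
      bg_to[picked + take] <- genes[j[take]]
      seen <- c(seen, key[take])
      picked <- picked + length(take)
    }
    if (picked)
      edges[[length(edges) + 1L]] <-
        data.frame(from = bg_from[seq_len(picked)],
                   to = bg_to[seq_len(picked)],
                   score = stats::runif(picked, 0.15, 0.95),
                   stringsAsFactors = FALSE)
  }
  edf <- if (length(edges)) do.call(rbind, edges)
         else data.frame(from = character(), to = character(),
                         score = numeric())
  g <- igraph::graph_from_data_frame(
    edf, directed = FALSE,
    vertices = data.frame(name = genes, stringsAsFactors = FALSE))
  g <- igraph::simplify(g, edge.attr.comb = "max")
  truth$clique_id <- unname(clique_id)
  list(network = g, truth = truth)
}

#' Generate annotation term sets with planted over-representation
#'
#' Creates `n_terms` gene sets. A designated fraction of terms is
#' "enriched": those draw `enriched_member_frac` of their members from the
#' genes of `enriched_group` (cycling through planted groups when the group
#' is too small) and the rest uniformly; all other terms sample the whole
#' universe uniformly.
#'
#' @param config A [synthetic_config()].
#' @param truth Truth table (used for group membership).
#' @param n_enriched_terms Number of enriched terms (default 1/5 of
#'   `n_terms`, at least 1).
#' @param enriched_group Planted group the enriched terms oversample
#'   (default `"2"`).
#' @param enriched_member_frac Fraction of an enriched term drawn from the
#'   target group (default 0.8).
#' @return A list with `terms` (named list of gene ID vectors), `term_info`
#'   (data.frame `term_id`, `size`, `enriched`) and `truth` (input truth
#'   with `enriched_terms`, a semicolon-joined list of the enriched terms
#'   containing each gene).
#' @export
generate_annotation_sets <- function(config, truth,
                                     n_enriched_terms = NULL,
                                     enriched_group = "2",
                                     enriched_member_frac = 0.8) {
  stopifnot(inherits(config, "synthetic_config"), is.data.frame(truth))
  set.seed(child_seed(config$seed, 4L))
  if (is.null(n_enriched_terms))
    n_enriched_terms <- max(1L, round(config$n_terms / 5))
  stopifnot(n_enriched_terms <= config$n_terms)
  genes <- truth$gene_id
  target <- genes[truth$group == enriched_group]
  sizes <- sample_range(config$term_size_range[1L],
                        config$term_size_range[2L], config$n_terms)
  enriched <- seq_len(config$n_terms) <= n_enriched_terms
  terms <- vector("list", config$n_terms)
  ids <- sprintf("term_%03d", seq_len(config$n_terms))
  names(terms) <- ids
  for (t in seq_len(config$n_terms)) {
    if (enriched[t] && length(target)) {
      k_in <- min(length(target), round(enriched_member_frac * sizes[t]))
      inside <- sample(target, k_in)
      outside <- sample(setdiff(genes, inside), sizes[t] - k_in)
      terms[[t]] <- sort(c(inside, outside))
    } else {
      terms[[t]] <- sort(sample(genes, sizes[t]))
    }
  }
  term_info <- data.frame(term_id = ids, size = sizes, enriched = enriched,
                          stringsAsFactors = FALSE)
  membership <- vapply(genes, function(g) {
    paste(ids[enriched][vapply(terms[enriched],
                               function(tg) g %in% tg, logical(1L))],
          collapse = ";")
  }, character(1L))
  truth$enriched_terms <- unname(membership)
  list(terms = terms, term_info = term_info, truth = truth)
}

#' Generate the complete synthetic input bundle
#'
#' Convenience wrapper running all four generators in sequence on one
#' configuration, sharing a single incrementally-extended truth table.
#'
#' @param config A [synthetic_config()].
#' @return A list with `transcript`, `protein`, `id_map`, `utrs`, `network`,
#'   `terms`, `term_info` and the final `truth`.
#' @export
generate_all <- function(config) {
  omics <- generate_omics_dataset(config)
  utr <- generate_utr_set(config, omics$truth)
  net <- generate_background_network(config, utr$truth)
  ann <- generate_annotation_sets(config, net$truth)
  list(transcript = omics$transcript, protein = omics$protein,
       id_map = omics$id_map, utrs = utr$utrs, network = net$network,
       terms = ann$terms, term_info = ann$term_info, truth = ann$truth)
}
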