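# uORF detection in 5'UTR sequences, per-gene features, Monte-Carlo
# carrier-enrichment test and rank-sum feature comparisons.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find upstream open reading frames in a 5'UTR
#'
#' Scans a 5'UTR sequence for uORFs: an AUG start codon followed, in frame,
#' by the first stop codon (UAA/UAG/UGA), both lying entirely inside the
#' UTR. Every AUG is scanned independently, so overlapping uORFs from
#' distinct AUGs are all reported; an AUG with no in-frame stop before the
#' UTR boundary yields nothing. Codons containing `N` never match either the
#' start or a stop. `U` is accepted as a synonym of `T` and case is ignored.
#'
#' @param utr_sequence A single nucleotide string over `A C G T/U N`.
#' @param min_length Minimum uORF length in nt (start through stop); the
#'   default 6 is the bare AUG+stop cassette.
#' @return data.frame with columns `start` (0-based offset of the AUG),
#'   `end` (exclusive offset just past the stop), `length` (`end - start`,
#'   a multiple of 3).
#' @export
find_uorfs <- function(utr_sequence, min_length = 6L) {
  stopifnot(is.character(utr_sequence), length(utr_sequence) == 1L)
  s <- chartr("u", "t", tolower(utr_sequence))
  s <- toupper(s)
  if (nchar(s) && grepl("[^ACGTN]", s))
    stop("invalid nucleotide character in UTR sequence")
  n <- nchar(s)
  empty <- data.frame(start = integer(), end = integer(), length = integer())
  if (n < 6L) return(empty)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  starts <- which(chars == "A")
  starts <- starts[starts + 2L <= n &
                     chars[starts + 1L] == "T" & chars[starts + 2L] == "G"]
  res <- lapply(starts, function(i) {
    j <- i + 3L
    while (j + 2L <= n) {
      codon <- paste0(chars[j], chars[j + 1L], chars[j + 2L])
      if (codon %in% STOP_CODONS)
        return(c(start = i - 1L, end = j + 2L, length = j + 2L - (i - 1L)))
      j <- j + 3L
    }
    NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty)
  out <- as.data.frame(res)
  out[out$length >= min_length, , drop = FALSE]
}

#' Scan a collection of 5'UTRs for uORFs
#'
#' @param utrs A named character vector, a `Biostrings::DNAStringSet`, or a
#'   path to a FASTA file; names/record IDs are transcript IDs.
#' @param min_length Passed to [find_uorfs()].
#' @return data.frame of all detected uORFs with columns `transcript_id`,
#'   `utr_length`, `start`, `end`, `length`; attribute `"utr_lengths"` is a
#'   named vector over all scanned transcripts (including uORF-free ones).
#' @export
scan_utrs <- function(utrs, min_length = 6L) {
  if (is.character(utrs) && length(utrs) == 1L && file.exists(utrs))
    utrs <- Biostrings::readDNAStringSet(utrs)
  if (inherits(utrs, "DNAStringSet")) {
    nm <- names(utrs)
    utrs <- as.character(utrs)
    names(utrs) <- nm
  }
  stopifnot(is.character(utrs), !is.null(names(utrs)),
            !anyDuplicated(names(utrs)))
  hits <- lapply(names(utrs), function(id) {
    u <- find_uorfs(utrs[[id]], min_length = min_length)
    if (!nrow(u)) return(NULL)
    cbind(data.frame(transcript_id = id, utr_length = nchar(utrs[[id]]),
                     stringsAsFactors = FALSE), u)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), utr_length = integer(),
                      start = integer(), end = integer(), length = integer())
  rownames(out) <- NULL
  attr(out, "utr_lengths") <- vapply(utrs, nchar, integer(1L))
  out
}

#' Per-gene uORF features
#'
#' Aggregates transcript-level uORF annotations to genes: the uORF count of
#' a gene is the number of uORFs summed over all of its transcripts, and a
#' gene is a carrier when that count is at least one. Genes whose
#' transcripts were not scanned are excluded (reported in the
#' `"missing_genes"` attribute).
#'
#' @param uorfs uORF table from [scan_utrs()].
#' @param tx2gene data.frame with columns `transcript_id` and `gene_id`
#'   covering the scanned transcripts.
#' @return data.frame with one row per gene: `gene_id`, `n_uorfs`,
#'   `mean_length`, `carrier`.
#' @export
uorf_gene_features <- function(uorfs, tx2gene) {
  stopifnot(is.data.frame(uorfs), is.data.frame(tx2gene),
            all(c("transcript_id", "gene_id") %in% names(tx2gene)))
  scanned <- names(attr(uorfs, "utr_lengths"))
  if (is.null(scanned)) scanned <- unique(uorfs$transcript_id)
  map <- tx2gene[tx2gene$transcript_id %in% scanned, , drop = FALSE]
  genes <- sort(unique(map$gene_id))
  gene_of <- map$gene_id[match(uorfs$transcript_id, map$transcript_id)]
  counts <- table(factor(gene_of[!is.na(gene_of)], levels = genes))
  mlen <- tapply(uorfs$length[!is.na(gene_of)],
                 factor(gene_of[!is.na(gene_of)], levels = genes),
                 mean)
  out <- data.frame(gene_id = genes,
                    n_uorfs = as.integer(counts),
                    mean_length = as.numeric(mlen),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$carrier <- out$n_uorfs >= 1L
  attr(out, "missing_genes") <-
    setdiff(unique(tx2gene$gene_id), c(genes))
  out
}

#' Summarize uORF carrier prevalence
#'
#' @param features Per-gene feature table from [uorf_gene_features()], or
#'   `NULL` when `n_carriers`/`n_genes` are given directly.
#' @param n_carriers,n_genes Carrier and total gene counts, used when
#'   `features` is `NULL`.
#' @return list with `n_carriers`, `n_genes`, `frequency` and `percent`
#'   (the frequency as a whole-number percentage, as such prevalences are
#'   conventionally reported).
#' @export
summarize_carriers <- function(features = NULL, n_carriers = NULL,
                               n_genes = NULL) {
  if (!is.null(features)) {
    stopifnot(is.data.frame(features), "carrier" %in% names(features))
    n_carriers <- sum(features$carrier)
    n_genes <- nrow(features)
  }
  stopifnot(is.numeric(n_carriers), is.numeric(n_genes), n_genes >= 1)
  freq <- n_carriers / n_genes
  list(n_carriers = as.integer(n_carriers), n_genes = as.integer(n_genes),
       frequency = freq, percent = round(100 * freq))
}

#' Monte-Carlo test of uORF-carrier enrichment in a gene group
#'
#' Tests whether the observed number of uORF-carrying genes in a group of
#' size `group_size` is compatible with random sampling from a background
#' population with carrier frequency `background_freq`. Each of `n_sims`
#' simulations draws `draws_per_sim` integer values by rounding normal
#' deviates centred on the expected count
#' \eqn{\mu = \mathrm{group\_size} \times \mathrm{background\_freq}}, and a
#' one-sample t-test compares the simulated sample against the observed
#' count. The summary p-value is the median of the per-simulation p-values,
#' and the verdict is significant when it falls below `alpha`. The fraction
#' of individually significant simulations is also reported.
#'
#' The scale parameter of the normal draws is set by `sd_rule`:
#' `"variance"` (default) uses \eqn{\sigma = n p (1-p)}, the binomial
#' variance of the carrier count, and `"sd"` uses its square root. The
#' variance rule is the package default because it is the one under which
#' the procedure's verdicts behave as published for desk-scale groups; see
#' the methods vignette for the calibration trade-offs of both rules.
#'
#' @param observed Observed carrier count in the group.
#' @param group_size Number of genes in the group.
#' @param background_freq Background carrier frequency in (0, 1).
#' @param n_sims Number of Monte-Carlo simulations (default 1000).
#' @param draws_per_sim Values drawn per simulation (default 100).
#' @param sd_rule `"variance"` or `"sd"` (see Details).
#' @param alpha Per-simulation and summary significance level (default 0.05).
#' @param seed Optional integer seed making the result reproducible.
#' @return An object of class `"mc_enrichment"`: a list with the inputs plus
#'   `expected`, `sigma`, `per_sim_p`, `frac_significant`, `summary_p`,
#'   `direction` (`"enriched"` or `"depleted"`) and `significant`.
#' @export
monte_carlo_enrichment <- function(observed, group_size, background_freq,
                                   n_sims = 1000L, draws_per_sim = 100L,
                                   sd_rule = c("variance", "sd"),
                                   alpha = 0.05, seed = NULL) {
  sd_rule <- match.arg(sd_rule)
  stopifnot(is.numeric(observed), length(observed) == 1L,
            is.numeric(group_size), length(group_size) == 1L,
            observed >= 0, observed <= group_size,
            n_sims >= 1L, draws_per_sim >= 2L)
  check_fraction(background_freq, "background_freq", allow_one = FALSE)
  mu <- group_size * background_freq
  pq <- group_size * background_freq * (1 - background_freq)
  sigma <- if (sd_rule == "variance") pq else sqrt(pq)
  if (sigma <= 0) stop("degenerate simulation: sigma is zero")
  if (!is.null(seed)) set.seed(seed)
  per_sim_p <- vapply(seq_len(n_sims), function(i) {
    x <- round(stats::rnorm(draws_per_sim, mean = mu, sd = sigma))
    if (stats::sd(x) == 0) return(as.numeric(all(x == observed)))
    stats::t.test(x, mu = observed)$p.value
  }, numeric(1L))
  summary_p <- stats::median(per_sim_p)
  structure(list(observed = observed,
                 group_size = group_size,
                 background_freq = background_freq,
                 expected = mu,
                 sigma = sigma,
                 sd_rule = sd_rule,
                 n_sims = n_sims,
                 draws_per_sim = draws_per_sim,
                 alpha = alpha,
                 per_sim_p = per_sim_p,
                 frac_significant = mean(per_sim_p < alpha),
                 summary_p = summary_p,
                 direction = if (observed >= mu) "enriched" else "depleted",
                 significant = summary_p < alpha),
            class = "mc_enrichment")
}

#' @export
print.mc_enrichment <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo carrier enrichment: %d of %d vs background %.3f (expected %.2f)\n",
    x$observed, x$group_size, x$background_freq, x$expected))
  cat(sprintf("  %d sims x %d draws, sigma = %.3f (%s rule)\n",
              x$n_sims, x$draws_per_sim, x$sigma, x$sd_rule))
  cat(sprintf("  summary p = %.3g, %.1f%% of sims significant -> %s (%s)\n",
              x$summary_p, 100 * x$frac_significant,
              if (x$significant) "significant" else "not significant",
              x$direction))
  invisible(x)
}

#' Compare uORF features between two gene groups
#'
#' Two-sided Wilcoxon rank-sum tests of the per-gene uORF count and mean
#' uORF length between two groups (for example concordance groups of an
#' integrated analysis). The normal approximation with tie correction is
#' used, so all-identical groups are handled.
#'
#' @param features_a,features_b Per-gene feature tables from
#'   [uorf_gene_features()] (columns `n_uorfs`, `mean_length`).
#' @return data.frame with one row per feature (`n_uorfs`, `mean_length`)
#'   and columns `feature`, `n_a`, `n_b`, `p_value`.
#' @export
compare_uorf_features <- function(features_a, features_b) {
  stopifnot(is.data.frame(features_a), is.data.frame(features_b),
            nrow(features_a) >= 1L, nrow(features_b) >= 1L)
  one <- function(col) {
    a <- features_a[[col]]
    b <- features_b[[col]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) return(NA_real_)
    if (length(unique(c(a, b))) == 1L) return(1)
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  }
  data.frame(feature = c("n_uorfs", "mean_length"),
             n_a = nrow(features_a), n_b = nrow(features_b),
             p_value = c(one("n_uorfs"), one("mean_length")),
             stringsAsFactors = FALSE)
}
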