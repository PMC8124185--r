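# Cross-layer integration: match transcript- and protein-layer DE results by
# gene, assign concordance groups, correlate fold changes, report groups.

#' Match transcript- and protein-layer DE results by gene
#'
#' Joins two classified DE tables through an ID map. One gene may map to
#' several transcripts or proteins; multi-feature genes are collapsed to a
#' single representative per layer, by default the feature with the largest
#' absolute log2 fold change. Genes with a transcript measurement but no
#' quantified protein get `protein_status = "unmeasured"`. Features absent
#' from the map are excluded and recorded in the `"unmapped"` attribute.
#'
#' @param transcript_de,protein_de Classified DE tables from [classify_de()]
#'   (columns `feature_id`, `log2fc`, `signed_fc`, `fdr`, `status`).
#' @param id_map data.frame with columns `transcript_id`, `protein_id`
#'   (`NA` for genes without a protein feature) and `gene_id`.
#' @param collapse Multi-mapping collapse rule; only `"max_abs_fc"` is
#'   implemented.
#' @return data.frame with one row per gene: `gene_id`,
#'   `transcript_status`, `transcript_fc`, `transcript_log2fc`,
#'   `transcript_fdr`, `protein_status`, `protein_fc`, `protein_log2fc`,
#'   `protein_fdr`. Attribute `"unmapped"` lists excluded feature IDs per
#'   layer.
#' @export
match_layers <- function(transcript_de, protein_de, id_map,
                         collapse = "max_abs_fc") {
  collapse <- match.arg(collapse)
  stopifnot(is.data.frame(id_map),
            all(c("transcript_id", "protein_id", "gene_id") %in% names(id_map)))
  need <- c("feature_id", "log2fc", "signed_fc", "fdr", "status")
  stopifnot(all(need %in% names(transcript_de)),
            all(need %in% names(protein_de)))

  pick_rep <- function(de, ids, genes) {
    hit <- match(de$feature_id, ids)
    mapped <- de[!is.na(hit), , drop = FALSE]
    mapped$gene_id <- genes[hit[!is.na(hit)]]
    unmapped <- de$feature_id[is.na(hit)]
    # representative per gene: largest |log2fc|, ties by feature_id
    ord <- order(mapped$gene_id, -abs(mapped$log2fc), mapped$feature_id)
    mapped <- mapped[ord, , drop = FALSE]
    rep <- mapped[!duplicated(mapped$gene_id), , drop = FALSE]
    list(rep = rep, unmapped = unmapped)
  }

  tx <- pick_rep(transcript_de, id_map$transcript_id, id_map$gene_id)
  pmap <- id_map[!is.na(id_map$protein_id), , drop = FALSE]
  pr <- pick_rep(protein_de, pmap$protein_id, pmap$gene_id)

  genes <- tx$rep$gene_id
  pj <- match(genes, pr$rep$gene_id)
  out <- data.frame(
    gene_id = genes,
    transcript_status = tx$rep$status,
    transcript_fc = tx$rep$signed_fc,
    transcript_log2fc = tx$rep$log2fc,
    transcript_fdr = tx$rep$fdr,
    protein_status = ifelse(is.na(pj), "unmeasured", pr$rep$status[pj]),
    protein_fc = pr$rep$signed_fc[pj],
    protein_log2fc = pr$rep$log2fc[pj],
    protein_fdr = pr$rep$fdr[pj],
    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- list(transcript = tx$unmapped, protein = pr$unmapped)
  out
}

#' Assign cross-layer concordance groups
#'
#' Labels each gene with its transcript/protein concordance class:
#' group `"1"` (up at both layers), `"2"` (transcript up, protein measured
#' but unchanged), `"3"` (down at both layers), `"discordant"` (opposite
#' significant directions), or `"none"`. Genes whose protein was never
#' measured are always `"none"`. A node colour class for network displays is
#' added alongside: `red` for group 2, `grey` for transcript-up genes with
#' no protein value, `green` for transcript-up/protein-down genes, and
#' `background` otherwise.
#'
#' @param integrated Output of [match_layers()].
#' @return The input with `group` and `node_class` columns added and a
#'   `"group_sizes"` attribute (named counts over 1/2/3/discordant/none).
#' @export
assign_groups <- function(integrated) {
  stopifnot(is.data.frame(integrated),
            all(c("transcript_status", "protein_status") %in% names(integrated)))
  ts <- integrated$transcript_status
  ps <- integrated$protein_status
  group <- rep("none", nrow(integrated))
  group[ts == "up"   & ps == "up"]   <- "1"
  group[ts == "up"   & ps == "ns"]   <- "2"
  group[ts == "down" & ps == "down"] <- "3"
  group[(ts == "up" & ps == "down") | (ts == "down" & ps == "up")] <- "discordant"

  node_class <- rep("background", nrow(integrated))
  node_class[group == "2"] <- "red"
  node_class[ts == "up" & ps == "unmeasured"] <- "grey"
  node_class[ts == "up" & ps == "down"] <- "green"

  out <- integrated
  out$group <- group
  out$node_class <- node_class
  sizes <- table(factor(group, levels = c("1", "2", "3", "discordant", "none")))
  attr(out, "group_sizes") <- c(sizes)
  out
}

#' Pearson correlation of cross-layer fold changes
#'
#' Correlates log2 fold changes between the two layers over all genes
#' measured in both (not only significant ones), with a two-sided p-value
#' from the t transform of r.
#'
#' @param integrated Output of [match_layers()] (or [assign_groups()]).
#' @return A list with `r`, `p_value` and `n`.
#' @export
correlate_fold_changes <- function(integrated) {
  stopifnot(is.data.frame(integrated),
            all(c("transcript_log2fc", "protein_log2fc") %in% names(integrated)))
  ok <- !is.na(integrated$transcript_log2fc) & !is.na(integrated$protein_log2fc)
  if (sum(ok) < 3L)
    stop("need at least 3 genes measured in both layers")
  ct <- stats::cor.test(integrated$transcript_log2fc[ok],
                        integrated$protein_log2fc[ok])
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Group report table
#'
#' Extracts the genes of one concordance group as a report table with the
#' two signed fold changes, sorted by descending transcript fold change
#' (within `category` when that column is present).
#'
#' @param integrated Output of [assign_groups()].
#' @param group Group label to report (default `"1"`).
#' @return data.frame with columns `gene_id`, `transcript_fc`, `protein_fc`
#'   (plus `category` when available); zero rows if the group is empty.
#' @export
group_report <- function(integrated, group = "1") {
  stopifnot(is.data.frame(integrated), "group" %in% names(integrated))
  sel <- integrated[integrated$group == group, , drop = FALSE]
  cols <- intersect(c("gene_id", "category", "transcript_fc", "protein_fc"),
                    names(sel))
  sel <- sel[, cols, drop = FALSE]
  if (nrow(sel)) {
    if ("category" %in% cols)
      sel <- sel[order(sel$category, -sel$transcript_fc), , drop = FALSE]
    else
      sel <- sel[order(-sel$transcript_fc), , drop = FALSE]
  }
  rownames(sel) <- NULL
  sel
}

#' Build an integrated table from pre-computed fold-change pairs
#'
#' Fixture-mode entry point: takes a table of already-screened targets with
#' signed transcript and protein fold changes (for example a published list
#' of significant hits) and builds an integrated table whose statuses are
#' derived from the fold-change cut alone, the FDR condition being satisfied
#' by construction of such a list.
#'
#' @param fc_table data.frame with columns `gene_id`, `transcript_fc`,
#'   `protein_fc` (signed fold changes; `NA` protein = unmeasured) and
#'   optionally `category`.
#' @param thresholds An [analysis_thresholds()] object.
#' @return An integrated, group-labelled table as from [assign_groups()].
#' @export
integrate_fc_table <- function(fc_table, thresholds = analysis_thresholds()) {
  stopifnot(is.data.frame(fc_table),
            all(c("gene_id", "transcript_fc", "protein_fc") %in% names(fc_table)))
  fc_status <- function(fc) {
    ifelse(is.na(fc), "unmeasured",
           ifelse(fc >= thresholds$fc_cut, "up",
                  ifelse(fc <= -thresholds$fc_cut, "down", "ns")))
  }
  signed_to_log2 <- function(fc) sign(fc) * log2(abs(fc))
  out <- data.frame(
    gene_id = fc_table$gene_id,
    transcript_status = fc_status(fc_table$transcript_fc),
    transcript_fc = fc_table$transcript_fc,
    transcript_log2fc = signed_to_log2(fc_table$transcript_fc),
    transcript_fdr = NA_real_,
    protein_status = fc_status(fc_table$protein_fc),
    protein_fc = fc_table$protein_fc,
    protein_log2fc = signed_to_log2(fc_table$protein_fc),
    protein_fdr = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
  out$transcript_status[out$transcript_status == "unmeasured"] <- "ns"
  if ("category" %in% names(fc_table)) out$category <- fc_table$category
  assign_groups(out)
}
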