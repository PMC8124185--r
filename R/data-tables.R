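#' Curated fold-change table of dPerk-induced group-1 targets
#'
#' The published list of Drosophila genes upregulated by dPerk
#' overexpression at both the transcript and the protein level, as signed
#' fold changes (treated over control) with a functional category per gene.
#' Shipped as a plain-text fixture; useful as a worked example for the
#' fixture-mode integration entry point ([integrate_fc_table()]) and as a
#' reference input for the group-report stage.
#'
#' @return data.frame with columns `gene_id`, `category`, `transcript_fc`,
#'   `protein_fc` (27 rows).
#' @examples
#' tab <- group1_fc_table()
#' rep <- group_report(integrate_fc_table(tab), "1")
#' nrow(rep)           # 27
#' max(rep$transcript_fc)  # 117 (a cytochrome P450)
#' @export
group1_fc_table <- function() {
  path <- system.file("extdata", "group1_targets.tsv", package = "duomics",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
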