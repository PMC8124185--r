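# Readers and writers for the pipeline's plain-text interchange formats:
# expression TSV (sample columns named <condition>_<rep>), ID-map TSV,
# FASTA UTRs, 3-column edge lists, GMT term sets and the truth table.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write an expression matrix as TSV
#'
#' First column `feature_id`, then one column per sample named
#' `<condition>_<rep>` so the design is recoverable from the header.
#'
#' @param m An [expression_matrix()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(feature_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read an expression matrix from TSV
#'
#' @param path TSV produced by [write_expression_matrix()]; sample columns
#'   must be named `<condition>_<rep>` with condition `control` or
#'   `treated`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1L] != "feature_id")
    stop("expected first column 'feature_id' in ", path)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df$feature_id
  condition <- sub("_[^_]*$", "", colnames(vals))
  expression_matrix(vals, condition)
}

#' Write / read the transcript-protein-gene ID map
#' @param id_map data.frame with columns `transcript_id`, `protein_id`,
#'   `gene_id`.
#' @param path File path.
#' @return The path (writer) or the data.frame (reader).
#' @export
write_id_map <- function(id_map, path) {
  stopifnot(all(c("transcript_id", "protein_id", "gene_id") %in%
                  names(id_map)))
  write_tsv(id_map, path)
}

#' @rdname write_id_map
#' @export
read_id_map <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("transcript_id", "protein_id", "gene_id") %in% names(df)))
  df$protein_id[df$protein_id %in% c("", "NA")] <- NA_character_
  df
}

#' Write / read UTR sequences as FASTA
#' @param utrs Named character vector (names are transcript IDs).
#' @param path FASTA file path.
#' @return The path (writer) or a named character vector (reader).
#' @export
write_fasta <- function(utrs, path) {
  stopifnot(is.character(utrs), !is.null(names(utrs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(utrs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write / read a scored network as a 3-column edge list
#' @param g igraph graph with edge attribute `score`.
#' @param path TSV path (columns `node_a`, `node_b`, `score`). Isolated
#'   nodes are preserved through a trailing commented node list.
#' @return The path (writer) or an igraph graph (reader).
#' @export
write_edge_list <- function(g, path) {
  stopifnot(igraph::is_igraph(g))
  edges <- igraph::as_data_frame(g, what = "edges")
  if (!nrow(edges))
    edges <- data.frame(from = character(), to = character(),
                        score = numeric())
  if (!"score" %in% names(edges)) edges$score <- rep(1, nrow(edges))
  names(edges)[1:2] <- c("node_a", "node_b")
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(edges[, c("node_a", "node_b", "score")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  isolated <- setdiff(igraph::V(g)$name,
                      unique(c(edges$node_a, edges$node_b)))
  if (length(isolated))
    writeLines(paste0("#node\t", isolated), con)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  nodes_extra <- sub("^#node\t", "", grep("^#node\t", lines, value = TRUE))
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          stringsAsFactors = FALSE)
  stopifnot(all(c("node_a", "node_b", "score") %in% names(df)))
  all_nodes <- unique(c(df$node_a, df$node_b, nodes_extra))
  igraph::graph_from_data_frame(
    df[, c("node_a", "node_b", "score")], directed = FALSE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE))
}

#' Write / read gene set collections in GMT format
#' @param terms Named list of gene ID vectors.
#' @param path GMT path; on write the description field holds the term ID.
#' @return The path (writer) or a named list (reader).
#' @export
write_gmt <- function(terms, path) {
  stopifnot(is.list(terms), !is.null(names(terms)))
  lines <- vapply(names(terms), function(id) {
    paste(c(id, id, terms[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
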