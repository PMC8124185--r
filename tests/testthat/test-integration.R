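make_de <- function(ids, log2fc, fdr) {
  data.frame(feature_id = ids, log2fc = log2fc,
             signed_fc = signed_fold_change(log2fc),
             p_value = fdr, fdr = fdr,
             status = ifelse(abs(signed_fold_change(log2fc)) >= 1.6 &
                               fdr <= 0.05,
                             ifelse(log2fc > 0, "up", "down"), "ns"),
             stringsAsFactors = FALSE)
}

test_that("layers are matched by gene with unmeasured proteins flagged", {
  idm <- data.frame(transcript_id = c("t1", "t2", "t3"),
                    protein_id = c("p1", NA, "p3"),
                    gene_id = c("gA", "gB", "gC"))
  tx <- make_de(c("t1", "t2", "t3"), c(2, 1, -2), c(0.01, 0.5, 0.01))
  pr <- make_de(c("p1", "p3"), c(1.5, -1.8), c(0.02, 0.01))
  m <- match_layers(tx, pr, idm)
  expect_identical(m$gene_id, c("gA", "gB", "gC"))
  expect_identical(m$protein_status, c("up", "unmeasured", "down"))
  expect_true(is.na(m$protein_fc[2]))
})

test_that("multi-feature genes collapse to the max-|FC| representative", {
  idm <- data.frame(transcript_id = c("t1", "t2", "t3"),
                    protein_id = c("p1", "p1", NA),
                    gene_id = c("gA", "gA", "gA"))
  tx <- make_de(c("t1", "t2", "t3"), c(0.5, -3, 1), c(0.01, 0.01, 0.01))
  pr <- make_de("p1", 2, 0.01)
  m <- match_layers(tx, pr, idm)
  expect_identical(nrow(m), 1L)
  expect_equal(m$transcript_log2fc, -3)  # largest magnitude wins

  # unmapped features are excluded and reported
  tx2 <- rbind(tx, make_de("t_orphan", 5, 0.001))
  m2 <- match_layers(tx2, pr, idm)
  expect_identical(attr(m2, "unmapped")$transcript, "t_orphan")
  expect_identical(nrow(m2), 1L)
})

test_that("matched gene count equals a brute-force join on the ID map", {
  set.seed(21)
  cfg <- synthetic_config(n_genes = 300, seed = 21)
  b <- generate_omics_dataset(cfg)
  tx <- run_de(b$transcript)
  pr <- run_de(b$protein)
  m <- match_layers(tx, pr, b$id_map)
  # oracle: genes of transcript features, intersected per layer
  tx_genes <- unique(b$id_map$gene_id[match(tx$feature_id,
                                            b$id_map$transcript_id)])
  expect_identical(nrow(m), length(tx_genes))
  pr_genes <- unique(b$id_map$gene_id[match(pr$feature_id,
                                            b$id_map$protein_id)])
  expect_identical(sum(m$protein_status != "unmeasured"), length(pr_genes))
})

test_that("concordance groups follow the up/up, up/ns, down/down definitions", {
  grid <- expand.grid(ts = c("up", "down", "ns"),
                      ps = c("up", "down", "ns", "unmeasured"),
                      stringsAsFactors = FALSE)
  integ <- data.frame(gene_id = sprintf("g%02d", seq_len(nrow(grid))),
                      transcript_status = grid$ts, protein_status = grid$ps,
                      stringsAsFactors = FALSE)
  out <- assign_groups(integ)
  expect_identical(out$group[out$transcript_status == "up" &
                               out$protein_status == "up"], "1")
  expect_identical(out$group[out$transcript_status == "up" &
                               out$protein_status == "ns"], "2")
  expect_identical(out$group[out$transcript_status == "down" &
                               out$protein_status == "down"], "3")
  expect_identical(out$group[out$transcript_status == "up" &
                               out$protein_status == "down"], "discordant")
  # unmeasured protein never yields a numbered group
  expect_true(all(out$group[out$protein_status == "unmeasured"] == "none"))
  # display classes
  expect_identical(out$node_class[out$group == "2"], "red")
  expect_identical(out$node_class[out$transcript_status == "up" &
                                    out$protein_status == "unmeasured"],
                   "grey")
  expect_identical(out$node_class[out$transcript_status == "up" &
                                    out$protein_status == "down"], "green")
  # labels are a partition
  expect_identical(sum(attr(out, "group_sizes")), nrow(out))
})

test_that("fold-change correlation is Pearson on co-measured genes and symmetric", {
  integ <- data.frame(transcript_log2fc = c(1, 2, 3),
                      protein_log2fc = c(1, 2, 3))
  expect_equal(correlate_fold_changes(integ)$r, 1)
  integ$protein_log2fc <- c(3, 2, 1)
  expect_equal(correlate_fold_changes(integ)$r, -1)
  expect_error(correlate_fold_changes(integ[1:2, ]), "at least 3")

  set.seed(22)
  n <- 2000
  z <- rnorm(n)   # shared effect gives cor(tx, pr) = 0.5 exactly
  tx <- sqrt(0.5) * z + sqrt(0.5) * rnorm(n)
  pr <- sqrt(0.5) * z + sqrt(0.5) * rnorm(n)
  integ <- data.frame(transcript_log2fc = tx, protein_log2fc = pr)
  r <- correlate_fold_changes(integ)$r
  expect_gt(r, 0.45)   # 3 SE band around the planted rho
  expect_lt(r, 0.55)
  swapped <- data.frame(transcript_log2fc = pr, protein_log2fc = tx)
  expect_equal(correlate_fold_changes(swapped)$r, r)
})

test_that("group report sorts by descending transcript FC and handles empty groups", {
  integ <- assign_groups(data.frame(
    gene_id = c("a", "b", "c"),
    transcript_status = "up", protein_status = "up",
    transcript_fc = c(2, 10, 5), protein_fc = c(1.7, 2, 3),
    transcript_log2fc = log2(c(2, 10, 5)), protein_log2fc = log2(c(1.7, 2, 3)),
    stringsAsFactors = FALSE))
  rep1 <- group_report(integ, "1")
  expect_identical(rep1$gene_id, c("b", "c", "a"))
  rep3 <- group_report(integ, "3")
  expect_identical(nrow(rep3), 0L)
  expect_true(all(c("gene_id", "transcript_fc", "protein_fc") %in%
                    names(rep3)))
})

test_that("fixture-mode integration derives statuses from the fold-change cut", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    transcript_fc = c(2, 1.5, -2, 3),
                    protein_fc = c(1.7, 2, -1.61, NA))
  out <- integrate_fc_table(tab)
  expect_identical(out$group, c("1", "none", "3", "none"))
  expect_identical(out$node_class[4], "grey")
})
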