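test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(100, frac_group1 = 0.5, frac_group2 = 0.4,
                                frac_group3 = 0.2), "sum to < 1")
  expect_error(synthetic_config(100, protein_coverage = 0), "fraction")
  expect_error(synthetic_config(4, protein_coverage = 0.1,
                                term_size_range = c(1, 2)), "at least 1")
  expect_error(synthetic_config(100, clique_size_range = c(2, 4)))
  cfg <- synthetic_config(100)
  expect_s3_class(cfg, "synthetic_config")
})

test_that("generators are bit-reproducible from the same config and seed", {
  cfg <- synthetic_config(n_genes = 150, seed = 61)
  a <- generate_all(cfg)
  b <- generate_all(cfg)
  expect_identical(a$transcript$values, b$transcript$values)
  expect_identical(a$protein$values, b$protein$values)
  expect_identical(a$utrs, b$utrs)
  expect_identical(igraph::as_data_frame(a$network),
                   igraph::as_data_frame(b$network))
  expect_identical(a$terms, b$terms)
  expect_identical(a$truth, b$truth)
  # different seed changes the data
  c <- generate_all(synthetic_config(n_genes = 150, seed = 62))
  expect_false(identical(a$transcript$values, c$transcript$values))
})

test_that("zero planted fractions give an all-null truth table", {
  cfg <- synthetic_config(n_genes = 80, frac_group1 = 0, frac_group2 = 0,
                          frac_group3 = 0, seed = 63)
  b <- generate_omics_dataset(cfg)
  expect_true(all(b$truth$group == "none"))
  expect_true(all(b$truth$de_transcript == "ns"))
})

test_that("planted group labels are a consistent partition at configured rates", {
  cfg <- synthetic_config(n_genes = 1000, seed = 64)
  b <- generate_omics_dataset(cfg)
  tr <- b$truth
  expect_identical(anyDuplicated(tr$gene_id), 0L)
  # label consistency with planted DE directions
  expect_true(all(tr$de_transcript[tr$group == "1"] == "up" &
                    tr$de_protein[tr$group == "1"] == "up"))
  expect_true(all(tr$de_transcript[tr$group == "2"] == "up" &
                    tr$de_protein[tr$group == "2"] == "ns"))
  expect_true(all(tr$de_transcript[tr$group == "3"] == "down" &
                    tr$de_protein[tr$group == "3"] == "down"))
  # realized counts at the rounded configured sizes
  expect_identical(sum(tr$group == "1"), 20L)
  expect_identical(sum(tr$group == "2"), 50L)
  expect_identical(sum(tr$group == "3"), 30L)
  # protein matrix size and coverage of planted genes
  expect_identical(nrow(b$protein$values), 370L)
  expect_true(all(tr$de_protein[tr$group != "none"] != "unmeasured"))
})

test_that("UTR carrier frequency is honoured at the extremes and in expectation", {
  cfg0 <- synthetic_config(n_genes = 60, uorf_carrier_freq = 0, seed = 65)
  b <- generate_omics_dataset(cfg0)
  u0 <- generate_utr_set(cfg0, b$truth)
  feats0 <- uorf_gene_features(
    scan_utrs(u0$utrs),
    data.frame(transcript_id = names(u0$utrs), gene_id = b$truth$gene_id))
  expect_identical(sum(feats0$carrier), 0L)

  cfg1 <- synthetic_config(n_genes = 60, uorf_carrier_freq = 1, seed = 65)
  u1 <- generate_utr_set(cfg1, b$truth)
  feats1 <- uorf_gene_features(
    scan_utrs(u1$utrs),
    data.frame(transcript_id = names(u1$utrs), gene_id = b$truth$gene_id))
  expect_identical(sum(feats1$carrier), 60L)

  # the scanner confirms exactly the planted carrier flags
  cfg <- synthetic_config(n_genes = 300, seed = 66)
  b <- generate_omics_dataset(cfg)
  u <- generate_utr_set(cfg, b$truth)
  feats <- uorf_gene_features(
    scan_utrs(u$utrs),
    data.frame(transcript_id = names(u$utrs), gene_id = b$truth$gene_id))
  expect_identical(feats$carrier[match(u$truth$gene_id, feats$gene_id)],
                   u$truth$uorf_carrier)
  # realized frequency within 3 binomial SDs of 0.43
  n <- nrow(u$truth)
  expect_lt(abs(sum(u$truth$uorf_carrier) - 0.43 * n),
            3 * sqrt(n * 0.43 * 0.57) + 1e-9)
  expect_error(generate_utr_set(synthetic_config(n_genes = 10,
                                                 utr_length = 12,
                                                 term_size_range = c(2, 5),
                                                 seed = 1),
                                b$truth[1:10, ]), "too short")
})

test_that("carrier prevalence at the reference scale lands near 43%", {
  cfg <- synthetic_config(n_genes = 5586, seed = 67)
  b <- generate_omics_dataset(cfg)
  u <- generate_utr_set(cfg, b$truth)
  n_carriers <- sum(u$truth$uorf_carrier)
  expect_lt(abs(n_carriers - 0.43 * 5586), 3 * sqrt(5586 * 0.43 * 0.57))
  pct <- summarize_carriers(n_carriers = n_carriers, n_genes = 5586)$percent
  expect_true(abs(pct - 43) <= 1)  # realized binomial draw rounds to 43 +/- 1
})

test_that("background network plants exact cliques over clean noise", {
  # no background edges, 2 cliques of 4: exactly 2 * C(4,2) = 12 edges
  cfg <- synthetic_config(n_genes = 50, background_edge_prob = 0,
                          n_clique_modules = 2, clique_size_range = c(4, 4),
                          seed = 68)
  b <- generate_omics_dataset(cfg)
  net <- generate_background_network(cfg, b$truth)
  expect_equal(igraph::ecount(net$network), 12)
  # every connected component of size > 1 is a clique
  comp <- igraph::components(net$network)
  for (cid in which(comp$csize > 1)) {
    members <- names(comp$membership)[comp$membership == cid]
    expect_true(is_clique(members, net$network))
  }
  # planted member sets are cliques and recorded in the truth
  for (k in 1:2) {
    members <- net$truth$gene_id[!is.na(net$truth$clique_id) &
                                   net$truth$clique_id == k]
    expect_identical(length(members), 4L)
    expect_true(is_clique(members, net$network))
  }
  # scores in (0, 1]
  cfg2 <- synthetic_config(n_genes = 80, background_edge_prob = 0.05,
                           seed = 69)
  b2 <- generate_omics_dataset(cfg2)
  net2 <- generate_background_network(cfg2, b2$truth)
  sc <- igraph::E(net2$network)$score
  expect_true(all(sc > 0 & sc <= 1))
})

test_that("annotation sets oversample the target group in enriched terms", {
  cfg <- synthetic_config(n_genes = 500, n_terms = 12,
                          term_size_range = c(25, 40), seed = 70)
  b <- generate_omics_dataset(cfg)
  ann <- generate_annotation_sets(cfg, b$truth, n_enriched_terms = 3)
  expect_length(ann$terms, 12L)
  sizes <- lengths(ann$terms)
  expect_true(all(sizes >= 25 & sizes <= 40))
  g2 <- b$truth$gene_id[b$truth$group == "2"]
  frac_in <- vapply(ann$terms, function(tg) mean(tg %in% g2), numeric(1))
  info <- ann$term_info
  expect_true(all(frac_in[info$enriched] > 0.5))
  expect_true(all(frac_in[!info$enriched] < 0.3))
  # per-gene membership strings list enriched terms only
  carriers <- ann$truth$enriched_terms != ""
  listed <- unique(unlist(strsplit(ann$truth$enriched_terms[carriers], ";")))
  expect_true(all(listed %in% info$term_id[info$enriched]))
})
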