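# Pipeline orchestration: generate or load inputs, run both DE layers,
# integrate, test uORF enrichment, enrich terms, deconstruct the network,
# and write a reproducible summary.

#' Pipeline configuration
#'
#' Bundles every stage's parameters. Either `synthetic` (a
#' [synthetic_config()], inputs are generated and written under the run
#' directory) or `inputs` (a named list of paths: `transcript`, `protein`,
#' `id_map`, `utrs`, `network`, `terms`) must be supplied.
#'
#' @param synthetic Optional [synthetic_config()].
#' @param inputs Optional named list of input file paths.
#' @param thresholds An [analysis_thresholds()].
#' @param score_cut Edge-score cut for the network stage (default 0.4).
#' @param inflation_schedule MCL inflation sweep (default `c(1.5, 2, 4, 6)`).
#' @param mc Monte-Carlo settings: list with `n_sims`, `draws_per_sim`,
#'   `sd_rule`, `alpha`.
#' @param enrich_alpha Significance level for term enrichment.
#' @param kappa_threshold Kappa cut for term grouping (default 0.4).
#' @param seed Global pipeline seed.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(synthetic = NULL, inputs = NULL,
                            thresholds = analysis_thresholds(),
                            score_cut = 0.4,
                            inflation_schedule = c(1.5, 2, 4, 6),
                            mc = list(n_sims = 1000L, draws_per_sim = 100L,
                                      sd_rule = "variance", alpha = 0.05),
                            enrich_alpha = 0.05,
                            kappa_threshold = 0.4,
                            seed = 1L) {
  if (is.null(synthetic) && is.null(inputs))
    stop("supply either a synthetic_config or a list of input paths")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  stopifnot(inherits(thresholds, "analysis_thresholds"))
  structure(list(synthetic = synthetic, inputs = inputs,
                 thresholds = thresholds, score_cut = score_cut,
                 inflation_schedule = inflation_schedule, mc = mc,
                 enrich_alpha = enrich_alpha,
                 kappa_threshold = kappa_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate pipeline input files
#'
#' Report-only consistency check of the input bundle: files exist and
#' parse, feature IDs are unique, condition labels are parseable, the ID
#' map resolves the matrix features, and every mapped transcript has a UTR
#' record. Problems are itemized rather than thrown.
#'
#' @param inputs Named list of paths (`transcript`, `protein`, `id_map`,
#'   `utrs`, `network`, `terms`).
#' @return data.frame with columns `level` (`error`/`warning`) and
#'   `message`; zero rows when everything is consistent.
#' @export
validate_inputs <- function(inputs) {
  problems <- list()
  note <- function(level, msg)
    problems[[length(problems) + 1L]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)
  need <- c("transcript", "protein", "id_map", "utrs", "network", "terms")
  for (nm in need)
    if (is.null(inputs[[nm]]) || !file.exists(inputs[[nm]]))
      note("error", paste0("missing input file: ", nm))
  done <- function() {
    out <- do.call(rbind, problems)
    if (is.null(out)) out <- data.frame(level = character(),
                                        message = character())
    out
  }
  if (nrow(done())) return(done())

  mats <- list()
  for (nm in c("transcript", "protein")) {
    df <- tryCatch(read_tsv(inputs[[nm]]), error = function(e) NULL)
    if (!is.null(df) && anyDuplicated(df$feature_id)) {
      note("error", paste0("duplicated feature ID in ", nm, " matrix: ",
                           df$feature_id[duplicated(df$feature_id)][1L]))
      next
    }
    mats[[nm]] <- tryCatch(read_expression_matrix(inputs[[nm]]),
                           error = function(e) {
                             note("error", paste0(nm, " matrix: ",
                                                  conditionMessage(e)))
                             NULL
                           })
  }
  idm <- tryCatch(read_id_map(inputs$id_map), error = function(e) {
    note("error", paste0("id map: ", conditionMessage(e))); NULL
  })
  utrs <- tryCatch(read_fasta(inputs$utrs), error = function(e) {
    note("error", paste0("utrs: ", conditionMessage(e))); NULL
  })
  if (!is.null(mats$transcript) && !is.null(idm)) {
    lost <- setdiff(feature_ids(mats$transcript), idm$transcript_id)
    if (length(lost))
      note("warning", paste0(length(lost),
                             " transcript feature(s) missing from id map, e.g. ",
                             lost[1L]))
  }
  if (!is.null(idm) && !is.null(utrs)) {
    no_utr <- setdiff(idm$transcript_id, names(utrs))
    if (length(no_utr))
      note("warning", paste0("UTR FASTA missing mapped transcript(s): ",
                             paste(utils::head(no_utr, 3L), collapse = ", ")))
  }
  tryCatch(read_edge_list(inputs$network), error = function(e)
    note("error", paste0("network: ", conditionMessage(e))))
  tryCatch(read_gmt(inputs$terms), error = function(e)
    note("error", paste0("terms: ", conditionMessage(e))))
  done()
}

#' Run the full pipeline
#'
#' Executes every stage in order, with all stage outputs written as
#' plain-text files under `outdir` (inputs under `inputs/`, results under
#' `results/`) and a machine-readable `summary.json`. Re-running with the
#' same configuration and seed reproduces every output.
#'
#' Stages: input generation (synthetic mode) or loading; validation;
#' per-layer differential expression; cross-layer integration and fold
#' change correlation; uORF scanning, per-gene features and Monte-Carlo
#' carrier-enrichment tests for groups 1 and 2; term enrichment of the
#' group-2 genes with kappa grouping; network deconstruction of the group-2
#' subnetwork into cliques and first-neighbour reconstruction against the
#' background network.
#'
#' @param config A [pipeline_config()].
#' @param outdir Run directory (created if needed).
#' @return The summary list, invisibly. Side effect: files under `outdir`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(file.path(outdir, "inputs"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outdir, "results"), showWarnings = FALSE)
  inp <- function(f) file.path(outdir, "inputs", f)
  res <- function(f) file.path(outdir, "results", f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # -- inputs ---------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    stage("generate", {
      bundle <- generate_all(config$synthetic)
      write_expression_matrix(bundle$transcript, inp("transcript.tsv"))
      write_expression_matrix(bundle$protein, inp("protein.tsv"))
      write_id_map(bundle$id_map, inp("id_map.tsv"))
      write_fasta(bundle$utrs, inp("utrs.fasta"))
      write_edge_list(bundle$network, inp("network.tsv"))
      write_gmt(bundle$terms, inp("terms.gmt"))
      write_tsv(bundle$truth, inp("truth.tsv"))
    })
    paths <- list(transcript = inp("transcript.tsv"),
                  protein = inp("protein.tsv"),
                  id_map = inp("id_map.tsv"),
                  utrs = inp("utrs.fasta"),
                  network = inp("network.tsv"),
                  terms = inp("terms.gmt"))
  } else paths <- config$inputs

  problems <- stage("validate", validate_inputs(paths))
  write_tsv(problems, res("validation.tsv"))
  if (any(problems$level == "error"))
    stop("pipeline stage 'validate' failed: ",
         paste(problems$message[problems$level == "error"], collapse = "; "))

  # -- differential expression ---------------------------------------------
  de <- stage("diffexpr", {
    tx <- run_de(read_expression_matrix(paths$transcript), config$thresholds)
    pr <- run_de(read_expression_matrix(paths$protein), config$thresholds)
    write_tsv(tx, res("de_transcript.tsv"))
    write_tsv(pr, res("de_protein.tsv"))
    list(tx = tx, pr = pr)
  })

  # -- integration ----------------------------------------------------------
  integ <- stage("integrate", {
    idm <- read_id_map(paths$id_map)
    m <- assign_groups(match_layers(de$tx, de$pr, idm))
    corr <- correlate_fold_changes(m)
    write_tsv(m, res("integrated.tsv"))
    write_tsv(group_report(m, "1"), res("group1_report.tsv"))
    list(table = m, corr = corr, sizes = attr(m, "group_sizes"))
  })

  # -- uORF -----------------------------------------------------------------
  uorf <- stage("uorf", {
    idm <- read_id_map(paths$id_map)
    uorfs <- scan_utrs(paths$utrs)
    feats <- uorf_gene_features(
      uorfs, idm[, c("transcript_id", "gene_id")])
    write_tsv(feats, res("uorf_features.tsv"))
    carriers <- summarize_carriers(feats)
    mc_for_group <- function(grp, k) {
      genes <- integ$table$gene_id[integ$table$group == grp]
      inside <- feats$carrier[match(genes, feats$gene_id)]
      inside <- inside[!is.na(inside)]
      if (length(inside) < 2L) return(NULL)
      monte_carlo_enrichment(sum(inside), length(inside),
                             carriers$frequency,
                             n_sims = config$mc$n_sims,
                             draws_per_sim = config$mc$draws_per_sim,
                             sd_rule = config$mc$sd_rule,
                             alpha = config$mc$alpha,
                             seed = child_seed(config$seed, 10L + k))
    }
    mc1 <- mc_for_group("1", 1L)
    mc2 <- mc_for_group("2", 2L)
    strip <- function(x) if (is.null(x)) NULL else x[setdiff(names(x), "per_sim_p")]
    jsonlite::write_json(list(carriers = carriers,
                              group1 = strip(mc1), group2 = strip(mc2)),
                         res("uorf_mc.json"), auto_unbox = TRUE, digits = NA)
    list(carriers = carriers, mc1 = mc1, mc2 = mc2)
  })

  # -- enrichment -----------------------------------------------------------
  enr <- stage("enrich", {
    terms <- read_gmt(paths$terms)
    universe <- intersect(unique(unlist(terms)), integ$table$gene_id)
    query <- intersect(integ$table$gene_id[integ$table$group == "2"],
                       universe)
    if (length(query)) {
      tab <- enrich_terms(query, terms, universe, alpha = config$enrich_alpha)
      tab <- group_terms(tab, terms, universe,
                         kappa_threshold = config$kappa_threshold)
    } else {
      tab <- data.frame()
    }
    write_tsv(tab, res("enrichment.tsv"))
    tab
  })

  # -- network --------------------------------------------------------------
  net <- stage("network", {
    background <- read_edge_list(paths$network)
    g2 <- integ$table$gene_id[integ$table$group == "2"]
    sub <- build_subnetwork(g2, background, config$score_cut)
    cliques <- if (igraph::vcount(sub))
      clique_refine(sub, config$inflation_schedule) else list()
    clique_tab <- do.call(rbind, lapply(seq_along(cliques), function(i)
      data.frame(clique_id = i, node = cliques[[i]]$nodes,
                 is_clique = cliques[[i]]$is_clique,
                 inflation = cliques[[i]]$inflation,
                 stringsAsFactors = FALSE)))
    if (is.null(clique_tab))
      clique_tab <- data.frame(clique_id = integer(), node = character(),
                               is_clique = logical(), inflation = numeric())
    write_tsv(clique_tab, res("cliques.tsv"))
    status <- integ$table$node_class
    names(status) <- integ$table$gene_id
    subnets <- lapply(Filter(function(x) x$is_clique, cliques), function(x)
      expand_first_neighbours(x$nodes, background, status))
    if (length(subnets)) {
      nn <- do.call(rbind, lapply(seq_along(subnets), function(i) {
        s <- subnets[[i]]
        data.frame(subnetwork = i,
                   node = names(s$node_classes),
                   class = unname(s$node_classes),
                   in_clique = names(s$node_classes) %in% s$clique,
                   stringsAsFactors = FALSE)
      }))
      write_tsv(nn, res("subnetwork_nodes.tsv"))
    }
    list(cliques = cliques, subnets = subnets)
  })

  # -- summary --------------------------------------------------------------
  summary <- list(
    seed = config$seed,
    de = list(
      transcript = as.list(attr(de$tx, "status_counts")),
      protein = as.list(attr(de$pr, "status_counts"))),
    groups = as.list(integ$sizes),
    correlation = integ$corr,
    uorf = list(
      carrier_percent = uorf$carriers$percent,
      n_carriers = uorf$carriers$n_carriers,
      n_genes = uorf$carriers$n_genes,
      group1 = if (!is.null(uorf$mc1))
        list(observed = uorf$mc1$observed, group_size = uorf$mc1$group_size,
             summary_p = uorf$mc1$summary_p,
             significant = uorf$mc1$significant),
      group2 = if (!is.null(uorf$mc2))
        list(observed = uorf$mc2$observed, group_size = uorf$mc2$group_size,
             summary_p = uorf$mc2$summary_p,
             significant = uorf$mc2$significant)),
    enrichment = list(
      n_tested = nrow(enr),
      n_significant = if (nrow(enr)) sum(enr$significant) else 0L,
      n_groups = if (nrow(enr) && "group_id" %in% names(enr))
        length(unique(enr$group_id)) else 0L),
    network = list(
      n_cliques = sum(vapply(net$cliques, `[[`, logical(1L), "is_clique")),
      n_flagged = sum(!vapply(net$cliques, `[[`, logical(1L), "is_clique"))))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
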