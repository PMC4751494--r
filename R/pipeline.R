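#' Assemble a pipeline configuration
#'
#' Inputs may be file paths (read with the package readers) or in-memory
#' objects; absent inputs cause the dependent stage to be skipped with a
#' warning.  Defaults carry the study's run parameters: miRNA DE at
#' FDR <= 0.01 and fold change >= 2 / <= 0.5, mRNA DE at FDR <= 0.05, an
#' abundance floor of 100 normalized counts, and 15 core miRNAs per
#' direction.
#'
#' @param mirna_counts,mrna_counts count tables (`count_matrix` or path).
#' @param mirna_meta,mrna_meta sample metadata paths when counts are
#'   paths.
#' @param mirna_fa,utr_fa mature miRNA / 3'UTR sequences (named vector or
#'   FASTA path).
#' @param gmt gene-set collection (`gene_set_collection` or GMT path).
#' @param ontology ontology edges (data.frame or TSV path).
#' @param panel list of cell-type matrices (`count_matrix` or paths).
#' @param alias optional feature alias map (named vector or 2-column TSV).
#' @param mirna_de_config,mrna_de_config [de_config()]s for the two
#'   contrasts.
#' @param enrich_alpha adjusted-p significance level for enrichment.
#' @param min_abundance,top_k network filters.
#' @param rank_window,min_similar specificity rank-similarity criteria.
#' @param out_dir output directory.
#' @param seed integer seed recorded in the manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mirna_counts, mrna_counts = NULL,
                            mirna_meta = NULL, mrna_meta = NULL,
                            mirna_fa = NULL, utr_fa = NULL, gmt = NULL,
                            ontology = NULL, panel = NULL, alias = NULL,
                            mirna_de_config = de_config(alpha = 0.01),
                            mrna_de_config = de_config(alpha = 0.05),
                            enrich_alpha = 0.05, min_abundance = 100,
                            top_k = 15, rank_window = 10,
                            min_similar = Inf,
                            out_dir = tempfile("mirnet_run_"), seed = 1) {
  cfg <- as.list(environment())
  for (f in c("mirna_counts", "mrna_counts", "mirna_fa", "utr_fa", "gmt",
              "ontology", "alias"))
    if (is.character(cfg[[f]]) && length(cfg[[f]]) == 1 &&
        !file.exists(cfg[[f]]))
      stop("input file not found: ", cfg[[f]])
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments (scalar values only); relative paths resolve against the
#'   file's directory.
#' @param ... overrides applied on top of the file values.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  for (f in c("mirna_counts", "mrna_counts", "mirna_meta", "mrna_meta",
              "mirna_fa", "utr_fa", "gmt", "ontology", "alias"))
    if (!is.null(vals[[f]]) && is.character(vals[[f]]))
      vals[[f]] <- file.path(dirname(path), vals[[f]])
  over <- list(...)
  vals[names(over)] <- over
  do.call(pipeline_config, vals)
}

resolve_counts <- function(x, meta) {
  if (inherits(x, "count_matrix")) x else read_count_table(x, meta)
}
resolve_seqs <- function(x) if (is.character(x) && length(x) == 1 &&
                                file.exists(x)) read_fasta(x) else x

#' Run the full integrated miRNA-mRNA analysis
#'
#' Stage order: miRNA differential expression, mRNA differential
#' expression, cross-cell-type specificity (skipped without a panel),
#' gene-set enrichment with ontology-tree summary (skipped without a
#' GMT), and regulatory-network construction (skipped without
#' sequences).  All tables and networks are written under
#' `config$out_dir`; a JSON manifest records parameters, filter counts
#' and output files per stage.
#'
#' @param config a [pipeline_config()].
#' @return the manifest list, invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("mirnet")),
                   seed = config$seed, started = format(Sys.time()),
                   stages = list())
  out <- list(manifest = manifest)
  note <- function(stage, rec) out$manifest$stages[[stage]] <<- rec

  ## -- differential expression ------------------------------------------
  mirna <- resolve_counts(config$mirna_counts, config$mirna_meta)
  de_mi <- run_de(mirna, config$mirna_de_config)
  mi_path <- file.path(config$out_dir, "de_mirna.tsv")
  write_de_table(de_mi, mi_path)
  note("de_mirna", list(
    n_features = nrow(de_mi),
    n_up = sum(de_mi$status == "up"), n_down = sum(de_mi$status == "down"),
    alpha = config$mirna_de_config$alpha,
    dispersion = attr(de_mi, "dispersion"), output = mi_path))
  out$de_mirna <- de_mi
  out$mirna_norm <- normalize_counts(mirna)

  de_mr <- NULL
  if (!is.null(config$mrna_counts)) {
    mrna <- resolve_counts(config$mrna_counts, config$mrna_meta)
    de_mr <- run_de(mrna, config$mrna_de_config)
    mr_path <- file.path(config$out_dir, "de_mrna.tsv")
    write_de_table(de_mr, mr_path)
    note("de_mrna", list(
      n_features = nrow(de_mr),
      n_up = sum(de_mr$status == "up"), n_down = sum(de_mr$status == "down"),
      alpha = config$mrna_de_config$alpha,
      dispersion = attr(de_mr, "dispersion"), output = mr_path))
    out$de_mrna <- de_mr
  } else note("de_mrna", list(skipped = "no mRNA counts supplied"))

  ## -- specificity -------------------------------------------------------
  if (!is.null(config$panel)) {
    panel <- lapply(config$panel, resolve_counts, meta = NULL)
    qn <- quantile_normalize(c(list(mirna), panel), alias = config$alias)
    hc <- hierarchical_cluster(qn, axis = "samples", center = "median")
    nwk_path <- file.path(config$out_dir, "panel_dendrogram.nwk")
    dendrogram_newick(hc, nwk_path)
    profiles <- lapply(colnames(qn), function(s)
      abundance_rank_profile(qn[, s], id = s))
    names(profiles) <- colnames(qn)
    opll_like <- samples(mirna)[1]
    rank_reports <- lapply(setdiff(colnames(qn), samples(mirna)),
                           function(s) compare_rank_profiles(
                             profiles[[opll_like]], profiles[[s]],
                             window = config$rank_window))
    specific <- define_specific_set(de_mi, overlaps = list(),
                                    rank_reports = rank_reports,
                                    min_similar = config$min_similar)
    sp_path <- file.path(config$out_dir, "specific_mirnas.txt")
    writeLines(specific, sp_path)
    note("specificity", list(
      n_panel_samples = ncol(qn) - ncol(mirna$counts),
      n_shared_features = nrow(qn), n_specific = length(specific),
      rank_window = config$rank_window, outputs = c(nwk_path, sp_path)))
    out$specific <- specific
    out$panel_normalized <- qn
  } else {
    warning("no cell-type panel supplied; specificity stage skipped")
    note("specificity", list(skipped = "no panel supplied"))
    out$specific <- c(de_features(de_mi, "up"), de_features(de_mi, "down"))
  }

  ## -- enrichment --------------------------------------------------------
  if (!is.null(config$gmt) && !is.null(de_mr)) {
    gmt <- if (inherits(config$gmt, "gene_set_collection")) config$gmt
           else read_gmt(config$gmt)
    universe <- de_mr$feature
    enr <- list()
    for (dir in c("up", "down")) {
      q <- de_features(de_mr, dir)
      if (length(q)) {
        enr[[dir]] <- enrich(q, gmt, universe, alpha = config$enrich_alpha)
        utils::write.table(enr[[dir]],
                           file.path(config$out_dir,
                                     sprintf("enrichment_%s.tsv", dir)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    tree_rec <- list()
    if (!is.null(config$ontology)) {
      edges <- if (is.character(config$ontology))
        read_ontology(config$ontology) else config$ontology
      sig <- lapply(enr, function(e) e$term[e$significant])
      in_onto <- unique(c(edges$child, edges$parent))
      tree <- build_go_tree(intersect(sig$up, in_onto),
                            intersect(sig$down, in_onto), edges)
      tree_path <- file.path(config$out_dir, "go_tree.graphml")
      write_go_tree(tree, tree_path)
      tree_rec <- list(n_tree_nodes = nrow(tree$nodes), tree_output = tree_path)
      out$go_tree <- tree
    }
    note("enrichment", c(list(
      n_terms_tested = if (length(enr)) nrow(enr[[1]]) else 0,
      n_significant_up = if (!is.null(enr$up)) sum(enr$up$significant) else 0,
      n_significant_down = if (!is.null(enr$down))
        sum(enr$down$significant) else 0,
      alpha = config$enrich_alpha), tree_rec))
    out$enrichment <- enr
  } else note("enrichment", list(skipped = "no gene sets or no mRNA DE"))

  ## -- network -----------------------------------------------------------
  if (!is.null(config$mirna_fa) && !is.null(config$utr_fa) &&
      !is.null(de_mr)) {
    mirna_seqs <- resolve_seqs(config$mirna_fa)
    utr_seqs <- resolve_seqs(config$utr_fa)
    pairs <- predict_targets(mirna_seqs, utr_seqs)
    admissible <- integrate_pairs(pairs, de_mi, de_mr, out$mirna_norm,
                                  min_abundance = config$min_abundance)
    nets <- list()
    for (dir in c("up", "down")) {
      core <- select_core_mirnas(de_mi, k = config$top_k, direction = dir,
                                 abundance = out$mirna_norm,
                                 min_abundance = config$min_abundance)
      net <- build_network(core, admissible)
      audit_network(net, mirna_seqs, utr_seqs, out$mirna_norm,
                    config$min_abundance)
      write_network(net, file.path(config$out_dir,
                                   sprintf("network_%s.graphml", dir)))
      write_network(net, file.path(config$out_dir,
                                   sprintf("network_%s.sif", dir)),
                    format = "sif")
      nets[[dir]] <- net
    }
    note("network", list(
      n_predicted_pairs = nrow(pairs), n_admissible = nrow(admissible),
      min_abundance = config$min_abundance, top_k = config$top_k,
      n_edges_up = nets$up$summary$n_edges,
      n_edges_down = nets$down$summary$n_edges))
    out$pairs <- pairs; out$admissible <- admissible; out$networks <- nets
  } else note("network", list(skipped = "no sequences or no mRNA DE"))

  out$manifest$finished <- format(Sys.time())
  jsonlite::write_json(out$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(out)
}

#' End-to-end demonstration on synthetic data
#'
#' Generates a synthetic study ([simulate_counts()],
#' [simulate_sequences()], [simulate_celltype_panel()],
#' [simulate_ontology()]), runs the full pipeline, and reports how well
#' the planted structure is recovered: directional DE power and
#' wrong-direction calls for miRNAs and genes, and precision/recall of
#' the planted regulatory pairs among those whose endpoints were
#' detected.
#'
#' @param seed integer seed for the generators.
#' @param config a [simulation_config()]; its seed is overridden by
#'   `seed`.
#' @param out_dir output directory.
#' @return list with `run` (pipeline outputs), `truth`, and `report`.
#' @export
run_demo <- function(seed = 1,
                     config = simulation_config(n_mirna = 60, n_gene = 150,
                                                frac_de = 0.2),
                     out_dir = tempfile("mirnet_demo_")) {
  config$seed <- as.integer(seed)
  sim <- simulate_counts(config)
  seqs <- simulate_sequences(config, sim$truth)
  panel <- simulate_celltype_panel(config)
  onto <- simulate_ontology(n_terms = 12, n_genes = config$n_gene,
                            seed = config$seed + 2L)
  pcfg <- pipeline_config(
    mirna_counts = sim$mirna, mrna_counts = sim$mrna,
    mirna_fa = seqs$mirna, utr_fa = seqs$utr,
    gmt = onto$gene_sets, ontology = onto$edges, panel = panel,
    out_dir = out_dir, seed = config$seed)
  run <- run_pipeline(pcfg)

  truth <- sim$truth
  recov <- function(de, truth_de) {
    called <- stats::setNames(de$status, de$feature)
    correct <- sum(called[truth_de$feature] == truth_de$direction)
    wrong <- sum(called[truth_de$feature] %in% c("up", "down") &
                   called[truth_de$feature] != truth_de$direction)
    list(n_planted = nrow(truth_de), n_correct = correct, n_wrong = wrong,
         power = if (nrow(truth_de)) correct / nrow(truth_de) else NA)
  }
  pair_key <- function(m, g) paste(m, g, sep = "->")
  truth_keys <- pair_key(truth$true_pairs$mirna, truth$true_pairs$gene)
  net_edges <- do.call(rbind, lapply(run$networks, function(n) n$edges))
  found_keys <- if (!is.null(net_edges) && nrow(net_edges))
    unique(pair_key(net_edges$mirna, net_edges$gene)) else character(0)
  mi_called <- stats::setNames(run$de_mirna$status, run$de_mirna$feature)
  mr_called <- stats::setNames(run$de_mrna$status, run$de_mrna$feature)
  mi_dir <- stats::setNames(truth$de_mirnas$direction, truth$de_mirnas$feature)
  mr_dir <- stats::setNames(truth$de_genes$direction, truth$de_genes$feature)
  endpoints_ok <-
    mi_called[truth$true_pairs$mirna] == mi_dir[truth$true_pairs$mirna] &
    mr_called[truth$true_pairs$gene] == mr_dir[truth$true_pairs$gene]
  ## restrict to pairs whose miRNA made the core set
  core_all <- unique(unlist(lapply(run$networks, function(n)
    n$nodes$id[n$nodes$kind == "miRNA"])))
  detectable <- truth_keys[endpoints_ok &
                             truth$true_pairs$mirna %in% core_all]
  report <- list(
    mirna_de = recov(run$de_mirna, truth$de_mirnas),
    gene_de = recov(run$de_mrna, truth$de_genes),
    n_true_pairs = length(truth_keys),
    n_detectable_pairs = length(detectable),
    n_recovered_pairs = length(intersect(found_keys, detectable)),
    n_spurious_pairs = length(setdiff(found_keys, truth_keys)),
    pair_precision = if (length(found_keys))
      mean(found_keys %in% truth_keys) else NA,
    pair_recall = if (length(detectable))
      mean(detectable %in% found_keys) else NA)
  jsonlite::write_json(report, file.path(out_dir, "recovery_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  list(run = run, truth = truth, report = report)
}
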