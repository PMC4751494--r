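#' Group-mean abundances of a normalized matrix
#' @param x a normalized `count_matrix` with group metadata.
#' @return feature x group matrix of group means.
#' @export
group_mean_abundance <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  vapply(group_levels(x), function(g)
    rowMeans(x$counts[, group_samples(x, g), drop = FALSE]),
    numeric(nrow(x$counts)))
}

#' Filter predicted pairs to inversely regulated, expressed pairs
#'
#' A predicted miRNA-gene pair is admitted to the network only when the
#' two members are regulated in opposite directions (miRNA up and gene
#' down, or miRNA down and gene up) and the miRNA is not lowly expressed
#' -- i.e. unless its group-mean normalized abundance is below
#' `min_abundance` in both groups.
#'
#' @param pairs data.frame from [predict_targets()].
#' @param mirna_de,gene_de classified DE tables.
#' @param mirna_abundance normalized miRNA `count_matrix` (group means are
#'   taken per group), or a precomputed feature x group matrix.
#' @param min_abundance abundance floor (default 100 normalized counts).
#' @return data.frame of admissible `target_pair` rows with expression
#'   columns (`mirna_status`, `gene_status`, `mirna_fold`, `gene_fold`).
#' @export
integrate_pairs <- function(pairs, mirna_de, gene_de, mirna_abundance,
                            min_abundance = 100) {
  if (!nrow(pairs)) return(annotate_pairs(pairs, mirna_de, gene_de))
  unknown_m <- setdiff(pairs$mirna, mirna_de$feature)
  unknown_g <- setdiff(pairs$gene, gene_de$feature)
  if (length(unknown_m) || length(unknown_g))
    stop("pairs reference unknown features: ",
         paste(c(unknown_m, unknown_g), collapse = ", "))
  ab <- if (inherits(mirna_abundance, "count_matrix"))
    group_mean_abundance(mirna_abundance) else mirna_abundance

  out <- annotate_pairs(pairs, mirna_de, gene_de)
  inverse <- (out$mirna_status == "up" & out$gene_status == "down") |
    (out$mirna_status == "down" & out$gene_status == "up")
  low <- apply(ab[out$mirna, , drop = FALSE] < min_abundance, 1, all)
  out[inverse & !low, , drop = FALSE]
}

annotate_pairs <- function(pairs, mirna_de, gene_de) {
  idx_m <- match(pairs$mirna, mirna_de$feature)
  idx_g <- match(pairs$gene, gene_de$feature)
  cbind(pairs,
        data.frame(mirna_status = mirna_de$status[idx_m],
                   gene_status = gene_de$status[idx_g],
                   mirna_fold = mirna_de$fold_change[idx_m],
                   gene_fold = gene_de$fold_change[idx_g],
                   stringsAsFactors = FALSE))
}

#' Select the top regulated core miRNAs
#'
#' Ranks DE miRNAs of one direction by fold change (largest first for up,
#' smallest first for down), breaking ties by smaller p-value and then by
#' id, optionally after the low-abundance filter.
#'
#' @param de classified miRNA DE table.
#' @param k number of core miRNAs (default 15; fewer returned when fewer
#'   qualify).
#' @param direction `"up"` or `"down"`.
#' @param abundance optional feature x group abundance matrix (or
#'   normalized `count_matrix`) used with `min_abundance` to drop lowly
#'   expressed miRNAs first.
#' @param min_abundance abundance floor when `abundance` is given.
#' @return character vector of miRNA ids, most extreme fold first.
#' @export
select_core_mirnas <- function(de, k = 15, direction = c("up", "down"),
                               abundance = NULL, min_abundance = 100) {
  direction <- match.arg(direction)
  cand <- de[de$status == direction, , drop = FALSE]
  if (!is.null(abundance)) {
    ab <- if (inherits(abundance, "count_matrix"))
      group_mean_abundance(abundance) else abundance
    low <- rownames(ab)[apply(ab < min_abundance, 1, all)]
    cand <- cand[!(cand$feature %in% low), , drop = FALSE]
  }
  key <- if (direction == "up") -cand$fold_change else cand$fold_change
  ord <- order(key, cand$p_value, cand$feature)
  utils::head(cand$feature[ord], k)
}

#' Build the bipartite miRNA-to-gene regulatory network
#'
#' Edges are the admissible pairs whose miRNA belongs to the core set;
#' core miRNAs with no admitted target are retained as degree-0 nodes.
#'
#' @param core character vector of core miRNA ids.
#' @param admissible data.frame from [integrate_pairs()].
#' @return a `regulatory_network`: `nodes` (id, kind, status), `edges`
#'   (the retained pairs) and `summary` (node/edge counts and the miRNA
#'   degree distribution).
#' @export
build_network <- function(core, admissible) {
  edges <- admissible[admissible$mirna %in% core, , drop = FALSE]
  genes <- unique(edges$gene)
  nodes <- data.frame(
    id = c(core, genes),
    kind = c(rep("miRNA", length(core)), rep("gene", length(genes))),
    status = c(edges$mirna_status[match(core, edges$mirna)],
               edges$gene_status[match(genes, edges$gene)]),
    stringsAsFactors = FALSE)
  deg <- table(factor(edges$mirna, levels = core))
  net <- structure(list(nodes = nodes, edges = edges,
                        summary = list(n_mirna = length(core),
                                       n_gene = length(genes),
                                       n_edges = nrow(edges),
                                       degree = deg)),
                   class = "regulatory_network")
  net
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d miRNAs, %d genes, %d edges\n",
              x$summary$n_mirna, x$summary$n_gene, x$summary$n_edges))
  invisible(x)
}

#' Re-validate every edge of a regulatory network
#'
#' Internal audit: checks bipartiteness, that each edge joins opposite DE
#' directions, that each edge's miRNA passes the abundance filter, and --
#' when sequences are supplied -- that a seed site of the recorded type is
#' actually present in the target UTR.
#'
#' @param net a [build_network()] result.
#' @param mirna_seqs,utr_seqs optional named sequence vectors for seed
#'   re-scanning.
#' @param mirna_abundance,min_abundance optional abundance re-check.
#' @return `TRUE` invisibly; stops with a message on any violation.
#' @export
audit_network <- function(net, mirna_seqs = NULL, utr_seqs = NULL,
                          mirna_abundance = NULL, min_abundance = 100) {
  e <- net$edges
  kind <- stats::setNames(net$nodes$kind, net$nodes$id)
  if (nrow(e)) {
    if (any(kind[e$mirna] != "miRNA") || any(kind[e$gene] != "gene"))
      stop("network is not bipartite miRNA -> gene")
    inverse <- (e$mirna_status == "up" & e$gene_status == "down") |
      (e$mirna_status == "down" & e$gene_status == "up")
    if (!all(inverse)) stop("edge with non-inverse regulation directions")
    if (!is.null(mirna_abundance)) {
      ab <- if (inherits(mirna_abundance, "count_matrix"))
        group_mean_abundance(mirna_abundance) else mirna_abundance
      if (any(apply(ab[e$mirna, , drop = FALSE] < min_abundance, 1, all)))
        stop("edge miRNA fails the abundance filter")
    }
    if (!is.null(mirna_seqs) && !is.null(utr_seqs)) {
      for (i in seq_len(nrow(e))) {
        s <- find_seed_sites(mirna_seqs[[e$mirna[i]]], utr_seqs[[e$gene[i]]])
        if (!nrow(s)) stop("edge ", e$mirna[i], " -> ", e$gene[i],
                           " has no seed site on re-scan")
      }
    }
  }
  invisible(TRUE)
}
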