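#!/usr/bin/env Rscript
# Functional enrichment of the DE genes: right-sided hypergeometric tests
# of the up- and down-regulated sets against the simulated ontology's
# gene sets (universe = all genes tested for DE), BH-corrected per
# direction, and the ontology-tree summary labelling each enriched term
# and its ancestors as up / down / ambiguous.

library(mirnet)

data_dir <- file.path("results", "data")
out_dir <- "results"

de_mr <- read_de_table(file.path(out_dir, "de_mrna.tsv"))
gmt <- read_gmt(file.path(data_dir, "ontology.gmt"))
edges <- read_ontology(file.path(data_dir, "ontology_edges.tsv"))
universe <- de_mr$feature

sig <- list()
for (dir in c("up", "down")) {
  query <- de_mr$feature[de_mr$status == dir]
  res <- enrich(query, gmt, universe, alpha = 0.05)
  write.table(res, file.path(out_dir, sprintf("enrichment_%s.tsv", dir)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig[[dir]] <- res$term[res$significant]
  cat(sprintf("%s genes (n = %d): %d/%d terms significant; best %s (p = %.2g)\n",
              dir, length(query), length(sig[[dir]]), nrow(res),
              res$term[1], res$p_value[1]))
}

tree <- build_go_tree(sig$up, sig$down, edges)
write_go_tree(tree, file.path(out_dir, "go_tree.graphml"))
write_go_tree(tree, file.path(out_dir, "go_tree.dot"), format = "dot")
cat(sprintf("Ontology tree: %d nodes (%s)\n", nrow(tree$nodes),
            paste(sprintf("%d %s", table(tree$nodes$label),
                          names(table(tree$nodes$label))), collapse = ", ")))
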