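#!/usr/bin/env Rscript
# The inverse-correlation regulatory network: canonical seed-match target
# prediction (8mer / 7mer-m8 / 7mer-A1) of every miRNA against every
# 3'UTR, filtering to pairs with opposite DE directions whose miRNA
# clears the abundance floor (100 normalized counts in at least one
# group), selection of the top-15 up- and down-regulated core miRNAs, and
# assembly + audit of the two bipartite networks, with a recovery check
# against the planted pairs.

library(mirnet)

data_dir <- file.path("results", "data")
out_dir <- "results"

mirna <- read_count_table(file.path(data_dir, "mirna_counts.tsv"),
                          file.path(data_dir, "mirna_meta.tsv"))
de_mi <- read_de_table(file.path(out_dir, "de_mirna.tsv"))
de_mr <- read_de_table(file.path(out_dir, "de_mrna.tsv"))
mirna_seqs <- read_fasta(file.path(data_dir, "mirna.fa"))
utr_seqs <- read_fasta(file.path(data_dir, "utrs.fa"))

norm <- normalize_counts(mirna)
pairs <- predict_targets(mirna_seqs, utr_seqs)
adm <- integrate_pairs(pairs, de_mi, de_mr, norm, min_abundance = 100)
cat(sprintf("%d predicted pairs; %d admissible after inverse-direction %s\n",
            nrow(pairs), nrow(adm), "and abundance filters"))

nets <- list()
for (dir in c("up", "down")) {
  core <- select_core_mirnas(de_mi, k = 15, direction = dir,
                             abundance = norm, min_abundance = 100)
  net <- build_network(core, adm)
  audit_network(net, mirna_seqs, utr_seqs, norm, min_abundance = 100)
  write_network(net, file.path(out_dir, sprintf("network_%s.graphml", dir)))
  write_network(net, file.path(out_dir, sprintf("network_%s.sif", dir)),
                format = "sif")
  cat(sprintf("core %s network: %d miRNAs, %d genes, %d edges\n",
              dir, net$summary$n_mirna, net$summary$n_gene,
              net$summary$n_edges))
  nets[[dir]] <- net
}

truth <- read.delim(file.path(data_dir, "truth_pairs.tsv"),
                    stringsAsFactors = FALSE)
truth_keys <- paste(truth$mirna, truth$gene)
got_keys <- unlist(lapply(nets, function(n) paste(n$edges$mirna,
                                                  n$edges$gene)))
cat(sprintf("planted-pair recovery: %d/%d recovered, %d spurious\n",
            length(intersect(got_keys, truth_keys)), length(truth_keys),
            length(setdiff(got_keys, truth_keys))))
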