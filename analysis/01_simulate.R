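#!/usr/bin/env Rscript
# Generate the synthetic study: a two-group (case/control, n = 3 vs 3)
# miRNA + mRNA count experiment with planted fold changes, mature-miRNA /
# 3'UTR sequences carrying planted seed sites, a multi-platform cell-type
# expression panel, and a small ontology with gene annotations.  All
# downstream analysis steps read these files back through the package
# readers, so this script defines the complete input contract.

library(mirnet)

data_dir <- file.path("results", "data")
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 1)   # defaults: 150 miRNA, 400 genes,
                                     # mean 200, phi 0.1, 10% DE at 4-fold
sim <- simulate_counts(cfg)
seqs <- simulate_sequences(cfg, sim$truth)
panel <- simulate_celltype_panel(cfg)
# concentrate the up-regulated genes on one term so the enrichment stage
# has a genuinely enriched function to find
up_genes <- sim$truth$de_genes$feature[sim$truth$de_genes$direction == "up"]
onto <- simulate_ontology(n_terms = 20, n_genes = cfg$n_gene,
                          seed = cfg$seed + 2L, concentrate = up_genes)

write_count_table(sim$mirna, file.path(data_dir, "mirna_counts.tsv"),
                  file.path(data_dir, "mirna_meta.tsv"))
write_count_table(sim$mrna, file.path(data_dir, "mrna_counts.tsv"),
                  file.path(data_dir, "mrna_meta.tsv"))
write_fasta(seqs$mirna, file.path(data_dir, "mirna.fa"))
write_fasta(seqs$utr, file.path(data_dir, "utrs.fa"))
write_gmt(onto$gene_sets, file.path(data_dir, "ontology.gmt"))
write_ontology(onto$edges, file.path(data_dir, "ontology_edges.tsv"))
for (ct in names(panel))
  write_count_table(panel[[ct]],
                    file.path(data_dir, sprintf("panel_%s.tsv", ct)))

truth <- sim$truth
write.table(truth$de_mirnas, file.path(data_dir, "truth_de_mirnas.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(truth$de_genes, file.path(data_dir, "truth_de_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(truth$true_pairs, file.path(data_dir, "truth_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(paste0(
  "Simulated %d miRNAs and %d genes (%d vs %d samples); planted %d DE\n",
  "miRNAs, %d DE genes and %d inverse miRNA->gene pairs; %d cell types.\n"),
  cfg$n_mirna, cfg$n_gene, cfg$n_per_group, cfg$n_per_group,
  nrow(truth$de_mirnas), nrow(truth$de_genes), nrow(truth$true_pairs),
  cfg$n_celltypes))
cat("Inputs written under", data_dir, "\n")
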