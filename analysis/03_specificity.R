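#!/usr/bin/env Rscript
# Cross-cell-type specificity of the DE miRNA signature: quantile
# normalization of the multi-platform panel, average-linkage clustering
# (samples should group by cell type despite platform distortion),
# rank-abundance profiles with top-k shares, rank-place comparison
# between the condition samples and the other cell types, and the
# resulting condition-specific miRNA set.  A directional-overlap report
# against the published two-contrast table illustrates the Venn step.

library(mirnet)

data_dir <- file.path("results", "data")
out_dir <- "results"

mirna <- read_count_table(file.path(data_dir, "mirna_counts.tsv"),
                          file.path(data_dir, "mirna_meta.tsv"))
de_mi <- read_de_table(file.path(out_dir, "de_mirna.tsv"))
panel_files <- list.files(data_dir, pattern = "^panel_", full.names = TRUE)
panel <- lapply(panel_files, read_count_table)
names(panel) <- sub("^panel_(.*)\\.tsv$", "\\1", basename(panel_files))

joined <- join_panel(c(list(case = mirna), panel))
qn <- quantile_normalize(joined)
hc <- hierarchical_cluster(log1p(qn), axis = "samples", center = "median")
dendrogram_newick(hc, file.path(out_dir, "panel_dendrogram.nwk"))

# shares come from each sample's own scale (quantile normalization would
# equalize them by construction); ranks are unchanged either way
profiles <- lapply(colnames(joined), function(s)
  abundance_rank_profile(joined[, s], s))
names(profiles) <- colnames(joined)
topk <- t(vapply(profiles, function(p)
  c(top11 = topk_share(p, min(11, nrow(p))),
    top25 = topk_share(p, min(25, nrow(p)))), numeric(2)))
write.table(data.frame(sample = rownames(topk), topk),
            file.path(out_dir, "topk_shares.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Top-11 miRNAs hold %.0f%%-%.0f%% of total abundance per sample\n",
            100 * min(topk[, "top11"]), 100 * max(topk[, "top11"])))

case_sample <- colnames(mirna$counts)[1]
other <- setdiff(colnames(qn), colnames(mirna$counts))
rank_reports <- lapply(other, function(s)
  compare_rank_profiles(profiles[[case_sample]], profiles[[s]], window = 10))
frac_dissimilar <- mean(!unlist(lapply(rank_reports, `[[`, "similar")))
cat(sprintf("%.0f%% of rank places shift by more than 10 in other cell types\n",
            100 * frac_dissimilar))

specific <- define_specific_set(de_mi, overlaps = list(),
                                rank_reports = rank_reports,
                                min_similar = length(other))
writeLines(specific, file.path(out_dir, "specific_mirnas.txt"))
cat(sprintf("%d of %d DE miRNAs are condition-specific by the rank criterion\n",
            length(specific), sum(de_mi$status != "not_significant")))

# directional Venn overlap on the published two-contrast status table
tab <- read.delim(system.file("extdata", "table1_mirna_de.tsv",
                              package = "mirnet"), stringsAsFactors = FALSE)
mk <- function(status) structure(
  data.frame(feature = tab$mirna, status = status, stringsAsFactors = FALSE),
  class = c("de_table", "data.frame"))
ov <- directional_overlap(mk(tab$status_opll_vs_pll),
                          mk(tab$status_msc_osteo_vs_msc))
print(ov)
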