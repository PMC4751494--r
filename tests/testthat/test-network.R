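test_that("seed extraction takes mature positions 2-8", {
  expect_identical(seed_of("UGAGGUAGUAGGUUGUAUAGUU"), "GAGGUAG")
  expect_identical(seed_of("ACGUACGU"), "CGUACGU")  # 8 nt: last 7
  expect_error(seed_of("ACGUACG"), "at least 8")
  expect_identical(rna_revcomp("GAGGUAG"), "CUACCUC")
})

test_that("site classification distinguishes 8mer, 7mer-m8 and 7mer-A1", {
  let7 <- "UGAGGUAGUAGGUUGUAUAGUU"
  s8 <- find_seed_sites(let7, "GGGCUACCUCAGGG")
  expect_equal(s8$site_type, "8mer")
  expect_equal(s8$start, 3); expect_equal(s8$end, 11)
  s7 <- find_seed_sites(let7, "GGGCUACCUCCGGG")
  expect_equal(s7$site_type, "7mer-m8")
  expect_equal(s7$end - s7$start, 7)
  # seed match to positions 2-7 plus A, without the m8 complement
  sA1 <- find_seed_sites(let7, "GGGGUACCUCAGGG")
  expect_equal(sA1$site_type, "7mer-A1")
  expect_equal(sA1$end - sA1$start, 7)
  expect_equal(nrow(find_seed_sites(let7, strrep("G", 40))), 0)
  # T-containing (DNA-alphabet) input is handled
  expect_equal(find_seed_sites("TGAGGTAGTAGGTTGTATAGTT",
                               "GGGCTACCTCAGGG")$site_type, "8mer")
})

test_that("site scan agrees with the exhaustive oracle on random draws", {
  set.seed(51)
  for (i in 1:100) {
    mir <- random_rna_str(22)
    utr <- random_rna_str(300)
    # embed the m7 complement occasionally so matches are not too rare
    if (i %% 2 == 0) {
      site <- paste0(as.character(Biostrings::reverseComplement(
        Biostrings::RNAString(substr(mir, 2, 8)))),
        sample(c("A", "C"), 1))
      pos <- sample(seq_len(300 - 8), 1)
      substr(utr, pos, pos + 7) <- site
    }
    got <- find_seed_sites(mir, utr)
    want <- oracle_seed_sites(mir, utr)
    expect_equal(got$site_type, want$site_type)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("target prediction recovers planted pairs exactly", {
  cfg <- simulation_config(n_mirna = 20, n_gene = 50, frac_de = 0.3,
                           seed = 52)
  sim <- simulate_counts(cfg)
  seqs <- simulate_sequences(cfg, sim$truth)
  pred <- predict_targets(seqs$mirna, seqs$utr)
  truth_keys <- paste(sim$truth$true_pairs$mirna, sim$truth$true_pairs$gene)
  expect_setequal(paste(pred$mirna, pred$gene), truth_keys)
  expect_true(all(pred$n_sites == cfg$n_planted_sites_per_target))
  tp <- sim$truth$true_pairs[match(paste(pred$mirna, pred$gene), truth_keys), ]
  expect_identical(pred$best_site_type, tp$site_type)
  expect_error(predict_targets(character(0), seqs$utr), "non-empty")
})

test_that("multiple sites collapse to one pair with the strongest type", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  utr <- paste0("GG", "CUACCUCC", "GGGG", "CUACCUCA", "GG")  # 7mer-m8 + 8mer
  pred <- predict_targets(c(m = mir), c(g = utr))
  expect_equal(nrow(pred), 1)
  expect_equal(pred$n_sites, 2)
  expect_equal(pred$best_site_type, "8mer")
})

test_that("pair integration keeps inverse, expressed pairs only", {
  pairs <- data.frame(mirna = c("m1", "m2", "m3", "m4"),
                      gene = c("g1", "g2", "g3", "g4"),
                      best_site_type = "8mer", n_sites = 1,
                      stringsAsFactors = FALSE)
  mirna_de <- toy_de_table(c("m1", "m2", "m3", "m4"),
                           c("up", "up", "down", "up"),
                           fold = c(4, 3, 0.2, 5))
  gene_de <- toy_de_table(c("g1", "g2", "g3", "g4"),
                          c("down", "up", "up", "down"),
                          fold = c(0.3, 2.5, 4, 0.1))
  ab <- matrix(c(500, 99, 150, 100, 20, 99, 80, 99), ncol = 2,
               dimnames = list(c("m1", "m2", "m3", "m4"), c("A", "B")))
  adm <- integrate_pairs(pairs, mirna_de, gene_de, ab, min_abundance = 100)
  # m2/g2 dropped (same direction), m2 also lowly expressed both groups;
  # m4 abundance 100 and 99 -> kept (strict "< 100 in both" reading)
  expect_setequal(adm$mirna, c("m1", "m3", "m4"))
  expect_identical(adm$gene_status[adm$mirna == "m1"], "down")
  low <- integrate_pairs(pairs[2, ], mirna_de, gene_de, ab)
  expect_equal(nrow(low), 0)
  expect_error(integrate_pairs(
    data.frame(mirna = "mX", gene = "g1", best_site_type = "8mer",
               n_sites = 1), mirna_de, gene_de, ab), "unknown")
})

test_that("core miRNA selection ranks by fold with p then id tie-breaks", {
  de <- toy_de_table(paste0("m", 1:6),
                     c("up", "up", "up", "down", "down", "not_significant"),
                     fold = c(10, 30, 30, 0.1, 0.4, 1),
                     p = c(1e-4, 1e-3, 1e-5, 1e-8, 1e-2, 0.5))
  expect_identical(select_core_mirnas(de, k = 2, direction = "up"),
                   c("m3", "m2"))  # equal folds: smaller p first
  expect_identical(select_core_mirnas(de, k = 10, direction = "down"),
                   c("m4", "m5"))  # ascending fold, fewer than k returned
  ab <- matrix(c(50, 500, 500, 500, 500, 500,
                 50, 500, 500, 500, 500, 500), ncol = 2,
               dimnames = list(paste0("m", 1:6), c("A", "B")))
  expect_identical(select_core_mirnas(de, k = 3, direction = "up",
                                      abundance = ab),
                   c("m3", "m2"))  # m1 fails the abundance floor
})

test_that("network construction is bipartite with audited edges", {
  adm <- data.frame(mirna = c("m1", "m2"), gene = c("g1", "g2"),
                    best_site_type = c("8mer", "7mer-A1"), n_sites = 1,
                    mirna_status = c("up", "down"),
                    gene_status = c("down", "up"),
                    mirna_fold = c(4, 0.2), gene_fold = c(0.3, 5),
                    stringsAsFactors = FALSE)
  net <- build_network("m1", adm)
  expect_equal(net$summary$n_edges, 1)
  expect_setequal(net$nodes$id, c("m1", "g1"))
  expect_silent(audit_network(net))
  # isolated core miRNA retained at degree 0
  net2 <- build_network(c("m1", "m9"), adm)
  expect_equal(unname(net2$summary$degree["m9"]), 0)
  expect_true("m9" %in% net2$nodes$id)
  # degree sum equals edge count on the miRNA side of the bipartite graph
  expect_equal(sum(net2$summary$degree), net2$summary$n_edges)
  empty <- build_network(c("m1", "m2"), adm[0, ])
  expect_equal(empty$summary$n_edges, 0)
  expect_silent(audit_network(empty))
  # tampered edge directions are caught
  bad <- net; bad$edges$gene_status <- "up"
  expect_error(audit_network(bad), "non-inverse")
})

test_that("synthetic networks recover planted pairs with perfect precision", {
  cfg <- simulation_config(n_mirna = 40, n_gene = 100, frac_de = 0.3,
                           fc_de = 4, baseline_mean = 200, dispersion = 0.1,
                           seed = 53)
  sim <- simulate_counts(cfg)
  seqs <- simulate_sequences(cfg, sim$truth)
  de_mi <- run_de(sim$mirna, de_config(alpha = 0.01))
  de_mr <- run_de(sim$mrna, de_config(alpha = 0.05))
  norm <- normalize_counts(sim$mirna)
  pairs <- predict_targets(seqs$mirna, seqs$utr)
  adm <- integrate_pairs(pairs, de_mi, de_mr, norm)
  core <- c(select_core_mirnas(de_mi, k = 100, direction = "up",
                               abundance = norm),
            select_core_mirnas(de_mi, k = 100, direction = "down",
                               abundance = norm))
  net <- build_network(core, adm)
  expect_silent(audit_network(net, seqs$mirna, seqs$utr, norm))
  truth_keys <- paste(sim$truth$true_pairs$mirna, sim$truth$true_pairs$gene)
  got_keys <- paste(net$edges$mirna, net$edges$gene)
  expect_true(all(got_keys %in% truth_keys))          # precision 1
  # recall limited only by DE detection of the endpoints
  mi_ok <- setNames(de_mi$status, de_mi$feature)
  mr_ok <- setNames(de_mr$status, de_mr$feature)
  mdir <- setNames(sim$truth$de_mirnas$direction, sim$truth$de_mirnas$feature)
  gdir <- setNames(sim$truth$de_genes$direction, sim$truth$de_genes$feature)
  tp <- sim$truth$true_pairs
  detectable <- truth_keys[mi_ok[tp$mirna] == mdir[tp$mirna] &
                             mr_ok[tp$gene] == gdir[tp$gene]]
  expect_setequal(got_keys, detectable)
})
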