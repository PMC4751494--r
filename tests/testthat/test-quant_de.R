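test_that("TPM follows the clean-total formula exactly", {
  m <- matrix(c(350L, 650L, 1000L, 0L), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  cm <- count_matrix(m)
  tpm <- compute_tpm(cm, clean_totals = c(s1 = 1000, s2 = 2000))
  expect_equal(tpm$counts["a", "s1"], 350000)
  expect_equal(tpm$counts["a", "s2"], 5e5)
  expect_equal(tpm$counts["b", "s2"], 0)
  # single feature holding all clean reads reaches 1e6
  one <- count_matrix(matrix(1000L, 1, 1, dimnames = list("a", "s")))
  expect_equal(compute_tpm(one, c(s = 1000))$counts[1, 1], 1e6)
  # column sums = mapped/clean * 1e6, never above 1e6
  expect_equal(unname(colSums(tpm$counts)),
               unname(colSums(m) / c(1000, 2000) * 1e6))
  expect_true(all(colSums(tpm$counts) <= 1e6))
  expect_error(compute_tpm(cm, c(s1 = 100, s2 = 2000)), "cannot be smaller")
  expect_error(compute_tpm(cm, c(s1 = 0, s2 = 2000)), "positive")
})

test_that("chromosome distribution averages per-sample fractions", {
  m <- matrix(c(50L, 50L, 30L, 70L), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  ann <- data.frame(chromosome = c("chr1", "chr2"),
                    row.names = c("a", "b"))
  cm <- count_matrix(m, groups = c(s1 = "g1", s2 = "g2"),
                     annotations = ann)
  d <- chromosome_distribution(cm)
  expect_equal(unname(d$per_sample[, "s1"]), c(0.5, 0.5))
  expect_equal(unname(colSums(d$per_sample)), c(1, 1))
  expect_equal(unname(d$group_means["chr1", ]), c(0.5, 0.3))
  zero <- count_matrix(matrix(0L, 2, 2, dimnames = dimnames(m)),
                       annotations = ann)
  expect_error(chromosome_distribution(zero), "all counts are zero")
  expect_error(chromosome_distribution(count_matrix(m)), "annotations")
})

test_that("TMM factors: identity, scale absorption, unit geometric mean", {
  m <- matrix(rep(c(10L, 20L, 400L, 5L), 2), 4,
              dimnames = list(paste0("f", 1:4), c("s1", "s2")))
  expect_equal(unname(tmm_factors(count_matrix(m))), c(1, 1))
  m2 <- cbind(m, s3 = 2L * m[, 1])
  expect_equal(unname(tmm_factors(count_matrix(m2))), c(1, 1, 1))
  set.seed(10)
  big <- matrix(rnbinom(500 * 4, mu = rep(exp(rnorm(500, 4, 1)), 4),
                        size = 10), 500,
                dimnames = list(paste0("f", 1:500), paste0("s", 1:4)))
  f <- tmm_factors(count_matrix(big))
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
})

test_that("TMM factors agree with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(42)
  counts <- matrix(rnbinom(2000 * 6, mu = rep(exp(rnorm(2000, 5, 1.5)), 6),
                           size = 5), 2000,
                   dimnames = list(paste0("f", 1:2000), paste0("s", 1:6)))
  counts[, 2] <- counts[, 2] * 2L
  expect_equal(unname(tmm_factors(count_matrix(counts))),
               unname(edgeR::calcNormFactors(counts, method = "TMM")),
               tolerance = 1e-10)
})

test_that("common dispersion is recovered by method of moments", {
  cfg <- simulation_config(n_mirna = 2000, n_gene = 10, n_per_group = 5,
                           dispersion = 0, frac_de = 0, baseline_mean = 100,
                           seed = 21)
  pois <- simulate_counts(cfg)$mirna
  expect_lt(estimate_common_dispersion(pois), 0.02)
  cfg$dispersion <- 0.1
  nb <- simulate_counts(cfg)$mirna
  est <- estimate_common_dispersion(nb)
  expect_gt(est, 0.05); expect_lt(est, 0.2)
  # constant counts within groups clamp at zero
  flat <- count_matrix(matrix(5L, 3, 4,
                              dimnames = list(paste0("f", 1:3),
                                              paste0("s", 1:4))),
                       groups = setNames(rep(c("a", "b"), each = 2),
                                         paste0("s", 1:4)))
  expect_equal(estimate_common_dispersion(flat), 0)
  solo <- count_matrix(matrix(5L, 3, 2,
                              dimnames = list(paste0("f", 1:3), c("x", "y"))),
                       groups = c(x = "a", y = "b"))
  expect_error(estimate_common_dispersion(solo), "replicates")
})

test_that("exact NB test matches binomial enumeration in the phi = 0 limit", {
  worst <- 0
  for (t in 1:50) for (a in 0:t) {
    worst <- max(worst, abs(exact_nb_test(a, t - a, 1, 1, 0) -
                              oracle_binom_p(a, t)))
  }
  expect_lt(worst, 1e-12)
})

test_that("exact NB test is symmetric, modal at even splits, flags t = 0", {
  expect_equal(exact_nb_test(5, 5, 1, 1, 0.1), 1)
  expect_equal(exact_nb_test(2, 9, 1, 1, 0.2),
               exact_nb_test(9, 2, 1, 1, 0.2))
  p0 <- exact_nb_test(0, 0, 1, 1, 0.1)
  expect_equal(as.numeric(p0), 1)
  expect_identical(attr(p0, "flagged"), "zero-total")
  # unequal sizes shift the null mode
  expect_gt(exact_nb_test(20, 10, 2, 1, 0), 0.5)
  expect_error(exact_nb_test(-1, 2, 1, 1, 0), "non-negative")
})

test_that("BH adjustment is step-up, order preserving and bounded below", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(1)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("classification uses inclusive fold and significance thresholds", {
  cfg <- de_config(alpha = 0.01)
  expect_equal(classify_de(c(630.71, 0.50, 1.5, 2.0, 3),
                           c(7.9e-36, 6.42e-3, 1e-9, 0.01, 0.02), cfg),
               c("up", "down", "not_significant", "up", "not_significant"))
})

test_that("run_de detects planted fold changes with accurate log2fc", {
  cfg <- simulation_config(n_mirna = 500, n_gene = 10, frac_de = 0.2,
                           fc_de = 4, dispersion = 0.1, baseline_mean = 200,
                           seed = 12)
  sim <- simulate_counts(cfg)
  de <- run_de(sim$mirna, de_config(alpha = 0.05))
  expect_equal(sum(de$status != "not_significant") +
                 sum(de$status == "not_significant"), nrow(de))
  truth <- sim$truth$de_mirnas
  called <- setNames(de$status, de$feature)
  expect_gte(mean(called[truth$feature] == truth$direction), 0.8)
  expect_equal(sum(called[truth$feature] %in% c("up", "down") &
                     called[truth$feature] != truth$direction), 0)
  lf <- setNames(de$log2fc, de$feature)
  err <- lf[truth$feature] - sim$truth$true_logfc$mirna[truth$feature]
  expect_lt(mean(abs(err)), 0.5)
  expect_error(run_de(sim$mirna, de_config(),
                      group_a = "case", group_b = "nope"))
})
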