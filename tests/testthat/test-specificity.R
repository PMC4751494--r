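test_that("quantile normalization reproduces order-statistic means", {
  m <- matrix(c(2, 4, 6, 1, 3, 5), ncol = 2)
  q <- quantile_normalize(m)
  expect_equal(q[, 1], c(1.5, 3.5, 5.5))
  expect_equal(q[, 2], c(1.5, 3.5, 5.5))
  # identical columns are left unchanged
  same <- matrix(c(1, 5, 9, 1, 5, 9), ncol = 2)
  expect_equal(quantile_normalize(same), same)
})

test_that("quantile normalization invariants hold on tie-free data", {
  set.seed(31)
  m <- matrix(rnorm(300), ncol = 3)
  q <- quantile_normalize(m)
  sorted <- apply(q, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-9)
  expect_lt(max(abs(colMeans(q) - mean(q))), 1e-9)
  expect_lt(max(abs(quantile_normalize(q) - q)), 1e-9)  # idempotent
  # ranks within each column are preserved
  for (j in 1:3) expect_identical(rank(q[, j]), rank(m[, j]))
})

test_that("quantile normalization matches the limma reference", {
  skip_if_not_installed("limma")
  set.seed(32)
  m <- matrix(rexp(400), ncol = 4)
  expect_equal(quantile_normalize(m), limma::normalizeQuantiles(m),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("panel joining restricts to shared features and applies aliases", {
  a <- matrix(1:4, 2, dimnames = list(c("x", "y"), c("s1", "s2")))
  b <- matrix(5:8, 2, dimnames = list(c("x_old", "z"), c("t1", "t2")))
  joined <- join_panel(list(a, b), alias = c(x_old = "x"))
  expect_identical(rownames(joined), "x")
  expect_identical(colnames(joined), c("s1", "s2", "t1", "t2"))
  expect_error(join_panel(list(a, b)), "no shared features")
})

test_that("average-linkage clustering follows hand-computed merge heights", {
  m <- matrix(c(0, 1, 10), nrow = 1, dimnames = list("f", c("a", "b", "c")))
  hc <- hierarchical_cluster(m, axis = "samples")
  expect_equal(hc$height, c(1, 9.5))
  # identical rows merge at height zero; heights never invert
  m2 <- rbind(p = c(1, 2, 9), q = c(1, 2, 9), r = c(5, 5, 5))
  colnames(m2) <- c("a", "b", "c")
  hc2 <- hierarchical_cluster(m2, axis = "features")
  expect_equal(hc2$height[1], 0)
  expect_true(all(diff(hc2$height) >= 0))
  expect_error(hierarchical_cluster(m[, 1, drop = FALSE], axis = "samples"),
               "at least 2")
})

test_that("median centering subtracts the row median", {
  m <- rbind(f1 = c(1, 2, 9), f2 = c(4, 4, 4))
  colnames(m) <- c("a", "b", "c")
  hc <- hierarchical_cluster(m, axis = "features", center = "median")
  # centered f1 = (-1, 0, 7), f2 = (0, 0, 0): distance sqrt(1 + 49)
  expect_equal(hc$height, sqrt(50))
  nwk <- dendrogram_newick(hierarchical_cluster(m, axis = "samples"))
  expect_match(nwk, "^\\(")
})

test_that("rank profiles carry descending shares and deterministic ranks", {
  x <- c(m2 = 100, m1 = 800, m4 = 50, m3 = 50)
  p <- abundance_rank_profile(x, id = "s1")
  expect_equal(p$share, c(0.8, 0.1, 0.05, 0.05))
  expect_equal(p$feature, c("m1", "m2", "m3", "m4"))  # tie broken by id
  expect_equal(p$rank, 1:4)
  expect_equal(sum(p$share), 1)
  expect_equal(topk_share(p, 1), 0.8)
  expect_equal(topk_share(p, 2), 0.9)
  expect_equal(topk_share(p, 4), 1.0)
  shares <- vapply(1:4, topk_share, numeric(1), profile = p)
  expect_true(all(diff(shares) >= 0))
  expect_error(topk_share(p, 5), "out of range")
  expect_error(abundance_rank_profile(c(a = 0, b = 0)), "positive")
})

test_that("topk_share is invariant to monotone platform distortion", {
  set.seed(33)
  x <- setNames(rexp(50, 1 / 100), paste0("m", 1:50))
  p <- abundance_rank_profile(x)
  pd <- abundance_rank_profile(2.5 * x^1.3)
  expect_identical(p$feature, pd$feature)   # same ranking
})

test_that("rank-profile comparison measures shifts within a window", {
  a <- abundance_rank_profile(c(x = 30, y = 20, z = 10))
  b <- abundance_rank_profile(c(x = 10, y = 20, z = 30))
  cmp <- compare_rank_profiles(a, b, window = 0)
  shifts <- setNames(cmp$shift, cmp$feature)
  expect_equal(unname(shifts[c("x", "y", "z")]), c(2, 0, 2))
  expect_equal(cmp$similar, cmp$shift == 0)
  same <- compare_rank_profiles(a, a, window = 0)
  expect_true(all(same$similar))
  expect_error(compare_rank_profiles(
    a, abundance_rank_profile(c(q = 1))), "no features")
})

test_that("directional overlap splits shared and specific DE features", {
  de_a <- toy_de_table(c("a", "b", "c", "d"), c("up", "up", "down", "down"))
  de_b <- toy_de_table(c("b", "c", "e"), c("up", "down", "up"))
  ov <- directional_overlap(de_a, de_b)
  expect_identical(ov$up_overlap, "b")
  expect_identical(ov$down_overlap, "c")
  expect_identical(ov$specific_up, "a")
  expect_identical(ov$specific_down, "d")
  disjoint <- directional_overlap(de_a, toy_de_table("z", "up"))
  expect_equal(unname(disjoint$counts[c("up_overlap", "down_overlap")]),
               c(0, 0))
})

test_that("specific set excludes overlaps and rank-similar features", {
  de <- toy_de_table(c("a", "b", "c"), c("up", "up", "down"))
  ov <- directional_overlap(de, toy_de_table("b", "up"))
  expect_identical(define_specific_set(de, list(ov)), c("a", "c"))
  expect_identical(define_specific_set(de, list()), c("a", "b", "c"))
  rr <- data.frame(feature = c("a", "c"), similar = c(TRUE, FALSE))
  expect_identical(define_specific_set(de, list(ov), list(rr),
                                       min_similar = 1), "c")
})

test_that("panel samples cluster by cell type after quantile normalization", {
  cfg <- simulation_config(n_mirna = 150, n_gene = 10, n_celltypes = 3,
                           n_per_group = 3, dispersion = 0.05,
                           platform_shift = 0.4, seed = 13)
  panel <- simulate_celltype_panel(cfg)
  qn <- quantile_normalize(lapply(panel, function(p) log1p(p$counts)))
  d <- as.matrix(dist(t(qn)))
  ct <- rep(names(panel), each = cfg$n_per_group)
  within <- d[outer(ct, ct, "==") & upper.tri(d)]
  between <- d[outer(ct, ct, "!=") & upper.tri(d)]
  expect_lt(max(within), min(between))
})
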