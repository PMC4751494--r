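#' Differential-expression configuration
#'
#' Thresholds follow the study design: features are called up when the
#' fold change is at least `fc_up` and the BH-adjusted p-value is at most
#' `alpha` (0.01 for miRNA, 0.05 for mRNA contrasts), down when the fold
#' change is at most `fc_down`; thresholds are inclusive.
#'
#' @param alpha significance level applied to the FDR (or raw p when
#'   `use_fdr = FALSE`).
#' @param fc_up,fc_down fold-change thresholds (defaults 2 and 0.5).
#' @param pseudocount added to each group mean before forming the ratio,
#'   so zero-expression groups yield large finite fold changes.
#' @param use_fdr filter on BH-adjusted p (default) or on raw p.
#' @param dispersion `"estimate"` (method of moments across features) or a
#'   fixed non-negative number.
#' @return a `de_config` list.
#' @export
de_config <- function(alpha = 0.01, fc_up = 2, fc_down = 0.5,
                      pseudocount = 0.5, use_fdr = TRUE,
                      dispersion = "estimate") {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  if (fc_up <= 1 || fc_down >= 1 || fc_down <= 0)
    stop("need fc_up > 1 and 0 < fc_down < 1")
  if (pseudocount <= 0) stop("`pseudocount` must be positive")
  if (is.numeric(dispersion) && dispersion < 0)
    stop("fixed dispersion must be non-negative")
  structure(list(alpha = alpha, fc_up = fc_up, fc_down = fc_down,
                 pseudocount = pseudocount, use_fdr = use_fdr,
                 dispersion = dispersion),
            class = "de_config")
}

#' Method-of-moments common dispersion
#'
#' Pools a negative-binomial dispersion estimate across features on
#' library-size-equalized counts: with per-feature within-group mean m and
#' variance v, Var = mu + phi*mu^2 gives phi = (v - m)/m^2; the common
#' estimate is the pooled ratio sum(v - m)/sum(m^2) over all replicated
#' groups, clamped at 0.
#'
#' @param x a raw `count_matrix` with group metadata.
#' @param factors optional TMM factors used to equalize library sizes.
#' @return non-negative dispersion estimate.
#' @export
estimate_common_dispersion <- function(x, factors = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  norm <- normalize_counts(x, factors)
  reps <- table(x$groups)
  if (all(reps < 2))
    stop("no group has replicates; use a fixed dispersion instead")
  num <- 0; den <- 0
  for (g in names(reps)[reps >= 2]) {
    sub <- norm$counts[, group_samples(x, g), drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    w <- ncol(sub) - 1
    ok <- m > 0
    num <- num + w * sum(v[ok] - m[ok])
    den <- den + w * sum(m[ok]^2)
  }
  if (den == 0) return(0)
  max(0, num / den)
}

#' Conditional negative-binomial exact test for a two-group count split
#'
#' Conditions on the total t = a + b.  Under the null the split follows
#' the distribution of one negative-binomial total against another with
#' means proportional to the effective library sizes: group A's term has
#' mean t * size_a / (size_a + size_b) and NB size n_a / phi (a pooled sum
#' of n_a replicates with dispersion phi has dispersion phi / n_a); phi = 0
#' is the binomial limit.  The two-sided p-value sums the probabilities of
#' all splits at most as probable as the observed one, capped at 1.
#'
#' @param count_a,count_b non-negative group total counts.
#' @param size_a,size_b positive effective library sizes.
#' @param phi common dispersion (>= 0).
#' @param n_a,n_b replicates pooled into each total (default 1).
#' @return p-value in (0, 1].
#' @export
exact_nb_test <- function(count_a, count_b, size_a, size_b, phi,
                          n_a = 1, n_b = 1) {
  if (count_a < 0 || count_b < 0) stop("counts must be non-negative")
  if (size_a <= 0 || size_b <= 0) stop("sizes must be positive")
  if (phi < 0) stop("`phi` must be non-negative")
  t <- round(count_a + count_b)
  if (t == 0) return(structure(1, flagged = "zero-total"))
  a <- round(count_a)
  pa <- size_a / (size_a + size_b)
  j <- 0:t
  if (phi == 0) {
    logp <- stats::dbinom(j, t, pa, log = TRUE)
  } else {
    logp <- stats::dnbinom(j, size = n_a / phi, mu = t * pa, log = TRUE) +
      stats::dnbinom(t - j, size = n_b / phi, mu = t * (1 - pa), log = TRUE)
    logp <- logp - log(sum(exp(logp - max(logp)))) - max(logp)
  }
  obs <- logp[a + 1]
  min(1, sum(exp(logp[logp <= obs + 1e-10])))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted values in the input order (each >= its raw p).
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Classify fold change and significance into up / down / not_significant
#'
#' @param fold_change positive fold changes (case over control).
#' @param stat FDR (or raw p) values to threshold.
#' @param config a [de_config()].
#' @return character vector of statuses; thresholds are inclusive.
#' @export
classify_de <- function(fold_change, stat, config = de_config()) {
  ifelse(stat <= config$alpha & fold_change >= config$fc_up, "up",
         ifelse(stat <= config$alpha & fold_change <= config$fc_down,
                "down", "not_significant"))
}

#' Two-group differential expression on a count matrix
#'
#' TMM-normalizes, estimates (or takes) a common dispersion, applies the
#' conditional NB exact test per feature on group totals, BH-adjusts, and
#' classifies with inclusive fold-change and significance thresholds.
#' Fold changes are ratios of group means of normalized counts with a
#' pseudocount added to each mean.
#'
#' @param x a raw `count_matrix` with exactly two groups.
#' @param config a [de_config()].
#' @param group_a,group_b numerator and denominator group labels; default
#'   to the first and second group in sample order.
#' @return data.frame of class `de_table` with columns `feature`,
#'   `fold_change`, `log2fc`, `p_value`, `fdr`, `status`, plus the
#'   dispersion used as attribute `dispersion`.
#' @export
run_de <- function(x, config = de_config(), group_a = NULL, group_b = NULL) {
  stopifnot(inherits(x, "count_matrix"), inherits(config, "de_config"))
  lv <- group_levels(x)
  if (length(lv) != 2) stop("exactly two groups are required")
  if (is.null(group_a)) group_a <- lv[1]
  if (is.null(group_b)) group_b <- lv[2]
  sa <- group_samples(x, group_a); sb <- group_samples(x, group_b)
  if (!length(sa) || !length(sb)) stop("each group needs at least 1 sample")

  factors <- tmm_factors(x)
  norm <- normalize_counts(x, factors)
  eff <- norm$effective_lib_sizes
  phi <- if (identical(config$dispersion, "estimate"))
    estimate_common_dispersion(x, factors) else config$dispersion

  tot_a <- rowSums(norm$counts[, sa, drop = FALSE])
  tot_b <- rowSums(norm$counts[, sb, drop = FALSE])
  ## counts are already on a common library scale, so the null split
  ## proportions are the replicate counts
  p <- vapply(seq_len(nrow(norm$counts)), function(i)
    exact_nb_test(tot_a[i], tot_b[i], length(sa), length(sb), phi,
                  n_a = length(sa), n_b = length(sb)),
    numeric(1))
  mean_a <- tot_a / length(sa)
  mean_b <- tot_b / length(sb)
  fold <- (mean_a + config$pseudocount) / (mean_b + config$pseudocount)
  fdr <- bh_adjust(p)
  stat <- if (config$use_fdr) fdr else p
  res <- data.frame(feature = features(x), fold_change = fold,
                    log2fc = log2(fold), p_value = p, fdr = fdr,
                    status = classify_de(fold, stat, config),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "dispersion") <- phi
  attr(res, "groups") <- c(group_a, group_b)
  class(res) <- c("de_table", "data.frame")
  res
}
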