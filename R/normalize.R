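#' TPM normalization of small-RNA counts
#'
#' Scales each sample's counts to transcripts per million clean reads:
#' `value[i, s] = counts[i, s] / clean_totals[s] * 1e6`.  The clean total
#' is the sequencing depth after read cleaning and is at least the mapped
#' total, so per-sample TPM sums never exceed 1e6.
#'
#' @param x a raw `count_matrix`.
#' @param clean_totals named numeric vector of per-sample total clean
#'   reads; defaults to the mapped column sums (so TPM columns sum to 1e6).
#' @return a `count_matrix` with `normalization = "TPM"` and the clean
#'   totals stored in `$clean_totals`.
#' @export
compute_tpm <- function(x, clean_totals = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  mapped <- colSums(x$counts)
  if (is.null(clean_totals)) clean_totals <- mapped
  if (is.null(names(clean_totals))) names(clean_totals) <- samples(x)
  clean_totals <- clean_totals[samples(x)]
  if (any(is.na(clean_totals)) || any(clean_totals <= 0))
    stop("clean totals must be positive for every sample")
  if (any(clean_totals < mapped))
    stop("clean totals cannot be smaller than mapped column sums (",
         paste(samples(x)[clean_totals < mapped], collapse = ", "), ")")
  tpm <- sweep(x$counts, 2, clean_totals, "/") * 1e6
  out <- count_matrix(tpm, groups = x$groups, annotations = x$annotations,
                      normalization = "TPM")
  out$clean_totals <- clean_totals
  out
}

#' Per-chromosome read distribution
#'
#' Fraction of mapped reads attributed to each chromosome, per sample,
#' with per-group averages -- the genome-wide read-distribution summary
#' used as a first look at global expression differences.
#'
#' @param x a `count_matrix` whose `annotations` contain a `chromosome`
#'   column.
#' @return list with `per_sample` (chromosome x sample fraction matrix,
#'   columns summing to 1) and, when groups are present, `group_means`.
#' @export
chromosome_distribution <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(x$annotations) || is.null(x$annotations$chromosome))
    stop("feature annotations with a `chromosome` column are required")
  chr <- x$annotations[features(x), "chromosome"]
  tot <- colSums(x$counts)
  if (all(tot == 0)) stop("all counts are zero; no reads to distribute")
  per_chr <- rowsum(x$counts, group = chr)
  frac <- sweep(per_chr, 2, tot, "/")
  out <- list(per_sample = frac)
  if (!is.null(x$groups)) {
    gm <- vapply(group_levels(x), function(g)
      rowMeans(frac[, group_samples(x, g), drop = FALSE]),
      numeric(nrow(frac)))
    out$group_means <- gm
  }
  out
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Between-library normalization for count data (Robinson & Oshlack): the
#' reference sample is the one whose 75th-percentile count rate is closest
#' to the mean across samples; each sample's factor is the precision-
#' weighted trimmed mean (30% trim on M, 5% on A) of log2 rate ratios
#' against the reference, over features expressed in both; factors are
#' rescaled to unit geometric mean.
#'
#' @param x a raw `count_matrix` (>= 2 samples, positive library sizes).
#' @param logratio_trim,sum_trim two-sided trim fractions on M and A.
#' @return named numeric vector of scaling factors, geometric mean 1.
#' @export
tmm_factors <- function(x, logratio_trim = 0.30, sum_trim = 0.05) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample needs a positive library size")
  f75 <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))

  one_factor <- function(j) {
    obs <- counts[, j]; r <- counts[, ref]
    keep <- obs > 0 & r > 0
    if (!any(keep))
      stop("sample ", colnames(counts)[j],
           " shares no expressed features with the reference")
    obs <- obs[keep]; r <- r[keep]
    nO <- lib[j]; nR <- lib[ref]
    M <- log2((obs / nO) / (r / nR))
    A <- (log2(obs / nO) + log2(r / nR)) / 2
    w <- (nO - obs) / (nO * obs) + (nR - r) / (nR * r)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    f <- sum(M[keep2] / w[keep2], na.rm = TRUE) /
      sum(1 / w[keep2], na.rm = TRUE)
    if (!is.finite(f)) f <- 0
    2^f
  }
  fac <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  stats::setNames(fac, colnames(counts))
}

#' Library-size normalized counts on a common scale
#'
#' Divides counts by the effective library size (raw library size times
#' the TMM factor) and rescales to the geometric-mean effective size, so
#' values remain on the scale of the original counts.
#'
#' @param x a raw `count_matrix`.
#' @param factors TMM factors; computed with [tmm_factors()] if `NULL`.
#' @return a `count_matrix` with `normalization = "TMM"`; effective
#'   library sizes in `$effective_lib_sizes`.
#' @export
normalize_counts <- function(x, factors = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(factors)) factors <- tmm_factors(x)
  eff <- colSums(x$counts) * factors[samples(x)]
  common <- exp(mean(log(eff)))
  norm <- sweep(x$counts, 2, common / eff, "*")
  out <- count_matrix(norm, groups = x$groups, annotations = x$annotations,
                      normalization = "TMM")
  out$effective_lib_sizes <- eff
  out
}
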