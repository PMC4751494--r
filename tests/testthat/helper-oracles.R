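# Independent brute-force oracles used by unit and acceptance tests.
# These deliberately avoid the code paths they check.

# two-sided minimum-likelihood binomial p-value by direct enumeration:
# the phi = 0 limit of the conditional NB exact test with equal sizes
oracle_binom_p <- function(a, t, prob = 0.5) {
  probs <- choose(t, 0:t) * prob^(0:t) * (1 - prob)^(t - (0:t))
  obs <- probs[a + 1]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# right-tail hypergeometric by explicit combinatorial summation
oracle_hyper_p <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# exhaustive substring scan for canonical seed sites, building patterns
# through Biostrings reverse-complementation (independent of rna_revcomp)
oracle_seed_sites <- function(mirna_seq, utr_seq) {
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::RNAString(x)))
  m7 <- rc(substr(mirna_seq, 2, 8))
  m6 <- rc(substr(mirna_seq, 2, 7))
  L <- nchar(utr_seq)
  sub <- function(p, w) substr(utr_seq, p, p + w - 1)
  rows <- list()
  for (p in seq_len(L)) {
    if (p + 7 <= L && sub(p, 8) == paste0(m7, "A")) {
      rows[[length(rows) + 1]] <- list("8mer", p - 1L, p + 7L)
    } else if (p + 6 <= L && sub(p, 7) == m7) {
      rows[[length(rows) + 1]] <- list("7mer-m8", p - 1L, p + 6L)
    } else if (p + 6 <= L && sub(p, 7) == paste0(m6, "A") &&
               !(p > 1 && sub(p - 1, 7) == m7)) {
      rows[[length(rows) + 1]] <- list("7mer-A1", p - 1L, p + 6L)
    }
  }
  if (!length(rows))
    return(data.frame(site_type = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(site_type = r[[1]], start = r[[2]], end = r[[3]],
               stringsAsFactors = FALSE)))
  df[order(df$start), , drop = FALSE]
}

random_rna_str <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                           replace = TRUE), collapse = "")

table1_path <- function() {
  system.file("extdata", "table1_mirna_de.tsv", package = "mirnet",
              mustWork = TRUE)
}

read_table1 <- function() {
  utils::read.delim(table1_path(), stringsAsFactors = FALSE)
}

# small helper: count_matrix from a plain matrix with two groups
toy_counts <- function(mat, groups = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("f", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  count_matrix(mat, groups = groups)
}

toy_de_table <- function(feature, status, fold = NULL, p = NULL) {
  n <- length(feature)
  structure(data.frame(feature = feature,
                       fold_change = if (is.null(fold)) rep(1, n) else fold,
                       p_value = if (is.null(p)) rep(1, n) else p,
                       status = status, stringsAsFactors = FALSE),
            class = c("de_table", "data.frame"))
}
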