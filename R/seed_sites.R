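## Canonical seed-match site prediction (TargetScan-style 8mer / 7mer-m8 /
## 7mer-A1).  Sequences are RNA strings 5'->3'; UTR coordinates are 0-based
## half-open.

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1")
SITE_STRENGTH <- c("8mer" = 3, "7mer-m8" = 2, "7mer-A1" = 1)

normalize_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' Reverse complement of an RNA string
#' @param x RNA string over A/C/G/U (T accepted and treated as U).
#' @return reverse complement, RNA alphabet.
#' @export
rna_revcomp <- function(x) {
  x <- normalize_rna(x)
  comp <- chartr("ACGUN", "UGCAN", x)
  vapply(strsplit(comp, NULL),
         function(ch) paste(rev(ch), collapse = ""), "")
}

#' Seed of a mature miRNA
#'
#' The seed is nucleotides 2-8 of the mature sequence (5'->3', 1-based
#' inclusive) -- the region whose Watson-Crick pairing with a 3'UTR defines
#' canonical target sites.
#'
#' @param mirna_sequence mature miRNA sequence, length >= 8.
#' @return 7-nt seed string.
#' @export
seed_of <- function(mirna_sequence) {
  s <- normalize_rna(mirna_sequence)
  if (nchar(s) < 8)
    stop("mature sequence must be at least 8 nt to have a seed")
  substr(s, 2, 8)
}

## all (including overlapping) occurrences; patterns are pure ACGUN
fixed_matches <- function(pattern, subject) {
  m <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Find canonical seed-match sites of one miRNA in one 3'UTR
#'
#' Site definitions (UTR sense strand, 5'->3'): with `m7` the reverse
#' complement of the seed (miRNA positions 2-8) and `m6` the reverse
#' complement of miRNA positions 2-7, a 7mer-m8 site is an occurrence of
#' `m7`; an 8mer is `m7` followed by `A`; a 7mer-A1 is `m6` followed by
#' `A`.  Overlapping classifications resolve to the strongest type
#' (8mer > 7mer-m8 > 7mer-A1): the m7 and m6+A matches inside an 8mer are
#' not reported separately.
#'
#' @param mirna_seq mature miRNA sequence (>= 8 nt).
#' @param utr_seq 3'UTR sequence.
#' @return data.frame with columns `site_type`, `start`, `end` (0-based
#'   half-open UTR coordinates); zero rows if no site.
#' @export
find_seed_sites <- function(mirna_seq, utr_seq) {
  utr <- normalize_rna(utr_seq)
  s <- normalize_rna(mirna_seq)
  m7 <- rna_revcomp(seed_of(s))
  m6a <- paste0(rna_revcomp(substr(s, 2, 7)), "A")

  hits7 <- fixed_matches(m7, utr)                       # 1-based starts
  sites <- data.frame(site_type = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (length(hits7)) {
    is8 <- substr(rep(utr, length(hits7)), hits7 + 7, hits7 + 7) == "A"
    sites <- data.frame(site_type = ifelse(is8, "8mer", "7mer-m8"),
                        start = hits7 - 1L,
                        end = hits7 - 1L + ifelse(is8, 8L, 7L),
                        stringsAsFactors = FALSE)
  }

  hitsA1 <- fixed_matches(m6a, utr)
  if (length(hitsA1)) {
    ## an m6+A immediately preceded by the m8 complement completes an m7
    ## match (always an 8mer, since the trailing A is present) that is
    ## already reported above -- drop it in favour of the stronger type
    inside <- vapply(hitsA1, function(p) p > 1 &&
                       substr(utr, p - 1, p + 5) == m7, logical(1))
    a1 <- hitsA1[!inside]
    if (length(a1))
      sites <- rbind(sites, data.frame(site_type = "7mer-A1",
                                       start = a1 - 1L, end = a1 + 6L,
                                       stringsAsFactors = FALSE))
  }
  sites[order(sites$start), , drop = FALSE]
}

## scan a UTR against a whole miRNA collection
find_seed_sites_all <- function(mirna_seqs, utr_seq) {
  out <- lapply(names(mirna_seqs), function(id) {
    s <- find_seed_sites(mirna_seqs[[id]], utr_seq)
    if (nrow(s)) cbind(mirna = id, s, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(mirna = character(0), site_type = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  out
}

#' Predict miRNA target genes by canonical seed matching
#'
#' Scans every (miRNA, UTR) combination and returns one candidate pair per
#' combination with at least one canonical site, recording the strongest
#' site type present and the number of sites.
#'
#' @param mirna_seqs named character vector of mature miRNA sequences.
#' @param utr_seqs named character vector of 3'UTR sequences (names = gene
#'   ids).
#' @return data.frame with columns `mirna`, `gene`, `best_site_type`,
#'   `n_sites`.
#' @export
predict_targets <- function(mirna_seqs, utr_seqs) {
  if (!length(mirna_seqs) || !length(utr_seqs))
    stop("need non-empty miRNA and UTR collections")
  rows <- list()
  for (g in names(utr_seqs)) {
    hits <- find_seed_sites_all(mirna_seqs, utr_seqs[[g]])
    if (!nrow(hits)) next
    for (m in unique(hits$mirna)) {
      h <- hits[hits$mirna == m, ]
      best <- h$site_type[which.max(SITE_STRENGTH[h$site_type])]
      rows[[length(rows) + 1L]] <-
        data.frame(mirna = m, gene = g, best_site_type = best,
                   n_sites = nrow(h), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(mirna = character(0), gene = character(0),
                      best_site_type = character(0), n_sites = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
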