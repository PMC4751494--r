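#' Configuration for the synthetic-data generators
#'
#' Defaults emulate a two-group small-RNA/mRNA study with three replicates
#' per group, negative-binomial counts with a common dispersion, and a
#' planted fraction of differentially expressed features whose fold change
#' mirrors the magnitude of real condition contrasts.
#'
#' @param n_mirna,n_gene number of miRNA / gene features.
#' @param n_per_group replicates per group (default 3, the study design).
#' @param baseline_mean expected count of a non-DE feature.
#' @param dispersion negative-binomial dispersion phi (Var = mu + phi*mu^2);
#'   0 gives Poisson counts.
#' @param frac_de fraction of features with a planted fold change.
#' @param fc_de fold change applied to planted features (up features are
#'   multiplied by `fc_de` in the case group, down features divided).
#' @param seed integer RNG seed; identical seeds give identical outputs.
#' @param utr_length length (nt) of simulated 3'UTRs.
#' @param n_planted_sites_per_target seed sites planted per target UTR.
#' @param n_celltypes cell types in the expression panel.
#' @param platform_shift magnitude of the monotone platform distortion
#'   applied to panel matrices (0 = none).
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_mirna = 150, n_gene = 400, n_per_group = 3,
                              baseline_mean = 200, dispersion = 0.1,
                              frac_de = 0.1, fc_de = 4, seed = 1,
                              utr_length = 200,
                              n_planted_sites_per_target = 1,
                              n_celltypes = 4, platform_shift = 0.3) {
  cfg <- list(n_mirna = n_mirna, n_gene = n_gene, n_per_group = n_per_group,
              baseline_mean = baseline_mean, dispersion = dispersion,
              frac_de = frac_de, fc_de = fc_de, seed = as.integer(seed),
              utr_length = utr_length,
              n_planted_sites_per_target = n_planted_sites_per_target,
              n_celltypes = n_celltypes, platform_shift = platform_shift)
  counts <- c("n_mirna", "n_gene", "n_per_group", "utr_length",
              "n_planted_sites_per_target", "n_celltypes")
  for (f in counts)
    if (cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop("`", f, "` must be a positive integer")
  if (baseline_mean <= 0) stop("`baseline_mean` must be positive")
  if (dispersion < 0) stop("`dispersion` must be non-negative")
  if (frac_de < 0 || frac_de > 1) stop("`frac_de` must be in [0, 1]")
  if (fc_de <= 0) stop("`fc_de` must be positive")
  if (platform_shift < 0) stop("`platform_shift` must be non-negative")
  class(cfg) <- "simulation_config"
  cfg
}

rnb <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu) else stats::rnbinom(n, size = 1 / phi, mu = mu)
}

## alternate up/down so both directions are always represented
de_directions <- function(n_de) {
  if (n_de == 0) character(0) else rep_len(c("up", "down"), n_de)
}

#' Simulate miRNA and mRNA count matrices with planted fold changes
#'
#' Counts are drawn feature-wise from a negative binomial with mean
#' `baseline_mean` and dispersion `dispersion`; a `frac_de` fraction of
#' features in each matrix carries a planted `fc_de` fold change in the
#' case group (alternating up/down).  Each planted DE gene is paired with a
#' planted DE miRNA of the opposite direction, yielding the ground-truth
#' regulatory pairs used downstream.
#'
#' @param config a [simulation_config()].
#' @return list with `mirna` and `mrna` [count_matrix()] objects (groups
#'   `case` / `control`) and `truth`, a list holding `de_mirnas`,
#'   `de_genes` (data.frames: feature, direction), `true_pairs`
#'   (data.frame: mirna, gene, site_type) and `true_logfc` (named log2
#'   fold-change vectors `mirna`, `gene`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  site_types <- c("8mer", "7mer-m8", "7mer-A1")

  sim_one <- function(prefix, n_feat) {
    ids <- sprintf("%s%04d", prefix, seq_len(n_feat))
    n_de <- round(config$frac_de * n_feat)
    dirs <- de_directions(n_de)
    fc <- rep(1, n_feat)
    fc[seq_len(n_de)] <- ifelse(dirs == "up", config$fc_de, 1 / config$fc_de)
    smp <- c(sprintf("case_%d", seq_len(config$n_per_group)),
             sprintf("control_%d", seq_len(config$n_per_group)))
    grp <- stats::setNames(rep(c("case", "control"),
                               each = config$n_per_group), smp)
    mu <- outer(config$baseline_mean * fc, as.numeric(grp == "case"), "*") +
      outer(rep(config$baseline_mean, n_feat), as.numeric(grp == "control"), "*")
    counts <- matrix(rnb(length(mu), as.vector(mu), config$dispersion),
                     nrow = n_feat, dimnames = list(ids, smp))
    list(mat = count_matrix(counts, groups = grp),
         de = data.frame(feature = ids[seq_len(n_de)], direction = dirs,
                         stringsAsFactors = FALSE),
         logfc = stats::setNames(log2(fc), ids))
  }

  mi <- sim_one("mir-", config$n_mirna)
  mr <- sim_one("gene", config$n_gene)

  pairs <- data.frame(mirna = character(0), gene = character(0),
                      site_type = character(0), stringsAsFactors = FALSE)
  if (nrow(mi$de) > 0 && nrow(mr$de) > 0) {
    up_mi <- mi$de$feature[mi$de$direction == "up"]
    dn_mi <- mi$de$feature[mi$de$direction == "down"]
    partner <- character(nrow(mr$de))
    used <- c(up = 0L, down = 0L)            # round-robin within each pool
    for (i in seq_len(nrow(mr$de))) {
      gd <- mr$de$direction[i]
      pool <- if (gd == "up") dn_mi else up_mi
      partner[i] <- if (length(pool))
        pool[used[gd] %% length(pool) + 1L] else NA
      used[gd] <- used[gd] + 1L
    }
    keep <- !is.na(partner)
    pairs <- data.frame(
      mirna = partner[keep], gene = mr$de$feature[keep],
      site_type = rep_len(site_types, sum(keep)), stringsAsFactors = FALSE)
  }

  list(mirna = mi$mat, mrna = mr$mat,
       truth = list(de_mirnas = mi$de, de_genes = mr$de, true_pairs = pairs,
                    true_logfc = list(mirna = mi$logfc, gene = mr$logfc)))
}

RNA_BASES <- c("A", "C", "G", "U")

random_rna <- function(n) paste(sample(RNA_BASES, n, replace = TRUE),
                                collapse = "")

#' Simulate mature miRNA and 3'UTR sequences consistent with the truth
#'
#' Each miRNA receives a random 22-nt RNA sequence with a seed (positions
#' 2-8) unique in the collection.  Every planted (miRNA, gene, site_type)
#' pair gets a site of exactly that type embedded in the gene's UTR;
#' all other UTR sequence -- and every non-target UTR -- is guaranteed free
#' of canonical sites (8mer, 7mer-m8, 7mer-A1) for every simulated miRNA,
#' by mutating any incidental match and re-scanning until clean.
#'
#' @param config a [simulation_config()].
#' @param truth the `truth` element returned by [simulate_counts()].
#' @return list with `mirna` and `utr`: named character vectors of RNA
#'   sequences.
#' @export
simulate_sequences <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$utr_length < 8)
    stop("`utr_length` must be at least 8 to host a seed site")
  bad <- setdiff(truth$true_pairs$site_type, SITE_TYPES)
  if (length(bad)) stop("unknown site_type: ", paste(bad, collapse = ", "))
  set.seed(config$seed + 1L)

  mirna_ids <- sprintf("mir-%04d", seq_len(config$n_mirna))
  seqs <- character(config$n_mirna)
  ## Seeds are sampled so that no miRNA's canonical match patterns (m7,
  ## m6+A) occur inside another miRNA's 8mer site string (m7+A, which also
  ## contains its 7mer-m8 and 7mer-A1 strings): a planted site can then
  ## never be a site for a second miRNA, keeping planted UTRs resolvable.
  m7s <- character(0); m6as <- character(0); site8s <- character(0)
  for (i in seq_len(config$n_mirna)) {
    repeat {
      s <- random_rna(22)
      m7 <- rna_revcomp(substr(s, 2, 8))
      m6a <- paste0(rna_revcomp(substr(s, 2, 7)), "A")
      s8 <- paste0(m7, "A")
      clash <- m7 == m6a ||     # degenerate seed: A1 string equals m7
        any(vapply(site8s, function(x)
        grepl(m7, x, fixed = TRUE) || grepl(m6a, x, fixed = TRUE),
        logical(1))) ||
        any(vapply(seq_along(m7s), function(j)
          grepl(m7s[j], s8, fixed = TRUE) || grepl(m6as[j], s8, fixed = TRUE),
          logical(1)))
      if (!clash) break
    }
    seqs[i] <- s
    m7s <- c(m7s, m7); m6as <- c(m6as, m6a); site8s <- c(site8s, s8)
  }
  names(seqs) <- mirna_ids

  ## any m7 or 6mer+A occurrence would be a canonical site for some miRNA
  pat7 <- vapply(seqs, function(s) rna_revcomp(substr(s, 2, 8)), "")
  pat6A <- vapply(seqs, function(s) paste0(rna_revcomp(substr(s, 2, 7)), "A"), "")
  all_pat <- unique(c(pat7, pat6A))

  scrub <- function(utr, protect = integer(0)) {
    ## mutate any canonical-site match outside protected ranges until clean
    for (iter in 1:200) {
      hit <- FALSE
      for (p in all_pat) {
        m <- gregexpr(p, utr, fixed = TRUE)[[1]]
        if (m[1] == -1) next
        for (st in m) {
          span <- st:(st + nchar(p) - 1)
          free <- setdiff(span, protect)
          if (!length(free)) next
          hit <- TRUE
          pos <- free[sample.int(length(free), 1)]
          old <- substr(utr, pos, pos)
          substr(utr, pos, pos) <- sample(setdiff(RNA_BASES, old), 1)
        }
      }
      if (!hit) return(utr)
    }
    stop("could not scrub UTR free of incidental seed sites")
  }

  site_string <- function(mirna_seq, type) {
    m7 <- rna_revcomp(substr(mirna_seq, 2, 8))
    switch(type,
           "8mer" = paste0(m7, "A"),
           "7mer-m8" = m7,
           "7mer-A1" = paste0(rna_revcomp(substr(mirna_seq, 2, 7)), "A"))
  }

  gene_ids <- sprintf("gene%04d", seq_len(config$n_gene))
  pair_by_gene <- split(truth$true_pairs, truth$true_pairs$gene)
  utrs <- character(config$n_gene)
  names(utrs) <- gene_ids
  for (g in gene_ids) {
    pr <- pair_by_gene[[g]]
    if (is.null(pr)) {                       # non-target: site-free
      utrs[g] <- scrub(random_rna(config$utr_length))
      next
    }
    n_sites <- config$n_planted_sites_per_target
    for (attempt in 1:100) {
      utr <- random_rna(config$utr_length)
      site <- site_string(seqs[[pr$mirna[1]]], pr$site_type[1])
      w <- nchar(site)
      slots <- seq(1, config$utr_length - w + 1, by = w + 1)
      if (length(slots) < n_sites)
        stop("`utr_length` too short for requested planted sites")
      starts <- sort(sample(slots, n_sites))
      protect <- integer(0)
      for (st in starts) {
        substr(utr, st, st + w - 1) <- site
        protect <- c(protect, st:(st + w - 1))
      }
      ## planting a 7mer-m8 must not be promoted to 8mer by a trailing A;
      ## planting a 7mer-A1 must not extend to m7 on the left
      utr <- scrub(utr, protect = protect)
      found <- find_seed_sites_all(seqs, utr)
      ok <- nrow(found) == n_sites &&
        all(found$mirna == pr$mirna[1]) &&
        all(found$site_type == pr$site_type[1])
      if (ok) break
      if (attempt == 100) stop("failed to plant sites in UTR for ", g)
    }
    utrs[g] <- utr
  }
  list(mirna = seqs, utr = utrs)
}

#' Simulate a multi-cell-type, multi-platform expression panel
#'
#' Each cell type has its own characteristic abundance ranking (a fixed
#' log-normal profile tied to the cell-type index, so rankings are stable
#' across simulation seeds); platforms apply a monotone power/scale
#' distortion so raw values differ across platforms while within-sample
#' rank structure is preserved.
#'
#' @param config a [simulation_config()] (`n_celltypes` >= 2).
#' @param n_platforms number of platforms cycled over cell types.
#' @return named list of `count_matrix` objects, one per cell type, each
#'   with a `platform` attribute.
#' @export
simulate_celltype_panel <- function(config, n_platforms = 2) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_celltypes < 2) stop("`n_celltypes` must be at least 2")
  ids <- sprintf("mir-%04d", seq_len(config$n_mirna))
  panel <- list()
  for (ct in seq_len(config$n_celltypes)) {
    set.seed(70000L + ct)                 # cell-type identity, seed-stable
    profile <- config$baseline_mean * exp(stats::rnorm(config$n_mirna, 0, 1.5))
    set.seed(config$seed + 100L + ct)     # sampling noise
    smp <- sprintf("ct%d_s%d", ct, seq_len(config$n_per_group))
    counts <- matrix(rnb(config$n_mirna * config$n_per_group,
                         rep(profile, config$n_per_group), config$dispersion),
                     nrow = config$n_mirna, dimnames = list(ids, smp))
    platform <- (ct - 1L) %% n_platforms + 1L
    exponent <- 1 + config$platform_shift * (platform - 1) * 0.5
    scale <- (1 + config$platform_shift)^(platform - 1)
    distorted <- scale * counts^exponent
    cm <- count_matrix(distorted,
                       groups = stats::setNames(rep(sprintf("celltype%d", ct),
                                                    length(smp)), smp),
                       normalization = if (config$platform_shift == 0)
                         "raw" else "platform-distorted")
    attr(cm, "platform") <- sprintf("platform%d", platform)
    panel[[sprintf("celltype%d", ct)]] <- cm
  }
  panel
}

#' Simulate a small rooted ontology DAG with gene annotations
#'
#' Terms form a single-rooted acyclic graph (each non-root term has one or
#' two parents among earlier terms).  Every term is annotated to at least
#' one gene directly, and annotations propagate to ancestors, so a term's
#' gene set always contains each child's gene set.
#'
#' @param n_terms number of terms (>= 2; first term is the root).
#' @param n_genes number of genes (must leave at least `n_terms`
#'   non-concentrated genes so every term can carry a direct annotation).
#' @param seed integer RNG seed.
#' @param concentrate optional character vector of gene ids whose direct
#'   annotation is placed on a single term (returned as
#'   `concentrated_term`), planting a genuinely enriched term for that
#'   gene group.
#' @return list with `edges` (data.frame child, parent), `gene_sets` (a
#'   `gene_set_collection` of propagated annotations), `direct` (named
#'   list of directly annotated genes per term) and `concentrated_term`
#'   (`NA` unless `concentrate` was given).
#' @export
simulate_ontology <- function(n_terms, n_genes, seed = 1,
                              concentrate = NULL) {
  if (n_terms < 2) stop("`n_terms` must be at least 2")
  set.seed(as.integer(seed))
  terms <- sprintf("T%03d", seq_len(n_terms))
  genes <- sprintf("gene%04d", seq_len(n_genes))
  concentrate <- intersect(concentrate, genes)
  free <- setdiff(genes, concentrate)
  if (length(free) < n_terms)
    stop("need at least `n_terms` non-concentrated genes")
  child <- character(0); parent <- character(0)
  for (i in 2:n_terms) {
    n_par <- if (i > 2 && stats::runif(1) < 0.3) 2L else 1L
    pars <- sample(seq_len(i - 1), min(n_par, i - 1))
    child <- c(child, rep(terms[i], length(pars)))
    parent <- c(parent, terms[pars])
  }
  edges <- data.frame(child = child, parent = parent, stringsAsFactors = FALSE)

  direct <- stats::setNames(vector("list", n_terms), terms)
  assign_term <- c(seq_len(n_terms),
                   sample(seq_len(n_terms), length(free) - n_terms,
                          replace = TRUE))
  for (i in seq_along(free))
    direct[[assign_term[i]]] <- c(direct[[assign_term[i]]], free[i])
  conc_term <- NA_character_
  if (length(concentrate)) {
    conc_term <- terms[n_terms]        # a late (leaf-like) term
    direct[[conc_term]] <- c(direct[[conc_term]], concentrate)
  }

  anc <- ontology_ancestors(edges)
  sets <- stats::setNames(vector("list", n_terms), terms)
  for (t in terms) {
    covered <- direct[[t]]
    for (s in terms)
      if (t %in% anc[[s]]) covered <- c(covered, direct[[s]])
    sets[[t]] <- sort(unique(covered))
  }
  list(edges = edges,
       gene_sets = gene_set_collection(sets,
                                       descriptions = stats::setNames(
                                         rep("synthetic term", n_terms), terms)),
       direct = direct, concentrated_term = conc_term)
}
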