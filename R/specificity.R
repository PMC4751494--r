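#' Join expression matrices from several platforms on shared features
#'
#' Features are matched by exact id after optional alias renaming (an
#' `old_id -> new_id` map harmonizing annotation releases); features
#' absent from any matrix are dropped rather than imputed.
#'
#' @param panel list of `count_matrix` objects or numeric matrices.
#' @param alias optional named character vector (names = old ids).
#' @return numeric matrix restricted to the shared features, columns from
#'   all panels in order.
#' @export
join_panel <- function(panel, alias = NULL) {
  mats <- lapply(panel, function(m) if (inherits(m, "count_matrix")) m$counts else m)
  if (!is.null(alias))
    mats <- lapply(mats, function(m) {
      hit <- rownames(m) %in% names(alias)
      rownames(m)[hit] <- alias[rownames(m)[hit]]
      m
    })
  shared <- Reduce(intersect, lapply(mats, rownames))
  if (!length(shared)) stop("no shared features across the panel")
  do.call(cbind, lapply(mats, function(m) m[shared, , drop = FALSE]))
}

#' Quantile normalization
#'
#' Classic order-statistic averaging: within each column values are
#' replaced by the across-column mean of the order statistics at their
#' rank, so all columns share an identical sorted vector; tied values
#' receive the mean of the quantile means their positions span.
#'
#' @param mat numeric matrix (>= 2 columns), or a list of matrices which
#'   is first joined on shared features via [join_panel()].
#' @param alias optional alias map passed to [join_panel()].
#' @return matrix of the same shape, quantile normalized.
#' @export
quantile_normalize <- function(mat, alias = NULL) {
  if (is.list(mat) && !is.data.frame(mat)) mat <- join_panel(mat, alias)
  if (inherits(mat, "count_matrix")) mat <- mat$counts
  if (ncol(mat) < 2) stop("quantile normalization needs >= 2 columns")
  target <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    vals <- target[rank(x, ties.method = "first")]
    out[, j] <- stats::ave(vals, x, FUN = mean)  # ties share their span mean
  }
  out
}

#' Average-linkage hierarchical clustering of features or samples
#'
#' Optional per-row median centering is applied first (rows = features);
#' rows with missing values are excluded.  Average linkage yields a
#' monotone dendrogram (no height inversions).
#'
#' @param mat numeric matrix or `count_matrix`.
#' @param axis cluster `"samples"` (columns) or `"features"` (rows).
#' @param center `"none"` or `"median"` (per-feature median centering).
#' @param metric `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @return an `hclust` object.
#' @export
hierarchical_cluster <- function(mat, axis = c("samples", "features"),
                                 center = c("none", "median"),
                                 metric = c("euclidean", "correlation")) {
  axis <- match.arg(axis); center <- match.arg(center)
  metric <- match.arg(metric)
  if (inherits(mat, "count_matrix")) mat <- mat$counts
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (center == "median")
    mat <- sweep(mat, 1, apply(mat, 1, stats::median), "-")
  items <- if (axis == "samples") t(mat) else mat
  if (nrow(items) < 2) stop("need at least 2 items to cluster")
  d <- if (metric == "euclidean") stats::dist(items)
       else stats::as.dist(1 - stats::cor(t(items)))
  stats::hclust(d, method = "average")
}

#' Export a dendrogram as a Newick string
#' @param hc an `hclust` object.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  nwk <- ape::write.tree(ape::as.phylo(hc))
  if (!is.null(path)) { writeLines(nwk, path); return(invisible(nwk)) }
  nwk
}

#' Rank-abundance profile of one sample or cell type
#'
#' Shares are each feature's fraction of the column's total abundance,
#' sorted descending; ranks are 1..n with ties broken lexicographically by
#' feature id, so profiles are deterministic.
#'
#' @param abundances named non-negative vector (TPM, intensity, counts).
#' @param id profile label.
#' @return a `rank_profile`: data.frame (feature, share, rank) sorted by
#'   rank, with attribute `id`.
#' @export
abundance_rank_profile <- function(abundances, id = "sample") {
  if (is.null(names(abundances))) stop("abundances must be named by feature")
  if (any(abundances < 0)) stop("abundances must be non-negative")
  total <- sum(abundances)
  if (total <= 0) stop("total abundance must be positive")
  ord <- order(-abundances, names(abundances))
  prof <- data.frame(feature = names(abundances)[ord],
                     share = unname(abundances[ord]) / total,
                     rank = seq_along(abundances),
                     stringsAsFactors = FALSE)
  structure(prof, id = id, class = c("rank_profile", "data.frame"))
}

#' Cumulative share of the top-k most abundant features
#' @param profile a [abundance_rank_profile()].
#' @param k number of top features, `1 <= k <= n`.
#' @return fraction of total abundance in the k most abundant features.
#' @export
topk_share <- function(profile, k) {
  stopifnot(inherits(profile, "rank_profile"))
  if (k < 1 || k > nrow(profile)) stop("`k` out of range")
  sum(profile$share[seq_len(k)])
}

#' Compare feature rank places between two profiles
#'
#' For each shared feature the absolute rank shift is computed; a feature
#' is called rank-similar when its shift is at most `window` places.
#'
#' @param profile_a,profile_b rank profiles (restricted to their shared
#'   features; ranks recomputed on the intersection).
#' @param window maximum rank distance still called similar (default 10).
#' @return data.frame (feature, rank_a, rank_b, shift, similar).
#' @export
compare_rank_profiles <- function(profile_a, profile_b, window = 10) {
  shared <- intersect(profile_a$feature, profile_b$feature)
  if (!length(shared)) stop("profiles share no features")
  rerank <- function(p) {
    p <- p[p$feature %in% shared, ]
    stats::setNames(rank(p$rank, ties.method = "first"), p$feature)
  }
  ra <- rerank(profile_a); rb <- rerank(profile_b)
  shift <- abs(ra[shared] - rb[shared])
  data.frame(feature = shared, rank_a = unname(ra[shared]),
             rank_b = unname(rb[shared]), shift = unname(shift),
             similar = unname(shift <= window), stringsAsFactors = FALSE)
}

de_features <- function(de, status) {
  if (inherits(de, "data.frame")) de$feature[de$status == status]
  else stop("expected a de_table data.frame")
}

#' Directional overlap of two differential-expression contrasts
#'
#' Features up (down) in both contrasts form the overlap; features DE in
#' the first contrast but not overlapping are contrast-specific.
#'
#' @param de_a,de_b classified DE tables (columns `feature`, `status`).
#' @return an `overlap_report` list: `up_overlap`, `down_overlap`,
#'   `specific_up`, `specific_down`, and `counts`.
#' @export
directional_overlap <- function(de_a, de_b) {
  up_a <- de_features(de_a, "up"); up_b <- de_features(de_b, "up")
  dn_a <- de_features(de_a, "down"); dn_b <- de_features(de_b, "down")
  up_overlap <- intersect(up_a, up_b)
  down_overlap <- intersect(dn_a, dn_b)
  rep <- list(up_overlap = up_overlap, down_overlap = down_overlap,
              specific_up = setdiff(up_a, up_overlap),
              specific_down = setdiff(dn_a, down_overlap))
  rep$counts <- vapply(rep, length, integer(1))
  class(rep) <- "overlap_report"
  rep
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(paste0("overlap_report: up overlap %d, down overlap %d, ",
                     "specific up %d, specific down %d\n"),
              x$counts["up_overlap"], x$counts["down_overlap"],
              x$counts["specific_up"], x$counts["specific_down"]))
  invisible(x)
}

#' Condition-specific DE features
#'
#' A DE feature is condition-specific unless it overlaps directionally
#' with any comparison contrast, or (optionally) keeps a similar rank
#' place in at least `min_similar` other cell types.
#'
#' @param de classified DE table for the condition contrast.
#' @param overlaps list of [directional_overlap()] reports (condition
#'   contrast first argument in each).
#' @param rank_reports optional list of [compare_rank_profiles()] outputs
#'   against other cell types.
#' @param min_similar number of rank-similar cell types that disqualifies
#'   a feature; `Inf` disables the rank criterion.
#' @return sorted character vector of specific feature ids.
#' @export
define_specific_set <- function(de, overlaps = list(), rank_reports = list(),
                                min_similar = Inf) {
  de_set <- c(de_features(de, "up"), de_features(de, "down"))
  shared <- unique(unlist(lapply(overlaps, function(o)
    c(o$up_overlap, o$down_overlap))))
  specific <- setdiff(de_set, shared)
  if (is.finite(min_similar) && length(rank_reports)) {
    sim_counts <- table(unlist(lapply(rank_reports, function(r)
      r$feature[r$similar])))
    too_similar <- names(sim_counts)[sim_counts >= min_similar]
    specific <- setdiff(specific, too_similar)
  }
  sort(specific)
}
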