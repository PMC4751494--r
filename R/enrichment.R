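#' Gene-set collection
#'
#' @param sets named list of character vectors (term id -> gene ids).
#' @param descriptions optional named character vector of term
#'   descriptions.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("term ids must be present and unique")
  if (any(vapply(sets, length, integer(1)) == 0))
    stop("empty gene sets are not allowed: ",
         paste(names(sets)[vapply(sets, length, integer(1)) == 0],
               collapse = ", "))
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, descriptions = descriptions[names(sets)]),
            class = "gene_set_collection")
}

#' Right-tail hypergeometric p-value
#'
#' P[X >= k] for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least k annotated genes when n genes are drawn without replacement
#' from a universe of N genes of which K carry the annotation.  Evaluated
#' through the log-space distribution function for numerical stability.
#'
#' @param k overlap between query and set.
#' @param K set size within the universe.
#' @param n query size.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @export
hypergeom_right_tail <- function(k, K, n, N) {
  if (K < 0 || K > N || n < 0 || n > N)
    stop("need 0 <= K <= N and 0 <= n <= N")
  if (k < 0 || k > min(K, n))
    stop("infeasible overlap k = ", k, " for K = ", K, ", n = ", n)
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' Tests each term for over-representation of the query in the universe by
#' a right-sided hypergeometric test; p-values are BH-adjusted across all
#' terms tested in the call, and a term is significant when its adjusted
#' p falls below `alpha` (strict).
#'
#' @param query character vector of gene ids (intersected with the
#'   universe).
#' @param collection a [gene_set_collection()].
#' @param universe background gene ids (conventionally all features tested
#'   for differential expression).
#' @param alpha significance level on the adjusted p-value.
#' @param min_set_size terms with fewer universe genes are skipped
#'   (default 2, avoiding degenerate single-gene hits).
#' @return data.frame sorted by p-value: `term`, `description`, `k`, `K`,
#'   `n`, `N`, `fold_enrichment`, `p_value`, `fdr`, `significant`.
#' @export
enrich <- function(query, collection, universe, alpha = 0.05,
                   min_set_size = 2) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(intersect(query, universe))
  if (!length(query)) stop("empty query (after restriction to universe)")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection$sets), function(term) {
    set <- intersect(collection$sets[[term]], universe)
    K <- length(set)
    if (K < min_set_size) return(NULL)
    k <- length(intersect(query, set))
    data.frame(term = term,
               description = unname(collection$descriptions[term]),
               k = k, K = K, n = n, N = N,
               fold_enrichment = (k / n) / (K / N),
               p_value = hypergeom_right_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no term passes the universe size filter")
  res$fdr <- bh_adjust(res$p_value)
  res$significant <- res$fdr < alpha
  res[order(res$p_value, res$term), , drop = FALSE]
}

## child -> all ancestors, from a child/parent edge table (assumed acyclic)
ontology_ancestors <- function(edges) {
  terms <- unique(c(edges$child, edges$parent))
  parents <- split(edges$parent, edges$child)
  anc <- stats::setNames(vector("list", length(terms)), terms)
  walk <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    ps <- parents[[t]]
    if (is.null(ps)) { anc[[t]] <<- character(0); return(character(0)) }
    res <- unique(c(ps, unlist(lapply(ps, walk))))
    anc[[t]] <<- res
    res
  }
  for (t in terms) walk(t)
  anc
}

#' Induce the ontology tree over enriched terms
#'
#' Builds the subgraph of the ontology spanned by the enriched terms and
#' all their ancestors, labelling each node by the direction of the gene
#' set in which it was enriched: `up`, `down`, `ambiguous` (both), or
#' `ancestor-only`.
#'
#' @param enriched_up,enriched_down character vectors of term ids.
#' @param ontology data.frame of edges (`child`, `parent`), acyclic.
#' @return a `go_tree` list: `nodes` (data.frame term, label) and `edges`
#'   (subgraph of the ontology among the nodes).
#' @export
build_go_tree <- function(enriched_up, enriched_down, ontology) {
  known <- unique(c(ontology$child, ontology$parent))
  missing <- setdiff(c(enriched_up, enriched_down), known)
  if (length(missing))
    stop("terms missing from the ontology: ", paste(missing, collapse = ", "))
  anc <- ontology_ancestors(ontology)
  enriched <- unique(c(enriched_up, enriched_down))
  nodes <- unique(c(enriched, unlist(anc[enriched])))
  label <- ifelse(nodes %in% enriched_up & nodes %in% enriched_down,
                  "ambiguous",
                  ifelse(nodes %in% enriched_up, "up",
                         ifelse(nodes %in% enriched_down, "down",
                                "ancestor-only")))
  sub <- ontology[ontology$child %in% nodes & ontology$parent %in% nodes, ,
                  drop = FALSE]
  structure(list(nodes = data.frame(term = nodes, label = label,
                                    stringsAsFactors = FALSE),
                 edges = sub),
            class = "go_tree")
}

#' Export a GO tree as GraphML or DOT
#' @param tree a [build_go_tree()] result.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @return the path, invisibly.
#' @export
write_go_tree <- function(tree, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  g <- igraph::graph_from_data_frame(
    tree$edges, directed = TRUE,
    vertices = data.frame(name = tree$nodes$term, label = tree$nodes$label,
                          stringsAsFactors = FALSE))
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    lines <- c("digraph go_tree {",
               sprintf('  "%s" [label="%s (%s)"];', tree$nodes$term,
                       tree$nodes$term, tree$nodes$label),
               sprintf('  "%s" -> "%s";', tree$edges$child, tree$edges$parent),
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}
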