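## Readers and writers for the plain-text formats the pipeline touches:
## count-matrix TSV (+ sample metadata), FASTA, GMT, ontology edge TSV,
## DE-result TSV, GraphML and SIF network exports.  All readers validate
## and report the offending record on malformed input.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a feature x sample count table with sample metadata
#'
#' The table is tab-separated with a header of sample ids and feature ids
#' in the first column; '#'-prefixed lines are ignored.  The metadata file
#' maps `sample<TAB>group` and must cover every sample.
#'
#' @param path count table TSV.
#' @param metadata_path sample metadata TSV (columns sample, group);
#'   `NULL` for an ungrouped matrix.
#' @param annotations_path optional TSV (feature, chromosome, ...).
#' @return a [count_matrix()] preserving the input sample order.
#' @export
read_count_table <- function(path, metadata_path = NULL,
                             annotations_path = NULL) {
  tab <- read_tsv_checked(path)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count entries in ", path)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative count at feature ", ids[neg[1, 1]], ", sample ",
         colnames(m)[neg[1, 2]])
  rownames(m) <- ids
  groups <- NULL
  if (!is.null(metadata_path)) {
    meta <- read_tsv_checked(metadata_path)
    groups <- stats::setNames(as.character(meta[[2]]), as.character(meta[[1]]))
  }
  annotations <- NULL
  if (!is.null(annotations_path)) {
    ann <- read_tsv_checked(annotations_path)
    annotations <- ann[, -1, drop = FALSE]
    rownames(annotations) <- as.character(ann[[1]])
  }
  raw <- all(m == round(m))
  count_matrix(m, groups = groups, annotations = annotations,
               normalization = if (raw) "raw" else "numeric")
}

#' Write a count matrix as TSV
#' @param x a `count_matrix` or numeric matrix.
#' @param path output file; first column `feature`, header = sample ids.
#' @param metadata_path optional path for a sample<TAB>group metadata TSV.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, metadata_path = NULL) {
  m <- if (inherits(x, "count_matrix")) x$counts else x
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path) && inherits(x, "count_matrix") &&
      !is.null(x$groups))
    utils::write.table(
      data.frame(sample = names(x$groups), group = unname(x$groups)),
      metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' Ids must be unique; `T`/`t` are mapped to `U` at parse time so that
#' miRNA/UTR matching is alphabet-agnostic downstream.
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- normalize_rna(as.character(set))
  if (any(nchar(seqs) == 0)) stop("empty sequence in ", path)
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in record ",
         paste(ids[bad], collapse = ", "))
  stats::setNames(seqs, ids)
}

#' Write sequences as FASTA (wrapped at 60 columns)
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Each line: term id, description, then one gene per field; lines with
#' fewer than three fields (no genes) are rejected.
#'
#' @param path GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3
  if (any(short))
    stop("GMT line with fewer than 3 fields: line ", which(short)[1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1)
  desc <- stats::setNames(vapply(fields, `[`, "", 2), names(sets))
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection as GMT
#' @param collection a [gene_set_collection()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(t)
    paste(c(t, collection$descriptions[[t]], collection$sets[[t]]),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read ontology parent edges (child<TAB>parent TSV)
#'
#' Validates acyclicity (reporting the terms on a cycle) and, by default,
#' that the ontology has a single root.
#'
#' @param path edge TSV with header.
#' @param require_single_root reject multi-root ontologies (default TRUE).
#' @return data.frame with columns `child`, `parent`.
#' @export
read_ontology <- function(path, require_single_root = TRUE) {
  tab <- read_tsv_checked(path)
  edges <- data.frame(child = as.character(tab[[1]]),
                      parent = as.character(tab[[2]]),
                      stringsAsFactors = FALSE)
  validate_ontology(edges, require_single_root)
  edges
}

validate_ontology <- function(edges, require_single_root = TRUE) {
  terms <- unique(c(edges$child, edges$parent))
  ## Kahn's algorithm; leftover terms lie on a cycle
  out_deg <- table(factor(edges$child, levels = terms))
  incoming <- split(edges$child, edges$parent)
  active <- stats::setNames(as.integer(out_deg), terms)
  queue <- names(active)[active == 0]
  seen <- character(0)
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]; seen <- c(seen, t)
    for (ch in incoming[[t]]) {
      active[ch] <- active[ch] - sum(edges$child == ch & edges$parent == t)
      if (active[ch] == 0) queue <- c(queue, ch)
    }
  }
  leftover <- setdiff(terms, seen)
  if (length(leftover))
    stop("ontology contains a cycle through: ",
         paste(sort(leftover), collapse = ", "))
  roots <- setdiff(terms, edges$child)
  if (require_single_root && length(roots) != 1)
    stop("ontology must have exactly one root; found: ",
         paste(sort(roots), collapse = ", "))
  invisible(TRUE)
}

#' Write ontology edges as child<TAB>parent TSV
#' @param edges data.frame (`child`, `parent`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(edges, path) {
  utils::write.table(edges[, c("child", "parent")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a regulatory network as GraphML or SIF
#'
#' GraphML carries a `kind` node attribute (miRNA / gene) and edge
#' attributes `site_type`, `mirna_direction`, `gene_direction`, ready for
#' network visualization tools.  The SIF dialect is
#' `mirna<TAB>targets<TAB>gene`, one edge per line.
#'
#' @param net a [build_network()] result.
#' @param path output file.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- if (nrow(net$edges))
      sprintf("%s\ttargets\t%s", net$edges$mirna, net$edges$gene)
    else character(0)
    writeLines(lines, path)
    return(invisible(path))
  }
  nodes <- net$nodes
  edf <- if (nrow(net$edges))
    data.frame(from = net$edges$mirna, to = net$edges$gene,
               site_type = net$edges$best_site_type,
               mirna_direction = net$edges$mirna_status,
               gene_direction = net$edges$gene_status,
               stringsAsFactors = FALSE)
  else data.frame(from = character(0), to = character(0))
  g <- igraph::graph_from_data_frame(
    edf, directed = TRUE,
    vertices = data.frame(name = nodes$id, kind = nodes$kind,
                          stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a DE table as TSV
#'
#' Fold changes are printed with two decimals (as in published DE tables);
#' p-values and FDRs keep scientific notation.
#'
#' @param de a `de_table` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  df <- data.frame(feature = de$feature,
                   fold_change = sprintf("%.2f", de$fold_change),
                   p_value = format(de$p_value, digits = 3),
                   fdr = format(de$fdr, digits = 3),
                   status = de$status, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DE table written by [write_de_table()] (or a compatible TSV)
#' @param path TSV with columns feature, fold_change, p_value, fdr, status.
#' @return a `de_table` data.frame.
#' @export
read_de_table <- function(path) {
  tab <- read_tsv_checked(path)
  need <- c("feature", "fold_change", "status")
  if (!all(need %in% names(tab)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  tab$fold_change <- as.numeric(tab$fold_change)
  if ("p_value" %in% names(tab)) tab$p_value <- as.numeric(tab$p_value)
  if ("fdr" %in% names(tab)) tab$fdr <- as.numeric(tab$fdr)
  class(tab) <- c("de_table", "data.frame")
  tab
}
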