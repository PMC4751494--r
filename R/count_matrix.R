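#' Feature-by-sample count matrix with group metadata
#'
#' The universal input container of the pipeline: an integer (raw) or
#' numeric (normalized) feature x sample matrix, a sample-to-group map, and
#' optional per-feature annotations (chromosome, gene symbol).
#'
#' @param counts numeric matrix with unique rownames (features) and unique
#'   colnames (samples); raw counts must be non-negative integers.
#' @param groups named character vector mapping every sample to a group
#'   label, or `NULL` when no group operations will be used.
#' @param annotations optional data.frame with rownames matching features
#'   and columns such as `chromosome` and `symbol`.
#' @param normalization label recording how values were scaled; `"raw"`
#'   for untransformed counts.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, groups = NULL, annotations = NULL,
                         normalization = "raw") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (identical(normalization, "raw") && any(counts != round(counts)))
    stop("raw counts must be integers")
  if (!is.null(groups)) {
    if (is.null(names(groups)))
      stop("`groups` must be named by sample id")
    missing <- setdiff(colnames(counts), names(groups))
    if (length(missing))
      stop("samples missing from group metadata: ",
           paste(missing, collapse = ", "))
    groups <- groups[colnames(counts)]
  }
  if (!is.null(annotations)) {
    if (!all(rownames(counts) %in% rownames(annotations)))
      stop("annotations must cover every feature")
    annotations <- annotations[rownames(counts), , drop = FALSE]
  }
  structure(
    list(counts = counts, groups = groups, annotations = annotations,
         normalization = normalization),
    class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts), x$normalization))
  if (!is.null(x$groups))
    cat("groups:", paste(sprintf("%s=%d", names(table(x$groups)),
                                 table(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

features <- function(x) rownames(x$counts)
samples <- function(x) colnames(x$counts)

#' Samples belonging to one group
#' @param x a `count_matrix` with group metadata.
#' @param group group label.
#' @return character vector of sample ids.
#' @export
group_samples <- function(x, group) {
  if (is.null(x$groups)) stop("count_matrix has no group metadata")
  names(x$groups)[x$groups == group]
}

group_levels <- function(x) {
  if (is.null(x$groups)) stop("count_matrix has no group metadata")
  unique(unname(x$groups))
}
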