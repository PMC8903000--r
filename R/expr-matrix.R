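#' Expression matrix with sample groups
#'
#' Lightweight container for a gene-by-sample count matrix of one biotype
#' (protein-coding, lncRNA or miRNA) together with the sample-to-group
#' assignment used throughout the pipeline (`NL` no labour, `EL` early
#' labour, `LL` late labour in the study design, but any labels work).
#'
#' @param counts non-negative integer matrix, genes in rows (rownames are
#'   gene ids), samples in columns (colnames are sample ids).
#' @param groups character or factor of group labels, one per sample;
#'   either named by sample id or in column order.
#' @param biotype one of `"coding"`, `"lncRNA"`, `"miRNA"`.
#' @return An object of class `expr_matrix`: a list with elements
#'   `counts`, `groups` (named factor) and `biotype`.
#' @examples
#' m <- matrix(rpois(20, 10), 5, 4,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' em <- expr_matrix(m, groups = c("NL", "NL", "LL", "LL"))
#' em
#' @export
expr_matrix <- function(counts, groups, biotype = c("coding", "lncRNA", "miRNA")) {
  biotype <- match.arg(biotype)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in counts")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (is.null(names(groups))) {
    if (length(groups) != ncol(counts))
      stop("groups must have one label per sample")
    names(groups) <- colnames(counts)
  }
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  groups <- factor(unname(groups[colnames(counts)]))
  names(groups) <- colnames(counts)
  structure(list(counts = counts, groups = groups, biotype = biotype),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d samples\n",
              x$biotype, nrow(x$counts), ncol(x$counts)))
  print(table(x$groups))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

# Accept either an expr_matrix or a bare counts matrix.
.as_counts <- function(x) {
  if (inherits(x, "expr_matrix")) x$counts else as.matrix(x)
}
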