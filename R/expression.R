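#' log2 counts-per-million
#'
#' Library-size normalisation used as the substrate of every downstream
#' statistic:
#' `log2((count + pseudocount) / (library size + 2 * pseudocount) * 1e6)`,
#' where the library size is the column sum of raw counts.
#'
#' @param x an [expr_matrix] or a genes-by-samples count matrix.
#' @param pseudocount added to each count (and twice to the library size)
#'   so zero counts stay finite. Default 0.5.
#' @return Numeric matrix of the same dimensions as the counts.
#' @examples
#' log_cpm(matrix(c(1, 1), 2, 1, dimnames = list(c("a", "b"), "s1")), 0)
#' @export
log_cpm <- function(x, pseudocount = 0.5) {
  counts <- .as_counts(x)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    bad <- colnames(counts)[lib == 0]
    stop("all-zero sample column(s): ", paste(bad, collapse = ", "))
  }
  log2(sweep(counts + pseudocount, 2, lib + 2 * pseudocount, "/") * 1e6)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, capped at 1, returned in the input order.
#' Thin validated front-end to [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric overrepresentation test
#'
#' Upper-tail probability of observing at least the realised overlap
#' between a hit list and a gene set, drawing `|hits|` genes without
#' replacement from the universe. Only the part of `gene_set` inside the
#' universe enters the test.
#'
#' @param hits character vector of selected genes (must be a subset of
#'   `universe`).
#' @param gene_set character vector, the annotated set being tested.
#' @param universe character vector of all testable genes.
#' @return list with `overlap`, `p` (P\[X >= overlap\]) and
#'   `enrichment_ratio` = (overlap/|hits|) / (|set in universe|/|universe|).
#' @examples
#' ora_hypergeometric(letters[1:5], letters[1:5], letters[1:10])$p  # 1/252
#' @export
ora_hypergeometric <- function(hits, gene_set, universe) {
  hits <- unique(hits); gene_set <- unique(gene_set); universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  if (length(hits) == 0) stop("empty hits")
  if (length(setdiff(hits, universe)))
    stop("hits must be a subset of the universe")
  set_u <- intersect(gene_set, universe)
  k <- length(intersect(hits, set_u))
  K <- length(set_u)
  N <- length(universe)
  n <- length(hits)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  ratio <- if (K == 0) NA_real_ else (k / n) / (K / N)
  list(overlap = k, p = p, enrichment_ratio = ratio)
}

#' Two-group differential expression on log-CPM
#'
#' Per-gene moderated Welch t-test between two sets of sample groups,
#' with BH adjustment and the fold-change/FDR call rule: a gene is `up`
#' or `down` only if `|log2FC| >= log2(fc_threshold)` and
#' `fdr <= fdr_threshold`, otherwise `unchanged`. Group variances are
#' shrunk towards the global median per-gene variance with weight
#' `shrink` before forming the Welch statistic; this stabilises the test
#' at the small group sizes of the study design (5 vs 11 after pooling
#' the two labouring groups).
#'
#' @param x an [expr_matrix].
#' @param groups_test,groups_ref character vectors of group labels forming
#'   the two sides of the contrast; e.g. `groups_test = c("EL","LL")`,
#'   `groups_ref = "NL"` for labour vs no-labour. log2FC is test minus ref.
#' @param fc_threshold fold-change call threshold on the natural scale
#'   (default 1.5, applied as `|log2FC| >= log2(1.5)`).
#' @param fdr_threshold FDR call threshold (default 0.05).
#' @param pseudocount passed to [log_cpm()].
#' @param shrink weight in \[0,1\] of the median-variance prior (default 0.1).
#' @return data.frame with columns `gene_id`, `log2_fold_change`, `raw_p`,
#'   `fdr`, `direction`, `degenerate` (TRUE where both groups had zero
#'   variance; such genes get p = 1 and are kept) and attribute
#'   `group_contrast`.
#' @export
differential_expression <- function(x, groups_test, groups_ref,
                                    fc_threshold = 1.5, fdr_threshold = 0.05,
                                    pseudocount = 0.5, shrink = 0.1) {
  stopifnot(inherits(x, "expr_matrix"))
  g <- as.character(x$groups)
  unknown <- setdiff(c(groups_test, groups_ref), unique(g))
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  ia <- which(g %in% groups_test)
  ib <- which(g %in% groups_ref)
  if (length(ia) < 2 || length(ib) < 2)
    stop("each side of the contrast needs at least 2 samples")
  lc <- log_cpm(x, pseudocount)
  a <- lc[, ia, drop = FALSE]
  b <- lc[, ib, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  degenerate <- va == 0 & vb == 0
  v0 <- stats::median((va + vb) / 2)
  va_s <- (1 - shrink) * va + shrink * v0
  vb_s <- (1 - shrink) * vb + shrink * v0
  se2 <- va_s / na + vb_s / nb
  tstat <- (ma - mb) / sqrt(se2)
  # Welch-Satterthwaite df on the shrunk variances
  df <- se2^2 / ((va_s / na)^2 / (na - 1) + (vb_s / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[degenerate] <- 1
  fdr <- bh_adjust(p)
  lfc <- ma - mb
  dir <- ifelse(abs(lfc) >= log2(fc_threshold) & fdr <= fdr_threshold,
                ifelse(lfc > 0, "up", "down"), "unchanged")
  dir[degenerate] <- "unchanged"
  out <- data.frame(gene_id = rownames(lc),
                    log2_fold_change = unname(lfc),
                    raw_p = unname(p),
                    fdr = unname(fdr),
                    direction = unname(dir),
                    degenerate = unname(degenerate),
                    stringsAsFactors = FALSE)
  attr(out, "group_contrast") <-
    paste(paste(groups_test, collapse = "+"), "vs",
          paste(groups_ref, collapse = "+"))
  out
}
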