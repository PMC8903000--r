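#' Panel z-score ranking of samples
#'
#' The labour-trajectory ("cigar plot") ordering: each panel gene is
#' z-scored across samples on log-CPM, each sample gets the mean z over
#' the panel, and samples are ranked 1 (lowest mean z) to n, with ties
#' broken by sample id.
#'
#' @param x an [expr_matrix].
#' @param panel character vector of panel gene ids (e.g. the 29-gene
#'   labour panel); all must be present. Zero-variance panel genes are
#'   dropped with a warning.
#' @param pseudocount passed to [log_cpm()].
#' @return data.frame `sample_id`, `mean_z`, `rank` (sorted by rank)
#'   with the per-gene z matrix in attribute `z`.
#' @export
panel_zscores <- function(x, panel, pseudocount = 0.5) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x$counts) < 2) stop("need at least 2 samples")
  panel <- unique(panel)
  missing <- setdiff(panel, rownames(x$counts))
  if (length(missing))
    stop("panel gene(s) missing: ", paste(missing, collapse = ", "))
  lc <- log_cpm(x, pseudocount)[panel, , drop = FALSE]
  sds <- apply(lc, 1, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance panel gene(s) dropped: ",
            paste(panel[sds == 0], collapse = ", "))
    lc <- lc[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(lc) == 0) {
    z <- matrix(0, 0, ncol(x$counts))
    mean_z <- stats::setNames(rep(0, ncol(x$counts)), colnames(x$counts))
  } else {
    z <- (lc - rowMeans(lc)) / sds
    mean_z <- colMeans(z)
  }
  ord <- order(mean_z, names(mean_z))
  out <- data.frame(sample_id = names(mean_z)[ord],
                    mean_z = unname(mean_z[ord]),
                    rank = seq_along(mean_z),
                    stringsAsFactors = FALSE)
  attr(out, "z") <- z
  out
}

#' Select low/middle/high samples from a panel ranking
#'
#' The sequencing-candidate selection: the `n_low` lowest-ranked and
#' `n_high` highest-ranked samples plus the `n_mid` samples closest to
#' the median rank (among samples not already taken). Defaults mirror
#' the 6 / 6 / 5 study selection.
#'
#' @param ranking output of [panel_zscores()].
#' @param n_low,n_high,n_mid set sizes (default 6, 6, 5).
#' @return list with character vectors `low`, `mid`, `high`.
#' @export
select_extremes <- function(ranking, n_low = 6, n_high = 6, n_mid = 5) {
  n <- nrow(ranking)
  if (n_low + n_mid + n_high > n)
    stop("requested more samples than available")
  ranking <- ranking[order(ranking$rank), ]
  low <- ranking$sample_id[seq_len(n_low)]
  high <- ranking$sample_id[seq(n - n_high + 1, length.out = n_high)]
  rest <- ranking[!(ranking$sample_id %in% c(low, high)), ]
  med <- stats::median(ranking$rank)
  mid <- rest$sample_id[order(abs(rest$rank - med), rest$sample_id)][seq_len(n_mid)]
  list(low = low, mid = sort(mid), high = high)
}
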