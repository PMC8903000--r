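#' Topologically associated domain interval set
#'
#' Validates and stores per-chromosome disjoint domain intervals in
#' 0-based half-open convention (as read from BED).
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`.
#' @return data.frame of class `tad_set`, sorted by chromosome and start.
#' @export
tad_set <- function(intervals) {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(intervals)))
    stop("intervals need columns chrom, start, end")
  intervals <- intervals[, req]
  if (any(intervals$end <= intervals$start)) {
    bad <- which(intervals$end <= intervals$start)[1]
    stop("malformed interval at line ", bad, ": end <= start")
  }
  intervals <- intervals[order(intervals$chrom, intervals$start), ]
  rownames(intervals) <- NULL
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, ]
    if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)]))
      stop("overlapping domains on ", ch)
  }
  class(intervals) <- c("tad_set", "data.frame")
  intervals
}

# strand-aware TSS (0-based position of the first transcribed base)
.gene_anchor <- function(annotation, anchor = c("tss", "midpoint")) {
  anchor <- match.arg(anchor)
  if (anchor == "tss") {
    ifelse(annotation$strand == "-", annotation$end - 1L, annotation$start)
  } else {
    floor((annotation$start + annotation$end - 1L) / 2)
  }
}

#' Localise genes relative to TADs
#'
#' Assigns each gene anchor (strand-aware TSS by default, or gene
#' midpoint) to a domain. Domain membership uses the half-open BED
#' convention `[start, end)`: an anchor at `start` is inside with
#' boundary distance 0; an anchor at `end` belongs to the gap that
#' follows. Inside a domain the distance is `min(anchor - start,
#' end - anchor)`; outside it is the negated distance to the nearest
#' domain edge (>= 1 by the half-open convention). Genes on chromosomes
#' with no domains are reported outside with `NA` distance and a warning.
#'
#' @param annotation data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (0-based half-open gene intervals).
#' @param tads a [tad_set()] (or data.frame coercible to one).
#' @param anchor `"tss"` (default) or `"midpoint"`.
#' @return data.frame with columns `gene_id`, `anchor`, `within_tad`,
#'   `boundary_distance`.
#' @export
localize_genes <- function(annotation, tads, anchor = c("tss", "midpoint")) {
  anchor <- match.arg(anchor)
  if (!inherits(tads, "tad_set")) tads <- tad_set(tads)
  pos <- .gene_anchor(annotation, anchor)
  n <- nrow(annotation)
  within <- logical(n)
  dist <- rep(NA_real_, n)
  no_tad_chroms <- character(0)
  for (ch in unique(annotation$chrom)) {
    gi <- which(annotation$chrom == ch)
    iv <- tads[tads$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0) {
      no_tad_chroms <- c(no_tad_chroms, ch)
      next
    }
    gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(pos[gi] + 1L,
                                                      pos[gi] + 1L))
    tr <- GenomicRanges::GRanges(ch, IRanges::IRanges(iv$start + 1L, iv$end))
    hit <- GenomicRanges::findOverlaps(gr, tr, select = "first")
    inside <- !is.na(hit)
    within[gi] <- inside
    p <- pos[gi]
    d <- rep(NA_real_, length(gi))
    d[inside] <- pmin(p[inside] - iv$start[hit[inside]],
                      iv$end[hit[inside]] - p[inside])
    if (any(!inside)) {
      edges <- c(iv$start, iv$end)
      d[!inside] <- -vapply(p[!inside],
                            function(a) min(abs(a - edges)), numeric(1))
      # half-open: position `end` itself is the first outside base
      d[!inside][d[!inside] == 0] <- -1
    }
    dist[gi] <- d
  }
  if (length(no_tad_chroms))
    warning("no domains on chromosome(s): ",
            paste(unique(no_tad_chroms), collapse = ", "),
            "; genes there reported outside with NA distance")
  data.frame(gene_id = annotation$gene_id, anchor = pos,
             within_tad = within, boundary_distance = dist,
             stringsAsFactors = FALSE)
}

#' Fraction of a gene subset located within a domain
#'
#' @param localizations output of [localize_genes()].
#' @param gene_subset non-empty character vector of gene ids.
#' @return proportion of the subset with `within_tad = TRUE`.
#' @export
within_fraction <- function(localizations, gene_subset) {
  if (length(gene_subset) == 0) stop("empty gene subset")
  idx <- match(unique(gene_subset), localizations$gene_id)
  if (all(is.na(idx)))
    stop("gene subset disjoint from localizations")
  mean(localizations$within_tad[idx[!is.na(idx)]])
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|`; two-sided p exact (via the distribution of
#' D under the permutation null) when `n_a * n_b <= 1e4` and the pooled
#' sample is tie-free, otherwise the asymptotic Kolmogorov distribution
#' with the standard effective sample size.
#'
#' @param sample_a,sample_b numeric vectors, each non-empty.
#' @return list with `D`, `p` and `exact` (logical).
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop("empty sample")
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  exact <- !ties && length(sample_a) * length(sample_b) <= 1e4
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b,
                                        alternative = "two.sided",
                                        exact = exact))
  list(D = unname(kt$statistic), p = unname(kt$p.value), exact = exact)
}

#' Non-random localization test for a gene module
#'
#' Compares the boundary-distance distribution of a module's genes
#' against pooled distances of size-matched random gene sets drawn from
#' the annotated universe excluding the module, with a two-sample KS
#' test. Also reports the within-domain fraction of each null draw so the
#' observed fraction can be placed on its null distribution.
#'
#' @param localizations output of [localize_genes()] for the full universe.
#' @param module_gene_ids character vector of module gene ids.
#' @param n_random genes per null draw (default: the module size).
#' @param n_reps number of null draws pooled into the reference sample
#'   (default 1000).
#' @param seed integer seed.
#' @return list with `D`, `p`, `observed_within`, `null_within`
#'   (per-replicate fractions) and `n_module`.
#' @export
localization_test <- function(localizations, module_gene_ids,
                              n_random = NULL, n_reps = 1000, seed = 1L) {
  idx <- match(unique(module_gene_ids), localizations$gene_id)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) stop("module genes not found in localizations")
  pool <- setdiff(seq_len(nrow(localizations)), idx)
  pool <- pool[!is.na(localizations$boundary_distance[pool])]
  if (is.null(n_random)) n_random <- length(idx)
  if (n_random > length(pool))
    stop("n_random exceeds the non-module universe")
  mod_d <- localizations$boundary_distance[idx]
  mod_d <- mod_d[!is.na(mod_d)]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draws <- replicate(n_reps, sample(pool, n_random), simplify = FALSE)
  null_d <- localizations$boundary_distance[unlist(draws)]
  null_within <- vapply(draws, function(i)
    mean(localizations$within_tad[i]), numeric(1))
  kt <- ks_two_sample(mod_d, null_d)
  list(D = kt$D, p = kt$p,
       observed_within = mean(localizations$within_tad[idx]),
       null_within = null_within,
       n_module = length(idx))
}
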