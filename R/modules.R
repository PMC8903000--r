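#' Detect co-expression modules by correlation tree cut
#'
#' Average-linkage hierarchical clustering of genes on the distance
#' `1 - |Pearson r|` over samples, cut at height
#' `1 - correlation_threshold`; clusters smaller than `min_module_size`
#' are folded into `"unassigned"`. Surviving modules are labelled
#' `M1, M2, ...` in decreasing size order.
#'
#' @param logexpr genes-by-samples numeric matrix (typically [log_cpm()]
#'   output). Genes with zero variance are dropped with a warning and
#'   reported as unassigned.
#' @param min_module_size smallest reportable module (default 30).
#' @param correlation_threshold absolute-correlation level of the tree cut
#'   (default 0.6).
#' @return Object of class `module_set`: list with `assignments` (named
#'   character, gene -> "M1"... or "unassigned"), `correlation_threshold`,
#'   `linkage` and `sizes`.
#' @export
detect_modules <- function(logexpr, min_module_size = 30,
                           correlation_threshold = 0.6) {
  logexpr <- as.matrix(logexpr)
  if (ncol(logexpr) < 4) stop("need at least 4 samples")
  if (is.null(rownames(logexpr))) stop("logexpr needs gene rownames")
  v <- apply(logexpr, 1, stats::var)
  assignments <- stats::setNames(rep("unassigned", nrow(logexpr)),
                                 rownames(logexpr))
  keep <- v > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance gene(s) dropped from clustering")
  expr <- logexpr[keep, , drop = FALSE]
  if (nrow(expr) < min_module_size) {
    warning("fewer than min_module_size genes; all unassigned")
  } else {
    d <- stats::as.dist(1 - abs(stats::cor(t(expr))))
    hc <- stats::hclust(d, method = "average")
    cl <- stats::cutree(hc, h = 1 - correlation_threshold)
    sizes <- table(cl)
    big <- names(sizes)[sizes >= min_module_size]
    # label by decreasing size, ties broken by first gene for determinism
    big <- big[order(-sizes[big], as.integer(big))]
    for (i in seq_along(big))
      assignments[names(cl)[cl == big[i]]] <- paste0("M", i)
  }
  mods <- setdiff(unique(assignments), "unassigned")
  structure(list(assignments = assignments,
                 correlation_threshold = correlation_threshold,
                 linkage = "average",
                 sizes = vapply(mods, function(m) sum(assignments == m),
                                integer(1))),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("module_set:", length(x$sizes), "modules (",
      paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "),
      "),", sum(x$assignments == "unassigned"), "unassigned\n")
  invisible(x)
}

#' Genes belonging to one module
#' @param modules a `module_set`.
#' @param module module label, e.g. `"M1"`.
#' @return character vector of gene ids.
#' @export
module_genes <- function(modules, module) {
  names(modules$assignments)[modules$assignments == module]
}

# Signed extremum of the weighted Kolmogorov-Smirnov running sum.
# ranked_values must already be sorted decreasing; hit increments are
# |value|/sum(|value| over hits), misses decrement 1/(N - |S|).
.es_running_sum <- function(sorted_abs, is_hit) {
  n <- length(sorted_abs)
  nh <- sum(is_hit)
  wsum <- sum(sorted_abs[is_hit])
  inc <- if (wsum > 0) sorted_abs / wsum else rep(1 / nh, n)
  step <- ifelse(is_hit, inc, -1 / (n - nh))
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}

#' GSEA running-sum enrichment of a gene set in a ranked list
#'
#' Weighted Kolmogorov-Smirnov statistic: genes are ranked by decreasing
#' value; walking down the list, members of the set add their normalised
#' |value| and non-members subtract `1/(N - |S|)`. ES is the signed
#' extremum of the running sum. NES divides ES by the mean |ES| of
#' size-matched random gene sets; the permutation p-value is the
#' fraction of permutations with |ES| at least as large, with +1
#' smoothing so it is never zero.
#'
#' @param ranked_values named numeric vector (gene-level statistic; sign
#'   and magnitude both matter).
#' @param gene_set character vector, a non-empty proper subset of the
#'   ranked genes.
#' @param nperm number of random-set permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @return list with `ES`, `NES`, `p`, and `running_sum` (for plotting).
#' @export
gsea_running_sum <- function(ranked_values, gene_set, nperm = 1000, seed = 1L) {
  if (is.null(names(ranked_values))) stop("ranked_values must be named")
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0) stop("empty gene set")
  if (length(setdiff(gene_set, names(ranked_values))))
    stop("gene_set must be a subset of the ranked genes")
  n <- length(ranked_values)
  nh <- length(gene_set)
  if (nh == n) stop("gene_set equals the full ranked list; miss weight undefined")
  ord <- order(ranked_values, decreasing = TRUE)
  vals <- abs(ranked_values[ord])
  hit <- names(ranked_values)[ord] %in% gene_set
  es <- .es_running_sum(vals, hit)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  es_perm <- vapply(seq_len(nperm), function(i) {
    h <- logical(n)
    h[sample.int(n, nh)] <- TRUE
    .es_running_sum(vals, h)
  }, numeric(1))
  nes <- es / mean(abs(es_perm))
  p <- (1 + sum(abs(es_perm) >= abs(es))) / (nperm + 1)

  # running sum retained for diagnostics
  wsum <- sum(vals[hit])
  step <- ifelse(hit, vals / wsum, -1 / (n - nh))
  list(ES = unname(es), NES = unname(nes), p = p,
       running_sum = cumsum(step))
}

#' Per-class module activity (net enrichment scores)
#'
#' For each sample class, genes are ranked by the class mean of their
#' z-scored log-CPM (standardised per gene across all samples) and each
#' module is scored with [gsea_running_sum()]. The resulting NES matrix
#' mirrors the module-by-class activity display of the study: positive
#' NES marks a class in which the module's genes sit high in the ranking.
#'
#' @param modules a `module_set`.
#' @param x an [expr_matrix] on the same gene universe.
#' @param nperm,seed passed to [gsea_running_sum()].
#' @param pseudocount passed to [log_cpm()].
#' @return data.frame with columns `module`, `class`, `NES`, `p`.
#' @export
module_activity <- function(modules, x, nperm = 1000, seed = 1L,
                            pseudocount = 0.5) {
  stopifnot(inherits(modules, "module_set"), inherits(x, "expr_matrix"))
  classes <- levels(x$groups)
  small <- classes[table(x$groups)[classes] < 2]
  if (length(small))
    stop("class with fewer than 2 samples: ", paste(small, collapse = ", "))
  lc <- log_cpm(x, pseudocount)
  common <- intersect(rownames(lc), names(modules$assignments))
  lc <- lc[common, , drop = FALSE]
  sds <- apply(lc, 1, stats::sd)
  keep <- sds > 0
  z <- (lc[keep, , drop = FALSE] - rowMeans(lc[keep, , drop = FALSE])) /
    sds[keep]
  mods <- names(modules$sizes)
  out <- do.call(rbind, lapply(classes, function(cl) {
    stat <- rowMeans(z[, x$groups == cl, drop = FALSE])
    do.call(rbind, lapply(seq_along(mods), function(i) {
      gs <- intersect(module_genes(modules, mods[i]), names(stat))
      r <- gsea_running_sum(stat, gs, nperm = nperm,
                            seed = seed + 7L * i + match(cl, classes))
      data.frame(module = mods[i], class = cl, NES = r$NES, p = r$p,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

# save/restore the RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
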