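#' Position weight matrix
#'
#' Builds a PWM from a 4-by-L count or probability matrix (rows A, C, G,
#' T). A pseudocount is added to every cell before column normalisation,
#' so zero counts never produce infinite log-odds.
#'
#' @param matrix 4-by-L numeric matrix with rownames A, C, G, T.
#' @param id motif identifier (e.g. a JASPAR accession).
#' @param name motif name (e.g. the TF symbol).
#' @param background length-4 base composition summing to 1 (default
#'   uniform).
#' @param pseudocount added per cell before normalisation (default 0.01).
#' @return Object of class `pwm` with normalised probability `matrix`,
#'   `background`, `id`, `name`, `pseudocount`.
#' @export
pwm <- function(matrix, id = "motif", name = id,
                background = rep(0.25, 4), pseudocount = 0.01) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (is.null(rownames(matrix))) rownames(matrix) <- c("A", "C", "G", "T")
  matrix <- matrix[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(matrix < 0)) stop("negative PWM entries")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  m <- sweep(matrix + pseudocount, 2, colSums(matrix) + 4 * pseudocount, "/")
  structure(list(id = id, name = name, matrix = m,
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s), length %d, consensus %s\n",
              x$id, x$name, ncol(x$matrix), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (most probable base per column)
#' @param x a [pwm].
#' @return character string of length L.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$matrix)[apply(x$matrix, 2, which.max)], collapse = "")
}

# log2-odds score matrix vs background
.pwm_logodds <- function(x) log2(x$matrix / x$background)

#' Reverse complement of a PWM
#' @param x a [pwm].
#' @return a [pwm] scoring the opposite strand.
#' @export
pwm_reverse_complement <- function(x) {
  m <- x$matrix[4:1, rev(seq_len(ncol(x$matrix))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  out <- x
  out$matrix <- m
  out$background <- x$background[4:1]
  out
}

#' Exact PWM score distribution by dynamic programming
#'
#' Distribution of the log2-odds score of a random word drawn from the
#' background model, computed by convolving per-position score
#' distributions on a discretised grid (default 0.01-bit bins; each cell
#' contribution is rounded to the grid before convolution, which is the
#' exactness limit of the method).
#'
#' @param x a [pwm].
#' @param bin bin width in bits (default 0.01).
#' @return list with `score` (bin values, ascending) and `prob`
#'   (probabilities summing to 1).
#' @export
pwm_score_distribution <- function(x, bin = 0.01) {
  lo <- round(.pwm_logodds(x) / bin)   # integer bin index per cell
  L <- ncol(lo)
  # running distribution as named-by-offset numeric vector
  probs <- 1
  offset <- 0L                         # bin index of probs[1]
  for (j in seq_len(L)) {
    col <- lo[, j]
    lo_min <- min(col); lo_max <- max(col)
    new <- numeric(length(probs) + (lo_max - lo_min))
    for (b in 1:4) {
      sh <- col[b] - lo_min
      idx <- seq_along(probs) + sh
      new[idx] <- new[idx] + probs * x$background[b]
    }
    probs <- new
    offset <- offset + lo_min
  }
  list(score = (seq_along(probs) - 1 + offset) * bin, prob = probs)
}

#' Score threshold for a PWM at a background p-value
#'
#' Smallest score whose upper-tail probability under the background model
#' is at most `p`, from [pwm_score_distribution()].
#'
#' @param x a [pwm].
#' @param p background tail probability (default 1e-4).
#' @param bin discretisation passed on.
#' @return numeric threshold in bits.
#' @export
pwm_score_threshold <- function(x, p = 1e-4, bin = 0.01) {
  d <- pwm_score_distribution(x, bin)
  tail <- rev(cumsum(rev(d$prob)))
  ok <- which(tail <= p)
  if (length(ok) == 0) return(Inf)
  d$score[min(ok)]
}

# encode an ACGTN string to integers 1..4 (NA for N/other)
.encode_seq <- function(s) {
  v <- utf8ToInt(toupper(s))
  code <- rep(NA_integer_, 128)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[v]
}

# score every window of length L on the encoded strand; NA where a
# window touches an unknown base
.scan_scores <- function(enc, lo) {
  L <- ncol(lo)
  nw <- length(enc) - L + 1
  if (nw < 1) return(numeric(0))
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    b <- enc[j:(j + nw - 1)]
    sc <- sc + lo[cbind(b, j)]
  }
  sc
}

#' Scan a sequence with a PWM
#'
#' Log2-odds scoring of every window on both strands; a hit is a window
#' whose score reaches the smallest score with background tail
#' probability <= `score_threshold_p` (exact DP threshold). Windows
#' containing N are skipped. Offsets are 0-based positions on the given
#' (plus) strand; minus-strand hits report the window's plus-strand
#' offset.
#'
#' @param sequence character string or `Biostrings::DNAString`.
#' @param x a [pwm].
#' @param score_threshold_p background p-value defining the hit threshold
#'   (default 1e-4).
#' @param threshold optional explicit score threshold overriding the DP
#'   computation (used to amortise the DP over many sequences).
#' @return data.frame with columns `offset`, `strand`, `score`.
#' @export
scan_pwm <- function(sequence, x, score_threshold_p = 1e-4, threshold = NULL) {
  s <- as.character(sequence)
  L <- ncol(x$matrix)
  if (nchar(s) < L) {
    warning("PWM longer than sequence; no hits")
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  if (is.null(threshold))
    threshold <- pwm_score_threshold(x, score_threshold_p)
  enc <- .encode_seq(s)
  fwd <- .scan_scores(enc, .pwm_logodds(x))
  rev <- .scan_scores(enc, .pwm_logodds(pwm_reverse_complement(x)))
  hf <- which(!is.na(fwd) & fwd >= threshold)
  hr <- which(!is.na(rev) & rev >= threshold)
  out <- data.frame(offset = c(hf, hr) - 1L,
                    strand = rep(c("+", "-"), c(length(hf), length(hr))),
                    score = c(fwd[hf], rev[hr]))
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Extract promoter sequences around TSS
#'
#' Strand-aware window of `upstream` bp before and `downstream` bp after
#' the TSS (the promoter definition used for the motif work: defaults
#' 10000/5000, with 1000/5000 available for the narrower convention).
#' Minus-strand windows are reverse-complemented so every promoter reads
#' 5' to 3'. Windows are truncated at chromosome edges.
#'
#' @param annotation data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param genome named character vector or `Biostrings::DNAStringSet`.
#' @param upstream,downstream window extents in bp.
#' @return `Biostrings::DNAStringSet` named by gene id, with a
#'   `coordinates` attribute (data.frame gene_id, chrom, start, end;
#'   0-based half-open plus-strand coordinates).
#' @export
extract_promoters <- function(annotation, genome, upstream = 10000,
                              downstream = 5000) {
  if (inherits(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else seqs <- genome
  missing <- setdiff(unique(annotation$chrom), names(seqs))
  if (length(missing))
    stop("genome lacks chromosome(s): ", paste(missing, collapse = ", "))
  tss <- .gene_anchor(annotation, "tss")
  out <- character(nrow(annotation))
  coords <- data.frame(gene_id = annotation$gene_id,
                       chrom = annotation$chrom,
                       start = NA_integer_, end = NA_integer_)
  for (i in seq_len(nrow(annotation))) {
    len <- nchar(seqs[[annotation$chrom[i]]])
    if (tss[i] < 0 || tss[i] >= len)
      stop("TSS beyond sequence end for gene ", annotation$gene_id[i])
    minus <- annotation$strand[i] == "-"
    if (!minus) {
      s <- max(0, tss[i] - upstream)
      e <- min(len, tss[i] + downstream)
    } else {
      s <- max(0, tss[i] - downstream + 1)
      e <- min(len, tss[i] + upstream + 1)
    }
    w <- substr(seqs[[annotation$chrom[i]]], s + 1, e)
    if (minus)
      w <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
    out[i] <- w
    coords$start[i] <- s; coords$end[i] <- e
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- annotation$gene_id
  attr(res, "coordinates") <- coords
  res
}

#' Count PWM hits per region
#'
#' Scans every region with every PWM once (thresholds computed once per
#' motif) and returns the hit-count matrix that feeds
#' [enrich_motifs()].
#'
#' @param regions `Biostrings::DNAStringSet` or named character vector.
#' @param pwms list of [pwm] objects.
#' @param score_threshold_p per-window background p-value (default 1e-4).
#' @return integer matrix, regions x motifs.
#' @export
count_hits <- function(regions, pwms, score_threshold_p = 1e-4) {
  seqs <- stats::setNames(as.character(regions), names(regions))
  ids <- vapply(pwms, `[[`, character(1), "id")
  out <- matrix(0L, length(seqs), length(pwms),
                dimnames = list(names(seqs), ids))
  encs <- lapply(seqs, .encode_seq)
  for (j in seq_along(pwms)) {
    thr <- pwm_score_threshold(pwms[[j]], score_threshold_p)
    lo_f <- .pwm_logodds(pwms[[j]])
    lo_r <- .pwm_logodds(pwm_reverse_complement(pwms[[j]]))
    for (i in seq_along(encs)) {
      if (length(encs[[i]]) < ncol(lo_f)) next
      f <- .scan_scores(encs[[i]], lo_f); r <- .scan_scores(encs[[i]], lo_r)
      out[i, j] <- sum(f >= thr, na.rm = TRUE) + sum(r >= thr, na.rm = TRUE)
    }
  }
  out
}

#' Background-subtracted motif enrichment Z-scores
#'
#' For each module and motif, the observed hit count over the module's
#' regions is compared to hit counts of size-matched region sets drawn
#' from the background regions: `z = (observed - mean(null)) / sd(null)`.
#' This subtracts the occurrence of motifs expected by chance; depleted
#' motifs carry negative z. Null sets are drawn with replacement: a
#' without-replacement null from a finite background pool would deflate
#' the null variance by the finite-population factor and inflate |z|.
#' The empirical two-sided p uses +1 smoothing and is BH-adjusted across
#' motifs within each module.
#'
#' @param hit_counts regions-by-motifs matrix from [count_hits()]
#'   covering both module and background regions.
#' @param module_regions named list: module label -> character vector of
#'   region (row) names.
#' @param background_regions character vector of row names forming the
#'   null pool.
#' @param n_shuffles null draws (default 1000).
#' @param seed integer seed.
#' @param region_class label recorded in the output (default "promoter").
#' @return data.frame with `motif_id`, `module`, `region_class`,
#'   `observed`, `expected`, `sd`, `z`, `p`, `adj_p`, `degenerate`.
#' @export
enrich_motifs <- function(hit_counts, module_regions, background_regions,
                          n_shuffles = 1000, seed = 1L,
                          region_class = "promoter") {
  if (length(background_regions) == 0) stop("no background regions")
  bad <- setdiff(unlist(module_regions), rownames(hit_counts))
  if (length(bad))
    stop("module region(s) missing from hit_counts: ",
         paste(utils::head(bad, 5), collapse = ", "))
  bg <- hit_counts[background_regions, , drop = FALSE]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  out <- lapply(names(module_regions), function(mod) {
    regs <- module_regions[[mod]]
    obs <- colSums(hit_counts[regs, , drop = FALSE])
    set.seed(seed + match(mod, names(module_regions)))
    null <- vapply(seq_len(n_shuffles), function(i) {
      colSums(bg[sample(nrow(bg), length(regs), replace = TRUE), ,
                 drop = FALSE])
    }, numeric(ncol(bg)))
    null <- if (is.matrix(null)) t(null) else matrix(null, ncol = 1L)
    mu <- colMeans(null)
    sdv <- apply(null, 2, stats::sd)
    degenerate <- sdv == 0
    z <- ifelse(degenerate, NA_real_, (obs - mu) / sdv)
    dev <- abs(sweep(null, 2, mu))
    p <- (1 + colSums(dev >= matrix(abs(obs - mu), n_shuffles,
                                    length(obs), byrow = TRUE))) /
      (n_shuffles + 1)
    data.frame(motif_id = colnames(hit_counts), module = mod,
               region_class = region_class,
               observed = unname(obs), expected = unname(mu),
               sd = unname(sdv), z = unname(z), p = unname(p),
               adj_p = bh_adjust(unname(p)),
               degenerate = unname(degenerate),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Shared and module-specific enriched TFs
#'
#' Motifs passing `z >= z_cutoff` and `adj_p <= adj_p_max` per module;
#' the shared set is their intersection across all modules, the specific
#' set of a module excludes motifs passing in any other module.
#'
#' @param enrichments output of [enrich_motifs()] covering >= 2 modules.
#' @param z_cutoff Z-score cutoff (default 10, the reporting convention
#'   of the promoter analysis).
#' @param adj_p_max adjusted-p cutoff (default 0.05).
#' @return list with `passing` (per-module motif ids), `shared`,
#'   `specific` (per-module).
#' @export
tf_module_specificity <- function(enrichments, z_cutoff = 10,
                                  adj_p_max = 0.05) {
  mods <- unique(enrichments$module)
  if (length(mods) < 2) stop("need enrichment for at least 2 modules")
  passing <- lapply(mods, function(m) {
    e <- enrichments[enrichments$module == m & !enrichments$degenerate, ]
    sort(e$motif_id[e$z >= z_cutoff & e$adj_p <= adj_p_max])
  })
  names(passing) <- mods
  shared <- Reduce(intersect, passing)
  specific <- lapply(mods, function(m)
    setdiff(passing[[m]], unique(unlist(passing[setdiff(mods, m)]))))
  names(specific) <- mods
  list(passing = passing, shared = shared, specific = specific)
}
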