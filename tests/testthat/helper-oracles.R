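# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately take the naive route.

# per-gene linear scan over every domain interval
naive_localize <- function(annotation, tads, anchor = "tss") {
  pos <- ifelse(annotation$strand == "-", annotation$end - 1L,
                annotation$start)
  if (anchor == "midpoint")
    pos <- floor((annotation$start + annotation$end - 1L) / 2)
  res <- lapply(seq_len(nrow(annotation)), function(i) {
    iv <- tads[tads$chrom == annotation$chrom[i], , drop = FALSE]
    a <- pos[i]
    if (nrow(iv) == 0)
      return(list(within = FALSE, dist = NA_real_))
    inside <- which(a >= iv$start & a < iv$end)
    if (length(inside)) {
      s <- iv$start[inside[1]]; e <- iv$end[inside[1]]
      list(within = TRUE, dist = min(a - s, e - a))
    } else {
      d <- min(abs(a - c(iv$start, iv$end)))
      list(within = FALSE, dist = -max(d, 1))
    }
  })
  data.frame(gene_id = annotation$gene_id, anchor = pos,
             within_tad = vapply(res, `[[`, logical(1), "within"),
             boundary_distance = vapply(res, `[[`, numeric(1), "dist"))
}

# exact two-sample KS: D by sup over pooled points, p by full enumeration
# of all C(m+n, m) group labelings of the pooled sample
enum_ks <- function(a, b) {
  Dstat <- function(x, y) {
    v <- sort(unique(c(x, y)))
    max(abs(stats::ecdf(x)(v) - stats::ecdf(y)(v)))
  }
  D <- Dstat(a, b)
  pool <- c(a, b)
  n <- length(a)
  combs <- utils::combn(length(pool), n)
  ds <- apply(combs, 2, function(ix) Dstat(pool[ix], pool[-ix]))
  list(D = D, p = mean(ds >= D - 1e-12))
}

# all-offsets, all-strands PWM scoring by explicit products
naive_scan <- function(seq, p, threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(seq, "")[[1]]
  L <- ncol(p$matrix)
  lo <- log2(p$matrix / p$background)
  hits <- list()
  for (o in seq_len(length(chars) - L + 1)) {
    w <- chars[o:(o + L - 1)]
    if (any(!w %in% c("A", "C", "G", "T"))) next
    sf <- sum(lo[cbind(match(w, rownames(lo)), seq_len(L))])
    wr <- rev(unname(comp[w]))
    sr <- sum(lo[cbind(match(wr, rownames(lo)), seq_len(L))])
    if (sf >= threshold)
      hits[[length(hits) + 1]] <- data.frame(offset = o - 1L, strand = "+",
                                             score = sf)
    if (sr >= threshold)
      hits[[length(hits) + 1]] <- data.frame(offset = o - 1L, strand = "-",
                                             score = sr)
  }
  if (!length(hits))
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  out <- do.call(rbind, hits)
  out[order(out$offset, out$strand), , drop = FALSE]
}

# exhaustive 4^L enumeration of the discretised score distribution tail
enum_pwm_tail <- function(p, score, bin = 0.01) {
  L <- ncol(p$matrix)
  lo <- round(log2(p$matrix / p$background) / bin)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- rowSums(matrix(lo[cbind(as.vector(words),
                                rep(seq_len(L), each = nrow(words)))],
                       nrow(words))) * bin
  pr <- apply(words, 1, function(w) prod(p$background[w]))
  sum(pr[sc >= score - 1e-9])
}

# betweenness by exhaustive geodesic counting (igraph-free)
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  all_paths <- function(s, t) {
    # enumerate all simple paths s -> t by DFS
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { out[[length(out) + 1]] <<- path; return(invisible()) }
      for (w in which(adj[v, ] == 1))
        if (!w %in% path) walk(c(path, w))
    }
    walk(s)
    out
  }
  for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    paths <- all_paths(s, t)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1))
    geo <- paths[lens == min(lens)]
    for (g in geo) {
      mid <- setdiff(g, c(s, t))
      btw[mid] <- btw[mid] + 1 / length(geo)
    }
  }
  btw
}

random_pwm <- function(L = sample(4:10, 1), seed = NULL) {
  m <- matrix(stats::rgamma(4 * L, 1), 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm(m, id = paste0("RND", L))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small fast simulation configuration for unit tests
small_config <- function(seed = 1, ...) {
  args <- list(module_sizes = c(40, 35, 30), n_background_genes = 120,
               chrom_length = 8e6, n_tads = 25, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}
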