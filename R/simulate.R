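#' Simulate count matrices with planted structure
#'
#' Negative-binomial counts for the three biotypes. Module genes share a
#' latent per-sample factor (giving within-module correlation) plus a
#' planted between-group shift of `module_log2fc` on the log2 scale;
#' planted miRNAs track the realised log deviation of their target gene
#' with an analytically derived coupling so that the miRNA:target
#' Pearson correlation is approximately `repression_r`. Library sizes
#' vary at most two-fold.
#'
#' @param config a [sim_config()].
#' @return list with [expr_matrix] elements `coding`, `lncrna`, `mirna`,
#'   the `design` data.frame (sample_id, group) and `truth` (list with
#'   `module_membership` and `planted_pairs`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  phi <- config$nb_dispersion
  genes <- .sim_gene_table(config)
  samples <- .sim_sample_table(config)
  ns <- nrow(samples)
  n_mod <- length(config$module_sizes)
  grp_idx <- match(samples$group, config$group_labels)

  # library-size factors within a 2-fold band
  libfac <- 2^stats::runif(ns, -0.5, 0.5)

  # latent module factor: planted group profile + unit noise
  profiles <- matrix(stats::runif(n_mod * config$n_groups), n_mod)
  if (n_mod >= 1) profiles[1, ] <- seq(0, 1, length.out = config$n_groups)
  if (n_mod >= 2) profiles[2, ] <- seq(1, 0, length.out = config$n_groups)
  if (n_mod >= 3) profiles[3, ] <- c(0, rep(1, config$n_groups - 1))
  f0 <- matrix(stats::rnorm(n_mod * ns), n_mod, ns)

  # loading chosen so the factor component alone gives within-group
  # within-module |r| of about 0.6 at a typical expression level
  mu_typ <- 2^7
  sigma_noise <- sqrt(1 / mu_typ + phi) / log(2)
  loading <- sigma_noise * sqrt(0.6 / 0.4)

  nb_row <- function(log2mu) {
    stats::rnbinom(ns, mu = libfac * 2^log2mu, size = 1 / phi)
  }

  ## protein-coding genes
  coding <- genes[genes$biotype == "coding", ]
  base <- pmin(pmax(stats::rnorm(nrow(coding), 7, 1.5), 3), 12)
  cmat <- matrix(0L, nrow(coding), ns,
                 dimnames = list(coding$gene_id, samples$sample_id))
  for (i in seq_len(nrow(coding))) {
    m <- match(coding$module[i], paste0("M", seq_len(n_mod)))
    log2mu <- base[i] +
      if (!is.na(m))
        config$module_log2fc * profiles[m, grp_idx] + loading * f0[m, ]
      else 0
    cmat[i, ] <- nb_row(log2mu)
  }

  ## lncRNA: half with a planted labour-associated shift, half flat
  lnc <- genes[genes$biotype == "lncRNA", ]
  lbase <- pmin(pmax(stats::rnorm(nrow(lnc), 5.5, 1.2), 3), 10)
  lshift <- rep(c(1, -1, 0, 0), length.out = nrow(lnc)) * config$module_log2fc
  labour <- as.numeric(grp_idx > 1)
  lmat <- matrix(0L, nrow(lnc), ns,
                 dimnames = list(lnc$gene_id, samples$sample_id))
  for (i in seq_len(nrow(lnc)))
    lmat[i, ] <- nb_row(lbase[i] + lshift[i] * labour)

  ## miRNA: planted ones anti-track a module-gene target. The coupling
  ## must survive CPM normalisation, whose denominator (the miRNA
  ## library size) itself moves with the planted rows; so non-planted
  ## rows are drawn first and each planted mean is pre-compensated by
  ## the predicted library size.
  mir <- genes[genes$biotype == "miRNA", ]
  module_gene_ids <- genes$gene_id[genes$module != "unassigned" &
                                     genes$biotype == "coding"]
  targets <- sample(module_gene_ids, config$n_planted_pairs)
  mbase <- pmin(pmax(stats::rnorm(nrow(mir), 9, 0.8), 6), 12)
  mshift <- rep(c(0, 1, -1), length.out = nrow(mir)) * config$module_log2fc
  mmat <- matrix(0L, nrow(mir), ns,
                 dimnames = list(mir$gene_id, samples$sample_id))
  planted <- seq_len(config$n_planted_pairs)
  for (i in setdiff(seq_len(nrow(mir)), planted))
    mmat[i, ] <- nb_row(mbase[i] + mshift[i] * labour)
  r <- max(config$repression_r, -0.995)   # coupling finite at r = -1
  d_of <- list(); kappa_of <- numeric(length(planted))
  coding_lib <- colSums(cmat)   # realised library, so d is exactly the
                                # target's log-CPM up to a constant
  for (i in planted) {
    tc <- cmat[targets[i], ]
    d <- log2(tc + 0.5) - log2(coding_lib + 1)
    d <- d - mean(d)
    d_of[[i]] <- d
    sigma_d <- stats::sd(d)
    # log-scale noise of this miRNA calibrated by pilot simulation
    # (the delta-method value underestimates it at NB dispersion phi)
    sigma_mi <- stats::sd(log2(stats::rnbinom(500, mu = 2^mbase[i],
                                              size = 1 / phi) + 0.5))
    kappa_of[i] <- if (sigma_d > 0)
      (sigma_mi / sigma_d) * abs(r) / sqrt(1 - r^2) else 0
  }
  if (length(planted)) {
    mu_prov <- vapply(planted, function(i)
      libfac * 2^(mbase[i] - kappa_of[i] * d_of[[i]]), numeric(ns))
    s_hat <- colSums(mmat) + rowSums(mu_prov)   # predicted library size
    comp <- log2(s_hat) - mean(log2(s_hat))
    for (i in planted)
      mmat[i, ] <- stats::rnbinom(ns, mu = 2^(mbase[i] - kappa_of[i] *
                                                d_of[[i]] + comp),
                                  size = 1 / phi)
  }

  storage.mode(cmat) <- "integer"
  storage.mode(lmat) <- "integer"
  storage.mode(mmat) <- "integer"
  truth <- list(
    module_membership = stats::setNames(genes$module, genes$gene_id),
    planted_pairs = data.frame(
      mirna = mir$gene_id[seq_len(config$n_planted_pairs)],
      target = targets, stringsAsFactors = FALSE))
  groups <- stats::setNames(samples$group, samples$sample_id)
  list(coding = expr_matrix(cmat, groups, "coding"),
       lncrna = expr_matrix(lmat, groups, "lncRNA"),
       mirna = expr_matrix(mmat, groups, "miRNA"),
       design = samples,
       truth = truth)
}

# module-specific planted motifs first, then uninformative background motifs
.sim_pwms <- function(config, n_background_motifs = 9) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 97L)
  n_mod <- length(config$module_sizes)
  n <- n_mod + n_background_motifs
  lapply(seq_len(n), function(i) {
    L <- sample(8:12, 1)
    dom <- sample(4, L, replace = TRUE)
    m <- matrix(0.05, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(dom, seq_len(L))] <- 0.85
    pwm(m, id = sprintf("SYN%04d.1", i),
        name = if (i <= n_mod) paste0("TF_M", i) else paste0("TF_BG", i - n_mod))
  })
}

#' Simulate the genomic layout: genes, TADs, sequence, motifs, enhancers
#'
#' Places genes on one synthetic chromosome so that the planted fraction
#' of each module's TSSs falls inside a contact domain (within one gene
#' of `frac_in_tad * module size`), background genes uniformly; plants
#' exact-consensus occurrences of each module's motif in module-gene
#' promoters over an i.i.d. background sequence; and assigns enhancers
#' to a random half of the module genes plus an unassigned background
#' pool.
#'
#' Genes are laid out on a slot grid wide enough that promoter windows
#' never overlap, and slots closer than 3 kb to a domain boundary are
#' not used, so the TSS jitter cannot flip a gene's planted side.
#'
#' @param config a [sim_config()].
#' @return list with `annotation` (data.frame gene_id, chrom, start, end,
#'   strand, tss, biotype; 0-based half-open), `tads` ([tad_set()]),
#'   `genome` (named character), `pwms` (list of [pwm]), `enhancers`
#'   (data.frame chrom, start, end, gene_id with NA for unassigned) and
#'   `truth` (list `genes_in_tad`, `planted_motif_hits`).
#' @export
simulate_genome_layout <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  genes <- .sim_gene_table(config)
  n_genes <- nrow(genes)
  n_mod <- length(config$module_sizes)
  chrom <- "chrS1"
  len <- config$chrom_length

  ## domains: alternate gap/domain segments scaled to the chromosome
  n_seg <- 2 * config$n_tads + 1
  w <- stats::rgamma(n_seg, shape = 4)
  bnd <- round(cumsum(w / sum(w)) * len)
  starts <- c(0, bnd[-n_seg])
  ends <- bnd
  dom <- seq(2, n_seg - 1, by = 2)
  tads <- tad_set(data.frame(chrom = chrom, start = starts[dom],
                             end = ends[dom]))

  ## slot grid for TSS placement
  win <- config$promoter_upstream + config$promoter_downstream
  slot_w <- max(win + 5000, 20000)
  centers <- seq(slot_w / 2, len - slot_w / 2, by = slot_w)
  if (length(centers) < n_genes)
    stop("generation error: chromosome of ", len,
         " bp has only ", length(centers), " gene slots for ", n_genes,
         " genes; increase chrom_length")
  # classify slot centers with a margin so jitter cannot change the side
  margin <- 3000
  edge_dist <- vapply(centers, function(p)
    min(abs(p - c(tads$start, tads$end))), numeric(1))
  inside <- vapply(centers, function(p)
    any(p >= tads$start & p < tads$end), logical(1))
  usable <- edge_dist > margin
  pool_in <- which(usable & inside)
  pool_out <- which(usable & !inside)

  slot_of <- integer(n_genes)
  for (m in seq_len(n_mod)) {
    gi <- which(genes$module == paste0("M", m))
    n_in <- round(config$frac_in_tad[m] * length(gi))
    if (n_in > length(pool_in) || (length(gi) - n_in) > length(pool_out))
      stop("generation error: not enough ",
           if (n_in > length(pool_in)) "inside-domain" else "outside-domain",
           " slots for module M", m,
           "; increase chrom_length or n_tads")
    s_in <- sample(pool_in, n_in)
    s_out <- sample(pool_out, length(gi) - n_in)
    slot_of[gi] <- sample(c(s_in, s_out))
    pool_in <- setdiff(pool_in, s_in)
    pool_out <- setdiff(pool_out, s_out)
  }
  rest <- which(slot_of == 0)
  pool_rest <- c(pool_in, pool_out)
  if (length(rest) > length(pool_rest))
    stop("generation error: not enough free slots for background genes")
  slot_of[rest] <- sample(pool_rest, length(rest))

  tss <- round(centers[slot_of] + stats::runif(n_genes, -1000, 1000))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  glen <- sample(2000:8000, n_genes, replace = TRUE)
  start <- ifelse(strand == "+", tss, tss + 1 - glen)
  end <- ifelse(strand == "+", tss + glen, tss + 1)
  annotation <- data.frame(gene_id = genes$gene_id, chrom = chrom,
                           start = as.integer(start), end = as.integer(end),
                           strand = strand, tss = as.integer(tss),
                           biotype = genes$biotype, stringsAsFactors = FALSE)

  ## i.i.d. background sequence with planted consensus occurrences
  seq_int <- sample.int(4L, len, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  pwms <- .sim_pwms(config)
  hits <- list()
  comp <- c(4L, 3L, 2L, 1L)
  for (m in seq_len(n_mod)) {
    cons <- pwm_consensus(pwms[[m]])
    cint <- match(strsplit(cons, "")[[1]], bases)
    Lm <- length(cint)
    for (gi in which(genes$module == paste0("M", m))) {
      n_hits <- stats::rpois(1, config$promoter_motif_rate)
      if (n_hits == 0) next
      offs <- sample.int(win - Lm, n_hits)  # 0-based offsets in the promoter
      for (o in offs) {
        if (annotation$strand[gi] == "+") {
          ws <- tss[gi] - config$promoter_upstream
          pos <- ws + o                      # 0-based genome position
          seq_int[(pos + 1):(pos + Lm)] <- cint
        } else {
          we <- tss[gi] + config$promoter_upstream + 1
          pos <- we - o - Lm
          seq_int[(pos + 1):(pos + Lm)] <- rev(comp[cint])
        }
        hits[[length(hits) + 1]] <- data.frame(
          motif_id = pwms[[m]]$id, gene_id = genes$gene_id[gi],
          offset = o, stringsAsFactors = FALSE)
      }
    }
  }
  genome <- stats::setNames(intToUtf8(utf8ToInt("ACGT")[seq_int]), chrom)

  ## enhancers: one per ~half of the module genes, plus unassigned pool
  mod_genes <- which(genes$module != "unassigned")
  with_enh <- mod_genes[stats::runif(length(mod_genes)) < 0.5]
  enh_pos <- function(n) pmin(pmax(round(stats::runif(n, 0, len - 500)), 0),
                              len - 500)
  e1 <- if (length(with_enh)) {
    p <- pmin(pmax(tss[with_enh] + round(stats::runif(length(with_enh),
                                                      -5e4, 5e4)), 0),
              len - 500)
    data.frame(chrom = chrom, start = p, end = p + 500,
               gene_id = genes$gene_id[with_enh], stringsAsFactors = FALSE)
  } else NULL
  p2 <- enh_pos(200)
  e2 <- data.frame(chrom = chrom, start = p2, end = p2 + 500,
                   gene_id = NA_character_, stringsAsFactors = FALSE)
  enhancers <- rbind(e1, e2)

  within <- !is.na(GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(chrom, IRanges::IRanges(tss + 1L, tss + 1L)),
    GenomicRanges::GRanges(chrom, IRanges::IRanges(tads$start + 1L, tads$end)),
    select = "first"))
  truth <- list(
    genes_in_tad = stats::setNames(within, genes$gene_id),
    planted_motif_hits = if (length(hits)) do.call(rbind, hits)
      else data.frame(motif_id = character(0), gene_id = character(0),
                      offset = integer(0)))
  list(annotation = annotation, tads = tads, genome = genome,
       pwms = pwms, enhancers = enhancers, truth = truth)
}

#' Simulate every pipeline input at once
#'
#' Convenience wrapper running [simulate_counts()] and
#' [simulate_genome_layout()] and merging their ground truths; also
#' emits a known-target pair table (the planted miRNA:target pairs plus
#' decoy lncRNA:mRNA pairs) standing in for curated interaction
#' databases.
#'
#' @param config a [sim_config()].
#' @return list combining both generators' outputs plus `known_pairs`
#'   and a merged `truth`.
#' @export
simulate_all <- function(config) {
  counts <- simulate_counts(config)
  layout <- simulate_genome_layout(config)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 2L)
  pp <- counts$truth$planted_pairs
  known <- data.frame(source = pp$mirna, source_class = "miRNA",
                      target = pp$target, target_class = "mRNA",
                      stringsAsFactors = FALSE)
  lnc_ids <- rownames(counts$lncrna$counts)
  coding_ids <- rownames(counts$coding$counts)
  n_decoy <- min(30, length(lnc_ids) * 2)
  decoy <- data.frame(source = sample(lnc_ids, n_decoy, replace = TRUE),
                      source_class = "lncRNA",
                      target = sample(coding_ids, n_decoy),
                      target_class = "mRNA", stringsAsFactors = FALSE)
  known <- unique(rbind(known, decoy))
  truth <- c(counts$truth, layout$truth)
  c(counts[c("coding", "lncrna", "mirna", "design")],
    layout[c("annotation", "tads", "genome", "pwms", "enhancers")],
    list(known_pairs = known, truth = truth, config = config))
}
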