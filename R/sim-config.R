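#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The defaults emulate the
#' structure of the study dataset: 16 samples in three labour-stage
#' groups (5 no-labour, 5 early-labour, 6 late-labour), three planted
#' co-expression modules of 81, 46 and 36 genes, planted
#' miRNA-to-target repression, module genes preferentially placed inside
#' contact domains at the published fractions (66% / 76% / 66%), and
#' module-specific motifs planted in module-gene promoters.
#'
#' @param n_groups number of sample groups (default 3).
#' @param group_sizes samples per group (default 5, 5, 6).
#' @param group_labels group names (default NL, EL, LL when 3 groups).
#' @param module_sizes planted module sizes (default 81, 46, 36).
#' @param n_background_genes coding genes outside any module (default 500).
#' @param n_mirna,n_lncrna non-coding gene counts (defaults 27, 30).
#' @param n_planted_pairs miRNAs coupled to a module-gene target
#'   (default 20, must be <= n_mirna).
#' @param nb_dispersion negative-binomial dispersion phi (default 0.05).
#' @param module_log2fc planted between-group shift of module genes on
#'   the log2 scale (default 1; larger shifts make the three modules'
#'   group profiles dominate the correlation structure and merge them
#'   under the absolute-correlation distance).
#' @param repression_r target Pearson correlation of planted
#'   miRNA:target pairs, in \[-1, 0) (default -0.9).
#' @param frac_in_tad per-module fraction of module genes whose TSS lies
#'   inside a planted domain; scalar recycled (default 0.66, 0.76, 0.66,
#'   matching the published fractions of M1/M2/M3).
#' @param n_tads planted domain count (default 40).
#' @param chrom_length synthetic chromosome length in bp (default 2e7).
#' @param promoter_motif_rate expected planted motif occurrences per
#'   module-gene promoter (default 1).
#' @param promoter_upstream,promoter_downstream promoter window around
#'   the TSS used for motif planting (defaults 10000 / 5000, the window
#'   of the promoter motif analysis).
#' @param seed root integer seed; every sub-generator derives its stream
#'   deterministically from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 3,
                       group_sizes = c(5, 5, 6),
                       group_labels = NULL,
                       module_sizes = c(81, 46, 36),
                       n_background_genes = 500,
                       n_mirna = 27,
                       n_lncrna = 30,
                       n_planted_pairs = 20,
                       nb_dispersion = 0.05,
                       module_log2fc = 1,
                       repression_r = -0.9,
                       frac_in_tad = c(0.66, 0.76, 0.66),
                       n_tads = 40,
                       chrom_length = 2e7,
                       promoter_motif_rate = 1,
                       promoter_upstream = 10000,
                       promoter_downstream = 5000,
                       seed = 1L) {
  if (length(group_sizes) != n_groups)
    stop("group_sizes must have n_groups entries")
  if (sum(group_sizes) < 4) stop("need at least 4 samples in total")
  if (any(c(group_sizes, module_sizes, n_background_genes, n_mirna,
            n_lncrna, n_tads) < 1))
    stop("all counts must be >= 1")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (!(repression_r >= -1 && repression_r < 0))
    stop("repression_r must lie in [-1, 0)")
  if (any(frac_in_tad < 0 | frac_in_tad > 1))
    stop("frac_in_tad must lie in [0, 1]")
  if (n_planted_pairs > n_mirna)
    stop("n_planted_pairs cannot exceed n_mirna")
  if (is.null(group_labels))
    group_labels <- if (n_groups == 3) c("NL", "EL", "LL")
      else paste0("G", seq_len(n_groups))
  frac_in_tad <- rep_len(frac_in_tad, length(module_sizes))
  structure(list(n_groups = n_groups, group_sizes = group_sizes,
                 group_labels = group_labels, module_sizes = module_sizes,
                 n_background_genes = n_background_genes,
                 n_mirna = n_mirna, n_lncrna = n_lncrna,
                 n_planted_pairs = n_planted_pairs,
                 nb_dispersion = nb_dispersion,
                 module_log2fc = module_log2fc,
                 repression_r = repression_r,
                 frac_in_tad = frac_in_tad, n_tads = n_tads,
                 chrom_length = chrom_length,
                 promoter_motif_rate = promoter_motif_rate,
                 promoter_upstream = promoter_upstream,
                 promoter_downstream = promoter_downstream,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic gene table shared by the count and layout generators
# (no randomness: both halves of the simulator must agree on ids)
.sim_gene_table <- function(config) {
  n_mod <- length(config$module_sizes)
  module <- rep(paste0("M", seq_len(n_mod)), config$module_sizes)
  n_coding <- sum(config$module_sizes) + config$n_background_genes
  data.frame(
    gene_id = c(sprintf("GENE%04d", seq_len(n_coding)),
                sprintf("LNC%04d", seq_len(config$n_lncrna)),
                sprintf("MIR%04d", seq_len(config$n_mirna))),
    biotype = rep(c("coding", "lncRNA", "miRNA"),
                  c(n_coding, config$n_lncrna, config$n_mirna)),
    module = c(module, rep("unassigned",
                           config$n_background_genes + config$n_lncrna +
                             config$n_mirna)),
    stringsAsFactors = FALSE)
}

.sim_sample_table <- function(config) {
  n <- sum(config$group_sizes)
  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
             group = rep(config$group_labels, config$group_sizes),
             stringsAsFactors = FALSE)
}
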