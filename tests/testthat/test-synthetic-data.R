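test_that("config validation catches bad parameters", {
  expect_error(sim_config(group_sizes = c(1, 1, 1)), "at least 4")
  expect_error(sim_config(nb_dispersion = 0), "positive")
  expect_error(sim_config(repression_r = 0.2), "repression_r")
  expect_error(sim_config(frac_in_tad = 1.2), "frac_in_tad")
  expect_error(sim_config(n_planted_pairs = 99), "n_planted_pairs")
})

test_that("the default design has 16 samples in groups 5+5+6", {
  cfg <- sim_config()
  sim <- simulate_counts(cfg)
  expect_equal(ncol(sim$coding$counts), 16)
  expect_equal(unname(table(sim$coding$groups)[c("NL", "EL", "LL")]),
               c(5, 5, 6), ignore_attr = TRUE)
  # design table partitions the sample columns
  expect_setequal(sim$design$sample_id, colnames(sim$coding$counts))
  expect_equal(anyDuplicated(sim$design$sample_id), 0L)
  # planted modules have the configured sizes
  expect_equal(unname(table(sim$truth$module_membership)[c("M1", "M2", "M3")]),
               c(81, 46, 36), ignore_attr = TRUE)
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_config(seed = 42)
  a <- simulate_counts(cfg); b <- simulate_counts(cfg)
  expect_identical(a$coding$counts, b$coding$counts)
  expect_identical(a$mirna$counts, b$mirna$counts)
  la <- simulate_genome_layout(cfg); lb <- simulate_genome_layout(cfg)
  expect_identical(la$annotation, lb$annotation)
  expect_identical(la$genome, lb$genome)
  # different seed changes the data
  expect_false(identical(
    a$coding$counts, simulate_counts(small_config(seed = 43))$coding$counts))
})

test_that("library sizes vary at most two-fold", {
  sim <- simulate_counts(small_config(seed = 3))
  lib <- colSums(sim$coding$counts)
  expect_lt(max(lib) / min(lib), 2.3)  # 2-fold factors + count noise
})

test_that("a null configuration rarely yields any DE call", {
  # with no planted shift, the fraction of simulations in which any gene
  # passes the FC/FDR filter stays near the nominal FDR level
  any_hit <- vapply(1:60, function(s) {
    cfg <- sim_config(module_sizes = c(15, 10), n_background_genes = 75,
                      n_mirna = 5, n_lncrna = 5, n_planted_pairs = 2,
                      module_log2fc = 0, seed = 1000 + s)
    sim <- simulate_counts(cfg)
    de <- differential_expression(sim$coding, c("EL", "LL"), "NL")
    any(de$direction != "unchanged")
  }, logical(1))
  expect_lte(mean(any_hit), 0.07 + 0.05)  # 7% criterion + MC slack at n=60
})

test_that("planted miRNA:target correlations track repression_r at large n", {
  cfg <- sim_config(group_sizes = c(66, 67, 67), module_sizes = c(40, 35, 30),
                    n_background_genes = 100, seed = 7)
  sim <- simulate_counts(cfg)
  lcM <- log_cpm(sim$mirna); lcC <- log_cpm(sim$coding)
  pp <- sim$truth$planted_pairs
  rs <- mapply(function(m, t) cor(lcM[m, ], lcC[t, ]), pp$mirna, pp$target)
  expect_true(all(rs < 0))
  expect_lt(abs(mean(rs) - cfg$repression_r), 0.1)
})

test_that("frac_in_tad boundaries place all or none of the module TSSs inside", {
  for (f in c(0, 1)) {
    cfg <- small_config(seed = 5, frac_in_tad = f)
    lay <- simulate_genome_layout(cfg)
    truth <- simulate_counts(cfg)$truth$module_membership
    mod_genes <- names(truth)[truth != "unassigned"]
    expect_equal(unname(mean(lay$truth$genes_in_tad[mod_genes])), f)
  }
})

test_that("planted within-domain fractions are recovered by localization", {
  cfg <- sim_config(seed = 11)
  lay <- simulate_genome_layout(cfg)
  truth <- simulate_counts(cfg)$truth$module_membership
  loc <- localize_genes(lay$annotation, lay$tads)
  for (m in c("M1", "M2", "M3")) {
    g <- names(truth)[truth == m]
    planted <- cfg$frac_in_tad[match(m, c("M1", "M2", "M3"))]
    expect_lte(abs(within_fraction(loc, g) * length(g) -
                     planted * length(g)), 1)
  }
})

test_that("planted motif offsets lie inside their gene's promoter window", {
  cfg <- small_config(seed = 9)
  lay <- simulate_genome_layout(cfg)
  hits <- lay$truth$planted_motif_hits
  expect_gt(nrow(hits), 0)
  win <- cfg$promoter_upstream + cfg$promoter_downstream
  expect_true(all(hits$offset >= 0 & hits$offset < win))
  # the extracted promoter actually contains the planted consensus
  proms <- extract_promoters(lay$annotation, lay$genome)
  cons <- vapply(lay$pwms, pwm_consensus, character(1))
  names(cons) <- vapply(lay$pwms, `[[`, character(1), "id")
  ok <- vapply(seq_len(nrow(hits)), function(i) {
    s <- as.character(proms[[hits$gene_id[i]]])
    cseq <- cons[[hits$motif_id[i]]]
    substr(s, hits$offset[i] + 1, hits$offset[i] + nchar(cseq)) == cseq
  }, logical(1))
  expect_true(all(ok))
})

test_that("infeasible packing fails with an explanation", {
  expect_error(
    simulate_genome_layout(small_config(chrom_length = 1e6)),
    "generation error")
})

test_that("emitted files round-trip through the package readers", {
  cfg <- sim_config(module_sizes = c(8, 6), n_background_genes = 20,
                    n_mirna = 5, n_lncrna = 4, n_planted_pairs = 3,
                    chrom_length = 2e6, n_tads = 8, seed = 21)
  sim <- simulate_all(cfg)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_inputs(sim, dir)
  expect_identical(read_counts_tsv(paths["counts_coding"]),
                   sim$coding$counts)
  d <- read_design_tsv(paths["design"])
  expect_equal(d$sample_id, sim$design$sample_id)
  ann <- read_annotation_gff3(paths["annotation_gff3"])
  expect_equal(ann[, c("gene_id", "chrom", "start", "end", "strand")],
               sim$annotation[, c("gene_id", "chrom", "start", "end", "strand")])
  annb <- read_annotation_bed(paths["annotation_bed"])
  expect_equal(annb[, c("gene_id", "start", "end", "strand")],
               sim$annotation[, c("gene_id", "start", "end", "strand")])
  tads <- read_tads_bed(paths["tads"])
  expect_equal(tads$start, sim$tads$start)
  expect_equal(tads$end, sim$tads$end)
  fa <- read_fasta(paths["genome"])
  expect_identical(as.character(fa[["chrS1"]]), unname(sim$genome))
  pwms <- read_jaspar(paths["pwms"])
  expect_equal(length(pwms), length(sim$pwms))
  expect_equal(pwms[[1]]$id, sim$pwms[[1]]$id)
  expect_equal(pwms[[1]]$matrix, sim$pwms[[1]]$matrix, tolerance = 1e-3)
  kp <- read_pairs_tsv(paths["known_pairs"])
  expect_equal(nrow(kp), nrow(sim$known_pairs))
  tr <- read_truth_json(paths["truth"])
  expect_equal(tr$planted_pairs$mirna, sim$truth$planted_pairs$mirna)
})
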