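test_that("promoter windows are strand-aware and edge-truncated", {
  set.seed(37)
  chrlen <- 50000
  genome <- c(chrA = random_dna(chrlen))
  ann <- data.frame(gene_id = c("plus", "minus", "edge"), chrom = "chrA",
                    start = c(20000, 25000, 100), end = c(21000, 30001, 1100),
                    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  pr <- extract_promoters(ann, genome, upstream = 10000, downstream = 5000)
  co <- attr(pr, "coordinates")
  # plus-strand TSS at 20000 -> [10000, 25000)
  expect_equal(c(co$start[1], co$end[1]), c(10000, 25000))
  expect_equal(as.character(pr[["plus"]]),
               unname(substr(genome, 10001, 25000)))
  # minus-strand promoter is the reverse complement of its plus window
  expect_equal(as.character(pr[["minus"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(genome, co$start[2] + 1,
                                              co$end[2])))))
  expect_equal(nchar(as.character(pr[["minus"]])), 15000)
  # TSS at 100 with upstream 10000: truncated to [0, 5100)
  expect_equal(c(co$start[3], co$end[3]), c(0, 5100))
  expect_equal(nchar(as.character(pr[["edge"]])), 5100)
  expect_error(extract_promoters(
    data.frame(gene_id = "far", chrom = "chrA", start = 50000, end = 51000,
               strand = "+"), genome), "far")
})

test_that("a background-equal PWM scores zero everywhere", {
  p <- pwm(matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL)),
           pseudocount = 0)
  hits <- scan_pwm(random_dna(50), p, threshold = -1)
  expect_true(all(abs(hits$score) < 1e-12))
  expect_equal(nrow(hits), 45 * 2)
})

test_that("scanning matches naive all-offset/all-strand enumeration", {
  set.seed(41)
  for (i in 1:20) {
    p <- random_pwm(sample(3:8, 1))
    s <- random_dna(sample(30:80, 1))
    thr <- pwm_score_threshold(p, 0.05)
    got <- scan_pwm(s, p, score_threshold_p = 0.05)
    want <- naive_scan(s, p, thr)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("scan skips windows containing N and warns on short sequences", {
  p <- random_pwm(5)
  s <- paste0(random_dna(10), "N", random_dna(10))
  hits <- scan_pwm(s, p, threshold = -1e6)
  # windows 7..11 (0-based 6..10) touch the N on each strand
  expect_false(any(hits$offset %in% 6:10))
  expect_warning(scan_pwm("ACG", p, threshold = -1e6), "longer")
})

test_that("scan is strand-symmetric under reverse complement", {
  set.seed(43)
  p <- random_pwm(6)
  s <- random_dna(60)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  a <- scan_pwm(s, p, threshold = -1e6)
  b <- scan_pwm(rc, p, threshold = -1e6)
  # a hit at plus offset o maps to a minus hit at n - L - o on the RC
  b_mapped <- data.frame(offset = 60 - 6 - b$offset,
                         strand = ifelse(b$strand == "+", "-", "+"),
                         score = b$score)
  b_mapped <- b_mapped[order(b_mapped$offset, b_mapped$strand), ]
  expect_equal(a$score, b_mapped$score, tolerance = 1e-9)
  expect_equal(a$offset, b_mapped$offset)
})

test_that("the DP score distribution is exact under discretisation", {
  set.seed(47)
  for (L in c(3, 5, 6)) {
    p <- random_pwm(L)
    d <- pwm_score_distribution(p, bin = 0.01)
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
    for (q in c(0.5, 0.9, 0.99)) {
      s <- d$score[min(which(cumsum(d$prob) >= q))]
      expect_equal(sum(d$prob[d$score >= s - 1e-9]),
                   enum_pwm_tail(p, s), tolerance = 1e-9)
    }
  }
  # the threshold honours the requested tail probability
  p <- random_pwm(6)
  thr <- pwm_score_threshold(p, 1e-3)
  expect_lte(enum_pwm_tail(p, thr), 1e-3)
})

test_that("motif enrichment z reflects planted occurrences", {
  set.seed(53)
  p <- random_pwm(8)
  cons <- pwm_consensus(p)
  n_mod <- 30; n_bg <- 300
  regions <- c(vapply(seq_len(n_mod), function(i) {
    s <- random_dna(300)
    pos <- sample(100, 1)
    paste0(substr(s, 1, pos), cons, substr(s, pos + 9, 300))
  }, character(1)), vapply(seq_len(n_bg), function(i) random_dna(300),
                           character(1)))
  names(regions) <- c(paste0("mod", seq_len(n_mod)),
                      paste0("bg", seq_len(n_bg)))
  hc <- count_hits(regions, list(p), score_threshold_p = 1e-4)
  enr <- enrich_motifs(hc, list(M1 = paste0("mod", seq_len(n_mod))),
                       paste0("bg", seq_len(n_bg)), n_shuffles = 300,
                       seed = 2)
  expect_gt(enr$z, 10)
  expect_lt(enr$adj_p, 0.05)
  # determinism
  enr2 <- enrich_motifs(hc, list(M1 = paste0("mod", seq_len(n_mod))),
                        paste0("bg", seq_len(n_bg)), n_shuffles = 300,
                        seed = 2)
  expect_identical(enr$z, enr2$z)
})

test_that("degenerate null variance is flagged", {
  hc <- matrix(c(rep(1L, 5), rep(0L, 10)), ncol = 1,
               dimnames = list(c(paste0("m", 1:5), paste0("b", 1:10)), "pw"))
  enr <- enrich_motifs(hc, list(M1 = paste0("m", 1:5)), paste0("b", 1:10),
                       n_shuffles = 50, seed = 1)
  expect_true(enr$degenerate)
  expect_true(is.na(enr$z))
})

test_that("TF specificity splits shared and module-specific motifs", {
  mk <- function(module, ids, z) {
    data.frame(motif_id = ids, module = module, region_class = "promoter",
               observed = 1, expected = 0, sd = 1, z = z, p = 0.001,
               adj_p = 0.001, degenerate = FALSE)
  }
  enr <- rbind(mk("M1", c("a", "b", "c"), c(20, 15, 12)),
               mk("M2", c("a", "b", "d"), c(30, 11, 18)))
  sp <- tf_module_specificity(enr, z_cutoff = 10, adj_p_max = 0.05)
  expect_setequal(sp$shared, c("a", "b"))
  expect_equal(sp$specific$M1, "c")
  expect_equal(sp$specific$M2, "d")
  # identical enriched sets leave no specific motifs
  enr2 <- rbind(mk("M1", c("a", "b"), c(20, 15)),
                mk("M2", c("a", "b"), c(30, 11)))
  sp2 <- tf_module_specificity(enr2)
  expect_length(sp2$specific$M1, 0)
  expect_length(sp2$specific$M2, 0)
})
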