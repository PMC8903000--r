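em_of <- function(counts, biotype, groups = rep(c("A", "B"), each = 2)) {
  expr_matrix(counts, groups, biotype)
}

test_that("cross-class correlation matches the covariance formula", {
  # construct counts whose log-CPMs are exactly affine with slope -1:
  # powers of two against reversed powers, fillers keep libraries constant
  a <- rbind(g = c(1, 2, 4, 8), fill = c(15, 14, 12, 8))
  colnames(a) <- paste0("s", 1:4)
  b <- rbind(h = c(16, 8, 4, 2), fill2 = c(1, 9, 13, 15))
  colnames(b) <- paste0("s", 1:4)
  ed <- correlate_classes(em_of(a, "miRNA"), em_of(b, "coding"),
                          filter = FALSE, pseudocount = 0)
  r_gh <- ed$r[ed$source == "g" & ed$target == "h"]
  expect_equal(r_gh, -1)
  expect_equal(ed$sign[ed$source == "g" & ed$target == "h"], "negative")
  # hand-computed Pearson r for an arbitrary pair
  la <- log_cpm(a, 0); lb <- log_cpm(b, 0)
  hand <- function(x, y) {
    n <- length(x)
    (sum(x * y) - n * mean(x) * mean(y)) /
      sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  }
  expect_equal(ed$r[ed$source == "g" & ed$target == "fill2"],
               hand(la["g", ], lb["fill2", ]))
})

test_that("correlation screen is symmetric and requires matching samples", {
  set.seed(59)
  a <- matrix(rpois(40, 50) + 1, 5, 8,
              dimnames = list(paste0("m", 1:5), paste0("s", 1:8)))
  b <- matrix(rpois(48, 50) + 1, 6, 8,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:8)))
  gr <- rep(c("A", "B"), each = 4)
  e1 <- correlate_classes(em_of(a, "miRNA", gr), em_of(b, "coding", gr),
                          filter = FALSE)
  e2 <- correlate_classes(em_of(b, "coding", gr), em_of(a, "miRNA", gr),
                          filter = FALSE)
  k1 <- paste(e1$source, e1$target); k2 <- paste(e2$target, e2$source)
  expect_setequal(k1, k2)
  expect_equal(e1$r[order(k1)], e2$r[order(k2)])
  b2 <- b; colnames(b2) <- paste0("x", 1:8)
  expect_error(correlate_classes(em_of(a, "miRNA", gr),
                                 expr_matrix(b2, setNames(gr, colnames(b2)),
                                             "coding")),
               "identical sample")
})

test_that("negative-fraction summary reports both proportions", {
  pairs <- data.frame(r = c(-0.9, -0.5, 0.3, 0.7, -0.2),
                      adj_p = c(0.001, 0.2, 0.01, 0.5, 0.005))
  pairs$sign <- ifelse(pairs$r < 0, "negative", "positive")
  s <- summarize_negative_fraction(pairs, adj_p_max = 0.01)
  expect_equal(s$fraction_negative, 3 / 5)
  expect_equal(s$fraction_negative_significant, 2 / 3)
  # independent noise is negative about half the time
  set.seed(61)
  a <- matrix(rnbinom(20 * 30, mu = 100, size = 20), 20, 30,
              dimnames = list(paste0("m", 1:20), paste0("s", 1:30)))
  b <- matrix(rnbinom(40 * 30, mu = 100, size = 20), 40, 30,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:30)))
  gr <- rep(c("A", "B"), each = 15)
  ed <- correlate_classes(em_of(a, "miRNA", gr), em_of(b, "coding", gr),
                          filter = FALSE)
  s2 <- summarize_negative_fraction(ed)
  expect_lt(abs(s2$fraction_negative - 0.5), 0.1)
})

test_that("betweenness and degree match exhaustive path counting", {
  # path graph A-B-C: B carries the single geodesic
  corr <- data.frame(source = c("A", "B"), source_class = "miRNA",
                     target = c("B", "C"), target_class = "coding")
  net <- assemble_network(corr, node_classes = c(A = "miRNA", B = "mRNA",
                                                 C = "mRNA"))
  expect_equal(net$nodes$betweenness[net$nodes$id == "B"], 1)
  expect_equal(sum(net$nodes$betweenness[net$nodes$id != "B"]), 0)
  # star: center degree equals the leaf count
  leaves <- sprintf("L%02d", 1:50)
  star <- data.frame(source = "hub", source_class = "lncRNA",
                     target = leaves, target_class = "coding")
  snet <- assemble_network(star)
  expect_equal(snet$nodes$degree[snet$nodes$id == "hub"], 50)
  # handshake: sum of degrees is twice the edge count
  expect_equal(sum(snet$nodes$degree), 2 * nrow(snet$edges))

  set.seed(67)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    adj <- matrix(0L, n, n)
    for (a in 1:(n - 1)) for (b in (a + 1):n)
      if (runif(1) < 0.45) adj[a, b] <- adj[b, a] <- 1L
    if (sum(adj) == 0) next
    ij <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    corr <- data.frame(source = paste0("n", ij[, 1]), source_class = "miRNA",
                       target = paste0("n", ij[, 2]), target_class = "coding")
    net <- assemble_network(corr, node_classes = setNames(
      rep("mRNA", n), paste0("n", 1:n)))
    want <- brute_betweenness(adj)
    got <- want * 0
    got[match(net$nodes$id, paste0("n", 1:n))] <- net$nodes$betweenness
    expect_equal(got[rowSums(adj) > 0], want[rowSums(adj) > 0],
                 tolerance = 1e-9)
    expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))
  }
})

test_that("parallel edges collapse with merged provenance", {
  corr <- data.frame(source = "m1", source_class = "miRNA",
                     target = "g1", target_class = "coding")
  known <- data.frame(source = "m1", source_class = "miRNA",
                      target = "g1", target_class = "mRNA")
  net <- assemble_network(corr, known_pairs = known)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$provenance, "correlation;known_target")
})

test_that("unknown node classes are rejected", {
  corr <- data.frame(source = "m1", source_class = "plasmid",
                     target = "g1", target_class = "coding")
  expect_error(assemble_network(corr), "invalid node class")
})

test_that("hub thresholds are inclusive for lncRNA/TF and strict for miRNA", {
  mk_star <- function(center, class, k) {
    data.frame(source = center, source_class = class,
               target = sprintf("%s_t%03d", center, seq_len(k)),
               target_class = "mRNA")
  }
  corr <- rbind(mk_star("lnc50", "lncRNA", 50),
                mk_star("lnc49", "lncRNA", 49),
                mk_star("tf50", "TF", 50),
                mk_star("mir10", "miRNA", 10),
                mk_star("mir11", "miRNA", 11))
  net <- assemble_network(corr)
  hubs <- call_hubs(net)
  expect_setequal(hubs$id, c("lnc50", "tf50", "mir11"))
  expect_false("mir10" %in% hubs$id)   # degree 10 is NOT a hub (strict >)
  expect_false("lnc49" %in% hubs$id)
  # sorted by degree then betweenness, descending
  expect_equal(hubs$degree, sort(hubs$degree, decreasing = TRUE))
  # empty network gives an empty report
  empty <- assemble_network()
  expect_equal(nrow(call_hubs(empty)), 0)
})

test_that("master regulators rank TFs by target overrepresentation", {
  universe <- sprintf("g%03d", 1:40)
  members <- universe[1:10]
  corr <- data.frame(source = "m1", source_class = "miRNA",
                     target = members, target_class = "coding")
  tf_edges <- rbind(
    data.frame(tf = "TF_ALL", target = members),          # targets the network
    data.frame(tf = "TF_OFF", target = universe[31:35]))  # disjoint from it
  net <- assemble_network(corr)
  mr <- master_regulators(net, tf_edges, universe)
  expect_equal(mr$tf[1], "TF_ALL")
  expect_equal(mr$p[mr$tf == "TF_OFF"], 1)
  expect_lt(mr$p[1], 1e-6)
  # deterministic tie ordering by id
  tf_tie <- rbind(data.frame(tf = "B", target = universe[31:32]),
                  data.frame(tf = "A", target = universe[33:34]))
  mr2 <- master_regulators(net, tf_tie, universe)
  expect_equal(mr2$tf, c("A", "B"))
})
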