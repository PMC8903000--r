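#' Pairwise cross-class expression correlations
#'
#' Pearson correlation on log-CPM between every gene of one biotype and
#' every gene of another (e.g. miRNA vs mRNA), with the two-sided p from
#' the t transform of r at n - 2 degrees of freedom and BH adjustment
#' across all tested pairs. miRNA-mediated repression shows up here as
#' negative, significant pairs.
#'
#' @param matrix_a,matrix_b [expr_matrix] objects with identical sample
#'   columns (classes may differ).
#' @param adj_p_max,r_min_abs,sign_filter edge filters; `sign_filter` one
#'   of `"negative"`, `"positive"`, `"any"`. Use `filter = FALSE` to get
#'   every tested pair (needed by [summarize_negative_fraction()]).
#' @param filter apply the filters (default TRUE).
#' @param pseudocount passed to [log_cpm()].
#' @return data.frame with `source`, `source_class`, `target`,
#'   `target_class`, `r`, `p`, `adj_p`, `sign`; constant genes are
#'   skipped and counted in the `skipped` attribute.
#' @export
correlate_classes <- function(matrix_a, matrix_b, adj_p_max = 0.05,
                              r_min_abs = 0, sign_filter = c("any", "negative", "positive"),
                              filter = TRUE, pseudocount = 0.5) {
  sign_filter <- match.arg(sign_filter)
  stopifnot(inherits(matrix_a, "expr_matrix"), inherits(matrix_b, "expr_matrix"))
  if (!identical(colnames(matrix_a$counts), colnames(matrix_b$counts)))
    stop("matrices must share identical sample columns")
  la <- log_cpm(matrix_a, pseudocount)
  lb <- log_cpm(matrix_b, pseudocount)
  n <- ncol(la)
  if (n < 4) stop("need at least 4 shared samples")
  va <- apply(la, 1, stats::var) > 0
  vb <- apply(lb, 1, stats::var) > 0
  skipped <- sum(!va) * nrow(lb) + sum(va) * sum(!vb)
  la <- la[va, , drop = FALSE]; lb <- lb[vb, , drop = FALSE]
  r <- stats::cor(t(la), t(lb))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  out <- data.frame(source = rep(rownames(la), times = ncol(r)),
                    source_class = matrix_a$biotype,
                    target = rep(colnames(r), each = nrow(r)),
                    target_class = matrix_b$biotype,
                    r = as.vector(r),
                    p = as.vector(p),
                    stringsAsFactors = FALSE)
  out$adj_p <- bh_adjust(out$p)
  out$sign <- ifelse(out$r < 0, "negative", "positive")
  attr(out, "skipped") <- skipped
  if (filter) {
    keep <- out$adj_p <= adj_p_max & abs(out$r) >= r_min_abs
    if (sign_filter != "any") keep <- keep & out$sign == sign_filter
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Negative-correlation summary over all tested pairs
#'
#' The two headline proportions of the miRNA:mRNA correlation screen:
#' the fraction of all tested pairs that are negative, and the fraction
#' of those negative pairs that are significant at `adj_p < adj_p_max`.
#'
#' @param pairs unfiltered output of `correlate_classes(..., filter = FALSE)`.
#' @param adj_p_max significance cutoff among negatives (default 0.01).
#' @return list with `fraction_negative` and
#'   `fraction_negative_significant`.
#' @export
summarize_negative_fraction <- function(pairs, adj_p_max = 0.01) {
  neg <- pairs$sign == "negative"
  list(fraction_negative = mean(neg),
       fraction_negative_significant =
         if (any(neg)) mean(pairs$adj_p[neg] < adj_p_max) else NA_real_)
}

#' Assemble the typed regulatory network
#'
#' Union of correlation edges, TF-binding edges and known-interaction
#' edges into one undirected graph over mRNA/miRNA/lncRNA/TF nodes.
#' Parallel edges are collapsed with provenances merged. Degree and
#' betweenness (unweighted shortest-path counting, unnormalised by
#' default) are attached per node.
#'
#' @param correlation_edges data.frame from [correlate_classes()] (or
#'   NULL). `source_class`/`target_class` of `"coding"` map to `"mRNA"`.
#' @param tf_edges data.frame with columns `tf`, `target` (or NULL), e.g.
#'   motifs passing enrichment mapped to module genes.
#' @param known_pairs data.frame with columns `source`, `source_class`,
#'   `target`, `target_class` of curated (e.g. CLIP-supported) pairs, or
#'   NULL.
#' @param node_classes optional named character vector overriding or
#'   completing node classes (`mRNA`, `miRNA`, `lncRNA`, `TF`).
#' @param normalized normalise betweenness (default FALSE).
#' @return Object of class `regulatory_network`: list with `graph`
#'   (igraph), `nodes` (data.frame id, class, degree, betweenness) and
#'   `edges` (data.frame with provenance).
#' @export
assemble_network <- function(correlation_edges = NULL, tf_edges = NULL,
                             known_pairs = NULL, node_classes = NULL,
                             normalized = FALSE) {
  .map_class <- function(x) ifelse(x == "coding", "mRNA", x)
  ed <- list()
  if (!is.null(correlation_edges) && nrow(correlation_edges))
    ed$correlation <- data.frame(
      from = correlation_edges$source, to = correlation_edges$target,
      from_class = .map_class(correlation_edges$source_class),
      to_class = .map_class(correlation_edges$target_class),
      provenance = "correlation", stringsAsFactors = FALSE)
  if (!is.null(tf_edges) && nrow(tf_edges))
    ed$tf <- data.frame(
      from = tf_edges$tf, to = tf_edges$target,
      from_class = "TF",
      to_class = NA_character_,
      provenance = "tf_binding", stringsAsFactors = FALSE)
  if (!is.null(known_pairs) && nrow(known_pairs))
    ed$known <- data.frame(
      from = known_pairs$source, to = known_pairs$target,
      from_class = .map_class(known_pairs$source_class),
      to_class = .map_class(known_pairs$target_class),
      provenance = "known_target", stringsAsFactors = FALSE)
  edges <- do.call(rbind, unname(ed))
  if (is.null(edges) || nrow(edges) == 0) {
    nodes <- data.frame(id = character(0), class = character(0),
                        degree = integer(0), betweenness = numeric(0))
    return(structure(list(graph = igraph::make_empty_graph(directed = FALSE),
                          nodes = nodes, edges = data.frame()),
                     class = "regulatory_network"))
  }
  edges <- edges[edges$from != edges$to, , drop = FALSE]  # no self-loops
  # resolve node classes
  cls <- c(stats::setNames(edges$from_class, edges$from),
           stats::setNames(edges$to_class, edges$to))
  cls <- cls[!is.na(cls)]
  cls <- cls[!duplicated(names(cls))]
  if (!is.null(node_classes)) cls[names(node_classes)] <- node_classes
  ids <- unique(c(edges$from, edges$to))
  unknown <- setdiff(ids, names(cls))
  if (length(unknown))
    stop("edge endpoints of unknown class: ",
         paste(utils::head(unknown, 10), collapse = ", "))
  valid <- c("mRNA", "miRNA", "lncRNA", "TF")
  bad <- names(cls)[!cls %in% valid]
  if (length(bad))
    stop("invalid node class for: ", paste(utils::head(bad, 10), collapse = ", "))
  # collapse parallel edges, merging provenance
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  prov <- tapply(edges$provenance, key, function(x)
    paste(sort(unique(x)), collapse = ";"))
  first <- !duplicated(key)
  simple <- data.frame(from = pmin(edges$from, edges$to)[first],
                       to = pmax(edges$from, edges$to)[first],
                       provenance = unname(prov[key[first]]),
                       stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    simple, directed = FALSE,
    vertices = data.frame(name = ids, class = unname(cls[ids])))
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = normalized)
  nodes <- data.frame(id = igraph::V(g)$name, class = igraph::V(g)$class,
                      degree = unname(deg), betweenness = unname(btw),
                      stringsAsFactors = FALSE)
  structure(list(graph = g, nodes = nodes, edges = simple),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) print(table(x$nodes$class))
  invisible(x)
}

#' Call network hubs by class-specific degree thresholds
#'
#' lncRNA and TF nodes with degree >= `lnc_tf_degree_min` (default 50)
#' and miRNA nodes with degree strictly > `mirna_degree_min` (default
#' 10) are flagged as hubs; the report is sorted by degree then
#' betweenness, both descending.
#'
#' @param network a `regulatory_network`.
#' @param lnc_tf_degree_min inclusive threshold for lncRNA/TF (default 50).
#' @param mirna_degree_min exclusive threshold for miRNA (default 10).
#' @return data.frame of hubs (id, class, degree, betweenness) with the
#'   thresholds in attributes.
#' @export
call_hubs <- function(network, lnc_tf_degree_min = 50, mirna_degree_min = 10) {
  n <- network$nodes
  hub <- (n$class %in% c("lncRNA", "TF") & n$degree >= lnc_tf_degree_min) |
    (n$class == "miRNA" & n$degree > mirna_degree_min)
  out <- n[hub, , drop = FALSE]
  out <- out[order(-out$degree, -out$betweenness, out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lnc_tf_degree_min") <- lnc_tf_degree_min
  attr(out, "mirna_degree_min") <- mirna_degree_min
  out
}

#' Rank TFs as candidate master regulators
#'
#' Each TF's target set is tested for overrepresentation among the
#' network's member genes with [ora_hypergeometric()] over the annotated
#' universe, BH-adjusted, and ranked by ascending p (ties by TF id).
#'
#' @param network a `regulatory_network`.
#' @param tf_edges data.frame with columns `tf`, `target`.
#' @param universe character vector of all annotated genes.
#' @return data.frame `tf`, `n_targets`, `overlap`, `p`, `adj_p`,
#'   `enrichment_ratio`, sorted by p.
#' @export
master_regulators <- function(network, tf_edges, universe) {
  members <- intersect(network$nodes$id[network$nodes$class != "TF"], universe)
  if (length(members) == 0) stop("no network members inside the universe")
  tfs <- sort(unique(tf_edges$tf))
  rows <- lapply(tfs, function(tf) {
    targets <- intersect(unique(tf_edges$target[tf_edges$tf == tf]), universe)
    if (length(targets) == 0) {
      warning("TF with empty target set excluded: ", tf)
      return(NULL)
    }
    o <- ora_hypergeometric(members, targets, universe)
    data.frame(tf = tf, n_targets = length(targets), overlap = o$overlap,
               p = o$p, enrichment_ratio = o$enrichment_ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$adj_p <- bh_adjust(out$p)
  out <- out[order(out$p, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}
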