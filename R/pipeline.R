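#' Pipeline configuration
#'
#' Single configuration object for [run_pipeline()]: either a
#' [sim_config()] in `sim` (synthetic mode, the default) or a named list
#' of input `paths` (counts/design/annotation/tads/genome/pwms/
#' enhancers/known_pairs as written by [write_synthetic_inputs()]),
#' plus every stage parameter and the root seed. Unknown parameter names
#' are rejected.
#'
#' @param sim a [sim_config()] or NULL when reading from `paths`.
#' @param paths named list of input file paths (see above); entries may
#'   be omitted, in which case the dependent stages are skipped.
#' @param out_dir output directory (default: a fresh temporary dir).
#' @param ... stage parameters overriding the defaults listed in
#'   `pipeline_defaults()`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            out_dir = tempfile("myoregnet_"), ...) {
  defaults <- pipeline_defaults()
  extra <- list(...)
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown))
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(extra)] <- extra
  structure(c(list(sim = sim, paths = paths, out_dir = out_dir), defaults),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
pipeline_defaults <- function() {
  list(pseudocount = 0.5,
       fc_threshold = 1.5, fdr_threshold = 0.05,
       min_module_size = 30, correlation_threshold = 0.6, nperm = 1000,
       anchor = "tss", n_reps_tad = 1000,
       promoter_upstream = 10000, promoter_downstream = 5000,
       score_threshold_p = 1e-4, n_shuffles = 500, z_cutoff = 10,
       adj_p_max = 0.05, r_min_abs = 0,
       hub_degree_lnc_tf = 50, hub_degree_mirna = 10,
       panel_size = 29, n_low = 6, n_high = 6, n_mid = 5,
       seed = 1L)
}

.log_stage <- function(report, name, msg) {
  line <- sprintf("[%s] %s", name, msg)
  message(line)
  report$log <- c(report$log, line)
  report
}

#' Run the integrative pipeline end to end
#'
#' Orchestrates: synthetic-data generation (or file input) ->
#' differential expression (pooled labour vs no-labour for the ncRNA
#' biotypes) -> co-expression module detection and per-class net
#' enrichment scores -> TAD localisation fractions and non-randomness
#' test -> promoter motif enrichment and TF module specificity ->
#' integrated miRNA/lncRNA/mRNA/TF network with hub calling and master
#' regulators -> panel z-score sample ranking. Stages whose inputs are
#' unavailable are skipped with a logged notice. All randomness derives
#' from `config$seed`; outputs are written as TSV/JSON under
#' `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param write_outputs write result tables under `out_dir` (default TRUE).
#' @return report list with one element per stage plus `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), write_outputs = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(log = character(0), parameters = config[-(1:2)])
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  ## ---- inputs -----------------------------------------------------
  if (!is.null(config$sim)) {
    report <- .log_stage(report, "simulate",
                         sprintf("synthetic inputs, seed %d", config$sim$seed))
    sim <- simulate_all(config$sim)
    inputs <- sim
    report$truth <- sim$truth
  } else {
    if (is.null(config$paths)) stop("either sim or paths must be given")
    pth <- config$paths
    need <- c("counts_coding", "counts_mirna", "counts_lncrna", "design")
    miss <- setdiff(need, names(pth))
    if (length(miss))
      stop("stage input: missing required path(s): ",
           paste(miss, collapse = ", "))
    design <- read_design_tsv(pth$design)
    groups <- stats::setNames(design$group, design$sample_id)
    inputs <- list(
      coding = expr_matrix(read_counts_tsv(pth$counts_coding), groups, "coding"),
      lncrna = expr_matrix(read_counts_tsv(pth$counts_lncrna), groups, "lncRNA"),
      mirna = expr_matrix(read_counts_tsv(pth$counts_mirna), groups, "miRNA"),
      design = design,
      annotation = if (!is.null(pth$annotation_gff3))
        read_annotation_gff3(pth$annotation_gff3) else NULL,
      tads = if (!is.null(pth$tads)) read_tads_bed(pth$tads) else NULL,
      genome = if (!is.null(pth$genome))
        as.character(read_fasta(pth$genome)) else NULL,
      pwms = if (!is.null(pth$pwms)) read_jaspar(pth$pwms) else NULL,
      enhancers = if (!is.null(pth$enhancers))
        read_enhancers_tsv(pth$enhancers) else NULL,
      known_pairs = if (!is.null(pth$known_pairs))
        read_pairs_tsv(pth$known_pairs) else NULL)
    report <- .log_stage(report, "input", "loaded inputs from files")
  }
  groups <- inputs$coding$groups
  labour_groups <- setdiff(levels(groups), levels(groups)[1])
  ref_group <- levels(groups)[1]
  if ("NL" %in% levels(groups)) {
    ref_group <- "NL"
    labour_groups <- setdiff(levels(groups), "NL")
  }

  ## ---- differential expression ------------------------------------
  report <- .log_stage(report, "de", sprintf(
    "contrast %s vs %s, FC >= %.2f, FDR <= %.2f",
    paste(labour_groups, collapse = "+"), ref_group,
    config$fc_threshold, config$fdr_threshold))
  de <- lapply(inputs[c("coding", "lncrna", "mirna")], function(m)
    differential_expression(m, labour_groups, ref_group,
                            fc_threshold = config$fc_threshold,
                            fdr_threshold = config$fdr_threshold,
                            pseudocount = config$pseudocount))
  report$de <- de

  ## ---- co-expression modules --------------------------------------
  lc <- log_cpm(inputs$coding, config$pseudocount)
  modules <- detect_modules(lc, min_module_size = config$min_module_size,
                            correlation_threshold = config$correlation_threshold)
  report <- .log_stage(report, "modules", sprintf(
    "%d modules (%s)", length(modules$sizes),
    paste(modules$sizes, collapse = "/")))
  activity <- module_activity(modules, inputs$coding, nperm = config$nperm,
                              seed = config$seed,
                              pseudocount = config$pseudocount)
  report$modules <- modules
  report$module_activity <- activity

  ## ---- TAD localisation -------------------------------------------
  if (!is.null(inputs$annotation) && !is.null(inputs$tads)) {
    ann_coding <- inputs$annotation[inputs$annotation$gene_id %in%
                                      rownames(inputs$coding$counts), ]
    loc <- localize_genes(ann_coding, inputs$tads, anchor = config$anchor)
    tad_tests <- lapply(names(modules$sizes), function(m) {
      g <- module_genes(modules, m)
      t <- localization_test(loc, g, n_reps = config$n_reps_tad,
                             seed = config$seed + match(m, names(modules$sizes)))
      data.frame(module = m, n_genes = t$n_module,
                 within_fraction = t$observed_within,
                 null_within_mean = mean(t$null_within),
                 D = t$D, p = t$p, stringsAsFactors = FALSE)
    })
    report$tad <- list(localizations = loc,
                       tests = do.call(rbind, tad_tests))
    report <- .log_stage(report, "tads", paste(
      apply(report$tad$tests, 1, function(r)
        sprintf("%s: %.0f%% within (p=%.2g)", r[["module"]],
                100 * as.numeric(r[["within_fraction"]]),
                as.numeric(r[["p"]]))), collapse = "; "))
  } else {
    report <- .log_stage(report, "tads",
                         "skipped: annotation or TAD intervals not provided")
  }

  ## ---- motif enrichment -------------------------------------------
  if (!is.null(inputs$annotation) && !is.null(inputs$genome) &&
      !is.null(inputs$pwms)) {
    ann_coding <- inputs$annotation[inputs$annotation$gene_id %in%
                                      rownames(inputs$coding$counts), ]
    proms <- extract_promoters(ann_coding, inputs$genome,
                               upstream = config$promoter_upstream,
                               downstream = config$promoter_downstream)
    hits <- count_hits(proms, inputs$pwms,
                       score_threshold_p = config$score_threshold_p)
    mod_regions <- lapply(stats::setNames(nm = names(modules$sizes)),
                          function(m) intersect(module_genes(modules, m),
                                                rownames(hits)))
    background <- setdiff(rownames(hits), unlist(mod_regions))
    enr <- enrich_motifs(hits, mod_regions, background,
                         n_shuffles = config$n_shuffles,
                         seed = config$seed + 11L)
    spec <- if (length(mod_regions) >= 2)
      tf_module_specificity(enr, z_cutoff = config$z_cutoff,
                            adj_p_max = config$adj_p_max) else NULL
    report$motifs <- list(enrichment = enr, specificity = spec)
    report <- .log_stage(report, "motifs", sprintf(
      "%d motifs x %d modules; %d passing z >= %g",
      length(inputs$pwms), length(mod_regions),
      sum(enr$z >= config$z_cutoff & enr$adj_p <= config$adj_p_max,
          na.rm = TRUE), config$z_cutoff))
  } else {
    report <- .log_stage(report, "motifs",
                         "skipped: annotation, genome or PWMs not provided")
  }

  ## ---- integrative network ----------------------------------------
  mm_all <- correlate_classes(inputs$mirna, inputs$coding, filter = FALSE,
                              pseudocount = config$pseudocount)
  report$negative_summary <- summarize_negative_fraction(mm_all)
  keep <- mm_all$adj_p <= config$adj_p_max &
    abs(mm_all$r) >= config$r_min_abs & mm_all$sign == "negative"
  mm_edges <- mm_all[keep, , drop = FALSE]
  ml_edges <- correlate_classes(inputs$mirna, inputs$lncrna,
                                adj_p_max = config$adj_p_max,
                                r_min_abs = config$r_min_abs,
                                sign_filter = "negative",
                                pseudocount = config$pseudocount)
  corr_edges <- rbind(mm_edges, ml_edges)
  tf_edges <- NULL
  if (!is.null(report$motifs)) {
    enr <- report$motifs$enrichment
    pass <- enr[!enr$degenerate & enr$z >= config$z_cutoff &
                  enr$adj_p <= config$adj_p_max, ]
    if (nrow(pass)) {
      name_of <- stats::setNames(vapply(inputs$pwms, `[[`, character(1), "name"),
                                 vapply(inputs$pwms, `[[`, character(1), "id"))
      tf_edges <- do.call(rbind, lapply(seq_len(nrow(pass)), function(i)
        data.frame(tf = unname(name_of[pass$motif_id[i]]),
                   target = module_genes(modules, pass$module[i]),
                   stringsAsFactors = FALSE)))
    }
  }
  node_classes <- c(
    stats::setNames(rep("mRNA", nrow(inputs$coding$counts)),
                    rownames(inputs$coding$counts)),
    stats::setNames(rep("lncRNA", nrow(inputs$lncrna$counts)),
                    rownames(inputs$lncrna$counts)),
    stats::setNames(rep("miRNA", nrow(inputs$mirna$counts)),
                    rownames(inputs$mirna$counts)))
  if (!is.null(tf_edges))
    node_classes[unique(tf_edges$tf)] <- "TF"
  net <- assemble_network(corr_edges, tf_edges, inputs$known_pairs,
                          node_classes = node_classes)
  hubs <- call_hubs(net, lnc_tf_degree_min = config$hub_degree_lnc_tf,
                    mirna_degree_min = config$hub_degree_mirna)
  masters <- if (!is.null(tf_edges))
    master_regulators(net, tf_edges,
                      universe = if (!is.null(inputs$annotation))
                        inputs$annotation$gene_id
                      else rownames(inputs$coding$counts)) else NULL
  report$network <- net
  report$hubs <- hubs
  report$master_regulators <- masters
  report <- .log_stage(report, "network", sprintf(
    "%d nodes, %d edges, %d hubs", nrow(net$nodes), nrow(net$edges),
    nrow(hubs)))

  ## ---- sample ranking ---------------------------------------------
  ord <- order(de$coding$raw_p)
  panel <- de$coding$gene_id[ord][seq_len(min(config$panel_size,
                                              nrow(de$coding)))]
  ranking <- panel_zscores(inputs$coding, panel,
                           pseudocount = config$pseudocount)
  n <- nrow(ranking)
  sel <- if (config$n_low + config$n_mid + config$n_high <= n)
    select_extremes(ranking, config$n_low, config$n_high, config$n_mid)
  else NULL
  report$ranking <- ranking
  report$selection <- sel
  report <- .log_stage(report, "rank",
                       sprintf("panel of %d genes over %d samples",
                               length(panel), n))

  ## ---- outputs ----------------------------------------------------
  if (write_outputs) {
    p <- function(f) file.path(config$out_dir, f)
    for (b in names(de))
      utils::write.table(de[[b]], p(sprintf("de_%s.tsv", b)), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene_id = names(modules$assignments),
                 module = unname(modules$assignments)),
      p("module_membership.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(activity, p("module_activity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(report$tad)) {
      utils::write.table(report$tad$localizations, p("tad_localization.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(report$tad$tests, p("tad_tests.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(report$motifs))
      utils::write.table(report$motifs$enrichment, p("motif_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(net$nodes, p("network_nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(net$edges, p("network_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(hubs, p("hubs.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(ranking, p("sample_ranking.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(report$log, p("pipeline.log"))
  }
  report
}
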