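#' @name io
#' @title Readers and writers for the pipeline's file formats
#'
#' @description Counts and design tables as TSV; gene annotation as GFF3
#' (1-based inclusive) or BED (0-based half-open) via `rtracklayer`;
#' TADs as BED3; genomes as FASTA via `Biostrings`; PWMs in JASPAR 2016
#' text format; ground truth and reports as JSON. Emitted files
#' round-trip through the matching reader with no loss.
NULL

#' @rdname io
#' @param x object to write (see details per function).
#' @param path file path.
#' @export
write_counts_tsv <- function(x, path) {
  counts <- .as_counts(x)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' @rdname io
#' @param design data.frame with columns `sample_id`, `group`.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_design_tsv <- function(path) utils::read.delim(path)

#' @rdname io
#' @param annotation data.frame gene_id, chrom, start, end, strand,
#'   biotype (0-based half-open).
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1L, annotation$end),
    strand = annotation$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  S4Vectors::mcols(gr)$biotype <- annotation$biotype
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname io
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(gene_id = S4Vectors::mcols(gr)$ID,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   biotype = S4Vectors::mcols(gr)$biotype,
                   stringsAsFactors = FALSE)
  df$tss <- .gene_anchor(df, "tss")
  df
}

#' @rdname io
#' @export
write_annotation_bed <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1L, annotation$end),
    strand = annotation$strand)
  S4Vectors::mcols(gr)$name <- annotation$gene_id
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname io
#' @export
read_annotation_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- data.frame(gene_id = S4Vectors::mcols(gr)$name,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$tss <- .gene_anchor(df, "tss")
  df
}

#' @rdname io
#' @param tads a [tad_set()] or data.frame chrom/start/end.
#' @export
write_tads_bed <- function(tads, path) {
  gr <- GenomicRanges::GRanges(tads$chrom,
                               IRanges::IRanges(tads$start + 1L, tads$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname io
#' @export
read_tads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tad_set(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE))
}

#' @rdname io
#' @param genome named character vector or `DNAStringSet`.
#' @export
write_fasta <- function(genome, path) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname io
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  names(s) <- sub("\\s.*", "", names(s))
  s
}

#' @rdname io
#' @param pwms list of [pwm] objects.
#' @export
write_jaspar <- function(pwms, path, counts_scale = 100) {
  lines <- unlist(lapply(pwms, function(p) {
    m <- round(p$matrix * counts_scale, 4)
    c(paste0(">", p$id, " ", p$name),
      vapply(c("A", "C", "G", "T"), function(b)
        sprintf("%s  [ %s ]", b, paste(m[b, ], collapse = " ")),
        character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname io
#' @param background,pseudocount passed to [pwm()] on read.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  lapply(heads, function(h) {
    hdr <- strsplit(sub("^>", "", lines[h]), "\\s+")[[1]]
    rows <- lines[h + 1:4]
    m <- do.call(rbind, lapply(rows, function(r) {
      body <- sub("^\\s*[ACGTacgt]", "", r)
      as.numeric(regmatches(body, gregexpr("-?[0-9.eE+-]+", body))[[1]])
    }))
    rownames(m) <- toupper(substr(trimws(rows), 1, 1))
    pwm(m, id = hdr[1], name = if (length(hdr) > 1) hdr[2] else hdr[1],
        background = background, pseudocount = pseudocount)
  })
}

#' @rdname io
#' @param enhancers data.frame chrom, start, end, gene_id.
#' @export
write_enhancers_tsv <- function(enhancers, path) {
  utils::write.table(enhancers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' @rdname io
#' @export
read_enhancers_tsv <- function(path) {
  df <- utils::read.delim(path, na.strings = ".")
  df$gene_id <- as.character(df$gene_id)
  df
}

#' @rdname io
#' @param pairs data.frame source, source_class, target, target_class.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_pairs_tsv <- function(path) utils::read.delim(path)

#' @rdname io
#' @param truth ground-truth list from the simulator.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname io
#' @export
read_truth_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Write every synthetic input to a directory
#'
#' Materialises a [simulate_all()] bundle as the pipeline's on-disk
#' input set (counts and design TSVs, GFF3 + BED annotation, TADs BED,
#' genome FASTA, enhancer TSV, JASPAR PWMs, known-pairs TSV, ground
#' truth JSON).
#'
#' @param sim output of [simulate_all()].
#' @param dir target directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_synthetic_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_counts_tsv(sim$coding, p("counts_coding.tsv"))
  write_counts_tsv(sim$lncrna, p("counts_lncrna.tsv"))
  write_counts_tsv(sim$mirna, p("counts_mirna.tsv"))
  write_design_tsv(sim$design, p("design.tsv"))
  write_annotation_gff3(sim$annotation, p("annotation.gff3"))
  write_annotation_bed(sim$annotation, p("annotation.bed"))
  write_tads_bed(sim$tads, p("tads.bed"))
  write_fasta(sim$genome, p("genome.fa"))
  write_enhancers_tsv(sim$enhancers, p("enhancers.tsv"))
  write_jaspar(sim$pwms, p("motifs.jaspar"))
  write_pairs_tsv(sim$known_pairs, p("known_pairs.tsv"))
  write_truth_json(sim$truth, p("truth.json"))
  out <- c(counts_coding = p("counts_coding.tsv"),
           counts_lncrna = p("counts_lncrna.tsv"),
           counts_mirna = p("counts_mirna.tsv"),
           design = p("design.tsv"),
           annotation_gff3 = p("annotation.gff3"),
           annotation_bed = p("annotation.bed"),
           tads = p("tads.bed"), genome = p("genome.fa"),
           enhancers = p("enhancers.tsv"), pwms = p("motifs.jaspar"),
           known_pairs = p("known_pairs.tsv"), truth = p("truth.json"))
  out
}
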