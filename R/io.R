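#' Read and write the pipeline's tabular formats
#'
#' Counts are TSV with gene ids in the first column and library ids in the
#' header; the tissue map is a two-column TSV (`library`, `tissue`); network
#' truth is a three-column TSV (`regulator`, `target`, `effect`); ranked edge
#' lists are three-column TSV (`regulator`, `target`, `weight`); peaks are
#' 6-column BED (0-based, half-open, summit as a single-base interval); gene
#' models are GFF3 (1-based, inclusive).
#'
#' @param counts gene x library matrix.
#' @param file path.
#' @name grn_io
NULL

#' @rdname grn_io
#' @export
write_counts <- function(counts, file) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname grn_io
#' @export
read_counts <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' @rdname grn_io
#' @param tissue_of named character vector, library -> tissue.
#' @export
write_tissue_map <- function(tissue_of, file) {
  utils::write.table(data.frame(library = names(tissue_of),
                                tissue = unname(tissue_of)),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname grn_io
#' @export
read_tissue_map <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  stats::setNames(df$tissue, df$library)
}

#' @rdname grn_io
#' @param net a `true_network`.
#' @export
write_network <- function(net, file) {
  utils::write.table(net$edges, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname grn_io
#' @param grn a [ranked_edges] network.
#' @export
write_edges <- function(grn, file) {
  utils::write.table(as.data.frame(grn), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname grn_io
#' @param tfs optional declared TF set for the edge list.
#' @export
read_edges <- function(file, tfs = NULL) {
  ranked_edges(utils::read.delim(file, stringsAsFactors = FALSE), tfs = tfs)
}

#' @rdname grn_io
#' @param peaks data.frame with `chrom`, `summit` (0-based), optional `score`.
#' @export
write_peaks_bed <- function(peaks, file) {
  n <- nrow(peaks)
  bed <- data.frame(chrom = peaks$chrom,
                    start = peaks$summit,
                    end = peaks$summit + 1L,
                    name = paste0("peak_", seq_len(max(n, 0))),
                    score = if ("score" %in% names(peaks)) peaks$score else 0,
                    strand = ".")
  utils::write.table(bed[seq_len(n), , drop = FALSE], file, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname grn_io
#' @export
read_peaks_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             summit = GenomicRanges::start(gr) - 1L,  # back to 0-based
             score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
             stringsAsFactors = FALSE)
}

#' @rdname grn_io
#' @param annotation data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based, inclusive).
#' @export
write_annotation_gff3 <- function(annotation, file) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    strand = annotation$strand)
  gr$type <- "gene"
  gr$ID <- annotation$gene_id
  gr$source <- "tissueGRN"
  rtracklayer::export(gr, file, format = "GFF3")
  invisible(file)
}

#' @rdname grn_io
#' @export
read_annotation_gff3 <- function(file) {
  gr <- rtracklayer::import(file, format = "GFF3")
  gr <- gr[gr$type == "gene"]
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  data.frame(gene_id = id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname grn_io
#' @param x a list-like report (e.g. an `eval_report`).
#' @export
write_report_json <- function(x, file) {
  jsonlite::write_json(unclass(x), file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
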