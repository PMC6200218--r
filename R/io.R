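## Plain-text writers for the standard formats the pipeline emits.

#' Write a genome bundle to a directory
#'
#' Emits `genome.fa`, `genes.gff3`, `tes.gff3`, `truth.tsv` and
#' `chrom_meta.tsv`. GFF3 coordinates are 1-based inclusive.
#'
#' @param genome a `mite_genome`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "mite_genome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(genome$seq, file.path(dir, "genome.fa"))
  feats <- genome$features
  gene_rows <- feats[is.na(feats$class) | feats$type == "gene", , drop = FALSE]
  gene_rows <- feats[feats$type != "transposable_element", , drop = FALSE]
  te_rows <- feats[feats$type == "transposable_element", , drop = FALSE]
  .write_gff3(gene_rows, file.path(dir, "genes.gff3"))
  .write_gff3(te_rows, file.path(dir, "tes.gff3"), te = TRUE)
  utils::write.table(as.data.frame(genome$truth),
                     file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(genome$chrom_meta, file.path(dir, "chrom_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

.write_gff3 <- function(rows, path, te = FALSE) {
  if (nrow(rows) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand)
  S4Vectors::mcols(gr)$type <- rows$type
  S4Vectors::mcols(gr)$ID <- rows$id
  if (!te) {
    S4Vectors::mcols(gr)$Parent <- ifelse(is.na(rows$parent), NA,
                                          rows$parent)
  } else {
    S4Vectors::mcols(gr)$family <- rows$parent
    S4Vectors::mcols(gr)$class <- rows$class
  }
  S4Vectors::mcols(gr)$source <- "mitescope"
  ## CDS rows carry no phase (synthetic models); the exporter warns
  suppressWarnings(rtracklayer::export(gr, path, format = "gff3"))
  invisible(path)
}

#' Write insertion records as TSV
#'
#' @param records a `mite_insertions` data.frame.
#' @param path output path.
#' @param stage,params optional header-comment metadata naming the producing
#'   stage and its parameters.
#' @return invisibly, `path`.
#' @export
write_insertions_tsv <- function(records, path, stage = NULL,
                                 params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(stage)) {
    writeLines(paste0("# stage: ", stage), con)
  }
  if (!is.null(params)) {
    writeLines(paste0("# params: ", paste(names(params), params, sep = "=",
                                          collapse = " ")), con)
  }
  utils::write.table(as.data.frame(records), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an insertion TSV written by [write_insertions_tsv()]
#'
#' @param path TSV path (header comments tolerated).
#' @return a `mite_insertions` data.frame.
#' @export
read_insertions_tsv <- function(path) {
  out <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  class(out) <- c("mite_insertions", "data.frame")
  out
}

#' Write insertion records as BED6
#'
#' BED is 0-based, half-open: `start - 1` and `end` of the 1-based inclusive
#' records. The score column carries `int(identity * 1000)`.
#'
#' @param records a `mite_insertions` data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_insertions_bed <- function(records, path) {
  sc <- records$identity
  sc[is.na(sc)] <- 0
  bed <- data.frame(chrom = records$chrom,
                    start = records$start - 1L,
                    end = records$end,
                    name = records$family,
                    score = as.integer(sc * 1000),
                    strand = records$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a position frequency matrix as TSV
#'
#' @param pfm a `mite_pfm`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pfm_tsv <- function(pfm, path) {
  df <- data.frame(position = seq_len(nrow(pfm)), unclass(pfm)[, , drop = FALSE],
                   information_content = information_content(pfm))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
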