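## Homology retrieval of MITE insertions.
##
## A family consensus is searched against both strands of every chromosome
## with seeded local alignment. Hits are kept when their e-value passes the
## threshold AND the alignment reaches within `end_tol` consensus bases of
## BOTH termini, so near-full-length (possibly end-truncated) copies are
## retrieved while internal fragments are not. 500 bp of flanking sequence
## is captured on each side for locus identity and annotation.

#' Retrieve MITE insertions of one family from a genome
#'
#' @param genome a `mite_genome`, or a named `DNAStringSet` / named character
#'   vector of chromosome sequences.
#' @param family family name (used to label records).
#' @param consensus family consensus DNA string. For a `mite_genome` input
#'   whose spec plants the family, the spec consensus is used when this is
#'   `NULL`; otherwise it must be supplied.
#' @param max_evalue e-value threshold (default 1e-3).
#' @param end_tol end mismatch tolerance in consensus bases: the alignment
#'   may stop up to this many bases short of each consensus terminus
#'   (default 20).
#' @param flank_len flank length captured on each side (default 500 bp).
#' @param scoring alignment scoring, see [default_scoring()].
#' @return a `mite_insertions` data.frame sorted by (chrom, start): one row
#'   per retrieved copy with coordinates (1-based inclusive, forward
#'   strand), strand, element and flank sequences, truncation flags, end
#'   gaps, identity, score and e-value.
#' @export
retrieve_insertions <- function(genome, family, consensus = NULL,
                                max_evalue = 1e-3, end_tol = 20L,
                                flank_len = 500L,
                                scoring = default_scoring()) {
  seqs <- .genome_seqs(genome)
  if (is.null(consensus) && inherits(genome, "mite_genome")) {
    fam <- genome$spec$families
    if (!is.null(fam) && family %in% fam$family) {
      consensus <- fam$consensus[fam$family == family]
    }
  }
  if (is.null(consensus) || !nzchar(consensus)) {
    stop("family '", family, "' lacks a consensus sequence")
  }
  qlen <- nchar(consensus)
  genome_len <- sum(nchar(seqs))
  queries <- c(`+` = consensus, `-` = revcomp(consensus))
  ## hits below this score cannot pass the e-value threshold; pruning at
  ## the alignment stage keeps per-window re-alignment bounded
  score_floor <- log(.KA_K * qlen * genome_len / max_evalue) /
    ka_lambda(scoring)
  recs <- list()
  for (ch in names(seqs)) {
    s <- seqs[[ch]]
    ch_hits <- list()
    for (strand in c("+", "-")) {
      hits <- local_align(queries[[strand]], s, scoring = scoring,
                          min_score = score_floor)
      if (nrow(hits) == 0L) next
      hits$evalue <- evalue(hits$score, qlen, genome_len, scoring)
      if (strand == "+") {
        hits$end_gap5 <- hits$query_start - 1L
        hits$end_gap3 <- qlen - hits$query_end
      } else {
        ## query was the reverse complement: its left end is the consensus 3'
        hits$end_gap5 <- qlen - hits$query_end
        hits$end_gap3 <- hits$query_start - 1L
      }
      hits$strand <- strand
      ch_hits[[strand]] <- hits
    }
    hits <- do.call(rbind, ch_hits)
    if (is.null(hits) || nrow(hits) == 0L) next
    hits <- hits[hits$evalue <= max_evalue &
                   hits$end_gap5 <= end_tol & hits$end_gap3 <= end_tol, ,
                 drop = FALSE]
    if (nrow(hits) == 0L) next
    hits <- .resolve_overlaps(hits)
    L <- nchar(s)
    n <- nrow(hits)
    f5s <- pmax(1L, hits$subject_start - flank_len)
    f3e <- pmin(L, hits$subject_end + flank_len)
    recs[[ch]] <- data.frame(
      family = family, chrom = ch,
      start = hits$subject_start, end = hits$subject_end,
      strand = hits$strand,
      element_seq = substring(s, hits$subject_start, hits$subject_end),
      flank5 = substring(s, f5s, hits$subject_start - 1L),
      flank3 = substring(s, hits$subject_end + 1L, f3e),
      flank5_truncated = (hits$subject_start - f5s) < flank_len,
      flank3_truncated = (f3e - hits$subject_end) < flank_len,
      end_gap5 = hits$end_gap5, end_gap3 = hits$end_gap3,
      identity = hits$identity, score = hits$score, evalue = hits$evalue,
      stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else data.frame(
    family = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), element_seq = character(0),
    flank5 = character(0), flank3 = character(0),
    flank5_truncated = logical(0), flank3_truncated = logical(0),
    end_gap5 = integer(0), end_gap3 = integer(0), identity = numeric(0),
    score = numeric(0), evalue = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mite_insertions", "data.frame")
  out
}

## Among hits overlapping by more than half the shorter interval (e.g. the
## same locus found on both strands of a TIR-bounded element), keep the
## higher score; ties broken by genomic order then '+' strand.
.resolve_overlaps <- function(hits) {
  ord <- order(-hits$score, hits$subject_start, hits$strand)
  hits <- hits[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    prior <- which(keep[seq_len(i - 1L)])
    ov <- pmin(hits$subject_end[prior], hits$subject_end[i]) -
      pmax(hits$subject_start[prior], hits$subject_start[i]) + 1L
    wmin <- pmin(hits$subject_end[prior] - hits$subject_start[prior],
                 hits$subject_end[i] - hits$subject_start[i]) + 1L
    if (any(ov > wmin / 2)) keep[i] <- FALSE
  }
  hits[keep, , drop = FALSE]
}

## Chromosome sequences of any accepted genome representation.
.genome_seqs <- function(genome) {
  if (inherits(genome, "mite_genome")) {
    seqs <- as.character(genome$seq)
  } else if (inherits(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome)) {
    seqs <- genome
  } else {
    stop("unsupported genome representation")
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("chromosome sequences must be named")
  }
  seqs
}

#' Remove exact assembly duplicates among insertion records
#'
#' Records whose element plus both flanks are character-identical are
#' assembly duplicates of one locus; one record per identical group is kept
#' (the lowest (chrom, start)). The operation is idempotent and the output
#' is sorted by (chrom, start).
#'
#' @param records a `mite_insertions` data.frame (one family, one genome).
#' @return the deduplicated `mite_insertions`.
#' @export
deduplicate <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) return(records)
  key <- paste(records$element_seq, records$flank5, records$flank3,
               sep = "\r")
  ord <- order(records$chrom, records$start)
  records <- records[ord, , drop = FALSE]
  key <- key[ord]
  out <- records[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mite_insertions", "data.frame")
  out
}

#' Scan a genome for every catalog family with a consensus
#'
#' Runs [retrieve_insertions()] followed by [deduplicate()] for each family
#' in the catalog that has a consensus sequence, and binds the results.
#'
#' @inheritParams retrieve_insertions
#' @param catalog a `mite_catalog` whose `consensus` holds the query
#'   sequences, or a data.frame with `family` and `consensus` columns (the
#'   planted-family table of a [genome_spec()] works).
#' @return a combined `mite_insertions` data.frame.
#' @export
scan_genome <- function(genome, catalog, max_evalue = 1e-3, end_tol = 20L,
                        flank_len = 500L, scoring = default_scoring()) {
  if (inherits(catalog, "mite_catalog")) {
    fams <- names(catalog$consensus)
    cons <- as.character(catalog$consensus)
  } else {
    stopifnot(is.data.frame(catalog),
              all(c("family", "consensus") %in% names(catalog)))
    fams <- catalog$family
    cons <- catalog$consensus
  }
  keep <- nzchar(cons) & !is.na(cons)
  fams <- fams[keep]
  cons <- cons[keep]
  if (length(fams) == 0L) stop("catalog has no family with a consensus")
  res <- lapply(seq_along(fams), function(i) {
    deduplicate(retrieve_insertions(genome, fams[i], cons[i],
                                    max_evalue = max_evalue,
                                    end_tol = end_tol, flank_len = flank_len,
                                    scoring = scoring))
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  class(out) <- c("mite_insertions", "data.frame")
  out
}

#' @export
print.mite_insertions <- function(x, ...) {
  cat("MITE insertion records: ", nrow(x), "\n", sep = "")
  if (nrow(x)) {
    tab <- sort(table(x$family), decreasing = TRUE)
    cat("  families: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
    show_cols <- c("family", "chrom", "start", "end", "strand", "identity",
                   "evalue")
    print(utils::head(as.data.frame(x)[, intersect(show_cols, names(x))], 6))
    if (nrow(x) > 6) cat("  ...\n")
  }
  invisible(x)
}
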