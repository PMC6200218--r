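## Genomic-context annotation of MITE insertions.
##
## Each insertion's element body and both flanks are aligned against a
## reference set (spliced gene transcripts, a host-TE library with class
## labels, ncRNA sequences); the single best hit at or below the e-value
## threshold fixes the category. Independently of homology, interval logic
## against the gene models classifies gene association (intron / exon /
## within 100 bp upstream or downstream) and locates in-transcript
## insertions by region (5'UTR / CDS / 3'UTR).

#' Build a reference set for annotation
#'
#' For a simulated genome this extracts spliced transcript sequences
#' (5'UTR + CDS + 3'UTR in transcription order, reverse-complemented for
#' minus-strand genes) and pairs them with the genome's host-TE library.
#'
#' @param genome a `mite_genome`.
#' @param ncrna optional named `DNAStringSet` of ncRNA sequences.
#' @return an object of class `mite_refset`: list with `cdna` (named
#'   `DNAStringSet`), `te` (named `DNAStringSet`), `te_class` (named
#'   character), `ncrna`, and `gene_models` (feature data.frame).
#' @export
reference_set <- function(genome, ncrna = Biostrings::DNAStringSet()) {
  stopifnot(inherits(genome, "mite_genome"))
  feats <- genome$features
  genes <- feats[feats$type == "gene", , drop = FALSE]
  cdna <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    parts <- feats[!is.na(feats$parent) & feats$parent == g$id &
                     feats$type %in% c("five_prime_UTR", "CDS",
                                       "three_prime_UTR"), , drop = FALSE]
    parts <- parts[order(parts$start), , drop = FALSE]
    s <- as.character(genome$seq[[g$chrom]])
    spliced <- paste(substring(s, parts$start, parts$end), collapse = "")
    if (g$strand == "-") spliced <- revcomp(spliced)
    cdna[[g$id]] <- spliced
  }
  te_classes <- attr(genome$te_library, "classes")
  structure(list(
    cdna = Biostrings::DNAStringSet(cdna),
    te = genome$te_library,
    te_class = stats::setNames(te_classes$class, te_classes$entry),
    ncrna = ncrna,
    gene_models = feats), class = "mite_refset")
}

## One pooled reference table: id, type, sequence.
.ref_table <- function(refs) {
  data.frame(
    id = c(names(refs$cdna), names(refs$te), names(refs$ncrna)),
    type = c(rep("cdna", length(refs$cdna)),
             rep("te", length(refs$te)),
             rep("ncrna", length(refs$ncrna))),
    seq = c(as.character(refs$cdna), as.character(refs$te),
            as.character(refs$ncrna)),
    stringsAsFactors = FALSE)
}

#' Annotate insertions against a reference set
#'
#' @param records a `mite_insertions` data.frame.
#' @param refs a `mite_refset` (see [reference_set()]).
#' @param max_evalue annotation e-value threshold (default 1e-10).
#' @param window gene-association window in bp (default 100, boundary
#'   inclusive).
#' @param scoring alignment scoring, see [default_scoring()].
#' @return `records` with columns appended: `category` (one of
#'   `protein_coding_gene`, `TE_classI`, `TE_classII`, `ncRNA`, `unknown`),
#'   `target_id`, `best_evalue`, `gene_relation` (`intron`, `exon`,
#'   `upstream_le100`, `downstream_le100`, `none`) and `distance_to_gene`.
#' @export
annotate_insertions <- function(records, refs, max_evalue = 1e-10,
                                window = 100L, scoring = default_scoring()) {
  stopifnot(inherits(refs, "mite_refset"), is.data.frame(records))
  rt <- .ref_table(refs)
  n <- nrow(records)
  category <- rep("unknown", n)
  target_id <- rep(NA_character_, n)
  best_ev <- rep(NA_real_, n)
  total_len <- sum(nchar(rt$seq))
  mat <- .subst_matrix(scoring)
  ref_set <- if (nrow(rt)) Biostrings::DNAStringSet(rt$seq) else NULL
  for (i in seq_len(n)) {
    queries <- c(records$element_seq[i], records$flank5[i],
                 records$flank3[i])
    queries <- queries[nzchar(queries)]
    ## references are stranded (spliced cDNA, library entries); search both
    ## orientations of each query
    queries <- c(queries, revcomp(queries))
    best <- NULL
    if (!is.null(ref_set)) {
      for (q in queries) {
        aln <- Biostrings::pairwiseAlignment(
          pattern = ref_set, subject = q, type = "local",
          substitutionMatrix = mat, gapOpening = -scoring$gap_open,
          gapExtension = -scoring$gap_extend)
        sc <- Biostrings::score(aln)
        ev <- evalue(pmax(sc, 0), nchar(q), total_len, scoring)
        hit <- which(ev <= max_evalue)
        if (length(hit) == 0L) next
        cand <- data.frame(id = rt$id[hit], type = rt$type[hit],
                           evalue = ev[hit], score = sc[hit],
                           stringsAsFactors = FALSE)
        best_q <- cand[order(cand$evalue, -cand$score, cand$id), ][1, ]
        if (is.null(best) || best_q$evalue < best$evalue ||
            (best_q$evalue == best$evalue && best_q$score > best$score) ||
            (best_q$evalue == best$evalue && best_q$score == best$score &&
               best_q$id < best$id)) {
          best <- best_q
        }
      }
    }
    if (!is.null(best)) {
      target_id[i] <- best$id
      best_ev[i] <- best$evalue
      category[i] <- switch(best$type,
        cdna = "protein_coding_gene",
        ncrna = "ncRNA",
        te = paste0("TE_", refs$te_class[[best$id]]))
    }
  }
  ga <- classify_gene_association(records, refs$gene_models, window = window)
  records$category <- category
  records$target_id <- target_id
  records$best_evalue <- best_ev
  records$gene_relation <- ga$gene_relation
  records$distance_to_gene <- ga$distance_to_gene
  class(records) <- c("mite_insertions", "data.frame")
  records
}

#' Classify gene association of insertions by interval logic
#'
#' Overlap with an exonic part (UTR or CDS) classifies as `exon`; otherwise
#' overlap with an intron as `intron`; otherwise an insertion whose distance
#' to the nearest gene is at most `window` bp (boundary inclusive) is
#' `upstream_le100` or `downstream_le100` according to that gene's strand;
#' anything else is `none`.
#'
#' @param records a `mite_insertions` data.frame (needs `chrom`, `start`,
#'   `end`).
#' @param gene_models feature data.frame with `gene` rows and
#'   `five_prime_UTR`/`CDS`/`three_prime_UTR`/`intron` parts (the simulator's
#'   `features` table).
#' @param window association window in bp.
#' @return data.frame with `gene_relation`, `distance_to_gene`,
#'   `nearest_gene`.
#' @export
classify_gene_association <- function(records, gene_models, window = 100L) {
  n <- nrow(records)
  rel <- rep("none", n)
  dist <- rep(NA_real_, n)
  nearest <- rep(NA_character_, n)
  genes <- gene_models[gene_models$type == "gene", , drop = FALSE]
  exonic <- gene_models[gene_models$type %in%
                          c("five_prime_UTR", "CDS", "three_prime_UTR"), ,
                        drop = FALSE]
  introns <- gene_models[gene_models$type == "intron", , drop = FALSE]
  overlaps <- function(tab, i) {
    hit <- tab$chrom == records$chrom[i] & tab$start <= records$end[i] &
      tab$end >= records$start[i]
    which(hit)
  }
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == records$chrom[i], , drop = FALSE]
    overlapping <- FALSE
    if (nrow(g)) {
      ov <- g$start <= records$end[i] & g$end >= records$start[i]
      ## gap in bases between the element and the gene (0 when adjacent or
      ## overlapping): half-open boundary arithmetic
      d <- ifelse(ov, 0, pmax(g$start - records$end[i] - 1L,
                              records$start[i] - g$end - 1L))
      j <- which.min(d)
      dist[i] <- d[j]
      nearest[i] <- g$id[j]
      overlapping <- any(ov)
    }
    if (length(overlaps(exonic, i))) {
      rel[i] <- "exon"
    } else if (length(overlaps(introns, i)) || overlapping) {
      ## inside the gene: an intron hit, or (degenerate) inside the gene
      ## interval but in no annotated part
      rel[i] <- "intron"
    } else if (!is.na(dist[i]) && dist[i] <= window) {
      ov <- g$start <= records$end[i] & g$end >= records$start[i]
      d <- ifelse(ov, 0, pmax(g$start - records$end[i] - 1L,
                              records$start[i] - g$end - 1L))
      j <- which.min(d)
      before <- records$end[i] < g$start[j]
      upstream <- (g$strand[j] == "+" && before) ||
        (g$strand[j] == "-" && !before)
      rel[i] <- if (upstream) "upstream_le100" else "downstream_le100"
    }
  }
  data.frame(gene_relation = rel, distance_to_gene = dist,
             nearest_gene = nearest, stringsAsFactors = FALSE)
}

#' Locate an insertion within a transcript
#'
#' Assigns the transcript region (5'UTR, CDS or 3'UTR) containing the
#' insertion midpoint; returns `"spanning"` when the insertion crosses a
#' region boundary with more than 10% of its length on each side.
#'
#' @param start,end insertion interval (1-based inclusive, genomic).
#' @param transcript_parts data.frame of the transcript's
#'   `five_prime_UTR`/`CDS`/`three_prime_UTR` features (genomic intervals
#'   with a `strand` column).
#' @return one of `"five_prime_utr"`, `"cds"`, `"three_prime_utr"`,
#'   `"spanning"`, or `NA` if the midpoint lies outside the transcript.
#' @export
locate_in_transcript <- function(start, end, transcript_parts) {
  stopifnot(end >= start, nrow(transcript_parts) > 0)
  parts <- transcript_parts[transcript_parts$type %in%
                              c("five_prime_UTR", "CDS",
                                "three_prime_UTR"), , drop = FALSE]
  len <- end - start + 1
  ov <- pmin(parts$end, end) - pmax(parts$start, start) + 1
  ov[ov < 0] <- 0
  ## merge CDS parts: region identity, not exon identity
  region_of <- c(five_prime_UTR = "five_prime_utr", CDS = "cds",
                 three_prime_UTR = "three_prime_utr")
  reg_ov <- tapply(ov, region_of[parts$type], sum)
  substantial <- reg_ov[reg_ov > 0.10 * len]
  if (length(substantial) >= 2L) return("spanning")
  mid <- (start + end) %/% 2
  inside <- which(parts$start <= mid & parts$end >= mid)
  if (length(inside) == 0L) return(NA_character_)
  unname(region_of[parts$type[inside[1]]])
}

#' Summarize in-transcript locations for a set of insertions
#'
#' @param records a `mite_insertions` data.frame.
#' @param gene_models the simulator's feature table.
#' @return a data.frame of per-record region calls (`region` column; `NA`
#'   when the insertion is not inside a transcript).
#' @export
locate_in_transcripts <- function(records, gene_models) {
  n <- nrow(records)
  region <- rep(NA_character_, n)
  genes <- gene_models[gene_models$type == "gene", , drop = FALSE]
  for (i in seq_len(n)) {
    hit <- which(genes$chrom == records$chrom[i] &
                   genes$start <= records$start[i] &
                   genes$end >= records$end[i])
    if (length(hit) == 0L) next
    gid <- genes$id[hit[1]]
    parts <- gene_models[!is.na(gene_models$parent) &
                           gene_models$parent == gid, , drop = FALSE]
    region[i] <- locate_in_transcript(records$start[i], records$end[i],
                                      parts)
  }
  data.frame(region = region, stringsAsFactors = FALSE)
}
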