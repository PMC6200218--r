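## Structural characterization of retrieved elements: terminal inverted
## repeats, target site duplications, position frequency matrices with
## information content, haplotype diversity, and consensus building.

#' Detect a terminal inverted repeat
#'
#' Returns the longest terminal prefix (length in `[min_len, max_len]`)
#' whose reverse complement matches the terminal suffix with at most
#' `max_mismatch` mismatches, or `NULL` if no length qualifies. The search
#' is strand-symmetric: a sequence and its reverse complement give the same
#' TIR length and mismatch count.
#'
#' @param element_seq DNA string of length at least `2 * min_len`.
#' @param min_len,max_len TIR length bounds in bp.
#' @param max_mismatch maximum tolerated mismatches between the prefix and
#'   the reverse complement of the suffix.
#' @return a list of class `tir_annotation` with `tir_len`, `mismatches`,
#'   `left_seq`, `right_seq`, or `NULL`.
#' @export
find_tir <- function(element_seq, min_len = 8L, max_len = 30L,
                     max_mismatch = 2L) {
  n <- nchar(element_seq)
  stopifnot(n >= 2L * min_len)
  max_len <- min(max_len, n %/% 2L)
  ch <- strsplit(element_seq, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ## per-position mismatch indicator between the prefix and the reverse
  ## complement of the suffix; cumulated so every length is O(1)
  mism <- cumsum(ch[seq_len(max_len)] !=
                   comp[ch[n - seq_len(max_len) + 1L]])
  for (len in seq(max_len, min_len)) {
    if (mism[len] <= max_mismatch) {
      return(structure(list(tir_len = len, mismatches = as.integer(mism[len]),
                            left_seq = substr(element_seq, 1L, len),
                            right_seq = substr(element_seq, n - len + 1L, n)),
                       class = "tir_annotation"))
    }
  }
  NULL
}

#' Call the target site duplication of an insertion record
#'
#' Compares the sequence immediately left of the element with the sequence
#' immediately right. For fixed-length superfamily rules the comparison is a
#' single k-mer pair (k = rule length); for variable rules (Mutator 7-10 bp)
#' the longest exact duplication with length in the rule's range is taken.
#' `matches_rule` requires both an exact left/right duplication and, for
#' fixed rules, agreement with the rule's IUPAC pattern.
#'
#' @param record one insertion record (a one-row `mite_insertions` subset,
#'   or any list with `flank5` and `flank3` strings).
#' @param superfamily superfamily name driving the rule, see [tsd_rule()].
#' @param family_pattern optional family pattern for `"Unknown"`.
#' @return a list of class `tsd_call` with `left_tsd`, `right_tsd`,
#'   `length`, `matches_rule` and `short_flank`.
#' @export
call_tsd <- function(record, superfamily, family_pattern = NULL) {
  rule <- tsd_rule(superfamily, family_pattern)
  f5 <- record$flank5
  f3 <- record$flank3
  need <- rule$max
  if (nchar(f5) < need || nchar(f3) < need) {
    return(structure(list(left_tsd = "", right_tsd = "", length = 0L,
                          matches_rule = FALSE, short_flank = TRUE),
                     class = "tsd_call"))
  }
  take <- function(k) {
    list(left = substr(f5, nchar(f5) - k + 1L, nchar(f5)),
         right = substr(f3, 1L, k))
  }
  if (rule$type == "fixed") {
    k <- rule$max
    p <- take(k)
    ok <- identical(p$left, p$right) && iupac_match(p$left, rule$pattern)
    return(structure(list(left_tsd = p$left, right_tsd = p$right,
                          length = k, matches_rule = ok,
                          short_flank = FALSE),
                     class = "tsd_call"))
  }
  ## variable rule: longest exact duplication within the length range
  for (k in seq(rule$max, rule$min)) {
    p <- take(k)
    if (identical(p$left, p$right)) {
      return(structure(list(left_tsd = p$left, right_tsd = p$right,
                            length = k, matches_rule = TRUE,
                            short_flank = FALSE),
                       class = "tsd_call"))
    }
  }
  structure(list(left_tsd = "", right_tsd = "", length = 0L,
                 matches_rule = FALSE, short_flank = FALSE),
            class = "tsd_call")
}

#' Call TSDs for a whole record table
#'
#' Vectorized driver for [call_tsd()] over a `mite_insertions` table.
#'
#' @param records a `mite_insertions` data.frame.
#' @param superfamily single superfamily applying to all records.
#' @param family_pattern optional family pattern for `"Unknown"`.
#' @return `records` with columns `tsd_left`, `tsd_right`, `tsd_len`,
#'   `tsd_matches_rule` appended.
#' @export
call_tsds <- function(records, superfamily, family_pattern = NULL) {
  n <- nrow(records)
  left <- character(n); right <- character(n)
  len <- integer(n); ok <- logical(n)
  for (i in seq_len(n)) {
    cl <- call_tsd(records[i, ], superfamily, family_pattern)
    left[i] <- cl$left_tsd; right[i] <- cl$right_tsd
    len[i] <- cl$length; ok[i] <- cl$matches_rule
  }
  records$tsd_left <- left
  records$tsd_right <- right
  records$tsd_len <- len
  records$tsd_matches_rule <- ok
  records
}

#' Build a position frequency matrix
#'
#' Tabulates per-position nucleotide counts over a set of sequences.
#' Sequences of unequal length are right-padded with `N` to the maximum
#' length; `N` is excluded from the counts, so each column sums to at most
#' the number of sequences.
#'
#' @param seqs non-empty character vector of DNA sequences.
#' @return an object of class `mite_pfm`: an integer matrix (positions x
#'   A/C/G/T) with attribute `n_sequences`.
#' @export
build_pfm <- function(seqs) {
  if (length(seqs) == 0L) stop("cannot build a PFM from zero sequences")
  width <- max(nchar(seqs))
  if (width == 0L) stop("cannot build a PFM from empty sequences")
  padded <- vapply(seqs, function(s) {
    paste0(s, strrep("N", width - nchar(s)))
  }, character(1), USE.NAMES = FALSE)
  mat <- matrix(0L, nrow = width, ncol = 4L,
                dimnames = list(NULL, DNA_BASES))
  chars <- do.call(rbind, strsplit(padded, "", fixed = TRUE))
  for (b in DNA_BASES) {
    mat[, b] <- colSums(chars == b)
  }
  structure(mat, n_sequences = length(seqs), class = "mite_pfm")
}

#' Information content of PFM positions
#'
#' Sequence-logo stack height in the Schneider-Stephens convention:
#' `R = 2 - H`, with `H` the Shannon entropy (bits) of the observed
#' nucleotide frequencies at the position (N-padded observations excluded).
#' A column of a single base scores 2 bits; a uniform column scores 0. No
#' small-sample correction is applied.
#'
#' @param pfm a `mite_pfm`.
#' @param position positions to evaluate (default: all).
#' @return numeric vector of information contents in `[0, 2]`.
#' @export
information_content <- function(pfm, position = seq_len(nrow(pfm))) {
  stopifnot(inherits(pfm, "mite_pfm"))
  vapply(position, function(p) {
    cnt <- pfm[p, ]
    tot <- sum(cnt)
    if (tot == 0L) return(0)
    f <- cnt[cnt > 0] / tot
    h <- -sum(f * log2(f))
    2 - h
  }, numeric(1))
}

#' Haplotype diversity of a set of sequences
#'
#' `Hd = n/(n-1) * (1 - sum(p_i^2))` over the frequencies of distinct
#' sequences (haplotypes); the probability that two sequences sampled
#' without replacement are different haplotypes. `Hd = 0` for a single
#' sequence.
#'
#' @param seqs non-empty character vector of sequences.
#' @return a list of class `diversity_stat` with `n`, `n_haplotypes`,
#'   `haplotype_freqs`, `Hd`.
#' @export
haplotype_diversity <- function(seqs) {
  n <- length(seqs)
  if (n == 0L) stop("no sequences")
  p <- as.vector(table(seqs)) / n
  hd <- if (n == 1L) 0 else (n / (n - 1)) * (1 - sum(p^2))
  structure(list(n = n, n_haplotypes = length(p), haplotype_freqs = p,
                 Hd = hd),
            class = "diversity_stat")
}

#' Build a consensus sequence from family members
#'
#' Lightweight center-star progressive scheme: members are globally aligned
#' to the longest member (the center), member bases are projected onto
#' center coordinates, and each column is called by majority rule. Ties
#' between bases give the corresponding IUPAC ambiguity code; columns where
#' gaps hold the majority are dropped.
#'
#' @param member_seqs non-empty character vector of member sequences.
#' @param scoring alignment scoring, see [default_scoring()].
#' @return consensus DNA string.
#' @export
build_consensus <- function(member_seqs, scoring = default_scoring()) {
  if (length(member_seqs) == 0L) stop("no member sequences")
  if (length(unique(member_seqs)) == 1L) return(member_seqs[[1]])
  center_i <- which.max(nchar(member_seqs))
  center <- member_seqs[[center_i]]
  width <- nchar(center)
  n <- length(member_seqs)
  ## profile over center columns: A/C/G/T/- counts
  prof <- matrix(0L, nrow = width, ncol = 5L,
                 dimnames = list(NULL, c(DNA_BASES, "-")))
  add_seq <- function(chars) {
    for (b in c(DNA_BASES, "-")) {
      idx <- which(chars == b)
      if (length(idx)) prof[idx, b] <<- prof[idx, b] + 1L
    }
  }
  add_seq(strsplit(center, "", fixed = TRUE)[[1]])
  mat <- .subst_matrix(scoring)
  for (i in seq_len(n)[-center_i]) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = member_seqs[[i]], subject = center, type = "global",
      substitutionMatrix = mat, gapOpening = -scoring$gap_open,
      gapExtension = -scoring$gap_extend)
    pa <- strsplit(as.character(Biostrings::pattern(aln)), "", fixed = TRUE)[[1]]
    sa <- strsplit(as.character(Biostrings::subject(aln)), "", fixed = TRUE)[[1]]
    ## project member characters onto center (subject) coordinates,
    ## skipping member insertions (center gap columns)
    keep <- sa != "-"
    proj <- pa[keep]
    add_seq(proj)
  }
  calls <- character(width)
  for (p in seq_len(width)) {
    cnt <- prof[p, ]
    if (cnt[["-"]] > n / 2) {
      calls[p] <- ""
      next
    }
    base_cnt <- cnt[DNA_BASES]
    top <- DNA_BASES[base_cnt == max(base_cnt) & base_cnt > 0L]
    calls[p] <- if (length(top) == 1L) top else iupac_code_for(top)
  }
  paste(calls, collapse = "")
}

#' @export
print.mite_pfm <- function(x, ...) {
  cat("Position frequency matrix: ", nrow(x), " positions, ",
      attr(x, "n_sequences"), " sequences\n", sep = "")
  print(unclass(x)[seq_len(min(nrow(x), 10L)), , drop = FALSE])
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' @export
print.tir_annotation <- function(x, ...) {
  cat("TIR: ", x$tir_len, " bp, ", x$mismatches, " mismatch(es)\n",
      "  left:  ", x$left_seq, "\n  right: ", x$right_seq, "\n", sep = "")
  invisible(x)
}

#' @export
print.tsd_call <- function(x, ...) {
  if (x$length == 0L) {
    cat("TSD: none",
        if (isTRUE(x$short_flank)) " (flank too short)", "\n", sep = "")
  } else {
    cat("TSD: ", x$left_tsd, " / ", x$right_tsd, " (", x$length, " bp, ",
        if (x$matches_rule) "matches" else "violates", " rule)\n", sep = "")
  }
  invisible(x)
}

#' @export
print.diversity_stat <- function(x, ...) {
  cat("Haplotype diversity: Hd = ", format(x$Hd, digits = 4), " (n = ",
      x$n, ", ", x$n_haplotypes, " haplotypes)\n", sep = "")
  invisible(x)
}
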