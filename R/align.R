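## Seeded local alignment and Karlin-Altschul e-values.
##
## Homology retrieval uses exact k-mer seeding followed by local
## (Smith-Waterman-style, affine gap) extension of a window around each seed
## cluster. The extension is delegated to Biostrings::pairwiseAlignment; the
## contract, checked in the test suite against an independently written
## exhaustive dynamic program, is that the reported score of a hit equals the
## maximal local alignment score of that interval pair under the package
## scoring scheme.

#' Default alignment scoring scheme
#'
#' Match +1, mismatch -2, affine gaps: a gap of length L scores
#' `gap_open + L * gap_extend` = -(5 + 2L).
#'
#' @return a named list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @export
default_scoring <- function() {
  list(match = 1, mismatch = -2, gap_open = -5, gap_extend = -2)
}

## Substitution matrix over A/C/G/T/N for a scoring scheme; N never matches.
.subst_matrix <- function(scoring) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(b, b))
  diag(m)[1:4] <- scoring$match
  m
}

## Karlin-Altschul lambda for the match/mismatch scheme at uniform base
## composition: the positive root of sum_ij p_i p_j exp(lambda * s_ij) = 1.
## For +1/-2 this reduces to x^3 - 4x^2 + 3 = 0 with x = exp(lambda); solved
## numerically for generality.
ka_lambda <- function(scoring = default_scoring()) {
  f <- function(lam) {
    0.25 * exp(lam * scoring$match) + 0.75 * exp(lam * scoring$mismatch) - 1
  }
  stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

## K for the default scheme (documented constant; ungapped approximation).
.KA_K <- 0.621

#' Karlin-Altschul e-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * score)` with `m` the query length, `n` the
#' searched (single-strand) genome length, and `(K, lambda)` fixed for the
#' package scoring scheme (`K = 0.621`; `lambda` solved exactly from the
#' scheme at uniform base composition, ~1.333 for +1/-2). Monotonically
#' decreasing in score, linear in both lengths.
#'
#' @param score non-negative alignment score.
#' @param query_len,genome_len lengths in bp.
#' @param scoring scoring scheme, see [default_scoring()].
#' @return the expected number of chance hits at or above `score`.
#' @export
evalue <- function(score, query_len, genome_len, scoring = default_scoring()) {
  stopifnot(all(score >= 0), query_len > 0, genome_len > 0)
  .KA_K * query_len * genome_len * exp(-ka_lambda(scoring) * score)
}

#' Seeded local alignment of a query against a subject
#'
#' Finds candidate regions by exact `seed_len`-mer matches, merges seeds
#' into windows, and extends each window by maximal-scoring local alignment
#' under the package scoring scheme. A query sharing no seed with the
#' subject yields no hits.
#'
#' @param query,subject uppercase DNA strings (A/C/G/T, N tolerated).
#' @param scoring scoring scheme, see [default_scoring()].
#' @param seed_len exact-match seed length.
#' @param min_score discard hits scoring below this.
#' @return a data.frame of hits (possibly empty) with columns
#'   `subject_start`, `subject_end`, `query_start`, `query_end` (1-based
#'   inclusive), `score`, `identity` (matches / alignment columns) and
#'   `evalue` (computed against `nchar(subject)`), sorted by decreasing
#'   score.
#' @export
local_align <- function(query, subject, scoring = default_scoring(),
                        seed_len = 11L, min_score = 0) {
  stopifnot(is.character(query), is.character(subject),
            nchar(query) > 0, nchar(subject) > 0)
  empty <- data.frame(subject_start = integer(0), subject_end = integer(0),
                      query_start = integer(0), query_end = integer(0),
                      score = numeric(0), identity = numeric(0),
                      evalue = numeric(0))
  qlen <- nchar(query)
  if (qlen < seed_len) return(empty)
  windows <- .seed_windows(query, subject, seed_len, qlen)
  if (nrow(windows) == 0L) return(empty)
  hits <- .extend_windows(query, subject, windows, scoring,
                          min_score = min_score)
  hits <- hits[hits$score >= min_score, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  hits <- .merge_contained(hits)
  hits$evalue <- evalue(hits$score, qlen, nchar(subject), scoring)
  hits <- hits[order(-hits$score), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

## Locate exact seed matches of all query k-mers in the subject and group
## them into candidate subject windows (one window per putative locus).
.seed_windows <- function(query, subject, seed_len, qlen) {
  kmers <- substring(query, 1:(qlen - seed_len + 1L), seed_len:qlen)
  keep <- !grepl("N", kmers, fixed = TRUE)
  q_pos <- which(keep)
  if (length(q_pos) == 0L) {
    return(data.frame(from = integer(0), to = integer(0)))
  }
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[keep]))
  m <- Biostrings::matchPDict(pd, Biostrings::DNAString(subject))
  starts <- IRanges::start(m)
  n_hit <- lengths(starts)
  if (sum(n_hit) == 0L) {
    return(data.frame(from = integer(0), to = integer(0)))
  }
  s_pos <- unlist(starts, use.names = FALSE)
  ## anchor = projected subject start of a full-length alignment through the
  ## seed; cluster anchors within one query length into windows
  anchor <- s_pos - rep(q_pos, n_hit) + 1L
  anchor <- sort(unique(anchor))
  grp <- cumsum(c(1L, diff(anchor) > qlen))
  from <- tapply(anchor, grp, min)
  to <- tapply(anchor, grp, max)
  slen <- nchar(subject)
  data.frame(from = pmax(1L, as.integer(from) - qlen %/% 2L),
             to = pmin(slen, as.integer(to) + qlen + qlen %/% 2L))
}

## Local alignment of the query against each candidate window. A window may
## span several copies (seed anchors from nearby copies can merge), so after
## the best hit is taken the flanking window segments are re-aligned until
## no positive-scoring hit remains; weak chance hits are removed later by
## the e-value filter.
.extend_windows <- function(query, subject, windows, scoring,
                            min_score = 0, max_hits_per_window = 64L) {
  mat <- .subst_matrix(scoring)
  res <- list()
  align_one <- function(from, to) {
    win <- substr(subject, from, to)
    aln <- Biostrings::pairwiseAlignment(
      pattern = win, subject = query, type = "local",
      substitutionMatrix = mat,
      gapOpening = -scoring$gap_open,
      gapExtension = -scoring$gap_extend)
    sc <- Biostrings::score(aln)
    if (sc <= 0) return(NULL)
    pat <- Biostrings::pattern(aln)  # window side
    sub <- Biostrings::subject(aln)  # query side
    aln_len <- nchar(as.character(pat))
    data.frame(
      subject_start = from + IRanges::start(pat) - 1L,
      subject_end = from + IRanges::end(pat) - 1L,
      query_start = IRanges::start(sub),
      query_end = IRanges::end(sub),
      score = sc,
      identity = Biostrings::nmatch(aln) / aln_len)
  }
  for (i in seq_len(nrow(windows))) {
    stack <- list(c(windows$from[i], windows$to[i]))
    found <- 0L
    while (length(stack) && found < max_hits_per_window) {
      seg <- stack[[1L]]
      stack <- stack[-1L]
      if (seg[2] - seg[1] + 1L < 16L) next
      hit <- align_one(seg[1], seg[2])
      if (is.null(hit) || hit$score < min_score) next
      res[[length(res) + 1L]] <- hit
      found <- found + 1L
      if (hit$subject_start - seg[1] >= 16L) {
        stack[[length(stack) + 1L]] <- c(seg[1], hit$subject_start - 1L)
      }
      if (seg[2] - hit$subject_end >= 16L) {
        stack[[length(stack) + 1L]] <- c(hit$subject_end + 1L, seg[2])
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(subject_start = integer(0), subject_end = integer(0),
                      query_start = integer(0), query_end = integer(0),
                      score = numeric(0), identity = numeric(0))
  }
  out
}

## Drop hits whose subject interval is contained in a higher-scoring hit,
## and collapse duplicates.
.merge_contained <- function(hits) {
  hits <- unique(hits)
  if (nrow(hits) <= 1L) return(hits)
  ord <- order(-hits$score, hits$subject_start)
  hits <- hits[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    prior <- which(keep[seq_len(i - 1L)])
    contained <- any(hits$subject_start[prior] <= hits$subject_start[i] &
                       hits$subject_end[prior] >= hits$subject_end[i])
    if (contained) keep[i] <- FALSE
  }
  hits[keep, , drop = FALSE]
}
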