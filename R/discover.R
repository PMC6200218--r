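## De novo discovery of TIR+TSD-bounded MITE families.
##
## The scan enumerates candidate target-site duplications from the cheap
## fixed patterns (TA dinucleotide first, then TWA), pairs occurrences whose
## enclosed segment has a qualifying terminal inverted repeat and a length
## in range, single-linkage clusters the candidates by sequence identity,
## drops clusters homologous to a known catalog family, and reports the
## remainder with a rebuilt consensus. Variable-length (Mutator-style 7-10
## bp) target duplications are not enumerated de novo; families with such
## targets are found by homology once a consensus is known.

#' Discover novel TIR/TSD-bounded families in a genome
#'
#' @param genome a `mite_genome` or named set of chromosome sequences.
#' @param known_catalog a `mite_catalog` (consensus sequences used to drop
#'   known families), a data.frame with `family`/`consensus` columns, or
#'   `NULL` to skip the known-family filter.
#' @param min_copies minimum cluster size reported (default 20).
#' @param len_range element length bounds in bp (default 50-800).
#' @param min_tir minimum TIR length (default 8).
#' @param identity_cluster single-linkage identity threshold (default 0.80).
#' @param tir_max_mismatch mismatches tolerated in the TIR (default 2).
#' @param tsd_patterns fixed IUPAC TSD patterns enumerated (default TA and
#'   TWA).
#' @param known_max_evalue clusters matching a known consensus at or below
#'   this e-value are dropped (default 1e-3).
#' @return a list of `candidate_family` objects, each with `consensus_seq`,
#'   `element_len`, `tir` (a `tir_annotation`), `tsd_pattern` (most common
#'   observed TSD), `member_loci` (data.frame chrom/start/end/tsd) and
#'   `copy_number`. Ordered by decreasing copy number.
#' @export
discover_families <- function(genome, known_catalog = NULL, min_copies = 20L,
                              len_range = c(50L, 800L), min_tir = 8L,
                              identity_cluster = 0.80,
                              tir_max_mismatch = 2L,
                              tsd_patterns = c("TA", "TWA"),
                              known_max_evalue = 1e-3) {
  seqs <- .genome_seqs(genome)
  cand <- list()
  for (ch in names(seqs)) {
    cand[[ch]] <- .tsd_tir_candidates(seqs[[ch]], ch, len_range, min_tir,
                                      tir_max_mismatch, tsd_patterns)
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0L) return(list())

  ## canonical orientation: a copy and its reverse complement are the same
  ## element on opposite strands; cluster on the lexicographically smaller
  ## of the two so strand does not split families
  rc <- revcomp(cand$seq)
  cand$canon <- ifelse(cand$seq <= rc, cand$seq, rc)

  clusters <- .cluster_candidates(cand, identity_cluster)

  known <- .known_consensi(known_catalog)
  out <- list()
  for (cl in clusters) {
    members <- cand[cl, , drop = FALSE]
    members <- .dedupe_members(members)
    if (nrow(members) < min_copies) next
    cons <- build_consensus(.orient_members(members$canon))
    if (length(known) && .matches_known(cons, known, known_max_evalue)) next
    tir <- find_tir(cons, min_len = min_tir, max_mismatch = tir_max_mismatch)
    if (is.null(tir)) next
    tsd_tab <- sort(table(members$tsd), decreasing = TRUE)
    out[[length(out) + 1L]] <- structure(list(
      consensus_seq = cons, element_len = nchar(cons), tir = tir,
      tsd_pattern = names(tsd_tab)[1],
      member_loci = members[, c("chrom", "start", "end", "tsd")],
      copy_number = nrow(members)), class = "candidate_family")
  }
  out[order(-vapply(out, `[[`, numeric(1), "copy_number"))]
}

## Enumerate candidate elements on one chromosome: segments bounded by a
## duplicated fixed-pattern TSD whose interior has a qualifying TIR.
.tsd_tir_candidates <- function(s, chrom, len_range, min_tir,
                                tir_max_mismatch, tsd_patterns) {
  res <- list()
  subj <- Biostrings::DNAString(s)
  chv <- strsplit(s, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (pat in tsd_patterns) {
    k <- nchar(pat)
    m <- Biostrings::matchPattern(pat, subj, fixed = !grepl("[^ACGT]", pat))
    pos <- IRanges::start(m)
    if (length(pos) < 2L) next
    tsd_str <- substring(s, pos, pos + k - 1L)
    ## pair left occurrence t with right occurrence u: element = (t+k, u-1);
    ## admissible u lie in [t+k+len_min, t+k+len_max]
    jlo <- findInterval(pos + k + len_range[1] - 1L, pos) + 1L
    jhi <- findInterval(pos + k + len_range[2], pos)
    cnt <- pmax(0L, jhi - jlo + 1L)
    if (sum(cnt) == 0L) next
    ti <- rep(seq_along(pos), cnt)
    jv <- unlist(lapply(which(cnt > 0L), function(i) jlo[i]:jhi[i]),
                 use.names = FALSE)
    same <- tsd_str[ti] == tsd_str[jv]
    ti <- ti[same]; jv <- jv[same]
    if (length(ti) == 0L) next
    es <- pos[ti] + k
    ee <- pos[jv] - 1L
    ## vectorized quick TIR filter: mismatches of the min_tir-long terminal
    ## prefix against the reverse complement of the terminal suffix
    mm <- integer(length(es))
    for (off in 0:(min_tir - 1L)) {
      mm <- mm + (chv[es + off] != comp[chv[ee - off]])
    }
    ok <- which(mm <= tir_max_mismatch)
    for (q in ok) {
      elem <- substr(s, es[q], ee[q])
      tir <- find_tir(elem, min_len = min_tir,
                      max_mismatch = tir_max_mismatch)
      if (is.null(tir)) next
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = es[q], end = ee[q], seq = elem,
        tsd = tsd_str[ti[q]], tir_len = tir$tir_len,
        tir_mm = tir$mismatches, stringsAsFactors = FALSE)
    }
  }
  if (length(res)) do.call(rbind, res) else NULL
}

## Single-linkage clustering of candidates at >= identity threshold.
## Identity = matched bases of the best local alignment / longer length.
## A 6-mer content prefilter keeps the number of alignments proportional to
## true family structure rather than quadratic in spurious candidates.
.cluster_candidates <- function(cand, identity_cluster) {
  n <- nrow(cand)
  if (n == 1L) return(list(1L))
  lens <- nchar(cand$canon)
  prof <- .kmer_profile(cand$canon, 6L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  shared <- tcrossprod(prof)  # counts of shared 6-mer types
  kcount <- diag(shared)
  ## candidate pairs: compatible lengths and substantial shared 6-mer
  ## content (random sequences essentially never pass), then verified by
  ## alignment identity
  lmin <- outer(lens, lens, pmin)
  lmax <- outer(lens, lens, pmax)
  pass <- lmin >= identity_cluster * lmax &
    shared >= 0.5 * outer(kcount, kcount, pmin)
  pass[lower.tri(pass, diag = TRUE)] <- FALSE
  idx <- which(pass, arr.ind = TRUE)
  if (nrow(idx)) {
    ## exact duplicates need no alignment
    same <- cand$canon[idx[, 1L]] == cand$canon[idx[, 2L]]
    for (r in which(same)) union(idx[r, 1L], idx[r, 2L])
    idx <- idx[!same, , drop = FALSE]
  }
  if (nrow(idx)) {
    mat <- .subst_matrix(default_scoring())
    rc <- revcomp(cand$canon)
    ## batch alignments per left index to amortize call overhead; identity
    ## is orientation-free (best of forward and reverse complement)
    for (i in unique(idx[, 1L])) {
      js <- idx[idx[, 1L] == i, 2L]
      js <- js[vapply(js, function(j) find(i) != find(j), logical(1))]
      if (length(js) == 0L) next
      alnf <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAStringSet(cand$canon[js]),
        subject = cand$canon[i], type = "local",
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
      alnr <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAStringSet(rc[js]),
        subject = cand$canon[i], type = "local",
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
      nm <- pmax(Biostrings::nmatch(alnf), Biostrings::nmatch(alnr))
      idok <- nm / pmax(lens[i], lens[js]) >= identity_cluster
      for (j in js[idok]) union(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

## Binary presence matrix of k-mer types per candidate; strand-invariant
## (k-mers of the sequence and of its reverse complement both count).
.kmer_profile <- function(seqs, k) {
  rc <- revcomp(seqs)
  all_kmers <- lapply(seq_along(seqs), function(i) {
    kmers <- function(s) {
      n <- nchar(s)
      if (n < k) return(character(0))
      substring(s, 1:(n - k + 1L), k:n)
    }
    unique(c(kmers(seqs[i]), kmers(rc[i])))
  })
  types <- unique(unlist(all_kmers))
  m <- matrix(0L, nrow = length(seqs), ncol = length(types))
  for (i in seq_along(seqs)) {
    m[i, match(all_kmers[[i]], types)] <- 1L
  }
  m
}

## Flip cluster members onto a common strand: each member keeps the
## orientation that aligns better to the longest member.
.orient_members <- function(seqs) {
  if (length(seqs) <= 1L) return(seqs)
  ref <- seqs[[which.max(nchar(seqs))]]
  rc <- revcomp(seqs)
  mat <- .subst_matrix(default_scoring())
  sf <- Biostrings::score(Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(seqs), subject = ref,
    type = "local", substitutionMatrix = mat, gapOpening = 5,
    gapExtension = 2))
  sr <- Biostrings::score(Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(rc), subject = ref,
    type = "local", substitutionMatrix = mat, gapOpening = 5,
    gapExtension = 2))
  ifelse(sr > sf, rc, seqs)
}

## Within a cluster, collapse members that overlap on the genome (nested or
## staggered TSD pairings of one physical copy). Family copies share one
## element length (the divergence model is substitution-only), so the
## boundary supported by most cluster members is the family boundary;
## chance super- or sub-pairings at single loci have no such support.
## Ties prefer the longer (maximal) boundary, then the stronger TIR.
.dedupe_members <- function(members) {
  len <- members$end - members$start + 1L
  tab <- table(len)
  support <- as.integer(tab[as.character(len)])
  tir_quality <- members$tir_len - 2L * members$tir_mm
  ord <- order(members$chrom, -support, -len, -tir_quality, members$start)
  members <- members[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(members))
  for (i in seq_len(nrow(members))[-1]) {
    prior <- which(keep[seq_len(i - 1L)] &
                     members$chrom[seq_len(i - 1L)] == members$chrom[i])
    if (length(prior) == 0L) next
    ov <- pmin(members$end[prior], members$end[i]) -
      pmax(members$start[prior], members$start[i]) + 1L
    if (any(ov > 0L)) keep[i] <- FALSE
  }
  out <- members[keep, , drop = FALSE]
  out[order(out$chrom, out$start), , drop = FALSE]
}

.known_consensi <- function(known_catalog) {
  if (is.null(known_catalog)) return(character(0))
  if (inherits(known_catalog, "mite_catalog")) {
    as.character(known_catalog$consensus)
  } else if (is.data.frame(known_catalog)) {
    cons <- known_catalog$consensus
    cons[!is.na(cons) & nzchar(cons)]
  } else {
    stop("unsupported known_catalog")
  }
}

.matches_known <- function(cons, known, max_evalue) {
  total_len <- sum(nchar(known))
  ## cluster consensi are strand-arbitrary; check both orientations
  for (q in c(cons, revcomp(cons))) {
    for (kc in known) {
      hits <- local_align(q, kc)
      if (nrow(hits) && min(evalue(hits$score, nchar(q), total_len)) <=
          max_evalue) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' @export
print.candidate_family <- function(x, ...) {
  cat("Candidate MITE family: ", x$element_len, " bp, ", x$copy_number,
      " copies\n", sep = "")
  cat("  TIR ", x$tir$tir_len, " bp (", x$tir$mismatches,
      " mm), TSD '", x$tsd_pattern, "'\n", sep = "")
  invisible(x)
}
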