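# Exhaustive Smith-Waterman-style local alignment with affine gaps,
# written independently of the package's seeded aligner. O(nm) dynamic
# program over the full matrix; a gap of length L scores gopen + L * gext.
sw_oracle_score <- function(query, subject, match = 1, mismatch = -2,
                            gopen = -5, gext = -2) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  s <- strsplit(subject, "", fixed = TRUE)[[1]]
  n <- length(q)
  m <- length(s)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)  # gap in subject (query consumed)
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in query
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      sub <- if (q[i] == s[j]) match else mismatch
      M[i + 1, j + 1] <- max(0, max(M[i, j], X[i, j], Y[i, j]) + sub)
      X[i + 1, j + 1] <- max(M[i, j + 1] + gopen + gext, X[i, j + 1] + gext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gopen + gext, Y[i + 1, j] + gext)
      if (M[i + 1, j + 1] > best) best <- M[i + 1, j + 1]
    }
  }
  best
}

# Brute-force interval-overlap gene association, used as an oracle for
# classify_gene_association: checks every exon/intron interval and every
# gene distance directly.
gene_assoc_oracle <- function(ins_start, ins_end, chrom, gene_models,
                              window = 100) {
  on_chrom <- gene_models[gene_models$chrom == chrom, , drop = FALSE]
  ex <- on_chrom[on_chrom$type %in% c("five_prime_UTR", "CDS",
                                      "three_prime_UTR"), , drop = FALSE]
  if (nrow(ex) && any(ex$start <= ins_end & ex$end >= ins_start)) {
    return("exon")
  }
  intr <- on_chrom[on_chrom$type == "intron", , drop = FALSE]
  if (nrow(intr) && any(intr$start <= ins_end & intr$end >= ins_start)) {
    return("intron")
  }
  genes <- on_chrom[on_chrom$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) return("none")
  ov <- genes$start <= ins_end & genes$end >= ins_start
  if (any(ov)) return("intron")     # inside gene but outside parts
  d <- pmax(genes$start - ins_end - 1, ins_start - genes$end - 1)
  j <- which.min(d)
  if (d[j] > window) return("none")
  before <- ins_end < genes$start[j]
  up <- (genes$strand[j] == "+" && before) ||
    (genes$strand[j] == "-" && !before)
  if (up) "upstream_le100" else "downstream_le100"
}
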