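## Low-level sequence helpers shared across modules. All sequences are plain
## uppercase character strings over A/C/G/T (N tolerated where stated);
## coordinates are 1-based inclusive throughout the package. BED output is the
## only place 0-based half-open coordinates appear, as that format requires.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N and IUPAC codes).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz])))
  }
  out
}

## Run `code` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. All stochastic operations in the package go
## through this so that seed arguments fully determine output.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Random i.i.d. DNA sequence
#'
#' Background model used by the genome simulator: independent draws with a
#' given GC content, A/T and C/G each split evenly.
#'
#' @param n length in bp.
#' @param gc GC content in `[0, 1]`.
#' @return a single DNA string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Mutate a sequence at a fixed per-site divergence
#'
#' Substitutes exactly `round(rate * length)` positions, sampled uniformly
#' without replacement, each by a base drawn uniformly from the three
#' alternatives. The fixed count (rather than an independent Bernoulli draw
#' per site) guarantees that every mutated copy realigns to its source at
#' identity `1 - rate` exactly, which downstream recovery contracts rely
#' on. Substitutions only, no indels.
#'
#' @param seq DNA string.
#' @param rate per-site substitution rate in `[0, 1)`.
#' @return mutated DNA string of the same length.
#' @export
mutate_seq <- function(seq, rate) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0 || nchar(seq) == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_mut <- round(rate * length(ch))
  if (n_mut == 0L) return(seq)
  hit <- sample.int(length(ch), n_mut)
  for (i in hit) {
    alt <- DNA_BASES[DNA_BASES != ch[i]]
    ch[i] <- alt[sample.int(3L, 1L)]
  }
  paste(ch, collapse = "")
}

## Does `seq` match an IUPAC pattern of the same length (e.g. "TWA")?
iupac_match <- function(seq, pattern) {
  if (nchar(seq) != nchar(pattern)) return(FALSE)
  if (nchar(seq) == 0L) return(FALSE)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[p], "", fixed = TRUE)
  all(mapply(function(base, ok) base %in% ok, s, allowed))
}

## Sample one concrete realization of an IUPAC pattern (for TSD generation).
sample_iupac <- function(pattern) {
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  alt <- strsplit(Biostrings::IUPAC_CODE_MAP[p], "", fixed = TRUE)
  paste(vapply(alt, function(a) a[sample.int(length(a), 1L)], character(1)), collapse = "")
}

## Hamming distance of two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

## IUPAC code for a set of bases (ties in consensus building).
iupac_code_for <- function(bases) {
  bases <- sort(unique(bases))
  key <- paste(bases, collapse = "")
  hit <- names(Biostrings::IUPAC_CODE_MAP)[
    vapply(Biostrings::IUPAC_CODE_MAP, function(v) {
      paste(sort(strsplit(v, "", fixed = TRUE)[[1]]), collapse = "") == key
    }, logical(1))
  ]
  if (length(hit) == 0L) "N" else hit[1]
}
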