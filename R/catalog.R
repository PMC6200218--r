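## MITE family catalog: domain types and loaders.
##
## A catalog is a data.frame of family metadata (one row per family) plus an
## optional named set of consensus sequences. The packaged catalog transcribes
## the published characterization of 36 wheat MITE families (consensus size,
## target-site preference and copy numbers in four Triticum/Aegilops genome
## drafts); those copy-number columns are treated as authoritative inputs for
## summary arithmetic, never recomputed from wheat data.

MITE_SUPERFAMILIES <- c("Stowaway", "Tourist", "Mutator", "Unknown")

#' TSD rule for a MITE superfamily
#'
#' Superfamilies differ in the target site duplication (TSD) they create on
#' insertion: Stowaway elements duplicate a TA dinucleotide, Tourist elements
#' a TWA trinucleotide (W = A or T), and Mutator elements a long, variable
#' 7-10 bp target with no base constraint. Families of unknown superfamily
#' use their catalog-recorded pattern when one is given, otherwise any exact
#' duplication qualifies.
#'
#' @param superfamily one of `"Stowaway"`, `"Tourist"`, `"Mutator"`, `"Unknown"`.
#' @param family_pattern optional family-specific IUPAC pattern used for the
#'   `"Unknown"` superfamily (ignored otherwise).
#' @return a list with elements `type` (`"fixed"`, `"range"` or `"any"`),
#'   `pattern` (IUPAC string, fixed rules only), and `min`/`max` length bounds.
#' @export
#' @examples
#' tsd_rule("Stowaway")$pattern   # "TA"
#' tsd_rule("Mutator")$min        # 7
tsd_rule <- function(superfamily, family_pattern = NULL) {
  superfamily <- match.arg(superfamily, MITE_SUPERFAMILIES)
  switch(superfamily,
    Stowaway = list(type = "fixed", pattern = "TA", min = 2L, max = 2L),
    Tourist  = list(type = "fixed", pattern = "TWA", min = 3L, max = 3L),
    Mutator  = list(type = "range", pattern = NULL, min = 7L, max = 10L),
    Unknown  = {
      if (!is.null(family_pattern) && !is.na(family_pattern) && nzchar(family_pattern)) {
        k <- nchar(family_pattern)
        list(type = "fixed", pattern = toupper(family_pattern), min = k, max = k)
      } else {
        list(type = "any", pattern = NULL, min = 2L, max = 10L)
      }
    }
  )
}

## Resolve the TSD rule for one catalog row: fixed family patterns take
## precedence for Unknown; Stowaway/Tourist/Mutator follow the superfamily.
family_tsd_rule <- function(family_row) {
  sf <- family_row$superfamily
  if (sf == "Unknown") {
    tsd_rule("Unknown", family_pattern = family_row$tsd_pattern)
  } else {
    tsd_rule(sf)
  }
}

#' Load a MITE family catalog
#'
#' Reads a TSV of family metadata and, optionally, a FASTA of consensus
#' sequences keyed by family name. Families without a consensus remain usable
#' for copy-number arithmetic but cannot be scanned for.
#'
#' @param tsv path to a tab-separated table with columns `family`,
#'   `superfamily`, `consensus_len_bp`, `tsd_pattern` and any number of
#'   `copies_*` integer columns.
#' @param consensus_fasta optional path to a FASTA whose names match `family`.
#' @return an object of class `mite_catalog`: a list with `families`
#'   (data.frame) and `consensus` (named `DNAStringSet`, possibly empty).
#' @export
load_family_catalog <- function(tsv, consensus_fasta = NULL) {
  stopifnot(file.exists(tsv))
  fam <- utils::read.delim(tsv, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (nrow(fam) > 0L) {
    required <- c("family", "superfamily", "consensus_len_bp", "tsd_pattern")
    missing_cols <- setdiff(required, names(fam))
    if (length(missing_cols)) {
      stop("catalog TSV lacks column(s): ", paste(missing_cols, collapse = ", "))
    }
    if (anyDuplicated(fam$family)) {
      stop("duplicate family name(s) in catalog: ",
           paste(unique(fam$family[duplicated(fam$family)]), collapse = ", "))
    }
    bad_sf <- setdiff(unique(fam$superfamily), MITE_SUPERFAMILIES)
    if (length(bad_sf)) {
      stop("unknown superfamily value(s): ", paste(bad_sf, collapse = ", "))
    }
    copy_cols <- grep("^copies_", names(fam), value = TRUE)
    for (cc in c("consensus_len_bp", copy_cols)) {
      v <- suppressWarnings(as.integer(fam[[cc]]))
      bad <- which(is.na(v) & !(is.na(fam[[cc]]) | fam[[cc]] == ""))
      if (length(bad)) {
        stop("malformed value in column '", cc, "' for family '",
             fam$family[bad[1]], "'")
      }
      if (any(v < 0, na.rm = TRUE)) {
        stop("negative value in column '", cc, "' for family '",
             fam$family[which(v < 0)[1]], "'")
      }
      fam[[cc]] <- v
    }
  }
  consensus <- Biostrings::DNAStringSet()
  if (!is.null(consensus_fasta)) {
    stopifnot(file.exists(consensus_fasta))
    consensus <- Biostrings::readDNAStringSet(consensus_fasta)
    names(consensus) <- sub("\\s.*$", "", names(consensus))
    extra <- setdiff(names(consensus), fam$family)
    if (length(extra)) {
      stop("consensus FASTA contains sequences for unlisted families: ",
           paste(extra, collapse = ", "))
    }
  }
  structure(list(families = fam, consensus = consensus), class = "mite_catalog")
}

#' Write a MITE family catalog
#'
#' Inverse of [load_family_catalog()]: writes the family table as TSV and, if
#' any consensus sequences are present, a FASTA alongside.
#'
#' @param catalog a `mite_catalog`.
#' @param tsv output TSV path.
#' @param consensus_fasta output FASTA path (required when the catalog holds
#'   consensus sequences).
#' @return invisibly, `tsv`.
#' @export
write_family_catalog <- function(catalog, tsv, consensus_fasta = NULL) {
  stopifnot(inherits(catalog, "mite_catalog"))
  utils::write.table(catalog$families, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  if (length(catalog$consensus)) {
    if (is.null(consensus_fasta)) {
      stop("catalog holds consensus sequences; supply `consensus_fasta`")
    }
    Biostrings::writeXStringSet(catalog$consensus, consensus_fasta)
  }
  invisible(tsv)
}

#' The packaged wheat MITE family catalog
#'
#' Loads the catalog of 36 wheat MITE families shipped with the package
#' (family, superfamily, consensus length, target-site preference, and copy
#' numbers in the T. aestivum, T. turgidum ssp. dicoccoides, Ae. tauschii and
#' T. urartu genome drafts). No consensus sequences are shipped; supply your
#' own FASTA or generate synthetic consensi with [synthetic_consensus()].
#'
#' @param consensus_fasta optional consensus FASTA keyed by family name.
#' @return a `mite_catalog`.
#' @export
wheat_mite_catalog <- function(consensus_fasta = NULL) {
  load_family_catalog(
    system.file("extdata", "mite_family_catalog.tsv", package = "mitescope",
                mustWork = TRUE),
    consensus_fasta = consensus_fasta
  )
}

#' Sub-genome insertion counts for the polyploid wheat drafts
#'
#' Published genome-wide and per-family counts of MITE insertions by
#' sub-genome (A/B/D plus an "unknown" bin for unplaced scaffolds) in the
#' tetraploid (`"Tturgidum"`) and hexaploid (`"Taestivum"`) drafts. `family`
#' is `"ALL"` for genome-wide rows. These are fixture inputs for summary
#' arithmetic.
#'
#' @return a data.frame with columns `genome`, `family`, `subgenome`, `count`.
#' @export
wheat_subgenome_counts <- function() {
  utils::read.delim(
    system.file("extdata", "subgenome_counts.tsv", package = "mitescope",
                mustWork = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic consensus sequence for a MITE family
#'
#' Builds a random element of the requested length bounded by perfect
#' terminal inverted repeats, the hallmark structure of a MITE. Used in place
#' of the published consensus sequences, which are distributed by the public
#' repeat databases and are not shipped here.
#'
#' @param length element length in bp (must exceed `2 * tir_len`).
#' @param tir_len terminal inverted repeat length in bp.
#' @param gc GC content of the random interior.
#' @param seed integer seed.
#' @return a DNA string.
#' @export
synthetic_consensus <- function(length, tir_len = 11L, gc = 0.5, seed = 1L) {
  stopifnot(length > 2 * tir_len, tir_len >= 1)
  with_seed(seed, {
    tir <- random_dna(tir_len, gc)
    core <- random_dna(length - 2L * tir_len, gc)
    paste0(tir, core, revcomp(tir))
  })
}

#' @export
print.mite_catalog <- function(x, ...) {
  fam <- x$families
  cat("MITE family catalog: ", nrow(fam), " families",
      if (length(x$consensus)) paste0(" (", length(x$consensus), " with consensus)"),
      "\n", sep = "")
  if (nrow(fam)) {
    tab <- table(factor(fam$superfamily, levels = MITE_SUPERFAMILIES))
    cat("  superfamilies: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
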