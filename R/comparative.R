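## Comparative tabulation and cross-genome common-insertion analysis.
##
## Insertions are binned by family x sub-genome x homoeologous chromosome
## group; summary reports give per-family, per-superfamily and per-subgenome
## fractions with the mixed rounding precision used in practice (2 decimals
## for superfamily fractions, 1 for family fractions, integers for
## sub-genome fractions). Common-insertion analysis matches records across
## two genomes by their flanking sequences: a shared locus has near-identical
## flanks on both sides of the element.

SUBGENOME_LEVELS <- c("A", "B", "D", "unknown")

## Round half up at `digits` decimals (reports use half-up, not banker's).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

## Parse homoeologous group and sub-genome from a chromosome name such as
## "3B"; anything not matching goes to the unknown bin.
parse_chrom_name <- function(chrom) {
  m <- regmatches(chrom, regexec("^([1-7])([ABD])", chrom))
  group <- vapply(m, function(x) if (length(x)) x[2] else NA_character_,
                  character(1))
  subg <- vapply(m, function(x) if (length(x)) x[3] else NA_character_,
                 character(1))
  data.frame(group = ifelse(is.na(group), "unknown", group),
             subgenome = ifelse(is.na(subg), "unknown", subg),
             stringsAsFactors = FALSE)
}

#' Tabulate insertions by family, sub-genome and chromosome group
#'
#' Each record contributes exactly one cell. The sub-genome label comes from
#' `chrom_meta` when provided (falling back to the chromosome-name pattern
#' `^[1-7][ABD]`); chromosomes absent from the metadata and not matching the
#' pattern land in the `"unknown"` bin.
#'
#' @param records a `mite_insertions` data.frame (or any data.frame with
#'   `family` and `chrom`).
#' @param chrom_meta optional data.frame with `chrom` and `subgenome`.
#' @param genome_label label stored on the table.
#' @return an object of class `mite_distribution`: a data.frame of counts
#'   (`family`, `subgenome`, `group`, `count`) with attribute `genome`.
#' @export
tabulate_insertions <- function(records, chrom_meta = NULL,
                                genome_label = "genome") {
  stopifnot(is.data.frame(records), all(c("family", "chrom") %in%
                                          names(records)))
  parsed <- parse_chrom_name(records$chrom)
  subg <- parsed$subgenome
  if (!is.null(chrom_meta)) {
    idx <- match(records$chrom, chrom_meta$chrom)
    known <- !is.na(idx)
    subg[known] <- chrom_meta$subgenome[idx[known]]
    subg[!known] <- "unknown"
  }
  subg[!subg %in% SUBGENOME_LEVELS] <- "unknown"
  tab <- as.data.frame(table(family = records$family, subgenome = subg,
                             group = parsed$group), stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "count"
  rownames(tab) <- NULL
  structure(tab, genome = genome_label,
            class = c("mite_distribution", "data.frame"))
}

#' Summary report of MITE composition
#'
#' Computes per-family and per-superfamily insertion totals and percentages
#' of the grand total, and per-subgenome totals where sub-genome information
#' is available. `x` may be a `mite_distribution` (counts from records), or
#' a `mite_catalog` whose `copies_*` columns are summarized for one species
#' column or for all columns combined.
#'
#' @param x a `mite_distribution` or `mite_catalog`.
#' @param species for a catalog: a `copies_*` column name (with or without
#'   the `copies_` prefix), or `"all"` to pool every species column.
#' @param digits_family,digits_superfamily,digits_subgenome rounding
#'   precision (half-up) of the three percentage groupings.
#' @return an object of class `mite_summary`: list with `grand_total`,
#'   `family` (count/percent table), `superfamily`, `subgenome` (or `NULL`),
#'   `group` (per chromosome-group totals, or `NULL`) and `empty` flag.
#' @export
mite_summary <- function(x, species = "all", digits_family = 1,
                         digits_superfamily = 2, digits_subgenome = 0, ...) {
  UseMethod("mite_summary")
}

#' @export
mite_summary.mite_catalog <- function(x, species = "all", digits_family = 1,
                                      digits_superfamily = 2,
                                      digits_subgenome = 0, ...) {
  fam <- x$families
  copy_cols <- grep("^copies_", names(fam), value = TRUE)
  if (identical(species, "all")) {
    cols <- copy_cols
  } else {
    want <- ifelse(grepl("^copies_", species), species,
                   paste0("copies_", species))
    stopifnot(all(want %in% copy_cols))
    cols <- want
  }
  counts <- rowSums(as.matrix(fam[, cols, drop = FALSE]), na.rm = TRUE)
  .build_summary(fam$family, fam$superfamily, counts,
                 subgenome_counts = NULL, group_counts = NULL,
                 digits_family, digits_superfamily, digits_subgenome)
}

#' @export
mite_summary.mite_distribution <- function(x, species = "all",
                                           digits_family = 1,
                                           digits_superfamily = 2,
                                           digits_subgenome = 0,
                                           superfamilies = NULL, ...) {
  if (nrow(x) == 0L) {
    return(.build_summary(character(0), character(0), integer(0),
                          subgenome_counts = NULL, group_counts = NULL,
                          digits_family, digits_superfamily,
                          digits_subgenome))
  }
  fam_counts <- tapply(x$count, x$family, sum)
  families <- names(fam_counts)
  sf <- if (is.null(superfamilies)) {
    rep("Unknown", length(families))
  } else {
    ifelse(families %in% names(superfamilies), superfamilies[families],
           "Unknown")
  }
  sub_counts <- tapply(x$count, x$subgenome, sum)
  grp_counts <- tapply(x$count, x$group, sum)
  .build_summary(families, sf, as.vector(fam_counts),
                 subgenome_counts = sub_counts, group_counts = grp_counts,
                 digits_family, digits_superfamily, digits_subgenome)
}

.build_summary <- function(families, superfamilies, counts, subgenome_counts,
                           group_counts, digits_family, digits_superfamily,
                           digits_subgenome) {
  grand <- sum(counts)
  empty <- grand == 0
  if (length(families) == 0L) {
    families <- character(0)
    superfamilies <- character(0)
    counts <- integer(0)
  }
  pct <- function(v, d) {
    if (empty) rep(0, length(v)) else round_half_up(100 * v / grand, d)
  }
  fam_tab <- data.frame(family = as.character(families),
                        superfamily = as.character(superfamilies),
                        count = as.integer(counts),
                        percent = pct(counts, digits_family),
                        stringsAsFactors = FALSE)
  fam_tab <- fam_tab[order(-fam_tab$count, fam_tab$family), , drop = FALSE]
  rownames(fam_tab) <- NULL
  sf_counts <- if (length(counts)) tapply(counts, superfamilies, sum) else
    stats::setNames(integer(0), character(0))
  sf_tab <- data.frame(superfamily = as.character(names(sf_counts)),
                       count = as.integer(sf_counts),
                       percent = pct(as.vector(sf_counts),
                                     digits_superfamily),
                       stringsAsFactors = FALSE)
  rownames(sf_tab) <- NULL
  sub_tab <- NULL
  if (!is.null(subgenome_counts)) {
    sub_tab <- data.frame(subgenome = names(subgenome_counts),
                          count = as.integer(subgenome_counts),
                          percent = pct(as.vector(subgenome_counts),
                                        digits_subgenome),
                          stringsAsFactors = FALSE)
    rownames(sub_tab) <- NULL
  }
  grp_tab <- NULL
  if (!is.null(group_counts)) {
    grp_tab <- data.frame(group = names(group_counts),
                          count = as.integer(group_counts),
                          stringsAsFactors = FALSE)
    rownames(grp_tab) <- NULL
  }
  structure(list(grand_total = as.integer(grand), family = fam_tab,
                 superfamily = sf_tab, subgenome = sub_tab, group = grp_tab,
                 empty = empty),
            class = "mite_summary")
}

#' Sub-genome percentage from a counts table
#'
#' Helper for fixture arithmetic: the percentage of counts falling in one
#' sub-genome, rounded half-up.
#'
#' @param counts data.frame with `subgenome` and `count`.
#' @param subgenome sub-genome label.
#' @param digits rounding precision.
#' @return a percentage.
#' @export
subgenome_percent <- function(counts, subgenome, digits = 0) {
  stopifnot(all(c("subgenome", "count") %in% names(counts)))
  round_half_up(100 * sum(counts$count[counts$subgenome == subgenome]) /
                  sum(counts$count), digits)
}

#' Match common insertions between two genomes by flank identity
#'
#' A record in `records_x` matches one in `records_y` when both are of the
#' same family and both flank pairs (5' with 5', 3' with 3') locally align
#' at `min_flank_identity` or better over at least `min_flank_overlap`
#' aligned columns. Candidate pairs are proposed by exact probe k-mers taken
#' at the element boundary and verified by alignment; matching is resolved
#' greedily, best mean identity first, each record in at most one pair.
#'
#' @param records_x,records_y `mite_insertions` tables carrying flanks.
#' @param min_flank_identity identity threshold per flank (default 0.90).
#' @param min_flank_overlap minimum aligned columns per flank (default 50).
#' @param probe_len exact probe k-mer length for candidate generation.
#' @param scoring alignment scoring, see [default_scoring()].
#' @return an object of class `mite_common_report`: list with `pairs`
#'   (data.frame of matched indices and identities), `n_common`,
#'   `n_unique_x`, `n_unique_y`, `shared_fraction_x`, `shared_fraction_y`,
#'   `n_excluded_x`, `n_excluded_y` (records lacking flanks).
#' @export
match_common_insertions <- function(records_x, records_y,
                                    min_flank_identity = 0.90,
                                    min_flank_overlap = 50L,
                                    probe_len = 24L,
                                    scoring = default_scoring()) {
  has_flanks <- function(r) nzchar(r$flank5) & nzchar(r$flank3)
  ok_x <- has_flanks(records_x)
  ok_y <- has_flanks(records_y)
  x <- records_x[ok_x, , drop = FALSE]
  y <- records_y[ok_y, , drop = FALSE]
  probes <- function(r) {
    ## anchored at the element boundary: end of the 5' flank, start of the
    ## 3' flank — identical at a shared locus
    p5 <- substr(r$flank5, pmax(1L, nchar(r$flank5) - probe_len + 1L),
                 nchar(r$flank5))
    p3 <- substr(r$flank3, 1L, probe_len)
    list(p5 = p5, p3 = p3)
  }
  px <- probes(x)
  py <- probes(y)
  key_y5 <- split(seq_len(nrow(y)), paste(y$family, py$p5))
  key_y3 <- split(seq_len(nrow(y)), paste(y$family, py$p3))
  cand_i <- integer(0)
  cand_j <- integer(0)
  for (i in seq_len(nrow(x))) {
    js <- unique(c(key_y5[[paste(x$family[i], px$p5[i])]],
                   key_y3[[paste(x$family[i], px$p3[i])]]))
    if (length(js)) {
      cand_i <- c(cand_i, rep(i, length(js)))
      cand_j <- c(cand_j, js)
    }
  }
  mat <- .subst_matrix(scoring)
  flank_id <- function(a, b) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = a, subject = b, type = "local", substitutionMatrix = mat,
      gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
    len <- nchar(as.character(Biostrings::pattern(aln)))
    if (len < min_flank_overlap) return(0)
    Biostrings::nmatch(aln) / len
  }
  pair_rows <- list()
  for (k in seq_along(cand_i)) {
    i <- cand_i[k]; j <- cand_j[k]
    id5 <- flank_id(x$flank5[i], y$flank5[j])
    if (id5 < min_flank_identity) next
    id3 <- flank_id(x$flank3[i], y$flank3[j])
    if (id3 < min_flank_identity) next
    pair_rows[[length(pair_rows) + 1L]] <-
      data.frame(i = i, j = j, identity5 = id5, identity3 = id3)
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(i = integer(0), j = integer(0), identity5 = numeric(0),
               identity3 = numeric(0))
  ## greedy best-first maximal matching
  pairs <- pairs[order(-(pairs$identity5 + pairs$identity3) / 2), ,
                 drop = FALSE]
  used_i <- logical(nrow(x)); used_j <- logical(nrow(y))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    if (!used_i[pairs$i[k]] && !used_j[pairs$j[k]]) {
      keep[k] <- TRUE
      used_i[pairs$i[k]] <- TRUE
      used_j[pairs$j[k]] <- TRUE
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  n_common <- nrow(pairs)
  n_unique_x <- nrow(x) - n_common
  n_unique_y <- nrow(y) - n_common
  structure(list(
    pairs = pairs, n_common = n_common,
    n_unique_x = n_unique_x, n_unique_y = n_unique_y,
    shared_fraction_x = if (n_common + n_unique_x > 0)
      n_common / (n_common + n_unique_x) else NA_real_,
    shared_fraction_y = if (n_common + n_unique_y > 0)
      n_common / (n_common + n_unique_y) else NA_real_,
    n_excluded_x = sum(!ok_x), n_excluded_y = sum(!ok_y)),
    class = "mite_common_report")
}

#' @export
print.mite_distribution <- function(x, ...) {
  cat("Insertion distribution (", attr(x, "genome"), "): ",
      sum(x$count), " insertions\n", sep = "")
  sub <- tapply(x$count, x$subgenome, sum)
  sub <- sub[sub > 0]
  if (length(sub)) {
    cat("  by sub-genome: ",
        paste(names(sub), sub, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.mite_summary <- function(x, ...) {
  cat("MITE summary: grand total ", x$grand_total, " insertions\n", sep = "")
  cat("  superfamilies:\n")
  print(x$superfamily)
  cat("  top families:\n")
  print(utils::head(x$family, 8))
  if (!is.null(x$subgenome)) {
    cat("  sub-genomes:\n")
    print(x$subgenome)
  }
  invisible(x)
}

#' @export
print.mite_common_report <- function(x, ...) {
  cat("Common-insertion report: ", x$n_common, " shared, ",
      x$n_unique_x, " unique to X, ", x$n_unique_y, " unique to Y\n",
      sep = "")
  cat("  shared fraction: X ", format(x$shared_fraction_x, digits = 3),
      ", Y ", format(x$shared_fraction_y, digits = 3), "\n", sep = "")
  invisible(x)
}
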