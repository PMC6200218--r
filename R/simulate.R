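## Synthetic allopolyploid genome simulator.
##
## Generates multi-chromosome genomes with labeled sub-genomes, i.i.d.
## background sequence, synthetic host TEs (class I / class II), gene models
## with 5'UTR / CDS / intron / 3'UTR structure, and planted MITE copies at
## controlled divergence with their target site duplicated on both sides.
## Every planted copy is recorded in a ground-truth table so that retrieval,
## structural calling, annotation and comparative stages can all be scored
## against known truth. A polyploid derivation step models inheritance of a
## controllable fraction of parental insertions, clean single-TSD excision of
## the rest, and fresh child-unique insertions.

MITE_CONTEXTS <- c("intergenic", "TE_classI", "TE_classII", "gene_intron",
                   "gene_exon", "gene_5utr", "gene_3utr",
                   "upstream_le100", "downstream_le100")

## Margins used by the placement sampler (bp): distance kept between
## features, from chromosome ends, and between insertion points.
.PAD_CHROM_END <- 600L
.PAD_FEATURE <- 150L
.PAD_HOST_EDGE <- 50L
.PAD_GENE_PART <- 10L
.MIN_INSERT_GAP <- 40L

#' Specification of a synthetic genome
#'
#' @param subgenomes character vector of sub-genome labels, from `"A"`,
#'   `"B"`, `"D"`.
#' @param n_chromosomes chromosomes per sub-genome; chromosome names follow
#'   the wheat convention `<group><subgenome>` (e.g. `"3B"`).
#' @param chromosome_length background length in bp of each chromosome
#'   before insertions.
#' @param gc_content background GC fraction.
#' @param families data.frame describing what to plant, one row per family,
#'   with columns `family`, `superfamily`, `consensus` (DNA string),
#'   `copies` (integer), `divergence` (per-site substitution rate in
#'   `[0, 1)`), and optionally `tsd_pattern` for `"Unknown"` superfamilies.
#' @param nesting_fractions named numeric vector over
#'   `r paste0('"', MITE_CONTEXTS[-1], '"', collapse = ", ")`; fractions must
#'   lie in `[0, 1]` and sum to at most 1, the remainder being intergenic.
#' @param n_genes,n_te_hosts gene models and host-TE instances (per class)
#'   placed on each chromosome.
#' @param seed integer seed; the same spec and seed give byte-identical
#'   output.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(subgenomes = "A", n_chromosomes = 1L,
                        chromosome_length = 1e5, gc_content = 0.46,
                        families = NULL, nesting_fractions = numeric(0),
                        n_genes = 3L, n_te_hosts = 1L, seed = 1L) {
  stopifnot(all(subgenomes %in% c("A", "B", "D")), !anyDuplicated(subgenomes),
            n_chromosomes >= 1, chromosome_length >= 5000,
            gc_content >= 0, gc_content <= 1, n_genes >= 0, n_te_hosts >= 0)
  if (is.null(families)) {
    families <- data.frame(family = character(0), superfamily = character(0),
                           consensus = character(0), copies = integer(0),
                           divergence = numeric(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("family", "superfamily", "consensus", "copies", "divergence")
                %in% names(families)))
  stopifnot(all(families$copies >= 0),
            all(families$divergence >= 0), all(families$divergence < 1),
            all(families$superfamily %in% MITE_SUPERFAMILIES),
            !anyDuplicated(families$family))
  if (length(nesting_fractions)) {
    stopifnot(!is.null(names(nesting_fractions)),
              all(names(nesting_fractions) %in% MITE_CONTEXTS),
              all(nesting_fractions >= 0), all(nesting_fractions <= 1),
              sum(nesting_fractions) <= 1 + 1e-9)
  }
  structure(list(subgenomes = subgenomes,
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = as.integer(chromosome_length),
                 gc_content = gc_content, families = families,
                 nesting_fractions = nesting_fractions,
                 n_genes = as.integer(n_genes),
                 n_te_hosts = as.integer(n_te_hosts),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

## Sample one position from a union of IRanges, weighted by width.
.sample_position <- function(ir) {
  if (length(ir) == 0L || sum(IRanges::width(ir)) == 0L) return(NA_integer_)
  w <- IRanges::width(ir)
  i <- sample.int(length(ir), 1L, prob = w)
  IRanges::start(ir)[i] + sample.int(w[i], 1L) - 1L
}

## Non-overlapping placement of n intervals of given widths inside
## [pad+1, L-pad], all at least `gap` apart from `occupied` and each other.
.place_intervals <- function(n, widths, L, occupied, gap = .PAD_FEATURE,
                             pad = .PAD_CHROM_END) {
  out <- IRanges::IRanges()
  for (i in seq_len(n)) {
    w <- widths[i]
    ok <- FALSE
    for (try in 1:500) {
      s <- sample.int(max(L - 2L * pad - w, 1L), 1L) + pad
      cand <- IRanges::IRanges(s, s + w - 1L)
      blocked <- c(occupied, out)
      if (length(blocked) == 0L ||
          !any(IRanges::overlapsAny(cand, blocked + gap))) {
        out <- c(out, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place feature of width ", w,
                  ": requested features exceed available space")
  }
  out
}

## Generate one TSD realization for a family row.
.generate_tsd <- function(fam_row) {
  rule <- family_tsd_rule(fam_row)
  switch(rule$type,
    fixed = sample_iupac(rule$pattern),
    range = random_dna(9L, 0.5),          # uniform random 9-mer (within 7-10)
    any   = random_dna(sample(rule$min:rule$max, 1L), 0.5)
  )
}

## Gene part layout in transcription order (widths in bp).
.GENE_PARTS <- data.frame(
  type = c("five_prime_UTR", "CDS", "intron", "CDS", "three_prime_UTR"),
  width = c(200L, 300L, 400L, 300L, 300L),
  stringsAsFactors = FALSE
)

#' Generate a synthetic genome with planted MITE insertions
#'
#' Builds each chromosome as i.i.d. background sequence carrying synthetic
#' host TEs and gene models, then splices in the requested MITE copies. Each
#' copy is the family consensus mutated at the stated per-site substitution
#' rate, inserted on a random strand with its TSD duplicated immediately on
#' both sides. The returned truth table records every insertion with final
#' coordinates (1-based inclusive), strand, planted TSD and genomic context.
#'
#' @param spec a [genome_spec()].
#' @return an object of class `mite_genome`: a list with `seq` (named
#'   `DNAStringSet`), `chrom_meta` (chrom, subgenome, length), `features`
#'   (gene/TE feature table in final coordinates), `te_library` (host TE
#'   sequences with a `class` data.frame attribute), `truth` (data.frame of
#'   planted insertions, class `mite_truth`) and `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, .generate_genome_impl(spec))
}

.generate_genome_impl <- function(spec) {
  subg_of <- setNames(rep(spec$subgenomes, times = spec$n_chromosomes),
                      as.vector(outer(seq_len(spec$n_chromosomes),
                                      spec$subgenomes, paste0)))
  chroms <- names(subg_of)

  ## host TE library: one class I and one class II entry, shared by all
  ## instances so flank annotation can hit them by homology
  te_lib_len <- c(classI = 6000L, classII = 4000L)
  te_library <- Biostrings::DNAStringSet(c(
    synthTE_classI_1 = random_dna(te_lib_len[["classI"]], spec$gc_content),
    synthTE_classII_1 = random_dna(te_lib_len[["classII"]], spec$gc_content)
  ))
  te_classes <- data.frame(entry = names(te_library),
                           class = c("classI", "classII"),
                           stringsAsFactors = FALSE)

  seqs <- character(length(chroms))
  names(seqs) <- chroms
  feat_list <- list()
  ins_list <- list()
  gene_counter <- 0L
  te_counter <- 0L

  ## per-chromosome scaffold: background + feature layout (pre-insertion
  ## coordinates), then genome-wide insertion placement, then assembly
  pre <- list()
  for (ch in chroms) {
    L <- spec$chromosome_length
    occupied <- IRanges::IRanges()
    feats <- data.frame(chrom = character(0), type = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), id = character(0),
                        parent = character(0), class = character(0),
                        stringsAsFactors = FALSE)
    ## host TEs: n_te_hosts instances of each library entry
    if (spec$n_te_hosts > 0) {
      for (k in seq_len(nrow(te_classes))) {
        entry <- te_classes$entry[k]
        wlen <- te_lib_len[[te_classes$class[k]]]
        ir <- .place_intervals(spec$n_te_hosts, rep(wlen, spec$n_te_hosts),
                               L, occupied)
        occupied <- c(occupied, ir)
        for (j in seq_along(ir)) {
          te_counter <- te_counter + 1L
          feats <- rbind(feats, data.frame(
            chrom = ch, type = "transposable_element",
            start = IRanges::start(ir)[j], end = IRanges::end(ir)[j],
            strand = "+", id = sprintf("TE%04d", te_counter),
            parent = entry, class = te_classes$class[k],
            stringsAsFactors = FALSE))
        }
      }
    }
    ## gene models
    if (spec$n_genes > 0) {
      glen <- sum(.GENE_PARTS$width)
      ir <- .place_intervals(spec$n_genes, rep(glen, spec$n_genes), L, occupied)
      occupied <- c(occupied, ir)
      for (j in seq_along(ir)) {
        gene_counter <- gene_counter + 1L
        gid <- sprintf("gene%04d", gene_counter)
        strand <- sample(c("+", "-"), 1L)
        a <- IRanges::start(ir)[j]
        parts <- .GENE_PARTS
        if (strand == "-") parts <- parts[rev(seq_len(nrow(parts))), ]
        s <- a
        for (p in seq_len(nrow(parts))) {
          feats <- rbind(feats, data.frame(
            chrom = ch, type = parts$type[p],
            start = s, end = s + parts$width[p] - 1L,
            strand = strand, id = sprintf("%s.p%d", gid, p),
            parent = gid, class = NA_character_, stringsAsFactors = FALSE))
          s <- s + parts$width[p]
        }
        feats <- rbind(feats, data.frame(
          chrom = ch, type = "gene", start = a, end = a + glen - 1L,
          strand = strand, id = gid, parent = NA_character_,
          class = NA_character_, stringsAsFactors = FALSE))
      }
    }
    pre[[ch]] <- list(L = L, feats = feats)
    seqs[[ch]] <- random_dna(L, spec$gc_content)
    ## paste host TE sequences over the background
    te_rows <- feats[feats$type == "transposable_element", , drop = FALSE]
    for (j in seq_len(nrow(te_rows))) {
      entry_seq <- as.character(te_library[[te_rows$parent[j]]])
      substr(seqs[[ch]], te_rows$start[j], te_rows$end[j]) <- entry_seq
    }
  }

  ## candidate insertion intervals per context, genome-wide
  ctx_intervals <- .context_intervals(pre, chroms)

  ## draw insertions
  nf <- spec$nesting_fractions
  ctx_names <- c(names(nf), "intergenic")
  ctx_probs <- c(unname(nf), max(0, 1 - sum(nf)))
  chosen <- list()  # per chromosome: integer vector of used points
  for (ch in chroms) chosen[[ch]] <- integer(0)
  ins <- list()
  fam_df <- spec$families
  n_total <- 0L
  for (f in seq_len(nrow(fam_df))) {
    frow <- fam_df[f, ]
    if (frow$copies == 0L) next
    for (cp in seq_len(frow$copies)) {
      ctx <- sample(ctx_names, 1L, prob = ctx_probs)
      placed <- FALSE
      for (try in 1:300) {
        cand <- ctx_intervals[[ctx]]
        if (is.null(cand) || nrow(cand) == 0L) break
        i <- sample.int(nrow(cand), 1L, prob = cand$end - cand$start + 1)
        h <- cand$start[i] + sample.int(cand$end[i] - cand$start[i] + 1L, 1L) - 1L
        ch <- cand$chrom[i]
        if (length(chosen[[ch]]) == 0L ||
            min(abs(chosen[[ch]] - h)) >= .MIN_INSERT_GAP) {
          chosen[[ch]] <- c(chosen[[ch]], h)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("requested copies exceed available placement space (context '",
             ctx, "')")
      }
      elem <- mutate_seq(frow$consensus, frow$divergence)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") elem <- revcomp(elem)
      tsd <- .generate_tsd(frow)
      n_total <- n_total + 1L
      ins[[n_total]] <- data.frame(
        chrom = ch, h = h, family = frow$family, strand = strand,
        elem = elem, tsd = tsd, context = ctx, stringsAsFactors = FALSE)
    }
  }
  ins <- if (n_total) do.call(rbind, ins) else
    data.frame(chrom = character(0), h = integer(0), family = character(0),
               strand = character(0), elem = character(0), tsd = character(0),
               context = character(0), stringsAsFactors = FALSE)

  ## assemble chromosomes and lift features
  truth_rows <- list()
  feat_final <- list()
  for (ch in chroms) {
    chi <- ins[ins$chrom == ch, , drop = FALSE]
    res <- .splice_insertions(seqs[[ch]], chi)
    seqs[[ch]] <- res$seq
    feats <- pre[[ch]]$feats
    if (nrow(feats)) {
      feats$start <- res$lift(feats$start)
      feats$end <- res$lift(feats$end)
    }
    feat_final[[ch]] <- feats
    if (nrow(chi)) {
      truth_rows[[ch]] <- data.frame(
        family = chi$family, chrom = ch,
        subgenome = unname(subg_of[ch]),
        start = res$elem_start, end = res$elem_end,
        strand = chi$strand, planted_tsd = chi$tsd, context = chi$context,
        lineage = NA_character_, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(family = character(0), chrom = character(0),
               subgenome = character(0), start = integer(0), end = integer(0),
               strand = character(0), planted_tsd = character(0),
               context = character(0), lineage = character(0),
               stringsAsFactors = FALSE)
  truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  class(truth) <- c("mite_truth", "data.frame")

  features <- do.call(rbind, feat_final)
  rownames(features) <- NULL
  attr(te_library, "classes") <- te_classes

  chrom_meta <- data.frame(chrom = chroms,
                           subgenome = unname(subg_of[chroms]),
                           length = nchar(seqs[chroms]),
                           stringsAsFactors = FALSE)
  structure(list(seq = Biostrings::DNAStringSet(seqs),
                 chrom_meta = chrom_meta, features = features,
                 te_library = te_library, truth = truth, spec = spec),
            class = "mite_genome")
}

## Per-context candidate intervals (pre-insertion coordinates), as one
## data.frame(chrom, start, end) per context.
.context_intervals <- function(pre, chroms) {
  out <- setNames(vector("list", length(MITE_CONTEXTS)), MITE_CONTEXTS)
  add <- function(ctx, ch, ir) {
    if (length(ir) == 0L) return()
    ir <- ir[IRanges::width(ir) >= 2L]
    if (length(ir) == 0L) return()
    out[[ctx]] <<- rbind(out[[ctx]],
      data.frame(chrom = ch, start = IRanges::start(ir),
                 end = IRanges::end(ir) - 1L,  # h and h+1 must be inside
                 stringsAsFactors = FALSE))
  }
  for (ch in chroms) {
    L <- pre[[ch]]$L
    feats <- pre[[ch]]$feats
    shrink <- function(rows, pad) {
      if (nrow(rows) == 0L) return(IRanges::IRanges())
      ir <- IRanges::IRanges(rows$start + pad, rows$end - pad)
      ir[IRanges::width(ir) > 0L]
    }
    te <- feats[feats$type == "transposable_element", , drop = FALSE]
    add("TE_classI", ch, shrink(te[te$class == "classI", , drop = FALSE],
                                .PAD_HOST_EDGE))
    add("TE_classII", ch, shrink(te[te$class == "classII", , drop = FALSE],
                                 .PAD_HOST_EDGE))
    add("gene_intron", ch, shrink(feats[feats$type == "intron", , drop = FALSE],
                                  .PAD_GENE_PART))
    add("gene_exon", ch, shrink(feats[feats$type == "CDS", , drop = FALSE],
                                .PAD_GENE_PART))
    add("gene_5utr", ch, shrink(feats[feats$type == "five_prime_UTR", , drop = FALSE],
                                .PAD_GENE_PART))
    add("gene_3utr", ch, shrink(feats[feats$type == "three_prime_UTR", , drop = FALSE],
                                .PAD_GENE_PART))
    genes <- feats[feats$type == "gene", , drop = FALSE]
    if (nrow(genes)) {
      up <- ifelse(genes$strand == "+", genes$start - 100L, genes$end + 1L)
      upe <- ifelse(genes$strand == "+", genes$start - 1L, genes$end + 100L)
      dn <- ifelse(genes$strand == "+", genes$end + 1L, genes$start - 100L)
      dne <- ifelse(genes$strand == "+", genes$end + 100L, genes$start - 1L)
      add("upstream_le100", ch, IRanges::IRanges(pmax(up, 1L), pmin(upe, L)))
      add("downstream_le100", ch, IRanges::IRanges(pmax(dn, 1L), pmin(dne, L)))
    }
    blocked <- IRanges::IRanges()
    if (nrow(feats)) {
      blocked <- IRanges::reduce(IRanges::IRanges(feats$start, feats$end) +
                                   .PAD_FEATURE)
    }
    inter <- BiocGenerics::setdiff(
      IRanges::IRanges(.PAD_CHROM_END + 1L, L - .PAD_CHROM_END), blocked)
    add("intergenic", ch, inter)
  }
  out
}

## Splice insertion texts (tsd+element+tsd) into a chromosome string.
## `ins` has columns h, elem, tsd (h = insert after this position). Returns
## the new string, final element coordinates (in input row order), and a
## lift function mapping pre-insertion boundary coordinates to final ones.
.splice_insertions <- function(seq, ins) {
  if (nrow(ins) == 0L) {
    return(list(seq = seq, elem_start = integer(0), elem_end = integer(0),
                lift = identity))
  }
  ord <- order(ins$h)
  ins_sorted <- ins[ord, , drop = FALSE]
  text <- paste0(ins_sorted$tsd, ins_sorted$elem, ins_sorted$tsd)
  tlen <- nchar(text)
  added_before <- c(0L, cumsum(tlen)[-length(tlen)])
  pieces <- character(2L * nrow(ins_sorted) + 1L)
  prev <- 0L
  for (k in seq_len(nrow(ins_sorted))) {
    pieces[2L * k - 1L] <- substr(seq, prev + 1L, ins_sorted$h[k])
    pieces[2L * k] <- text[k]
    prev <- ins_sorted$h[k]
  }
  pieces[2L * nrow(ins_sorted) + 1L] <- substr(seq, prev + 1L, nchar(seq))
  new_seq <- paste(pieces, collapse = "")
  tsd_len <- nchar(ins_sorted$tsd)
  es <- ins_sorted$h + added_before + tsd_len + 1L
  ee <- es + nchar(ins_sorted$elem) - 1L
  elem_start <- integer(nrow(ins)); elem_end <- integer(nrow(ins))
  elem_start[ord] <- es
  elem_end[ord] <- ee
  hs <- ins_sorted$h
  lift <- function(x) {
    x + vapply(x, function(xi) sum(tlen[hs < xi]), numeric(1))
  }
  list(seq = new_seq, elem_start = elem_start, elem_end = elem_end,
       lift = lift)
}

#' Derive an allopolyploid genome from two parents
#'
#' The child carries every parental chromosome. Each parental insertion is
#' retained with probability `inherit_fraction` (lineage `"inherited"`);
#' otherwise it is excised cleanly, removing the element and one copy of its
#' TSD so that exactly one TSD copy remains at the empty site (lineage
#' `"parent_unique"` in the returned parental truth). `n_new` fresh
#' intergenic insertions, drawn from the parental family mix, are then added
#' (lineage `"child_unique"`).
#'
#' @param parent1,parent2 `mite_genome` objects with disjoint chromosome
#'   names (typically different sub-genomes).
#' @param inherit_fraction probability in `[0, 1]` that a parental insertion
#'   is retained in the child.
#' @param n_new number of fresh child-unique insertions.
#' @param seed integer seed.
#' @return a `mite_genome` for the child whose `truth` holds inherited and
#'   child-unique records in child coordinates, plus a `parent_truth`
#'   element: the combined parental truth labeled `"inherited"` /
#'   `"parent_unique"`.
#' @export
derive_polyploid <- function(parent1, parent2, inherit_fraction, n_new = 0L,
                             seed = 1L) {
  stopifnot(inherits(parent1, "mite_genome"), inherits(parent2, "mite_genome"))
  if (!is.numeric(inherit_fraction) || length(inherit_fraction) != 1L ||
      inherit_fraction < 0 || inherit_fraction > 1) {
    stop("`inherit_fraction` must be a single value in [0, 1]")
  }
  if (length(intersect(parent1$chrom_meta$chrom, parent2$chrom_meta$chrom))) {
    stop("parents share chromosome names; use distinct sub-genomes")
  }
  with_seed(seed, .derive_polyploid_impl(parent1, parent2, inherit_fraction,
                                         as.integer(n_new)))
}

.derive_polyploid_impl <- function(parent1, parent2, inherit_fraction, n_new) {
  seqs <- character(0)
  feat_list <- list()
  truth_list <- list()
  parent_truth_list <- list()
  for (p in list(parent1, parent2)) {
    pt <- p$truth
    keep <- if (nrow(pt)) stats::runif(nrow(pt)) < inherit_fraction else logical(0)
    ptl <- as.data.frame(pt)
    ptl$lineage <- ifelse(keep, "inherited", "parent_unique")
    parent_truth_list[[length(parent_truth_list) + 1L]] <- ptl
    for (ch in p$chrom_meta$chrom) {
      s <- as.character(p$seq[[ch]])
      rows <- which(pt$chrom == ch)
      drop <- rows[!keep[rows]]
      hold <- rows[keep[rows]]
      ## removal interval = left TSD copy + element; one TSD copy remains
      if (length(drop)) {
        tsd_len <- nchar(pt$planted_tsd[drop])
        rs <- pt$start[drop] - tsd_len
        re <- pt$end[drop]
        ord <- order(rs)
        rs <- rs[ord]; re <- re[ord]
        keep_pieces <- character(length(rs) + 1L)
        prev <- 0L
        for (k in seq_along(rs)) {
          keep_pieces[k] <- substr(s, prev + 1L, rs[k] - 1L)
          prev <- re[k]
        }
        keep_pieces[length(rs) + 1L] <- substr(s, prev + 1L, nchar(s))
        s <- paste(keep_pieces, collapse = "")
        rlen <- re - rs + 1L
        lift_down <- function(x) {
          x - vapply(x, function(xi) sum(rlen[re < xi]), numeric(1))
        }
      } else {
        lift_down <- identity
      }
      seqs[[ch]] <- s
      fe <- p$features[p$features$chrom == ch, , drop = FALSE]
      if (nrow(fe)) {
        fe$start <- lift_down(fe$start)
        fe$end <- lift_down(fe$end)
      }
      feat_list[[ch]] <- fe
      if (length(hold)) {
        tr <- as.data.frame(pt[hold, , drop = FALSE])
        tr$start <- lift_down(tr$start)
        tr$end <- lift_down(tr$end)
        tr$lineage <- "inherited"
        truth_list[[ch]] <- tr
      }
    }
  }
  chrom_meta <- rbind(parent1$chrom_meta, parent2$chrom_meta)
  chrom_meta$length <- nchar(seqs[chrom_meta$chrom])
  truth <- if (length(truth_list)) do.call(rbind, truth_list) else
    parent1$truth[0, , drop = FALSE]
  features <- do.call(rbind, c(feat_list, list(parent1$features[0, ])))

  ## fresh child-unique insertions, intergenic in child coordinates
  fam_df <- unique(rbind(parent1$spec$families, parent2$spec$families))
  if (n_new > 0L && nrow(fam_df) == 0L) {
    stop("cannot add new insertions: parents plant no families")
  }
  if (n_new > 0L) {
    new_ins <- list()
    chosen <- lapply(setNames(nm = chrom_meta$chrom),
                     function(ch) c(truth$start[truth$chrom == ch]))
    for (k in seq_len(n_new)) {
      frow <- fam_df[sample.int(nrow(fam_df), 1L), ]
      placed <- FALSE
      for (try in 1:300) {
        ch <- sample(chrom_meta$chrom, 1L,
                     prob = chrom_meta$length)
        L <- chrom_meta$length[chrom_meta$chrom == ch]
        h <- sample.int(L - 2L * .PAD_CHROM_END, 1L) + .PAD_CHROM_END
        fe <- features[features$chrom == ch, , drop = FALSE]
        in_feat <- nrow(fe) && any(h >= fe$start - .PAD_FEATURE &
                                     h <= fe$end + .PAD_FEATURE)
        near <- length(chosen[[ch]]) && min(abs(chosen[[ch]] - h)) < 700L
        if (!in_feat && !near) {
          chosen[[ch]] <- c(chosen[[ch]], h)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place child-unique insertion ", k)
      elem <- mutate_seq(frow$consensus, frow$divergence)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") elem <- revcomp(elem)
      new_ins[[k]] <- data.frame(chrom = ch, h = h, family = frow$family,
                                 strand = strand, elem = elem,
                                 tsd = .generate_tsd(frow),
                                 context = "intergenic",
                                 stringsAsFactors = FALSE)
    }
    new_ins <- do.call(rbind, new_ins)
    for (ch in unique(new_ins$chrom)) {
      chi <- new_ins[new_ins$chrom == ch, , drop = FALSE]
      res <- .splice_insertions(seqs[[ch]], chi)
      seqs[[ch]] <- res$seq
      fe_idx <- which(features$chrom == ch)
      if (length(fe_idx)) {
        features$start[fe_idx] <- res$lift(features$start[fe_idx])
        features$end[fe_idx] <- res$lift(features$end[fe_idx])
      }
      tr_idx <- which(truth$chrom == ch)
      if (length(tr_idx)) {
        truth$start[tr_idx] <- res$lift(truth$start[tr_idx])
        truth$end[tr_idx] <- res$lift(truth$end[tr_idx])
      }
      truth <- rbind(truth, data.frame(
        family = chi$family, chrom = ch,
        subgenome = chrom_meta$subgenome[chrom_meta$chrom == ch],
        start = res$elem_start, end = res$elem_end, strand = chi$strand,
        planted_tsd = chi$tsd, context = chi$context,
        lineage = "child_unique", stringsAsFactors = FALSE))
    }
    chrom_meta$length <- nchar(seqs[chrom_meta$chrom])
  }

  truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  class(truth) <- c("mite_truth", "data.frame")
  parent_truth <- do.call(rbind, parent_truth_list)
  rownames(parent_truth) <- NULL
  rownames(features) <- NULL

  te_library <- parent1$te_library
  structure(list(seq = Biostrings::DNAStringSet(seqs[chrom_meta$chrom]),
                 chrom_meta = chrom_meta, features = features,
                 te_library = te_library, truth = truth,
                 spec = list(families = fam_df,
                             parents = list(parent1$spec, parent2$spec)),
                 parent_truth = parent_truth),
            class = "mite_genome")
}

#' Build insertion records directly from a genome's truth table
#'
#' Slices each planted element and its flanks out of the genome sequence,
#' yielding the same record layout as [retrieve_insertions()] but taken from
#' ground truth rather than homology search. Useful for scoring and for
#' truth-driven comparative analyses.
#'
#' @param genome a `mite_genome`.
#' @param flank_len flank length in bp (each side).
#' @return a `mite_insertions` data.frame.
#' @export
insertions_from_truth <- function(genome, flank_len = 500L) {
  stopifnot(inherits(genome, "mite_genome"))
  tr <- genome$truth
  n <- nrow(tr)
  rec <- data.frame(
    family = tr$family, chrom = tr$chrom, start = tr$start, end = tr$end,
    strand = tr$strand,
    element_seq = character(n), flank5 = character(n), flank3 = character(n),
    flank5_truncated = logical(n), flank3_truncated = logical(n),
    end_gap5 = 0L, end_gap3 = 0L,
    identity = 1, score = NA_real_, evalue = NA_real_,
    stringsAsFactors = FALSE)
  seqs <- as.character(genome$seq)
  for (i in seq_len(n)) {
    s <- seqs[[tr$chrom[i]]]
    L <- nchar(s)
    rec$element_seq[i] <- substr(s, tr$start[i], tr$end[i])
    f5s <- max(1L, tr$start[i] - flank_len)
    rec$flank5[i] <- substr(s, f5s, tr$start[i] - 1L)
    rec$flank5_truncated[i] <- (tr$start[i] - f5s) < flank_len
    f3e <- min(L, tr$end[i] + flank_len)
    rec$flank3[i] <- substr(s, tr$end[i] + 1L, f3e)
    rec$flank3_truncated[i] <- (f3e - tr$end[i]) < flank_len
  }
  class(rec) <- c("mite_insertions", "data.frame")
  rec
}

#' @export
print.mite_genome <- function(x, ...) {
  cat("Synthetic genome: ", nrow(x$chrom_meta), " chromosome(s), ",
      sum(x$chrom_meta$length), " bp total\n", sep = "")
  cat("  sub-genomes: ",
      paste(unique(x$chrom_meta$subgenome), collapse = ", "), "\n", sep = "")
  cat("  planted insertions: ", nrow(x$truth), "\n", sep = "")
  invisible(x)
}

#' @export
print.mite_truth <- function(x, ...) {
  cat("Truth set: ", nrow(x), " planted insertion(s)\n", sep = "")
  if (nrow(x)) {
    print(head(as.data.frame(x), 6))
    if (nrow(x) > 6) cat("  ...\n")
  }
  invisible(x)
}
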