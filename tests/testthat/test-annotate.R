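# Genome with insertions split across host-TE, gene and intergenic
# contexts, used for annotation category checks.
annotation_genome <- function() {
  fixture("annotation_genome", function() {
    fams <- plant_df("Sto1", "Stowaway", stowaway_consensus(), 40, 0)
    generate_genome(genome_spec(
      subgenomes = "A", n_chromosomes = 1, chromosome_length = 8e4,
      families = fams,
      nesting_fractions = c(TE_classI = 0.25, TE_classII = 0.25,
                            gene_intron = 0.2),
      n_genes = 3, n_te_hosts = 2, seed = 71))
  })
}

annotated_records <- function() {
  fixture("annotated_records", function() {
    g <- annotation_genome()
    rec <- insertions_from_truth(g)
    annotate_insertions(rec, reference_set(g))
  })
}

test_that("host-TE insertions are annotated with the host class", {
  g <- annotation_genome()
  ann <- annotated_records()
  ctx <- g$truth$context
  in_te1 <- ctx == "TE_classI"
  in_te2 <- ctx == "TE_classII"
  expect_gt(sum(in_te1), 0)
  expect_gt(sum(in_te2), 0)
  ## at divergence 0 the class comes from the library label: no confusion
  expect_true(all(ann$category[in_te1] == "TE_classI"))
  expect_true(all(ann$category[in_te2] == "TE_classII"))
})

test_that("gene-intron insertions annotate as genic with intron relation", {
  g <- annotation_genome()
  ann <- annotated_records()
  in_intron <- g$truth$context == "gene_intron"
  expect_gt(sum(in_intron), 0)
  expect_true(all(ann$category[in_intron] == "protein_coding_gene"))
  expect_true(all(ann$gene_relation[in_intron] == "intron"))
})

test_that("insertions far from any reference stay unknown", {
  g <- annotation_genome()
  ann <- annotated_records()
  feats <- g$features
  far <- vapply(seq_len(nrow(ann)), function(i) {
    d <- pmax(0, pmax(feats$start - ann$end[i], ann$start[i] - feats$end))
    all(d[feats$chrom == ann$chrom[i]] > 600)
  }, logical(1))
  expect_gt(sum(far), 0)
  expect_true(all(ann$category[far] == "unknown"))
  ## the annotation invariant: a gene relation implies genic category or
  ## close proximity
  rel <- ann$gene_relation != "none"
  expect_true(all(ann$category[rel] == "protein_coding_gene" |
                    ann$distance_to_gene[rel] <= 100))
})

test_that("an empty reference set yields only unknown calls", {
  g <- annotation_genome()
  rec <- insertions_from_truth(g)[1:5, ]
  empty_refs <- structure(list(cdna = Biostrings::DNAStringSet(),
                               te = Biostrings::DNAStringSet(),
                               te_class = character(0),
                               ncrna = Biostrings::DNAStringSet(),
                               gene_models = g$features[0, ]),
                          class = "mite_refset")
  ann <- annotate_insertions(rec, empty_refs)
  expect_true(all(ann$category == "unknown"))
  expect_true(all(ann$gene_relation == "none"))
})

test_that("gene association follows the 100-bp window rule", {
  ## one + strand gene at 1000..2499 and one - strand gene at 5000..6499
  gm <- data.frame(
    chrom = "1A",
    type = c("gene", "five_prime_UTR", "CDS", "intron", "CDS",
             "three_prime_UTR", "gene", "three_prime_UTR", "CDS", "intron",
             "CDS", "five_prime_UTR"),
    start = c(1000, 1000, 1200, 1500, 1900, 2200,
              5000, 5000, 5300, 5600, 6000, 6200),
    end = c(2499, 1199, 1499, 1899, 2199, 2499,
            6499, 5299, 5599, 5999, 6199, 6499),
    strand = c(rep("+", 6), rep("-", 6)),
    id = paste0("f", 1:12),
    parent = c(NA, rep("f1", 5), NA, rep("f7", 5)),
    class = NA_character_, stringsAsFactors = FALSE)
  mk <- function(start, end) {
    data.frame(chrom = "1A", start = start, end = end)
  }
  assoc <- function(s, e) {
    classify_gene_association(mk(s, e), gm)$gene_relation
  }
  expect_equal(assoc(920, 949), "upstream_le100")      # 50 bp upstream (+)
  expect_equal(assoc(800, 849), "none")                # 150 bp away
  expect_equal(assoc(870, 899), "upstream_le100")      # exactly 100 bp
  expect_equal(assoc(2520, 2560), "downstream_le100")  # just past gene (+)
  expect_equal(assoc(1600, 1700), "intron")
  expect_equal(assoc(1250, 1300), "exon")
  expect_equal(assoc(6520, 6560), "upstream_le100")    # 5' side of - gene
  expect_equal(assoc(4920, 4950), "downstream_le100")  # 3' side of - gene
})

test_that("gene association agrees with a brute-force oracle", {
  g <- annotation_genome()
  gm <- g$features
  set.seed(72)
  L <- g$chrom_meta$length[1]
  starts <- sample.int(L - 300L, 1000L)
  recs <- data.frame(chrom = "1A", start = starts,
                     end = starts + sample(20:250, 1000L, replace = TRUE))
  got <- classify_gene_association(recs, gm)$gene_relation
  want <- vapply(seq_len(nrow(recs)), function(i) {
    gene_assoc_oracle(recs$start[i], recs$end[i], recs$chrom[i], gm)
  }, character(1))
  expect_equal(got, want)
})

test_that("in-transcript location is assigned by region", {
  parts <- data.frame(
    type = c("five_prime_UTR", "CDS", "intron", "CDS", "three_prime_UTR"),
    start = c(100, 300, 600, 1000, 1300),
    end = c(299, 599, 999, 1299, 1599),
    strand = "+", stringsAsFactors = FALSE)
  expect_equal(locate_in_transcript(1350, 1450, parts), "three_prime_utr")
  expect_equal(locate_in_transcript(350, 420, parts), "cds")
  expect_equal(locate_in_transcript(150, 240, parts), "five_prime_utr")
  ## crossing the CDS/3'UTR boundary with >10% on each side
  expect_equal(locate_in_transcript(1250, 1400, parts), "spanning")
})

test_that("a planted 70/17/13 transcript-region mix is recovered", {
  ## synthetic transcript: region widths set so each region can hold the
  ## insertions planted into it
  parts <- data.frame(
    type = c("five_prime_UTR", "CDS", "intron", "CDS", "three_prime_UTR"),
    start = c(1, 501, 1501, 2001, 3001),
    end = c(500, 1500, 2000, 3000, 5000),
    strand = "+", stringsAsFactors = FALSE)
  set.seed(73)
  n <- 400L
  region <- sample(rep(c("three_prime_utr", "five_prime_utr", "cds"),
                       c(280L, 68L, 52L)))
  ins_len <- 30L
  pick <- function(lo, hi) as.integer(lo + sample.int(hi - lo - ins_len, 1L))
  starts <- vapply(region, function(r) {
    switch(r,
           five_prime_utr = pick(1, 500),
           cds = if (runif(1) < 0.5) pick(501, 1500) else pick(2001, 3000),
           three_prime_utr = pick(3001, 5000))
  }, integer(1))
  calls <- vapply(seq_len(n), function(i) {
    locate_in_transcript(starts[i], starts[i] + ins_len - 1L, parts)
  }, character(1))
  ## recovered calls match the planted regions record by record
  expect_equal(unname(calls), unname(region))
  ## and the recovered mix reproduces the planted 70/17/13 split
  prop <- as.vector(table(calls)[c("three_prime_utr", "five_prime_utr",
                                   "cds")]) / n
  expect_true(all(abs(prop - c(0.70, 0.17, 0.13)) <= 0.03))
})
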