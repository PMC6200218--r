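test_that("planted copies carry their TSD on both sides in the sequence", {
  g <- genome_100_stowaway()
  tr <- g$truth
  expect_equal(nrow(tr), 100L)
  expect_true(all(tr$planted_tsd == "TA"))
  seqs <- as.character(g$seq)
  for (i in seq_len(nrow(tr))) {
    s <- seqs[[tr$chrom[i]]]
    expect_equal(substr(s, tr$start[i] - 2L, tr$start[i] - 1L), "TA")
    expect_equal(substr(s, tr$end[i] + 1L, tr$end[i] + 2L), "TA")
  }
})

test_that("truth records satisfy their structural invariants", {
  g <- genome_100_stowaway()
  tr <- g$truth
  expect_true(all(tr$end > tr$start))
  lens <- g$chrom_meta$length[match(tr$chrom, g$chrom_meta$chrom)]
  expect_true(all(tr$start >= 1 & tr$end <= lens))
  ## sorted by (chrom, start), no duplicated loci
  expect_identical(order(tr$chrom, tr$start), seq_len(nrow(tr)))
  expect_false(any(duplicated(tr[, c("chrom", "start", "end", "family")])))
})

test_that("planted elements realign to the consensus within the divergence budget", {
  g <- genome_recall()
  cons <- g$spec$families$consensus[1]
  div <- g$spec$families$divergence[1]
  tr <- g$truth
  seqs <- as.character(g$seq)
  ident <- vapply(seq_len(nrow(tr)), function(i) {
    e <- substr(seqs[[tr$chrom[i]]], tr$start[i], tr$end[i])
    if (tr$strand[i] == "-") e <- revcomp(e)
    1 - mitescope:::hamming(e, cons) / nchar(cons)
  }, numeric(1))
  expect_true(all(ident >= 1 - div - 0.05))
})

test_that("zero-copy specs produce a clean genome and nothing is retrieved", {
  fams <- plant_df("Sto1", "Stowaway", stowaway_consensus(), 0, 0)
  g <- generate_genome(genome_spec(subgenomes = "A", n_chromosomes = 1,
                                   chromosome_length = 3e4, families = fams,
                                   n_genes = 0, n_te_hosts = 0, seed = 12))
  expect_equal(nrow(g$truth), 0L)
  rec <- retrieve_insertions(g, "Sto1", stowaway_consensus())
  expect_equal(nrow(rec), 0L)
})

test_that("nesting fractions control insertion context", {
  fams <- plant_df("Sto1", "Stowaway", stowaway_consensus(), 30, 0)
  g <- generate_genome(genome_spec(
    subgenomes = "A", n_chromosomes = 1, chromosome_length = 4e4,
    families = fams, nesting_fractions = c(TE_classII = 1.0),
    n_genes = 1, n_te_hosts = 2, seed = 13))
  expect_true(all(g$truth$context == "TE_classII"))
  ## every insertion lies inside a class II host interval
  hosts <- g$features[g$features$type == "transposable_element" &
                        g$features$class == "classII", , drop = FALSE]
  inside <- vapply(seq_len(nrow(g$truth)), function(i) {
    any(hosts$chrom == g$truth$chrom[i] &
          hosts$start <= g$truth$start[i] & hosts$end >= g$truth$end[i])
  }, logical(1))
  expect_true(all(inside))
})

test_that("generation is byte-identical under a fixed spec and seed", {
  fams <- plant_df("Sto1", "Stowaway", stowaway_consensus(), 20, 0.03)
  sp <- genome_spec(subgenomes = c("A", "B"), n_chromosomes = 1,
                    chromosome_length = 3e4, families = fams,
                    n_genes = 2, n_te_hosts = 1, seed = 77)
  g1 <- generate_genome(sp)
  g2 <- generate_genome(sp)
  expect_identical(as.character(g1$seq), as.character(g2$seq))
  expect_identical(as.data.frame(g1$truth), as.data.frame(g2$truth))
  expect_identical(g1$features, g2$features)
})

test_that("overfull placement requests fail loudly", {
  fams <- plant_df("Sto1", "Stowaway", stowaway_consensus(), 5000, 0)
  sp <- genome_spec(subgenomes = "A", n_chromosomes = 1,
                    chromosome_length = 6e3, families = fams,
                    n_genes = 0, n_te_hosts = 0, seed = 14)
  expect_error(generate_genome(sp), "exceed available placement space")
})

test_that("polyploid derivation respects inheritance boundaries", {
  gA <- parent_A_500()
  gB <- parent_B_empty()
  all_in <- derive_polyploid(gA, gB, inherit_fraction = 1.0, n_new = 0,
                             seed = 41)
  expect_equal(sum(all_in$truth$lineage == "inherited"), nrow(gA$truth))
  expect_true(all(all_in$parent_truth$lineage == "inherited"))

  none_in <- derive_polyploid(gA, gB, inherit_fraction = 0.0, n_new = 0,
                              seed = 42)
  expect_equal(nrow(none_in$truth), 0L)
  expect_true(all(none_in$parent_truth$lineage == "parent_unique"))

  expect_error(derive_polyploid(gA, gB, inherit_fraction = 1.5), "\\[0, 1\\]")
  expect_error(derive_polyploid(gA, gA, inherit_fraction = 0.5),
               "share chromosome names")
})

test_that("inherited counts follow the binomial sampling model", {
  gA <- parent_A_500()
  gB <- parent_B_empty()
  child <- derive_polyploid(gA, gB, inherit_fraction = 0.4, n_new = 0,
                            seed = 43)
  n <- nrow(gA$truth)
  k <- sum(child$parent_truth$lineage == "inherited")
  ## within 3 standard deviations of Binomial(500, 0.4)
  expect_lt(abs(k - n * 0.4), 3 * sqrt(n * 0.4 * 0.6))
})

test_that("excision removes the element and exactly one TSD copy", {
  gA <- parent_A_500()
  gB <- parent_B_empty()
  child <- derive_polyploid(gA, gB, inherit_fraction = 0.5, n_new = 0,
                            seed = 44)
  pt <- child$parent_truth
  gone <- pt[pt$lineage == "parent_unique", , drop = FALSE][1:20, ]
  child_seqs <- as.character(child$seq)
  parent_seqs <- as.character(gA$seq)
  for (i in seq_len(nrow(gone))) {
    s <- parent_seqs[[gone$chrom[i]]]
    k <- nchar(gone$planted_tsd[i])
    before <- substr(s, gone$start[i] - k - 20L, gone$start[i] - k - 1L)
    after <- substr(s, gone$end[i] + k + 1L, gone$end[i] + k + 20L)
    healed <- paste0(before, gone$planted_tsd[i], after)
    expect_true(grepl(healed, child_seqs[[gone$chrom[i]]], fixed = TRUE),
                info = paste("excision site", i))
  }
})

test_that("child-unique insertions are added with correct coordinates", {
  gA <- parent_A_500()
  gB <- parent_B_empty()
  child <- derive_polyploid(gA, gB, inherit_fraction = 0.5, n_new = 15,
                            seed = 45)
  newr <- child$truth[child$truth$lineage == "child_unique", , drop = FALSE]
  expect_equal(nrow(newr), 15L)
  recs <- insertions_from_truth(child)
  ## every truth record (inherited or new) slices out a TA-flanked element
  expect_true(all(substr(recs$flank3, 1, 2) == "TA"))
  n5 <- nchar(recs$flank5)
  expect_true(all(substr(recs$flank5, n5 - 1, n5) == "TA"))
})
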