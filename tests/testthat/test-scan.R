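test_that("undiverged planted copies are retrieved at truth coordinates", {
  g <- genome_100_stowaway()
  rec <- retrieve_insertions(g, "Sto1", stowaway_consensus())
  expect_equal(nrow(rec), 100L)
  tr <- g$truth
  expect_equal(rec$start, tr$start)
  expect_equal(rec$end, tr$end)
  expect_equal(rec$strand, tr$strand)
  expect_true(all(rec$identity == 1))
  expect_true(all(rec$end_gap5 == 0L & rec$end_gap3 == 0L))
})

test_that("a decoy consensus absent from the genome retrieves nothing", {
  g <- genome_100_stowaway()
  decoy <- synthetic_consensus(253, tir_len = 14, seed = 999)
  rec <- retrieve_insertions(g, "decoy", decoy)
  expect_equal(nrow(rec), 0L)
})

test_that("retrieved records satisfy their structural invariants", {
  g <- genome_recall()
  rec <- retrieve_insertions(g, "Fam1", g$spec$families$consensus[1])
  expect_gt(nrow(rec), 0L)
  expect_equal(nchar(rec$element_seq), rec$end - rec$start + 1L)
  expect_true(all(nchar(rec$flank5) <= 500L))
  expect_true(all(nchar(rec$flank3) <= 500L))
  expect_equal(rec$flank5_truncated, nchar(rec$flank5) < 500L)
  expect_equal(rec$flank3_truncated, nchar(rec$flank3) < 500L)
  expect_true(all(rec$end_gap5 <= 20L & rec$end_gap3 <= 20L))
  lens <- g$chrom_meta$length[match(rec$chrom, g$chrom_meta$chrom)]
  expect_true(all(rec$start >= 1L & rec$end <= lens))
  expect_true(all(rec$evalue <= 1e-3))
})

test_that("retrieval at 5% divergence keeps recall high and precision clean", {
  g <- genome_recall()
  rec <- retrieve_insertions(g, "Fam1", g$spec$families$consensus[1])
  sc <- truth_overlap(rec, g$truth)
  expect_gte(sc$recall, 0.95)
  expect_lte(sc$fp_rate, 0.01)
})

test_that("deduplication removes exact element+flank duplicates only", {
  g <- genome_100_stowaway()
  rec <- retrieve_insertions(g, "Sto1", stowaway_consensus())
  ## construct assembly duplicates: same element and flanks at shifted
  ## coordinates on another chromosome name
  dup <- rec[1:5, ]
  dup$chrom <- "9Z"
  dup$start <- dup$start + 1000L
  dup$end <- dup$end + 1000L
  both <- rbind(rec, dup)
  dd <- deduplicate(both)
  expect_equal(nrow(dd), nrow(rec))
  ## the kept copy of each duplicated group is the lowest (chrom, start)
  expect_true(all(dd$chrom != "9Z"))
  ## records identical in element but differing in flanks are both kept
  var <- rec[1, ]
  var$chrom <- "9Z"
  var$flank5 <- mutate_seq(var$flank5, 0.2)
  dd2 <- deduplicate(rbind(rec, var))
  expect_equal(nrow(dd2), nrow(rec) + 1L)
  ## idempotence
  expect_equal(as.data.frame(deduplicate(dd)), as.data.frame(dd))
  ## output sorted by (chrom, start)
  expect_identical(order(dd$chrom, dd$start), seq_len(nrow(dd)))
})

test_that("scan_genome runs all catalog families and binds records", {
  fams <- rbind(
    plant_df("F1", "Stowaway", stowaway_consensus(), 8, 0),
    plant_df("F2", "Tourist", tourist_consensus(), 6, 0))
  g <- generate_genome(genome_spec(subgenomes = "A", n_chromosomes = 1,
                                   chromosome_length = 3e4, families = fams,
                                   n_genes = 0, n_te_hosts = 0, seed = 55))
  rec <- scan_genome(g, fams)
  expect_equal(as.vector(table(rec$family)[c("F1", "F2")]), c(8L, 6L))
})

test_that("mutate_seq respects the divergence rate", {
  base <- random_dna(5000, 0.5)
  set.seed(10)
  mut <- mutate_seq(base, 0.05)
  d <- mitescope:::hamming(base, mut) / nchar(base)
  expect_lt(abs(d - 0.05), 0.01)
  expect_identical(mutate_seq(base, 0), base)
})
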