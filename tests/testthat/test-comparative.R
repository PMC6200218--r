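test_that("tabulation bins records by sub-genome and chromosome group", {
  rec <- data.frame(family = "Fam1", chrom = rep("3B", 10))
  tab <- tabulate_insertions(rec)
  expect_equal(tab$count[tab$family == "Fam1" & tab$subgenome == "B" &
                           tab$group == "3"], 10L)
  expect_equal(sum(tab$count), 10L)

  ## unlabeled scaffolds land in the unknown bin
  rec2 <- data.frame(family = "Fam1",
                     chrom = c("3B", "scaffold_17", "chrUn"))
  tab2 <- tabulate_insertions(rec2)
  expect_equal(sum(tab2$count[tab2$subgenome == "unknown"]), 2L)

  ## metadata overrides the name pattern
  meta <- data.frame(chrom = c("3B", "scaffold_17"),
                     subgenome = c("B", "D"))
  tab3 <- tabulate_insertions(rec2, meta)
  expect_equal(sum(tab3$count[tab3$subgenome == "D"]), 1L)
  expect_equal(sum(tab3$count[tab3$subgenome == "unknown"]), 1L)
})

test_that("scan-based tabulation equals truth tabulation at divergence 0", {
  g <- genome_100_stowaway()
  rec <- retrieve_insertions(g, "Sto1", stowaway_consensus())
  t_scan <- tabulate_insertions(rec, g$chrom_meta)
  t_truth <- tabulate_insertions(as.data.frame(g$truth), g$chrom_meta)
  expect_equal(t_scan$count, t_truth$count)
})

test_that("summary percentages conserve totals and order invariance", {
  g <- genome_100_stowaway()
  rec <- as.data.frame(g$truth)
  tab <- tabulate_insertions(rec, g$chrom_meta)
  s <- mite_summary(tab, superfamilies = c(Sto1 = "Stowaway"))
  expect_equal(s$grand_total, 100L)
  expect_equal(sum(s$superfamily$count), s$grand_total)
  expect_equal(sum(s$family$count), s$grand_total)
  expect_equal(s$family$percent[1], 100)

  ## permutation invariance of input record order
  tab2 <- tabulate_insertions(rec[sample(nrow(rec)), ], g$chrom_meta)
  s2 <- mite_summary(tab2, superfamilies = c(Sto1 = "Stowaway"))
  expect_equal(s, s2)

  ## empty table: zero totals, flagged percentages
  empty <- tabulate_insertions(rec[0, ], g$chrom_meta)
  s3 <- mite_summary(empty)
  expect_equal(s3$grand_total, 0L)
  expect_true(s3$empty)
})

test_that("rounding is half-up at the configured precision", {
  expect_equal(mitescope:::round_half_up(81.005, 2), 81.01)
  expect_equal(mitescope:::round_half_up(35.75, 1), 35.8)
  expect_equal(mitescope:::round_half_up(58.5, 0), 59)
  expect_equal(mitescope:::round_half_up(41.49, 0), 41)
})

test_that("matching a record set against itself is total", {
  g <- genome_100_stowaway()
  rec <- insertions_from_truth(g)
  cr <- match_common_insertions(rec, rec)
  expect_equal(cr$n_common, nrow(rec))
  expect_equal(cr$shared_fraction_x, 1)
  expect_equal(cr$shared_fraction_y, 1)
})

test_that("genomes with disjoint loci share nothing", {
  g1 <- genome_100_stowaway()
  fams <- plant_df("Sto1", "Stowaway", stowaway_consensus(), 30, 0)
  g2 <- generate_genome(genome_spec(subgenomes = "D", n_chromosomes = 1,
                                    chromosome_length = 5e4,
                                    families = fams, n_genes = 0,
                                    n_te_hosts = 0, seed = 81))
  rx <- insertions_from_truth(g1)
  ry <- insertions_from_truth(g2)
  cr <- match_common_insertions(rx, ry)
  expect_equal(cr$n_common, 0L)
  expect_equal(cr$shared_fraction_x, 0)
})

test_that("n_common is symmetric under swapping the two genomes", {
  gA <- parent_A_500()
  gB <- parent_B_empty()
  child <- derive_polyploid(gA, gB, inherit_fraction = 0.5, n_new = 20,
                            seed = 82)
  rx <- insertions_from_truth(child)
  ry <- insertions_from_truth(gA)
  ab <- match_common_insertions(rx, ry)
  ba <- match_common_insertions(ry, rx)
  expect_equal(ab$n_common, ba$n_common)
  expect_equal(ab$shared_fraction_x, ba$shared_fraction_y)
})

test_that("records without flanks are excluded and counted", {
  g <- genome_100_stowaway()
  rec <- insertions_from_truth(g)
  rec$flank5[1:3] <- ""
  cr <- match_common_insertions(rec, rec)
  expect_equal(cr$n_excluded_x, 3L)
  expect_equal(cr$n_common, nrow(rec) - 3L)
})

test_that("flank matching recovers the realized inherited fraction", {
  gA <- parent_A_500()
  gB <- parent_B_empty()
  child <- derive_polyploid(gA, gB, inherit_fraction = 0.4, n_new = 25,
                            seed = 83)
  rx <- insertions_from_truth(child)
  ry <- insertions_from_truth(gA)
  cr <- match_common_insertions(rx, ry)
  realized <- mean(child$parent_truth$lineage[
    child$parent_truth$chrom %in% gA$chrom_meta$chrom] == "inherited")
  expect_lt(abs(cr$shared_fraction_y - realized), 0.03)
})

test_that("fixture sub-genome arithmetic reproduces published fractions", {
  sub <- wheat_subgenome_counts()
  emmer <- sub[sub$genome == "Tturgidum" & sub$family == "ALL", ]
  expect_equal(subgenome_percent(emmer, "B"), 59)
  bread <- sub[sub$genome == "Taestivum" & sub$family == "ALL", ]
  expect_equal(subgenome_percent(bread, "B"), 41)
  thalos <- sub[sub$genome == "Tturgidum" & sub$family == "Thalos", ]
  expect_equal(subgenome_percent(thalos, "B", digits = 1), 62.7)
  minos <- sub[sub$genome == "Tturgidum" & sub$family == "Minos", ]
  expect_equal(subgenome_percent(minos, "A", digits = 2), 80.92)
})
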