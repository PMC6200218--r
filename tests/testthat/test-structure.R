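test_that("terminal inverted repeats are detected by construction", {
  set.seed(3)
  p <- random_dna(11, 0.5)
  core <- random_dna(80, 0.5)
  elem <- paste0(p, core, revcomp(p))
  tir <- find_tir(elem, max_mismatch = 0)
  expect_gte(tir$tir_len, 11L)
  expect_equal(tir$mismatches, 0L)

  ## one suffix base mutated, tolerance 1
  ch <- strsplit(elem, "", fixed = TRUE)[[1]]
  pos <- length(ch) - 5L
  ch[pos] <- setdiff(c("A", "C", "G", "T"), ch[pos])[1]
  mut <- paste(ch, collapse = "")
  tir1 <- find_tir(mut, max_mismatch = 1)
  expect_gte(tir1$tir_len, 11L)
  expect_lte(tir1$mismatches, 1L)
  ## the annotation's own invariant: right reverse-complements left within
  ## the reported mismatch count
  expect_equal(mitescope:::hamming(tir1$left_seq, revcomp(tir1$right_seq)),
               tir1$mismatches)
})

test_that("find_tir is strand-symmetric", {
  set.seed(4)
  for (i in 1:20) {
    elem <- paste0("GGCCATTAGCA", random_dna(60, 0.5),
                   revcomp("GGCCATTAGCA"))
    elem <- mutate_seq(elem, 0.02)
    a <- find_tir(elem)
    b <- find_tir(revcomp(elem))
    if (is.null(a)) {
      expect_null(b)
    } else {
      expect_equal(a$tir_len, b$tir_len)
      expect_equal(a$mismatches, b$mismatches)
    }
  }
})

test_that("random sequences rarely contain a qualifying TIR", {
  ## union bound over lengths 8..30 of P(Binomial(L, 3/4) <= 2 mismatches)
  bound <- sum(vapply(8:30, function(L) {
    sum(choose(L, 0:2) * 3^(0:2)) / 4^L
  }, numeric(1)))
  set.seed(5)
  hits <- 0L
  n <- 1000L
  for (i in seq_len(n)) {
    if (!is.null(find_tir(random_dna(200, 0.5)))) hits <- hits + 1L
  }
  expect_lte(hits / n, bound + 3 * sqrt(bound * (1 - bound) / n))
})

test_that("TSD calls recover the planted target site by rule type", {
  g <- genome_100_stowaway()
  rec <- insertions_from_truth(g)
  called <- call_tsds(rec, "Stowaway")
  expect_true(all(called$tsd_left == "TA"))
  expect_true(all(called$tsd_right == "TA"))
  expect_true(all(called$tsd_matches_rule))

  ## no duplication at all
  fake <- list(flank5 = "ACGTACGTACGTAAAC", flank3 = "GGTTGGTTCCAACGGA")
  cl <- call_tsd(fake, "Stowaway")
  expect_false(cl$matches_rule)

  ## short flanks are flagged, not errored
  cl2 <- call_tsd(list(flank5 = "A", flank3 = "T"), "Mutator")
  expect_false(cl2$matches_rule)
  expect_true(cl2$short_flank)
})

test_that("variable-length Mutator TSDs are recovered exactly", {
  fams <- plant_df("Mut1", "Mutator", mutator_consensus(), 200, 0)
  g <- generate_genome(genome_spec(subgenomes = "A", n_chromosomes = 1,
                                   chromosome_length = 25e4,
                                   families = fams, n_genes = 0,
                                   n_te_hosts = 0, seed = 61))
  rec <- insertions_from_truth(g)
  called <- call_tsds(rec, "Mutator")
  expect_equal(called$tsd_left, g$truth$planted_tsd)
  expect_equal(called$tsd_right, g$truth$planted_tsd)
  expect_true(all(called$tsd_matches_rule))
  expect_true(all(called$tsd_len == 9L))
})

test_that("position frequency matrices count and pad correctly", {
  pfm <- build_pfm(c("TA", "TA", "TA"))
  expect_equal(unname(pfm[1, "T"]), 3L)
  expect_equal(unname(pfm[2, "A"]), 3L)
  expect_equal(sum(pfm), 6L)

  pfm2 <- build_pfm(c("TA", "TT"))
  expect_equal(unname(pfm2[2, "A"]), 1L)
  expect_equal(unname(pfm2[2, "T"]), 1L)

  ## unequal lengths are N-padded; N never counts
  pfm3 <- build_pfm(c("TAG", "TA"))
  expect_equal(nrow(pfm3), 3L)
  expect_equal(sum(pfm3[3, ]), 1L)
  expect_error(build_pfm(character(0)), "zero sequences")

  ## conservation: counts + N-pad exclusions account for every sequence
  seqs <- c("ACGT", "ACG", "AC", "A")
  pfm4 <- build_pfm(seqs)
  n_at <- vapply(seq_len(4), function(p) sum(nchar(seqs) >= p), integer(1))
  expect_equal(unname(rowSums(pfm4)), n_at)
})

test_that("information content hits its boundary values exactly", {
  pure <- build_pfm(rep("A", 10))
  expect_equal(information_content(pure, 1), 2)
  uniform <- build_pfm(c("A", "C", "G", "T"))
  expect_equal(information_content(uniform, 1), 0)
  half <- build_pfm(c("A", "A", "T", "T"))
  expect_equal(information_content(half, 1), 1)
  ## always within [0, 2]
  set.seed(6)
  rnd <- build_pfm(replicate(30, random_dna(12, 0.3)))
  ic <- information_content(rnd)
  expect_true(all(ic >= 0 & ic <= 2))
})

test_that("haplotype diversity follows its closed form", {
  expect_equal(haplotype_diversity(rep("ACGT", 4))$Hd, 0)
  expect_equal(haplotype_diversity(c("AAAA", "CCCC", "GGGG", "TTTT"))$Hd, 1)
  expect_equal(haplotype_diversity(c("AA", "AA", "CC", "CC"))$Hd,
               (4 / 3) * (1 - 0.5))
  expect_equal(haplotype_diversity("ACGT")$Hd, 0)
  ## in [0, 1] on arbitrary inputs
  set.seed(7)
  for (i in 1:20) {
    seqs <- sample(c("AC", "AG", "AT", "CC"), sample(2:30, 1),
                   replace = TRUE)
    hd <- haplotype_diversity(seqs)$Hd
    expect_gte(hd, 0)
    expect_lte(hd, 1)
  }
})

test_that("consensus building recovers the founder sequence", {
  expect_equal(build_consensus(rep("ACGTACGT", 5)), "ACGTACGT")
  ## explicit tie: two members differing at one column give an IUPAC code
  expect_equal(build_consensus(c("CCCACCC", "CCCGCCC")), "CCCRCCC")
  ## 50 members mutated at 2%: rebuilt consensus within 1 mismatch
  set.seed(8)
  founder <- random_dna(120, 0.5)
  members <- vapply(1:50, function(i) mutate_seq(founder, 0.02),
                    character(1))
  rebuilt <- build_consensus(members)
  expect_equal(nchar(rebuilt), nchar(founder))
  expect_lte(mitescope:::hamming(rebuilt, founder), 1L)
})
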