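# Shared fixtures, built once per test run and cached. All inputs are
# generated in code under fixed seeds; nothing is read from disk except the
# packaged family catalog.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Synthetic consensi for the three superfamily archetypes.
stowaway_consensus <- function() synthetic_consensus(158, tir_len = 12, seed = 7)
tourist_consensus <- function() synthetic_consensus(272, tir_len = 10, seed = 8)
mutator_consensus <- function() synthetic_consensus(345, tir_len = 9, seed = 9)

plant_df <- function(family, superfamily, consensus, copies, divergence,
                     tsd_pattern = NA_character_) {
  data.frame(family = family, superfamily = superfamily,
             consensus = consensus, copies = as.integer(copies),
             divergence = divergence, tsd_pattern = tsd_pattern,
             stringsAsFactors = FALSE)
}

# 100 undiverged Stowaway copies on one A chromosome: the workhorse genome
# for retrieval and TSD tests.
genome_100_stowaway <- function() {
  fixture("genome_100_stowaway", function() {
    fams <- plant_df("Sto1", "Stowaway", stowaway_consensus(), 100, 0)
    generate_genome(genome_spec(subgenomes = "A", n_chromosomes = 1,
                                chromosome_length = 12e4, families = fams,
                                n_genes = 0, n_te_hosts = 0, seed = 31))
  })
}

# 500 copies at 5% divergence: the retrieval performance genome.
genome_recall <- function() {
  fixture("genome_recall", function() {
    fams <- plant_df("Fam1", "Stowaway", stowaway_consensus(), 500, 0.05)
    generate_genome(genome_spec(subgenomes = "A", n_chromosomes = 2,
                                chromosome_length = 35e4, families = fams,
                                n_genes = 0, n_te_hosts = 0, seed = 101))
  })
}

# Tetraploid inheritance scenario: a 500-insertion A-genome parent and a
# small insertion-free B-genome parent.
parent_A_500 <- function() {
  fixture("parent_A_500", function() {
    fams <- plant_df("Fam1", "Stowaway", stowaway_consensus(), 500, 0)
    generate_genome(genome_spec(subgenomes = "A", n_chromosomes = 2,
                                chromosome_length = 35e4, families = fams,
                                n_genes = 0, n_te_hosts = 0, seed = 201))
  })
}

parent_B_empty <- function() {
  fixture("parent_B_empty", function() {
    fams <- plant_df("Fam1", "Stowaway", stowaway_consensus(), 0, 0)
    generate_genome(genome_spec(subgenomes = "B", n_chromosomes = 1,
                                chromosome_length = 3e4, families = fams,
                                n_genes = 0, n_te_hosts = 0, seed = 202))
  })
}

# Discovery scenario: a known catalog family plus a novel 60-bp,
# 11-bp-TIR, TA-TSD family absent from the catalog.
novel_consensus <- function() {
  fixture("novel_consensus", function() {
    ## pick a seed whose mismatch-free TIR is exactly 11 bp
    for (seed in 1:100) {
      cons <- synthetic_consensus(60, tir_len = 11, seed = seed)
      if (find_tir(cons, max_mismatch = 0)$tir_len == 11L) return(cons)
    }
    stop("no suitable consensus found")
  })
}

discovery_genome <- function() {
  fixture("discovery_genome", function() {
    fams <- rbind(
      plant_df("Known1", "Stowaway", stowaway_consensus(), 30, 0),
      plant_df("Novel1", "Stowaway", novel_consensus(), 50, 0))
    generate_genome(genome_spec(subgenomes = "A", n_chromosomes = 2,
                                chromosome_length = 5e4, families = fams,
                                n_genes = 2, n_te_hosts = 0, seed = 21))
  })
}

discovery_candidates <- function() {
  fixture("discovery_candidates", function() {
    g <- discovery_genome()
    known <- g$spec$families[g$spec$families$family == "Known1", ]
    discover_families(g, known, min_copies = 20)
  })
}

# Genomes of 200 undiverged copies per superfamily rule, for TSD recovery.
genome_tsd <- function(superfamily) {
  fixture(paste0("genome_tsd_", superfamily), function() {
    cons <- switch(superfamily,
                   Stowaway = stowaway_consensus(),
                   Tourist = tourist_consensus(),
                   Mutator = mutator_consensus())
    fams <- plant_df(paste0(superfamily, "1"), superfamily, cons, 200, 0)
    generate_genome(genome_spec(subgenomes = "A", n_chromosomes = 2,
                                chromosome_length = 15e4, families = fams,
                                n_genes = 0, n_te_hosts = 0,
                                seed = 90 + nchar(superfamily)))
  })
}

# Score retrieved records against a truth table by interval overlap.
truth_overlap <- function(records, truth) {
  rec_matched <- logical(nrow(records))
  truth_hit <- logical(nrow(truth))
  for (i in seq_len(nrow(records))) {
    j <- which(truth$chrom == records$chrom[i] &
                 truth$start <= records$end[i] &
                 truth$end >= records$start[i])
    if (length(j)) {
      rec_matched[i] <- TRUE
      truth_hit[j] <- TRUE
    }
  }
  list(recall = if (nrow(truth)) mean(truth_hit) else NA_real_,
       fp_rate = if (nrow(records)) mean(!rec_matched) else 0)
}
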