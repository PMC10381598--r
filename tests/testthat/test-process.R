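cfg <- pipeline_config()
rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

test_that("exact overlaps merge to the concatenation minus the overlap", {
  set.seed(41)
  left <- random_dna_string(60); ov <- random_dna_string(40); right <- random_dna_string(60)
  r1 <- paste0(left, ov)
  r2 <- rc(paste0(ov, right))
  m <- merge_pairs(r1, r2, min_overlap = 20, max_mismatch_rate = 0.1)
  expect_equal(unname(m$merged), paste0(left, ov, right))
  expect_equal(m$n_discarded, 0L)
})

test_that("overlaps below the minimum are discarded; mismatched overlaps resolve to r1", {
  set.seed(42)
  left <- random_dna_string(80); ov <- random_dna_string(10); right <- random_dna_string(80)
  m <- merge_pairs(paste0(left, ov), rc(paste0(ov, right)), 20, 0.1)
  expect_equal(m$n_discarded, 1L)
  expect_length(m$merged, 0L)
  # one mismatch in a 50-nt overlap (rate 0.02 <= 0.10): merged, r1 base wins
  ov50 <- random_dna_string(50)
  ov50_mut <- mutate_string(ov50, 1)
  left <- random_dna_string(70); right <- random_dna_string(70)
  m2 <- merge_pairs(paste0(left, ov50), rc(paste0(ov50_mut, right)), 20, 0.1)
  expect_equal(unname(m2$merged), paste0(left, ov50, right))
})

test_that("merge picks the score-optimal overlap among all enumerated candidates", {
  set.seed(43)
  for (rep in 1:20) {
    amp <- random_dna_string(sample(120:200, 1))
    L <- nchar(amp)
    rl <- sample(90:140, 1)
    r1 <- substr(amp, 1, min(rl, L))
    r2 <- rc(substr(amp, max(1, L - rl + 1), L))
    m <- merge_pairs(r1, r2, 20, 0.1)
    # brute-force enumeration of ungapped overlap layouts; NA = no candidate
    s2 <- rc(r2)
    best <- -Inf; best_merged <- NA_character_
    for (s in 0:(nchar(r1) - 20)) {
      ovl <- min(nchar(r1) - s, nchar(s2))
      if (ovl < 20) next
      mm <- sum(strsplit(substr(r1, s + 1, s + ovl), "")[[1]] !=
                strsplit(substr(s2, 1, ovl), "")[[1]])
      if (mm / ovl > 0.1) next
      score <- ovl - 2 * mm
      if (score > best) {
        best <- score
        best_merged <- paste0(substr(r1, 1, s + ovl),
                              if (ovl < nchar(s2)) substr(s2, ovl + 1, nchar(s2)) else "")
      }
    }
    if (is.na(best_merged)) {
      expect_equal(m$n_discarded, 1L)
    } else {
      expect_equal(unname(m$merged), best_merged)
    }
  }
})

test_that("primer trimming matches the protocol primers and discards failures", {
  core <- random_dna_string(250)
  amp <- paste0("GCATCGATGAAGAACGCAGC", core, rc("TCCTCCGCTTATTGATATGC"))
  t1 <- trim_primers(amp, cfg$primer_fwd, cfg$primer_rev, 0.1)
  expect_equal(unname(t1$trimmed), core)
  # sequence lacking the forward primer is discarded
  t2 <- trim_primers(paste0(random_dna_string(20), core), cfg$primer_fwd,
                     cfg$primer_rev, 0.1)
  expect_equal(t2$n_discarded, 1L)
  # one mismatch in a 20-nt primer (rate 0.05 <= 0.10) is tolerated
  amp_mut <- amp
  substr(amp_mut, 3, 3) <- if (substr(amp_mut, 3, 3) == "A") "C" else "A"
  t3 <- trim_primers(amp_mut, cfg$primer_fwd, cfg$primer_rev, 0.1)
  expect_equal(unname(t3$trimmed), core)
  # three mismatches (rate 0.15) is not
  amp_bad <- paste0("GCTTCGTTGAAGATCGCAGC", core, rc(cfg$primer_rev))
  expect_equal(trim_primers(amp_bad, cfg$primer_fwd, cfg$primer_rev, 0.1)$n_discarded, 1L)
})

test_that("swarm clustering handles the aggregation-distance-1 textbook cases", {
  # one step apart: one cluster, representative by count, abundance summed
  cl <- swarm_cluster(c(ACGT = 10, ACGA = 3), d = 1)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$representative, "ACGT")
  expect_equal(cl$abundance, 13L)
  # distance 2 with no intermediate: two clusters
  cl2 <- swarm_cluster(c(ACGT = 10, AGGA = 3), d = 1)
  expect_equal(nrow(cl2), 2L)
  # chain closure through an intermediate
  cl3 <- swarm_cluster(c(AAAA = 9, AAAT = 5, AATT = 2), d = 1)
  expect_equal(nrow(cl3), 1L)
  expect_equal(cl3$abundance, 16L)
  expect_equal(cl3$representative, "AAAA")
  # indels join too (Levenshtein, not Hamming)
  cl4 <- swarm_cluster(c(ACGTA = 6, ACGA = 2), d = 1)
  expect_equal(nrow(cl4), 1L)
  # empty input
  expect_equal(nrow(swarm_cluster(data.frame(sequence = character(0), count = integer(0)))), 0L)
  expect_error(swarm_cluster(data.frame(sequence = c("A", "A"), count = c(1, 1))),
               "dereplicated")
})

test_that("swarm partition equals brute-force connected components (random fixtures)", {
  set.seed(44)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    base <- random_dna_string(sample(18:30, 1))
    seqs <- unique(vapply(seq_len(n), function(i) {
      s <- mutate_string(base, sample(0:3, 1))
      if (runif(1) < 0.2) s <- substr(s, 2, nchar(s)) # occasional deletion
      s
    }, character(1)))
    counts <- sample(1:50, length(seqs), replace = TRUE)
    cl <- swarm_cluster(setNames(counts, seqs), d = 1)
    memb <- attr(cl, "membership")
    comp <- oracle_components(names(memb), 1)
    # identical partitions: same grouping of sequences
    expect_equal(length(unique(comp)), nrow(cl))
    expect_true(all(tapply(memb, comp, function(x) length(unique(x))) == 1))
  }
})

test_that("cluster partition is invariant to input order", {
  set.seed(45)
  base <- random_dna_string(25)
  seqs <- unique(vapply(1:30, function(i) mutate_string(base, sample(0:2, 1)), character(1)))
  counts <- sample(1:40, length(seqs), replace = TRUE)
  cl1 <- swarm_cluster(setNames(counts, seqs), d = 1)
  perm <- sample(length(seqs))
  cl2 <- swarm_cluster(setNames(counts[perm], seqs[perm]), d = 1)
  expect_identical(cl1[, c("otu_id", "representative", "abundance", "n_members")],
                   cl2[, c("otu_id", "representative", "abundance", "n_members")])
})

test_that("swarm honors larger aggregation distances via the exhaustive path", {
  cl <- swarm_cluster(c(ACGT = 10, AGGA = 3), d = 2)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$abundance, 13L)
})

test_that("constructed chimeras are flagged; identical sequences are not", {
  set.seed(46)
  a <- random_dna_string(200); b <- mutate_string(a, 30)
  chim <- paste0(substr(a, 1, 100), substr(b, 101, 200))
  cl <- data.frame(otu_id = c("O1", "O2", "O3"),
                   representative = c(a, b, chim),
                   abundance = c(100L, 100L, 5L), stringsAsFactors = FALSE)
  res <- remove_chimeras(cl, parent_identity = 0.99, parent_ratio = 2)
  expect_equal(res$flagged$otu_id, "O3")
  expect_setequal(res$kept$otu_id, c("O1", "O2"))
  # a low-abundance cluster identical to a parent is kept (full-length identity)
  cl2 <- data.frame(otu_id = c("O1", "O2", "O3"),
                    representative = c(a, b, a),
                    abundance = c(100L, 100L, 5L), stringsAsFactors = FALSE)
  res2 <- remove_chimeras(cl2, 0.99, 2)
  expect_equal(nrow(res2$flagged), 0L)
  # parents must carry at least ratio x abundance
  cl3 <- cl; cl3$abundance <- c(8L, 8L, 5L)
  expect_equal(nrow(remove_chimeras(cl3, 0.99, 2)$flagged), 0L)
})

test_that("the abundance filter applies the inclusive minimum proportion", {
  cl <- data.frame(otu_id = c("O1", "O2", "O3"),
                   representative = c("AAAA", "CCCC", "GGGG"),
                   abundance = c(999991L, 5L, 4L), stringsAsFactors = FALSE)
  kept <- filter_low_abundance(cl, 0.000005, total = 1e6)
  expect_setequal(kept$otu_id, c("O1", "O2")) # 5e-6 kept (boundary), 4e-6 dropped
  # all clusters above threshold: identity
  expect_identical(filter_low_abundance(cl, 1e-9, total = 1e6), cl)
  # zero total: empty output
  expect_equal(nrow(filter_low_abundance(cl[0, ], 0.000005)), 0L)
})

test_that("reads are conserved through merge and cluster stages", {
  p <- small_sim(rng_seed = 47, reads_per_site = 400)
  pool <- simulate_species_pool(p, cfg)
  comm <- simulate_communities(pool, p)
  rd <- simulate_paired_reads(comm[[2]], pool, p, cfg)
  m <- merge_pairs(rd$r1, rd$r2, cfg$merge_min_overlap, cfg$merge_max_mismatch_rate)
  expect_equal(length(m$merged) + m$n_discarded, length(rd$r1))
  t <- trim_primers(m$merged, cfg$primer_fwd, cfg$primer_rev, cfg$primer_max_mismatch_rate)
  derep <- dereplicate(unname(t$trimmed))
  cl <- swarm_cluster(derep, 1)
  expect_equal(sum(cl$abundance), length(t$trimmed))
})

test_that("a noiseless site yields one OTU per distinct source amplicon", {
  p <- small_sim(per_base_error = 0, chimera_rate = 0, reads_per_site = 300,
                 rng_seed = 48)
  pool <- simulate_species_pool(p, cfg)
  comm <- simulate_communities(pool, p)
  rd <- simulate_paired_reads(comm[[1]], pool, p, cfg)
  ps <- process_site(rd$r1, rd$r2, cfg, "site01")
  expect_equal(nrow(ps$clusters), length(unique(rd$truth$source_sh)))
  # and every read maps to the OTU of its own species
  by_otu <- split(rd$truth$source_sh, ps$read_otu[rd$truth$read_id])
  expect_true(all(vapply(by_otu, function(x) length(unique(x)) == 1L, logical(1))))
})
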