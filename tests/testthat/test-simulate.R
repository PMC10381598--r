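cfg <- pipeline_config()

test_that("species pool generation is byte-identical across runs of one seed", {
  p <- sim_params(n_families = 1, species_per_family = 2, rng_seed = 7,
                  n_sites = 1, species_per_site = 2, core_set_size = 1,
                  site_unique_fraction = 0)
  a <- simulate_species_pool(p, cfg)
  b <- simulate_species_pool(p, cfg)
  expect_identical(a$species, b$species)
  expect_identical(write_newick(a$trees[[1]]), write_newick(b$trees[[1]]))
})

test_that("every interspecific ITS2 pair respects the divergence floor (brute force)", {
  p <- sim_params(n_families = 3, species_per_family = 6, rng_seed = 3,
                  n_sites = 1, species_per_site = 6, core_set_size = 2,
                  site_unique_fraction = 0)
  pool <- simulate_species_pool(p, cfg)
  m <- do.call(rbind, strsplit(pool$species$core, ""))
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    if (pool$species$family[i] == pool$species$family[j]) {
      expect_gte(mean(m[i, ] != m[j, ]), p$interspecific_min_divergence)
    }
  }
})

test_that("primer sites are embedded unmutated in every species", {
  p <- sim_params(n_families = 2, species_per_family = 4, rng_seed = 5,
                  n_sites = 1, species_per_site = 4, core_set_size = 1,
                  site_unique_fraction = 0)
  pool <- simulate_species_pool(p, cfg)
  rc_rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cfg$primer_rev)))
  for (s in pool$species$true_sequence) {
    expect_true(grepl(cfg$primer_fwd, s, fixed = TRUE))
    expect_true(grepl(rc_rev, s, fixed = TRUE))
  }
})

test_that("single-species families are generated without a divergence constraint", {
  p <- sim_params(n_families = 2, species_per_family = 1, rng_seed = 2,
                  n_sites = 1, species_per_site = 2, core_set_size = 1,
                  site_unique_fraction = 0)
  pool <- simulate_species_pool(p, cfg)
  expect_equal(nrow(pool$species), 2L)
  expect_null(pool$trees[[1]])
})

test_that("library coverage bitmaps realize the requested fractions exactly", {
  p <- sim_params(n_families = 20, species_per_family = 10,
                  regional_coverage = 0.75, global_coverage = 0.30,
                  n_sites = 2, species_per_site = 20, core_set_size = 4,
                  site_unique_fraction = 0.1, rng_seed = 8)
  pool <- simulate_species_pool(p, cfg)
  libs <- build_libraries(pool, p)
  expect_equal(sum(libs$regional$coverage), round(0.75 * 200)) # exactly 150
  expect_equal(sum(libs$global$coverage), round(0.30 * 200))
  expect_equal(length(libs$regional$sh_index), 150L)
  # full coverage covers everyone; zero coverage errors
  p2 <- sim_params(n_families = 2, species_per_family = 3, regional_coverage = 1,
                   global_coverage = 0.01, n_sites = 1, species_per_site = 3,
                   core_set_size = 1, site_unique_fraction = 0, rng_seed = 1)
  pool2 <- simulate_species_pool(p2, cfg)
  expect_error(build_libraries(pool2, p2), "coverage")
  p2$global_coverage <- 1
  libs2 <- build_libraries(pool2, p2)
  expect_true(all(libs2$regional$coverage))
})

test_that("reference sequences stay within the intraspecific ceiling of the truth", {
  p <- sim_params(n_families = 2, species_per_family = 4, regional_coverage = 1,
                  refs_per_species = c(2, 3), n_sites = 1, species_per_site = 4,
                  core_set_size = 1, site_unique_fraction = 0, rng_seed = 21)
  pool <- simulate_species_pool(p, cfg)
  libs <- build_libraries(pool, p)
  for (i in seq_len(nrow(libs$regional$sequences))) {
    row <- libs$regional$sequences[i, ]
    truth <- pool$species$true_sequence[pool$species$sh_id == row$sh_id]
    d <- mean(strsplit(row$sequence, "")[[1]] != strsplit(truth, "")[[1]])
    # divergence measured over the full ITS dilutes the core-only mutations
    expect_lte(d * nchar(truth) / p$its2_length, p$intraspecific_max_divergence)
  }
})

test_that("communities contain the core set everywhere and honor size limits", {
  p <- sim_params(n_families = 10, species_per_family = 10, n_sites = 5,
                  species_per_site = 20, core_set_size = 8,
                  site_unique_fraction = 0.25, rng_seed = 13)
  pool <- simulate_species_pool(p, cfg)
  comm <- simulate_communities(pool, p)
  core <- comm[[1]]$core_set
  expect_length(core, 8L)
  shared_by_all <- Reduce(intersect, lapply(comm, function(cm) cm$species$sh_id))
  expect_true(all(core %in% shared_by_all))
  expect_true(all(vapply(comm, function(cm) nrow(cm$species), integer(1)) == 20L))
  expect_true(all(vapply(comm, function(cm) all(cm$species$weight > 0), logical(1))))
  # with site_unique_fraction = 0, every species is drawn from shared pools
  p0 <- sim_params(n_families = 4, species_per_family = 5, n_sites = 4,
                   species_per_site = 8, core_set_size = 3,
                   site_unique_fraction = 0, rng_seed = 14)
  pool0 <- simulate_species_pool(p0, cfg)
  comm0 <- simulate_communities(pool0, p0)
  tallies <- table(unlist(lapply(comm0, function(cm) cm$species$sh_id)))
  expect_gte(mean(tallies[comm0[[1]]$species$sh_id] >= 2), 0.5)
  # single-site community is trivially all-unique
  p1 <- sim_params(n_families = 2, species_per_family = 3, n_sites = 1,
                   species_per_site = 4, core_set_size = 2,
                   site_unique_fraction = 0.25, rng_seed = 15)
  comm1 <- simulate_communities(simulate_species_pool(p1, cfg), p1)
  expect_length(comm1, 1L)
  # inconsistent sizes error
  pbad <- sim_params(n_families = 2, species_per_family = 2, n_sites = 3,
                     species_per_site = 4, core_set_size = 2,
                     site_unique_fraction = 0.5, rng_seed = 1)
  expect_error(simulate_communities(simulate_species_pool(pbad, cfg), pbad),
               "inconsistent sizes")
})

test_that("noiseless reads reproduce their source amplicons exactly after merging", {
  p <- small_sim(per_base_error = 0, chimera_rate = 0, reads_per_site = 200,
                 rng_seed = 30)
  pool <- simulate_species_pool(p, cfg)
  comm <- simulate_communities(pool, p)
  rd <- simulate_paired_reads(comm[[1]], pool, p, cfg)
  merged <- merge_pairs(rd$r1, rd$r2, cfg$merge_min_overlap, cfg$merge_max_mismatch_rate)
  expect_equal(merged$n_discarded, 0L)
  amp_of <- setNames(paste0(cfg$primer_fwd, pool$species$core,
                            as.character(Biostrings::reverseComplement(
                              Biostrings::DNAString(cfg$primer_rev)))),
                     pool$species$sh_id)
  expect_identical(unname(merged$merged),
                   unname(amp_of[rd$truth$source_sh]))
})

test_that("chimera counts and abundance splits follow their binomial models", {
  p <- sim_params(n_families = 2, species_per_family = 5, n_sites = 1,
                  species_per_site = 10, core_set_size = 2,
                  site_unique_fraction = 0, chimera_rate = 0.05,
                  reads_per_site = 10000, rng_seed = 31)
  pool <- simulate_species_pool(p, cfg)
  comm <- simulate_communities(pool, p)
  rd <- simulate_paired_reads(comm[[1]], pool, p, cfg)
  ci <- qbinom(c(0.005, 0.995), 10000, 0.05) # binomial 99% interval around 500
  expect_gte(sum(rd$truth$is_chimera), ci[1])
  expect_lte(sum(rd$truth$is_chimera), ci[2])
  # two-species 9:1 abundance, noiseless: read shares match the weights
  p2 <- sim_params(n_families = 1, species_per_family = 2, n_sites = 1,
                   species_per_site = 2, core_set_size = 0, site_unique_fraction = 0,
                   per_base_error = 0, chimera_rate = 0, reads_per_site = 5000,
                   rng_seed = 32)
  pool2 <- simulate_species_pool(p2, cfg)
  comm2 <- simulate_communities(pool2, p2)
  comm2[[1]]$species$weight <- c(9, 1)
  rd2 <- simulate_paired_reads(comm2[[1]], pool2, p2, cfg)
  n_a <- sum(rd2$truth$source_sh == comm2[[1]]$species$sh_id[1])
  ci2 <- qbinom(c(0.005, 0.995), 5000, 0.9)
  expect_gte(n_a, ci2[1]); expect_lte(n_a, ci2[2])
})

test_that("divergence sandwich holds: intraspecific pairs < interspecific pairs", {
  p <- sim_params(n_families = 2, species_per_family = 5, regional_coverage = 1,
                  refs_per_species = c(3, 3), n_sites = 1, species_per_site = 5,
                  core_set_size = 1, site_unique_fraction = 0, rng_seed = 33)
  pool <- simulate_species_pool(p, cfg)
  libs <- build_libraries(pool, p)
  seqs <- libs$regional$sequences
  m <- do.call(rbind, strsplit(seqs$sequence, ""))
  fam <- pool$species$family[match(seqs$sh_id, pool$species$sh_id)]
  intra <- c(); inter <- c()
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    if (fam[i] != fam[j]) next
    d <- mean(m[i, ] != m[j, ])
    if (seqs$sh_id[i] == seqs$sh_id[j]) intra <- c(intra, d) else inter <- c(inter, d)
  }
  expect_lt(max(intra), min(inter))
})

test_that("with noiseless reads and perfect clustering, assignable fraction equals realized coverage", {
  p <- sim_params(n_families = 6, species_per_family = 6, regional_coverage = 0.6,
                  global_coverage = 0.6, n_sites = 1, species_per_site = 20,
                  core_set_size = 4, site_unique_fraction = 0,
                  per_base_error = 0, chimera_rate = 0, reads_per_site = 2000,
                  rng_seed = 34)
  pool <- simulate_species_pool(p, cfg)
  libs <- build_libraries(pool, p)
  comm <- simulate_communities(pool, p)
  rd <- simulate_paired_reads(comm[[1]], pool, p, cfg)
  ps <- process_site(rd$r1, rd$r2, cfg, "s1")
  seen <- unique(rd$truth$source_sh)
  asg <- assign_by_identity_threshold(ps$clusters, libs$regional, 98, cfg)
  identified <- unique(asg$assigned_sh[asg$success])
  realized <- names(libs$regional$coverage)[libs$regional$coverage]
  expect_setequal(identified, intersect(seen, realized))
  expect_equal(length(identified) / length(seen),
               length(intersect(seen, realized)) / length(seen))
})
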