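#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Builds a 200-species, 20-family pool with ITS2 divergence structure
# (interspecific floor 1.5%, intraspecific ceiling 0.5%), a regional
# library covering 75% of the pool and a global library covering 30%,
# five bulk-community sites (shared core of 8 species, ~25% site-unique
# species, log-normal abundances), and 5,000 error-bearing read pairs per
# site with 2% two-parent chimeras. The problem size is chosen to run on
# a desk machine in a few minutes; all knobs live in sim_params().

suppressPackageStartupMessages(library(lichid))

outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- pipeline_config(rng_seed = 20260927L)
sim <- sim_params(n_families = 20, species_per_family = 10,
                  regional_coverage = 0.75, global_coverage = 0.30,
                  n_sites = 5, species_per_site = 60, core_set_size = 8,
                  site_unique_fraction = 0.25, reads_per_site = 5000,
                  rng_seed = 20260927L)
write_pipeline_config(cfg, file.path(outdir, "config.yaml"))

pool <- simulate_species_pool(sim, cfg)
message("pool: ", nrow(pool$species), " species in ",
        length(unique(pool$species$family)), " families")

libs <- build_libraries(pool, sim)
for (nm in names(libs)) {
  write_reference_library(libs[[nm]], file.path(outdir, paste0(nm, ".fasta")),
                          file.path(outdir, paste0(nm, ".tsv")))
  message(nm, " library: ", nrow(libs[[nm]]$sequences), " sequences, ",
          sum(libs[[nm]]$coverage), " species covered")
}
write.table(data.frame(sh_id = names(libs$regional$coverage),
                       regional = unname(libs$regional$coverage),
                       global = unname(libs$global$coverage)),
            file.path(outdir, "coverage_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

communities <- simulate_communities(pool, sim)
for (cm in communities) {
  rd <- simulate_paired_reads(cm, pool, sim, cfg)
  write_fastq(rd$r1, file.path(outdir, paste0(cm$site_id, "_R1.fastq")))
  write_fastq(rd$r2, file.path(outdir, paste0(cm$site_id, "_R2.fastq")))
  lichid:::write_truth(rd$truth, file.path(outdir, paste0(cm$site_id, "_truth.tsv")))
  message(cm$site_id, " (", cm$region, "): ", nrow(cm$species), " species, ",
          length(rd$r1), " read pairs, ", sum(rd$truth$is_chimera), " chimeric")
}
sites <- data.frame(site_id = vapply(communities, `[[`, "", "site_id"),
                    region = vapply(communities, `[[`, "", "region"))
write.table(sites, file.path(outdir, "sites.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("done; inputs under ", outdir)
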