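# Programmatic fixtures: small libraries and read sets built in code.

tiny_library <- function(name = "fixture") {
  sequences <- data.frame(
    seq_id = c("s1", "s2", "s3"),
    sh_id = c("Lecanora garovaglii", "Lecanora garovaglii", "Rusavskia elegans"),
    sequence = c(strrep("ACGT", 60), mutate_string(strrep("ACGT", 60), 1),
                 random_dna_string(240)),
    region = "regional", stringsAsFactors = FALSE)
  sh <- data.frame(sh_id = unique(sequences$sh_id),
                   name = unique(sequences$sh_id),
                   kind = "formal",
                   family = c("Lecanoraceae", "Teloschistaceae"),
                   stringsAsFactors = FALSE)
  reference_library(sequences, sh, name = name)
}

write_tiny_library_files <- function(dir, lib = tiny_library()) {
  fa <- file.path(dir, "ref.fasta"); md <- file.path(dir, "ref.tsv")
  write_reference_library(lib, fa, md)
  list(fasta = fa, metadata = md)
}

# small simulation settings reused by several tests
small_sim <- function(reads_per_site = 600, ...) {
  sim_params(n_families = 4, species_per_family = 5, n_sites = 3,
             species_per_site = 10, core_set_size = 3,
             site_unique_fraction = 0.2, reads_per_site = reads_per_site, ...)
}

# family tree fixture from explicit newick + tip roles
ftree_fixture <- function(newick, ref_shs, queries = character(0)) {
  tree <- read_newick(newick)
  lichid:::new_family_tree("FamX", phangorn::midpoint(tree),
                           ref_tips = ref_shs, query_tips = queries)
}
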