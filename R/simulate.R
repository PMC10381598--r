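#' Simulation parameters
#'
#' Study conditions for the synthetic generator: a family-structured pool
#' of species with ITS-like sequences (conserved 5.8S-style left flank
#' ending in the forward-primer site, hypervariable ITS2 core, conserved
#' LSU-style right flank beginning with the reverse-primer site), two
#' reference libraries of contrasting coverage, multi-site communities
#' with a shared core and site-unique fractions, and error-bearing paired
#' ITS2 amplicons with two-parent chimeras.
#'
#' Divergence structure follows the usual ITS species-hypothesis geometry:
#' interspecific ITS2 divergence at least `interspecific_min_divergence`
#' (1.5%, the SH clustering radius used for fungal ITS), intraspecific
#' divergence below `intraspecific_max_divergence` (0.5%).
#'
#' @param n_families,species_per_family pool structure; the defaults give a
#'   pool of 600 species across 30 families, matching the scale of a
#'   regional lichen reference library.
#' @param birth_rate Yule pure-birth rate for the per-family trees.
#' @param family_depth expected root-to-tip substitutions/site on the ITS2
#'   core before any divergence-floor rescaling.
#' @param its2_length,flank_left,flank_right sequence geometry in nt; full
#'   ITS length is the sum of the three.
#' @param interspecific_min_divergence,intraspecific_max_divergence pairwise
#'   p-distance floor between species and ceiling within species over the
#'   ITS2 core.
#' @param refs_per_species integer range (length 2) of reference sequences
#'   per covered species.
#' @param regional_coverage,global_coverage fraction of pool species
#'   represented in the regional and global libraries.
#' @param n_sites,species_per_site,core_set_size,site_unique_fraction
#'   community structure: number of bulk-sample sites, site richness, size
#'   of the core species set shared by every site, and the expected
#'   fraction of a site's species found nowhere else.
#' @param region_map integer vector (length `n_sites`) mapping sites to
#'   regions for overlap summaries; `NULL` groups the sites into five
#'   regions in the default layout.
#' @param reads_per_site,read_length sequencing depth and read length
#'   (2 x 300 MiSeq-style).
#' @param abundance_lognormal_sigma log-normal sigma of species abundances.
#' @param per_base_error per-base substitution error rate on reads.
#' @param chimera_rate probability a read pair is a two-parent chimera.
#' @param rng_seed master seed; all generator functions derive their
#'   streams from it, so identical params imply byte-identical outputs.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_families = 30L, species_per_family = 20L,
                       birth_rate = 1, family_depth = 0.05,
                       its2_length = 250L, flank_left = 120L, flank_right = 130L,
                       interspecific_min_divergence = 0.015,
                       intraspecific_max_divergence = 0.005,
                       refs_per_species = c(1L, 4L),
                       regional_coverage = 0.75, global_coverage = 0.30,
                       n_sites = 11L, species_per_site = 90L,
                       core_set_size = 8L, site_unique_fraction = 0.25,
                       region_map = NULL,
                       reads_per_site = 50000L, read_length = 300L,
                       abundance_lognormal_sigma = 1.5,
                       per_base_error = 0.001, chimera_rate = 0.02,
                       rng_seed = 1L) {
  p <- list(n_families = as.integer(n_families),
            species_per_family = as.integer(species_per_family),
            birth_rate = birth_rate, family_depth = family_depth,
            its2_length = as.integer(its2_length),
            flank_left = as.integer(flank_left), flank_right = as.integer(flank_right),
            interspecific_min_divergence = interspecific_min_divergence,
            intraspecific_max_divergence = intraspecific_max_divergence,
            refs_per_species = as.integer(refs_per_species),
            regional_coverage = regional_coverage, global_coverage = global_coverage,
            n_sites = as.integer(n_sites), species_per_site = as.integer(species_per_site),
            core_set_size = as.integer(core_set_size),
            site_unique_fraction = site_unique_fraction,
            region_map = region_map,
            reads_per_site = as.integer(reads_per_site),
            read_length = as.integer(read_length),
            abundance_lognormal_sigma = abundance_lognormal_sigma,
            per_base_error = per_base_error, chimera_rate = chimera_rate,
            rng_seed = as.integer(rng_seed))
  stopifnot(p$n_families >= 1L, p$species_per_family >= 1L,
            length(p$refs_per_species) == 2L,
            p$refs_per_species[1] >= 1L,
            p$refs_per_species[1] <= p$refs_per_species[2])
  if (!(p$regional_coverage > 0 && p$regional_coverage <= 1) ||
      !(p$global_coverage >= 0 && p$global_coverage <= 1))
    stop("coverage fractions must lie in (0, 1]")
  if (p$interspecific_min_divergence <= p$intraspecific_max_divergence)
    stop("divergence bounds must be ordered: intraspecific max < interspecific min")
  for (r in c(p$site_unique_fraction, p$per_base_error, p$chimera_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (is.null(p$region_map)) p$region_map <- default_region_map(p$n_sites)
  if (length(p$region_map) != p$n_sites) stop("region_map must have one entry per site")
  class(p) <- "sim_params"
  p
}

# five-region layout echoing a multi-ecoregion sampling design: one large
# region of several sites, one urban site, two two-site regions, one alpine
# site; degenerates gracefully for few sites
default_region_map <- function(n_sites) {
  if (n_sites <= 5L) return(seq_len(n_sites))
  extra <- n_sites - 5L
  c(rep(1L, 1L + extra), 2L, 3L, 3L, 4L, 4L, 5L)[seq_len(n_sites)]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

mutate_positions <- function(seq, n_sub) {
  if (n_sub == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(ch), n_sub)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# lengthen terminal branches of tips whose patristic distance falls below
# d_target, by half the deficit on each side; leaves the rest of the tree
# untouched so family structure stays realistic
stretch_close_tips <- function(tr, d_target) {
  n_tip <- length(tr$tip.label)
  ph <- ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label]
  deficit <- vapply(seq_len(n_tip), function(i) {
    d <- ph[i, -i]
    max(0, (d_target - min(d)) / 2)
  }, numeric(1))
  term <- match(seq_len(n_tip), tr$edge[, 2])
  tr$edge.length[term] <- tr$edge.length[term] + deficit
  tr
}

# pairwise p-distance matrix over equal-length sequences
p_distance_matrix <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) return(matrix(0, n, n))
  m <- do.call(rbind, strsplit(seqs, ""))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- mean(m[i, ] != m[j, ])
  d
}

#' Simulate the species pool
#'
#' Draws a Yule pure-birth tree per family and evolves the ITS2 core along
#' it under Jukes-Cantor; branch lengths are rescaled (geometrically, with
#' re-simulation) until every interspecific pairwise p-distance over the
#' core reaches `interspecific_min_divergence + 2 * intraspecific_max_divergence`,
#' which guarantees the divergence sandwich (intraspecific < interspecific)
#' even after reference sequences are mutated away from the ancestral
#' sequence. Primer sites sit in the conserved flanks and are never
#' mutated. Fully reproducible from `rng_seed`.
#'
#' @param params a [sim_params()].
#' @param config a [pipeline_config()]; supplies the primer sequences
#'   embedded in the flanks.
#' @return object of class `species_pool`: a species table (`sh_id`,
#'   `name`, `kind`, `family`, `core`, `true_sequence`), the per-family
#'   trees, and the shared flanks.
#' @export
simulate_species_pool <- function(params, config = pipeline_config()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$rng_seed)
  pf <- config$primer_fwd
  pr_rc <- revcomp(config$primer_rev)
  if (params$flank_left < nchar(pf) || params$flank_right < nchar(pr_rc))
    stop("flanks must be at least as long as the primers")
  flank_left <- paste0(random_dna(params$flank_left - nchar(pf)), pf)
  flank_right <- paste0(pr_rc, random_dna(params$flank_right - nchar(pr_rc)))
  floor_div <- params$interspecific_min_divergence +
    2 * params$intraspecific_max_divergence
  fam_names <- sprintf("Family_%02d", seq_len(params$n_families))
  n_prov_fam <- min(2L, max(0L, params$n_families - 3L))
  if (n_prov_fam > 0L)
    fam_names[params$n_families - seq_len(n_prov_fam) + 1L] <-
      sprintf("Incertae_sedis_%d", seq_len(n_prov_fam))
  species <- list(); trees <- list()
  idx <- 0L
  for (f in seq_len(params$n_families)) {
    nsp <- params$species_per_family
    if (nsp == 1L) {
      cores <- random_dna(params$its2_length)
      tr <- NULL
    } else {
      tr <- ape::rphylo(nsp, birth = params$birth_rate, death = 0)
      depth <- max(ape::node.depth.edgelength(tr)[seq_len(nsp)])
      tr$edge.length <- tr$edge.length / depth * params$family_depth
      # JC-corrected branch-length target for the realized p-distance floor
      p_target <- min(floor_div * 1.3, 0.74)
      d_target <- -0.75 * log(1 - 4 / 3 * p_target)
      ok <- FALSE
      for (attempt in seq_len(15L)) {
        tr <- stretch_close_tips(tr, d_target)
        sim <- phangorn::simSeq(tr, l = params$its2_length, type = "DNA", rate = 1)
        cores <- apply(toupper(as.character(sim)), 1L, paste, collapse = "")
        cores <- cores[tr$tip.label]
        if (min(p_distance_matrix(cores)[upper.tri(diag(nsp))]) >= floor_div) {
          ok <- TRUE; break
        }
        d_target <- d_target * 1.25
      }
      if (!ok) stop("could not reach the interspecific divergence floor in family ", fam_names[f])
    }
    ids <- sprintf("SH_%04d", idx + seq_len(nsp))
    kinds <- sample(c("formal", "aff", "agg", "cf", "provisional"), nsp,
                    replace = TRUE, prob = c(0.70, 0.10, 0.05, 0.05, 0.10))
    genus <- sprintf("Genus%02d", f)
    epithet <- sprintf("species%d", seq_len(nsp))
    nm <- ifelse(kinds == "formal", paste(genus, epithet),
          ifelse(kinds == "aff", paste(genus, "aff.", epithet),
          ifelse(kinds == "agg", paste(genus, "agg.", epithet),
          ifelse(kinds == "cf", paste(genus, "cf.", epithet),
                 paste(fam_names[f], "sp.", seq_len(nsp))))))
    if (!is.null(tr)) tr$tip.label <- ids
    trees[fam_names[f]] <- list(tr) # keep NULL entries for single-tip families
    species[[f]] <- data.frame(sh_id = ids, name = nm, kind = kinds,
                               family = fam_names[f], core = unname(cores),
                               stringsAsFactors = FALSE)
    idx <- idx + nsp
  }
  species <- do.call(rbind, species)
  species$true_sequence <- paste0(flank_left, species$core, flank_right)
  rownames(species) <- NULL
  pool <- list(species = species, trees = trees,
               flank_left = flank_left, flank_right = flank_right,
               params = params)
  class(pool) <- "species_pool"
  pool
}

#' @export
print.species_pool <- function(x, ...) {
  cat(sprintf("<species_pool>: %d species in %d families, ITS %d nt (ITS2 core %d nt)\n",
              nrow(x$species), length(unique(x$species$family)),
              nchar(x$species$true_sequence[1]), x$params$its2_length))
  invisible(x)
}

#' Build regional and global reference libraries from a pool
#'
#' Samples the species covered by each library independently
#' (`regional_coverage` resp. `global_coverage` of the pool, rounded), then
#' draws `refs_per_species` full-length ITS reference sequences per covered
#' species, each mutated from the ancestral sequence at no more than
#' `intraspecific_max_divergence` of ITS2 core positions (flanks and primer
#' sites untouched). The realized coverage bitmap is attached to each
#' library as `$coverage` for parameter-recovery checks.
#'
#' @param pool a [simulate_species_pool()] result.
#' @param params the [sim_params()] used for the pool.
#' @return list with elements `regional` and `global`, both
#'   [reference_library()] objects.
#' @export
build_libraries <- function(pool, params = pool$params) {
  stopifnot(inherits(pool, "species_pool"))
  set.seed(params$rng_seed + 1L)
  out <- list()
  for (libname in c("regional", "global")) {
    cov <- if (libname == "regional") params$regional_coverage else params$global_coverage
    n_cov <- round(cov * nrow(pool$species))
    if (n_cov < 1L) stop("coverage x pool size < 1 species for the ", libname, " library")
    covered_idx <- sort(sample.int(nrow(pool$species), n_cov))
    max_sub <- floor(params$intraspecific_max_divergence * params$its2_length)
    rows <- vector("list", n_cov)
    for (k in seq_len(n_cov)) {
      sp <- pool$species[covered_idx[k], ]
      nref_range <- seq(params$refs_per_species[1], params$refs_per_species[2])
      nref <- nref_range[sample.int(length(nref_range), 1L)]
      cores <- vapply(seq_len(nref), function(j)
        mutate_positions(sp$core, sample.int(max_sub + 1L, 1L) - 1L), character(1))
      rows[[k]] <- data.frame(
        seq_id = sprintf("%s_%s_%d", toupper(substr(libname, 1, 1)), sp$sh_id, seq_len(nref)),
        sh_id = sp$sh_id,
        sequence = paste0(pool$flank_left, cores, pool$flank_right),
        region = libname, stringsAsFactors = FALSE)
    }
    sequences <- do.call(rbind, rows)
    sh <- pool$species[covered_idx, c("sh_id", "name", "kind", "family")]
    lib <- reference_library(sequences, sh, name = libname)
    lib$coverage <- setNames(seq_len(nrow(pool$species)) %in% covered_idx,
                             pool$species$sh_id)
    out[[libname]] <- lib
  }
  out
}

#' Simulate multi-site communities
#'
#' Every site contains the shared core set; each site additionally draws
#' `site_unique_fraction * species_per_site` species reserved exclusively
#' for it and fills the remainder from a common shared pool. Abundance
#' weights are log-normal(0, `abundance_lognormal_sigma`).
#'
#' @param pool a [simulate_species_pool()] result.
#' @param params the [sim_params()] used.
#' @return list of community specs, each with `site_id`, `site_index`,
#'   `region`, and a `species` data.frame (`sh_id`, `weight`).
#' @export
simulate_communities <- function(pool, params = pool$params) {
  stopifnot(inherits(pool, "species_pool"))
  n_pool <- nrow(pool$species)
  if (params$core_set_size > n_pool) stop("core_set_size exceeds the pool")
  set.seed(params$rng_seed + 2L)
  n_unique <- round(params$site_unique_fraction * params$species_per_site)
  n_shared <- params$species_per_site - params$core_set_size - n_unique
  if (n_shared < 0L)
    stop("inconsistent sizes: core_set_size + unique species exceed species_per_site")
  all_ids <- pool$species$sh_id
  core <- sample(all_ids, params$core_set_size)
  remainder <- setdiff(all_ids, core)
  need_unique <- params$n_sites * n_unique
  if (need_unique > length(remainder))
    stop("inconsistent sizes: pool too small to reserve site-unique species")
  unique_reserve <- sample(remainder, need_unique)
  shared_pool <- setdiff(remainder, unique_reserve)
  if (n_shared > length(shared_pool))
    stop("inconsistent sizes: shared pool smaller than the per-site shared draw")
  communities <- vector("list", params$n_sites)
  for (s in seq_len(params$n_sites)) {
    uniq <- if (n_unique > 0L)
      unique_reserve[((s - 1L) * n_unique + 1L):(s * n_unique)] else character(0)
    shared <- if (n_shared > 0L) sample(shared_pool, n_shared) else character(0)
    ids <- c(core, uniq, shared)
    communities[[s]] <- list(
      site_id = sprintf("site%02d", s), site_index = s,
      region = sprintf("region%d", params$region_map[s]),
      core_set = core,
      species = data.frame(sh_id = ids,
                           weight = rlnorm(length(ids), 0, params$abundance_lognormal_sigma),
                           stringsAsFactors = FALSE))
  }
  communities
}

#' Simulate paired ITS2 amplicon reads for one community
#'
#' Reads are drawn per species proportional to abundance. Each amplicon is
#' forward primer + ITS2 core + reverse-complemented reverse primer; the
#' forward read starts at the forward primer and the reverse read at the
#' reverse primer, overlapping across the core. Per-base substitution
#' errors are applied to both reads independently; with probability
#' `chimera_rate` a pair derives from a two-parent chimera with a single
#' breakpoint uniform in the core. Truth labels accompany the reads.
#'
#' @param community one element of [simulate_communities()].
#' @param pool the [simulate_species_pool()] result.
#' @param params the [sim_params()] used.
#' @param config a [pipeline_config()] for the primers.
#' @param n_reads number of read pairs (defaults to `params$reads_per_site`).
#' @return list with named character vectors `r1` and `r2` and a `truth`
#'   data.frame (`read_id`, `source_sh`, `source_sh2`, `is_chimera`).
#' @export
simulate_paired_reads <- function(community, pool, params = pool$params,
                                  config = pipeline_config(),
                                  n_reads = params$reads_per_site) {
  stopifnot(inherits(pool, "species_pool"))
  set.seed(params$rng_seed + 1000L + community$site_index)
  pf <- config$primer_fwd; prc <- revcomp(config$primer_rev)
  plen <- nchar(pf); rlen <- nchar(prc)
  amp_len <- plen + params$its2_length + rlen
  if (amp_len > 2L * params$read_length - config$merge_min_overlap)
    stop("amplicon too long for the read length and minimum overlap")
  sp <- community$species
  amplicons <- setNames(
    paste0(pf, pool$species$core[match(sp$sh_id, pool$species$sh_id)], prc),
    sp$sh_id)
  src <- sample(sp$sh_id, n_reads, replace = TRUE, prob = sp$weight)
  is_chim <- runif(n_reads) < params$chimera_rate
  src2 <- rep(NA_character_, n_reads)
  amp <- unname(amplicons[src])
  if (any(is_chim) && nrow(sp) >= 2L) {
    ci <- which(is_chim)
    for (i in ci) {
      other <- sample(sp$sh_id, 1L, prob = sp$weight)
      while (other == src[i]) other <- sample(sp$sh_id, 1L, prob = sp$weight)
      src2[i] <- other
      k <- sample.int(params$its2_length - 1L, 1L) # breakpoint within the core
      amp[i] <- paste0(substr(amplicons[src[i]], 1L, plen + k),
                       substr(amplicons[other], plen + k + 1L, amp_len))
    }
  } else {
    is_chim[] <- FALSE
  }
  rl <- params$read_length
  r1 <- substr(amp, 1L, pmin(rl, nchar(amp)))
  r2 <- revcomp(substr(amp, pmax(1L, nchar(amp) - rl + 1L), nchar(amp)))
  r1 <- add_read_errors(r1, params$per_base_error)
  r2 <- add_read_errors(r2, params$per_base_error)
  ids <- sprintf("%s_%06d", community$site_id, seq_len(n_reads))
  names(r1) <- names(r2) <- ids
  truth <- data.frame(read_id = ids, source_sh = src, source_sh2 = src2,
                      is_chimera = is_chim, stringsAsFactors = FALSE)
  list(r1 = r1, r2 = r2, truth = truth)
}

add_read_errors <- function(reads, p) {
  if (p <= 0) return(reads)
  n_err <- rbinom(length(reads), nchar(reads), p)
  hit <- which(n_err > 0L)
  for (i in hit) reads[i] <- mutate_positions(reads[i], n_err[i])
  reads
}
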