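#' Run the full identification-benchmark pipeline
#'
#' Executes the stages in protocol order: simulate (or load) paired reads
#' per site, merge, primer-trim, cluster (swarm d = 1), remove chimeras,
#' drop low-abundance OTUs, place OTUs in families and on family trees,
#' assign them to SHs by monophyly against the regional library and by
#' percent identity against the global library at each configured
#' threshold, collapse OTUs into SHs, and compute the success tables,
#' ANOVA/Tukey comparisons, and regional overlap summary. Identical
#' parameters and seed give identical results and manifests.
#'
#' The benchmark mirrors the field design: the regional (high-coverage)
#' library is assessed with the phylogenetic monophyly criterion, the
#' global (low-coverage) library with the BLAST-style threshold criterion,
#' and all databases are scored against the same collapsed SH inventory.
#'
#' @param sim a [sim_params()] (synthetic mode).
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, all stage outputs (FASTQ,
#'   truth sidecars, OTU FASTA, assignment and inventory TSVs, stats JSON,
#'   manifest JSON) are written under it with fixed names.
#' @param mode `"synthetic"` or `"real"`.
#' @param real for real mode: list with `sites` (data.frame `site_id`,
#'   `r1`, `r2`, `region`), `regional` and `global`
#'   ([reference_library()] objects or `c(fasta, metadata)` paths).
#' @param external_trees optional directory of per-family Newick files
#'   (`<family>.nwk`) from external ML runs, used instead of the built-in
#'   NJ path.
#' @return object of class `pipeline_run`: libraries, clusters,
#'   assignments, `inventory` (long format), success tables, comparisons,
#'   overlap summary, and `manifest`.
#' @export
run_pipeline <- function(sim = sim_params(), config = pipeline_config(),
                         outdir = NULL, mode = c("synthetic", "real"),
                         real = NULL, external_trees = NULL) {
  mode <- match.arg(mode)
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(path) { written <<- c(written, path); path }

  # --- stage 1: reads per site -------------------------------------------
  if (mode == "synthetic") {
    pool <- simulate_species_pool(sim, config)
    libs <- build_libraries(pool, sim)
    communities <- simulate_communities(pool, sim)
    sites <- lapply(communities, function(cm) {
      rd <- simulate_paired_reads(cm, pool, sim, config)
      if (!is.null(outdir)) {
        write_fastq(rd$r1, emit(file.path(outdir, paste0(cm$site_id, "_R1.fastq"))))
        write_fastq(rd$r2, emit(file.path(outdir, paste0(cm$site_id, "_R2.fastq"))))
        write_truth(rd$truth, emit(file.path(outdir, paste0(cm$site_id, "_truth.tsv"))))
      }
      list(site_id = cm$site_id, region = cm$region, r1 = rd$r1, r2 = rd$r2,
           truth = rd$truth)
    })
  } else {
    if (is.null(real)) stop("real mode needs the 'real' input description")
    for (p in c(real$sites$r1, real$sites$r2))
      if (!file.exists(p)) stop("missing FASTQ: ", p)
    as_lib <- function(x, nm) if (inherits(x, "reference_library")) x
      else load_reference_library(x[1], x[2], name = nm)
    libs <- list(regional = as_lib(real$regional, "regional"),
                 global = as_lib(real$global, "global"))
    pool <- NULL
    sites <- lapply(seq_len(nrow(real$sites)), function(i) {
      list(site_id = real$sites$site_id[i],
           region = if ("region" %in% names(real$sites)) real$sites$region[i]
                    else real$sites$site_id[i],
           r1 = read_fastq(real$sites$r1[i]), r2 = read_fastq(real$sites$r2[i]),
           truth = NULL)
    })
  }

  # --- stage 2: per-site processing to OTUs ------------------------------
  processed <- lapply(sites, function(s)
    process_site(s$r1, s$r2, config, site_id = s$site_id))
  names(processed) <- vapply(sites, `[[`, "", "site_id")
  clusters <- do.call(rbind, lapply(names(processed), function(sid) {
    cl <- processed[[sid]]$clusters
    if (nrow(cl) > 0L) cl$otu_id <- paste(sid, cl$otu_id, sep = ":")
    cl
  }))
  if (is.null(clusters) || nrow(clusters) == 0L) stop("no OTUs survived processing")
  otu_seqs <- setNames(clusters$representative, clusters$otu_id)
  otu_site <- setNames(clusters$site_id, clusters$otu_id)
  site_region <- setNames(vapply(sites, `[[`, "", "region"),
                          vapply(sites, `[[`, "", "site_id"))
  if (!is.null(outdir)) write_otu_fasta(clusters, emit(file.path(outdir, "otus.fasta")))

  # --- stage 3: assignment -----------------------------------------------
  scan_regional <- identity_scan(clusters, trim_library_to_amplicon(libs$regional, config), config)
  scan_global <- identity_scan(clusters, trim_library_to_amplicon(libs$global, config), config)
  global_assign <- lapply(config$identity_thresholds, function(th) {
    ok <- !scan_global$ambiguous & scan_global$best_identity > th &
      scan_global$coverage >= config$min_query_coverage
    data.frame(otu_id = clusters$otu_id, method = "identity_threshold",
               assigned_sh = ifelse(ok, scan_global$best_sh, NA_character_),
               score = scan_global$best_identity, success = ok,
               threshold_used = th, stringsAsFactors = FALSE)
  })
  names(global_assign) <- paste0("global_", config$identity_thresholds)

  families <- sort(unique(scan_regional$best_family))
  trees <- list(); mono_assign <- list()
  for (fam in families) {
    q <- otu_seqs[scan_regional$otu_id[scan_regional$best_family == fam]]
    ext <- NULL
    if (!is.null(external_trees)) {
      cand <- file.path(external_trees, paste0(fam, ".nwk"))
      if (file.exists(cand)) ext <- cand
    }
    ft <- build_family_tree(fam, q, libs$regional, external_tree = ext,
                            config = config)
    trees[[fam]] <- ft
    mono_assign[[fam]] <- assign_by_monophyly(ft)
  }
  mono <- do.call(rbind, mono_assign)
  rownames(mono) <- NULL

  # --- stage 4: collapse OTUs into SHs -----------------------------------
  entries <- collapse_to_species_hypotheses(mono, trees, otu_seqs,
                                            config$conspecific_identity, config)
  succ_of <- function(asg) { # entry identified iff any member OTU succeeded
    ok_otus <- asg$otu_id[asg$success]
    vapply(entries$members, function(m) any(m %in% ok_otus), logical(1))
  }
  db_flags <- c(list(regional = entries$identified),
                lapply(global_assign, succ_of))
  inventory <- do.call(rbind, lapply(names(db_flags), function(db) {
    do.call(rbind, lapply(seq_len(nrow(entries)), function(i) {
      sts <- unique(unname(otu_site[entries$members[[i]]]))
      data.frame(entry_id = entries$entry_id[i], family = entries$family[i],
                 site = sts, database = db, identified = db_flags[[db]][i],
                 stringsAsFactors = FALSE)
    }))
  }))

  # --- stage 5: statistics ------------------------------------------------
  site_table <- compute_success_rates(inventory, "site")
  family_table <- compute_success_rates(inventory, "family")
  total_table <- compute_success_rates(inventory, "total")
  fam_split <- exclude_small_families(family_table, config$family_min_sh)
  site_cmp <- tryCatch(compare_databases(site_table, config$alpha),
                       error = function(e) NULL)
  family_cmp <- tryCatch(compare_databases(fam_split$kept, config$alpha),
                         error = function(e) NULL)
  region_sets <- lapply(split(names(site_region), unname(site_region)), function(ss) {
    unique(inventory$entry_id[inventory$site %in% ss])
  })
  overlap <- if (length(region_sets) >= 2L) overlap_summary(region_sets) else NULL

  # --- manifest -----------------------------------------------------------
  stage_counts <- do.call(rbind, lapply(names(processed), function(sid)
    data.frame(site = sid, t(processed[[sid]]$counts))))
  manifest <- list(
    mode = mode, seed = sim$rng_seed,
    config = unclass(config),
    sim_params = if (mode == "synthetic") unclass(sim) else NULL,
    stage_counts = stage_counts,
    n_otus = nrow(clusters), n_sh = nrow(entries),
    sh_per_site = tapply(inventory$entry_id[inventory$database == "regional"],
                         inventory$site[inventory$database == "regional"],
                         function(x) length(unique(x))),
    assigned = c(regional_monophyly = sum(mono$success),
                 vapply(global_assign, function(a) sum(a$success), numeric(1))),
    total_success = setNames(total_table$pct_identified, total_table$database))
  if (!is.null(outdir)) {
    for (db in names(global_assign))
      write.table(global_assign[[db]],
                  emit(file.path(outdir, paste0("assignments_", db, ".tsv"))),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(mono, emit(file.path(outdir, "assignments_regional_monophyly.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(inventory, emit(file.path(outdir, "sh_inventory.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in c("site_table", "family_table", "total_table"))
      write.table(get(nm), emit(file.path(outdir, paste0(nm, ".tsv"))),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$file_hashes <- setNames(unname(tools::md5sum(written)), basename(written))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  }
  res <- list(libraries = libs, pool = pool, clusters = clusters,
              processed = processed, trees = trees,
              assignments = c(list(regional_monophyly = mono), global_assign),
              entries = entries, inventory = inventory,
              site_table = site_table, family_table = family_table,
              total_table = total_table, family_excluded = fam_split$excluded,
              site_comparison = site_cmp, family_comparison = family_cmp,
              overlap = overlap, manifest = manifest,
              truths = lapply(sites, `[[`, "truth"))
  class(res) <- "pipeline_run"
  res
}

#' Human-readable run report
#'
#' Summarises a pipeline run the way the benchmark is reported: totals,
#' SH counts, per-database success at total/site/family level, the
#' ANOVA/Tukey comparison, and the regional overlap.
#'
#' @param run a [run_pipeline()] result.
#' @param file optional path to also write the report to.
#' @return the report lines, invisibly.
#' @export
report <- function(run, file = NULL) {
  stopifnot(inherits(run, "pipeline_run"))
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("== Identification benchmark report ==")
  add("Total OTUs: %d   Total SHs after collapsing: %d",
      run$manifest$n_otus, run$manifest$n_sh)
  if (run$manifest$n_sh == 0L) {
    add("0 SHs in the inventory; statistics skipped (nothing to compare).")
  } else {
    for (i in seq_len(nrow(run$total_table)))
      add("Total success [%s]: %d / %d SHs (%.1f%%)",
          run$total_table$database[i], run$total_table$n_identified[i],
          run$total_table$n_total_sh[i], run$total_table$pct_identified[i])
    for (i in seq_len(nrow(run$site_table)))
      add("Site %s [%s]: %.1f%% (%d / %d)", run$site_table$grouping_key[i],
          run$site_table$database[i], run$site_table$pct_identified[i],
          run$site_table$n_identified[i], run$site_table$n_total_sh[i])
    if (nrow(run$family_excluded) > 0L)
      add("Families excluded from testing (< %d SHs): %s",
          run$manifest$config$family_min_sh,
          paste(unique(run$family_excluded$grouping_key), collapse = ", "))
    if (!is.null(run$site_comparison)) {
      add("-- Site-level comparison --")
      ln <- c(ln, utils::capture.output(print(run$site_comparison)))
    }
    if (!is.null(run$family_comparison)) {
      add("-- Family-level comparison --")
      ln <- c(ln, utils::capture.output(print(run$family_comparison)))
    }
    if (!is.null(run$overlap))
      ln <- c(ln, utils::capture.output(print(run$overlap)))
  }
  if (!is.null(file)) writeLines(ln, file)
  cat(ln, sep = "\n")
  invisible(ln)
}
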