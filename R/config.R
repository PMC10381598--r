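#' Pipeline configuration
#'
#' Collects every numeric knob of the processing and assignment pipeline in
#' one validated object. Defaults follow the source protocol where one is
#' stated (aggregation distance 1, minimum OTU proportion 5e-6, identity
#' thresholds 98 and 98.5, family exclusion below 5 SHs, ITS3F/ITS4R
#' primers) and conventional amplicon settings otherwise.
#'
#' @param aggregation_distance integer edit distance for swarm-style
#'   clustering; members join a cluster through chains of at most this many
#'   edits per step.
#' @param min_otu_proportion minimum abundance proportion (per site) for an
#'   OTU to be kept; the boundary is inclusive.
#' @param identity_thresholds percent identity thresholds tested for the
#'   BLAST-style classifier; success requires identity strictly above the
#'   threshold.
#' @param family_min_sh families with fewer than this many SHs are excluded
#'   from statistical testing (they still count toward totals).
#' @param alpha significance level for the normality gate and ANOVA.
#' @param primer_fwd,primer_rev amplification primers (forward primer and
#'   reverse primer, both written 5'-3').
#' @param merge_min_overlap minimum read overlap accepted when merging pairs.
#' @param merge_max_mismatch_rate maximum mismatch fraction in the overlap.
#' @param primer_max_mismatch_rate maximum IUPAC-aware mismatch fraction
#'   tolerated when matching/trimming primers.
#' @param chimera_parent_identity segment identity required of each chimera
#'   parent, and the full-length identity below which a candidate cannot be
#'   explained by a single parent.
#' @param chimera_parent_ratio abundance multiple a parent must have over
#'   the candidate chimera.
#' @param conspecific_identity percent identity (as a fraction) at or above
#'   which unassigned OTUs in a query-only clade collapse into one
#'   provisional SH; the default 0.99 matches twice the simulator's
#'   intraspecific divergence ceiling (two conspecific variants can sit
#'   up to 1% apart).
#' @param min_query_coverage minimum fraction of the query covered by the
#'   best-scoring alignment for an identity-threshold assignment to count
#'   (the BLAST-style query-coverage gate that keeps short spurious
#'   overlaps from passing as species-level hits).
#' @param length_min,length_max accepted amplicon core length window after
#'   primer trimming (stand-in for HMM-based ITS2 extraction).
#' @param match,mismatch,gap_open,gap_extend integer alignment scores for the
#'   semi-global percent-identity alignment; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param pooled_abundance_filter apply the abundance filter over the pooled
#'   run instead of per site.
#' @param rng_seed integer seed recorded with the run.
#' @return an object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(aggregation_distance = 1L,
                            min_otu_proportion = 0.000005,
                            identity_thresholds = c(98, 98.5),
                            family_min_sh = 5L,
                            alpha = 0.05,
                            primer_fwd = "GCATCGATGAAGAACGCAGC",
                            primer_rev = "TCCTCCGCTTATTGATATGC",
                            merge_min_overlap = 20L,
                            merge_max_mismatch_rate = 0.10,
                            primer_max_mismatch_rate = 0.10,
                            chimera_parent_identity = 0.99,
                            chimera_parent_ratio = 2,
                            conspecific_identity = 0.99,
                            min_query_coverage = 0.8,
                            length_min = 100L,
                            length_max = 400L,
                            match = 1L, mismatch = -1L,
                            gap_open = 2L, gap_extend = 1L,
                            pooled_abundance_filter = FALSE,
                            rng_seed = 1L) {
  cfg <- list(aggregation_distance = as.integer(aggregation_distance),
              min_otu_proportion = min_otu_proportion,
              identity_thresholds = as.numeric(identity_thresholds),
              family_min_sh = as.integer(family_min_sh),
              alpha = alpha,
              primer_fwd = toupper(primer_fwd),
              primer_rev = toupper(primer_rev),
              merge_min_overlap = as.integer(merge_min_overlap),
              merge_max_mismatch_rate = merge_max_mismatch_rate,
              primer_max_mismatch_rate = primer_max_mismatch_rate,
              chimera_parent_identity = chimera_parent_identity,
              chimera_parent_ratio = chimera_parent_ratio,
              conspecific_identity = conspecific_identity,
              min_query_coverage = min_query_coverage,
              length_min = as.integer(length_min),
              length_max = as.integer(length_max),
              match = as.integer(match), mismatch = as.integer(mismatch),
              gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
              pooled_abundance_filter = isTRUE(pooled_abundance_filter),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!(cfg$min_otu_proportion > 0 && cfg$min_otu_proportion < 1))
    stop("min_otu_proportion must lie in (0, 1)")
  if (any(cfg$identity_thresholds <= 0 | cfg$identity_thresholds > 100))
    stop("identity_thresholds must lie in (0, 100]")
  if (cfg$aggregation_distance < 1L)
    stop("aggregation_distance must be >= 1")
  for (p in c(cfg$primer_fwd, cfg$primer_rev)) {
    if (nchar(p) == 0L) stop("primers must be non-empty")
    if (grepl("[^ACGTRYSWKMBDHVN]", p)) stop("primers must be IUPAC DNA")
  }
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' One key per configuration field; unknown keys are rejected so that typos
#' do not silently fall back to defaults.
#'
#' @param path file path.
#' @param cfg a `pipeline_config`.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  validate_pipeline_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
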