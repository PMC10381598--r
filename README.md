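# lichid

Benchmarking species-level identification in ITS2 metabarcoding of
lichen-forming fungi: does a high-coverage **regional** DNA barcode
reference library identify substantially more of a community's species
hypotheses (SHs) than a low-coverage **global** one?

Metabarcoding surveys sequence the fungal barcode region (here the
hypervariable ITS2, amplified with ITS3F/ITS4R), cluster the amplicons
into OTUs, and assign OTUs to species against a reference library. For
lichen-forming fungi, global libraries cover only a fraction of
species-level diversity, so identification success is bounded by library
coverage. `lichid` implements the whole chain as tested R code:

* a **synthetic-data generator** producing family-structured species
  pools (Yule trees, Jukes-Cantor evolution, interspecific ITS2
  divergence >= 1.5%, intraspecific < 0.5%), reference libraries of
  chosen coverage, multi-site communities with a shared core and
  site-unique fractions, and 2x300 paired reads with substitution errors
  and two-parent chimeras plus truth labels;
* the **amplicon pipeline**: read merging, IUPAC-aware primer trimming,
  swarm-style single-linkage clustering at aggregation distance 1, de
  novo two-parent chimera removal, inclusive abundance filtering at
  proportion 5e-6;
* two **classifiers**: a BLAST-style percent-identity threshold (strict
  "above 98%" / "above 98.5%", semi-global alignment with free terminal
  gaps, hits ranked by score, a query-coverage gate) and a phylogenetic
  **monophyly criterion** -- a query OTU is identified when the smallest
  reference-containing clade of its family tree holds a single SH;
* **OTU-to-SH collapsing** and the **statistical comparison**: success
  tables by site/family/total, exclusion of families with fewer than
  five SHs, a Shapiro-Wilk gate with `log10(x+1)` transform, one-way
  ANOVA with Tukey HSD, and exact Venn summaries of regional overlap.

The headline statistic is the identification percentage
`100 * n_identified / n_total` over the collapsed SH inventory, with the
same denominator for every database.

## Worked example

```r
library(lichid)

sim <- sim_params(n_families = 6, species_per_family = 6,
                  regional_coverage = 0.75, global_coverage = 0.30,
                  n_sites = 3, species_per_site = 15, core_set_size = 5,
                  site_unique_fraction = 0.2, reads_per_site = 1500,
                  rng_seed = 11)
run <- run_pipeline(sim, pipeline_config(rng_seed = 11))
run$total_table
#  grouping_key    database n_total_sh n_identified pct_identified
#         total   global_98         29           10       34.48276
#         total global_98.5         29           10       34.48276
#         total    regional         29           20       68.96552
run$site_comparison
# Database comparison (one-way ANOVA + Tukey HSD)
#   Shapiro-Wilk p = 0.1153
#   ANOVA: F = 7.931, p = 0.02067
#   Tukey global_98.5-global_98: p = 1
#   Tukey regional-global_98: p = 0.03154
#   Tukey regional-global_98.5: p = 0.03154
#   global_98: 34.0% +/- 6.37% (n = 3)
#   global_98.5: 34.0% +/- 6.37% (n = 3)
#   regional: 76.9% +/- 12.27% (n = 3)
```

Reading: the three sites carried 29 SHs after collapsing OTUs. The
regional library (75% species coverage) identified 20 of them (69.0%);
the global library (30% coverage) identified 10 (34.5%) at both
thresholds -- identification tracks coverage, and the ANOVA/Tukey
comparison flags the regional advantage while the two global thresholds
are indistinguishable. `report(run)` prints the full per-site/per-family
breakdown and the regional overlap summary.

## The analysis workflow

Numbered drivers under `analysis/` rerun the study end to end at a
desk-scale problem size (200 species, 5 sites, 5,000 read pairs/site;
a few minutes total), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # pool, libraries, communities, reads
Rscript analysis/02_pipeline.R   # file-based pipeline run (real mode)
Rscript analysis/03_compare.R    # ANOVA/Tukey, overlap, figures
Rscript analysis/04_report.R     # report + coverage-recovery check
```

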