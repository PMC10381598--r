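#!/usr/bin/env Rscript
# Stage 3: statistical comparison of the reference libraries.
#
# Reads the success tables written by stage 2, excludes families with
# fewer than 5 SHs from testing, runs the Shapiro-Wilk normality gate,
# one-way ANOVAs (site-level and family-level) with Tukey HSD post hoc
# tests, summarises the regional overlap, and draws the summary figures.

suppressPackageStartupMessages({ library(lichid); library(ggplot2) })

rundir <- "results/run"
outdir <- "results/stats"
figdir <- "results/figures"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
dir.create(figdir, showWarnings = FALSE, recursive = TRUE)
if (!file.exists("scratch/run.rds")) stop("run analysis/02_pipeline.R first")
run <- readRDS("scratch/run.rds")
cfg <- pipeline_config()

site_tab <- run$site_table
fam_tab <- run$family_table
fam_split <- exclude_small_families(fam_tab, cfg$family_min_sh)
message("families excluded from testing (fewer than ", cfg$family_min_sh,
        " SHs): ", length(unique(fam_split$excluded$grouping_key)))

site_cmp <- compare_databases(site_tab, cfg$alpha)
fam_cmp <- tryCatch(compare_databases(fam_split$kept, cfg$alpha),
                    error = function(e) { message("family ANOVA skipped: ",
                                                  conditionMessage(e)); NULL })
message("site-level ANOVA p = ", format(site_cmp$anova_p, digits = 3))
if (!is.null(fam_cmp))
  message("family-level ANOVA p = ", format(fam_cmp$anova_p, digits = 3),
          if (fam_cmp$transform_applied) " (log10(x+1) transformed)" else "")

stats <- list(
  site = list(shapiro_p = site_cmp$shapiro_p, anova_F = site_cmp$anova_F,
              anova_p = site_cmp$anova_p, tukey = site_cmp$tukey,
              transform_applied = site_cmp$transform_applied,
              group_stats = site_cmp$group_stats),
  family = if (!is.null(fam_cmp))
    list(shapiro_p = fam_cmp$shapiro_p, anova_F = fam_cmp$anova_F,
         anova_p = fam_cmp$anova_p, tukey = fam_cmp$tukey,
         transform_applied = fam_cmp$transform_applied,
         group_stats = fam_cmp$group_stats),
  overlap = if (!is.null(run$overlap))
    list(cells = as.list(run$overlap$cells), core = run$overlap$core,
         unique_fractions = as.list(run$overlap$unique_fractions)))
jsonlite::write_json(stats, file.path(outdir, "comparison.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
for (nm in c("site_tab", "fam_tab"))
  write.table(get(nm), file.path(outdir, paste0(nm, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)

# figures: identification success by database, per site and per family
p1 <- ggplot(site_tab, aes(database, pct_identified / 100, fill = database)) +
  geom_col() + facet_wrap(~grouping_key) +
  labs(x = NULL, y = "proportion of SHs identified") +
  theme_bw() + theme(legend.position = "none",
                     axis.text.x = element_text(angle = 45, hjust = 1))
ggsave(file.path(figdir, "success_by_site.pdf"), p1, width = 8, height = 5)
p2 <- ggplot(fam_split$kept, aes(database, pct_identified / 100, fill = database)) +
  geom_col() + facet_wrap(~grouping_key) +
  labs(x = NULL, y = "proportion of SHs identified") +
  theme_bw() + theme(legend.position = "none",
                     axis.text.x = element_text(angle = 45, hjust = 1))
ggsave(file.path(figdir, "success_by_family.pdf"), p2, width = 9, height = 7)
ov <- run$overlap
if (!is.null(ov)) {
  df <- data.frame(region = names(ov$region_sizes),
                   total = as.integer(ov$region_sizes),
                   unique = as.integer(ov$unique_counts))
  p3 <- ggplot(df, aes(region)) +
    geom_col(aes(y = total), fill = "grey80") +
    geom_col(aes(y = unique), fill = "steelblue") +
    labs(y = "SHs (total, unique in blue)", x = NULL,
         title = sprintf("core set shared by all regions: %d SHs", length(ov$core))) +
    theme_bw()
  ggsave(file.path(figdir, "regional_overlap.pdf"), p3, width = 6, height = 4)
}
message("stats under ", outdir, "; figures under ", figdir)
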