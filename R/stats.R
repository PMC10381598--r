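#' Identification success table
#'
#' Aggregates an SH inventory into per-group identification percentages.
#' The inventory is long-format: one row per (entry, site, database) with
#' an `identified` flag; entries are deduplicated by `entry_id` within
#' each grouping key, and `grouping = "total"` pools all SHs per database
#' (deduplicated across sites).
#'
#' @param inventory data.frame with columns `entry_id`, `family`, `site`,
#'   `database`, `identified`.
#' @param grouping one of `"site"`, `"family"`, `"total"`.
#' @return data.frame with `grouping_key`, `database`, `n_total_sh`,
#'   `n_identified`, `pct_identified` (percent, full precision).
#' @export
compute_success_rates <- function(inventory, grouping = c("site", "family", "total")) {
  grouping <- match.arg(grouping)
  if (nrow(inventory) == 0L) stop("empty inventory")
  key <- switch(grouping,
                site = inventory$site,
                family = inventory$family,
                total = rep("total", nrow(inventory)))
  parts <- split(seq_len(nrow(inventory)), list(key, inventory$database), drop = TRUE)
  rows <- lapply(parts, function(ii) {
    sub <- inventory[ii, , drop = FALSE]
    sub <- sub[!duplicated(sub$entry_id), , drop = FALSE]
    data.frame(grouping_key = key[ii[1]], database = sub$database[1],
               n_total_sh = nrow(sub), n_identified = sum(sub$identified),
               pct_identified = 100 * sum(sub$identified) / nrow(sub),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$grouping_key, out$database), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude small families from statistical testing
#'
#' Families represented by fewer than `family_min_sh` SHs are moved to the
#' excluded set so that outlier percentages do not skew the comparison;
#' they still contribute to total-level counts upstream.
#'
#' @param table a family-level success table from
#'   [compute_success_rates()].
#' @param family_min_sh exclusion cutoff (strict "fewer than").
#' @return list with `kept` and `excluded` tables.
#' @export
exclude_small_families <- function(table, family_min_sh = 5L) {
  small_fams <- unique(table$grouping_key[table$n_total_sh < family_min_sh])
  sel <- table$grouping_key %in% small_fams
  list(kept = table[!sel, , drop = FALSE], excluded = table[sel, , drop = FALSE])
}

#' Normality gate with add-one-log transform
#'
#' Shapiro-Wilk on the pooled within-group residuals; when p < alpha the
#' values are transformed x -> log10(x + 1) (uniformly; the +1 keeps zero
#' percentages finite) and re-tested. Constant input is flagged degenerate
#' (the test is undefined there).
#'
#' @param values numeric observations (e.g. percentages).
#' @param group grouping factor (residuals are taken about group means).
#' @param alpha significance level.
#' @param zeros_only apply the +1 shift only to zero values before the log
#'   (alternative reading of "adding one to zero values").
#' @return list with `values`, `shapiro_p` (first test), `shapiro_p_after`
#'   (`NA` unless transformed), `transform_applied`, `degenerate`.
#' @export
normality_gate_and_transform <- function(values, group = rep(1L, length(values)),
                                         alpha = 0.05, zeros_only = FALSE) {
  stopifnot(length(values) == length(group))
  if (length(values) < 3L) stop("need at least 3 values per group-set")
  resid_of <- function(v) v - ave(v, group)
  if (sd(resid_of(values)) == 0)
    return(list(values = values, shapiro_p = NA_real_, shapiro_p_after = NA_real_,
                transform_applied = FALSE, degenerate = TRUE))
  p1 <- shapiro.test(resid_of(values))$p.value
  if (p1 >= alpha)
    return(list(values = values, shapiro_p = p1, shapiro_p_after = NA_real_,
                transform_applied = FALSE, degenerate = FALSE))
  tv <- if (zeros_only) log10(ifelse(values == 0, values + 1, values))
        else log10(values + 1)
  r2 <- resid_of(tv)
  p2 <- if (sd(r2) == 0) NA_real_ else shapiro.test(r2)$p.value
  list(values = tv, shapiro_p = p1, shapiro_p_after = p2,
       transform_applied = TRUE, degenerate = FALSE)
}

#' Compare identification success between databases
#'
#' One-way ANOVA with the database label as factor and the per-group
#' percentages as observations, preceded by the normality gate, followed
#' by Tukey HSD post hoc pairwise comparisons. Group means are reported
#' with standard errors (SD / sqrt(n)). The degenerate no-variance case
#' (identical values everywhere) reports F = 0 and all p-values 1.
#'
#' @param table a success table ([compute_success_rates()]) restricted to
#'   one grouping (site or family), with >= 2 databases and >= 3
#'   observations each.
#' @param alpha significance level for the normality gate.
#' @param zeros_only passed to [normality_gate_and_transform()].
#' @return object of class `db_comparison`: `shapiro_p`,
#'   `transform_applied`, `anova_F`, `anova_p`, `tukey` (data.frame of
#'   pairs with adjusted p), `group_stats` (mean, se, n per database).
#' @export
compare_databases <- function(table, alpha = 0.05, zeros_only = FALSE) {
  dbs <- unique(table$database)
  if (length(dbs) < 2L) stop("need at least two databases to compare")
  n_per <- table(table$database)
  if (any(n_per < 3L)) stop("need at least 3 observations per database")
  group_stats <- do.call(rbind, lapply(dbs, function(db) {
    v <- table$pct_identified[table$database == db]
    data.frame(database = db, mean = mean(v), se = sd(v) / sqrt(length(v)),
               n = length(v), stringsAsFactors = FALSE)
  }))
  gate <- normality_gate_and_transform(table$pct_identified, table$database,
                                       alpha = alpha, zeros_only = zeros_only)
  pairs_df <- function(p) {
    cmb <- utils::combn(sort(dbs), 2L)
    data.frame(pair = paste(cmb[2, ], cmb[1, ], sep = "-"), p_adj = p,
               stringsAsFactors = FALSE)
  }
  if (gate$degenerate) {
    res <- list(shapiro_p = NA_real_, transform_applied = FALSE,
                anova_F = 0, anova_p = 1, tukey = pairs_df(1),
                group_stats = group_stats, degenerate = TRUE)
    class(res) <- "db_comparison"
    return(res)
  }
  df <- data.frame(y = gate$values, db = factor(table$database))
  fit <- aov(y ~ db, data = df)
  sm <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$db
  res <- list(shapiro_p = gate$shapiro_p,
              shapiro_p_after = gate$shapiro_p_after,
              transform_applied = gate$transform_applied,
              anova_F = sm[["F value"]][1], anova_p = sm[["Pr(>F)"]][1],
              tukey = data.frame(pair = rownames(tk), p_adj = tk[, "p adj"],
                                 row.names = NULL, stringsAsFactors = FALSE),
              group_stats = group_stats, degenerate = FALSE)
  class(res) <- "db_comparison"
  res
}

#' @export
print.db_comparison <- function(x, ...) {
  cat("Database comparison (one-way ANOVA + Tukey HSD)\n")
  if (isTRUE(x$degenerate)) {
    cat("  degenerate input: no variance; F = 0, all p = 1\n")
  } else {
    cat(sprintf("  Shapiro-Wilk p = %.4g%s\n", x$shapiro_p,
                if (x$transform_applied) " (log10(x+1) transform applied)" else ""))
    cat(sprintf("  ANOVA: F = %.4g, p = %.4g\n", x$anova_F, x$anova_p))
    for (i in seq_len(nrow(x$tukey)))
      cat(sprintf("  Tukey %s: p = %.4g\n", x$tukey$pair[i], x$tukey$p_adj[i]))
  }
  for (i in seq_len(nrow(x$group_stats)))
    cat(sprintf("  %s: %.1f%% +/- %.2f%% (n = %d)\n", x$group_stats$database[i],
                x$group_stats$mean[i], x$group_stats$se[i], x$group_stats$n[i]))
  invisible(x)
}

#' Regional overlap summary (Venn cells)
#'
#' Exact set algebra over per-region SH sets: every exclusive Venn cell,
#' all pairwise and k-way intersections, the core set shared by all
#' regions, and per-region unique counts and fractions.
#'
#' @param region_sets named list of character vectors (SH ids per region).
#' @return object of class `overlap_summary` with `cells` (exclusive Venn
#'   cell counts, names like `"A&B"`), `intersections` (plain intersection
#'   sizes per region subset), `core` (character vector), `unique_counts`,
#'   `unique_fractions`, `region_sizes`.
#' @export
overlap_summary <- function(region_sets) {
  stopifnot(is.list(region_sets), length(region_sets) >= 2L,
            !is.null(names(region_sets)))
  region_sets <- lapply(region_sets, unique)
  rn <- names(region_sets)
  k <- length(rn)
  universe <- unique(unlist(region_sets))
  memb <- vapply(region_sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L, dimnames = list(NULL, rn))
  cells <- integer(0); inters <- integer(0)
  for (mask in seq_len(2^k - 1L)) {
    in_set <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
    nm <- paste(rn[in_set], collapse = "&")
    exclusive <- apply(memb, 1L, function(r) all(r[in_set]) && !any(r[!in_set]))
    plain <- apply(memb, 1L, function(r) all(r[in_set]))
    cells[nm] <- sum(exclusive)
    inters[nm] <- sum(plain)
  }
  core <- universe[apply(memb, 1L, all)]
  uniq <- vapply(seq_len(k), function(i)
    sum(memb[, i] & rowSums(memb) == 1L), integer(1))
  sizes <- vapply(region_sets, length, integer(1))
  structure(list(cells = cells, intersections = inters, core = sort(core),
                 unique_counts = setNames(uniq, rn),
                 unique_fractions = setNames(ifelse(sizes > 0, uniq / sizes, NA_real_), rn),
                 region_sizes = sizes, region_sets = region_sets),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("<overlap_summary>: %d regions, union %d SHs, core %d SHs\n",
              length(x$region_sizes), sum(x$cells), length(x$core)))
  for (nm in names(x$region_sizes))
    cat(sprintf("  %s: %d SHs, %d unique (%.1f%%)\n", nm, x$region_sizes[[nm]],
                x$unique_counts[[nm]], 100 * x$unique_fractions[[nm]]))
  invisible(x)
}
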