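#' Merge paired-end reads
#'
#' Finds the best ungapped overlap of the reverse-complemented reverse read
#' against the forward read. A candidate overlap is acceptable when it is
#' at least `min_overlap` long with a mismatch fraction at most
#' `max_mismatch_rate`; among acceptable candidates the one maximising
#' `overlap - 2 * mismatches` wins (ties to the longer overlap).
#' Disagreeing overlap positions resolve to the forward-read base. Pairs
#' with no acceptable overlap are discarded (a counted, normal outcome).
#'
#' @param r1,r2 character vectors of forward/reverse reads (names kept).
#' @param min_overlap,max_mismatch_rate acceptance knobs.
#' @return list with `merged` (named character vector of merged amplicons)
#'   and `n_discarded`.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 20L, max_mismatch_rate = 0.10) {
  stopifnot(length(r1) == length(r2), all(nzchar(r1)), all(nzchar(r2)))
  merged <- cpp_merge_pairs(r1, r2, as.integer(min_overlap), max_mismatch_rate)
  names(merged) <- names(r1)
  keep <- !is.na(merged)
  list(merged = merged[keep], n_discarded = sum(!keep))
}

#' Trim amplification primers
#'
#' Matches the forward primer anchored at the 5' end and the
#' reverse-complemented reverse primer anchored at the 3' end, IUPAC-aware,
#' tolerating at most `floor(max_mismatch_rate * primer length)` mismatches
#' per primer. Sequences missing either primer are discarded.
#'
#' @param seqs character vector of merged amplicons (names kept).
#' @param primer_fwd,primer_rev primers as in [pipeline_config()].
#' @param max_mismatch_rate per-primer mismatch tolerance.
#' @return list with `trimmed` (named character vector of cores) and
#'   `n_discarded`.
#' @export
trim_primers <- function(seqs, primer_fwd, primer_rev, max_mismatch_rate = 0.10) {
  stopifnot(length(seqs) >= 0, nzchar(primer_fwd), nzchar(primer_rev))
  if (length(seqs) == 0L) return(list(trimmed = character(0), n_discarded = 0L))
  pf <- toupper(primer_fwd); prc <- revcomp(toupper(primer_rev))
  max_f <- floor(max_mismatch_rate * nchar(pf))
  max_r <- floor(max_mismatch_rate * nchar(prc))
  mm_f <- cpp_iupac_mismatches(seqs, pf, FALSE)
  mm_r <- cpp_iupac_mismatches(seqs, prc, TRUE)
  core_len <- nchar(seqs) - nchar(pf) - nchar(prc)
  keep <- mm_f <= max_f & mm_r <= max_r & core_len > 0L
  trimmed <- substr(seqs[keep], nchar(pf) + 1L, nchar(seqs[keep]) - nchar(prc))
  names(trimmed) <- names(seqs)[keep]
  list(trimmed = trimmed, n_discarded = sum(!keep))
}

#' Dereplicate sequences
#'
#' @param seqs character vector of sequences.
#' @return data.frame (`sequence`, `count`) sorted by decreasing count,
#'   ties in lexicographic sequence order.
#' @export
dereplicate <- function(seqs) {
  if (length(seqs) == 0L)
    return(data.frame(sequence = character(0), count = integer(0)))
  tab <- table(seqs)
  d <- data.frame(sequence = names(tab), count = as.integer(tab),
                  stringsAsFactors = FALSE)
  d <- d[order(-d$count, d$sequence), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# --- single-linkage neighbour search ---------------------------------------

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# edges at Levenshtein distance exactly <= 1 via positional deletion hashing;
# avoids the quadratic scan that utils::adist would need
lev1_components <- function(seqs) {
  n <- length(seqs)
  parent <- seq_len(n)
  union_groups <- function(idx) {
    if (length(idx) < 2L) return()
    roots <- vapply(idx, function(i) uf_find(parent, i), integer(1))
    r0 <- min(roots)
    parent[unique(roots)] <<- r0
  }
  lens <- nchar(seqs)
  by_len <- split(seq_len(n), lens)
  for (gl in names(by_len)) {
    L <- as.integer(gl)
    idx <- by_len[[gl]]
    s <- seqs[idx]
    # substitutions: identical after deleting the same position
    for (pos in seq_len(L)) {
      key <- paste0(substr(s, 1L, pos - 1L), substr(s, pos + 1L, L))
      for (grp in split(idx, key)) union_groups(grp)
    }
    # single indels: deletion variant equals a full sequence one shorter
    short <- by_len[[as.character(L - 1L)]]
    if (!is.null(short)) {
      short_seqs <- seqs[short]
      for (pos in seq_len(L)) {
        key <- paste0(substr(s, 1L, pos - 1L), substr(s, pos + 1L, L))
        hit <- match(key, short_seqs)
        ok <- which(!is.na(hit))
        for (i in ok) union_groups(c(idx[i], short[hit[i]]))
      }
    }
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

levd_components <- function(seqs, d) {
  n <- length(seqs)
  dm <- adist(seqs)
  parent <- seq_len(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (dm[i, j] <= d) {
      ri <- uf_find(parent, i); rj <- uf_find(parent, j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

#' Swarm-style single-linkage clustering at aggregation distance d
#'
#' Clusters dereplicated sequences by transitive closure of the "within
#' Levenshtein distance d" relation: a sequence joins a cluster if it is
#' within d edits of any current member, iterated to closure. This is the
#' partition produced by abundance-sorted greedy agglomeration, and it is
#' invariant to input order (determinism comes from the sort plus
#' tie-break rules). The representative is the highest-count member, ties
#' broken by lexicographic sequence order; clusters are numbered by
#' decreasing abundance (ties by representative).
#'
#' At `d = 1` (the default aggregation distance) neighbours are found by
#' positional deletion hashing; larger d falls back to a full edit-distance
#' matrix, appropriate for the small inputs where it is used.
#'
#' @param derep a [dereplicate()] table, or a named integer vector of
#'   counts (names = sequences).
#' @param d integer aggregation distance, >= 1.
#' @return data.frame with columns `otu_id`, `representative`, `abundance`,
#'   `n_members`, and a list-column `members` (named count vectors). The
#'   attribute `membership` maps each input sequence to its `otu_id`.
#' @export
swarm_cluster <- function(derep, d = 1L) {
  if (is.numeric(derep) && !is.null(names(derep)))
    derep <- data.frame(sequence = names(derep), count = as.integer(derep),
                        stringsAsFactors = FALSE)
  stopifnot(is.data.frame(derep), d >= 1L)
  if (nrow(derep) == 0L)
    return(structure(data.frame(otu_id = character(0), representative = character(0),
                                abundance = integer(0), n_members = integer(0)),
                     membership = setNames(character(0), character(0))))
  if (anyDuplicated(derep$sequence)) stop("input must be dereplicated")
  derep <- derep[order(-derep$count, derep$sequence), , drop = FALSE]
  comp <- if (d == 1L) lev1_components(derep$sequence) else levd_components(derep$sequence, d)
  groups <- split(seq_len(nrow(derep)), comp)
  reps <- character(length(groups)); abund <- integer(length(groups))
  members <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    sub <- derep[rows, , drop = FALSE]
    top <- sub[order(-sub$count, sub$sequence), , drop = FALSE][1L, ]
    reps[g] <- top$sequence
    abund[g] <- sum(sub$count)
    members[[g]] <- setNames(sub$count, sub$sequence)
  }
  ord <- order(-abund, reps)
  out <- data.frame(otu_id = sprintf("OTU_%04d", seq_along(ord)),
                    representative = reps[ord], abundance = abund[ord],
                    n_members = vapply(members[ord], length, integer(1)),
                    stringsAsFactors = FALSE)
  out$members <- members[ord]
  membership <- character(nrow(derep))
  for (g in seq_along(ord)) {
    sel <- groups[[ord[g]]]
    membership[sel] <- out$otu_id[g]
  }
  attr(out, "membership") <- setNames(membership, derep$sequence)
  out
}

#' Remove chimeric clusters (de novo two-parent test)
#'
#' A cluster is flagged chimeric when two distinct more-abundant clusters
#' (each at least `parent_ratio` times its abundance, themselves not
#' flagged) explain it as prefix + suffix around a single breakpoint at
#' segment identity >= `parent_identity`, while no single candidate parent
#' explains it full-length at that identity. Evaluation proceeds in
#' decreasing abundance order so parents are never themselves chimeric.
#'
#' @param clusters a [swarm_cluster()] table.
#' @param parent_identity,parent_ratio detection knobs (see
#'   [pipeline_config()]).
#' @return list with `kept` and `flagged` cluster tables.
#' @export
remove_chimeras <- function(clusters, parent_identity = 0.99, parent_ratio = 2) {
  if (nrow(clusters) == 0L) return(list(kept = clusters, flagged = clusters))
  ord <- order(-clusters$abundance, clusters$representative)
  cl <- clusters[ord, , drop = FALSE]
  flagged <- cpp_chimera_scan(cl$representative, as.numeric(cl$abundance),
                              parent_identity, parent_ratio)
  list(kept = cl[!flagged, , drop = FALSE], flagged = cl[flagged, , drop = FALSE])
}

#' Drop low-abundance clusters
#'
#' Keeps a cluster iff `abundance / total >= min_otu_proportion`
#' (inclusive boundary), where `total` defaults to the summed abundance of
#' the clusters handed in (per site, after chimera removal).
#'
#' @param clusters a cluster table.
#' @param min_otu_proportion minimum proportion to keep an OTU.
#' @param total proportion denominator override (e.g. a pooled-run total).
#' @return the kept cluster table.
#' @export
filter_low_abundance <- function(clusters, min_otu_proportion = 0.000005,
                                 total = sum(clusters$abundance)) {
  if (nrow(clusters) == 0L || total <= 0) return(clusters[integer(0), , drop = FALSE])
  clusters[clusters$abundance / total >= min_otu_proportion, , drop = FALSE]
}

#' Process one site's paired reads into filtered OTUs
#'
#' Runs merge -> primer trim -> length window -> dereplicate -> swarm ->
#' chimera removal -> abundance filter, and keeps the per-stage counts and
#' the read-to-OTU map needed to score clusters against simulation truth.
#'
#' @param r1,r2 named character vectors of paired reads.
#' @param config a [pipeline_config()].
#' @param site_id site label attached to the clusters.
#' @return list with `clusters` (kept OTUs), `flagged` (chimeric clusters),
#'   `read_otu` (named vector read id -> otu id, `NA` for reads lost along
#'   the way), and `counts` (per-stage totals).
#' @export
process_site <- function(r1, r2, config = pipeline_config(), site_id = "site") {
  m <- merge_pairs(r1, r2, config$merge_min_overlap, config$merge_max_mismatch_rate)
  t <- trim_primers(m$merged, config$primer_fwd, config$primer_rev,
                    config$primer_max_mismatch_rate)
  len_ok <- nchar(t$trimmed) >= config$length_min & nchar(t$trimmed) <= config$length_max
  cores <- t$trimmed[len_ok]
  derep <- dereplicate(unname(cores))
  clusters <- swarm_cluster(derep, config$aggregation_distance)
  chim <- remove_chimeras(clusters, config$chimera_parent_identity,
                          config$chimera_parent_ratio)
  kept <- filter_low_abundance(chim$kept, config$min_otu_proportion)
  membership <- attr(clusters, "membership")
  read_otu <- setNames(rep(NA_character_, length(r1)), names(r1))
  mapped <- membership[cores]
  mapped[!mapped %in% kept$otu_id] <- NA_character_
  read_otu[names(cores)] <- mapped
  kept$site_id <- if (nrow(kept) > 0L) site_id else character(0)
  counts <- c(reads_in = length(r1), merged = length(m$merged),
              trimmed = length(t$trimmed), length_ok = length(cores),
              unique_seqs = nrow(derep), clusters = nrow(clusters),
              chimeric = nrow(chim$flagged), otus_kept = nrow(kept))
  list(clusters = kept, flagged = chim$flagged, read_otu = read_otu, counts = counts)
}
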