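#' BLAST-style percent identity between two sequences
#'
#' Semi-global alignment (terminal gaps free in both sequences) under
#' integer scores match +1, mismatch -1, with affine gaps costing
#' `gap_open + L * gap_extend` for a gap of length L. Identity is
#' 100 * matches / aligned columns, where the aligned span excludes
#' terminal-gap columns but counts internal gap columns; IUPAC ambiguity
#' codes match iff their base sets intersect. Among co-optimal alignments
#' the traceback canonically prefers diagonal moves, then gaps in the
#' second sequence, then gaps in the first, closing gaps as early as
#' possible, so the value is deterministic.
#'
#' The semi-global form is the natural score for ITS2-only OTUs queried
#' against full-length ITS references: the reference overhangs are free.
#'
#' @param a,b non-empty IUPAC DNA strings.
#' @param match,mismatch,gap_open,gap_extend integer scoring weights.
#' @param details return matches/columns/score alongside the identity.
#' @return percent identity (numeric scalar), or a list when
#'   `details = TRUE`.
#' @export
pairwise_percent_identity <- function(a, b, match = 1L, mismatch = -1L,
                                      gap_open = 2L, gap_extend = 1L,
                                      details = FALSE) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  r <- cpp_percent_identity(toupper(a), toupper(b), match, mismatch, gap_open, gap_extend)
  if (details) r else r$identity
}

#' Assign OTUs by percent-identity threshold
#'
#' For each OTU representative, the best hit is the reference sequence
#' with the highest alignment score (the BLAST convention: hits are ranked
#' by score, and the percent identity of the best-scoring alignment is
#' what gets thresholded; ranking by identity itself is degenerate under
#' free terminal gaps, where unrelated sequences meet in short perfect
#' overlaps of identity 100). Ties resolve to the first hit in `seq_id`
#' order; the assignment is successful iff the best hit's identity is
#' strictly greater than the threshold ("above" semantics). Equally
#' best-scoring hits spanning different SHs make the assignment ambiguous
#' and therefore unsuccessful.
#'
#' @param clusters an OTU cluster table (needs `otu_id`,
#'   `representative`), or a named character vector of sequences.
#' @param library a [reference_library()].
#' @param threshold percent identity threshold (e.g. 98 or 98.5).
#' @param config a [pipeline_config()] supplying the alignment scores.
#' @return data.frame of assignments: `otu_id`, `method`, `assigned_sh`,
#'   `score`, `success`, `threshold_used`, `ambiguous`.
#' @export
assign_by_identity_threshold <- function(clusters, library, threshold,
                                         config = pipeline_config()) {
  stopifnot(inherits(library, "reference_library"), nrow(library$sequences) >= 1L)
  if (is.character(clusters))
    clusters <- data.frame(otu_id = names(clusters), representative = unname(clusters),
                           stringsAsFactors = FALSE)
  scan <- identity_scan(clusters, library, config)
  out <- data.frame(otu_id = clusters$otu_id, method = "identity_threshold",
                    assigned_sh = NA_character_, score = scan$best_identity,
                    success = FALSE, threshold_used = threshold,
                    ambiguous = scan$ambiguous, stringsAsFactors = FALSE)
  ok <- !scan$ambiguous & scan$best_identity > threshold &
    scan$coverage >= config$min_query_coverage
  out$assigned_sh[ok] <- scan$best_sh[ok]
  out$success[ok] <- TRUE
  out
}

# one alignment sweep per OTU against a library: hits are ranked by
# alignment score (as BLAST ranks by score, not by the identity of the
# reported alignment -- identity alone is degenerate under free terminal
# gaps, where unrelated sequences meet in short perfect overlaps), and the
# identity of the best-scoring alignment is reported; equally best-scoring
# hits spanning several SHs are ambiguous
identity_scan <- function(clusters, library, config = pipeline_config()) {
  refseq <- library$sequences$sequence
  n <- nrow(clusters)
  out <- data.frame(otu_id = clusters$otu_id, best_sh = NA_character_,
                    best_family = NA_character_, best_identity = NA_real_,
                    coverage = NA_real_, ambiguous = FALSE, stringsAsFactors = FALSE)
  fam_of <- setNames(library$sh$family, library$sh$sh_id)
  for (i in seq_len(n)) {
    ids <- cpp_percent_identity_many(clusters$representative[i], refseq,
                                     config$match, config$mismatch,
                                     config$gap_open, config$gap_extend)
    best <- max(ids[, "score"])
    hits <- which(ids[, "score"] == best)
    hit_sh <- unique(library$sequences$sh_id[hits])
    top <- hits[which.max(ids[hits, "identity"])]
    out$best_identity[i] <- ids[top, "identity"]
    out$coverage[i] <- ids[top, "columns"] / nchar(clusters$representative[i])
    out$best_sh[i] <- hit_sh[1] # first in seq_id order
    out$best_family[i] <- unname(fam_of[hit_sh[1]])
    out$ambiguous[i] <- length(hit_sh) > 1L # best hits span SHs: ambiguous
  }
  out
}

#' Trim a reference library to the amplified region
#'
#' Replaces every reference sequence by its primer-anchored ITS2 core (the
#' region a primer-trimmed OTU can actually align to), leaving sequences
#' without recognisable primer sites untouched. Scanning a trimmed library
#' gives the same best hits as the full-length library -- the flanks
#' outside the amplicon are free terminal gaps either way -- at about half
#' the alignment cost.
#'
#' @param library a [reference_library()].
#' @param config a [pipeline_config()] for the primers.
#' @return the library with trimmed sequences.
#' @export
trim_library_to_amplicon <- function(library, config = pipeline_config()) {
  stopifnot(inherits(library, "reference_library"))
  cores <- vapply(library$sequences$sequence, extract_amplicon_core, character(1),
                  config = config, USE.NAMES = FALSE)
  keep_full <- is.na(cores) | !nzchar(cores)
  cores[keep_full] <- library$sequences$sequence[keep_full]
  library$sequences$sequence <- cores
  library
}

# locate the amplified core inside a full-length reference (primer-anchored
# extraction standing in for HMM-based ITS2 detection); NA when either
# primer site is absent
extract_amplicon_core <- function(seq, config) {
  pf <- config$primer_fwd; prc <- revcomp(config$primer_rev)
  i <- regexpr(pf, seq, fixed = TRUE)
  if (i < 0L) return(NA_character_)
  rest <- substr(seq, i + nchar(pf), nchar(seq))
  j <- regexpr(prc, rest, fixed = TRUE)
  if (j < 0L) return(NA_character_)
  substr(rest, 1L, j - 1L)
}

#' Build a family-level tree of reference and query sequences
#'
#' Either adopts an externally computed tree (Newick passthrough; tip
#' labels must reconcile with the supplied ids) or infers one: sequences
#' are aligned (an external MSA if given; otherwise the primer-anchored
#' ITS2 cores, which are directly comparable when equal-length, with a
#' `mafft` fallback for length-variable input), JC69 pairwise distances
#' are computed, a neighbour-joining tree is built and midpoint-rooted.
#'
#' @param family family name.
#' @param otu_sequences named character vector of query (OTU) sequences;
#'   may be empty.
#' @param library a [reference_library()] holding the family's references.
#' @param external_tree optional Newick string or file path.
#' @param external_msa optional FASTA path of a precomputed alignment
#'   covering all reference and query ids.
#' @param config a [pipeline_config()].
#' @return object of class `family_tree`: `family`, `tree` (a rooted
#'   `phylo`, or `NULL` for a single-sequence family), `ref_tips` (named
#'   vector tip label -> SH id), `query_tips`.
#' @export
build_family_tree <- function(family, otu_sequences, library,
                              external_tree = NULL, external_msa = NULL,
                              config = pipeline_config()) {
  stopifnot(inherits(library, "reference_library"))
  sh_ids <- library$family_index[[family]]
  if (is.null(sh_ids)) stop("family not present in library: ", family)
  ref_rows <- library$sequences[library$sequences$sh_id %in% sh_ids, , drop = FALSE]
  ref_tips <- setNames(ref_rows$sh_id, ref_rows$seq_id)
  query_tips <- names(otu_sequences)
  all_ids <- c(ref_rows$seq_id, query_tips)
  if (anyDuplicated(all_ids)) stop("reference and query ids must be unique")

  if (!is.null(external_tree)) {
    tree <- if (file.exists(external_tree)) read_newick_file(external_tree)
            else read_newick(external_tree)
    extra <- setdiff(tree$tip.label, all_ids)
    miss <- setdiff(all_ids, tree$tip.label)
    if (length(extra) || length(miss))
      stop("external tree tips do not reconcile with provided ids",
           if (length(extra)) paste0("; unknown tips: ", paste(extra, collapse = ", ")),
           if (length(miss)) paste0("; missing tips: ", paste(miss, collapse = ", ")))
    tree <- phangorn::midpoint(tree)
    return(new_family_tree(family, tree, ref_tips, query_tips))
  }

  if (!is.null(external_msa)) {
    aln <- Biostrings::readDNAStringSet(external_msa)
    names(aln) <- sub("\\s.*$", "", names(aln))
    miss <- setdiff(all_ids, names(aln))
    if (length(miss)) stop("external MSA missing ids: ", paste(miss, collapse = ", "))
    mat <- do.call(rbind, strsplit(as.character(aln[all_ids]), ""))
    rownames(mat) <- all_ids
  } else {
    cores <- vapply(ref_rows$sequence, extract_amplicon_core, character(1),
                    config = config, USE.NAMES = FALSE)
    cores[is.na(cores)] <- ref_rows$sequence[is.na(cores)]
    seqs <- c(setNames(cores, ref_rows$seq_id), otu_sequences)
    if (length(seqs) == 1L)
      return(new_family_tree(family, NULL, ref_tips, query_tips))
    if (length(unique(nchar(seqs))) > 1L) seqs <- mafft_align(seqs)
    mat <- do.call(rbind, strsplit(unname(seqs), ""))
    rownames(mat) <- names(seqs)
  }
  dna <- ape::as.DNAbin(tolower(mat))
  dm <- ape::dist.dna(dna, model = "JC69", pairwise.deletion = TRUE)
  dmm <- as.matrix(dm)
  if (any(!is.finite(dmm))) { # saturated pairs: cap at a large distance
    cap <- max(dmm[is.finite(dmm)], 1) * 1.5
    dmm[!is.finite(dmm)] <- cap
  }
  tree <- if (nrow(dmm) == 2L) {
    d <- dmm[1, 2]
    read_newick(sprintf("(%s:%.8f,%s:%.8f);", rownames(dmm)[1], d / 2,
                        rownames(dmm)[2], d / 2))
  } else {
    tr <- ape::nj(stats::as.dist(dmm))
    tr$edge.length[tr$edge.length < 0] <- 0
    tr
  }
  tree <- phangorn::midpoint(tree)
  new_family_tree(family, tree, ref_tips, query_tips)
}

new_family_tree <- function(family, tree, ref_tips, query_tips) {
  structure(list(family = family, tree = tree,
                 ref_tips = ref_tips, query_tips = query_tips),
            class = "family_tree")
}

#' @export
print.family_tree <- function(x, ...) {
  cat(sprintf("<family_tree '%s'>: %d reference tips (%d SHs), %d query tips\n",
              x$family, length(x$ref_tips), length(unique(x$ref_tips)),
              length(x$query_tips)))
  invisible(x)
}

mafft_align <- function(seqs) {
  if (Sys.which("mafft") == "")
    stop("sequences are length-variable and no external MSA was given; ",
         "mafft is not available for the built-in fallback")
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fin)
  system2("mafft", c("--auto", "--quiet", fin), stdout = fout)
  aln <- Biostrings::readDNAStringSet(fout)
  setNames(as.character(aln), sub("\\s.*$", "", names(aln)))
}

# parent lookup and per-node tip descendants for a rooted phylo
tree_maps <- function(tree) {
  n_tip <- length(tree$tip.label)
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  desc <- phangorn::Descendants(tree, seq_len(n_tip + tree$Nnode), type = "tips")
  list(parent = parent, desc = desc, n_tip = n_tip)
}

#' Test each SH for monophyly on a family tree
#'
#' An SH is monophyletic iff the smallest clade containing all of its
#' reference tips contains no reference tips of another SH; query tips are
#' ignored for this test, and single-sequence SHs are trivially
#' monophyletic.
#'
#' @param ftree a [build_family_tree()] result.
#' @return named logical vector over the SHs with reference tips.
#' @export
evaluate_sh_monophyly <- function(ftree) {
  stopifnot(inherits(ftree, "family_tree"))
  shs <- unique(ftree$ref_tips)
  out <- setNames(rep(TRUE, length(shs)), shs)
  if (is.null(ftree$tree)) return(out)
  tree <- ftree$tree
  maps <- tree_maps(tree)
  tip_index <- match(names(ftree$ref_tips), tree$tip.label)
  for (sh in shs) {
    tips <- tip_index[ftree$ref_tips == sh]
    if (length(tips) < 2L) next
    node <- ape::getMRCA(tree, tips)
    clade_tips <- tree$tip.label[maps$desc[[node]]]
    clade_refs <- ftree$ref_tips[intersect(clade_tips, names(ftree$ref_tips))]
    out[sh] <- all(clade_refs == sh)
  }
  out
}

#' Assign query OTUs by the monophyly criterion
#'
#' For each query tip, the smallest clade containing the query and at
#' least one reference tip is located by walking rootward; the assignment
#' succeeds iff every reference tip in that clade belongs to a single SH.
#' Queries whose smallest reference-containing clade mixes SHs are left
#' unassigned. The score is the number of supporting reference tips.
#'
#' @param ftree a [build_family_tree()] result (midpoint-rooted).
#' @return data.frame of assignments: `otu_id`, `method`, `assigned_sh`,
#'   `score`, `success`, `threshold_used`.
#' @export
assign_by_monophyly <- function(ftree) {
  stopifnot(inherits(ftree, "family_tree"))
  if (length(ftree$ref_tips) == 0L) stop("tree has no reference tips")
  queries <- ftree$query_tips
  out <- data.frame(otu_id = queries, method = "monophyly",
                    assigned_sh = NA_character_, score = NA_real_,
                    success = FALSE, threshold_used = NA_real_,
                    stringsAsFactors = FALSE)
  if (length(queries) == 0L) return(out)
  if (is.null(ftree$tree)) return(out) # no tree means no query placements
  tree <- ftree$tree
  maps <- tree_maps(tree)
  for (qi in seq_along(queries)) {
    tip <- match(queries[qi], tree$tip.label)
    node <- maps$parent[tip]
    repeat {
      clade_tips <- tree$tip.label[maps$desc[[node]]]
      refs <- ftree$ref_tips[intersect(clade_tips, names(ftree$ref_tips))]
      if (length(refs) > 0L) break
      if (maps$parent[node] == 0L) break # rooted at node already
      node <- maps$parent[node]
    }
    shs <- unique(refs)
    if (length(shs) == 1L) {
      out$assigned_sh[qi] <- shs
      out$score[qi] <- length(refs)
      out$success[qi] <- TRUE
    } else {
      out$score[qi] <- length(refs)
    }
  }
  out
}

#' Collapse OTUs into species hypotheses
#'
#' All OTUs assigned to one SH collapse to a single inventory entry.
#' Unassigned OTUs collapse together iff they sit in one query-only clade
#' (no intervening reference tip) and are linked at `conspecific_identity`
#' or better (single linkage within the clade: an uncovered species'
#' central OTU chains its satellite error variants together even when two
#' satellites are slightly further apart); the remainder become singleton
#' provisional SHs. An entry is identified when any member OTU carries a
#' successful assignment.
#'
#' @param assignments a data.frame as returned by [assign_by_monophyly()]
#'   covering all OTUs in `trees`.
#' @param trees list of [build_family_tree()] objects covering the OTUs.
#' @param otu_sequences named character vector of all query sequences.
#' @param conspecific_identity fraction, e.g. 0.99.
#' @param config a [pipeline_config()].
#' @return data.frame inventory: `entry_id`, `sh_id` (`NA` for provisional
#'   entries), `family`, `identified`, `n_otus`, list-column `members`.
#' @export
collapse_to_species_hypotheses <- function(assignments, trees, otu_sequences,
                                           conspecific_identity = 0.99,
                                           config = pipeline_config()) {
  entries <- list()
  assigned <- assignments[assignments$success & !is.na(assignments$assigned_sh), , drop = FALSE]
  fam_of_sh <- do.call(c, unname(lapply(trees, function(ft)
    setNames(rep(ft$family, length(unique(ft$ref_tips))), unique(ft$ref_tips)))))
  for (sh in unique(assigned$assigned_sh)) {
    otus <- assigned$otu_id[assigned$assigned_sh == sh]
    entries[[length(entries) + 1L]] <- data.frame(
      entry_id = sh, sh_id = sh, family = unname(fam_of_sh[sh]),
      identified = TRUE, n_otus = length(otus), stringsAsFactors = FALSE)
    entries[[length(entries)]]$members <- list(otus)
  }
  unassigned <- setdiff(assignments$otu_id, assigned$otu_id)
  prov_n <- 0L
  for (ft in trees) {
    qs <- intersect(ft$query_tips, unassigned)
    if (length(qs) == 0L) next
    groups <- query_only_clades(ft)
    done <- character(0)
    for (grp in groups) {
      grp <- intersect(grp, qs)
      if (length(grp) < 2L) next
      # single-linkage components of the >= conspecific_identity relation
      comp <- seq_along(grp)
      for (i in seq_len(length(grp) - 1L)) for (j in (i + 1L):length(grp)) {
        pid <- pairwise_percent_identity(otu_sequences[[grp[i]]], otu_sequences[[grp[j]]],
                                         config$match, config$mismatch,
                                         config$gap_open, config$gap_extend)
        if (pid >= 100 * conspecific_identity)
          comp[comp == comp[j]] <- comp[i]
      }
      for (cc in unique(comp)) {
        sub <- grp[comp == cc]
        if (length(sub) < 2L) next
        prov_n <- prov_n + 1L
        entries[[length(entries) + 1L]] <- data.frame(
          entry_id = sprintf("PROV_%04d", prov_n), sh_id = NA_character_,
          family = ft$family, identified = FALSE, n_otus = length(sub),
          stringsAsFactors = FALSE)
        entries[[length(entries)]]$members <- list(sub)
        done <- c(done, sub)
      }
    }
    for (q in setdiff(qs, done)) {
      prov_n <- prov_n + 1L
      entries[[length(entries) + 1L]] <- data.frame(
        entry_id = sprintf("PROV_%04d", prov_n), sh_id = NA_character_,
        family = ft$family, identified = FALSE, n_otus = 1L,
        stringsAsFactors = FALSE)
      entries[[length(entries)]]$members <- list(q)
    }
  }
  if (length(entries) == 0L)
    return(data.frame(entry_id = character(0), sh_id = character(0),
                      family = character(0), identified = logical(0),
                      n_otus = integer(0)))
  do.call(rbind, entries)
}

# maximal clades whose tips are all queries (a leaf query under a mixed
# parent is itself such a clade)
query_only_clades <- function(ftree) {
  if (is.null(ftree$tree)) return(lapply(ftree$query_tips, identity))
  tree <- ftree$tree
  maps <- tree_maps(tree)
  n_nodes <- length(maps$desc)
  is_q <- vapply(seq_len(n_nodes), function(nd)
    all(tree$tip.label[maps$desc[[nd]]] %in% ftree$query_tips), logical(1))
  maximal <- which(is_q & (maps$parent == 0L | !is_q[pmax(maps$parent, 1L)]))
  lapply(maximal, function(nd) tree$tip.label[maps$desc[[nd]]])
}
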