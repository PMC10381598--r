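#' Newick read/write with validation
#'
#' Thin wrappers around ape's Newick parser that (a) reject malformed input
#' with the character position of the first offending token, and (b)
#' preserve single-quoted tip labels containing spaces, which the plain
#' parser mangles. Serialising a parsed tree preserves topology, tip
#' labels, and branch lengths (ape writes branch lengths with 10
#' significant digits).
#'
#' @param text a Newick string.
#' @param path file path.
#' @param tree a `phylo` object.
#' @return `read_newick`/`read_newick_file` return a `phylo`;
#'   `write_newick` returns the Newick string invisibly.
#' @export
read_newick <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string")
  # balance check with position reporting
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("Newick parse error at position ", i, ": unmatched ')'")
    }
  }
  if (in_quote) stop("Newick parse error: unterminated quoted label")
  if (depth != 0L)
    stop("Newick parse error at position ", nchar(text), ": ", depth, " unclosed '('")
  if (!grepl(";\\s*$", text))
    stop("Newick parse error at position ", nchar(text), ": missing terminal ';'")
  # shelter quoted labels from ape
  quoted <- regmatches(text, gregexpr("'[^']*'", text))[[1]]
  placeholders <- character(0)
  if (length(quoted)) {
    placeholders <- sprintf("QUOTEDLBL%03d", seq_along(quoted))
    for (i in seq_along(quoted))
      text <- sub(quoted[i], placeholders[i], text, fixed = TRUE)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: parser returned no tree")
  if (length(quoted)) {
    restore <- gsub("^'|'$", "", quoted)
    idx <- match(tree$tip.label, placeholders)
    tree$tip.label[!is.na(idx)] <- restore[idx[!is.na(idx)]]
    if (!is.null(tree$node.label)) {
      idx <- match(tree$node.label, placeholders)
      tree$node.label[!is.na(idx)] <- restore[idx[!is.na(idx)]]
    }
  }
  if (anyDuplicated(tree$tip.label)) stop("Newick tree has duplicate tip labels")
  tree
}

#' @rdname read_newick
#' @export
read_newick_file <- function(path) read_newick(paste(readLines(path, warn = FALSE), collapse = ""))

#' @rdname read_newick
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  lab <- tree$tip.label
  needs_quote <- which(grepl("[ (),:;]", lab))
  # shelter labels needing quotes from ape's label sanitiser
  placeholders <- sprintf("QUOTEDLBL%03d", seq_along(needs_quote))
  tree$tip.label[needs_quote] <- placeholders
  txt <- ape::write.tree(tree)
  for (i in seq_along(needs_quote))
    txt <- sub(placeholders[i], paste0("'", lab[needs_quote[i]], "'"), txt, fixed = TRUE)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' Read/write paired FASTQ and truth sidecars
#'
#' Reads are stored as plain FASTQ with constant quality; the pipeline is
#' abundance-based and never consults quality values. The truth sidecar is
#' a TSV with columns `read_id`, `source_sh`, `source_sh2`, `is_chimera`
#' emitted by the simulator.
#'
#' @param path file path.
#' @param reads named character vector of read sequences.
#' @return `read_fastq` returns a named character vector.
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(dna), sub("\\s.*$", "", names(dna)))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

read_truth <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write OTU clusters as FASTA with size annotations
#'
#' Representatives are written with `;size=N` abundance suffixes in the
#' usual amplicon-tool convention.
#'
#' @param clusters an OTU cluster table (see [swarm_cluster()]).
#' @param path output FASTA path.
#' @export
write_otu_fasta <- function(clusters, path) {
  ids <- sprintf("%s;size=%d", clusters$otu_id, clusters$abundance)
  dna <- Biostrings::DNAStringSet(setNames(clusters$representative, ids))
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
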