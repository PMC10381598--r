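#' Reference library of vouchered ITS sequences
#'
#' A `reference_library` binds IUPAC DNA sequences to species hypotheses
#' (SHs) and families. It is the object both classifiers query: the
#' identity-threshold classifier scans its sequences, the monophyly
#' classifier places them on family trees together with query OTUs.
#'
#' @param sequences data.frame with columns `seq_id`, `sh_id`, `sequence`
#'   and optionally `region`; sequence ids must be unique, sequences
#'   non-empty IUPAC DNA.
#' @param sh data.frame with columns `sh_id`, `name`, `kind`, `family`;
#'   every `sh_id` referenced from `sequences` must resolve here.
#' @param name library label, e.g. `"regional"` or `"global"`.
#' @return an object of class `reference_library` with consistent
#'   `sh_index` (SH -> sequence ids) and `family_index` (family -> SH ids).
#' @export
reference_library <- function(sequences, sh, name = "library") {
  stopifnot(is.data.frame(sequences), is.data.frame(sh))
  req <- c("seq_id", "sh_id", "sequence")
  if (!all(req %in% names(sequences)))
    stop("sequences needs columns: ", paste(req, collapse = ", "))
  if (!all(c("sh_id", "name", "kind", "family") %in% names(sh)))
    stop("sh needs columns sh_id, name, kind, family")
  if (nrow(sequences) < 1L) stop("library must contain at least one sequence")
  if (anyDuplicated(sequences$seq_id))
    stop("duplicate seq_id: ",
         paste(unique(sequences$seq_id[duplicated(sequences$seq_id)]), collapse = ", "))
  if (anyDuplicated(sh$sh_id)) stop("duplicate sh_id in SH table")
  if (!"region" %in% names(sequences)) sequences$region <- NA_character_
  seqs <- toupper(sequences$sequence)
  if (any(!nzchar(seqs)) || any(grepl("[^ACGTRYSWKMBDHVN]", seqs)))
    stop("sequences must be non-empty IUPAC DNA")
  sequences$sequence <- seqs
  missing_sh <- setdiff(sequences$sh_id, sh$sh_id)
  if (length(missing_sh))
    stop("sh_id not resolvable in SH table: ", paste(missing_sh, collapse = ", "))
  sh <- sh[sh$sh_id %in% sequences$sh_id, , drop = FALSE] # every SH has >= 1 sequence
  rownames(sequences) <- rownames(sh) <- NULL
  obj <- list(name = name,
              sequences = sequences,
              sh = sh,
              sh_index = split(sequences$seq_id, sequences$sh_id),
              family_index = split(sh$sh_id, sh$family))
  class(obj) <- "reference_library"
  obj
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("<reference_library '%s'>: %d sequences, %d SHs, %d families\n",
              x$name, nrow(x$sequences), nrow(x$sh), length(x$family_index)))
  invisible(x)
}

#' Load a reference library from FASTA + metadata
#'
#' The metadata table is tab-separated with a header row and columns
#' `seq_id`, `sh_name`, `family`, `region`. Every FASTA id must appear
#' exactly once in the metadata and vice versa; SH kinds are derived from
#' the names with [parse_sh_name()], and each distinct `sh_name` becomes
#' one SH.
#'
#' @param fasta_path FASTA file of reference sequences.
#' @param metadata_path TSV metadata file.
#' @param name library label.
#' @return a [reference_library()].
#' @export
load_reference_library <- function(fasta_path, metadata_path, name = "library") {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dna) == 0L) stop("empty FASTA: ", fasta_path)
  ids <- sub("\\s.*$", "", names(dna))
  meta <- read.table(metadata_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, quote = "", comment.char = "")
  req <- c("seq_id", "sh_name", "family", "region")
  if (!all(req %in% names(meta)))
    stop("metadata needs columns: ", paste(req, collapse = ", "))
  only_fasta <- setdiff(ids, meta$seq_id)
  only_meta <- setdiff(meta$seq_id, ids)
  if (length(only_fasta) || length(only_meta))
    stop("FASTA/metadata ids do not reconcile",
         if (length(only_fasta)) paste0("; only in FASTA: ", paste(only_fasta, collapse = ", ")),
         if (length(only_meta)) paste0("; only in metadata: ", paste(only_meta, collapse = ", ")))
  if (anyDuplicated(ids)) stop("duplicate seq_id in FASTA")
  if (anyDuplicated(meta$seq_id)) stop("duplicate seq_id in metadata")
  meta <- meta[match(ids, meta$seq_id), , drop = FALSE]
  sh_names <- unique(meta$sh_name)
  kinds <- vapply(sh_names, function(nm) parse_sh_name(nm)$kind, character(1))
  sh <- data.frame(sh_id = sh_names, name = sh_names, kind = unname(kinds),
                   family = meta$family[match(sh_names, meta$sh_name)],
                   stringsAsFactors = FALSE)
  sequences <- data.frame(seq_id = ids, sh_id = meta$sh_name,
                          sequence = as.character(dna), region = meta$region,
                          stringsAsFactors = FALSE)
  reference_library(sequences, sh, name = name)
}

#' Write a reference library to FASTA + metadata
#'
#' Inverse of [load_reference_library()]: a written library reloads to an
#' identical object (round-trip identity on all fields).
#'
#' @param lib a [reference_library()].
#' @param fasta_path,metadata_path output paths.
#' @export
write_reference_library <- function(lib, fasta_path, metadata_path) {
  stopifnot(inherits(lib, "reference_library"))
  dna <- Biostrings::DNAStringSet(setNames(lib$sequences$sequence, lib$sequences$seq_id))
  Biostrings::writeXStringSet(dna, fasta_path)
  meta <- data.frame(seq_id = lib$sequences$seq_id,
                     sh_name = lib$sh$name[match(lib$sequences$sh_id, lib$sh$sh_id)],
                     family = lib$sh$family[match(lib$sequences$sh_id, lib$sh$sh_id)],
                     region = lib$sequences$region,
                     stringsAsFactors = FALSE)
  write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(lib)
}
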