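#' Parse a species-hypothesis name
#'
#' Classifies an SH display name into one of the naming-convention kinds
#' used in voucher-backed lichen reference libraries:
#'
#' * `aff`  -- name contains the token `" aff. "` (phylogenetic substructure
#'   split off from a described species);
#' * `agg`  -- name contains `" agg. "` (species aggregate);
#' * `cf`   -- name contains `" cf. "` (uncertain determination);
#' * `provisional` -- names of the form `"<Taxon> sp. <n>"` (unidentified
#'   material given a numbered placeholder);
#' * `formal` -- everything else (a formally applied taxonomic name).
#'
#' Matching is token-based and case-sensitive. Unrecognised patterns fall
#' back to `formal`; a malformed `" sp. "` usage (no trailing integer) also
#' falls back to `formal` with a warning.
#'
#' @param label non-empty SH name string.
#' @return list with elements `name`, `kind`, and `genus` (first token, or
#'   `NA` when the label is a single word).
#' @examples
#' parse_sh_name("Rusavskia elegans")$kind                  # "formal"
#' parse_sh_name("Xanthoparmelia aff. coloradoensis")$kind  # "aff"
#' parse_sh_name("Lecanora cf. garovaglii")$kind            # "cf"
#' parse_sh_name("Acarosporaceae sp. 3")$kind               # "provisional"
#' @export
parse_sh_name <- function(label) {
  if (length(label) != 1L || is.na(label) || !nzchar(trimws(label)))
    stop("SH name must be a non-empty string")
  label <- trimws(label)
  kind <- if (grepl(" aff. ", label, fixed = TRUE)) "aff"
  else if (grepl(" agg. ", label, fixed = TRUE)) "agg"
  else if (grepl(" cf. ", label, fixed = TRUE)) "cf"
  else if (grepl(" sp\\. [0-9]+$", label)) "provisional"
  else {
    if (grepl(" sp\\. ", label)) {
      warning("unrecognised 'sp.' pattern in '", label, "'; classified as formal")
    }
    "formal"
  }
  tokens <- strsplit(label, " ", fixed = TRUE)[[1]]
  genus <- if (length(tokens) > 1L) tokens[1] else NA_character_
  list(name = label, kind = kind, genus = genus)
}

sh_kinds <- c("formal", "aff", "agg", "cf", "provisional")
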