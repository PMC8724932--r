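#' Candidate-selection thresholds for de novo peptides
#'
#' Defaults follow standard HLA class I immunopeptidome practice: peptide
#' lengths 8-14, average local confidence (ALC) strictly above 50%, and
#' isoleucine/leucine treated as equivalent (tandem MS cannot distinguish
#' them).
#'
#' @param min_len,max_len Inclusive peptide length bounds.
#' @param min_alc ALC threshold in percent; retention requires `alc >
#'   min_alc` (strict).
#' @param il_equivalence Treat I and L as the same residue when matching
#'   against the reference proteome and the translated database.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_len = 8L, max_len = 14L, min_alc = 50,
                          il_equivalence = TRUE) {
  if (min_len > max_len) stopf("min_len exceeds max_len")
  if (min_alc < 0 || min_alc > 100) stopf("min_alc outside [0, 100]")
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 min_alc = min_alc, il_equivalence = isTRUE(il_equivalence)),
            class = "filter_config")
}

#' Select candidate de novo peptides
#'
#' Retains observations that are de novo-only, within the length bounds, and
#' strictly above the ALC threshold; duplicate sequences are collapsed to a
#' single candidate keeping the maximum ALC. The result is independent of
#' input order and idempotent.
#'
#' @param observations Data.frame of peptide observations (see
#'   [read_peptide_table()]).
#' @param config A [filter_config()].
#' @param audit If `TRUE`, attach an `"audit"` attribute: a data.frame with a
#'   drop reason code per input row (`retained`, `not_de_novo_only`,
#'   `length_out_of_range`, `alc_too_low`, `duplicate`).
#' @return Data.frame of candidates with columns `peptide`, `alc`,
#'   `sample_id`, sorted by peptide.
#' @export
filter_denovo <- function(observations, config = filter_config(),
                          audit = FALSE) {
  len <- nchar(observations$peptide)
  reason <- rep("retained", nrow(observations))
  reason[observations$origin != "de_novo_only"] <- "not_de_novo_only"
  ok_origin <- reason == "retained"
  reason[ok_origin & (len < config$min_len | len > config$max_len)] <-
    "length_out_of_range"
  ok <- reason == "retained"
  reason[ok & observations$alc <= config$min_alc] <- "alc_too_low"
  keep <- reason == "retained"
  kept <- observations[keep, c("peptide", "alc", "sample_id"), drop = FALSE]
  # collapse duplicates: keep max ALC; ties resolved by sample then row order
  kept <- kept[order(kept$peptide, -kept$alc, kept$sample_id), , drop = FALSE]
  dup <- duplicated(kept$peptide)
  idx <- match(rownames(kept)[dup], rownames(observations))
  reason[idx] <- "duplicate"
  out <- kept[!dup, , drop = FALSE]
  rownames(out) <- NULL
  if (audit)
    attr(out, "audit") <- data.frame(peptide = observations$peptide,
                                     reason = reason,
                                     stringsAsFactors = FALSE)
  out
}

#' Exclude candidates present in the reference proteome
#'
#' Removes any candidate occurring as a contiguous substring of a reference
#' proteome sequence; these are explainable by annotated proteins and are not
#' noncanonical candidates. With `il_equivalence`, I and L are collapsed on
#' both sides before matching, which is the conservative choice for
#' MS-derived sequences.
#'
#' @param candidates Character vector of peptides, or a data.frame with a
#'   `peptide` column (e.g. from [filter_denovo()]).
#' @param proteome Data.frame with columns `id` and `sequence`
#'   (see [read_fasta()]).
#' @param il_equivalence Collapse I/L before matching. Default `TRUE`.
#' @return Same shape as `candidates`, restricted to peptides absent from
#'   the proteome.
#' @export
exclude_proteome <- function(candidates, proteome, il_equivalence = TRUE) {
  if (nrow(proteome) == 0L) stopf("empty proteome")
  peps <- if (is.data.frame(candidates)) candidates$peptide else candidates
  hit <- proteome_hits(peps, proteome, il_equivalence)
  if (is.data.frame(candidates)) candidates[!hit, , drop = FALSE]
  else candidates[!hit]
}

# Logical vector: is each peptide a substring of any proteome sequence?
proteome_hits <- function(peptides, proteome, il_equivalence = TRUE) {
  # '#' cannot occur in either alphabet, so concatenation cannot create
  # spurious junction-spanning matches
  hay <- paste(proteome$sequence, collapse = "#")
  if (il_equivalence) {
    hay <- il_collapse(hay)
    peptides <- il_collapse(peptides)
  }
  vapply(peptides, function(p) grepl(p, hay, fixed = TRUE), NA,
         USE.NAMES = FALSE)
}
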