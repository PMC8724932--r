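#' Peptide length distribution
#'
#' @param peptides Character vector of peptides with lengths inside
#'   `[min_len, max_len]`.
#' @param min_len,max_len Length range of the histogram (defaults 8-14, the
#'   HLA class I window).
#' @return Data.frame with columns `length` and `count`, one row per length
#'   in the range; counts sum to `length(peptides)`.
#' @export
length_distribution <- function(peptides, min_len = 8L, max_len = 14L) {
  len <- nchar(peptides)
  if (any(len < min_len | len > max_len))
    stopf("peptide(s) outside length range [%d, %d]: %s", min_len, max_len,
          paste(peptides[len < min_len | len > max_len], collapse = ", "))
  lengths <- min_len:max_len
  data.frame(length = lengths,
             count = vapply(lengths, function(l) sum(len == l), 0L))
}

#' Binder counts per peptide length
#'
#' Tabulates, per peptide length, the total number of peptides, the binders
#' (best rank strictly below `cutoff`) and the strong binders (strictly
#' below `strong_cutoff`). Strong binders are a subset of binders, which are
#' a subset of the totals.
#'
#' @param peptide_ranks Data.frame with columns `peptide` and `best_rank`
#'   (`NA` rank = no prediction, counted in totals only).
#' @param cutoff,strong_cutoff Rank cutoffs (strict `<`), defaults 2.0/0.5.
#' @param min_len,max_len Length range.
#' @return Data.frame with columns `length`, `total`, `binders`, `strong`.
#' @export
binder_fraction_by_length <- function(peptide_ranks, cutoff = 2.0,
                                      strong_cutoff = 0.5, min_len = 8L,
                                      max_len = 14L) {
  len <- nchar(peptide_ranks$peptide)
  rk <- peptide_ranks$best_rank
  lengths <- min_len:max_len
  data.frame(
    length = lengths,
    total = vapply(lengths, function(l) sum(len == l), 0L),
    binders = vapply(lengths, function(l)
      sum(len == l & !is.na(rk) & rk < cutoff), 0L),
    strong = vapply(lengths, function(l)
      sum(len == l & !is.na(rk) & rk < strong_cutoff), 0L)
  )
}

#' Amino-acid composition of a protein set
#'
#' Background residue frequencies for [motif_percent_difference()], computed
#' from a reference proteome.
#'
#' @param proteome Data.frame with a `sequence` column, or a character
#'   vector of protein sequences.
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
aa_composition <- function(proteome) {
  seqs <- if (is.data.frame(proteome)) proteome$sequence else proteome
  counts <- Biostrings::letterFrequency(
    Biostrings::AAStringSet(seqs), letters = AA20)
  tot <- colSums(counts)
  tot / sum(tot)
}

#' Positional percent-difference motif matrix
#'
#' For a set of 9-mers, computes per position the difference between the
#' observed residue frequency and a reference (background) frequency,
#' expressed in percentage points:
#' \deqn{value(a, j) = 100 (f_{obs}(a, j) - f_{ref}(a)).}
#' This is the percentage-difference readout used by sequence-logo tools;
#' anchor-position preferences of an HLA motif show up as large positive
#' values at positions 2 and 9.
#'
#' @param nine_mers Character vector of peptides, all of length 9.
#' @param reference Named numeric vector of background residue frequencies
#'   over the 20 amino acids, summing to 1 (see [aa_composition()]).
#' @return A `motif_matrix`: 20 x 9 numeric matrix (residues x positions)
#'   with the reference stored in attribute `"reference"`.
#' @export
motif_percent_difference <- function(nine_mers, reference) {
  if (length(nine_mers) == 0L) stopf("empty peptide set")
  if (any(nchar(nine_mers) != 9L))
    stopf("non-9-mer peptide(s): %s",
          paste(nine_mers[nchar(nine_mers) != 9L], collapse = ", "))
  if (!all(AA20 %in% names(reference)))
    stopf("reference must name all 20 amino acids")
  reference <- reference[AA20]
  if (abs(sum(reference) - 1) > 1e-6)
    stopf("reference frequencies must sum to 1")
  mat <- matrix(0, nrow = 20L, ncol = 9L,
                dimnames = list(AA20, paste0("P", 1:9)))
  chars <- do.call(rbind, strsplit(nine_mers, ""))
  for (j in 1:9) {
    obs <- table(factor(chars[, j], levels = AA20)) / length(nine_mers)
    mat[, j] <- 100 * (as.numeric(obs) - reference)
  }
  structure(mat, reference = reference, class = c("motif_matrix", "matrix"))
}
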