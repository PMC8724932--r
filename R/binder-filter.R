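#' Typed HLA class I alleles per sample
#'
#' @param sample_id Sample label.
#' @param alleles Character vector of HLA allele names (e.g.
#'   `"HLA-A*02:06"`); must be nonempty and unique.
#' @return A `sample_alleles` list.
#' @export
sample_alleles <- function(sample_id, alleles) {
  if (length(alleles) == 0L) stopf("sample %s: no alleles", sample_id)
  if (anyDuplicated(alleles)) stopf("sample %s: duplicate alleles", sample_id)
  structure(list(sample_id = sample_id, alleles = alleles),
            class = "sample_alleles")
}

#' Best-ranked allele for one peptide
#'
#' Among the sample's typed alleles, returns the allele with the minimum
#' predicted percentile rank for the peptide. Ties are broken by
#' lexicographic allele order (and reported via a message, since a
#' documented tie is unusual in practice).
#'
#' @param peptide Peptide sequence.
#' @param calls Data.frame of rank calls (see [read_rank_table()]).
#' @param alleles A [sample_alleles()] object.
#' @return List with `allele` and `rank_percent`, or `NULL` when the peptide
#'   has no call for any of the sample's alleles.
#' @export
assign_best_allele <- function(peptide, calls, alleles) {
  sel <- calls[calls$peptide == peptide & calls$allele %in% alleles$alleles, ,
               drop = FALSE]
  if (nrow(sel) == 0L) return(NULL)
  best <- min(sel$rank_percent)
  at_best <- sort(sel$allele[sel$rank_percent == best])
  if (length(at_best) > 1L)
    message(sprintf("peptide %s: rank tie between %s; keeping %s",
                    peptide, paste(at_best, collapse = ", "), at_best[1]))
  list(allele = at_best[1], rank_percent = best)
}

#' Best-ranked allele for many peptides
#'
#' Vectorised form of [assign_best_allele()].
#'
#' @inheritParams assign_best_allele
#' @param peptides Character vector of peptide sequences.
#' @return Data.frame with columns `peptide`, `allele`, `rank_percent`;
#'   peptides without any call get `NA` allele and rank.
#' @export
assign_best_alleles <- function(peptides, calls, alleles) {
  res <- lapply(peptides, assign_best_allele, calls = calls,
                alleles = alleles)
  data.frame(
    peptide = peptides,
    allele = vapply(res, function(r) if (is.null(r)) NA_character_ else
      r$allele, ""),
    rank_percent = vapply(res, function(r) if (is.null(r)) NA_real_ else
      r$rank_percent, 0),
    stringsAsFactors = FALSE
  )
}

#' Apply the HLA binder cutoff to peptide matches
#'
#' Annotates each match with its best allele and rank and the binder
#' category: `binder` when the best rank is strictly below `cutoff`
#' (default 2.0), `strong_binder` when strictly below `strong_cutoff`
#' (default 0.5; strong binders are a subset of binders), otherwise
#' `nonbinder`. Matches without any rank call are nonbinders.
#'
#' @param matches Data.frame with a `peptide` column (and optionally
#'   `sample_id`, used to pick the right typed-allele set).
#' @param calls Rank calls (see [read_rank_table()]).
#' @param alleles A [sample_alleles()] object, or a list of them keyed by
#'   sample when `matches` carries `sample_id`.
#' @param cutoff Binder threshold on percentile rank (strict `<`).
#' @param strong_cutoff Strong-binder threshold (strict `<`).
#' @param drop_nonbinders Drop nonbinder rows from the result.
#' @return `matches` with added columns `best_allele`, `best_rank`,
#'   `binder_class`, plus a `"binder_counts"` attribute with totals per
#'   category.
#' @export
filter_binders <- function(matches, calls, alleles, cutoff = 2.0,
                           strong_cutoff = 0.5, drop_nonbinders = TRUE) {
  allele_set_for <- function(sample_id) {
    if (inherits(alleles, "sample_alleles")) return(alleles)
    hit <- alleles[[sample_id]]
    if (is.null(hit)) stopf("no typed alleles for sample %s", sample_id)
    hit
  }
  n <- nrow(matches)
  best_allele <- character(n); best_rank <- numeric(n)
  for (i in seq_len(n)) {
    al <- allele_set_for(if ("sample_id" %in% names(matches))
      matches$sample_id[i] else NULL)
    r <- assign_best_allele(matches$peptide[i], calls, al)
    best_allele[i] <- if (is.null(r)) NA_character_ else r$allele
    best_rank[i] <- if (is.null(r)) NA_real_ else r$rank_percent
  }
  cls <- rep("nonbinder", n)
  cls[!is.na(best_rank) & best_rank < cutoff] <- "binder"
  cls[!is.na(best_rank) & best_rank < strong_cutoff] <- "strong_binder"
  matches$best_allele <- best_allele
  matches$best_rank <- best_rank
  matches$binder_class <- cls
  counts <- c(total = n,
              binder = sum(cls != "nonbinder"),
              strong_binder = sum(cls == "strong_binder"),
              nonbinder = sum(cls == "nonbinder"))
  if (drop_nonbinders)
    matches <- matches[cls != "nonbinder", , drop = FALSE]
  rownames(matches) <- NULL
  attr(matches, "binder_counts") <- counts
  matches
}
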