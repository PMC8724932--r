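#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] adding the validation
#' this pipeline relies on: unique record IDs, no empty sequences, uppercase
#' normalisation, and optional U->T conversion for RNA-alphabet transcript
#' files.
#'
#' @param path Path to a FASTA file.
#' @param u_to_t Convert U residues to T (for nucleotide files given in the
#'   RNA alphabet). Default `FALSE`.
#' @return A data.frame with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path, u_to_t = FALSE) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids))
    stopf("duplicate FASTA ID(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs)))
    stopf("empty sequence for FASTA ID(s): %s",
          paste(ids[!nzchar(seqs)], collapse = ", "))
  if (u_to_t) seqs <- chartr("U", "T", seqs)
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' @param records A data.frame with columns `id` and `sequence` (as returned
#'   by [read_fasta()]), or a named character vector.
#' @param path Output path.
#' @param width Line width for sequence folding.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records))
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read transcripts from a BED12 file
#'
#' Parses 12-column BED transcript models, attaches spliced sequences by ID,
#' and validates the block structure. All coordinates are 0-based half-open
#' (BED native). `blockStarts` must be relative to `chromStart` and the block
#' sizes must sum to the length of the attached sequence.
#'
#' @param path Path to a BED12 file.
#' @param fasta_by_id Named character vector (or `id`/`sequence` data.frame)
#'   of spliced transcript sequences, 5'->3' on the transcript strand.
#' @return A `transcript_set`: a data.frame with one row per transcript and
#'   columns `transcript_id`, `gene_id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`, list-columns `block_starts` (absolute genomic) and
#'   `block_sizes`, and `sequence`.
#' @export
read_bed12 <- function(path, fasta_by_id) {
  if (!file.exists(path)) stopf("BED12 file not found: %s", path)
  if (is.data.frame(fasta_by_id))
    fasta_by_id <- stats::setNames(fasta_by_id$sequence, fasta_by_id$id)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L)
      stopf("BED12 line %d has %d fields (12 required)", i, length(f))
    n_blocks <- as.integer(f[10])
    sizes <- as.integer(strsplit(f[11], ",", fixed = TRUE)[[1]])
    rel_starts <- as.integer(strsplit(f[12], ",", fixed = TRUE)[[1]])
    if (length(sizes) != n_blocks || length(rel_starts) != n_blocks)
      stopf("BED12 line %d: blockCount %d does not match comma lists",
            i, n_blocks)
    chrom_start <- as.integer(f[2])
    chrom_end <- as.integer(f[3])
    starts <- chrom_start + rel_starts
    if (rel_starts[1] != 0L)
      stopf("transcript %s: blockStarts must be relative to chromStart (first offset is %d, expected 0)",
            f[4], rel_starts[1])
    if (starts[n_blocks] + sizes[n_blocks] != chrom_end)
      stopf("transcript %s: last block does not end at chromEnd", f[4])
    list(transcript_id = f[4], chrom = f[1], strand = f[6],
         tx_start = chrom_start, tx_end = chrom_end,
         block_starts = starts, block_sizes = sizes)
  })
  ids <- vapply(rows, `[[`, "", "transcript_id")
  if (anyDuplicated(ids))
    stopf("duplicate transcript ID(s) in BED12: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  missing <- setdiff(ids, names(fasta_by_id))
  if (length(missing))
    stopf("no FASTA sequence for transcript(s): %s",
          paste(missing, collapse = ", "))
  seqs <- toupper(unname(fasta_by_id[ids]))
  tx <- data.frame(
    transcript_id = ids,
    gene_id = sub(":[0-9]+$", "", ids),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    tx_start = vapply(rows, function(r) r$tx_start, 0L),
    tx_end = vapply(rows, function(r) r$tx_end, 0L),
    stringsAsFactors = FALSE
  )
  tx$block_starts <- lapply(rows, `[[`, "block_starts")
  tx$block_sizes <- lapply(rows, `[[`, "block_sizes")
  tx$sequence <- seqs
  validate_transcripts(tx)
  class(tx) <- c("transcript_set", "data.frame")
  tx
}

validate_transcripts <- function(tx) {
  for (i in seq_len(nrow(tx))) {
    starts <- tx$block_starts[[i]]
    sizes <- tx$block_sizes[[i]]
    id <- tx$transcript_id[i]
    if (!tx$strand[i] %in% c("+", "-"))
      stopf("transcript %s: strand must be '+' or '-'", id)
    if (is.unsorted(starts, strictly = TRUE) && length(starts) > 1L)
      stopf("transcript %s: blocks not sorted by genomic start", id)
    ends <- starts + sizes
    if (length(starts) > 1L && any(starts[-1] < ends[-length(ends)]))
      stopf("transcript %s: blocks overlap", id)
    if (tx$tx_start[i] > starts[1] || ends[length(ends)] > tx$tx_end[i])
      stopf("transcript %s: blocks outside transcript span", id)
    if (sum(sizes) != nchar(tx$sequence[i]))
      stopf("transcript %s: block sizes sum to %d but sequence length is %d",
            id, sum(sizes), nchar(tx$sequence[i]))
    if (grepl("[^ACGTN]", tx$sequence[i]))
      stopf("transcript %s: sequence contains characters outside {A,C,G,T,N}",
            id)
  }
  invisible(tx)
}

#' Write a transcript set to BED12
#'
#' @param transcripts A `transcript_set` (see [read_bed12()]).
#' @param path Output path.
#' @export
write_bed12 <- function(transcripts, path) {
  lines <- vapply(seq_len(nrow(transcripts)), function(i) {
    starts <- transcripts$block_starts[[i]]
    sizes <- transcripts$block_sizes[[i]]
    paste(transcripts$chrom[i], transcripts$tx_start[i],
          transcripts$tx_end[i], transcripts$transcript_id[i], 0,
          transcripts$strand[i], transcripts$tx_start[i],
          transcripts$tx_start[i], "0", length(sizes),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts - transcripts$tx_start[i], collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a de novo peptide observation table
#'
#' Consumes a tab-separated export of de novo sequenced peptides (one row per
#' observation) with required columns `peptide`, `alc` and `sample`, and
#' optional `intensity` and `origin` columns. Post-translational modification
#' annotations written in parentheses, e.g. `M(+15.99)PEPTIDE`, are stripped
#' from the sequence and kept in a `modifications` column.
#'
#' @param path Path to a TSV file with a header line.
#' @return A data.frame with columns `peptide`, `alc`, `sample_id`,
#'   `intensity`, `origin` and `modifications`.
#' @export
read_peptide_table <- function(path) {
  if (!file.exists(path)) stopf("peptide table not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("peptide", "alc", "sample")) {
    if (!col %in% names(tab))
      stopf("peptide table is missing required column '%s'", col)
  }
  raw <- as.character(tab$peptide)
  mods <- vapply(raw, function(p) {
    m <- regmatches(p, gregexpr("\\([^)]*\\)", p))[[1]]
    paste(m, collapse = ";")
  }, "", USE.NAMES = FALSE)
  bare <- toupper(gsub("\\([^)]*\\)", "", raw))
  bad <- which(!is_valid_peptide(bare))
  if (length(bad))
    stopf("peptide table row(s) %s: sequence contains non-amino-acid residues",
          paste(bad, collapse = ", "))
  alc <- suppressWarnings(as.numeric(tab$alc))
  if (anyNA(alc))
    stopf("peptide table row(s) %s: 'alc' is not numeric",
          paste(which(is.na(alc)), collapse = ", "))
  if (any(alc < 0 | alc > 100))
    stopf("peptide table row(s) %s: 'alc' outside [0, 100]",
          paste(which(alc < 0 | alc > 100), collapse = ", "))
  data.frame(
    peptide = bare,
    alc = alc,
    sample_id = as.character(tab$sample),
    intensity = if ("intensity" %in% names(tab))
      as.numeric(tab$intensity) else NA_real_,
    origin = if ("origin" %in% names(tab))
      as.character(tab$origin) else "de_novo_only",
    modifications = mods,
    stringsAsFactors = FALSE
  )
}

#' Read an HLA binding rank table
#'
#' Consumes a TSV of binding-prediction percentile ranks with columns
#' `peptide`, `allele` and `rank` (a `%Rank` header is accepted). Duplicate
#' (peptide, allele) rows are collapsed to the minimum rank, i.e. the most
#' favourable prediction, with a warning.
#'
#' @param path Path to a TSV file with a header line.
#' @return A data.frame with columns `peptide`, `allele`, `rank_percent`.
#' @export
read_rank_table <- function(path) {
  if (!file.exists(path)) stopf("rank table not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  rank_col <- intersect(c("rank", "%Rank", "rank_percent"), names(tab))[1]
  if (!all(c("peptide", "allele") %in% names(tab)) || is.na(rank_col))
    stopf("rank table requires columns 'peptide', 'allele' and 'rank'")
  calls <- data.frame(
    peptide = as.character(tab$peptide),
    allele = as.character(tab$allele),
    rank_percent = as.numeric(tab[[rank_col]]),
    stringsAsFactors = FALSE
  )
  if (nrow(calls) == 0L) return(calls)
  if (anyNA(calls$rank_percent)) stopf("rank table contains non-numeric ranks")
  if (any(calls$rank_percent < 0)) stopf("rank table contains negative ranks")
  key <- paste(calls$peptide, calls$allele, sep = "\r")
  if (anyDuplicated(key)) {
    warnf("rank table: %d duplicate (peptide, allele) row(s) collapsed to minimum rank",
          sum(duplicated(key)))
    agg <- stats::aggregate(rank_percent ~ peptide + allele, data = calls, FUN = min)
    calls <- agg[order(agg$peptide, agg$allele), , drop = FALSE]
    rownames(calls) <- NULL
  }
  calls
}

#' Read per-sample read-coverage intervals from BED
#'
#' Loads BED intervals (first three columns used) and merges overlapping or
#' bookended intervals per chromosome, yielding the covered space of one
#' sample's transcriptome.
#'
#' @param path Path to a BED file (3+ columns).
#' @param sample_id Sample label to attach.
#' @return A `coverage_set`: list with `sample_id` and `intervals`, a
#'   data.frame of merged `chrom`/`start`/`end` rows (0-based half-open).
#' @export
read_coverage_bed <- function(path, sample_id) {
  if (!file.exists(path)) stopf("coverage BED not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    iv <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), stringsAsFactors = FALSE)
  } else {
    f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    iv <- data.frame(chrom = f[, 1], start = as.integer(f[, 2]),
                     end = as.integer(f[, 3]), stringsAsFactors = FALSE)
    if (any(iv$end <= iv$start)) stopf("coverage BED has empty interval(s)")
    iv <- merge_intervals(iv)
  }
  structure(list(sample_id = sample_id, intervals = iv),
            class = "coverage_set")
}

# Merge possibly-overlapping intervals per chromosome (union).
merge_intervals <- function(iv) {
  out <- lapply(split(iv, iv$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(chrom = d$chrom[1], start = BiocGenerics::start(r) - 1L,
               end = BiocGenerics::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write intervals to BED6
#'
#' @param intervals Data.frame with columns `chrom`, `start`, `end`, and
#'   optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @export
write_bed6 <- function(intervals, path) {
  name <- if ("name" %in% names(intervals)) intervals$name else "."
  score <- if ("score" %in% names(intervals)) intervals$score else 0
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  lines <- paste(intervals$chrom, intervals$start, intervals$end,
                 name, score, strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a BED12 file
#'
#' Interprets 12-column BED rows as gene models: blocks are exons and the
#' `thickStart`/`thickEnd` span marks the coding region. CDS intervals are the
#' intersection of the exon blocks with the thick span; a gene whose thick
#' span is empty (`thickStart == thickEnd`) is noncoding.
#'
#' @param path Path to a BED12 gene-model file.
#' @return A `genome_annotation`: list with data.frames `genes` (`gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `coding`), `exons` and `cds`
#'   (`gene_id`, `chrom`, `start`, `end`). Coordinates 0-based half-open.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stopf("gene model BED not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  genes <- list(); exons <- list(); cds <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L)
      stopf("gene model line %d has %d fields (12 required)", i, length(f))
    gstart <- as.integer(f[2]); gend <- as.integer(f[3])
    thick_s <- as.integer(f[7]); thick_e <- as.integer(f[8])
    sizes <- as.integer(strsplit(f[11], ",", fixed = TRUE)[[1]])
    rel <- as.integer(strsplit(f[12], ",", fixed = TRUE)[[1]])
    ex_s <- gstart + rel
    ex_e <- ex_s + sizes
    genes[[i]] <- data.frame(gene_id = f[4], chrom = f[1], strand = f[6],
                             start = gstart, end = gend,
                             coding = thick_e > thick_s,
                             stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(gene_id = f[4], chrom = f[1], start = ex_s,
                             end = ex_e, stringsAsFactors = FALSE)
    cs <- pmax(ex_s, thick_s); ce <- pmin(ex_e, thick_e)
    keep <- ce > cs
    if (any(keep))
      cds[[i]] <- data.frame(gene_id = f[4], chrom = f[1], start = cs[keep],
                             end = ce[keep], stringsAsFactors = FALSE)
  }
  ann <- structure(list(
    genes = do.call(rbind, genes),
    exons = do.call(rbind, exons),
    cds = if (length(cds)) do.call(rbind, cds) else
      data.frame(gene_id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0))
  ), class = "genome_annotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  for (g in seq_len(nrow(ann$genes))) {
    id <- ann$genes$gene_id[g]
    ex <- ann$exons[ann$exons$gene_id == id, , drop = FALSE]
    cd <- ann$cds[ann$cds$gene_id == id, , drop = FALSE]
    if (any(ex$start < ann$genes$start[g]) || any(ex$end > ann$genes$end[g]))
      stopf("gene %s: exon outside gene span", id)
    if (nrow(cd)) {
      exr <- IRanges::IRanges(ex$start + 1L, ex$end)
      cdr <- IRanges::IRanges(cd$start + 1L, cd$end)
      within <- IRanges::countOverlaps(cdr, exr, type = "within")
      if (any(within == 0L))
        stopf("gene %s: CDS interval not contained in exons", id)
    }
  }
  invisible(ann)
}

#' Write gene models to BED12
#'
#' Inverse of [read_gene_models()].
#'
#' @param annotation A `genome_annotation`.
#' @param path Output path.
#' @export
write_gene_models <- function(annotation, path) {
  lines <- vapply(seq_len(nrow(annotation$genes)), function(g) {
    row <- annotation$genes[g, ]
    ex <- annotation$exons[annotation$exons$gene_id == row$gene_id, ,
                           drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cd <- annotation$cds[annotation$cds$gene_id == row$gene_id, , drop = FALSE]
    thick <- if (nrow(cd)) c(min(cd$start), max(cd$end)) else
      c(row$start, row$start)
    paste(row$chrom, row$start, row$end, row$gene_id, 0, row$strand,
          thick[1], thick[2], "0", nrow(ex),
          paste0(paste(ex$end - ex$start, collapse = ","), ","),
          paste0(paste(ex$start - row$start, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
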