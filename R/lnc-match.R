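#' Match candidate peptides against the translated database
#'
#' Scans every stop-free segment of every (transcript, frame) entry for
#' exact occurrences of each candidate peptide. Matching never crosses a
#' stop codon and an `X` residue (ambiguous codon) never matches. A peptide
#' occurring several times — in several transcripts, frames, or positions —
#' yields one match per occurrence.
#'
#' @param candidates Character vector of peptides, or a data.frame with
#'   `peptide` (and optionally `sample_id`) columns.
#' @param db A `translated_db` from [build_translated_db()].
#' @param il_equivalence Collapse I/L on both sides before matching.
#' @return Data.frame with columns `peptide`, `transcript_id`, `frame`,
#'   `aa_start` (0-based within the frame translation), plus `sample_id`
#'   when supplied.
#' @export
match_peptides <- function(candidates, db, il_equivalence = TRUE) {
  cand_df <- if (is.data.frame(candidates)) candidates else
    data.frame(peptide = candidates, stringsAsFactors = FALSE)
  peps <- unique(cand_df$peptide)
  keys <- if (il_equivalence) il_collapse(peps) else peps
  hits <- list()
  for (e in seq_len(nrow(db))) {
    segs <- frame_segments(db$aa_sequence[e])
    if (nrow(segs) == 0L) next
    seg_txt <- if (il_equivalence) il_collapse(segs$segment) else segs$segment
    for (s in seq_len(nrow(segs))) {
      for (p in seq_along(peps)) {
        if (nchar(keys[p]) > nchar(seg_txt[s])) next
        at <- str_find_all(seg_txt[s], keys[p])
        if (length(at))
          hits[[length(hits) + 1L]] <- data.frame(
            peptide = peps[p],
            transcript_id = db$transcript_id[e],
            frame = db$frame[e],
            aa_start = segs$aa_start[s] + at,
            stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(peptide = character(0), transcript_id = character(0),
               frame = integer(0), aa_start = integer(0),
               stringsAsFactors = FALSE)
  if ("sample_id" %in% names(cand_df)) {
    out <- merge(out, unique(cand_df[, c("peptide", "sample_id")]),
                 by = "peptide", sort = FALSE)
  }
  out <- out[order(out$peptide, out$transcript_id, out$frame, out$aa_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Project a transcript interval onto the genome through BED12 blocks
#'
#' Maps a 0-based half-open nucleotide interval on the stored transcript
#' sequence (5'->3' on the transcript strand) to genomic intervals,
#' splitting at exon-block boundaries. Minus-strand transcripts are stored
#' 3'->5' relative to the genome, so their intervals are mirrored before
#' walking the blocks.
#'
#' @param transcript One row of a `transcript_set` (a data.frame row, with
#'   list-columns `block_starts`/`block_sizes`).
#' @param nt_start,nt_end 0-based half-open interval on the transcript.
#' @return Data.frame of genomic intervals `chrom`, `start`, `end`,
#'   `strand`, sorted by genomic start; total width equals
#'   `nt_end - nt_start`.
#' @export
map_to_genome <- function(transcript, nt_start, nt_end) {
  L <- sum(transcript$block_sizes[[1]])
  if (nt_start < 0L || nt_end > L || nt_start >= nt_end)
    stopf("transcript %s: nt interval [%d, %d) outside transcript of length %d",
          transcript$transcript_id, nt_start, nt_end, L)
  if (transcript$strand == "-") {
    # mirror onto the genomic (plus) layout of the spliced blocks
    tmp <- nt_start
    nt_start <- L - nt_end
    nt_end <- L - tmp
  }
  starts <- transcript$block_starts[[1]]
  sizes <- transcript$block_sizes[[1]]
  offs <- cumsum(c(0L, sizes))  # transcript offset (plus layout) per block
  out <- list()
  for (b in seq_along(starts)) {
    lo <- max(nt_start, offs[b])
    hi <- min(nt_end, offs[b + 1L])
    if (lo < hi)
      out[[length(out) + 1L]] <- data.frame(
        chrom = transcript$chrom,
        start = starts[b] + (lo - offs[b]),
        end = starts[b] + (hi - offs[b]),
        strand = transcript$strand,
        stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Fill genomic coordinates for peptide matches
#'
#' For each match, converts the amino-acid window to transcript nucleotide
#' coordinates ([aa_to_nt_interval()]) and projects it through the
#' transcript's block structure ([map_to_genome()]).
#'
#' @param matches Data.frame from [match_peptides()].
#' @param transcripts The `transcript_set` the database was built from.
#' @return `matches` with added columns `nt_start`, `nt_end` (transcript
#'   coordinates) and a list-column `genomic_intervals`.
#' @export
locate_matches <- function(matches, transcripts) {
  idx <- match(matches$transcript_id, transcripts$transcript_id)
  if (anyNA(idx))
    stopf("match references unknown transcript(s): %s",
          paste(unique(matches$transcript_id[is.na(idx)]), collapse = ", "))
  n <- nrow(matches)
  nt_start <- integer(n); nt_end <- integer(n)
  giv <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- transcripts[idx[i], , drop = FALSE]
    L <- nchar(tr$sequence)
    iv <- aa_to_nt_interval(matches$frame[i], matches$aa_start[i],
                            nchar(matches$peptide[i]), L)
    nt_start[i] <- iv[1]; nt_end[i] <- iv[2]
    giv[[i]] <- map_to_genome(tr, iv[1], iv[2])
  }
  matches$nt_start <- nt_start
  matches$nt_end <- nt_end
  matches$genomic_intervals <- giv
  matches
}

# GRanges views of an annotation restricted to coding genes: CDS exons, all
# exons, gene spans, and intronic space (span minus exons).
annotation_ranges <- function(ann) {
  coding <- ann$genes[ann$genes$coding, , drop = FALSE]
  gr <- function(d, strand = NULL) {
    if (nrow(d) == 0L)
      return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(d$chrom,
                           IRanges::IRanges(d$start + 1L, d$end),
                           strand = if (is.null(strand)) "*" else strand)
  }
  spans <- gr(coding, coding$strand)
  exons <- gr(ann$exons[ann$exons$gene_id %in% coding$gene_id, , drop = FALSE])
  cds <- gr(ann$cds[ann$cds$gene_id %in% coding$gene_id, , drop = FALSE])
  introns_by_gene <- lapply(seq_len(nrow(coding)), function(g) {
    ex <- ann$exons[ann$exons$gene_id == coding$gene_id[g], , drop = FALSE]
    span <- IRanges::IRanges(coding$start[g] + 1L, coding$end[g])
    intr <- BiocGenerics::setdiff(span, IRanges::IRanges(ex$start + 1L, ex$end))
    if (length(intr) == 0L) return(NULL)
    data.frame(chrom = coding$chrom[g], start = BiocGenerics::start(intr),
               end = BiocGenerics::end(intr), strand = coding$strand[g],
               stringsAsFactors = FALSE)
  })
  intr_df <- do.call(rbind, introns_by_gene)
  introns <- if (is.null(intr_df)) GenomicRanges::GRanges() else
    GenomicRanges::GRanges(intr_df$chrom,
                           IRanges::IRanges(intr_df$start, intr_df$end),
                           strand = intr_df$strand)
  list(spans = spans, exons = exons, cds = cds, introns = introns)
}

match_granges <- function(genomic_intervals) {
  GenomicRanges::GRanges(
    genomic_intervals$chrom,
    IRanges::IRanges(genomic_intervals$start + 1L, genomic_intervals$end),
    strand = genomic_intervals$strand)
}

#' Classify a peptide-coding region by genomic context
#'
#' Classification (strand-agnostic, since the peptide is by construction
#' absent from the reference proteome):
#' * `novel_orf` — any peptide-coding base overlaps a CDS exon of a coding
#'   gene (a frameshifted or alternate-start product);
#' * `intronic` — otherwise, any base lies in intronic space of a coding
#'   gene;
#' * `noncoding` — otherwise (including UTR-exon-only overlap, since only
#'   coding exons define `novel_orf`).
#'
#' @param genomic_intervals Data.frame of `chrom`/`start`/`end`/`strand`
#'   intervals (one peptide's coding region).
#' @param annotation A `genome_annotation` (see [read_gene_models()]).
#' @return One of `"novel_orf"`, `"intronic"`, `"noncoding"`.
#' @export
classify_region <- function(genomic_intervals, annotation) {
  rng <- annotation_ranges(annotation)
  known <- unique(c(as.character(GenomicRanges::seqnames(rng$spans)),
                    annotation$genes$chrom))
  if (!all(genomic_intervals$chrom %in% known)) {
    warnf("peptide interval on unannotated chromosome %s; classified noncoding",
          paste(setdiff(genomic_intervals$chrom, known), collapse = ", "))
    return("noncoding")
  }
  pg <- match_granges(genomic_intervals)
  if (any(GenomicRanges::countOverlaps(pg, rng$cds, ignore.strand = TRUE) > 0L))
    return("novel_orf")
  if (any(GenomicRanges::countOverlaps(pg, rng$introns,
                                       ignore.strand = TRUE) > 0L))
    return("intronic")
  "noncoding"
}

#' Classify a source lncRNA transcript
#'
#' Precedence: `antisense` (transcript span overlaps a coding gene on the
#' opposite strand) over `sense_intronic` (transcript span contained in an
#' intron of a same-strand coding gene) over `intergenic_lncRNA`.
#'
#' @param transcript One row of a `transcript_set`.
#' @param annotation A `genome_annotation`.
#' @return One of `"antisense"`, `"sense_intronic"`, `"intergenic_lncRNA"`.
#' @export
classify_source <- function(transcript, annotation) {
  rng <- annotation_ranges(annotation)
  span <- GenomicRanges::GRanges(
    transcript$chrom,
    IRanges::IRanges(transcript$tx_start + 1L, transcript$tx_end),
    strand = transcript$strand)
  anti <- GenomicRanges::countOverlaps(
    span, BiocGenerics::invertStrand(rng$spans)) > 0L
  if (anti) return("antisense")
  within_intron <- GenomicRanges::countOverlaps(
    span, rng$introns, type = "within") > 0L
  if (within_intron) return("sense_intronic")
  "intergenic_lncRNA"
}

#' Check transcript-level expression of a peptide-coding region
#'
#' A peptide's coding region is called expressed only when *every* base of
#' every genomic interval lies within the sample's merged read-coverage
#' intervals — lncRNA-level overlap is not enough; the specific coding
#' region must be transcribed.
#'
#' @param genomic_intervals Data.frame of the peptide's genomic intervals.
#' @param coverage A `coverage_set` (see [read_coverage_bed()]).
#' @return Logical scalar.
#' @export
check_expression <- function(genomic_intervals, coverage) {
  iv <- coverage$intervals
  if (nrow(iv) == 0L) return(FALSE)
  cov <- GenomicRanges::GRanges(iv$chrom,
                                IRanges::IRanges(iv$start + 1L, iv$end))
  pg <- match_granges(genomic_intervals)
  all(GenomicRanges::countOverlaps(pg, cov, type = "within",
                                   ignore.strand = TRUE) > 0L)
}

#' Classify and annotate located matches
#'
#' Convenience wrapper applying [classify_region()], [classify_source()] and
#' (optionally) [check_expression()] to every located match.
#'
#' @param matches Output of [locate_matches()].
#' @param transcripts The `transcript_set`.
#' @param annotation A `genome_annotation`.
#' @param coverage_by_sample Optional named list of `coverage_set` objects
#'   keyed by sample; requires a `sample_id` column in `matches`.
#' @return `matches` with added columns `region_class`, `source_class` and
#'   (when coverage is given) `expressed`.
#' @export
classify_matches <- function(matches, transcripts, annotation,
                             coverage_by_sample = NULL) {
  idx <- match(matches$transcript_id, transcripts$transcript_id)
  n <- nrow(matches)
  region <- character(n); source <- character(n)
  expressed <- rep(NA, n)
  for (i in seq_len(n)) {
    region[i] <- classify_region(matches$genomic_intervals[[i]], annotation)
    source[i] <- classify_source(transcripts[idx[i], , drop = FALSE],
                                 annotation)
    if (!is.null(coverage_by_sample)) {
      cov <- coverage_by_sample[[matches$sample_id[i]]]
      if (is.null(cov)) stopf("no coverage for sample %s", matches$sample_id[i])
      expressed[i] <- check_expression(matches$genomic_intervals[[i]], cov)
    }
  }
  matches$region_class <- region
  matches$source_class <- source
  if (!is.null(coverage_by_sample)) matches$expressed <- expressed
  matches
}

#' Recover a peptide's nucleotide sequence from the genome
#'
#' Extracts the genomic bases of a peptide's coding intervals and
#' reassembles the transcript-orientation coding sequence (reverse
#' complemented for minus-strand matches). Translating the result must
#' reproduce the peptide — the round-trip guarantee of the coordinate
#' bookkeeping.
#'
#' @param genome Named character vector (or `id`/`sequence` data.frame) of
#'   chromosome sequences.
#' @param genomic_intervals Data.frame of the peptide's genomic intervals.
#' @return The coding nucleotide sequence, 5'->3' on the transcript strand.
#' @export
extract_coding_sequence <- function(genome, genomic_intervals) {
  if (is.data.frame(genome))
    genome <- stats::setNames(genome$sequence, genome$id)
  iv <- genomic_intervals[order(genomic_intervals$start), , drop = FALSE]
  pieces <- vapply(seq_len(nrow(iv)), function(i)
    substr(genome[[iv$chrom[i]]], iv$start[i] + 1L, iv$end[i]), "")
  nt <- paste(pieces, collapse = "")
  if (all(iv$strand == "-")) nt <- revcomp(nt)
  nt
}
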