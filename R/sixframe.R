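#' Six-frame translation of a nucleotide sequence
#'
#' Translates a transcript sequence in all six reading frames under the
#' standard genetic code: frames `+1..+3` read the stored sequence at offsets
#' 0..2, frames `-1..-3` read the reverse complement at offsets 0..2. Stop
#' codons are recorded as `*` and codons containing `N` translate to `X`
#' (which never matches a peptide residue). Trailing 1-2 nt that do not
#' complete a codon are dropped.
#'
#' @param sequence A nucleotide string over `{A,C,G,T,N}`, length >= 3.
#' @return A data.frame with one row per frame and columns `frame`
#'   (integer, one of 1, 2, 3, -1, -2, -3) and `aa_sequence`.
#' @examples
#' translate_six_frames("ATGAAATAG")
#' @export
translate_six_frames <- function(sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 3L) stopf("sequence shorter than one codon")
  if (grepl("[^ACGTN]", sequence))
    stopf("sequence contains characters outside {A,C,G,T,N}")
  ds <- Biostrings::DNAStringSet(sequence)
  aa <- six_frame_aa(ds)
  data.frame(frame = FRAME_IDS,
             aa_sequence = vapply(aa, function(x) as.character(x)[1], ""),
             stringsAsFactors = FALSE)
}

FRAME_IDS <- c(1L, 2L, 3L, -1L, -2L, -3L)

# Vectorised core: list of 6 AAStringSet (frames +1,+2,+3,-1,-2,-3), each
# parallel to the input set. Sequences shorter than offset+3 translate to "".
six_frame_aa <- function(ds) {
  rc <- Biostrings::reverseComplement(ds)
  out <- vector("list", 6L)
  for (f in 1:3) {
    out[[f]] <- translate_frame(ds, f)
    out[[f + 3L]] <- translate_frame(rc, f)
  }
  names(out) <- as.character(FRAME_IDS)
  out
}

translate_frame <- function(ds, offset1) {
  w <- Biostrings::width(ds)
  n_codon <- pmax((w - offset1 + 1L) %/% 3L, 0L)
  ends <- offset1 - 1L + 3L * n_codon
  empty <- n_codon == 0L
  starts <- ifelse(empty, 1L, offset1)
  ends <- ifelse(empty, 0L, ends)
  # no.init.codon: plain codon-table translation (a search space has no
  # privileged initiator; TTG/CTG must stay L, not become M)
  Biostrings::translate(Biostrings::subseq(ds, start = starts, end = ends),
                        if.fuzzy.codon = "X", no.init.codon = TRUE)
}

#' Stop-free segments of a frame translation
#'
#' Splits a translated frame at stop codons (`*`) into maximal stop-free
#' runs. A presented peptide cannot span a stop codon, so downstream peptide
#' matching is confined to these segments.
#'
#' @param aa_sequence Amino-acid string possibly containing `*`.
#' @return Data.frame with columns `aa_start` (0-based offset of the segment
#'   in the frame) and `segment`. Empty runs (adjacent stops) are omitted.
#' @export
frame_segments <- function(aa_sequence) {
  if (!nzchar(aa_sequence))
    return(data.frame(aa_start = integer(0), segment = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(aa_sequence, "*", fixed = TRUE)[[1]]
  if (length(parts) == 0L) parts <- ""
  # strsplit drops trailing empty strings; starts derive from cumulated widths
  starts <- cumsum(c(0L, nchar(parts) + 1L))[seq_along(parts)]
  keep <- nzchar(parts)
  data.frame(aa_start = as.integer(starts[keep]), segment = parts[keep],
             stringsAsFactors = FALSE)
}

#' Build the six-frame translated protein database
#'
#' Translates every transcript in all six frames, producing one database
#' entry per (transcript, frame) — so a set of N transcripts yields exactly
#' 6N protein entries. Entry IDs encode the transcript ID and frame
#' reversibly as `<transcript_id>|F<frame>`.
#'
#' @param transcripts A `transcript_set` (see [read_bed12()]), or a
#'   data.frame with columns `transcript_id` and `sequence`.
#' @return A `translated_db`: data.frame with columns `entry_id`,
#'   `transcript_id`, `frame` and `aa_sequence`.
#' @export
build_translated_db <- function(transcripts) {
  if (nrow(transcripts) == 0L) stopf("empty transcript set")
  if (any(nchar(transcripts$sequence) < 3L))
    stopf("transcript(s) shorter than one codon: %s",
          paste(transcripts$transcript_id[nchar(transcripts$sequence) < 3L],
                collapse = ", "))
  bad <- grepl("[^ACGTN]", toupper(transcripts$sequence))
  if (any(bad))
    stopf("transcript(s) with invalid residues: %s",
          paste(transcripts$transcript_id[bad], collapse = ", "))
  ds <- Biostrings::DNAStringSet(toupper(transcripts$sequence))
  aa <- six_frame_aa(ds)
  n <- nrow(transcripts)
  db <- data.frame(
    entry_id = paste0(rep(transcripts$transcript_id, times = 6L), "|F",
                      rep(FRAME_IDS, each = n)),
    transcript_id = rep(transcripts$transcript_id, times = 6L),
    frame = rep(FRAME_IDS, each = n),
    aa_sequence = unlist(lapply(aa, as.character), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  class(db) <- c("translated_db", "data.frame")
  db
}

#' Parse a translated-database entry ID
#'
#' @param entry_id Entry ID of the form `<transcript_id>|F<frame>`.
#' @return List with `transcript_id` and `frame`.
#' @export
parse_entry_id <- function(entry_id) {
  m <- regmatches(entry_id, regexec("^(.*)\\|F(-?[123])$", entry_id))[[1]]
  if (length(m) != 3L) stopf("malformed translated-DB entry ID: %s", entry_id)
  list(transcript_id = m[2], frame = as.integer(m[3]))
}

#' Map an amino-acid interval to transcript nucleotide coordinates
#'
#' Converts an amino-acid window in a reading frame to the 0-based half-open
#' nucleotide interval on the *stored* transcript orientation (5'->3' on the
#' transcript strand). Reverse-frame windows are mirrored back onto the
#' stored sequence.
#'
#' @param frame Frame ID, one of 1, 2, 3, -1, -2, -3.
#' @param aa_start 0-based amino-acid start index within the frame.
#' @param aa_len Number of amino acids.
#' @param transcript_len Transcript length in nucleotides.
#' @return Integer vector `c(nt_start, nt_end)`, 0-based half-open.
#' @export
aa_to_nt_interval <- function(frame, aa_start, aa_len, transcript_len) {
  if (!frame %in% FRAME_IDS) stopf("invalid frame: %s", frame)
  if (aa_len < 1L || aa_start < 0L) stopf("invalid amino-acid window")
  offset <- abs(frame) - 1L
  n_codon <- (transcript_len - offset) %/% 3L
  if (aa_start + aa_len > n_codon)
    stopf("amino-acid window [%d, %d) exceeds frame %d of a %d-nt transcript",
          aa_start, aa_start + aa_len, frame, transcript_len)
  if (frame > 0L) {
    nt_start <- offset + 3L * aa_start
  } else {
    nt_start <- transcript_len - offset - 3L * (aa_start + aa_len)
  }
  c(nt_start, nt_start + 3L * aa_len)
}
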