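# Internal helpers shared across modules.

# All occurrences (including overlapping ones) of a fixed pattern in a string.
# Returns 0-based start positions. gregexpr() skips overlapping hits, which
# would lose tandem-repeat peptide placements, so we advance one character at
# a time.
str_find_all <- function(text, pattern) {
  starts <- integer(0)
  from <- 1L
  n <- nchar(text)
  w <- nchar(pattern)
  while (from + w - 1L <= n) {
    hit <- regexpr(pattern, substr(text, from, n), fixed = TRUE)
    if (hit == -1L) break
    pos <- from + as.integer(hit) - 1L
    starts <- c(starts, pos - 1L)
    from <- pos + 1L
  }
  starts
}

# Collapse isoleucine/leucine to a single symbol ('J', unused by the standard
# code) so that MS-indistinguishable residues compare equal.
il_collapse <- function(x) chartr("IL", "JJ", x)

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

is_valid_peptide <- function(x) {
  nchar(x) > 0L & !grepl(paste0("[^", paste(AA20, collapse = ""), "]"), x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
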