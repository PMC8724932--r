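#' Decoy-database sampling parameters
#'
#' Defaults mirror the decoy construction used for the significance
#' analysis: 50,000 non-overlapping genomic segments of 2,000 nt each (the
#' mean lncRNA length in the transcript compendium), sampled uniformly at
#' random from the reference genome.
#'
#' @param n_segments Number of decoy segments.
#' @param segment_len_nt Segment length in nucleotides (>= 33, one average
#'   peptide-coding stretch).
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @param exclude_N Resample segments containing `N` bases.
#' @return A `decoy_config` list.
#' @export
decoy_config <- function(n_segments = 50000L, segment_len_nt = 2000L,
                         seed = 1L, exclude_N = TRUE) {
  if (n_segments < 1L) stopf("n_segments must be >= 1")
  if (segment_len_nt < 33L) stopf("segment_len_nt must be >= 33")
  structure(list(n_segments = as.integer(n_segments),
                 segment_len_nt = as.integer(segment_len_nt),
                 seed = as.integer(seed), exclude_N = isTRUE(exclude_N)),
            class = "decoy_config")
}

#' Sample non-overlapping decoy segments from a genome
#'
#' Draws `n_segments` pairwise non-overlapping intervals of fixed length,
#' each fully inside one chromosome, uniformly at random by rejection
#' sampling of start positions. Segments containing `N` are resampled when
#' `exclude_N`. Output is deterministic for a given seed.
#'
#' @param genome Named character vector (or `id`/`sequence` data.frame) of
#'   chromosome sequences.
#' @param config A [decoy_config()].
#' @return Data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `name` and `sequence`, in sampling order.
#' @export
generate_decoy_segments <- function(genome, config = decoy_config()) {
  if (is.data.frame(genome))
    genome <- stats::setNames(genome$sequence, genome$id)
  len <- config$segment_len_nt
  chrom_len <- vapply(genome, nchar, 0L)
  usable <- pmax(chrom_len - len + 1L, 0L)
  if (sum(as.numeric(chrom_len[usable > 0L])) < as.numeric(config$n_segments) * len)
    stopf("genome too small: need %.0f usable nt for %d segments of %d nt",
          as.numeric(config$n_segments) * len, config$n_segments, len)
  # cumulative layout over per-chromosome start positions
  chroms <- names(genome)[usable > 0L]
  u <- as.numeric(usable[usable > 0L])
  cum <- cumsum(u)
  total <- cum[length(cum)]
  taken <- stats::setNames(vector("list", length(chroms)), chroms)
  out_chrom <- character(config$n_segments)
  out_start <- integer(config$n_segments)
  out_seq <- character(config$n_segments)
  with_seed(config$seed, {
    got <- 0L
    attempts <- 0L
    max_attempts <- 1000L * config$n_segments + 10000L
    while (got < config$n_segments) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stopf("decoy sampling failed after %d attempts; genome too crowded",
              attempts)
      x <- floor(stats::runif(1) * total)
      ci <- findInterval(x, cum) + 1L
      start <- as.integer(x - c(0, cum)[ci])
      chrom <- chroms[ci]
      prev <- taken[[chrom]]
      if (!is.null(prev) &&
          any(start < prev[, 2L] & prev[, 1L] < start + len)) next
      seg <- substr(genome[[chrom]], start + 1L, start + len)
      if (config$exclude_N && grepl("N", seg, fixed = TRUE)) next
      got <- got + 1L
      taken[[chrom]] <- rbind(prev, c(start, start + len))
      out_chrom[got] <- chrom
      out_start[got] <- start
      out_seq[got] <- seg
    }
  })
  data.frame(chrom = out_chrom, start = out_start, end = out_start + len,
             name = sprintf("decoy_%05d", seq_len(config$n_segments)),
             sequence = out_seq, stringsAsFactors = FALSE)
}

#' Chance probability of a single peptide match
#'
#' The null model's per-candidate match probability: observed decoy matches
#' divided by the number of candidate peptide positions in the decoy
#' database,
#' \deqn{p = m / (n_{transcripts} \times frames \times seg\_len / pep\_nt).}
#' With the default decoy construction (66 matches, 50,000 segments, 6
#' frames, 2,000 nt segments, 33 nt per average peptide) this evaluates to
#' 3.63e-6.
#'
#' @param m Observed match count in the decoy database.
#' @param n_transcripts Number of decoy segments ("transcripts").
#' @param frames Reading frames per segment (6).
#' @param seg_len Segment length in nucleotides.
#' @param pep_nt Nucleotides per average peptide (33 for an 11-mer).
#' @return The chance-match probability.
#' @export
p_chance <- function(m, n_transcripts, frames = 6L, seg_len = 2000L,
                     pep_nt = 33L) {
  if (n_transcripts <= 0 || frames <= 0 || seg_len <= 0 || pep_nt <= 0)
    stopf("all denominator counts must be positive")
  if (m < 0) stopf("m must be nonnegative")
  denom <- n_transcripts * frames * seg_len / pep_nt
  if (m > denom) stopf("m exceeds the number of candidate positions")
  m / denom
}

#' Upper-tail binomial probability P(X >= k)
#'
#' Numerically stable survival function of the binomial distribution,
#' evaluated by log-space term recursion: the leading term is computed via
#' log-gamma binomial coefficients and successive terms by the exact ratio
#' \eqn{t_{j+1}/t_j = (n-j)p / ((j+1)(1-p))}, summing whichever tail is
#' smaller. Handles n of order 1e7+ with p of order 1e-6 without overflow
#' or cancellation.
#'
#' @param k Match count (the tail starts at `k`).
#' @param n Number of candidate trials.
#' @param p Per-trial success probability.
#' @return P(X >= k) for X ~ Binomial(n, p).
#' @export
binomial_tail <- function(k, n, p) {
  if (length(k) != 1L || length(n) != 1L || length(p) != 1L)
    stopf("k, n, p must be scalars")
  if (is.na(k) || is.na(n) || is.na(p)) stopf("k, n, p must be non-missing")
  if (n < 0 || k < 0 || k > n) stopf("require 0 <= k <= n")
  if (p < 0 || p > 1) stopf("require 0 <= p <= 1")
  if (k == 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  q <- 1 - p
  log_term <- function(j) lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)
  if (k > n * p) {
    # sum the upper tail directly; terms decrease
    term <- exp(log_term(k))
    s <- term
    j <- k
    while (j < n) {
      term <- term * ((n - j) * p) / ((j + 1) * q)
      s <- s + term
      j <- j + 1
      if (term <= s * 1e-17) break
    }
    min(s, 1)
  } else {
    # complement of the lower tail; sum j = k-1 downward
    j <- k - 1
    term <- exp(log_term(j))
    s <- term
    while (j > 0) {
      term <- term * (j * q) / ((n - j + 1) * p)
      s <- s + term
      j <- j - 1
      if (term <= s * 1e-17) break
    }
    max(1 - s, 0)
  }
}

#' Null-model parameters for the empirical p-value
#'
#' Bundles the decoy-derived chance probability inputs with the observed
#' real-database match count. The number of candidate trials is
#' `n_real_transcripts * frames * mean_len_nt / pep_nt` (each transcript
#' contributes `frames * mean_len_nt / pep_nt` potential peptides).
#'
#' @param m_decoy_matches Matches observed against the decoy database.
#' @param n_decoy_transcripts Decoy segment count.
#' @param frames Reading frames (6).
#' @param segment_len_nt Decoy segment length.
#' @param peptide_len_nt Nucleotides per average peptide (33).
#' @param n_real_transcripts Transcript count of the real database.
#' @param mean_len_nt Mean transcript length of the real database.
#' @param k_observed Matches observed against the real database.
#' @return A `null_model_params` list.
#' @export
null_model_params <- function(m_decoy_matches, n_decoy_transcripts = 50000L,
                              frames = 6L, segment_len_nt = 2000L,
                              peptide_len_nt = 33L, n_real_transcripts,
                              mean_len_nt = 2000L, k_observed) {
  structure(list(m_decoy_matches = m_decoy_matches,
                 n_decoy_transcripts = n_decoy_transcripts, frames = frames,
                 segment_len_nt = segment_len_nt,
                 peptide_len_nt = peptide_len_nt,
                 n_real_transcripts = n_real_transcripts,
                 mean_len_nt = mean_len_nt, k_observed = k_observed),
            class = "null_model_params")
}

#' Empirical p-value of the observed match count
#'
#' Chains the chance-probability and binomial-tail computations: the decoy
#' database fixes the per-candidate chance probability `p`, the real
#' database size fixes the number of candidate trials `n`, and the p-value
#' is P(X >= k) for X ~ Binomial(n, p) — the probability of seeing at least
#' the observed number of matches if every match were a chance event.
#'
#' @param params A [null_model_params()] object.
#' @return List with `p_chance`, `n_candidates`, `k_observed` and `p_value`.
#' @export
empirical_pvalue <- function(params) {
  p <- p_chance(params$m_decoy_matches, params$n_decoy_transcripts,
                params$frames, params$segment_len_nt, params$peptide_len_nt)
  n <- round(params$n_real_transcripts * params$frames *
               params$mean_len_nt / params$peptide_len_nt)
  if (params$k_observed > n)
    stopf("k_observed (%d) exceeds candidate count (%.0f)",
          params$k_observed, n)
  list(p_chance = p, n_candidates = n, k_observed = params$k_observed,
       p_value = binomial_tail(params$k_observed, n, p))
}
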