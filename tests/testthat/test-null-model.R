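# enumeration oracle: direct summation of C(n,j) p^j (1-p)^(n-j)
enum_tail <- function(k, n, p) {
  if (k == 0) return(1)
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - k:n))
}

test_that("decoy segments are disjoint, in-bounds, and seed-reproducible", {
  genome <- c(c1 = random_dna(6000, 1), c2 = random_dna(4000, 2))
  cfg <- decoy_config(n_segments = 3L, segment_len_nt = 2000L, seed = 1L)
  seg <- generate_decoy_segments(genome, cfg)
  expect_equal(nrow(seg), 3L)
  expect_true(all(seg$end - seg$start == 2000L))
  expect_true(all(seg$start >= 0))
  for (chr in unique(seg$chrom)) {
    s <- seg[seg$chrom == chr, ]
    expect_true(all(s$end <= nchar(genome[[chr]])))
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
  # segment sequences match the genome
  expect_equal(seg$sequence[1],
               substr(genome[[seg$chrom[1]]], seg$start[1] + 1, seg$end[1]))
  # identical seed, identical output (byte-level on the BED)
  seg2 <- generate_decoy_segments(genome, cfg)
  expect_identical(seg, seg2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_bed6(seg[, c("chrom", "start", "end", "name")], f1)
  write_bed6(seg2[, c("chrom", "start", "end", "name")], f2)
  expect_true(files_identical_bytes(f1, f2))
  # a different seed moves the segments
  seg3 <- generate_decoy_segments(genome, decoy_config(3L, 2000L, seed = 99L))
  expect_false(identical(seg$start, seg3$start))
  # over-capacity request errors
  expect_error(generate_decoy_segments(genome, decoy_config(10L, 2000L)),
               "too small")
})

test_that("the chance probability follows the decoy-normalised formula", {
  expect_equal(signif(p_chance(66, 50000, 6, 2000, 33), 3), 3.63e-6)
  expect_equal(p_chance(0, 50000, 6, 2000, 33), 0)
  expect_equal(p_chance(1, 1, 1, 33, 33), 1)
  expect_error(p_chance(2, 1, 1, 33, 33), "exceeds")
  expect_error(p_chance(1, 0, 6, 2000, 33), "positive")
})

test_that("binomial_tail matches exhaustive enumeration to 1e-12", {
  expect_equal(binomial_tail(0, 10, 0.5), 1.0)
  expect_equal(binomial_tail(5, 10, 0.5), 638 / 1024)
  for (n in c(1, 2, 5, 13, 30)) {
    for (p in c(0.1, 0.5, 0.9)) {
      for (k in 0:n) {
        expect_equal(binomial_tail(k, n, p), enum_tail(k, n, p),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("binomial_tail keeps 1e-9 relative accuracy at n up to 1000", {
  for (n in c(200, 1000)) {
    for (p in c(0.003, 0.05, 0.4)) {
      for (k in unique(pmin(n, c(0, 1, round(n * p), round(n * p * 2), n)))) {
        ref <- enum_tail(k, n, p)
        if (ref > 1e-280)
          expect_equal(binomial_tail(k, n, p), ref,
                       tolerance = 1e-9)
      }
    }
  }
})

test_that("binomial_tail is monotone in k and p and matches stats::pbinom", {
  n <- 5000; p <- 1e-3
  tails <- vapply(0:30, binomial_tail, 0, n = n, p = p)
  expect_true(all(diff(tails) <= 0))
  ps <- c(1e-4, 1e-3, 1e-2, 0.1)
  at_k <- vapply(ps, function(pp) binomial_tail(10, n, pp), 0)
  expect_true(all(diff(at_k) >= 0))
  for (k in c(0, 3, 10, 25))
    expect_equal(binomial_tail(k, n, p),
                 stats::pbinom(k - 1, n, p, lower.tail = FALSE),
                 tolerance = 1e-12)
})

test_that("binomial and Poisson tails agree for large n, moderate np", {
  n <- 1e6
  for (np in c(50, 100, 200, 500)) {
    p <- np / n
    k <- round(np * 1.2)
    b <- binomial_tail(k, n, p)
    pois <- stats::ppois(k - 1, np, lower.tail = FALSE)
    expect_lt(abs(b - pois) / pois, 0.02)
  }
})

test_that("empirical p-value chains chance probability and binomial tail", {
  params <- null_model_params(m_decoy_matches = 66,
                              n_real_transcripts = 107039,
                              k_observed = 195)
  res <- empirical_pvalue(params)
  expect_equal(res$p_chance, 3.63e-6, tolerance = 1e-3)
  expect_equal(res$n_candidates, round(107039 * 12000 / 33))
  expect_equal(res$p_value, 1.1e-5, tolerance = 0.1)
  # k = 0 spans the whole sample space
  params0 <- null_model_params(m_decoy_matches = 66,
                               n_real_transcripts = 107039, k_observed = 0)
  expect_equal(empirical_pvalue(params0)$p_value, 1.0)
  # doubling the decoy match rate with k fixed raises the p-value
  params2 <- null_model_params(m_decoy_matches = 132,
                               n_real_transcripts = 107039, k_observed = 195)
  expect_gt(empirical_pvalue(params2)$p_value, res$p_value)
})
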