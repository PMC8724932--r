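# Brute-force oracle: scan all six frame translations of all transcripts for
# a peptide with a simple character loop, respecting stop segmentation.
oracle_scan <- function(peptide, transcripts) {
  hits <- list()
  key <- chartr("IL", "JJ", peptide)
  for (i in seq_len(nrow(transcripts))) {
    fr <- translate_six_frames(transcripts$sequence[i])
    for (j in seq_len(nrow(fr))) {
      aa <- chartr("IL", "JJ", fr$aa_sequence[j])
      n <- nchar(aa); w <- nchar(peptide)
      if (n < w) next
      for (start in 0:(n - w)) {
        win <- substr(aa, start + 1, start + w)
        if (win == key && !grepl("*", win, fixed = TRUE))
          hits[[length(hits) + 1L]] <- data.frame(
            peptide = peptide, transcript_id = transcripts$transcript_id[i],
            frame = fr$frame[j], aa_start = start)
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else NULL
}

test_that("peptide matching finds planted occurrences and respects stops", {
  tx <- data.frame(transcript_id = "t1",
                   sequence = "ATGAAACCCGGGTAGATGTTT")
  db <- build_translated_db(tx)
  aa <- db$aa_sequence[db$frame == 1]   # MKPG*MF
  expect_equal(aa, "MKPG*MF")
  hits <- match_peptides("KPG", db)
  expect_equal(hits$aa_start, 1L)
  expect_equal(hits$frame, 1L)
  # a window spanning the stop never matches
  expect_equal(nrow(match_peptides("PGM", db)), 0L)
  expect_equal(nrow(match_peptides("G*M", db)), 0L)
})

test_that("matching equals the exhaustive six-frame scan on fixtures", {
  u <- fixture_universe()
  tx <- u$transcripts[1:6, ]
  db <- build_translated_db(tx)
  spiked <- u$truth[u$truth$origin == "lncRNA_spiked" &
                      u$truth$transcript_id %in% tx$transcript_id, ]
  peps <- c(spiked$peptide[1:8], "WWWWWWWW")
  got <- match_peptides(peps, db)
  oracle <- do.call(rbind, lapply(peps, oracle_scan, transcripts = tx))
  ord <- function(d) {
    d <- d[order(d$peptide, d$transcript_id, d$frame, d$aa_start), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(got), ord(oracle))
})

test_that("a peptide planted in two transcripts yields two matches", {
  common <- "ATGGATTACAAGGATGACGACGATAAG"
  tx <- data.frame(
    transcript_id = c("a", "b"),
    sequence = c(paste0(common, "GGGTTT"), paste0("CCCACC", common)))
  db <- build_translated_db(tx)
  hits <- match_peptides("MDYKDDDDK", db)
  expect_equal(nrow(hits), 2L)
  expect_equal(sort(hits$transcript_id), c("a", "b"))
})

test_that("transcript intervals project through blocks to the genome", {
  one <- data.frame(transcript_id = "t", chrom = "chr1", strand = "+",
                    tx_start = 100L, tx_end = 130L)
  one$block_starts <- list(100L); one$block_sizes <- list(30L)
  expect_equal(map_to_genome(one, 3L, 12L),
               data.frame(chrom = "chr1", start = 103L, end = 112L,
                          strand = "+"))
  two <- data.frame(transcript_id = "t", chrom = "chr1", strand = "+",
                    tx_start = 100L, tx_end = 170L)
  two$block_starts <- list(c(100L, 150L)); two$block_sizes <- list(c(10L, 20L))
  expect_equal(map_to_genome(two, 6L, 15L),
               data.frame(chrom = "chr1", start = c(106L, 150L),
                          end = c(110L, 155L), strand = c("+", "+")))
  minus <- one; minus$strand <- "-"
  expect_equal(map_to_genome(minus, 0L, 9L),
               data.frame(chrom = "chr1", start = 121L, end = 130L,
                          strand = "-"))
  expect_error(map_to_genome(one, 10L, 40L), "outside")
})

test_that("block projection agrees with a per-base oracle on random structures", {
  set.seed(42)
  for (rep in 1:12) {
    n_blocks <- sample(1:4, 1)
    sizes <- sample(3:20, n_blocks, replace = TRUE)
    gaps <- sample(5:50, n_blocks)
    starts <- 1000L + cumsum(gaps) + cumsum(c(0L, sizes[-n_blocks]))
    strand <- sample(c("+", "-"), 1)
    L <- sum(sizes)
    tr <- data.frame(transcript_id = "t", chrom = "chrZ", strand = strand,
                     tx_start = starts[1], tx_end = starts[n_blocks] +
                       sizes[n_blocks])
    tr$block_starts <- list(as.integer(starts))
    tr$block_sizes <- list(as.integer(sizes))
    # per-base oracle: genomic position of each transcript base
    plus_layout <- unlist(mapply(function(s, w) s:(s + w - 1), starts, sizes,
                                 SIMPLIFY = FALSE))
    base_of <- if (strand == "+") plus_layout else rev(plus_layout)
    s0 <- sample(0:(L - 2), 1)
    e0 <- sample((s0 + 1):L, 1)
    iv <- map_to_genome(tr, s0, e0)
    got_bases <- sort(unlist(mapply(function(s, e) s:(e - 1), iv$start,
                                    iv$end, SIMPLIFY = FALSE)))
    expect_equal(got_bases, sort(base_of[(s0 + 1):e0]))
    expect_equal(sum(iv$end - iv$start), e0 - s0)
    expect_false(is.unsorted(iv$start, strictly = TRUE))
  }
})

test_that("region classification follows the CDS > intronic > noncoding precedence", {
  u <- fixture_universe()
  ann <- u$annotation
  g <- ann$genes[1, ]
  cds1 <- ann$cds[ann$cds$gene_id == g$gene_id, ][1, ]
  iv <- function(chrom, s, e, strand = "+")
    data.frame(chrom = chrom, start = s, end = e, strand = strand)
  # fully intergenic
  expect_equal(classify_region(iv(g$chrom, 10L, 40L), ann), "noncoding")
  # inside the gene span, between exons
  expect_equal(classify_region(iv(g$chrom, g$start + 700L, g$start + 730L),
                               ann), "intronic")
  # overlapping a CDS exon (any strand)
  expect_equal(classify_region(iv(g$chrom, cds1$start + 3L, cds1$start + 33L,
                                  "-"), ann), "novel_orf")
  # unannotated chromosome -> noncoding with a warning
  expect_warning(cls <- classify_region(iv("chrUn", 0L, 30L), ann),
                 "unannotated")
  expect_equal(cls, "noncoding")
})

test_that("region classification is invariant to interval splitting", {
  u <- fixture_universe()
  matches <- match_peptides(
    u$truth$peptide[u$truth$origin == "lncRNA_spiked"][1:12],
    build_translated_db(u$transcripts))
  matches <- locate_matches(matches, u$transcripts)
  for (i in seq_len(nrow(matches))) {
    iv <- matches$genomic_intervals[[i]]
    merged <- data.frame(chrom = iv$chrom[1], start = min(iv$start),
                         end = max(iv$end), strand = iv$strand[1])
    expect_equal(classify_region(iv, u$annotation),
                 classify_region(merged, u$annotation))
  }
})

test_that("source classification recovers the constructed class of every lncRNA", {
  u <- fixture_universe()
  for (i in seq_len(nrow(u$transcripts))) {
    expect_equal(
      classify_source(u$transcripts[i, , drop = FALSE], u$annotation),
      u$transcripts$true_source[i])
  }
})

test_that("expression requires full coverage of the peptide-coding region", {
  iv <- data.frame(chrom = "chr1", start = 100L, end = 130L, strand = "+")
  cov <- function(d) structure(list(sample_id = "s", intervals = d),
                               class = "coverage_set")
  full <- cov(data.frame(chrom = "chr1", start = 50L, end = 200L))
  expect_true(check_expression(iv, full))
  onebp_short <- cov(data.frame(chrom = "chr1", start = 101L, end = 200L))
  expect_false(check_expression(iv, onebp_short))
  empty <- cov(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0)))
  expect_false(check_expression(iv, empty))
})

test_that("genome extraction and translation round-trips every fixture match", {
  u <- fixture_universe()
  spiked <- u$truth[u$truth$origin == "lncRNA_spiked", ]
  matches <- locate_matches(
    match_peptides(spiked$peptide, build_translated_db(u$transcripts)),
    u$transcripts)
  expect_equal(nrow(matches), nrow(spiked))
  for (i in seq_len(nrow(matches))) {
    nt <- extract_coding_sequence(u$genome, matches$genomic_intervals[[i]])
    expect_equal(oracle_translate(nt), matches$peptide[i])
  }
})
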