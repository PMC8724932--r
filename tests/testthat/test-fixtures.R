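test_that("genome and gene models are deterministic and well-formed", {
  g1 <- make_genome(seed = 7)
  g2 <- make_genome(seed = 7)
  expect_identical(g1, g2)
  g3 <- make_genome(seed = 8)
  expect_false(identical(g1$genome, g3$genome))
  ann <- g1$annotation
  for (i in seq_len(nrow(ann$genes))) {
    id <- ann$genes$gene_id[i]
    ex <- ann$exons[ann$exons$gene_id == id, ]
    cd <- ann$cds[ann$cds$gene_id == id, ]
    expect_true(all(ex$start >= ann$genes$start[i] &
                      ex$end <= ann$genes$end[i]))
    expect_true(all(vapply(seq_len(nrow(cd)), function(j)
      any(cd$start[j] >= ex$start & cd$end[j] <= ex$end), NA)))
    expect_true(ann$genes$end[i] <= nchar(g1$genome[[ann$genes$chrom[i]]]))
  }
})

test_that("generated lncRNAs carry their constructed source class and round-trip BED12", {
  u <- fixture_universe()
  expect_equal(unname(table(u$transcripts$true_source)[
    c("antisense", "sense_intronic", "intergenic_lncRNA")]),
    c(6L, 5L, 5L), ignore_attr = TRUE)
  # spliced sequence length equals the block sum for every transcript
  expect_true(all(vapply(seq_len(nrow(u$transcripts)), function(i)
    sum(u$transcripts$block_sizes[[i]]) ==
      nchar(u$transcripts$sequence[i]), NA)))
})

test_that("spiked peptides are recoverable, proteome peptides excluded, decoys absent", {
  u <- fixture_universe()
  db <- build_translated_db(u$transcripts)
  truth <- u$truth
  spiked <- truth[truth$origin == "lncRNA_spiked", ]
  hits <- match_peptides(spiked$peptide, db)
  # each spiked peptide occurs exactly once, at its recorded location
  expect_equal(nrow(hits), nrow(spiked))
  m <- merge(hits, spiked, by = "peptide")
  expect_equal(m$transcript_id.x, m$transcript_id.y)
  expect_equal(m$frame.x, m$frame.y)
  expect_equal(m$aa_start.x, m$aa_start.y)
  # proteome-substring peptides are all removed by exclusion
  prot <- truth$peptide[truth$origin == "proteome_substring"]
  expect_equal(exclude_proteome(prot, u$proteome), character(0))
  # decoy peptides match nothing
  dec <- truth$peptide[truth$origin == "random_decoy"]
  expect_equal(nrow(match_peptides(dec, db)), 0L)
  expect_equal(sort(exclude_proteome(dec, u$proteome)), sort(dec))
})

test_that("rank-table designation drives the binder filter exactly", {
  u <- fixture_universe()
  peps <- data.frame(peptide = u$truth$peptide[1:20],
                     sample_id = u$truth$sample_id[1:20])
  all_b <- make_rank_table(peps, u$alleles_by_sample, binder = 1.0, seed = 2)
  got <- filter_binders(peps, all_b$calls, u$alleles_by_sample)
  expect_equal(sort(got$peptide), sort(peps$peptide))
  none <- make_rank_table(peps, u$alleles_by_sample, binder = 0.0, seed = 2)
  expect_equal(nrow(filter_binders(peps, none$calls, u$alleles_by_sample)),
               0L)
  # a designated half is recovered exactly
  flags <- rep(c(TRUE, FALSE), 10)
  half <- make_rank_table(peps, u$alleles_by_sample, binder = flags, seed = 2)
  got_half <- filter_binders(peps, half$calls, u$alleles_by_sample)
  expect_equal(sort(got_half$peptide), sort(peps$peptide[flags]))
})

test_that("the universe is deterministic under a seed and includes negative expression cases", {
  u1 <- fixture_universe()
  u2 <- make_fixture_universe(seed = 1)
  expect_identical(u1$truth, u2$truth)
  expect_identical(u1$observations, u2$observations)
  expect_identical(u1$calls, u2$calls)
  spiked <- u1$truth[u1$truth$origin == "lncRNA_spiked", ]
  expect_true(any(!spiked$expressed))   # truncated-transcript cases
  expect_true(any(spiked$expressed))
  expect_true(any(spiked$alc <= 50))    # failing-ALC mix
})

test_that("fixture directories are written in readable standard formats", {
  u <- fixture_universe()
  dir <- withr::local_tempdir()
  write_fixture_dir(u, dir)
  expect_equal(read_fasta(file.path(dir, "genome.fa"))$sequence,
               unname(u$genome))
  tx <- read_bed12(file.path(dir, "transcripts.bed"),
                   read_fasta(file.path(dir, "transcripts.fa")))
  expect_equal(tx$sequence, u$transcripts$sequence)
  obs <- read_peptide_table(file.path(dir, "peptides.tsv"))
  expect_equal(obs$peptide, u$observations$peptide)
  calls <- read_rank_table(file.path(dir, "ranks.tsv"))
  expect_equal(sort(unique(calls$peptide)),
               sort(unique(u$calls$peptide)))
  cov <- read_coverage_bed(file.path(dir, "coverage_s1.bed"), "s1")
  expect_equal(cov$intervals, u$coverage_by_sample$s1$intervals,
               ignore_attr = TRUE)
})
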