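test_that("FASTA reading handles single records, folding, and normalisation", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT"), f)
  expect_equal(read_fasta(f), data.frame(id = "a", sequence = "ACGT"))

  writeLines(c(">w desc ignored", "ACGTAC", "GTACGT", "AC"), f)
  expect_equal(read_fasta(f)$sequence, "ACGTACGTACGTAC")
  expect_equal(read_fasta(f)$id, "w")

  writeLines(c(">r", "acgu"), f)
  expect_equal(read_fasta(f, u_to_t = TRUE)$sequence, "ACGT")
})

test_that("FASTA reading rejects duplicate IDs and empty sequences", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate.*a")
  writeLines(c(">a", "ACGT", ">b", "", ">c", "GG"), f)
  expect_error(read_fasta(f), "empty sequence.*b")
})

test_that("FASTA write/read round-trips records exactly", {
  f <- withr::local_tempfile(fileext = ".fa")
  recs <- data.frame(id = c("x1", "x2", "x3"),
                     sequence = c("ACGTACGTAA", strrep("ACGT", 40), "TTTT"))
  write_fasta(recs, f)
  expect_equal(read_fasta(f), recs)
})

test_that("BED12 transcripts parse with absolute block coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("chr1", 100, 130, "t1", 0, "+", 100, 100, "0", 1,
                   "30,", "0,", sep = "\t"), bed)
  seqs <- c(t1 = strrep("ACG", 10))
  tx <- read_bed12(bed, seqs)
  expect_equal(tx$block_starts[[1]], 100L)
  expect_equal(tx$block_sizes[[1]], 30L)
  expect_equal(tx$tx_start, 100L)

  writeLines(paste("chr1", 100, 170, "t2", 0, "+", 100, 100, "0", 2,
                   "10,20,", "0,50,", sep = "\t"), bed)
  tx2 <- read_bed12(bed, c(t2 = strrep("A", 30)))
  expect_equal(tx2$block_starts[[1]], c(100L, 150L))
  # block sum != sequence length is rejected, naming the transcript
  expect_error(read_bed12(bed, c(t2 = strrep("A", 29))), "t2.*sum")
})

test_that("BED12 dialect guard rejects non-relative blockStarts", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("chr1", 100, 130, "t1", 0, "+", 100, 100, "0", 1,
                   "30,", "100,", sep = "\t"), bed)
  expect_error(read_bed12(bed, c(t1 = strrep("A", 30))),
               "relative to chromStart")
})

test_that("BED12 write/read round-trips a multi-block transcript set", {
  u <- fixture_universe()
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed12(u$transcripts, bed)
  back <- read_bed12(bed, stats::setNames(u$transcripts$sequence,
                                          u$transcripts$transcript_id))
  expect_equal(back$transcript_id, u$transcripts$transcript_id)
  expect_equal(back$block_starts, u$transcripts$block_starts)
  expect_equal(back$block_sizes, u$transcripts$block_sizes)
  expect_equal(back$strand, u$transcripts$strand)
  expect_equal(back$sequence, u$transcripts$sequence)
})

test_that("peptide tables parse, strip PTM annotations, and validate", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("peptide\talc\tsample",
               "SIINFEKL\t92.1\ts1",
               "M(+15.99)PEPTIDE\t77\ts2"), f)
  tab <- read_peptide_table(f)
  expect_equal(tab$peptide, c("SIINFEKL", "MPEPTIDE"))
  expect_equal(tab$alc, c(92.1, 77))
  expect_equal(tab$sample_id, c("s1", "s2"))
  expect_equal(tab$modifications, c("", "(+15.99)"))
  expect_equal(tab$origin, rep("de_novo_only", 2))

  writeLines(c("peptide\talc\tsample", "SIINFEKL\tabc\ts1"), f)
  expect_error(read_peptide_table(f), "row.*1")
  writeLines(c("peptide\tsample", "SIINFEKL\ts1"), f)
  expect_error(read_peptide_table(f), "alc")
  writeLines(c("peptide\talc\tsample", "SIINFEB1\t50\ts1"), f)
  expect_error(read_peptide_table(f), "non-amino-acid")
})

test_that("rank tables parse, collapse duplicates to the minimum, and validate", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("peptide\tallele\trank", "FLLSSSLTL\tHLA-A*02:06\t0.11"), f)
  calls <- read_rank_table(f)
  expect_equal(calls$rank_percent, 0.11)
  expect_equal(calls$allele, "HLA-A*02:06")

  writeLines("peptide\tallele\trank", f)
  expect_equal(nrow(read_rank_table(f)), 0L)

  writeLines(c("peptide\tallele\trank",
               "AAAAKAAAA\tHLA-A*01:01\t1.5",
               "AAAAKAAAA\tHLA-A*01:01\t0.7"), f)
  expect_warning(calls <- read_rank_table(f), "collapsed")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$rank_percent, 0.7)

  writeLines(c("peptide\tallele\trank", "AAAAKAAAA\tHLA-A*01:01\t-1"), f)
  expect_error(read_rank_table(f), "negative")
})

test_that("coverage BEDs load merged and sorted", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t150\t300", "chr1\t300\t400",
               "chr2\t0\t50"), f)
  cov <- read_coverage_bed(f, "s1")
  expect_s3_class(cov, "coverage_set")
  expect_equal(cov$intervals,
               data.frame(chrom = c("chr1", "chr2"), start = c(100L, 0L),
                          end = c(400L, 50L)),
               ignore_attr = TRUE)
  writeLines(character(0), f)
  expect_equal(nrow(read_coverage_bed(f, "s1")$intervals), 0L)
})

test_that("gene models round-trip through BED12 with CDS in exons", {
  u <- fixture_universe()
  bed <- withr::local_tempfile(fileext = ".bed")
  write_gene_models(u$annotation, bed)
  back <- read_gene_models(bed)
  expect_equal(back$genes$gene_id, u$annotation$genes$gene_id)
  expect_equal(back$exons, u$annotation$exons, ignore_attr = TRUE)
  expect_equal(back$cds, u$annotation$cds, ignore_attr = TRUE)
  # thick span reaching into an intron yields CDS clipped to the exons
  writeLines(paste("chr1", 100, 1000, "g1", 0, "+", 150, 950, "0", 2,
                   "100,100,", "0,800,", sep = "\t"), bed)
  clipped <- read_gene_models(bed)
  expect_equal(clipped$cds$start, c(150L, 900L))
  expect_equal(clipped$cds$end, c(200L, 950L))
})
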