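# Shared fixtures: build the seeded universe once per test run and reuse it.

.fixture_cache <- new.env(parent = emptyenv())

fixture_universe <- function(seed = 1L) {
  key <- paste0("u", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_fixture_universe(seed = seed)
  .fixture_cache[[key]]
}

# Write a universe to disk and build a run_config for it.
fixture_run_config <- function(universe, dir, out_dir, seed = 7L,
                               decoy_segments = 12L) {
  write_fixture_dir(universe, dir)
  samples <- names(universe$coverage_by_sample)
  run_config(
    transcripts_fa = file.path(dir, "transcripts.fa"),
    transcripts_bed = file.path(dir, "transcripts.bed"),
    proteome_fa = file.path(dir, "proteome.fa"),
    genome_fa = file.path(dir, "genome.fa"),
    genes_bed = file.path(dir, "genes.bed"),
    peptides_tsv = file.path(dir, "peptides.tsv"),
    ranks_tsv = file.path(dir, "ranks.tsv"),
    alleles_tsv = file.path(dir, "alleles.tsv"),
    coverage_beds = stats::setNames(
      file.path(dir, sprintf("coverage_%s.bed", samples)), samples),
    out_dir = out_dir, seed = seed, decoy_segments = decoy_segments)
}

# Plain codon-table translation, independent of the package's translation
# path (used as oracle).
oracle_translate <- function(nt) {
  codons <- substring(nt, seq(1, nchar(nt) - 2, by = 3),
                      seq(3, nchar(nt), by = 3))
  tab <- Biostrings::GENETIC_CODE
  paste(ifelse(grepl("N", codons), "X", unname(tab[codons])), collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

files_identical_bytes <- function(a, b) {
  identical(readBin(a, "raw", file.size(a)), readBin(b, "raw", file.size(b)))
}
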