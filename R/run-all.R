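#' Pipeline run configuration
#'
#' Collects input paths and stage parameters for [run_all()]. Coverage BEDs
#' are given as a named vector keyed by sample ID. All referenced paths must
#' exist at validation time.
#'
#' @param transcripts_fa,transcripts_bed lncRNA transcript FASTA and BED12.
#' @param proteome_fa Reference proteome FASTA.
#' @param genome_fa Reference genome FASTA (decoy sampling and round-trip
#'   checks).
#' @param genes_bed Gene models BED12 (exon/CDS structure).
#' @param peptides_tsv De novo peptide observation TSV.
#' @param ranks_tsv HLA rank table TSV.
#' @param alleles_tsv Sample-allele TSV (columns `sample`, `allele`).
#' @param coverage_beds Named character vector of per-sample coverage BEDs.
#' @param out_dir Output directory.
#' @param seed Seed recorded in the run summary and used for decoy sampling.
#' @param filter A [filter_config()].
#' @param decoy_segments,decoy_segment_len Decoy database dimensions.
#' @param cutoff,strong_cutoff Binder rank cutoffs.
#' @param peptide_len_nt Nucleotides per average peptide in the null model.
#' @return A `run_config` list.
#' @export
run_config <- function(transcripts_fa, transcripts_bed, proteome_fa,
                       genome_fa, genes_bed, peptides_tsv, ranks_tsv,
                       alleles_tsv, coverage_beds, out_dir, seed = 1L,
                       filter = filter_config(), decoy_segments = 500L,
                       decoy_segment_len = 2000L, cutoff = 2.0,
                       strong_cutoff = 0.5, peptide_len_nt = 33L) {
  paths <- c(transcripts_fa, transcripts_bed, proteome_fa, genome_fa,
             genes_bed, peptides_tsv, ranks_tsv, alleles_tsv, coverage_beds)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stopf("input path(s) not found: %s", paste(missing, collapse = ", "))
  structure(list(transcripts_fa = transcripts_fa,
                 transcripts_bed = transcripts_bed, proteome_fa = proteome_fa,
                 genome_fa = genome_fa, genes_bed = genes_bed,
                 peptides_tsv = peptides_tsv, ranks_tsv = ranks_tsv,
                 alleles_tsv = alleles_tsv, coverage_beds = coverage_beds,
                 out_dir = out_dir, seed = as.integer(seed), filter = filter,
                 decoy_segments = as.integer(decoy_segments),
                 decoy_segment_len = as.integer(decoy_segment_len),
                 cutoff = cutoff, strong_cutoff = strong_cutoff,
                 peptide_len_nt = as.integer(peptide_len_nt)),
            class = "run_config")
}

#' Run the full lncRNA-peptide discovery pipeline
#'
#' Executes the stages in order: six-frame translation of the transcript
#' database, de novo peptide filtering (length/ALC/de novo-only), reference
#' proteome exclusion, translated-database matching, genomic coordinate
#' projection, HLA binder filtering, RNA-level expression verification,
#' region/source classification, decoy-database empirical p-value, and the
#' descriptive summaries. Every stage's input/output counts appear in the
#' run summary; intermediate tables are written to `out_dir`. Reruns with an
#' identical config and seed produce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list with the final match table, the null-model
#'   result and the per-stage counts.
#' @export
run_all <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(x) file.path(config$out_dir, x)

  tx_fa <- read_fasta(config$transcripts_fa, u_to_t = TRUE)
  transcripts <- read_bed12(config$transcripts_bed, tx_fa)
  proteome <- read_fasta(config$proteome_fa)
  genome <- read_fasta(config$genome_fa)
  annotation <- read_gene_models(config$genes_bed)
  observations <- read_peptide_table(config$peptides_tsv)
  calls <- read_rank_table(config$ranks_tsv)
  allele_tab <- utils::read.delim(config$alleles_tsv,
                                  stringsAsFactors = FALSE)
  alleles_by_sample <- lapply(split(allele_tab, allele_tab$sample),
                              function(d) sample_alleles(d$sample[1],
                                                         d$allele))
  coverage_by_sample <- stats::setNames(
    lapply(names(config$coverage_beds), function(s)
      read_coverage_bed(config$coverage_beds[[s]], s)),
    names(config$coverage_beds))

  db <- build_translated_db(transcripts)

  candidates <- filter_denovo(observations, config$filter, audit = TRUE)
  candidates <- exclude_proteome(candidates, proteome,
                                 config$filter$il_equivalence)
  utils::write.table(candidates, out("candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  matches <- match_peptides(candidates[, c("peptide", "sample_id")],
                            db, config$filter$il_equivalence)
  matches <- locate_matches(matches, transcripts)
  k_observed <- length(unique(matches$peptide))

  binder_annot <- filter_binders(matches, calls, alleles_by_sample,
                                 cutoff = config$cutoff,
                                 strong_cutoff = config$strong_cutoff,
                                 drop_nonbinders = TRUE)
  binder_counts <- attr(binder_annot, "binder_counts")

  classified <- classify_matches(binder_annot, transcripts, annotation,
                                 coverage_by_sample)
  final <- classified[classified$expressed, , drop = FALSE]
  rownames(final) <- NULL

  flatten <- function(m) {
    m$genomic_intervals <- vapply(m$genomic_intervals, function(iv)
      paste(sprintf("%s:%d-%d(%s)", iv$chrom, iv$start, iv$end, iv$strand),
            collapse = ";"), "")
    m
  }
  utils::write.table(flatten(classified), out("matches.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(flatten(final), out("final_peptides.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  regions_bed <- do.call(rbind, lapply(seq_len(nrow(final)), function(i) {
    iv <- final$genomic_intervals[[i]]
    iv$name <- final$peptide[i]
    iv
  }))
  if (is.null(regions_bed))
    regions_bed <- data.frame(chrom = character(0), start = integer(0),
                              end = integer(0), name = character(0),
                              strand = character(0))
  write_bed6(regions_bed, out("peptide_regions.bed"))

  # decoy database and empirical p-value: the candidate set is rematched
  # against a translated database of randomly sampled genomic segments
  decoy <- generate_decoy_segments(
    genome, decoy_config(n_segments = config$decoy_segments,
                         segment_len_nt = config$decoy_segment_len,
                         seed = config$seed))
  write_bed6(decoy[, c("chrom", "start", "end", "name")],
             out("decoy_segments.bed"))
  decoy_db <- build_translated_db(
    data.frame(transcript_id = decoy$name, sequence = decoy$sequence,
               stringsAsFactors = FALSE))
  decoy_hits <- match_peptides(candidates$peptide, decoy_db,
                               config$filter$il_equivalence)
  m_decoy <- length(unique(decoy_hits$peptide))
  mean_len <- round(mean(nchar(transcripts$sequence)))
  null_res <- empirical_pvalue(null_model_params(
    m_decoy_matches = m_decoy, n_decoy_transcripts = config$decoy_segments,
    frames = 6L, segment_len_nt = config$decoy_segment_len,
    peptide_len_nt = config$peptide_len_nt,
    n_real_transcripts = nrow(transcripts), mean_len_nt = mean_len,
    k_observed = k_observed))

  utils::write.table(length_distribution(candidates$peptide,
                                         config$filter$min_len,
                                         config$filter$max_len),
                     out("length_distribution.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ranks_all <- assign_best_alleles(
    candidates$peptide, calls,
    sample_alleles("all", unique(allele_tab$allele)))
  names(ranks_all)[names(ranks_all) == "rank_percent"] <- "best_rank"
  utils::write.table(binder_fraction_by_length(ranks_all, config$cutoff,
                                               config$strong_cutoff,
                                               config$filter$min_len,
                                               config$filter$max_len),
                     out("binder_by_length.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nine <- final$peptide[nchar(final$peptide) == 9L]
  if (length(nine) > 0L) {
    motif <- motif_percent_difference(nine, aa_composition(proteome))
    utils::write.table(round(unclass(motif), 6), out("motif_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }

  counts <- list(
    n_transcripts = nrow(transcripts),
    n_translated_entries = nrow(db),
    n_observations = nrow(observations),
    n_candidates = nrow(candidates),
    n_matches = nrow(matches),
    k_matched_peptides = k_observed,
    n_binder_matches = nrow(binder_annot),
    n_binders = unname(binder_counts[["binder"]]),
    n_final = nrow(final),
    m_decoy_matches = m_decoy,
    p_chance = null_res$p_chance,
    n_null_candidates = null_res$n_candidates,
    p_value = null_res$p_value,
    seed = config$seed
  )
  jsonlite::write_json(counts, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(final = final, classified = classified,
                 null_model = null_res, counts = counts))
}
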