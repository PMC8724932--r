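# Synthetic-fixture generators: a fully specified toy universe (genome, gene
# models, lncRNAs, proteome, coverage, peptides, rank tables) with
# ground-truth labels, so every pipeline stage can be tested end-to-end
# without external downloads. All generators are deterministic under a seed
# and emit the standard formats read by the formats_io layer.

#' Generate a random genome with gene models
#'
#' Random uniform bases; genes are laid out deterministically on each
#' chromosome with a fixed 3-exon / 2-intron structure (600 nt exons,
#' 1,500 nt introns) and a CDS spanning from mid-exon-1 to mid-exon-3, on
#' alternating strands. The layout leaves intergenic gaps wide enough to
#' host intergenic lncRNAs.
#'
#' @param seed RNG seed.
#' @param chrom_lengths Named integer vector of chromosome lengths
#'   (each >= 10 kb).
#' @param genes_per_chrom Number of genes per chromosome.
#' @return List with `genome` (named character vector) and `annotation`
#'   (a `genome_annotation`).
#' @export
make_genome <- function(seed = 1L, chrom_lengths = c(chr1 = 30000L,
                                                     chr2 = 30000L),
                        genes_per_chrom = 3L) {
  if (any(chrom_lengths < 10000L)) stopf("chromosome lengths must be >= 10 kb")
  need <- 2500L + (genes_per_chrom - 1L) * 9000L + 4800L + 200L
  if (any(chrom_lengths < need))
    stopf("chromosomes too short for %d genes (need >= %d nt)",
          genes_per_chrom, need)
  genome <- with_seed(seed, {
    vapply(chrom_lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      "")
  })
  names(genome) <- names(chrom_lengths)
  genes <- list(); exons <- list(); cds <- list()
  gi <- 0L
  for (ci in seq_along(genome)) {
    for (g in seq_len(genes_per_chrom)) {
      gi <- gi + 1L
      gstart <- 2500L + (g - 1L) * 9000L
      strand <- if ((gi %% 2L) == 1L) "+" else "-"
      id <- sprintf("gene%02d", gi)
      ex_s <- gstart + c(0L, 2100L, 4200L)
      ex_e <- ex_s + 600L
      thick <- c(gstart + 300L, gstart + 4500L)
      genes[[gi]] <- data.frame(gene_id = id, chrom = names(genome)[ci],
                                strand = strand, start = gstart,
                                end = gstart + 4800L, coding = TRUE,
                                stringsAsFactors = FALSE)
      exons[[gi]] <- data.frame(gene_id = id, chrom = names(genome)[ci],
                                start = ex_s, end = ex_e,
                                stringsAsFactors = FALSE)
      cs <- pmax(ex_s, thick[1]); ce <- pmin(ex_e, thick[2])
      cds[[gi]] <- data.frame(gene_id = id, chrom = names(genome)[ci],
                              start = cs[ce > cs], end = ce[ce > cs],
                              stringsAsFactors = FALSE)
    }
  }
  ann <- structure(list(genes = do.call(rbind, genes),
                        exons = do.call(rbind, exons),
                        cds = do.call(rbind, cds)),
                   class = "genome_annotation")
  validate_annotation(ann)
  list(genome = genome, annotation = ann)
}

#' Generate a random reference proteome
#'
#' @param seed RNG seed.
#' @param n_proteins Number of protein entries.
#' @param protein_len Length of each protein in residues.
#' @return Data.frame with columns `id` and `sequence`.
#' @export
make_proteome <- function(seed = 1L, n_proteins = 40L, protein_len = 300L) {
  with_seed(seed + 101L, {
    data.frame(
      id = sprintf("prot%03d", seq_len(n_proteins)),
      sequence = vapply(seq_len(n_proteins), function(i)
        paste(sample(AA20, protein_len, replace = TRUE), collapse = ""), ""),
      stringsAsFactors = FALSE)
  })
}

#' Generate lncRNA transcripts of known source classes
#'
#' Places transcripts so that their source class is fixed by construction:
#' antisense transcripts span a coding gene's middle (fully coding) exon
#' plus flanking intron on the opposite strand; sense-intronic transcripts
#' sit entirely inside intron 1 on the gene's strand; intergenic
#' transcripts are two-exon models placed in gaps that overlap no gene.
#'
#' @param genome_ann Output of [make_genome()].
#' @param counts Named integer vector with elements `antisense`,
#'   `sense_intronic`, `intergenic`.
#' @return A `transcript_set` with an extra `true_source` column.
#' @export
make_lncRNAs <- function(genome_ann,
                         counts = c(antisense = 6L, sense_intronic = 5L,
                                    intergenic = 5L)) {
  genome <- genome_ann$genome
  ann <- genome_ann$annotation
  n_genes <- nrow(ann$genes)
  if (counts[["antisense"]] > n_genes || counts[["sense_intronic"]] > n_genes)
    stopf("not enough genes to host the requested antisense/sense-intronic transcripts; enlarge the genome")
  rows <- list()
  add <- function(id, gene_or_chrom, strand, starts, sizes, true_source) {
    chrom <- gene_or_chrom
    pieces <- vapply(seq_along(starts), function(b)
      substr(genome[[chrom]], starts[b] + 1L, starts[b] + sizes[b]), "")
    seq <- paste(pieces, collapse = "")
    if (strand == "-") seq <- revcomp(seq)
    rows[[length(rows) + 1L]] <<- list(
      transcript_id = id, gene_id = sub(":.*$", "", id), chrom = chrom,
      strand = strand, tx_start = starts[1],
      tx_end = starts[length(starts)] + sizes[length(sizes)],
      block_starts = as.integer(starts), block_sizes = as.integer(sizes),
      sequence = seq, true_source = true_source)
  }
  opp <- function(s) if (s == "+") "-" else "+"
  for (i in seq_len(counts[["antisense"]])) {
    g <- ann$genes[i, ]
    # exon 2 spans gene_start + [2100, 2700); flank 500 nt into the introns
    add(sprintf("lnc-AS-%d:1", i), g$chrom, opp(g$strand),
        starts = g$start + 1600L, sizes = 1600L, true_source = "antisense")
  }
  for (i in seq_len(counts[["sense_intronic"]])) {
    g <- ann$genes[i, ]
    # intron 1 spans gene_start + [600, 2100); stay clear of the antisense
    # transcript (which begins at gene_start + 1600) so no genomic region is
    # shared between two transcripts
    add(sprintf("lnc-SI-%d:1", i), g$chrom, g$strand,
        starts = g$start + 700L, sizes = 850L, true_source = "sense_intronic")
  }
  # intergenic gaps: maximal intervals free of gene spans, per chromosome
  gaps <- list()
  for (chrom in names(genome)) {
    gs <- ann$genes[ann$genes$chrom == chrom, , drop = FALSE]
    gs <- gs[order(gs$start), , drop = FALSE]
    bounds <- c(0L, as.vector(rbind(gs$start, gs$end)), nchar(genome[[chrom]]))
    for (k in seq(1L, length(bounds) - 1L, by = 2L)) {
      if (bounds[k + 1L] - bounds[k] >= 2000L)
        gaps[[length(gaps) + 1L]] <- list(chrom = chrom, start = bounds[k],
                                          end = bounds[k + 1L])
    }
  }
  if (counts[["intergenic"]] > length(gaps))
    stopf("not enough intergenic gaps (%d) for %d intergenic transcripts; enlarge the genome",
          length(gaps), counts[["intergenic"]])
  for (i in seq_len(counts[["intergenic"]])) {
    gp <- gaps[[i]]
    s0 <- gp$start + 200L
    add(sprintf("lnc-IG-%d:1", i), gp$chrom, if (i %% 2L == 1L) "+" else "-",
        starts = c(s0, s0 + 900L), sizes = c(600L, 600L),
        true_source = "intergenic_lncRNA")
  }
  tx <- data.frame(
    transcript_id = vapply(rows, `[[`, "", "transcript_id"),
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    tx_start = vapply(rows, function(r) r$tx_start, 0L),
    tx_end = vapply(rows, function(r) r$tx_end, 0L),
    stringsAsFactors = FALSE)
  tx$block_starts <- lapply(rows, function(r) r$block_starts)
  tx$block_sizes <- lapply(rows, function(r) r$block_sizes)
  tx$sequence <- vapply(rows, `[[`, "", "sequence")
  tx$true_source <- vapply(rows, `[[`, "", "true_source")
  validate_transcripts(tx)
  class(tx) <- c("transcript_set", "data.frame")
  tx
}

# Plain-arithmetic region call used to label fixtures at generation time
# (kept free of the GRanges machinery that classify_region() uses, so the
# two can serve as independent routes in tests).
region_of_intervals <- function(iv, ann) {
  overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  for (r in seq_len(nrow(iv))) {
    hit_cds <- any(ann$cds$chrom == iv$chrom[r] &
                     overlaps(iv$start[r], iv$end[r], ann$cds$start,
                              ann$cds$end))
    if (hit_cds) return("novel_orf")
  }
  for (r in seq_len(nrow(iv))) {
    for (g in seq_len(nrow(ann$genes))) {
      gene <- ann$genes[g, ]
      if (!gene$coding || gene$chrom != iv$chrom[r]) next
      if (!overlaps(iv$start[r], iv$end[r], gene$start, gene$end)) next
      # positions in the gene span that are not exonic
      ex <- ann$exons[ann$exons$gene_id == gene$gene_id, , drop = FALSE]
      pos <- seq.int(max(iv$start[r], gene$start),
                     min(iv$end[r], gene$end) - 1L)
      in_exon <- rep(FALSE, length(pos))
      for (e in seq_len(nrow(ex)))
        in_exon <- in_exon | (pos >= ex$start[e] & pos < ex$end[e])
      if (any(!in_exon)) return("intronic")
    }
  }
  "noncoding"
}

# Count occurrences (I/L collapsed) of a peptide across all stop-free
# segments of a translated DB.
db_occurrence_count <- function(peptide, db_segments) {
  key <- il_collapse(peptide)
  sum(vapply(db_segments, function(s) length(str_find_all(s, key)), 0L))
}

#' Spike ground-truth peptides into a synthetic universe
#'
#' Generates three kinds of de novo peptide observations with recorded
#' truth: `lncRNA_spiked` peptides cut from stop-free frame segments of the
#' lncRNA set (placed so each has an intended genomic region class and
#' occurs exactly once in the whole translated database), `proteome_substring`
#' peptides cut from the reference proteome, and `random_decoy` peptides
#' absent from both. ALC scores mix values above and below the 50%
#' threshold (a stated fraction of spiked peptides is given failing ALC).
#'
#' @param transcripts A `transcript_set` from [make_lncRNAs()].
#' @param annotation The `genome_annotation`.
#' @param proteome Reference proteome (see [make_proteome()]).
#' @param n_spiked,n_proteome,n_decoy Peptide counts per origin.
#' @param samples Character vector of sample IDs (peptides assigned
#'   round-robin).
#' @param seed RNG seed.
#' @param frac_low_alc Fraction of spiked peptides given ALC below the
#'   threshold (default 0.15).
#' @return List with `observations` (a peptide table as from
#'   [read_peptide_table()]) and `truth` (per-peptide origin, intended
#'   transcript/frame/aa_start, intended region and source class).
#' @export
spike_peptides <- function(transcripts, annotation, proteome, n_spiked = 54L,
                           n_proteome = 8L, n_decoy = 12L,
                           samples = c("s1", "s2"), seed = 1L,
                           frac_low_alc = 0.15) {
  db <- build_translated_db(transcripts)
  db_segments <- unlist(lapply(db$aa_sequence, function(a)
    il_collapse(frame_segments(a)$segment)))
  prot_hay <- il_collapse(paste(proteome$sequence, collapse = "#"))
  used <- character(0)
  lens <- rep(8:14, length.out = n_spiked)
  truth <- list(); obs <- list()
  n_low <- max(0L, round(frac_low_alc * n_spiked))
  low_alc_idx <- if (n_low > 0L)
    seq.int(4L, by = max(1L, n_spiked %/% n_low), length.out = n_low) else
      integer(0)
  alc_vals <- with_seed(seed + 202L, {
    list(high = stats::runif(n_spiked, 60, 99),
         low = stats::runif(n_spiked, 20, 49.9),
         prot = stats::runif(n_proteome, 55, 99),
         decoy = stats::runif(n_decoy, 55, 99))
  })
  anti_counter <- 0L
  for (i in seq_len(n_spiked)) {
    ti <- ((i - 1L) %% nrow(transcripts)) + 1L
    tr <- transcripts[ti, , drop = FALSE]
    target <- switch(tr$true_source,
                     intergenic_lncRNA = "noncoding",
                     sense_intronic = "intronic",
                     antisense = {
                       anti_counter <- anti_counter + 1L
                       if (anti_counter %% 2L == 1L) "novel_orf" else "intronic"
                     })
    pep_len <- lens[i]
    placed <- FALSE
    for (fr in FRAME_IDS) {
      entry <- db[db$transcript_id == tr$transcript_id & db$frame == fr, ]
      segs <- frame_segments(entry$aa_sequence)
      for (s in seq_len(nrow(segs))) {
        seg <- segs$segment[s]
        max_start <- nchar(seg) - pep_len
        if (max_start < 0L) next
        for (off in 0:max_start) {
          pep <- substr(seg, off + 1L, off + pep_len)
          if (grepl("X", pep, fixed = TRUE)) next
          aa_start <- segs$aa_start[s] + off
          iv <- aa_to_nt_interval(fr, aa_start, pep_len, nchar(tr$sequence))
          giv <- map_to_genome(tr, iv[1], iv[2])
          if (region_of_intervals(giv, annotation) != target) next
          if (pep %in% used) next
          if (grepl(il_collapse(pep), prot_hay, fixed = TRUE)) next
          if (db_occurrence_count(pep, db_segments) != 1L) next
          used <- c(used, pep)
          alc <- if (i %in% low_alc_idx) alc_vals$low[i] else alc_vals$high[i]
          truth[[length(truth) + 1L]] <- data.frame(
            peptide = pep, origin = "lncRNA_spiked",
            sample_id = samples[((i - 1L) %% length(samples)) + 1L],
            alc = alc, transcript_id = tr$transcript_id, frame = fr,
            aa_start = aa_start, region_class = target,
            source_class = tr$true_source, stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (placed) break
      }
      if (placed) break
    }
    if (!placed)
      stopf("could not place spiked peptide %d (len %d) on transcript %s; segments too short",
            i, pep_len, tr$transcript_id)
  }
  # proteome substrings: deterministic cut sites spread over entries
  plens <- rep(8:14, length.out = n_proteome)
  for (i in seq_len(n_proteome)) {
    entry <- proteome[((i - 1L) %% nrow(proteome)) + 1L, ]
    off <- 10L * i
    pep <- substr(entry$sequence, off + 1L, off + plens[i])
    truth[[length(truth) + 1L]] <- data.frame(
      peptide = pep, origin = "proteome_substring",
      sample_id = samples[((i - 1L) %% length(samples)) + 1L],
      alc = alc_vals$prot[i], transcript_id = NA_character_,
      frame = NA_integer_, aa_start = NA_integer_,
      region_class = NA_character_, source_class = NA_character_,
      stringsAsFactors = FALSE)
  }
  # random decoys: absent from proteome and translated DB (checked, resampled)
  decoys <- with_seed(seed + 303L, {
    out <- character(0)
    dlens <- rep(8:14, length.out = n_decoy)
    while (length(out) < n_decoy) {
      pep <- paste(sample(AA20, dlens[length(out) + 1L], replace = TRUE),
                   collapse = "")
      if (grepl(il_collapse(pep), prot_hay, fixed = TRUE)) next
      if (db_occurrence_count(pep, db_segments) != 0L) next
      if (pep %in% used || pep %in% out) next
      out <- c(out, pep)
    }
    out
  })
  for (i in seq_len(n_decoy)) {
    truth[[length(truth) + 1L]] <- data.frame(
      peptide = decoys[i], origin = "random_decoy",
      sample_id = samples[((i - 1L) %% length(samples)) + 1L],
      alc = alc_vals$decoy[i], transcript_id = NA_character_,
      frame = NA_integer_, aa_start = NA_integer_,
      region_class = NA_character_, source_class = NA_character_,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  observations <- data.frame(
    peptide = truth$peptide, alc = truth$alc, sample_id = truth$sample_id,
    intensity = NA_real_, origin = "de_novo_only", modifications = "",
    stringsAsFactors = FALSE)
  list(observations = observations, truth = truth)
}

#' Generate an HLA rank table with designated binders
#'
#' Each peptide receives one call per allele of its sample. Designated
#' binders get their best rank drawn uniformly below the 2.0 cutoff (with
#' alternate designated strong binders below 0.5); non-binders get all
#' ranks above 2.0.
#'
#' @param peptides Data.frame with `peptide` and `sample_id` columns.
#' @param alleles_by_sample Named list of [sample_alleles()] keyed by sample.
#' @param binder Either a fraction in `[0, 1]` (binders designated by seeded
#'   sampling) or a logical vector parallel to `peptides`.
#' @param seed RNG seed.
#' @return List with `calls` (a rank table as from [read_rank_table()]) and
#'   `truth` (per-peptide `binder` and `strong_binder` flags).
#' @export
make_rank_table <- function(peptides, alleles_by_sample, binder = 0.8,
                            seed = 1L) {
  n <- nrow(peptides)
  is_binder <- if (is.logical(binder)) binder else
    with_seed(seed + 404L, stats::runif(n) < binder)
  is_strong <- is_binder & (seq_len(n) %% 2L == 1L)
  calls <- list()
  ranks <- with_seed(seed + 505L, {
    list(strong = stats::runif(n, 0.05, 0.45),
         weak = stats::runif(n, 0.55, 1.95),
         non = matrix(stats::runif(n * 8L, 2.05, 50), nrow = n))
  })
  for (i in seq_len(n)) {
    al <- alleles_by_sample[[peptides$sample_id[i]]]$alleles
    rk <- ranks$non[i, seq_along(al)]
    if (is_binder[i]) {
      best_at <- ((i - 1L) %% length(al)) + 1L
      rk[best_at] <- if (is_strong[i]) ranks$strong[i] else ranks$weak[i]
    }
    calls[[i]] <- data.frame(peptide = peptides$peptide[i], allele = al,
                             rank_percent = rk, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  list(calls = calls,
       truth = data.frame(peptide = peptides$peptide, binder = is_binder,
                          strong_binder = is_strong,
                          stringsAsFactors = FALSE))
}

# subtract interval set b from interval set a (both chrom/start/end dfs)
subtract_intervals <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    pieces <- data.frame(start = a$start[i], end = a$end[i])
    bs <- b[b$chrom == a$chrom[i], , drop = FALSE]
    for (j in seq_len(nrow(bs))) {
      nxt <- list()
      for (k in seq_len(nrow(pieces))) {
        s <- pieces$start[k]; e <- pieces$end[k]
        if (bs$end[j] <= s || e <= bs$start[j]) {
          nxt[[length(nxt) + 1L]] <- data.frame(start = s, end = e)
        } else {
          if (s < bs$start[j])
            nxt[[length(nxt) + 1L]] <- data.frame(start = s, end = bs$start[j])
          if (bs$end[j] < e)
            nxt[[length(nxt) + 1L]] <- data.frame(start = bs$end[j], end = e)
        }
      }
      pieces <- if (length(nxt)) do.call(rbind, nxt) else
        data.frame(start = integer(0), end = integer(0))
    }
    if (nrow(pieces))
      out[[length(out) + 1L]] <- data.frame(chrom = a$chrom[i],
                                            start = pieces$start,
                                            end = pieces$end,
                                            stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
}

# is every base of every interval in iv contained in the merged set cov?
intervals_covered <- function(iv, cov) {
  all(vapply(seq_len(nrow(iv)), function(i) {
    any(cov$chrom == iv$chrom[i] & cov$start <= iv$start[i] &
          iv$end[i] <= cov$end)
  }, NA))
}

#' Build a complete synthetic universe with ground truth
#'
#' Chains the fixture generators into one seeded universe: genome and gene
#' models, lncRNAs of all three source classes, a reference proteome,
#' spiked/proteome/decoy peptide observations, HLA rank tables, and
#' per-sample coverage. Coverage fully covers every transcript used by a
#' sample except one deliberately truncated transcript per sample (the
#' transcript of the sample's last spiked peptide loses the region coding
#' that peptide), giving negative expression cases. The per-peptide truth
#' (`expressed`, `binder`, `retained_final`) is derived from the constructed
#' coverage and rank designations by plain interval arithmetic.
#'
#' @param seed RNG seed driving every random choice.
#' @param n_spiked,n_proteome,n_decoy Peptide counts per origin.
#' @param lnc_counts Transcript counts per source class.
#' @param samples Sample IDs.
#' @return List with elements `genome`, `annotation`, `transcripts`,
#'   `proteome`, `observations`, `calls`, `alleles_by_sample`,
#'   `coverage_by_sample` and `truth`.
#' @export
make_fixture_universe <- function(seed = 1L, n_spiked = 54L, n_proteome = 8L,
                                  n_decoy = 12L,
                                  lnc_counts = c(antisense = 6L,
                                                 sense_intronic = 5L,
                                                 intergenic = 5L),
                                  samples = c("s1", "s2")) {
  ga <- make_genome(seed)
  transcripts <- make_lncRNAs(ga, lnc_counts)
  proteome <- make_proteome(seed)
  sp <- spike_peptides(transcripts, ga$annotation, proteome,
                       n_spiked = n_spiked, n_proteome = n_proteome,
                       n_decoy = n_decoy, samples = samples, seed = seed)
  truth <- sp$truth
  alleles_by_sample <- stats::setNames(lapply(seq_along(samples), function(i)
    sample_alleles(samples[i], c(sprintf("HLA-A*%02d:01", i),
                                 sprintf("HLA-B*%02d:01", 6 + i),
                                 sprintf("HLA-C*%02d:02", 11 + i)))),
    samples)
  # binder designation: every 5th peptide a nonbinder, cycling
  binder_flags <- (seq_len(nrow(truth)) %% 5L) != 0L
  rt <- make_rank_table(truth[, c("peptide", "sample_id")], alleles_by_sample,
                        binder = binder_flags, seed = seed)
  truth$binder <- rt$truth$binder
  truth$strong_binder <- rt$truth$strong_binder
  # genomic intervals of every spiked peptide (needed for coverage truth)
  spiked <- which(truth$origin == "lncRNA_spiked")
  giv_list <- stats::setNames(vector("list", nrow(truth)), NULL)
  for (i in spiked) {
    tr <- transcripts[transcripts$transcript_id == truth$transcript_id[i], ,
                      drop = FALSE]
    iv <- aa_to_nt_interval(truth$frame[i], truth$aa_start[i],
                            nchar(truth$peptide[i]), nchar(tr$sequence))
    giv_list[[i]] <- map_to_genome(tr, iv[1], iv[2])
  }
  # coverage: full blocks of each sample's used transcripts, minus the
  # region coding the sample's last spiked peptide (truncated-transcript
  # negative case)
  coverage_by_sample <- stats::setNames(lapply(samples, function(s) {
    mine <- spiked[truth$sample_id[spiked] == s]
    tx_ids <- unique(truth$transcript_id[mine])
    blocks <- list()
    for (id in tx_ids) {
      tr <- transcripts[transcripts$transcript_id == id, , drop = FALSE]
      blocks[[id]] <- data.frame(
        chrom = tr$chrom,
        start = pmax(tr$block_starts[[1]] - 5L, 0L),
        end = tr$block_starts[[1]] + tr$block_sizes[[1]] + 5L,
        stringsAsFactors = FALSE)
    }
    cov <- merge_intervals(do.call(rbind, blocks))
    drop_pep <- mine[length(mine)]
    hole <- giv_list[[drop_pep]]
    hole$start <- hole$start - 1L
    hole$end <- hole$end + 1L
    cov <- subtract_intervals(cov, hole[, c("chrom", "start", "end")])
    structure(list(sample_id = s, intervals = cov), class = "coverage_set")
  }), samples)
  truth$expressed <- NA
  for (i in spiked) {
    cov <- coverage_by_sample[[truth$sample_id[i]]]$intervals
    truth$expressed[i] <- intervals_covered(giv_list[[i]], cov)
  }
  truth$retained_final <- truth$origin == "lncRNA_spiked" &
    truth$alc > 50 & truth$binder & !is.na(truth$expressed) & truth$expressed
  list(genome = ga$genome, annotation = ga$annotation,
       transcripts = transcripts, proteome = proteome,
       observations = sp$observations, calls = rt$calls,
       alleles_by_sample = alleles_by_sample,
       coverage_by_sample = coverage_by_sample, truth = truth)
}

#' Generate random transcript sequences
#'
#' A plain random transcript set (uniform bases, no genome placement) used
#' for scale exercises such as counting translated-database entries at the
#' full database size.
#'
#' @param n Number of transcripts.
#' @param len Transcript length in nucleotides.
#' @param seed RNG seed.
#' @return Data.frame with columns `transcript_id` and `sequence`.
#' @export
random_transcripts <- function(n, len = 2000L, seed = 1L) {
  with_seed(seed, {
    idx <- sample.int(4L, as.numeric(n) * len, replace = TRUE)
    long <- rawToChar(as.raw(c(65L, 67L, 71L, 84L))[idx])
    starts <- seq(1L, by = len, length.out = n)
    data.frame(transcript_id = sprintf("tx%06d", seq_len(n)),
               sequence = substring(long, starts, starts + len - 1L),
               stringsAsFactors = FALSE)
  })
}

#' Write a fixture universe to a directory of standard files
#'
#' Emits the complete toy universe in the formats the pipeline consumes:
#' genome/proteome/transcript FASTA, transcript and gene-model BED12,
#' peptide and rank TSVs, an allele TSV, per-sample coverage BED6 and a
#' truth TSV.
#'
#' @param universe Output of [make_fixture_universe()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(universe, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_fasta(universe$genome, fp("genome.fa"))
  write_fasta(universe$proteome, fp("proteome.fa"))
  write_fasta(stats::setNames(universe$transcripts$sequence,
                              universe$transcripts$transcript_id),
              fp("transcripts.fa"))
  write_bed12(universe$transcripts, fp("transcripts.bed"))
  write_gene_models(universe$annotation, fp("genes.bed"))
  obs <- universe$observations
  names(obs)[names(obs) == "sample_id"] <- "sample"
  utils::write.table(obs, fp("peptides.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  calls <- universe$calls
  names(calls)[names(calls) == "rank_percent"] <- "rank"
  utils::write.table(calls, fp("ranks.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  al <- do.call(rbind, lapply(universe$alleles_by_sample, function(a)
    data.frame(sample = a$sample_id, allele = a$alleles,
               stringsAsFactors = FALSE)))
  utils::write.table(al, fp("alleles.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (s in names(universe$coverage_by_sample))
    write_bed6(universe$coverage_by_sample[[s]]$intervals,
               fp(sprintf("coverage_%s.bed", s)))
  utils::write.table(universe$truth, fp("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
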