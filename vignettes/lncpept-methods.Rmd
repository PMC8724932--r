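---
title: "Methods: lncRNA-encoded HLA class I peptide discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA-encoded HLA class I peptide discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncpept)
```

## The problem

HLA class I molecules present 8–14-mer peptides to CD8+ T cells. Tumours
with few somatic mutations offer few classical neoantigens, which motivates
looking beyond annotated proteins: long noncoding RNAs (lncRNAs) can
produce ribosome-associated products whose peptides reach the cell surface.
Database search cannot find them (they are absent from the reference
proteome by definition), and building a sample-specific noncoding search
space from RNA-seq inflates the database enormously. `lncpept` takes the
inverse route: peptides are sequenced *de novo* from the MS/MS spectra and
then looked up in a six-frame translation of an lncRNA compendium.

## Translation model

Each transcript (spliced sequence, 5'→3' on the transcript strand) is
translated in six frames: offsets 0–2 on the stored sequence and offsets
0–2 on its reverse complement. We use the plain standard codon table with
`no.init.codon` semantics — a search space has no privileged start, so a
leading `TTG`/`CTG` stays leucine rather than becoming an initiator
methionine. Stop codons are kept in the frame string as `*`; matching is
confined to maximal stop-free segments because a contiguous presented
peptide cannot span a stop. Codons containing `N` translate to `X`, which
never matches any peptide residue — conservative with respect to fabricated
matches. One database entry is emitted per (transcript, frame), so *N*
transcripts give exactly 6*N* entries; translation operates on the spliced
transcript sequence, not on genomic sequence, consistent with the
transcript-level character of the compendium.

Amino-acid windows map back to transcript nucleotides by exact offset
arithmetic (`aa_to_nt_interval`): forward frame *f* starts at
3·aa_start + (f−1); reverse frames mirror the interval onto the stored
orientation. Projection to the genome walks the BED12 blocks (minus-strand
transcripts 3'→5'), splitting at exon boundaries. Both directions are
covered by an exhaustive oracle test (all frames × all windows of random
sequences, and a per-base projection oracle), and every final match is
verified by extracting its genomic bases and re-translating.

## Peptide filtering

Candidates are de novo–only observations with length 8–14 and average
local confidence (ALC) strictly greater than 50 %; duplicates collapse to
the maximum ALC. Candidates occurring as substrings of the reference
proteome are removed: plain substring matching rather than enzymatic
windows, because HLA ligands are natural peptides without defined cleavage
termini. Isoleucine/leucine equivalence is *on* by default — MS/MS cannot
distinguish the isobaric pair, so exclusion (and database matching) is done
on I/L-collapsed strings; the flag can be disabled. No false-discovery rate
is estimated for the de novo identifications themselves, as no decoy
database exists for spectrum-level de novo calls; the decoy-genome null
model below plays that role at the level of database matches.

## Binder and expression filters, classification

Each peptide is assigned the minimum %Rank over the sample's typed HLA
alleles (ties broken lexicographically and logged; the predictor itself is
external and consumed as a table). Binder means best rank < 2.0 strictly,
strong binder < 0.5. Expression requires *every* base of the peptide-coding
genomic intervals to fall inside the sample's merged coverage — lncRNA-level
overlap is not sufficient, since a truncated transcript may be transcribed
without the peptide-coding region. The stage order
(match → binder → expression → classification) follows the discovery
narrative the pipeline emulates; the stages commute for the final set, and
the driver records every stage's counts.

Genomic-context classes use annotated CDS exons as "coding": a match
overlapping a CDS exon on either strand is a `novel_orf` (the candidate is
already proteome-excluded, so such overlap implies a frameshifted or
alternate-start product); otherwise a match with any base in intronic space
of a coding gene is `intronic`; everything else — including UTR-exon-only
overlap — is `noncoding`. Source lncRNAs are `antisense` (span overlaps a
coding gene on the opposite strand), else `sense_intronic` (contained in a
same-strand intron), else `intergenic_lncRNA`; the precedence resolves rare
mixed placements deterministically where a manual browser inspection would
adjudicate case by case.

## Null model

A decoy database of `n_segments` non-overlapping genomic segments of fixed
length (defaults 50,000 × 2,000 nt, the compendium's mean lncRNA length) is
sampled uniformly at random by seeded rejection sampling; segments with `N`
runs are resampled. Matching the candidate set against its six-frame
translation yields `m` chance matches, giving the per-candidate chance
probability

$$p = \frac{m}{n_{\text{segments}} \times 6 \times L_{\text{seg}} / 33},$$

with 33 nt the coding length of an average (11-mer) peptide. The real
database contributes $n = N \times 6 \times \bar{L} / 33$ candidate
peptides, and the significance of $k$ observed matches is the binomial
upper tail $P(X \ge k)$, $X \sim \mathrm{Binomial}(n, p)$. At the published
scale ($m = 66$, $N = 107{,}039$, $k = 195$) this gives $p = 3.63\times
10^{-6}$ and a p-value of $1.09\times 10^{-5}$:

```{r}
p <- p_chance(66, 50000, 6, 2000, 33)
p
binomial_tail(195, round(107039 * (6 * 2000) / 33), p)
```

Two numerical choices matter. First, the tail is computed by log-gamma
leading term plus exact term-ratio recursion, summing whichever tail is
smaller — naive factorials overflow at $n \approx 4\times 10^7$ and naive
pmf summation underflows. The implementation agrees with exhaustive
enumeration to $10^{-12}$ for $n \le 30$ and with the Poisson limit within
2 % for $n = 10^6$, $np \in [50, 500]$. Second, the candidate count uses
the per-transcript formula $6 \bar{L} / 33$ per transcript; the transcript
count enters linearly and a one-unit ambiguity in it is far below the
printed precision of the result.

## Synthetic universe

The fixture generator builds a toy genome (2 × 30 kb, uniform random
bases) with six 3-exon coding genes on alternating strands, then places
lncRNAs whose source class is fixed by construction: antisense transcripts
span a gene's fully-coding middle exon plus flanking intron on the opposite
strand, sense-intronic transcripts sit inside intron 1, and two-exon
intergenic transcripts occupy gene-free gaps. Spiked peptides (default 54,
lengths cycling 8–14) are cut from stop-free frame segments at positions
chosen to realise an intended region class; every spiked peptide is
verified at generation time to occur exactly once in the whole translated
database and never in the proteome (I/L-collapsed), so pipeline recovery is
exact by construction. Proteome-substring and random-decoy peptides provide
negative controls, a stated fraction of spiked peptides receives failing
ALC, designated binder flags drive the rank table, and per-sample coverage
fully covers each used transcript except one deliberately truncated
transcript per sample — reproducing the truncated-transcript pattern where
a lncRNA is transcribed but the specific peptide-coding region is not.

The generation-time truth labels are computed with plain interval
arithmetic, deliberately separate from the GRanges-based classifiers the
pipeline uses, so tests compare two independent routes. Problem sizes (16
transcripts, 74 peptides, 60 kb genome) are chosen so that exhaustive
oracles — all-frames scans, per-base projection, all-substrings proteome
enumeration — run in seconds; the full-scale translation check (107,039 ×
2 kb transcripts) runs once and takes about a minute. What the fixtures do
*not* model: MS spectral noise beyond the ALC mix, real HLA binding motifs
(ranks are designated, not predicted), genomic repeats and homology (a real
genome makes decoy segments partially overlap real lncRNA loci far less
often than a 60 kb toy genome does), and sequencing-depth variation in
coverage. Passing the recovery tests therefore demonstrates the
correctness of the bookkeeping and filters, not the biological error rates
of de novo sequencing.

## Defaults and tunables

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `min_len`, `max_len` | 8, 14 | residues | HLA class I ligand window |
| `min_alc` | 50 (strict >) | % | de novo confidence threshold |
| `il_equivalence` | TRUE | — | I/L isobaric in MS/MS |
| binder `cutoff` | 2.0 (strict <) | %Rank | standard binder call |
| `strong_cutoff` | 0.5 (strict <) | %Rank | standard strong-binder call |
| `n_segments` | 50,000 | segments | decoy sized like the compendium |
| `segment_len_nt` | 2,000 | nt | mean lncRNA length |
| `peptide_len_nt` | 33 | nt | average 11-mer |

Duplicate rank rows collapse to the *minimum* rank (most favourable
prediction) with a warning; degenerate inputs (empty coverage, unannotated
chromosomes, empty candidate sets) yield defined results (`FALSE`,
`noncoding` with a warning, empty tables) rather than errors, while
malformed files (non-relative BED12 blockStarts, block-sum/sequence-length
mismatches, negative ranks, non-amino-acid residues) fail fast with the
offending record named.

## Known limitations

Matching is exact substring matching (optionally I/L-collapsed); near-match
tolerance, PTM-aware matching, and ribosome-profiling evidence are out of
scope. The classifiers assume a single annotation source of well-formed
gene models. Decoy sampling is uniform over the genome and does not match
GC or repeat content of real lncRNAs — consistent with its role as a
pessimistic (chance-inflating) null rather than a calibrated generative
model.
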