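---
title: "Methods: four-library salivary-gland enrichment analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: four-library salivary-gland enrichment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sialoquant)
```

# Overview

`sialoquant` classifies coding sequences (CDS) by tissue and sex
enrichment from four bulk RNA-seq libraries: female and male salivary
gland (FSG, MSG) and female and male whole body (FWB, MWB). The chain
is read trimming, seeded read-to-CDS assignment, within-library
normalization (RPKM/TPM/expression index), per-CDS chi-square testing
of pooled salivary versus whole-body counts with multiple-testing
correction, and a two-level fold classification (tenfold salivary
filter, fivefold sex partition, extreme-specificity screen). A seeded
synthetic-data generator with planted truth makes every stage testable
without external data.

# Read assignment

## Trimming

Reads are trimmed from the 3' end: the maximal trailing run of bases
with Phred quality below 13 is removed, and reads shorter than 25 nt
(the seed word size) afterwards are dropped. Whether the original
protocol trimmed bases or discarded whole reads below the threshold is
ambiguous in this kind of pipeline; base trimming is the default
because it preserves the informative 5' portion of tail-degraded
Illumina reads, and a whole-read `discard` mode is available for
comparison.

## Alignment rule

The mapping contract is blastn-like and deliberately narrow — it is a
read-to-CDS assigner, not a general aligner:

* candidate (CDS, strand) pairs are those sharing an exact 25-mer with
  the read (`word_size`, the blastn seed);
* an alignment places the entire read inside the CDS, either ungapped
  on a seeded diagonal or with exactly one gap of length 1–3 (in read
  or reference) where one of the two ungapped segments lies on a seeded
  diagonal. "One gap allowed" is read as one gap *opening* of bounded
  length because substitution errors dominate short-read data and a
  narrow band keeps the search exact;
* scoring is megablast-like: match +2, mismatch −3, a length-g gap
  costs 5 + 2g. Identity is matching columns over alignment columns
  (gap columns count against identity) and alignments under 95% are
  discarded;
* per read, only assignments tied at the maximal score are retained, at
  most five of them; ties beyond five are resolved by ascending
  `cds_id`, a deterministic stand-in for an unspecified original
  behavior.

The compiled seed-and-extend implementation is validated against an
independent brute-force R aligner (same contract, exhaustive search,
different code and language) on randomized instances including
duplicated CDS; the retained (read, CDS) pair sets must be identical.

## Multi-mapping

A read tied between k CDS contributes a whole count to each (so library
totals count it k times). This keeps the count matrix additive over
assignments and treats splice variants/alleles symmetrically; a
fractional 1/k policy is available behind `policy = "fractional"` where
conservation of read totals matters more.

# Quantification

For CDS length L, per-CDS count r and per-library mapped total R:

* RPKM = 1e9 · r / (L · R), each library using its own total;
* TPM: length-normalized rates rescaled to sum to 1e6 per library;
* expression index EI = 100 · r / max(r), anchored to the FSG library
  by default (the reference library whose most abundant CDS defines
  EI = 100);
* normalized read ratio r1·R2 / [R1·(r2+1)] — the +1 pseudocount
  avoids division by zero;
* directed TPM ratios with +0.1 added to the denominator, for the six
  reported pairs FSG/MSG, FSG/FWB, FSG/MWB, FWB/MWB, MSG/MWB, MSG/FWB.

TPM is used for cross-library fold comparisons (it is composition-
normalized); RPKM and the normalized read ratio are carried along as
the conventional absolute-expression views.

# Testing and classification

Each CDS is tested with a Pearson chi-square (1 df, no continuity
correction) on the 2×2 table of pooled salivary counts
(r_FSG + r_MSG vs the rest) against pooled whole-body counts. Yates
correction is off by default because the intended regime has expected
counts well above 20, where the uncorrected statistic is calibrated
(the test suite verifies the type-I error at depth 40,000 over 1,000
CDS); a `correct` flag enables it for sparse data. Bonferroni and
Benjamini–Hochberg adjustments use `stats::p.adjust`.

Classification has three levels, with threshold conventions chosen
once: "at least 10-fold" and "at least 5-fold" are inclusive (≥),
"above 1,000" is strict (>).

1. **Salivary filter**: pooled TPM fold
   (tpm_FSG + tpm_MSG) / (tpm_FWB + tpm_MWB + 0.1) ≥ 10 *and*
   BH q ≤ alpha (default 0.05). The fold metric is the pseudocounted
   TPM ratio rather than the raw read ratio because TPM is the scale
   used for every other cross-library comparison; the normalized read
   ratio is emitted alongside for inspection. The significance gate is
   never binding at deep sequencing (q-values there are astronomically
   small) but protects desk-scale data.
2. **Sex partition** of filtered CDS: female-enriched if
   tpm_FSG/(tpm_MSG+0.1) ≥ 5, male-enriched if the reverse ratio is,
   shared otherwise; the two conditions cannot both hold for
   nonnegative TPM at fold ≥ 5, but the tie rule (larger ratio wins) is
   implemented defensively.
3. **Extreme screen**: flags ratios above 1,000 of one sex's salivary
   TPM over the *opposite* sex's whole-body TPM (FSG/(MWB+0.1),
   MSG/(FWB+0.1)) — the cross-sex denominator is the most selective
   indicator of gland-restricted expression, since the same-sex whole
   body contains the gland itself. The FSG/(MSG+0.1) ratio is also
   reported so both views are available.

Row Z-scores ((x − mean)/sd per CDS across the four TPM columns) are
provided for heatmap display; constant rows map to zeros so clustering
tools receive finite input.

# Synthetic data

The generator emulates the study design: four libraries, 101-nt
single-end reads, uniform-composition CDS (300–1800 nt), a 3:1 FSG:MSG
depth imbalance mirroring the molar pooling of the female and male
salivary cDNA libraries, per-base substitution errors (default 1%,
within the regime the 95%-identity filter tolerates at 101 nt), and an
optional low-quality 3' tail on 2% of reads to exercise trimming.

Enrichment structure is planted directly in expected-TPM space so
planted folds are exact, not approximate: an enriched CDS receives
per-library masses u (enriched-sex gland), u/sex_fold (other gland) and
(FSG+MSG)/(2·sg_fold) in each whole-body library — i.e. whole body is
modeled as the salivary signal diluted sg_fold-fold into a background
pool, which is how the module's open question on whole-body composition
is resolved. Enriched masses are scaled so their largest per-library
share is 0.5, and background CDS split each library's remainder
equally; this pins every library's total mass to the same constant, so
cross-library TPM ratios equal the planted folds exactly and background
CDS sit near fold 1.

Default conditions (the regime the recovery guarantees refer to):
500 CDS; class proportions 11.5% female- / 3.8% male- / 4.7%
shared-salivary / 80% background (the relative sizes of the three
enriched groups mirror the 207:68:85 split of the motivating corpus);
salivary folds uniform in 25–150 and sex folds in 25–120 (comfortably
past the 10× and 5× thresholds, matching the fold regime in which
recovery is claimed); depths FSG 200,000 / MSG 66,667 / WB 100,000
each, which give every enriched CDS at least ~200 expected salivary
reads under those proportions. Reads are drawn multinomially from the
per-library masses, uniformly positioned, strand-symmetric.

What the generator does **not** model — and therefore what passing
recovery tests do not show about real data: transcript isoforms and
alleles (beyond exact duplicate CDS for multi-mapping tests),
paired-end structure, PCR duplicates, coverage bias, indel sequencing
errors, biological replicate variance, and realistic whole-body
transcriptome complexity (background CDS stand in for it). Recovery
results certify the pipeline's arithmetic and thresholds, not its
robustness to assembly artifacts.

# ORF bookkeeping

`longest_orf()` scans all six frames; an ORF is a maximal stop-free
codon run, optionally bounded by a stop. A methionine start is *not*
required — reference CDS sets routinely contain Met-less partial
proteins, so Met presence and terminal-stop presence are reported as
completeness flags rather than used as filters. Ties in protein length
are broken by frame order (+1, +2, +3, −1, −2, −3), then by leftmost
start in the frame's scanning orientation. Codons containing N
translate to X and do not terminate a run. Coordinates are 0-based
half-open on the forward strand and include the terminal stop codon
when present. "Longest" is per contig (not corpus-wide), the natural
unit for per-contig coding-potential bookkeeping.

Extension and validation helpers apply fixed gates: an extension counts
at ≥ 25% added protein length (inclusive); outgroup validation accepts
e-value < 1e-15 with query length within 10% of the *subject* length
(the reference proteome is the yardstick, so the window is relative to
it), or coverage > 90% with identity < 95%.

# qPCR validation

`delta_delta_ct()` implements the pure 2^-ddCt model without
amplification-efficiency correction. Technical duplicates are averaged
per biological replicate before statistics (configurable); dCt is
target minus reference Ct per replicate; ddCt is the difference of
group means; its standard error combines the two group standard errors
in quadrature (the conventional propagation for a difference of
independent means, which the "± SE" reporting convention leaves
unstated); the interval is (2^−(ddCt+SE), 2^−(ddCt−SE)). With a single
replicate the point estimate is returned with SE = NA.
`qpcr_concordance()` regresses log2 RNA-seq folds on log2 qPCR folds
(Pearson r, OLS with 95% CIs); assay duplicates with different primer
pairs may be pooled as independent points or pre-averaged by the
caller — both inputs are accepted since the regression is agnostic to
how pairs were formed.

# Numerical and design notes

* Identity thresholds compare with a 1e-9 epsilon so rational values
  like 96/101 are classified exactly.
* Degenerate chi-square margins (no reads on either side) return
  statistic 0, p 1 rather than NaN.
* All randomness flows through a single integer seed; generator
  functions restore the caller's RNG state, and a fixed seed yields
  byte-identical FASTQ output and end-to-end identical tables.
* Problem sizes in the test suite (up to 500 CDS and ~470,000 reads
  for the study-scale recovery check; 20 randomized mapper-oracle
  instances of ≤ 15 CDS × ≤ 80 reads) were chosen so the whole suite
  completes in a few minutes on one CPU while keeping expected counts
  in the regime the statistical claims refer to.
* Known limitations: the mapper requires the full read inside a CDS
  (no clipping, no spliced alignment, no paired-end rescue); no
  between-sample normalization beyond TPM/RPKM (none is used by the
  analysis this package implements); no signal-peptide prediction or
  homology search execution — outgroup validation consumes externally
  produced alignment summaries.
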