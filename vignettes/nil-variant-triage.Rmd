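---
title: "Triage of NIL-pair variants and candidate-gene prioritization: methods"
author: "niltriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of NIL-pair variants and candidate-gene prioritization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niltriage)
```

## The analysis this package implements

A near-isogenic line (NIL) pair isolates the genetic basis of one trait —
here, flowering time in chickpea — in an almost identical genomic
background: the two lines descend from residual heterozygosity in a
recombinant inbred line and differ only in small genomic segments. Whole
genome resequencing of such a pair yields a two-sample VCF in which almost
every record is noise (sequencing artifacts, residual heterozygosity,
unanchored scaffolds), and the analytical problem is *triage*: narrow
~10^5 raw variant calls down to a handful of candidate genes that can
plausibly explain the trait difference.

The pipeline has five stages, each exposed as ordinary functions:

1. **Tiered filtering** (`run_triage()`): read-depth filter, quality
   criterion filter, contrasting-homozygosity selection, intragenic
   restriction, and finally restriction to CDS/exon of protein-coding
   genes. The tiers are nested record sets — DETECTED ⊇ HQ ⊇ HHQ ⊇ HHQ-I ⊇
   HHQ-I-C/E — reported per chromosome with the count of affected
   protein-coding genes.
2. **Region classification** (`assign_loci()`): each variant footprint is
   intersected with every locus span; protein-coding loci classify with the
   total precedence CDS > EXON (non-coding exon, i.e. UTR) > INTRON across
   all isoforms, non-coding loci map to their biotype (lncRNA, rRNA, snRNA,
   snoRNA, tRNA, pseudogene/misc RNA). Overlapping opposite-strand loci can
   give one variant two region calls (CDS for one locus, EXON for the
   other), which `cds_exon_both_tally()` counts separately.
3. **Effect classification** (`classify_effect()`,
   `translate_consequence()`): a deliberately minimal coding-effect
   classifier covering the term vocabulary that matters for this kind of
   report — frameshift vs in-frame indels, synonymous / missense /
   stop-gained SNVs, UTR, intron and non-coding-transcript terms — with the
   snpEff impact tiers HIGH > MODERATE > LOW > MODIFIER.
4. **Enrichment and candidate selection** (`fisher_enrichment()`,
   `select_candidates()`): one-sided Fisher exact over-representation of
   GO-slim terms among variant-bearing genes against the genome universe,
   and selection of the genes annotated with flowering-associated enriched
   terms.
5. **Population and expression context** (`assign_haplotype_groups()`,
   `dtf_compare()`, `fpkm_to_tpm()`, `cluster_expression()`): conservation
   of the NIL haplotypes across a germplasm panel with days-to-flowering
   (DTF) contrasts, and co-expression clustering of candidates in a
   multi-tissue atlas.

## Models and conventions

**Between-NIL variant.** A record counts as a homozygous (HHQ) variant
only when both lines are homozygous *for different alleles*. Identical
hom-alt calls in both lines describe a shared divergence from the
reference, not a difference between the lines, and are excluded. This
reading follows from defining variants as positions where the NILs differ.

**Quality filter.** FILTER is treated as a semicolon-separated list of
failed criteria; `PASS` and `.` mean zero failed. A record is retained
when it fails at most `max_failed_filters` (default 1) criteria. The
criterion names themselves are opaque tokens — only the count matters.

**Depth filter.** Retained iff both samples have depth ≥ `min_depth`
(default 10 reads). Records with missing DP are excluded and tallied with
a warning rather than silently dropped.

**Residual heterozygosity.** Under selfing, heterozygosity halves every
generation from a fully heterozygous founder. `selfing_model()` maps `g`
stated generations of self-fertilization to `g − 1` effective halvings:
the founder generation establishes heterozygosity rather than halving it.
This convention is what reconciles a stated 11-generation pedigree with an
expectation of 100·(1/2)^10 ≈ 0.098%, and it is surfaced as an explicit,
overridable parameter (`n_halvings`) rather than buried in the formula.
Observed heterozygosity is simply 100·n_het/n_positions, reported to three
decimals.

**Coordinates.** VCF and GFF3 are 1-based inclusive. A variant's footprint
for overlap purposes is its full REF span (left-anchored VCF
representation): a SNV occupies one base, a deletion `POS .. POS +
len(REF) − 1`. Deletions spanning a region boundary classify by the
highest-precedence region touched. Hotspot BED output converts to 0-based
half-open.

**UTR sides.** 5′/3′ is decided in transcript orientation, so
complement-strand genes place low genomic coordinates on the 3′ side.

**Disruptive vs plain in-frame deletion.** An in-frame (length divisible
by 3) deletion is `inframe_deletion` when it removes whole codons on codon
boundaries and `disruptive_inframe_deletion` when it breaks codon
boundaries — the conventional reading of the snpEff distinction.

**t-tests.** Both the phenotype table and the panel DTF contrasts use the
pooled-variance Student t-test (df = n1 + n2 − 2), matching the stated
method; Welch is deliberately not the default. Stars follow
`*` 0.01 < P ≤ 0.05, `**` 0.001 < P ≤ 0.01, `***` P ≤ 0.001.
`summary_ttest()` works from summary statistics so printed tables
(mean ± SD, n) are directly checkable.

**Fisher test.** One-sided (greater), because the scientific question is
over-representation; no multiple-testing correction by default, with
Benjamini–Hochberg behind `adjust = "BH"`. These were genuinely open
choices: the source analyses do not state sidedness or correction, so the
package defaults to the most common practice for GO enrichment and makes
both explicit arguments.

**Haplotype groups.** Relative to the late-line haplotype over the
defining sites, with precedence H1 (exact match) > H2 (exact match to the
early haplotype) > H3 (exactly one mismatch) > H4 (match fraction in
[0.6, 1)) > OTHER. H4 generalizes a single observed 36-of-51 pattern to a
configurable band; missing calls are ignored and accessions under an 80%
call rate are excluded and tallied. The single-SNP DTF mode keeps only the
two homozygous classes.

**Expression.** TPM rescales each tissue column of the FPKM matrix to
10^6. Clustering is agglomerative with complete linkage on Euclidean
distances over `log2(TPM + 1)` rows; the log transform is a package choice
(the upstream heatmap tool's scaling is not documented) and `raw` and
`zscore` are available. `k` defaults to 5, matching the number of
discussed co-expression clusters; merge ties resolve by `stats::hclust`'s
deterministic ordering.

## What the synthetic generators emulate — and what they do not

All fixtures are generated, none downloaded. One master seed derives
independent child streams per generator, so adding a fixture never
perturbs the others, and equal seeds give byte-identical files.

* `simulate_annotation()` lays out loci from a biotype mix over the eight
  chickpea pseudomolecule lengths (Ca1 48.36 Mb … Ca8 16.48 Mb), mRNA loci
  with 1–6 exons, UTRs and up to 3 isoforms whose CDS always lies within
  exons, plus one planted pair of overlapping opposite-strand loci per
  chromosome to exercise dual-locus "both" calls.
* `simulate_nil_vcf()` plants, per chromosome, exactly the study-scale
  tier counts (77,170 detected down to 1,610 HHQ-I-C/E in 246 genes),
  spreading the HHQ-I-C/E variants over exactly the configured number of
  distinct protein-coding loci, plus depth-failing records, ≥2-token
  low-quality records (some multi-allelic), missing-DP records and
  unanchored scaffold records. Every record carries a truth label, so the
  whole cascade is checkable exactly.
* `simulate_pangenome()` plants the observed group structure (2,219 H1 /
  749 H2 / 120 H3 / 63 H4 / 20 other of 3,171 accessions over 51 sites)
  and per-location DTF normals: mean 70 d, SD 10 d across locations spread
  ±8 d, with a −6 d shift for the early-haplotype group in three of six
  location/seasons. These DTF parameters are package choices of realistic
  germplasm-scale values; the source data's per-location distributions are
  not published as parameters.
* `simulate_expression()` draws 5 cluster profiles as distinct even-parity
  on/off patterns over the 7 tissues (pairwise log2 separation ≥
  `cluster_separation·√2`, default 4·√2) and genes as noisy copies
  (log2 SD 0.5).

Deliberately **not** emulated: linkage disequilibrium and recombination
structure, read-level error models, the uneven genomic geography of the
real variant hotspots (planted loci and variants are spread uniformly, so
hotspot windows are exercised with direct plants in tests rather than by
the study-scale generator), sequence-level mutation spectra, and any GO
DAG structure (the annotation is a flat gene→term table). Passing
planted-truth tests therefore demonstrates the correctness of the
*computations*, not robustness to real-data pathologies such as reference
errors or segmental duplications.

## Numerical and degenerate-input choices

* Heterozygosity percentages round to 3 decimals;
  `expected_selfing_heterozygosity(..., digits = NULL)` returns the exact
  value (which halves exactly per generation).
* Fisher p-values come from the exact hypergeometric tail
  (`stats::fisher.test`); the test suite checks them against an
  independent summation of binomial coefficients to 1e-12.
* Zero pooled variance in `summary_ttest()`: equal means give t = 0 / ns;
  unequal means give p = 0 with a `zero_variance` flag instead of NaN.
* An all-zero tissue column is an error naming the tissue (TPM undefined);
  a constant expression matrix with k > 1 warns that the cut is decided by
  ties alone.
* A translated alternate CDS with no stop codon is flagged `no_stop`
  (stop-lost/readthrough) with the full translated length reported.
* Multi-allelic VCF rows are split before any filter; the original
  per-sample allele indices are preserved so contrasting homozygosity is
  judged on the original calls.

## Problem sizes

The test suite and acceptance checks run the generators at the full
study-scale defaults (77,170 planted records over 8 chromosomes; 3,171
accessions × 51 sites; 132 genes × 7 tissues), plus an exhaustive
100-kb-annotation sweep for the region classifier, 10,000 random CDS
indels for the frameshift criterion, and 1,000 replicates for the t-test
type-I calibration. The whole suite completes in well under a minute on a
single core.

## A compact worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
models <- simulate_annotation(cfg)
sim <- simulate_nil_vcf(cfg, models)
write_vcf(sim$rows, "nil_pair.vcf", contigs = cfg$chrom_lengths)

records <- read_vcf("nil_pair.vcf")
res <- run_triage(records, models)
res$report                      # per-chromosome tier counts + totals

pan <- simulate_pangenome(cfg)
labels <- assign_haplotype_groups(pan$geno, pan$refs)
group_frequencies(labels)       # H1 ~70%, H2 ~23.6%, ...

tpm <- fpkm_to_tpm(simulate_expression(cfg)$fpkm)
cluster_expression(tpm, k = 5)
```

## Known limitations

The effect classifier is intentionally minimal: no splice-site,
start-lost, regulatory or NMD modeling, and no indel re-normalization
(left-aligned input is assumed). The enrichment module consumes a flat
term table and performs no DAG-aware filtering. The haplotype rules are
match-pattern rules, not a statistical assignment; they do exactly what
the definitions above say and nothing more.
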