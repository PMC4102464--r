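---
title: "petalseq: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petalseq: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

petalseq reimplements, as a tested reusable pipeline, a de novo
transcriptome comparison between two flower-color morphs (purple, P, and
white, W) sampled as pooled individuals in two populations. The design has
no biological replicates and 40 bp single-end reads, so inference is
threshold-based, not model-based: no dispersion estimation, no negative
binomial testing. What the pipeline *does* guarantee is bookkeeping
discipline (every read and gene accounted for), reproducibility (one seed
drives everything), and a ground-truthed synthetic world in which each
stage's error behaviour can be measured.

The stages and their statistics:

* **Homology**: contigs are identified against a reference-species gene
  set by an ungapped seeded search scored +1/−2 and judged by
  Karlin–Altschul E-values, with a reciprocal best-hit (RBH) filter at
  `E < 1e-10` in both directions.
* **Consensus**: per gene and kmer, contigs from both morphs are anchored
  to the reference frame; column-wise base sets become IUPAC ambiguity
  codes; uncovered columns become `n`. The kmer whose consensus is longest
  while keeping the ambiguity fraction (excluding n's) under 1.9% is
  chosen.
* **Mapping**: hash-seeded (h = 14) alignment with at most 2 mismatches,
  IUPAC-compatible matching, and a strict uniqueness rule.
* **Expression**: RPKM over uniquely mapped reads;
  `RD = (P − W)/max(P, W)`; `consistency = RD_pop1 − RD_pop2`; calls at
  |mean RD| > 0.5 and |consistency| < 0.25.
* **Enrichment**: top-2% study sets per direction, exact hypergeometric
  tails, Benjamini–Hochberg step-up at q < 0.01 and q < 0.05.
* **Validation arithmetic**: ΔΔCT standardization, `(1+E)^ΔCT`
  linearization, log–log OLS, and the pg→bp genome-size conversion
  (978 Mbp per pg of diploid DNA).

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `evalue_threshold` | 1e-10 | – | stringent homolog identification; deliberately sacrifices fast-evolving genes |
| `ambiguity_threshold` | 0.019 | fraction | ceiling of intraspecific variation; above it, variation is assumed to be misassembly/misalignment/paralogy |
| `hash_length` | 14 | bp | seed length of the mapper |
| `max_mismatch` | 2 | bases/read | tolerates ~1.9% variation plus sequencing error over 40 bp |
| `min_reads` | 10 | reads/sample | below this, fold changes are spurious; removal corresponds to roughly RPKM < 1 |
| `rd_cutoff` | 0.5 | RD | "difference greater than 50% of the larger value" |
| `consistency_cutoff` | 0.25 | RD difference | keeps the most consistent quartile if consistency were uniform on [−1, 1] |
| `top_fraction` | 0.02 | – | study-set size for GO enrichment (92 genes at the scale of ~4,600 consistent genes) |
| `word_size` | 11 | bp | homology seed; blastn-like default |
| kmers | 19–29 odd | bp | assembly parameter sweep; max kmer = read length − 10 |

# What the synthetic world emulates — and what it does not

`sim_params()` defaults are the stated world: 300 reference genes with a
log-normal length distribution (median 676 bp), coding divergence 0.11
(≈89% identity to the reference species), two haplotypes per morph pool
differing at ≤1.9% of sites, 5% of genes carrying a paralog with ≥98% CDS
identity but 30% UTR divergence, 3′-biased 40 bp reads at 1% substitution
error, 3 × 10⁵ reads per sample, per-kmer contig sets averaging 1.475
contigs/gene, and a planted truth of 8 P>W plus 25 W>P genes at ~3.3×
fold (one CHS-like flagship at ~7×).

Choices the generator makes once, and why:

* **3′ bias** is a single exponential tilt of fragment start positions
  (inverse-CDF sampling), one knob for the poly-A-selection artifact.
* **Biological noise** is multiplicative log-normal (sd 0.10) per gene and
  sample — enough to make null RD fluctuate visibly without manufacturing
  false positives.
* **DE planting eligibility**: differential labels are planted only on
  non-paralog genes whose *downregulated* morph stays at base RPKM ≥ 20
  and an expected unique-read count at least twice the 10-read filter.
  Lowly expressed DE genes are invisible to any threshold method (the real
  flagship gene is in the top fraction of a percent of expression), so
  planting them would only blur what a green recovery test establishes.
* **Quality strings** are constant (the emulated pipeline used unfiltered
  FASTQ); no PCR duplicates, adapters, quality decay, or paired ends.

A green end-to-end test therefore establishes that the *pipeline* recovers
a clean, well-powered truth — it says nothing about adapter contamination,
degraded RNA, unmodeled isoforms, or fold changes near the detection
floor.

# Numerical and algorithmic choices

* **Karlin–Altschul K**: λ solves `Σ p_i p_j exp(λ s_ij) = 1` by bracketed
  root-finding (|f| < 1e-10). K uses the standard ungapped lattice
  approximation `K = δλ e^{−2σ} / (H (1 − e^{−δλ}))` with σ a Spitzer-type
  series over n-step score sums; for +1/−2 this reproduces blastn's
  printed constants (λ 1.33, K 0.621, H 1.12).
* **Mapper completeness**: exact 14-mer seeding of a 40 bp read is
  pigeonhole-complete only at ≤1 mismatch. Reads whose best seeded
  placement still has ≥2 mismatches are re-collected through three
  disjoint 13 bp rescue chunks (one of which must be mismatch-free), so
  the minimal-mismatch placement set — and hence unique/multi/filtered
  classification — is provably identical to an exhaustive scan. A read
  with two placements *anywhere*, including the same gene, is non-unique.
* **Consensus denominators**: the ambiguity fraction divides by non-n
  positions only; `n` is missing data, not a fifth state; a gap under one
  contig but a base under another uses the bases present.
* **Tie-breaks**: best hits break ties by lower E-value then lexicographic
  subject id; kmer selection breaks length ties toward the smaller kmer;
  study-set boundaries break mean-RD ties by lexicographic gene id.
  Study-set size uses round-half-up (R's `round()` is round-half-even).
* **Rounding in reports**: percentages round half-up to one decimal;
  RPKM prints at 3 significant figures; RD and consistency at 3 decimals.
* **Degenerate inputs**: RD is computed only after the low-count filter,
  so 0/0 cannot occur; `hypergeom_test` clamps its exact tail sum at 1
  against float round-up; the fold-change profile adds a pseudocount of 1
  read to both windowed depths because end-of-gene depths reach zero.
* **Triage order**: re-anchor first (misalignment is the most common
  cause), then the paralog signature (pairwise CDS identity ≥ 98% with UTR
  identity < 90% — kept and labeled, even if the UTR columns keep the
  record above the 1.9% gate, since the ambiguity is confined to UTRs),
  then removal of contigs whose CDS identity to the reference trails the
  best contig by > 5 points. Genes that still fail are dropped.
* **RBH scope**: within one (sample × kmer) assembly, at most one contig
  per gene survives RBH (the gene's best hit must be that contig); genes
  accumulate multiple contigs because the pipeline runs RBH per sample and
  per kmer and merges afterwards.

# Open design points, resolved

* The exact blastn task/word size behind the original filter is unstated;
  petalseq fixes ungapped seed-and-extend at word 11 with +1/−2, which
  reproduces the intended behaviour at these divergences (11% passes,
  22.5% fails at short gene lengths, at equal length and threshold).
* Whether the 1.9% denominator includes columns covered only by removed
  contigs: fixed as non-n positions of the final consensus.
* Whether the ±0.5 RD cutoff precedes or follows averaging across
  populations: applied to the mean RD.
* "Unique" mapping is per-position, not per-reference: two placements on
  one gene disqualify a read. This marginally raises the multi rate but is
  the strictest reading.

# Known limitations

* Power of the planted-GO-enrichment check: with a 25-gene study, a
  40%-vs-5% planted term cannot clear BH q < 0.01 in ≥95% of replicates
  for any realistic term count (the binomial lower tail of the study count
  is too heavy); the property is tested at the pipeline's own top-2%
  study size (92 genes), where detection is essentially certain.
* Fold-change recovery is Poisson-limited near the expression floor: at
  3 × 10⁵ reads, a true RPKM of 10 corresponds to only a handful of
  reads, so the recovery invariant is asserted as ≥90% of eligible genes
  within 25% of the true level ratio (median error ≤ 10%), not per-gene.
* The contig-length-vs-kmer model is a stylized stand-in; no assembler
  graph dynamics are simulated.
* No GO-DAG ancestor propagation; annotations are flat gene–term pairs.
* No isoform-aware consensus: isoforms are flattened into the contig pool.
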