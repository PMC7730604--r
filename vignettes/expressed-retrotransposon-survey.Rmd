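---
title: "Methods: surveying expressed LTR retrotransposons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying expressed LTR retrotransposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models each
stage implements, the assumptions behind them, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where conventions were genuinely open.

## The survey in one paragraph

LTR retrotransposons (RTEs) are annotated by upstream structural tools
(LTRharvest/LTRdigest-style output is consumed, never recomputed). Most
annotated elements are transcriptionally silent decay products; the survey's
job is to isolate the expressed minority (exRTEs) with per-sample RNA-seq
evidence, then characterize what distinguishes them from the silent majority
(n-exRTEs): insertion age from LTR divergence, protein-coding capacity and
the GAG RNA-binding motif, proximity to genes, and copy-number variation
across cultivars as a proxy for recent mobility.

## Expression calling

An element is called expressed when three conditions hold:

* **RPKM ≥ 0.25** in at least one sample, with
  `RPKM = reads × 10⁹ / (length × library size)`. Counts are taken at face
  value (one increment per read); multi-mapping policy is an upstream
  aligner concern.
* **Breadth of coverage ≥ 0.60** in at least one sample: the fraction of
  element bases covered at depth ≥ 1. This is the filter that removes
  pervasive-transcription artifacts where only an LTR or a fragment inside a
  gene UTR is covered.
* **Best domain match ≥ 50 aa**, the manual-curation analog that removes
  elements whose only protein evidence is a trivially short hit.

Two genuinely open conventions are resolved as follows, both configurable:

* Thresholds are **inclusive** (≥ 0.25, ≥ 0.60). The source conventions mix
  strict and non-strict readings; the inclusive reading is used consistently.
* The RPKM and coverage criteria may be satisfied in **different samples**
  (default), because nothing ties them together; a strict mode
  (`strict_same_sample = TRUE`) requires one sample passing both. Coverage
  is evaluated **per sample** by default; `pooled_coverage = TRUE` uses the
  best per-sample breadth as a pooled approximation.

Redundancy removal (global identity > 0.95) is applied to the expressed set
only; elements dropped there rejoin the n-exRTE set, so the two sets always
partition the catalog. The identity measure is Needleman–Wunsch global
alignment identity (match +1, mismatch −1, linear gap −2; identity =
matching columns / alignment columns). No similarity tool is canonical for
this step, so the package defines it explicitly and resolves *which copy
survives* deterministically: greedy keep-longest, ties by chromosome then
start coordinate.

## Insertion dating

The two LTRs of an element are identical at insertion; divergence accumulates
afterwards at the neutral rate. The 5′ and 3′ LTRs are globally aligned
(same scoring as above), substitutions are counted over **gap-free columns
only** (transitions: A↔G, C↔T; everything else a transversion), and the
Kimura two-parameter distance is

$$k = -\tfrac{1}{2}\,\ln\big((1 - 2p - q)\sqrt{1 - 2q}\big),$$

with insertion time `T = k / (2r)`, `r = 1.3 × 10⁻⁸` substitutions · site⁻¹
· year⁻¹ by default. Insertions with `T < 0.5` Mya are *recent*; the
boundary itself is *late*. Elements whose divergence saturates the K2P
domain (`1 − 2p − q ≤ 0` or `1 − 2q ≤ 0`) are reported as undatable rather
than silently dropped.

Numerical notes:

* The K2P formula is sometimes printed without the leading minus sign; since
  its log argument is below 1, the signed (standard) form is the only one
  that yields a non-negative distance, and that is what the package
  implements.
* "log" is the natural logarithm.
* Optimal-alignment ties are resolved by the alignment engine's
  deterministic choice; because p and q are counted on gap-free columns
  only, tie choice does not move the estimates in practice.
* For a 350-bp LTR pair near the 0.5-Mya boundary the standard error of `T`
  is roughly 0.1–0.15 Mya, so per-element recency calls near the boundary
  are intrinsically noisy; the package's tests therefore assert *parameter
  recovery in expectation* (mean over replicates within 10%) and per-element
  classification only away from the boundary.

## ORF and RNA-binding-motif screen

Six-frame ORF prediction reports every maximal start-to-stop region of
≥ 300 nt: the span runs from the first ATG after the previous terminator
through the last codon before the stop; the stop codon is excluded.
Reverse-strand ORFs are mapped back to input coordinates. An ambiguous (N)
codon truncates an ORF at that codon.

Domain labeling is pluggable: production mode ingests an external hit table
(BLAST-vs-REXdb style, `orf_id → domain`); synthetic mode matches planted
peptide tags exactly. Profile/HMM search is deliberately out of scope.

The RNA-binding motif is the CCHC zinc knuckle `C-X₂-C-X₄-H-X₄-C`
(14 residues), counted as **non-overlapping, left-to-right** matches —
overlap handling is not canonical, and the non-overlapping count is the
conservative choice. The empirical false-discovery rate of the motif scan is
the motif rate among ORFs *not* labeled GAG; because a count ambiguity
(ORF-level vs element-level) exists in this kind of bookkeeping, the per-set
summary reports both granularities.

## Gene proximity

Distance to the nearest gene uses full gene spans (introns and UTRs
included) and ignores strand. Categories, in precedence order: *insertion*
(element entirely inside a gene), *overlapped* (≥ 1 shared base without
containment), *close* (gap < 1000 bp), *distant* (gap ≥ 1000 bp). Two edge
conventions: a gap of exactly 1 kb is distant, and adjacency (gap 0 without
a shared base) is close with distance 0. A chromosome without genes yields
an infinite distance and category distant.

## Mobilome: the ACM ratio

Per cultivar, an element's mean read depth is divided by the unweighted mean
depth of single-copy reference genes in the same cultivar — this cancels
library-size differences and converts depth to a copy-number proxy. The ACM
ratio divides each cultivar's normalized coverage by the element's minimum
across cultivars, so the least-covered cultivar is the within-element
baseline (ACM = 1). The cutoff is derived from the reference genes
themselves: for each reference gene, its maximum ACM divided by its minimum
(1 by construction), maximized over genes — the largest apparent swing a
locus with *no* copy-number variation shows. A fixed override (e.g. the
conventional ~1.7) is available because the derived cutoff tracks the noise
of the particular depth data. Elements whose ACM exceeds the cutoff
(strictly) in more than one cultivar (strictly) form group 1; elements with
zero depth in any cultivar are excluded from ACM arithmetic and reported as
presence/absence variation, since the ratio is undefined there.

## Statistics

The two-sided Fisher exact test uses the minimum-likelihood convention: the
p-value sums hypergeometric probabilities, over tables with the observed
margins, that do not exceed the observed table's probability — with a
relative tolerance of 10⁻⁷ when comparing probabilities, guarding against
floating-point ties. Probabilities are computed via log-binomial
coefficients and remain stable for totals in the tens of thousands. The
implementation is validated two independent ways: exhaustive enumeration
over every 2×2 table with total ≤ 40, and agreement with `stats::fisher.test`.

Wilcoxon rank-sum comparisons are exact when both samples have ≤ 25
observations and no ties, otherwise the normal approximation with tie and
continuity corrections; the mode used is recorded per call. Reported
percentages round half away from zero. No multiple-testing correction is
applied: the enrichment report deliberately reports raw p-values.

## The synthetic-data generator

`simulate_dataset()` emulates exactly the inputs the pipeline consumes, with
full ground truth:

* **Genome**: i.i.d. uniform background nucleotides — adequate because no
  homology search is in scope. Elements are placed in disjoint
  per-chromosome slots with random jitter: collision-free by construction,
  and each element keeps a private neighborhood so its planted nearest-gene
  class is always the realized one. Reference single-copy genes sit in a
  reserved tail far from every element.
* **LTR divergence**: the 3′ LTR is the 5′ LTR passed through a single-hit
  per-site mutation process with planted transition/transversion rates
  solved (at a 2:1 ts/tv ratio) from a target insertion time; planted times
  are bimodal around the 0.5-Mya boundary (uniform on 0.05–0.4 and
  0.6–2.5 Mya).
* **ORFs**: reverse-translated peptides (random synonymous codons) carrying
  one distinctive tryptophan-delimited tag per domain and, for GAG, planted
  CCHC motifs; filler residues exclude cysteine so planted motif counts are
  exact. Each cassette is preceded by an in-frame stop so the planted start
  is the maximal one. A flag plants ORFs on the reverse strand to exercise
  six-frame finding.
* **Expression**: emitted as what aligners would have produced — a
  read-count table inverting the RPKM formula and per-sample bedGraph depth
  realizing the target breadth exactly. Expressed elements get RPKM 1–50
  and breadth 0.8–1.0 in a random non-empty sample subset; decoys cycle
  three failure modes (RPKM ≤ 0.05 with high breadth; breadth ≤ 0.2 with
  high RPKM; fully silent), so every arm of the calling cascade is
  exercised.
* **Cultivar depth**: per-cultivar scale factors (library size differences)
  times planted copy-number multipliers (mobile elements: 2–4× in ≥ 2
  cultivars) times multiplicative gaussian noise of configurable CV
  (default 5%).
* **Determinism**: sequence, expression, and cultivar noise each draw from
  their own stream derived from the master seed, so adding samples never
  perturbs the genome; identical config + seed gives byte-identical files.

What it does **not** emulate — and what passing tests therefore do not show
about real data: read-level noise (no FASTQ, no sequencing-error model),
nested and solo-LTR structures, homologous element families (background is
uniform random, so dedup is only exercised by explicitly planted
duplicates), pervasive low-level transcription, and mapping ambiguity.
Recovery at 100% precision/recall on synthetic data demonstrates that the
filter cascade implements its definitions correctly, not that the
thresholds are optimal for any particular genome.

## Problem sizes and defaults

The validation suite runs a full survey on a ~1-Mb, two-chromosome genome
with 50 planted elements (25 expressed), 5 RNA-seq samples, and 13
cultivars; unit tests use a 200-kb, 10-element reduction. LTRs default to
350 bp and planted domain ORFs to 150 aa (so domain hits comfortably clear
the 50-aa curation filter and elements clear the 500-bp candidate filter).
Insertion-age recovery is validated on 100 replicates of 1,000-bp LTR pairs
at planted (p, q) = (0.02, 0.01). These sizes were chosen so each
statistical property is tested at a scale where its expected error is well
inside the asserted tolerance.

## Known limitations

* The dedup identity metric and the surviving-copy rule are package
  conventions; other reasonable choices (local alignment, coverage-weighted
  identity, cluster representatives) would retain slightly different sets
  near the 95% boundary.
* K2P dating assumes both LTRs evolve neutrally and independently at a
  single rate; gene conversion between LTRs and rate heterogeneity bias
  ages downward and are not modeled.
* The ACM ratio is depth-based and loses sensitivity for high-copy
  elements, where one extra copy changes relative coverage little.
* The enrichment report tests each attribute marginally; attributes are
  correlated (age, clade, GAG content), and no joint model is attempted.
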