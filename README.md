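# exrte

Genome-wide surveys of LTR retrotransposons (RTEs) typically annotate tens of
thousands of elements, yet only a small minority are transcribed, and fewer
still are mobile. `exrte` implements, as a tested and reusable R pipeline, the
full survey that separates that minority out of an annotated genome:

1. **Candidate catalog** — parse LTRdigest-style GFF3 (element + paired LTR +
   protein-match features), keep elements > 500 bp with at least one canonical
   domain hit (GAG, AP, INT, RT, RH), and collapse near-duplicates above 95%
   global alignment identity.
2. **Expression calling** — an element is an *exRTE* when RPKM ≥ 0.25 in at
   least one RNA-seq sample **and** breadth of coverage ≥ 60% **and** its best
   domain match is ≥ 50 aa; everything else is an *n-exRTE*. RPKM is
   `reads × 10⁹ / (length × library size)`; breadth is the fraction of bases
   covered at depth ≥ 1.
3. **Insertion dating** — the two LTRs of an element are identical on
   insertion and diverge afterwards; aligning the 5′ and 3′ LTRs and counting
   transition (*p*) and transversion (*q*) frequencies gives the Kimura
   two-parameter distance
   `k = −½ ln((1 − 2p − q)·√(1 − 2q))` and the insertion time
   `T = k / (2r)` with `r = 1.3 × 10⁻⁸` substitutions · site⁻¹ · year⁻¹;
   insertions younger than 0.5 Mya are *recent*.
4. **ORF and motif screen** — six-frame ORF prediction (≥ 300 nt,
   start-to-stop), domain labeling (external hit table or planted peptide
   tags), and a scan of every protein for the CCHC zinc-knuckle RNA-binding
   motif `C-X₂-C-X₄-H-X₄-C`, with an empirical false-discovery rate: the
   motif rate among non-GAG ORFs.
5. **Gene proximity** — distance to the nearest annotated gene with four
   categories: insertion (inside a gene), overlapped, close (< 1 kb),
   distant (≥ 1 kb).
6. **Mobilome (ACM) analysis** — per-cultivar element depth normalized by
   single-copy reference genes, divided by the element's minimum across
   cultivars (the ACM ratio); the cutoff is the largest ACM swing any
   reference gene shows (~1.7 in practice), and elements exceeding it in
   more than one cultivar form mobility group 1.
7. **Enrichment statistics** — two-sided Fisher's exact tests
   (minimum-likelihood convention, log-factorial arithmetic) and Wilcoxon
   rank-sum comparisons between the exRTE and n-exRTE sets.

A first-class synthetic-data generator (`simulate_dataset()`) plants all of
this ground truth — LTR divergence at controlled transition/transversion
rates, expression at target RPKM/breadth, domain tags and CCHC motifs, genes
at controlled distances, per-cultivar copy-number multipliers — so the whole
pipeline is validated offline against known answers.

Everything is tidyverse-native: functions take a data frame first and return
tibbles, results chain with the pipe, fitted objects have `tidy()` /
`glance()` methods and `autoplot()` visualizations.

## Worked example

```r
library(exrte)
library(dplyr)

cfg <- simulation_config(n_chrom = 1, chrom_length = 200000, n_rte = 10,
                         n_expressed = 5, n_cultivars = 6)
ds  <- simulate_dataset(cfg, seed = 42, out_dir = tempfile("exrte_demo"))
res <- run_pipeline(ds, pipeline_config(seed = 42), tempfile("exrte_out"))

str(res$summary$funnel)
#> List of 7
#>  $ n_annotated        : int 10
#>  $ n_candidates       : int 10
#>  $ n_rpkm_pass        : int 7
#>  $ n_rpkm_and_coverage: int 5
#>  $ n_curated          : int 5
#>  $ n_exrte            : int 5
#>  $ n_nexrte           : int 5
```

The funnel shows the candidate filter cascade: 10 annotated elements, 7 pass
the RPKM screen, 5 also pass breadth-of-coverage, all 5 survive curation and
dedup — exactly the 5 elements the simulator planted as expressed.

```r
res$ages |> select(rte_id, p, q, k, t_mya, recency) |> head(4)
#>   rte_id           p           q           k     t_mya recency
#> 1   TE01 0.028571429 0.014285714 0.044300870 1.7038796    late
#> 2   TE02 0.005714286 0.000000000 0.005747190 0.2210458  recent
#> 3   TE03 0.002857143 0.002857143 0.005736856 0.2206483  recent
#> 4   TE04 0.014285714 0.008571429 0.023247986 0.8941533    late
```

Per element: transition/transversion frequencies from the LTR-pair
alignment, the K2P distance, and the implied insertion time in Mya.

```r
res$acm
#> ACM mobilome analysis: 10 elements x 6 cultivars; cutoff 1.181 (derived)
#> # A tibble: 2 × 2
#>   group      n
#>   <chr>  <int>
#> 1 group1     6
#> 2 group2     4
```

The derived cutoff (1.18 here) is the largest copy-number swing a single-copy
reference gene shows across cultivars; six elements exceed it in more than
one cultivar and are called potentially mobile. `autoplot(res$acm)` draws the
log2 ACM heatmap.

Set-level statistics work directly on published count tables too:

```r
fisher_exact_two_sided(matrix(c(21, 23, 5932, 29037), 2))
#> Fisher's Exact Test for Count Data (two-sided)
#>      [,1]  [,2]
#> [1,]   21  5932
#> [2,]   23 29037
#> p-value = 2.384e-06, sample odds ratio = 4.469

percent(25, 44)$label
#> [1] "57%"
```

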