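# annoshift

Enrichment testing for trait-associated variants against genomic
annotations, with a **locus-local shifting null**.

Genome-wide association studies report index SNPs whose causal variants are
usually unknown; deciding which functional annotation (open chromatin,
histone-mark peaks, exons, promoters, ...) best prioritizes causal variants
requires asking whether the associated loci overlap that annotation more
than chance allows. Genome-wide backgrounds answer the wrong question:
associated loci live in regions whose gene density, variant density and
linkage disequilibrium (LD) differ from the genome at large, and
annotations colocalize with each other. `annoshift` addresses both problems
for R users working with GWAS results, fine-mapping pipelines, or
epigenomic annotation catalogues.

## The statistic

For index SNP *i*, let the locus be the span of all variants in LD with it
(r² > 0.8 by default) extended by twice the median annotation interval size
on each side, of length *L<sub>i</sub>*. The observed overlap is

> *o* = (1/*n*) · #{loci with at least one linked SNP inside the annotation},

with half-open BED coordinates (a SNP at *p* overlaps `[start, end)` iff
`start ≤ p < end`). Each of *n<sub>iter</sub>* null iterations draws an
independent uniform integer offset *k<sub>i</sub>* ∈ {0, ..., *L<sub>i</sub>*−1}
per locus, circularly shifts the locus's annotation intervals by
*k<sub>i</sub>* (wrapping at the boundary) while SNPs stay fixed, and
records the shifted overlap proportion *o<sub>s</sub>*. Then

* **p-value** = #{*s* : *o<sub>s</sub>* ≥ *o*} / *n<sub>iter</sub>* (reported
  as `< 1/n` when the count is zero),
* **delta-overlap** = *o* − mean(*o<sub>s</sub>*), the effect size,
* **overlap score** of locus *ℓ* = *l<sub>s</sub>*/*n*, the fraction of
  iterations in which that locus overlaps by chance — low-score loci drive
  the enrichment and are fine-mapping candidates.

A **stratified** variant tests annotation X while controlling a
colocalizing annotation Y: each locus is cut at Y boundaries, the fragments
are concatenated into a Y segment and a complement segment, and X is
shifted within the two segments independently. A **matching** baseline
(`matching_test()`) draws null SNP sets matched on gene overlap, MAF, TSS
and TES distance bins and LD proxy counts, mainly to demonstrate when
background matching fails. A **simulation harness** generates synthetic
genomes (LD blocks, annotation tracks with tunable density and
colocalization, gene tables, array-like tag panels) for power, calibration
and causal-proportion studies without any external data.

## Worked example

Everything below is synthetic and reproducible; no downloads.

```r
library(annoshift)

g <- simulate_genome(sim_config(seed = 1))
g
#> sim_genome (seed 1): 4e+07 bp on 20 chromosomes, 40000 variants x 100 haplotypes
#>   tracks: x (16.6%)
#>   genes: 1500, array variants: 24000

# a SNP set in which every locus tags a causal variant inside the annotation
set <- draw_functional_set(g, category = "x", n_loci = 200,
                           causal_fraction = 1, tag_r2_min = 0.8, seed = 2)
res <- shift_test_set(g, set$snps$id, n_iterations = 1000, seed = 3)
res
#> Local-shifting enrichment test
#>   loci: 200
#>   iterations: 1000 (seed 3)
#>   observed overlap: 1.0000
#>   mean null overlap: 0.7256
#>   delta-overlap: +0.2744
#>   p-value: <1e-03
#>   200 overlapping locus/loci; best overlap scores: v006703=0.117, v025165=0.165, v021237=0.213
```

All 200 loci overlap the annotation, against a mean of 72.6% under random
local shifts; no shift iteration matched the observed count, so p is
bounded by the iteration count. Locus `v006703` would overlap by chance in
only 11.7% of shifts — the strongest single-locus evidence, hence the best
candidate for functional follow-up.

With a moderately enriched set, delta-overlap can be inverted to estimate
the proportion of loci whose causal variant lies inside the annotation:

```r
set3 <- draw_functional_set(g, category = "x", n_loci = 200,
                            causal_fraction = 0.3, tag_r2_min = 0.8, seed = 106)
res3 <- shift_test_set(g, set3$snps$id, n_iterations = 1000, seed = 206)
sprintf("observed %.3f, delta %+.4f, p = %s",
        res3$observed_overlap, res3$delta_overlap, res3$p_report)
#> [1] "observed 0.595, delta +0.0325, p = 0.129"

ic <- infer_causal_proportion(res3$delta_overlap, g, set_size = 200,
                              n_sets_per_increment = 100, seed = 4)
sprintf("inferred causal fraction: mean %.2f, 95%% CI [%.2f, %.2f]",
        ic$mean, ic$ci[1], ic$ci[2])
#> [1] "inferred causal fraction: mean 0.27, 95% CI [0.00, 0.42]"
```

The interval comfortably covers the planted fraction (0.30); a single
200-locus set constrains the proportion only loosely, which is exactly what
the width communicates.

Real data enter through files: `read_snpmap()` (index SNPs),
`read_vcf_panel()` (phased haplotypes) or `read_proxy_table()` (precomputed
LD), `read_bed()` / `read_narrowpeak()` (annotations, with
`summit_windows()` for ±flank summit regions), `read_gene_table()` +
`gene_features()` (promoters, exons, introns). `build_loci()` +
`enrichment_test()` / `stratified_test()` run the analysis;
`write_results()` emits summary and per-locus TSVs. A thin command-line
wrapper with the same functionality ships at `inst/cli/annoshift.R`
(subcommands `test`, `stratified`, `match`, `simulate`, `prep`).

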