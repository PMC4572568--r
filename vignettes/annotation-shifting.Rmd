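---
title: "Local annotation shifting: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local annotation shifting: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annoshift)
```

## The question and the null model

Given a set of trait-associated index SNPs, do these associations overlap a
genomic annotation (open chromatin, histone-mark peaks, exons, ...) more
often than chance would allow? The difficulty is that "chance" is not
genome-wide uniformity: associated loci sit in regions with their own gene
density, variant density and linkage disequilibrium (LD), and annotations
cluster in the same places. A genome-wide background therefore inflates
enrichment estimates unless every relevant confounder is matched away — and
the relevant confounders are not known in advance.

`annoshift` instead builds the null *locally*. For each index SNP we take
all variants in LD with it (r² strictly above a threshold, 0.8 by default,
computed from phased haplotypes or supplied as a proxy table), define the
locus as the span of those variants extended by twice the median annotation
interval size on **each** side, and ask whether any of the linked SNPs falls
inside an annotation interval (half-open BED semantics: a SNP at position
*p* overlaps `[start, end)` iff `start <= p < end`). The null distribution
is obtained by circularly shifting the annotation intervals within each
locus — a uniform integer offset in `{0, ..., L-1}` per locus per
iteration, independent across loci, with intervals wrapping around the
locus boundary — while SNP positions stay fixed. Shifting preserves the
number, sizes and spacing of local annotation intervals exactly, so local
structure is controlled by construction.

Per analysis we report:

* the **observed overlap**: the proportion of loci with at least one linked
  SNP in the annotation;
* the **p-value**: the proportion of iterations whose shifted overlap count
  is greater than or equal to the observed count (ties count against
  enrichment; a zero count is reported as `< 1/n`, and a `(count+1)/(n+1)`
  estimator is available behind `add_one = TRUE`);
* **delta-overlap**: observed overlap minus the mean null overlap — the
  effect size, robust to the number of proxies per locus;
* per-locus **overlap scores** `ls/n`: the chance that each
  observed-overlapping locus would overlap under a random shift. Loci with
  low scores carry the enrichment signal and are the fine-mapping
  candidates.

### Why two-sided window extension

The locus is extended by `2 * median_size(annotation)` on each side (total
`4m + 1` guaranteed window length). A single-SNP locus then always admits
both overlap and non-overlap states under shifting; a one-sided extension
would make the achievable offset set asymmetric around the observed
configuration and bias the null for short loci.

### The stratified test

Colocalizing annotations confound each other: if open chromatin sits on
exons, an exon-driven signal shows up as open-chromatin enrichment too. The
stratified test of X given Y cuts each locus wherever Y starts or ends,
concatenates the fragments into a Y segment and a complement segment
(X intervals split at fragment boundaries; a SNP exactly at a Y end belongs
to the complement, by half-open convention), and shifts X *within each
segment independently*, with per-segment circularization. A locus counts as
overlapping when any SNP meets shifted X in either segment. If X overlaps
SNPs only through its colocalization with Y, the within-segment shifts
erase the signal; a genuinely independent X signal survives. With an empty
Y the construction degenerates to the unstratified test — the test suite
checks that the null draws are then *identical*, not merely similar.
Stratification constrains the shift space and can cost some power; the
simulations below quantify that this cost is small when the causal
annotation is the one being tested.

### The matching baseline

For comparison, `matching_test()` implements the classical background
approach: null SNP sets drawn from a panel matched on configurable axes —
gene overlap, 5%-wide MAF bins, distance-to-nearest-TSS bins (0.5/2/5/10/
20/100 kb), distance bins to the TES of the gene with the nearest TSS
(1/2/5/10/20/100 kb), and the number of LD proxies. Pools smaller than 20
candidates widen along the LD axis only (±1, ±2, ... bins); other axes
never relax, and an unsatisfiable pool is a hard error. Overlap is counted
at the locus level (SNP plus proxies), exactly as in the shifting test.
Its purpose here is diagnostic: on LD-heterogeneous panels, omitting the
LD axis inflates type-I error badly, and the simulation harness reproduces
that failure mode.

## The synthetic genome

Real inputs (reference haplotypes, consolidated open-chromatin tracks) are
tens of gigabytes; the simulation harness emulates their statistical
features at desk scale so that power, calibration and inference studies run
in seconds. Defaults of `sim_config()`, chosen once as the package's
standard study conditions:

| parameter | default | rationale |
|---|---|---|
| genome | 40 Mb, 20 chromosomes | room for ~300 loci spaced >100 kb |
| variants | 40,000 on 100 phased haplotypes | ~1/kb common-variant density |
| LD blocks | 5 kb, target within-block r² 0.9 | ~5 proxies per index SNP and per-locus null overlap ~0.3–0.5, the regime of GWAS loci tested against DHS-scale annotations at this variant density |
| annotation coverage | 16% of the genome | the coverage of a consolidated multi-cell-type DHS track |
| interval sizes | lognormal, median 500 bp, log-sd 0.5 | peak-call-like size spread |
| genes | 1,500 transcripts, 2–5 exons | supports GEN/TSS/TES matching axes |
| array fraction | 0.6 | tag SNP ascertainment on an array subset |
| SNP sets | 200 loci, >100 kb apart | independence filter |

Haplotypes use a copy-with-mutation scheme: each block draws a founder
frequency q and per-haplotype founder states, and every variant copies its
haplotype's founder state with a per-site flip probability solved (given q)
so that pairwise within-block correlation hits the r² target; blocks are
mutually independent. `block_density_dispersion` modulates per-block
variant density to create LD-heterogeneous ("confounded") panels. A
colocalization rule can anchor a second track's intervals near the first
track's interval centres with a jitter, to study stratification.

What the generator does *not* emulate: coalescent LD decay (block
boundaries are hard), allele-frequency spectra of real populations,
functional clustering of annotations around genes, and chromosome-scale
coverage waves. Passing tests therefore demonstrate the statistical
properties of the method under controlled conditions, not performance on
any particular real dataset.

## Simulation studies and their numerical conditions

All randomized computations take explicit seeds, and study-level seeds are
derived from one root seed; results are reproducible bit-for-bit from
(inputs, seed). The test suite runs each study at the sizes below.

* **Exactness** — for loci of integer length ≤ 50, the Monte Carlo p-value
  is checked against exhaustive enumeration of all joint offsets and
  against the analytic product law (Poisson-binomial tail over exact
  per-locus overlap-offset measures), within three binomial standard
  errors at 10,000 iterations.
* **Type-I error** — 200 annotation-independent SNP sets of 200 loci at
  1,000 iterations: the share reaching p < 0.05 must lie within three
  binomial SEs of 5%. The plug-in estimator with ties counted as extreme is
  conservative at this locus count (overlap counts are coarse, so top-tail
  ties are common), and observed rates run at 1–3%.
* **Power** — with every locus tagging a causal variant inside the
  annotation (tags at r² ≥ 0.8 from the array subset, falling back to the
  functional variant), 100 of 100 sets reach p < 0.001.
* **Stratification** — with causal variants in X and Y anchored around X,
  the unstratified test of Y rejects in most sets, the X-stratified test of
  Y returns to nominal, and the Y-stratified test of X keeps >90% power at
  p < 0.001.
* **Delta-overlap** — under the null, delta sits within three null SDs of
  zero, and its mean does not depend on whether index SNPs come from
  sparse- or dense-LD regions. Because sets simulated on one genome share
  that genome's annotation realization, the mean-zero and invariance
  checks average over six independent genome replicates and use
  across-genome standard errors.
* **Causal-proportion inference** — `infer_causal_proportion()` inverts an
  observed delta against a reference distribution simulated on a fraction
  grid (0–45% in 3% steps, 100 sets per increment; the grid step is a
  parameter, as published figures have used both 3% and 5%). Sets whose
  delta falls within ±0.002 (0.2 percentage points — delta is reported in
  percent, and the published ±0.2 band is read on that scale) of the
  observed value form the posterior-like distribution of the true
  fraction; its mean and central 95% interval are reported. The interval
  covers a planted fraction of 0.1/0.2/0.3 in ≥90% of repetitions at set
  size 100. The reference table is built once per genome and reused across
  observed values.
* **Matching failure mode** — on a panel with `block_density_dispersion =
  1` and test sets drawn from high-LD-count regions, matching on
  GEN/MAF/TSS rejects the (true) null in most sets, while adding the LD
  axis (GEN/TSS/TES/LD) restores calibration. At this panel size some
  matching keys hold fewer than 20 background variants; study sets are
  drawn from keys with at least 40 members so that both axis
  configurations are runnable — the under-supported-pool error path is
  exercised separately.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere (BED convention); summit
  windows are `2*flank + 1` bp (the summit base ± flank, 201 bp at the
  default, width parameterizable since published summit regions are
  described only as ±100 bp), clipped at coordinate 0.
* The median interval size of an even-length set is the lower central
  value — a pure integer, reproducible without rounding policy.
* Touching intervals merge: for point-overlap queries they are
  indistinguishable.
* Thresholds are strict where conventionally printed as strict (`r² >
  0.8` proxies, `r² > 0.1` pruning); tag selection uses `≥` with ties
  broken by distance, then position.
* Loci with no local annotation overlap nothing, observed and null alike;
  they dilute both proportions equally and need no special handling.
* A locus window is clipped at coordinate 0 only; chromosome ends are not
  known to the test and long windows simply see no annotation beyond them.
* In the stratified test, an annotation fragment longer than its segment
  wraps onto itself; covered bases are recomputed after wrapping, so
  conservation holds at the fragment level.
* The Monte Carlo engine precomputes, per locus, the exact set of offsets
  producing overlap (an interval union on offset space) and samples
  offsets into it; this is distributionally identical to shifting
  intervals explicitly and is verified against that route, and against a
  per-base rotation oracle, in the unit tests. It also yields the exact
  per-locus overlap chance (`locus_overlap_probability()`), the
  infinite-iteration limit of the overlap score.
* RNG: one root seed per analysis, loci processed in input order on a
  single stream. Derived per-component streams were considered and
  rejected — base R has no cheap counter-based generators, and the
  reproducibility contract (same inputs and seed, same output, tested
  byte-for-byte on written results) is what comparable R permutation tools
  provide.

## Known limitations

* Unphased genotypes are not supported; LD comes from phased haplotypes or
  precomputed proxy tables.
* One stratifying annotation at a time (pairwise stratification), matching
  published usage; multi-way stratification would need a different
  segment bookkeeping.
* Posterior-probability-weighted overlap (weighting proxies by fine-mapping
  probabilities) is out of scope.
* The conservative tie-handling of the plug-in p-value is noticeable for
  sets of a few hundred loci (see type-I error above); `add_one = TRUE`
  gives the strictly positive variant but does not change discreteness.
* The matching baseline requires every test SNP's pool to be satisfiable;
  small panels with many active axes will error rather than silently relax
  a non-LD axis.
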