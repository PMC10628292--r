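---
title: "Quantifying mosaic 11p15.5 alterations across data modalities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mosaic 11p15.5 alterations across data modalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaic11p)
```

## The problem

The imprinted 11p15.5 locus carries *IGF2*, *H19* and *CDKN1C* under the
control of two imprinting centers: IC1, methylated on the paternal allele,
and IC2, methylated on the maternal allele. Early post-zygotic alterations of
this locus — paternal copy-neutral loss of heterozygosity (cn-LOH), paternal
duplication, or isolated IC1/IC2 epimutations — create mosaic tissues in
which only a fraction $\rho$ of cells carries the defect. `mosaic11p`
detects such mosaicism and estimates $\rho$ from four independent
measurements: bulk SNP allele depths in matched non-tumor/tumor pairs,
MS-MLPA probe and RRBS CpG methylation, per-nucleus allele counts at phased
SNPs, and annotated areas of stained sections. A synthetic-data generator
reproduces the statistical structure each stage assumes, so the whole
pipeline is testable without controlled-access sequencing data.

## The allelic-dosage mixture model

Consider a germline-heterozygous SNP inside the altered interval. Fully
altered cells carry $N_{maj}$ copies of the gained (paternal) allele and
$N_{min}$ of the other; unaltered cells carry one of each. In a tissue with
altered-cell fraction $\rho$ the expected frequency of the gained allele is

$$\mathrm{GAF} = \frac{1 + \rho\,(N_{maj}-1)}{2 + \rho\,(N_{maj}+N_{min}-2)},$$

which inverts to

$$\rho = \frac{2\,\mathrm{GAF} - 1}
            {\mathrm{GAF}\,(2 - N_{maj} - N_{min}) + N_{maj} - 1}.$$

For cn-LOH $(N_{maj}, N_{min}) = (2, 0)$ and the inversion collapses to
$\rho = 2\,\mathrm{GAF} - 1$; for a paternal duplication
$(N_{maj}, N_{min}) = (2, 1)$, where the denominator $1-\mathrm{GAF}$
degenerates as $\mathrm{GAF} \to 1$ (an error, not a clamp). Both forms are
implemented in `mosaicFraction()` / `mosaicFractionCnLoh()` and the package
tests verify the closed-form inversion identities to $10^{-9}$ on a dense
$\rho$ grid.

The observable is the B-allele frequency (BAF): alternate reads over total
reads at a SNP. `orientGainedAlleles()` keeps SNPs that look heterozygous in
a germline reference and uses the tumor — where the same alteration is
clonal and the disequilibrium strong — to decide which allele is gained
(tumor BAF strictly above or below 0.5; exact ties are uninformative and
dropped). The GAF estimate is the *median* non-tumor BAF of the gained
alleles, the even-count median being the midpoint of the middle pair;
the median's robustness to outlying SNPs (mis-genotyped or
poorly covered sites) is why it is preferred over the mean.

Detection uses a single aggregated one-sided exact binomial test: gained
reads versus total reads over all oriented SNPs against $p = 0.5$. A single
aggregated test, rather than per-SNP tests combined, mirrors the summing
logic of the single-nucleus caller and maximizes power at low $\rho$, where
each SNP individually is far from significance. Per-SNP tail p-values are
retained in the `MosaicEstimate` for inspection.

```{r bulk-example}
sim <- simulateBulkSnps(rho = 0.30, "cn_LOH", nSnps = 2000, depthNt = 30,
                        seed = 1)
oriented <- orientGainedAlleles(sim$sites, sim$locus,
                                germlineBaf = sim$germline$baf,
                                germlineDepth = sim$germline$depth)
detectMosaicism(oriented, sim$locus)
```

### Tunable parameters

* `hetLow`/`hetHigh` (default 0.2/0.8) — germline BAF window accepted as
  heterozygous; a standard window wide enough to keep true heterozygotes at
  30x coverage while rejecting homozygous sites.
* `minDepth` (default 8 reads) — below this the heterozygosity call is too
  noisy to trust.
* `alpha` (default 0.05) — level of the aggregated binomial detection test.

The heterozygosity reference should be a sample without the alteration
(blood, when available). When the non-tumor sample itself is used, a high
mosaic fraction shifts its BAF towards the window edge and the filter starts
truncating informative SNPs, biasing the estimate downward; the package
warns whenever the estimated fraction exceeds 40% under a non-tumor-derived
filter. Estimates are clamped to $[0, 100]$% because sampling noise near
$\rho = 0$ legitimately produces small negatives; the raw value is kept in
an attribute and in the `MosaicEstimate`.

## Methylation: IC1/IC2 ratio, mosaic fraction, epimutation calls

In balanced tissue both imprinting centers are methylated on exactly one
parental allele, so their mean methylation is equal and the IC1/IC2 ratio is
1. A paternal gain (cn-LOH, duplication, or paired epimutation) raises IC1
and lowers IC2 symmetrically; with baseline methylation $b$ the mixture gives
$IC1 = b(1-\rho) + \rho$ and $IC2 = b(1-\rho)$, and the normalized
difference

$$\%\,\text{altered} = 100 \times \frac{IC1 - IC2}{IC1 + IC2}$$

recovers $100\rho$ exactly when $b = 0.5$. With the $b \approx 0.6$
baseline observed in fetal liver the estimator reads
$\rho / (1.2 - 0.2\rho)$ under cn-LOH — a modest downward-compressed bias
documented here rather than corrected, since $b$ is not identifiable from a
single sample; the synthetic generator can produce both baselines.

MS-MLPA probe summaries (`icMeans()`) average non-excluded probes per
center; one IC1 probe (`H19.11.001.976583`) is excluded by default because
its distribution does not separate gain-of-methylation samples. RRBS region
summaries (`rrbsRegionMethylation()`) pool methylated over total cytosine
counts across in-region CpGs — a coverage-weighted ratio, invariant to CpG
ordering and to splitting a CpG's counts across records, rather than an
unweighted mean of per-CpG ratios. Default IC1/IC2 intervals (hg38) ship
with the package and as an editable TSV under `inst/extdata/`; an optional
exclusion list handles protocol-biased CpGs.

Epimutation classification (`classifyEpimutation()`) thresholds each probe
by a two-group k-means across the cohort and calls gain-of-methylation IC1
when at least 2 of 3 usable IC1 probes lie above their thresholds, and
loss-of-methylation IC2 when at least 2 of 4 IC2 probes lie *below* theirs
— "beyond the threshold" is read in the direction of the epimutation, since
a literal "above" for a methylation loss would be self-contradictory. Two
numerical choices matter:

* the 1-D 2-means problem is solved *exactly* (every split of the sorted
  values scored by within-cluster sum of squares; threshold at the midpoint
  of the two cluster means). Iteratively seeded k-means can stall in a
  local optimum on probes with no real cluster structure and split the
  normal samples in half, which destroys the false-positive behavior of
  the 2-of-3 rule. The exact solution is deterministic and needs no
  initialization or iteration cap.
* probes whose values are all identical carry no threshold and contribute
  no calls; a cohort in which every probe is degenerate yields all-negative
  calls with a warning.

The cohort-level outlier flag (`classifyMosaicByRatio()`) compares a
sample's IC1/IC2 ratio against presumed-normal samples and flags strict
exceedance of mean $\pm\,k$ SD (default $k = 3$); both tails are screened
so that IC2-loss-driven elevation and symmetric anomalies are caught.

## Single-nucleus cn-LOH genotyping

`assignParentalAlleles()` phases heterozygous SNPs with the tumor
disequilibrium (majority tumor allele = paternal, duplicated);
`aggregateCellCounts()` sums paternal and maternal reads per cell over the
phased SNPs and `callCell()` applies the three-way rule: cells with fewer
than 8 informative reads are `unknown`; otherwise BAF $\geq 0.85$ calls
`cn_LOH`, BAF $\leq 0.60$ calls `no_cnLOH`, and the interval between is
`unknown`. Both boundaries are inclusive. Cells from a sample whose tumor
carries no alteration are all forced to `no_cnLOH`
(`annotateReferenceSample()`), and per-cell-type summaries report the
cn-LOH fraction over determinate calls with unknown counts always shown
(an all-unknown type reports fraction 0 alongside its `n_unknown`).
Counts are consumed from a generic (cell, SNP, allele, count) table so any
upstream single-cell allele counter can feed the caller; counts are treated
as deduplicated units and no internal UMI collapsing is attempted.

## IGF2 promoter usage

Junction depths are summarised per category (`P0-P1` adult; `P2`, `P3`,
`P4` fetal) as the maximum junction depth in the category, normalized by
the depth of "universal" junctions shared by all transcripts, and rescaled
to proportions summing to 1; the fetal fraction is the P2+P3+P4 share.
Within one sample the universal normalization cancels in the proportions —
they are computed from the normalized maxima, which is identical to using
raw maxima — but the normalized values are retained because they support
cross-sample comparison of absolute promoter activity. Junction-to-category
assignment comes from a user-supplied map, because categories are defined
by transcript structure, not fixed coordinates.

## What the synthetic generators emulate

* `simulateBulkSnps()` — heterozygous SNPs with per-SNP depth drawn Poisson
  around the target mean (the realistic model of shotgun coverage; it also
  gives the BAF a dense support so the median is well behaved) and
  gained-allele reads Binomial at the mixture dosage; the gained allele is
  randomly the reference or alternate base per SNP; a balanced germline
  (blood-like) sample is emitted alongside for heterozygosity filtering.
  An optional beta-binomial overdispersion parameter is provided because
  real capture data are overdispersed; the default is pure binomial.
* `simulateMethylationCohort()` — probe values are mixture means plus
  truncated Gaussian noise; cn-LOH/paternal-UPD moves both centers,
  `epi_IC1`/`epi_IC2` move one.
* `simulateCells()` — each cell is LOH with probability $\rho$, its read
  count Poisson, reads spread uniformly over a phased SNP panel, and each
  read reports the paternal allele with probability $1-\varepsilon$ (LOH)
  or $0.5$ (balanced).
* `simulateJunctions()` — multinomial category reads at a fixed usage
  vector.

What they do **not** emulate: mapping and genotyping artifacts, allelic
mapping bias, copy-number changes outside the locus, spatial correlation of
mosaic clones, batch structure in methylation arrays, and ambient RNA
beyond a flat per-read error rate. Passing recovery tests on these
generators therefore demonstrates correctness of the estimators under their
own model assumptions, not robustness to every artifact of real data.

## Test problem sizes

The recovery suites run 5,000 SNPs at 30x over 20 seeds per mosaic fraction
(3, 6, 30 and 58% — the extremes and spatially profiled fractions of the
motivating cohort) demanding errors under 3 percentage points; null
calibration uses 1,000 cohorts at $\alpha = 0.05$; the per-cell caller is
checked exhaustively to 20 reads and on 2,000 LOH / 4,000 balanced
simulated nuclei against exact binomial tails; epimutation classification
runs 20 cohorts of 30 samples at effect size 0.25 and probe noise SD 0.05;
promoter usage uses multinomial depth 2,000 over 20 seeds with a 0.03
tolerance. These sizes make the statistical bounds sharp while keeping the
default test run fast.

## Known limitations

* The methylation fraction assumes the symmetric baseline; fetal-liver-like
  baselines bias it downward (documented above).
* The bulk estimator needs a germline heterozygosity reference to stay
  unbiased above roughly 40% mosaicism.
* The aggregated binomial test treats reads as independent; regional
  overdispersion would make the p-value anti-conservative, which is why the
  generator offers a beta-binomial mode for sensitivity analysis.
* Tumor-guided phasing requires the tumor to carry the same alteration
  clonally; a tumor without the alteration cannot orient the SNPs.
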