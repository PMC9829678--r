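---
title: "In silico introgression mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico introgression mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introtrace)
```

## The problem

Modern bread wheat carries little variation in its D subgenome, and
pre-breeding programmes widen it by crossing in wild relatives —
*Aegilops tauschii* (via synthetic hexaploids), *Thinopyrum ponticum*,
*Secale cereale*. When an alien chromosome segment carries a useful allele
(here: heat tolerance detected as a marker–trait association), two
questions follow: *which lines carry the introgression, and exactly where
is it?* Sequencing coverage answers both without assembling anything:
reads from an alien segment map poorly against the wheat reference, so a
carrier line shows depressed mapping coverage over the segment, and the
SNPs it does produce there match alleles private to the donor species.
`introtrace` implements this in-silico mapping, the phenotype analytics
that motivate it, and the synteny lift of the mapped interval onto the
donor's own assembly.

## Coverage deviation

Each chromosome is tiled into windows (1 Mbp by default, 0-based
half-open internally; reports print Mbp). For line $l$, raw window read
counts are divided by the line's filtered mapped-read total, giving
normalised counts $c_i$. Windows differ enormously in intrinsic
mappability, so each window is compared only with *itself* across the
panel: $m_i$ is the across-line median of $c_i$. The deviation is

$$d_i = \frac{c_i}{m_i \cdot \varepsilon},$$

where $\varepsilon$ is a per-line scaling factor. We define
$\varepsilon$ as the median of $c_i/m_i$ over non-masked windows, which
makes $\mathrm{median}(d) = 1$ exactly for every line; defining it
self-referentially as "the median of $d$" is circular, and the fixed
point of that iteration is the same value, so the pre-ratio median is
used. Windows with $m_i = 0$ are masked — invisible to $\varepsilon$,
to outlier scoring and to block calling — rather than zero-filled,
because a zero median means the window carries no usable signal for
anyone.

Outliers are scored per line, genome-wide, with a robust z-score
$z_i = (d_i - \mathrm{median}(d)) / (1.4826\,\mathrm{MAD}(d))$ and
flagged beyond $\Phi^{-1}(p)$ with $p = 0.99$ by default. Only *low*
flags are introgression evidence — coverage significantly below 1 marks a
break in synteny — while high flags are kept for QC (duplications,
reference collapse). Scoring per line rather than per chromosome keeps
the MAD stable when a whole chromosome arm is introgressed.

## Donor-specific SNPs

SNP sets for donor accessions are filtered on read support (homozygous:
10–60 alternative reads, allele frequency ≥ 0.8; heterozygous: 10–60
total reads, biallelic, ≥ 5 reads per allele, frequency ≥ 0.3; we take
the site-level alternative-read fraction as the frequency, since the
convention is not fixed elsewhere). An allele is *species-specific* when
at least one accession of exactly one donor carries it and no other
donor or wheat cultivar does. Panel SNPs match on identical
`(chrom, pos, alt)` after decomposing multi-allelic records.

Per window and line, the matched count is divided by the *panel mean*
matched count for that window — all lines included, carriers too, which
deflates ratios in windows where many lines share a segment but keeps
the statistic simple and monotone. Ratios at or above 1.45 are retained
as enrichment evidence; the threshold is inclusive ("below 1.45" is
removed). The panel genotype track for association work uses its own
filters: heterozygous calls, quality < 30 or depth < 5 dropped,
homozygous-reference asserted at ≥ 5 reads with no alternative, then
loci with > 10% missing data or minor allele frequency < 5% removed.

## Segment calling, zygosity, core region

Donor sequence from the primary genepool is close enough to wheat that
some windows inside a true segment map normally; they still carry donor
SNPs. A window is *evidence* if low-flagged or SNP-retained; runs of
evidence windows are merged, bridging interior gaps of up to 2 windows
when every bridged window has at least one matched donor SNP. Blocks
need ≥ 3 evidence windows, and more than half of a block's windows must
be low-flagged ("most of the block shows significant coverage
deviation"). The gap and minimum-block values are design choices of this
package, exposed in `segment_params()`, not published constants.

Zygosity: a heterozygous segment retains one intact host homologue, so
its coverage deviation is intermediate and its matched donor SNPs are
heterozygous. A block is called `het` iff mean $d \ge 0.65$ *and* the
heterozygous fraction of matched donor SNPs is ≥ 0.5 — both thresholds
sit midway between the homozygous expectation (~0.5 deviation, ~0 het
fraction) and the heterozygous one (~0.75, ~1), and are configurable.
With no matched SNPs the coverage criterion decides alone, with a
warning.

The *core introgressed region* for a focal marker intersects, over all
carrier lines, the union of each carrier's segments, then subtracts
anything overlapping a non-carrier's segment; when the result is
disconnected the largest interval is reported, and every non-carrier
line with any segment on the chromosome is used for exclusion. An empty
core is a valid outcome.

## Stress phenotypics

Derived traits: grain number GM2 = (YLD/TGW)×1000; biomass at maturity
BM_PM = YLD/HI; spikes SM2 = BM_PM/(shoot dry weight per shoot);
grain-filling fraction PGF = (DTM − DTA)/DTM. The stress susceptibility
index for a trait is

$$\mathrm{SSI} = \frac{1 - Y_{ht}/Y_{yp}}{1 - \bar{Y}_{ht}/\bar{Y}_{yp}},$$

computed from across-year adjusted means (one value per line and
environment; mixed-model BLUE estimation happens upstream and is out of
scope). SSI < 1 means above-average tolerance; the $Y_{yp}$-weighted
panel mean of SSI is exactly 1, a useful algebraic check. Broad-sense
heritability is
$H^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_{ge}^2/e + \sigma^2/(re))$
with $e$ environments and $r$ replicates.

Group contrasts use Welch's two-tailed t test (no equal-variance
assumption) with significance tiers \*, \*\*, \*\*\* at p < 0.01, 0.001,
0.0001; correlations are Pearson with pairwise deletion, displayed as
significant at p ≤ 0.01. Allele-stacking effects group lines by their
combination at the focal markers, report percent change against the
all-unfavourable reference class (°C difference for canopy temperature),
and test the class effect with one-way ANOVA plus Tukey HSD at the
conventional 0.05 family level (no level is prescribed elsewhere). The
single-allele helper reports both the multiplicative and the subtractive
decomposition of a stacked effect, because the two disagree on percent
scales and the right one depends on the assumed gene action.

## Synteny anchoring

Whole-genome alignment blocks (PAF) are filtered at ≥ 2.5 kb and mapping
quality ≥ 40 for host-to-donor alignments (≥ 5 kb for donor-to-donor).
Interval boundaries are projected linearly within the covering block —
base-level CIGAR mapping adds nothing at window resolution — strand
aware, onto the majority target chromosome by overlap length. A boundary
falling in an alignment gap snaps to the nearest edge of a block that
overlaps the interval (inward, onto covered sequence), with a warning;
an interval with no overlapping blocks is unanchorable. Genes are
extracted from the donor GFF3 by any overlap with the anchored interval,
a deliberately conservative candidate-capture rule.

## The synthetic panel generator

The generator exists so that every stage above is testable end-to-end at
the study's scale without sequencing data. What it emulates, and its
defaults:

* **Geometry** — 149 lines, seven chromosomes of 60 Mbp at 1 Mbp windows
  (a scaled-down genome keeping per-chromosome window counts realistic
  for the short arms where the focal segment sits).
* **Coverage** — negative-binomial counts, mean = line depth ×
  window mappability × segment factor. Line depth ~ U(800, 1200)
  reads/window; per-window mappability drawn once log-normally
  (sdlog 0.25) and *shared across lines*, so the panel median is the
  correct normaliser by construction; dispersion size 300 (≈ 6–7%
  extra-Poisson noise at depth 1000, modest overdispersion as seen in
  deduplicated capture data); `Inf` gives the Poisson limit. Homozygous
  segments scale the mean by 0.5, heterozygous by 0.75 — one factor, not
  a mixture, matching the intermediate deviation that identifies
  heterozygous carriers.
* **Donor SNPs** — Poisson, 5 matched SNPs per window inside segments
  and 0.2 spurious matches per window elsewhere; heterozygous genotypes
  inside heterozygous segments.
* **Allele classes** — 87:14:31:17 out of 149 lines for A+A+G, A+C+C,
  T+C+C and A/T het-6D classes, the field panel's proportions. Every 6D
  favourable carrier gets a chr6D segment containing the 5–7 Mbp core
  (one unbroken 32 Mbp segment; the rest recombined at random extents);
  no A/A line carries chr6D donor material; a few elite lines carry
  *Th. ponticum* (7D) and *S. cereale* (1B) segments.
* **Phenotypes** — genetic yield ~ N(600, 45) g·m⁻²; heat multiplies
  expectation by 1 − 0.481; favourable alleles multiply heat yield by
  √1.243, √1.243 and 1.565/1.243 (so the full stack is +56.5% and the
  1B+2B pair +24.3%) and shift heat canopy temperature by −0.5, −0.5,
  −1.0 °C; effects are expressed only under heat and are dominant
  (heterozygous carriers show the full effect, as the field data
  suggest). Residual sds default to 25/20 g·m⁻² (YP/heat) and 0.5 °C —
  adjusted-mean-level noise, not plot-level.

All randomness flows from one integer seed through fixed per-component
offsets, so a configuration is bit-reproducible and the coverage draw
does not perturb the SNP draw.

What the generator does **not** emulate: read-level artefacts (GC,
mapping bias beyond a static window factor), linkage disequilibrium and
pedigree structure, segregating heterogeneity within a line, genotype ×
year variance structure, or trait correlations beyond those induced by
the planted alleles. Passing tests therefore demonstrate that the
statistics and the calling logic are implemented correctly and recover
planted signal under realistic noise — not that the thresholds are
optimal for any particular real capture dataset.

## Numerical notes and problem sizes

Equivalence of the deviation statistic with a straight-line
re-implementation is asserted to 10⁻¹² on 10 × 50 matrices. End-to-end
recovery runs on the full 149-line, 7 × 60-window panel: ≥ 95% of
planted segments of ≥ 5 windows must be recovered with ≤ 1 window
boundary error, with ≤ 1 false segment per 100 line-chromosomes and
≥ 95% zygosity accuracy. Core-region interval algebra is checked against
brute-force set intersection on 200 random configurations, and
allele-stack recovery on a 400-line panel (±3 percentage points on
yield, ±0.2 °C on canopy temperature). These sizes keep the whole suite
under a minute on one CPU while leaving the statistical checks
well-powered.

Degenerate inputs error early and loudly: zero mapped-read totals name
the offending line, an all-masked grid or a zero MAD stops outlier
scoring with advice, equal panel means make SSI undefined, a "carrier"
with no segment contradicts its own definition. Ties: the retention
boundary at ratio 1.45 is inclusive; block majority is strict;
disconnected cores return the widest piece.

## A worked example

```{r example, eval = FALSE}
library(introtrace)

cfg   <- default_panel_config(n_lines = 149, seed = 1)
panel <- simulate_panel(cfg)

dev   <- flag_outliers(panel_deviation(normalize_counts(panel$counts),
                                       panel$grid))
ratio <- snp_ratio_profile(panel$snps, panel$grid, cfg$lines)
calls <- call_introgressions(dev, ratio, panel$snps)

mg       <- cfg$marker_genotypes
g6       <- mg[mg$marker == "chr6D-6276646", ]
carriers <- g6$line[g6$genotype %in% c("T/T", "A/T")]
core_region(calls, carriers,
            excluded = intersect(g6$line[g6$genotype == "A/A"],
                                 calls$line[calls$chrom == "chr6D"]),
            chrom = "chr6D")
```

## Known limitations

* Window-resolution breakpoints only; no sub-window refinement.
* The panel-mean denominator of the SNP ratio deflates enrichment when
  most lines carry the same segment; with > 50% carriers the panel
  median also stops being a clean null for coverage. Both statistics
  assume introgressions are minority features per window.
* Donor assignment of a block follows the majority of matched SNPs; it
  does not identify the donor *accession*.
* Protein-anchor reconciliation for synteny lifting accepts a
  pre-tabulated anchor set; alignment anchors take precedence.
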