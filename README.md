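# introtrace

In silico introgression mapping and stress phenotypics for wheat panels.

Wheat pre-breeding programmes introduce chromosome segments from wild
relatives (*Aegilops tauschii*, *Thinopyrum ponticum*, *Secale cereale*)
to widen the crop's narrow genetic base. When a GWAS flags a marker–trait
association inside exotic-derived material, the segment behind it can be
mapped without any assembly, directly from short reads aligned to the
wheat reference: introgressed sequence maps poorly, so carriers show
depressed windowed coverage there, and the SNPs they do produce match
alleles private to the donor species. `introtrace` implements this
pipeline and the phenotype analytics around it, for breeders and
genebank/pre-breeding researchers working with resequenced panels.

## The statistics at the core

Per 1 Mbp window *i*, a line's depth-normalised read count *cᵢ* is
compared with the panel median *mᵢ* for that window:

    dᵢ = cᵢ / (mᵢ · ε)

with ε the line's median *c/m*, so median(*d*) = 1. Windows with *d*
significantly below 1 (MAD z-score beyond Φ⁻¹(0.99)) mark breaks in
synteny. Independently, donor-specific SNP enrichment per window —
matched count over the panel-mean matched count, retained at ≥ 1.45 —
marks donor ancestry. Runs of either kind of evidence are merged into
segments (gaps of ≤ 2 windows bridged when donor SNPs are present),
zygosity is called from intermediate coverage plus heterozygous donor
SNPs, and intersecting all carriers' segments minus non-carriers yields
the **core introgressed region** that delimits the causal interval. The
phenotype layer provides the stress susceptibility index
SSI = (1 − Yht/Yyp)/(1 − Ȳht/Ȳyp), broad-sense heritability
H² = σ²g/(σ²g + σ²ge/e + σ²/(re)), derived agronomic traits, Welch group
contrasts, Pearson correlations and allele-stacking ANOVA/Tukey effects.
A synteny module lifts the core interval onto the donor assembly through
filtered whole-genome alignments and extracts candidate genes from its
GFF3.

A fully specified synthetic panel generator (negative-binomial coverage,
Poisson donor SNPs, two-environment phenotypes with planted allele
effects) reproduces the statistical structure the analysis assumes, so
the entire pipeline is testable end-to-end without sequencing data.

## Worked example

```r
library(introtrace)

cfg   <- default_panel_config(n_lines = 149, seed = 1)  # 57 planted segments
panel <- simulate_panel(cfg)

dev   <- flag_outliers(panel_deviation(normalize_counts(panel$counts),
                                       panel$grid))
ratio <- snp_ratio_profile(panel$snps, panel$grid, cfg$lines)
calls <- call_introgressions(dev, ratio, panel$snps)
nrow(calls)
#> [1] 57

rep_ <- segment_report(calls, panel$truth$segments,
                       n_line_chroms = 149 * 7)
rep_[c("recall", "false_per_100_line_chroms", "zygosity_accuracy")]
#> $recall
#> [1] 1
#> $false_per_100_line_chroms
#> [1] 0
#> $zygosity_accuracy
#> [1] 1

g6       <- subset(cfg$marker_genotypes, marker == "chr6D-6276646")
carriers <- g6$line[g6$genotype %in% c("T/T", "A/T")]
core_region(calls, carriers,
            excluded = intersect(g6$line[g6$genotype == "A/A"],
                                 calls$line[calls$chrom == "chr6D"]),
            chrom = "chr6D")
#>   chrom start     end n_carriers n_excluded
#> 1 chr6D 5e+06 7000000         48          0
```

Every planted segment is recovered with no false calls and correct
zygosity, and the core region is exactly the planted 5–7 Mbp interval
shared by all 48 carriers of the favourable 6D allele. See
`vignettes/introgression-mapping.Rmd` for the models, parameter
rationale and limitations.

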