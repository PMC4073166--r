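# ipsomatic

Somatic SNV selection and Q-FISH telomere quantification for iPS cell lines.

When induced pluripotent stem (iPS) cells are derived from a patient
fibroblast line and expanded in culture, they acquire somatic single
nucleotide variants (SNVs). Counting those variants honestly from
multi-sample exome calls requires more than a variant caller: stringent
post-calling hard filters, allelic-depth rules that depend on the genotype
class, removal of calls that sit inside large structural alterations
(copy-neutral LOH, deletions) where an apparent SNV is really the shadow of
a segmental event, and an auditable manual-exclusion step. `ipsomatic`
implements that selection pipeline, the downstream mutation accounting
(annotation-category tallies, base-change spectra, per-population-doubling
mutation rate), quantitative FISH (Q-FISH) telomere-length estimation from
per-telomere fluorescence intensity tables, and small culture metrics
(reprogramming efficiency, post-irradiation survival). A seeded
synthetic-data generator emulates a parental line plus four derived iPS
clones so every stage is testable without sequencing data.

It is written tidyverse-style: every user-facing function takes a data
frame first and returns a tibble, so stages chain with the pipe.

## The selection rules

A call for the focal sample is eliminated when any site clause holds

```
QUAL < 400 | QD < 2.0 | MQ < 40.0 | FS > 60.0 | HaplotypeScore > 13.0 | GQ <= 60
```

and must additionally pass the genotype-class allelic-depth (AD) rule:

* **heterozygous** (0/1, 0/2, 1/2): both genotype-allele depths >= 8 and
  within twofold of each other (ratio <= 2, inclusive);
* **homozygous** (0/0, 1/1, 2/2): with `a >= b` the ordered pair of the
  genotype allele's depth and the largest other-allele depth, pass iff
  `a/b >= 32` (b > 0), or `b == 1 & a >= 16`, or `b == 0 & a >= 8`.

A site is **somatic** for a derived line when both the parental and derived
calls pass, the parental genotype is homozygous reference, and the derived
genotype carries a de novo allele. Calls inside structural-alteration
intervals and calls on the manual exclusion list are then removed, with a
conservation-checked accounting at every stage.

Telomere length is estimated from Q-FISH as
`length = (sample TFI / control TFI) * control length`, where each TFI is
the mean over metaphase spreads of the per-spread **median** telomere
fluorescence intensity, and the control is a fibroblast standard of known
length (6.91 kbp).

## Worked example

```r
library(ipsomatic)

# a seeded bundle shaped like a published iPS-cell exome study:
# 212 candidate somatic SNVs across 4 derived lines, three structural
# regions containing 2/37/1 of them, and 5 ambiguous calls
b <- scenario_paper(seed = 1)
res <- somatic_pipeline(b$variants, b$parental, b$lines,
                        b$regions, b$ambiguous)
res$accounting
#> Somatic SNV accounting
#>   candidate calls:      212
#>   removed in region region1: 2
#>   removed in region region2: 37
#>   removed in region region3: 1
#>   removed manually:     5
#>   final somatic SNVs:   167
res$per_line
#> # A tibble: 4 x 2
#>   sample    n_snvs
#>   <chr>      <int>
#> 1 ATiPS-262     43
#> 2 ATiPS-263     48
#> 3 ATiPS-264     35
#> 4 ATiPS-024     41

# telomere length from a printed TFI pair (parental line vs its control)
telomere_length(5187, 8671, control_length_kbp = 6.91)[, c("ratio_display", "length_display")]
#> # A tibble: 1 x 2
#>   ratio_display length_display
#>           <dbl>          <dbl>
#> 1         0.598           4.13

# mutation rate per population doubling, pooling lines
mutation_rate_per_pd(
  tibble::tibble(line = c("262", "263", "264", "024"),
                 snvs = c(43, 48, 35, 41),
                 passages = c(17, 27, 25, 25)),
  pd_per_passage = 3.7
)$rate
#> [1] 0.480161
```

The accounting says: of 212 candidate de novo SNVs, 2 + 37 + 1 lie inside
the three structural regions (so they are structural shadows, not point
mutations), 5 more are manually excluded as ambiguous, leaving 167 somatic
SNVs; divided by the pooled population doublings this is ~0.48 SNVs per
doubling.

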