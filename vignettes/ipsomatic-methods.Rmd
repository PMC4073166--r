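---
title: "Somatic SNV selection and Q-FISH telomere quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic SNV selection and Q-FISH telomere quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipsomatic)
library(dplyr)
```

## The problem

An iPS clone derived from a patient fibroblast line accumulates somatic
single-nucleotide variants during reprogramming and expansion. Estimating
how many, and of what kind, from multi-sample exome calls is dominated not
by the caller but by the post-calling selection: exome calls at moderate
depth contain systematic artifacts (strand bias, mapping ambiguity,
allelic-depth imbalance) and genuine genotype changes that are *not* point
mutations (the footprint of a deletion or a copy-neutral LOH segment looks
like a burst of clustered "SNVs"). `ipsomatic` implements that selection as
a chain of small, conservation-checked table transformations.

## Data model and coordinates

All stages operate on a long call table: one row per site per sample, with
site annotations (QUAL, QD, MQ, FS, HaplotypeScore) repeated across the
sample rows, the genotype as a string (`"0/1"`), and allelic depths as a
list column with one count per allele, reference first. `read_vcf()` /
`write_vcf()` bridge to VCF 4.2. A missing annotation is `NA`, never a
default value: the filter must decide on missingness explicitly.

Two coordinate conventions coexist deliberately: VCF positions are
1-based, interval tables are 0-based half-open (the BED dialect). The
single bridge is `overlaps()`: position `pos` is inside `[start, end)` iff
`start < pos <= end`. Keeping both conventions native and fixing one
conversion rule avoids the classic off-by-one at both boundaries, and the
test suite checks both edges explicitly against a brute-force evaluator.

## The stringent filter

Site clauses are applied with the operators exactly as written —
`QUAL < 400`, `QD < 2.0`, `MQ < 40.0`, `FS > 60.0`,
`HaplotypeScore > 13.0`, `GQ <= 60` — so boundary values of the strict
clauses pass while a GQ of exactly 60 is eliminated. GQ is evaluated on
the focal sample's call; the other clauses are site-level. Every failed
clause is recorded, so the verdict table doubles as a filter audit.

The allelic-depth rules are interpreted as **fold-ratio** conditions, not
arithmetic differences. The homozygous rule's two carve-outs — "depth 1
against at least 16" and "depth 0 against at least 8" — only make sense as
exceptions to a ratio rule whose denominator degenerates, which settles
the reading:

* het (two distinct genotype alleles): both addressed depths `>= 8` and
  `max/min <= 2` (inclusive). Depths of alleles outside the genotype are
  ignored, so a 1/2 call with AD (50, 12, 12) passes on (12, 12).
* hom: the genotype allele's depth against the **largest** other-allele
  depth — the most conservative choice of contaminant; `hom_pair =
  "sum_other"` is available for the pooled alternative. With the pair
  ordered `a >= b`: pass iff `a/b >= 32` (inclusive), or `(b, a)` is
  `(1, >= 16)` or `(0, >= 8)`.

Missing required fields eliminate the record under the default strict
policy (`MISSING_FIELD`), with a documented permissive switch. The whole
filter is idempotent and is tested for exact agreement with an
independently written transcription of the printed boolean on more than a
thousand randomized boundary-heavy records.

## Somatic definition and the exclusion channels

A site is somatic for a derived line iff both the parental and derived
calls pass the filter, the parent is homozygous reference, and the derived
genotype carries an allele the parent lacks. Requiring the parent to pass
is a choice (the alternative — only the derived call audited — is exposed
via `require_parental_pass = FALSE`): a parent failing its own AD rule at
a site usually means the "de novo" allele was present sub-clonally all
along. Genotype changes *without* a new allele are LOH, and are left to
the structural channel.

Exclusion then proceeds in two audited steps: interval exclusion
(`exclude_structural()`, removals grouped per region) and an explicit
exclusion-list table (`apply_exclusion_list()`), which turns a manual
curation step into a reproducible input artifact. Each step returns both
partitions, and `somatic_accounting()` enforces
`final = called - regions - manual`, erroring rather than silently
reporting an inconsistent ledger. All outputs are sorted in karyotype
order for determinism.

## Mutation profile

Each SNV receives exactly one annotation category, resolved from its
(possibly multiple) effect labels by a fixed precedence: coding (stop
gained/lost, start lost, non-synonymous, synonymous) over splice over UTR
over intron over up/downstream over non-coding exon over intergenic. This
is a reporting precedence printed in the docs (`SNV_CATEGORIES`), not a
re-implementation of any annotator's internal ranking.

Spectra are reported both as the 12 ordered ref>alt classes and as the 6
pyrimidine-collapsed classes (each purine-reference change pooled with its
reverse complement), since published figures use either convention and the
text rarely says which; `counts6` is exactly the complement-collapse of
`counts12` by construction and by test. The Ti/Tv ratio counts A<->G and
C<->T as transitions, reporting `Inf` when no transversion is observed.
Per-line spectra are obtained by splitting the table before calling
`mutation_spectrum()`; the pooled and per-line modes are the same code
path.

The per-population-doubling rate pools lines:
`rate = sum(snvs) / (sum(passages) * pd_per_passage)`. With the cohort's
final counts (43, 48, 35, 41 over 17, 27, 25, 25 passages) the rate is
`167 / (94 p)` for any doublings-per-passage `p`. The default `p = 3.7` is
**back-solved** so that this expression gives 0.48 SNVs/PD — about 3–4
doublings per passage, plausible for routine human iPS passaging, but an
assumption, flagged as such in the documentation; supply a measured value
when one exists.

## Q-FISH telomere length

Each metaphase spread contributes the median of its per-telomere
fluorescence intensities (p- and q-arms of every chromosome; the median is
robust to saturated or near-background signals); a sample is the mean of
its per-spread medians; length is that TFI divided by the paired control's
TFI, scaled by the control's known length (6.91 kbp). Two conventions are
fixed here:

* **Pairing is input, never inferred.** Control batches drift between
  staining sessions (the same control line can legitimately read 8671,
  7751 and 7378 in different batches), so each sample row names its
  control batch explicitly.
* **The ratio is rounded to 3 decimals before scaling.** The two rounding
  orders disagree at the second length decimal for two of the four
  reference TFI pairs, and only the rounded-ratio order reproduces a
  published measurement table's lengths exactly from its own ratios; we
  adopt it as the table-consistent convention and also return the
  unrounded ratio. Intensity units are arbitrary — ratio and length are
  invariant under common rescaling — and no image processing is modelled:
  the intensity table is the input boundary.

## Culture metrics

Reprogramming efficiency is colonies per plated cell in percent; the fold
comparison between two lines assumes equal plating when a denominator is
not recorded (documented in `efficiency_ratio()`). Post-irradiation
survival normalises each dose's replicate counts to the mean of the
matched non-irradiated counts, so 0 Gy is 100% by construction and the
statistic is unit-free; normalisation is per clone before pooling.

## The synthetic cohort generator

`generate_cohort()` emulates the input structure the pipeline assumes: one
parental line plus derived lines (default 4) in a multi-sample call set at
Poisson depth around 90 reads — matching typical exome depths for this
design — with binomial allelic depths (het draws truncated to the
detection rule, since a planted call models a variant that *was*
detected), Hardy–Weinberg parental genotypes
at background sites inherited by all lines, and planted de novo het SNVs
per line on that line's own synthetic chromosome. Quality annotations fail
each filter clause at configurable fractions, drawn from disjoint
pass/fail ranges; "ambiguous" planted calls get depth ratios skewed into
(1.6, 2], inside the passing region, so they escape the automated filter
and exercise the manual exclusion channel — a mechanism chosen because it
is the simplest depth-level account of a call that passes thresholds yet
looks unreliable. Every generator is a pure function of its configuration
including the seed, and emits a truth table sufficient to score each
downstream stage.

What the generator does **not** emulate: linkage between sites, mapping
artifacts correlated along the genome, batch effects between samples, or
realistic joint distributions of QD/MQ/FS/HaplotypeScore (their true joint
distribution in any given study is unknown; parametric stand-ins are
documented in the code). Passing the planted-truth tests therefore shows
the selection logic is correct, not that the thresholds are optimal for
any particular dataset.

`scenario_paper()` is the fixed reference bundle: 212 candidate somatic
SNVs split 84/49/36/43 across four lines, with a 23,314-kb CNLOH region
and a 3,586-kb deletion capturing 2 and 37 of the first line's calls, a
234-kb deletion capturing 1 of the fourth line's, and 5 ambiguous calls
split 2/1/1/1 — so the pipeline ends at 167 somatic SNVs split
43/48/35/41. The per-line candidate and ambiguous splits are the
reconstruction consistent with those stage totals (the totals determine
the splits only jointly); they are fixed here once as part of the
scenario definition. Q-FISH fixtures targeting ratios 0.598, 1.902,
2.263 and 2.393 against their respective control batches complete the
bundle.

## Numerical and scale choices

Positions are drawn on 2×10^8-bp synthetic chromosomes; ties at identical
(chrom, pos) are de-duplicated at planning time. Test problem sizes —
1000–1200 records for oracle equivalence, n = 1000 planted SNVs for
mix-recovery at 3 binomial SDs, 20 seeds for Q-FISH ratio recovery at
3 SE, 200-replicate sampling checks — are chosen so the statistical
assertions have negligible false-failure probability while the whole
suite stays interactive. Degenerate inputs error early and informatively:
empty spread, zero control TFI, negative accounting, inverted intervals,
unknown category labels.

## Known limitations

* The pipeline consumes called VCFs; nothing upstream (alignment,
  duplicate marking, recalibration, calling) is modelled, so caller-level
  biases are invisible to it.
* Effect labels are consumed, not computed; the category precedence is a
  reporting convention.
* The per-PD rate is only as good as `pd_per_passage`; treat the default
  as an assumption.
* Structural intervals are inputs from array analysis; the package does
  not detect LOH or CNVs.
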