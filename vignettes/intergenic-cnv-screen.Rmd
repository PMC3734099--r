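---
title: "Screening for rare recurrent intergenic CNV regions: methods and design notes"
author: "cnvscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for rare recurrent intergenic CNV regions}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvscan)
```

## The problem and the model

Copy-number variants (CNVs) that disrupt genes are an established source
of risk for neurodevelopmental disorders, but most of the genome is not
exonic, and regulatory elements, non-coding RNAs and unannotated
transcript isoforms live in the intervals between genes. `cnvscan`
implements a screen for such intervals: genomic regions hit by **rare**
CNVs in **two or more unrelated cases**, with **no overlapping call of
the same type in any control**, lying **entirely outside every annotated
transcript span**. The screen is a deterministic cascade of set-shrinking
filters rather than a statistical test: its output is a shortlist of
candidate loci with a complete audit trail, not a p-value. (A formal
burden test is a deliberate non-goal; at the carrier counts this design
targets — two or three cases per locus — a per-locus test would be
hopelessly underpowered, and the value of the screen is the shortlist
plus its annotations.)

### Coordinate and size conventions

All intervals are 1-based and fully closed, exactly as printed in the
bundled reference table; overlap arithmetic therefore uses closed
lengths, `end − start + 1`. The *size* of a call is defined as
`end − start`, because that identity holds for every one of the 45 rows
of the reference table (checked on every load). BED input and output are
converted at the boundary (+1 to starts on read, −1 on write).
Chromosome names are normalized by stripping a leading `chr`. Sex
chromosomes are accepted with a warning: carrier-frequency handling does
not model hemizygosity, and sex-chromosome imbalances are outside the
screen's scope.

### Call equivalence and rarity

Two calls are the same CNV when they are on one chromosome, have the
same type (loss/gain), and their reciprocal overlap

$$\mathrm{RO}(a,b) \;=\; \min\!\left(\frac{|a \cap b|}{|a|},
\frac{|a \cap b|}{|b|}\right)$$

is at least `rarity.ro_threshold` (default **0.5**, the field-standard
criterion for CNV equivalence; exposed in configuration). A call's
frequency is the number of distinct samples in the pooled case+control
dataset owning an equivalent call, divided by the number of genotyped
samples. The denominator is the *cohort size*, not the number of samples
with calls — pipelines should pass it explicitly (`dataset_size`),
because samples with no CNV calls still count as genotyped. Rarity is a
strict inequality: a call carried by exactly 1% of samples is removed.
Type matching during frequency counting is on by default and can be
turned off; per-platform stratified counting (`stratify_by_platform`)
is available for cohorts genotyped on heterogeneous arrays, since a
platform with denser probes sees more calls and platform-matched
case/control frequencies are then the fairer comparison.

### Genic masking

"Known gene" means the full transcript span, strand-agnostic, with
any-overlap (1 bp suffices) triggering removal. Span-level masking is
the right reading for an *intergenic* screen whose candidate loci are
allowed to — indeed expected to — overlap mRNA/EST evidence that is not
part of an annotated gene: exon-level masking would leave intronic calls
in the set. Passing exon intervals instead of gene spans switches the
screen to exon-level masking; nothing else changes.

### Clustering and locus merging

Case calls surviving rarity and genic masking are clustered per
chromosome by single-linkage, any-overlap, ignoring type — the reference
data show losses and gains interleaved at one locus, and a locus is
defined by position, not by direction of dosage change. Clusters whose
spans lie within `locus_merge_gap` (default **1 Mb**) of each other are
then merged into loci, keeping the sub-cluster partition.

The 1 Mb default is the value consistent with the bundled reference set:
its sub-cluster gaps within printed loci range up to ~700 kb (2p16.3),
while the two 11p12 entries printed as separate loci are ~1.29 Mb apart.
Any value in (0.70 Mb, 1.29 Mb) reproduces the printed grouping; 1 Mb is
the round number in that window and is a configuration knob, not a
constant.

A locus is reported as harbouring *multiple distinct clusters* when at
least two of its sub-clusters are each supported by two or more distinct
samples (`n_recurrent_clusters >= 2`). A singleton sub-cluster that the
gap rule merged into a locus is evidence about the locus's extent, not
an independent recurrent cluster — on the reference data this definition
yields exactly the three multi-cluster loci (2p16.3 with three recurrent
clusters, 4q13.1 and 6p21.2 with two each), while the raw sub-cluster
count would also flag the second 11p12 locus, whose first sub-cluster is
a single carrier. Both counts (`n_clusters`,
`n_recurrent_clusters`) are reported per locus so the distinction is
visible in output.

### Region-level filters

Filters run on clusters *before* locus merging (so a locus is assembled
only from clusters that individually survive) and only ever remove:

* **recurrence** — at least `min_cases = 2` distinct unrelated carriers;
  unrelatedness is defined by `family_id` where present, falling back to
  sample identity. Carriers are counted once per family and once per
  sample, so two calls from one individual (or two affected siblings)
  support a cluster only once.
* **control absence** — strict by default (`max_control_carriers = 0`):
  one control sample with a same-type call overlapping any member CNV by
  1 bp removes the cluster. This is deliberately conservative
  (any-overlap, not reciprocal overlap): a control carrier of even a
  partial event undermines a rare-disease-variant interpretation.
  Reciprocal-overlap matching is available via `match = "ro"`.
* **common-variant coverage** — clusters whose span is covered at or
  above `dgv_max_overlap = 0.5` by the common-variant track are removed
  as catalogued polymorphism. Coverage is computed on the union of track
  intervals (sweep over reduced intervals, no double counting). The 0.5
  default is a documented package choice; published screens state no
  numeric criterion for this elimination, which is why this threshold is
  excluded from regression comparisons.
* **repeat fraction** — removal strictly above
  `repeat_max_fraction = 0.8`: a region masked exactly 80% is retained,
  matching the usual phrasing ">80% masked were removed". The measured
  fraction is stored in the filter trail.

The two coverage filters are pure region-level predicates, so their
order cannot change the final set; the test suite asserts this
commutation rather than assuming it.

### Annotation

The nearest gene minimizes the closed-interval gap to the locus span
(0 if abutting), ties broken toward the smaller gene start for
determinism. Two distances are reported: the span gap, and the largest
gap from any individual member CNV to that gene ("furthest distance").
The furthest-distance column of the reference table is never used as a
regression target — its original measurement endpoints (gene span vs
transcription start; which member CNV) are not recoverable from the
publication, and reproducing it would require the original annotation
freeze — but the definition here (max over member CNVs of the gap to the
named gene; nearest = furthest for single-member loci) reproduces its
structure and is stated in the output schema.

Mechanism bins are a transparent rule set over evidence geometry, not a
reproduction of any manual curation. For an intergenic CNV near a gene,
a regulatory interpretation (bin *i*) can never be excluded, so *i* is
assigned whenever a nearest gene exists. Overlapping expressed-sequence
evidence adds *iii* when the evidence reaches to within
`gene_link_gap` (default 1 Mb, shared with the candidate-gene window) of
the nearest gene's span — the signature of an uncharacterized extended
isoform — and *ii* when it does not (a possible novel transcript inside
the region); conserved-element evidence contributes *ii* only. Ambiguity
is encoded as compound bins (`"i or ii"`), mirroring how such tables are
published, rather than forcing a choice.

Inheritance is called per proband CNV by reciprocal-overlap matching
(same threshold as rarity, default 0.5) against each parent's call set:
mother first, then father; both-parent matches are reported as maternal
with a `both_parents` flag; `de_novo` requires both parents present and
neither matching; any missing parent yields `unknown` rather than an
unsupported de novo call.

## The synthetic cohort generator

`simulate_cohort()` produces the full input set of the screen with exact
ground truth, so every downstream stage is testable without any external
data. What it emulates, and the defaults:

| parameter | default | role |
|---|---|---|
| `n_cases`, `n_controls` | 150 / 150 | cohort sizes (desk scale) |
| `genome` | 2 × 50 Mb | chromosome lengths |
| `n_genes` | 40 | non-overlapping transcript spans |
| `n_planted_regions` | 5 | true rare intergenic recurrent regions |
| `planted_cases_per_region` | 2 | carriers per planted region |
| `n_common_cnp`, `common_cnp_freq` | 5, 0.05 | common polymorphism loci and carrier frequency |
| `background_rate` | 1 | Poisson singleton calls per sample |
| `repeat_fraction_target` | 0.1 | random repeat-mask coverage |
| `trio_fraction`, `inherited_fraction` | 0.5, 0.9 | trio availability; inherited vs de novo |
| `seed` | 1 | single global RNG stream |

Design notes, in the generator's own terms:

* **Carriers per planted region defaults to 2** because rarity is strict:
  with the default 300-sample pool, 2/300 ≈ 0.67% passes the 1% bound
  while 3/300 = 1% would (correctly) be removed. Configurations that
  shrink the cohort below 200 samples make planted regions common enough
  to be filtered — that is the rarity filter working as specified, not a
  generator defect.
* **Boundary jitter.** Each carrier's call jitters both template
  boundaries uniformly within ±10% of length, so copies of one event
  have non-identical boundaries (as real carrier tables show) while all
  copies share the central 80% of the template, keeping pairwise
  reciprocal overlap at or above (1−2·0.1)/(1+2·0.1) ≈ 0.67 > 0.5 by
  construction. Parent copies of inherited calls jitter once more, with
  worst-case parent–child RO of 0.8.
* **Placement is rejection sampling under kind-aware separation rules**:
  planted regions (and the repeat decoy) keep > 1 Mb clear of each other
  so surviving loci never merge; planted templates keep jitter headroom
  (20% of length + 10 kb) away from genes so carriers stay intergenic;
  background calls avoid planted/decoy/polymorphism zones; and *case*
  background calls additionally never overlap each other across samples.
  That last rule is what makes the generator's ground truth exact — the
  screen's correct output on a simulated cohort is *exactly* the planted
  regions — at the cost of not modelling coincidental background
  recurrence. A bounded retry budget turns an over-packed genome into an
  immediate error rather than a hang.
* **Decoys with a single point of failure each**: common polymorphisms
  are intergenic and rare-filter-removable only by frequency; genic
  decoys are recurrent and rare but lie inside gene spans; the repeat
  decoy is recurrent, rare, intergenic and control-absent, and dies only
  at the repeat filter (its region is ~95% masked). Each filter
  therefore has a true positive to remove, and ablation (`skip =`)
  makes the corresponding decoy reappear.
* **Background rates are chosen for test power, not realism** — real
  per-sample rare-CNV rates depend on platform and calling pipeline and
  are not modelled here; nor are probe density, platform-specific
  breakpoint error, or SNP genotypes. Passing the recovery tests
  therefore demonstrates the filter cascade's correctness on data with
  the assumed structure, not calibrated performance on any real cohort.
* The `paper_scale` preset (1491 cases / 3644 controls) exists for
  runtime exercises; the desk-scale defaults are what the test suite
  runs.

## Numerical and degenerate-input choices

* Strict vs non-strict boundaries are taken from the defining phrases
  and tested at the boundary: rarity `< 1%`, common-variant coverage
  removal at `>= 0.5`, repeat removal at `> 0.8`, locus merge at
  `gap <= 1 Mb`.
* The closed-interval gap between spans is `start₂ − end₁ − 1`
  (0 for overlapping or abutting spans); a merge gap of 0 makes locus
  merging a no-op beyond overlap clustering.
* Empty inputs flow through: an empty case file yields an empty report
  and zero-count summary; an empty gene list retains all calls; filters
  on an empty region set are identities. An empty *overall dataset* for
  frequency computation is an error, not a silent division by zero.
* Records violating `start < end`, with unparseable coordinates, or
  with unknown type tokens are rejected per record with line numbers
  (fatal only for unreadable annotation files); reversed-coordinate
  records are never silently swapped.
* Cluster, region and locus identifiers are assigned in
  (chromosome, start) order with numeric-then-lexicographic chromosome
  ordering, and reports are sorted the same way, so two runs on
  identical inputs are byte-identical.

## Problem sizes used by the tests

The suite validates primitives against brute-force oracles —
all-pairs carrier counting and union-find clustering at 2,000 calls,
per-base genic membership at 10⁴-bp scale, coverage by manual sweep —
and runs the end-to-end recovery property on the default desk-scale
simulation (150+150 samples, 5 planted regions, ~400 calls), which
completes in seconds. These sizes were chosen as the smallest at which
every code path (per-chromosome indexing, multi-cluster loci, trio
matching) is exercised; the screen itself is O(n log n) in calls per
chromosome and has no per-base data structures, so cohort-scale inputs
(thousands of samples) are well within a single-machine run.

## Known limitations

* Frequencies count carriers, not alleles; no Hardy–Weinberg or
  penetrance modelling (inherited risk CNVs in unaffected parents are
  reported, not interpreted).
* Sex chromosomes get naive diploid frequency handling (with a warning).
* One annotation file defines "known gene"; no isoform arbitration, no
  liftover — all inputs must share one genome build, asserted only via a
  declared build string.
* The control-absence filter treats control cohorts as a pool;
  per-control-cohort logic (e.g. requiring absence in each of several
  panels separately) is not implemented.
* Bin assignment is intentionally mechanical; it flags geometry
  compatible with each mechanism, it does not adjudicate between them.
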