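---
title: "Mapping mitotic recombination from SNP-array LOH data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mitotic recombination from SNP-array LOH data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohmapper)
```

## The biological system and the measurement

`lohmapper` analyzes mitotic recombination in hybrid yeast diploids formed by
crossing two sequence-diverged haploids (a W303-1A-like parent, haplotype A,
and a YJM789-like parent, haplotype B). Such diploids are heterozygous at
thousands of single-nucleotide polymorphisms, so any event that transfers or
removes one parent's sequence — a crossover (CO), a gene conversion (GC),
break-induced replication (BIR), a deletion or duplication, or whole-chromosome
aneuploidy — leaves a tract of loss of heterozygosity (LOH) or a copy-number
signature that an allele-specific microarray can read out.

Each SNP is interrogated by four 25-mer oligonucleotide probes: Watson and
Crick strands of each parental allele. Genomic DNA from an experimental sample
and from a heterozygous control are labeled in two fluorescent channels and
co-hybridized; the per-probe ratio of median intensities carries the genotype
signal. After normalization, heterozygous markers sit at a ratio near 1,
markers homozygous for the probe's allele near 1.5, and markers homozygous for
the other allele near 0.2–0.3.

A selectable system on the chromosome V left arm makes reciprocal crossovers
visible as red/white sectored colonies: a heterozygous suppressor tRNA gene
(selection locus near coordinate 32 kb; the centromere is near 152 kb) is
lost from one daughter and retained duplicated in the other when a CO between
the locus and the centromere segregates its products to different daughters.
Because the alternative segregation pattern is equally likely and invisible,
the crossover rate is **twice** the sectored-colony frequency
(`crossover_rate()`).

The two sectors of one colony carry, between them, the four chromatids of the
cell in which the CO happened. Pairing the sectors' genotype calls
region-by-region therefore yields four-chromatid allele counts that reveal the
structure of the conversion tract at the crossover:

* `2:2` — parental (heterozygous in both sectors), or the reciprocal LOH
  region distal to the CO itself;
* `3:1` — one converted chromatid: the signature of repair of a **single
  chromatid break (SCB)**, a lesion formed in S/G2;
* `4:0` — both sister chromatids converted at the same position: the
  signature of a **double sister-chromatid break (DSCB)**, the replication
  product of a chromosome broken in G1;
* `4:0/3:1` hybrid — two sister chromatids repaired with tracts of different
  lengths.

The classifier (`classify_tract()`) applies this decision table operationally:
`NONE` without any non-`2:2` region; `THREE_ONE`/`FOUR_ZERO` for exactly one
such region; `HYBRID` for one contiguous block made of a single `4:0` region
plus same-donor `3:1` regions; `COMPLEX` otherwise (disjoint conversion
regions or donor switching, the signature of "patchy" repair, branch migration
or template switching). The lesion origin is `DSCB` whenever any `4:0` region
is present, `SCB` when only single-donor `3:1` regions are seen, and
`UNCLASSIFIED` for mixed-donor tracts without a `4:0` region — complex events
mixing donors cannot be assigned a single initiating lesion without
case-by-case reconstruction, so the package deliberately refuses to guess.

## From probe ratios to events

1. **Normalization** (`normalize_ratios()`): per-probe experimental/control
   ratio, rescaled by one global constant so the genome-wide median is 1.
   Because the vast majority of a genome stays heterozygous, the median
   anchors the heterozygous state. This is the only normalization step
   implemented; spatial, print-tip and dye-bias corrections belong to array
   preprocessing and are out of scope.
2. **Genotype calling** (`call_genotypes()`): Watson/Crick ratios are averaged
   per allele. A marker is `HET` when both allele means fall in the band
   0.7–1.3, `HOM_A`/`HOM_B` when the matching allele clears 1.35 and the other
   stays below 0.5, otherwise `AMBIGUOUS`. The thresholds sit midway between
   the expected state means (1, 1.5, 0.25) and are exposed in
   `call_thresholds()`. A secondary, independent pass flags copy states: one
   allele near 1 with the other collapsed below 0.5 reads as a deletion
   (`DEL`); one allele mildly elevated (1.15–1.45) with the other mildly
   depressed (0.6–0.95) reads as a duplication (`DUP`). Zygosity calling is
   never conditioned on the copy pass. The copy-state ratio means (1.3/0.8
   for gains, 0.25/1.0 for losses) are tunable constants; assay literature
   reports no canonical values for these states.
3. **Ambiguity resolution** (`resolve_ambiguous()`): each `AMBIGUOUS` marker
   takes the majority state of its five nearest unambiguous neighbours —
   local consistency at ~1 kb marker spacing justifies neighbourhood voting,
   and markers are never re-thresholded.
4. **Segmentation** (`segment_calls()`): maximal runs of constant state; runs
   shorter than `min_markers = 2` are absorbed into a flanking run (the
   larger flank; ties go to the preceding run — arbitrary but fixed). A
   single-marker state at this resolution is indistinguishable from noise.
   Every state change yields a transition carrying *both* boundary marker
   coordinates, because the true breakpoint is only localized to the interval
   between the last marker of one state and the first marker of the next.
5. **Event classification** (`classify_unselected_events()`): an LOH run
   touching a chromosome-end marker is `BIR_OR_CO_TERMINAL` (a single sector
   cannot distinguish BIR from a crossover in an earlier division — the
   package does not try); an internal LOH run is `GC_INTERSTITIAL` (crossover
   association of unselected conversions is likewise deliberately not
   inferred); terminal copy runs are `TERMINAL_DUP`/`TERMINAL_DEL`; a copy
   gain covering most of a chromosome **and reaching both ends** is
   `TRISOMY` — requiring both ends prevents large terminal duplications from
   masquerading as trisomies.

### Tract lengths

The converted markers bound the tract from inside, the nearest unconverted
markers from outside; the reported length is the mean of the two spans
(`tract_length()`). A tract reaching a chromosome end is clipped there and
flagged. For DSCB events the measurable tract is the union of both
chromatids' conversion tracts — the span from the most proximal to the most
distal converted SNP.

### Association windows and enrichment

For every unselected event an association window approximates where the
initiating lesion must have been: ±10 kb around the homozygous SNP nearest
the breakpoint for terminal events, and the full interval between the
flanking heterozygous SNPs for interstitial conversions
(`build_association_windows()`). Windows within one genome are merged before
summation so no base pair is counted twice (merging is idempotent; whether
the original analysis merged is unstated, so the choice is documented here).
Against an analyzed universe of 11.6 Mb per genome times the number of
genomes, `enrichment_table()` computes, per element class, expected and
observed counts inside/outside the windows, a 1-df goodness-of-fit chi-square,
and a Hochberg–Benjamini step-up FDR correction across classes. An element is
"inside" when it overlaps a window by ≥1 bp (switchable to
midpoint-containment; overlap is the default because breakpoint windows are
meant to *contain* candidate lesion sites, and partial overlap suffices for
that). The continuity (Yates) correction is on by default — it is the variant
that reproduces the published p-values from the published counts — and the
correction is clamped at zero so observed = expected gives a statistic of 0.
Note that the corrected statistic is conservative; the type-I calibration
test in the suite therefore exercises the uncorrected variant
(`correction = FALSE`), whose rejection rate on uniformly placed elements is
the one expected to match the nominal level.

## The statistical kernel

The kernel is self-contained and oracle-tested:

* `fisher_exact_2x2()` — exact hypergeometric test; the two-sided p sums all
  tables (fixed margins) with probability ≤ the observed table's. One-tailed
  values are available via `alternative`: classical web calculators print
  both tails, and published analyses sometimes quote the one-tailed figure.
* `chisq_gof_1df()` — goodness of fit on inside/outside counts, with the
  clamped continuity correction described above.
* `mann_whitney()` — exact null distribution when the smaller sample has ≤8
  observations and no ties; otherwise the normal approximation with tie and
  continuity corrections.
* `hochberg_benjamini()` — step-up FDR: the largest k with
  p(k) ≤ k·q/m defines the rejection set.
* `median_with_ci()` — distribution-free CI from binomial order statistics,
  using the tightest *symmetric* pair of order statistics whose coverage
  reaches the level (for n = 9 at 95% this is the 2nd and 8th order
  statistic, coverage 0.961). Asymmetric minimal-width conventions exist; the
  symmetric one is used because it is the common textbook construction and
  is invariant under sign flips.

## What the simulator emulates — and what it does not

`sim_config()` fixes the study conditions: 16 chromosomes with the standard
yeast lengths, ~13,000 markers genome-wide with 750 on the 577-kb chromosome
V, an 11.6-Mb analyzed universe, state ratio means (1, 1.5, 0.25),
multiplicative lognormal probe noise (default sd 0.1 on the log scale — real
arrays' noise level is not published, so this is a free parameter chosen to
keep state distributions well separated, as they visibly are in real data),
a selected-CO interval between 32 kb and 152 kb on chromosome V, a DSCB
fraction of 0.75 among conversion-bearing crossovers, a conversionless-CO
probability of 1/43, and unselected events at a mean of 3 per sectored colony
(10 per sub-cultured isolate) with type mixture 62% interstitial conversion,
31% terminal LOH, 3% + 3% terminal duplication/deletion, 1% trisomy —
matching the reported composition of ~200 unselected events.

Tract lengths are lognormal: strictly positive, right-skewed, two-parameter.
Medians are 18.2 kb (DSCB, full tract extent) and 7.9 kb (SCB). The sdlog
parameters (0.39 and 1.05) are derived from the published 95% confidence
limits on those medians: for a lognormal sample median, the log CI half-width
is ≈ 1.96·sdlog·√(π/2n), which inverts to sdlog ≈ 0.39 from the DSCB limits
(15.6–22.2 kb, n = 30) and ≈ 1.05 from the SCB limits (3.2–18.4 kb, n = 9).
For DSCB events the *full extent* is drawn and the shorter chromatid tract is
placed inside it (uniform 0.2–0.9 of the extent, equal with probability 0.3),
so the measured DSCB tract median matches the configured median by
construction rather than inflating as the maximum of two draws would.
"Patchy" complex tracts are simulated as 1–2 heterozygous interruptions
punched into a parent tract (`p_complex`, default 0 — complex-tract
frequency is a strain property, and the recovery guarantees below are stated
for non-complex events).

The simulator does **not** emulate: raw scanner images, per-oligo
sequence-dependent hybridization efficiency, dye bias, spatial artifacts, the
known cross-hybridization between the chromosome IX and XV sub-telomeric
regions (a documented caveat of the real arrays), or sub-telomeric repeat
families — markers simply do not extend into regions absent from the array.
Passing tests on simulated data therefore demonstrate the correctness of the
calling/segmentation/classification logic under the stated noise model, not
robustness to array artifacts.

A detectability convention is applied consistently on both sides: a
conversion region must span at least `min_tract_markers = 2` markers to count,
in the generator's ground-truth labels as in the classifier. A DSCB whose 4:0
region covers fewer than two markers is visibly a 3:1 tract and is recorded
as such (its true origin remains DSCB); this affects well under 1% of events
at the default marker density and is the irreducible resolution limit of the
assay.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout (SGD style); BED input/output
  converts at the boundary (+1 on start), preserving interval length.
* Unknown probes in an intensity table are retained and flagged, never
  dropped, so totals stay auditable.
* Seeds: every simulation entry point takes an explicit integer seed;
  `run_pipeline()` derives per-sample substreams from one master seed and
  stamps it into output headers. Identical (config, seed) gives
  byte-identical outputs.
* Degenerate inputs: empty probe tables, all-zero control channels,
  nonpositive intensities, duplicated probes or marker coordinates, and
  windows exceeding the universe all raise informative errors; a window
  wider than a chromosome's marker complement falls back with a warning.
* The test suite runs cohorts sized for tight Monte-Carlo bounds at modest
  cost: 200 rendered noise-free colonies for classifier recovery, a
  1000-colony ground-truth cohort for tract-length remeasurement, 500
  replicate genomes for enrichment type-I calibration, and 500 replicates
  for median-CI coverage.

## Known limitations

* Copy-state calling under noise is weaker than zygosity calling (the DUP
  band is narrow); trisomy detection relies on majority copy-gain reaching
  both chromosome ends.
* BIR versus crossover for terminal LOH, and crossover association of
  unselected conversions, are intrinsically unresolvable from this data and
  are reported as merged categories.
* Complex tracts mixing donors without a 4:0 region are `UNCLASSIFIED`; the
  operational complex-tract rules approximate a case-by-case expert
  classification.
* The enrichment machinery takes user-supplied element BEDs; it does not
  curate element lists, and permutation-based enrichment is not implemented
  beyond the calibration test.
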