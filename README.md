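# lohmapper

Mapping and classification of mitotic recombination events from allele-specific
SNP-microarray loss-of-heterozygosity (LOH) data in hybrid yeast diploids.

## The problem

In a diploid formed by crossing two sequence-diverged yeast strains
(W303-1A-like "A" × YJM789-like "B"), every mitotic crossover, gene
conversion, break-induced replication event, deletion, duplication or trisomy
leaves a diagnostic footprint across thousands of heterozygous SNPs. A
two-channel microarray with four allele-specific probes per SNP reads this
footprint out as hybridization ratios: ~1 at heterozygous markers, ~1.5 where
the sample is homozygous for the probe's allele, ~0.2–0.3 where it is
homozygous for the other allele.

`lohmapper` is for researchers who map such events — in particular from the
colony-sectoring assay in which a selected crossover on the chromosome V left
arm produces a red/white sectored colony whose two sectors carry, between
them, all four chromatids of the recombinant cell. The package:

* normalizes probe ratios and calls per-marker zygosity and copy states;
* segments chromosomes into LOH runs with SNP-bounded transitions;
* pairs red/white sectors into four-chromatid allele counts (`2:2`, `3:1`,
  `4:0`) and classifies crossover-associated conversion tracts
  (`THREE_ONE`, `FOUR_ZERO`, `HYBRID`, `COMPLEX`) and their inferred lesion
  origin — single-chromatid break (**SCB**, an S/G2 lesion, 3:1 tract) versus
  double sister-chromatid break (**DSCB**, a replicated G1 lesion, 4:0 or
  4:0/3:1 tract). Any tract containing a 4:0 region is DSCB;
* measures tract lengths as the mean of the converted-marker span (minimum)
  and the flanking-marker span (maximum);
* classifies unselected genome-wide events (interstitial gene conversion,
  terminal BIR-or-crossover, terminal duplication/deletion, trisomy);
* tests recombination breakpoints for association with genomic element
  classes: ±10 kb windows around terminal breakpoints (the full
  inter-flanking-SNP interval for interstitial events), expected vs observed
  element counts inside/outside windows over an 11.6-Mb-per-genome universe,
  1-df continuity-corrected chi-square per class, and Hochberg–Benjamini FDR
  correction across classes;
* estimates crossover rates from sectored-colony counts (rate = 2 × sector
  frequency, with a binomial CI);
* and ships a fully seeded simulator (marker maps, sectored colonies,
  sub-cultured isolates, noisy probe intensities) with ground truth, so the
  entire pipeline is testable without any array download.

The statistical kernel (Fisher exact, chi-square goodness of fit,
Mann–Whitney, step-up FDR, distribution-free median CIs) is self-contained
and verified against enumeration oracles.

## Worked example

```r
library(lohmapper)

cfg <- sim_config(noise_sd = 0.1)            # study-condition defaults
res <- run_pipeline(n_colonies = 12, n_isolates = 3,
                    config = cfg, seed = 42, verbose = FALSE)
print(res)
#> LOH mapping pipeline result (seed 42)
#>   genomes analyzed: 15
#>   selected crossovers: 12
#>   DSCB fraction among classified tracts: 0.818
#>   DSCB tract median: 24.6 kb (14.7-31.2 kb, 95% CI, n=9)
#>   SCB tract median: 9.3 kb (6.9-11.7 kb, 95% CI, n=2)
#>   unselected events:
#>     BIR_OR_CO_TERMINAL: 14
#>     GC_INTERSTITIAL: 40
#>     TERMINAL_DUP: 3
```

Every one of the 12 simulated colonies passed selection (reciprocal LOH over
the selection locus); 9 of the 11 classified conversion tracts carried a 4:0
region and are therefore DSCB-derived — at this small cohort size the
fraction (0.818) scatters widely around the configured 0.75. Tract medians
come with distribution-free 95% CIs from binomial order statistics.
Unselected events are dominated by interstitial conversions over terminal
BIR/CO events, as configured.

The kernel reproduces published contingency statistics directly:

```r
fisher_exact_2x2(matrix(c(9, 30, 45, 76), 2, byrow = TRUE))   # 0.12
chisq_gof_1df(234, 27028, 189, 27073)$p.value                 # 0.0012
```

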