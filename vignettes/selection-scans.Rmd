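---
title: "Diversity, ROH islands and windowed FST scans for multi-breed SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity, ROH islands and windowed FST scans for multi-breed SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohfst)
```

## What the package computes

`rohfst` is a pipeline for the genome-wide analyses that livestock
population-genetics studies run on medium-density SNP-array panels (tens of
thousands of biallelic autosomal SNPs, tens to hundreds of animals per
breed):

1. **Quality control** of PLINK-format genotypes (per-SNP call rate, minor
   allele frequency, per-individual missingness).
2. **Per-breed diversity**: observed heterozygosity (Ho), unbiased expected
   heterozygosity (uHe, the Hardy–Weinberg expectation with the
   $2n/(2n-1)$ small-sample correction), and the inbreeding coefficient
   $F_{IS} = 1 - \bar{H}_o / \bar{uH}_e$ computed from the across-locus
   means.
3. **Runs of homozygosity** (ROH) per individual with a scanning-window
   detector, and the genomic inbreeding coefficient
   $F_{ROH} = L_{ROH}/L_{aut}$ with $L_{aut} = 2522$ Mb, the autosomal
   length of the goat genome for which the defaults are tuned.
4. **ROH islands**: per-breed regions where an unusually high fraction of
   animals are homozygous, called by thresholding per-SNP ROH occurrence at
   an upper percentile.
5. **Windowed Weir–Cockerham FST** between environment-defined
   metapopulations (wet- vs dry-adapted breeds) and between individual
   breed pairs, with percentile-based outlier windows.
6. **Population structure summaries**: Reynolds' drift distance between
   breeds (exported in PHYLIP and NEXUS formats for external tree/network
   software), individual identity-by-state distances, and classical
   (principal-coordinate) MDS.

A Balding–Nichols simulator with injected selective sweeps and
breed-shared homozygous tracts provides ground-truth datasets, so every
stage has an end-to-end recovery test without any external data.

## The diversity model

For one locus in one breed with $n$ called genotypes and A1 frequency $p$,

$$H_{o,l} = \frac{\#\text{heterozygotes}}{n}, \qquad
  uH_{e,l} = \left(1 - p^2 - q^2\right)\frac{2n}{2n-1}.$$

Breed summaries are the means and standard deviations of these per-locus
values across all loci with at least one call in the breed, and
$F_{IS}$ is computed from the unrounded means. Two conventions deserve
mention because they are genuinely open choices:

* **SDs are across-locus population SDs** (divisor $N_{loci}$): the only
  dispersion available per breed from a single panel.
* **Within-breed monomorphic loci are kept in the means** (contributing
  zeros), because genome-wide means over all retained SNPs are the
  standard reporting unit; `breed_diversity(include_monomorphic = FALSE)`
  excludes them instead.

Under Hardy–Weinberg equilibrium both $H_{o,l}$ and $uH_{e,l}$ are
unbiased for $2pq$, so $F_{IS}$ of a drift-simulated breed with no
inbreeding is zero up to Monte-Carlo error — the null-calibration test
asserts $|F_{IS}| < 0.01$ on 20,000 simulated SNPs.

## The ROH detector

`detect_roh()` implements the scanning-window procedure of the standard
SNP-array ROH callers, with all seven criteria exposed in `roh_params()`:

| parameter | default | meaning |
|---|---|---|
| `window_snp` | 20 | sliding window length, SNPs |
| `window_het` | 0 | max heterozygous calls per hit window |
| `window_missing` | 2 | max missing calls per hit window |
| `window_hit_frac` | 0.05 | min fraction of covering windows that are hits |
| `min_snp` | 20 | min SNPs per reported run |
| `min_kb` | 2000 | min run length (kb) |
| `min_density_kb_per_snp` | 100 | max kb per SNP within a run |
| `max_gap_kb` | 500 | max gap between consecutive run SNPs (kb) |

The hit-proportion threshold (`window_hit_frac`) is the one criterion the
published parameter lists of such scans usually leave implicit; 0.05 is
the long-standing default of the reference implementation of this scan
and is exposed as a parameter. Numerical conventions: run length is
`end_bp - start_bp` of the outermost SNPs; minima are inclusive (a run of
exactly 2.000 Mb passes); SNPs near chromosome ends are covered by fewer
windows and their hit proportion uses the actual covering-window count;
missing calls never break a run (only heterozygous calls do), consistent
with `window_missing = 2`. The detector is validated against a
brute-force enumeration oracle on 1000 randomized chromosomes with
randomized parameters.

## ROH islands and the FST scan

Per-SNP ROH occurrence in a breed is the fraction of the breed's animals
whose ROH cover the SNP (inclusive bounds, all genotyped animals in the
denominator). Islands are maximal runs of map-consecutive SNPs whose
occurrence reaches the breed's 99.9th percentile. Percentiles use the
linear-interpolation definition (R's default `type = 7`), ties at the
threshold are all included, and islands never cross chromosome
boundaries. If every SNP has the same occurrence the threshold is
meaningless; the caller warns and returns no islands.

FST uses the Weir–Cockerham (1984) two-level diploid estimator with
$r = 2$ populations. Per locus the among-population ($a$),
among-individual ($b$) and within-individual ($c$) variance components
are computed from the two samples' sizes, allele frequencies and observed
heterozygote frequencies; the weighted (ratio-of-sums) window estimate is
$\sum a / \sum(a+b+c)$ over member SNPs. Windows span 500 kb and advance
in 250-kb steps from bp 1 of each chromosome, inclusive bounds, so each
SNP belongs to two windows; loci monomorphic across both populations or
with fewer than two genotyped individuals in either population are
excluded from the sums. Significant windows reach the 99.95th percentile
of the weighted FST over **all** windows of the contrast and contain at
least five SNPs; the percentile-before-filter order follows the usual
reading of such rules, and `significant_windows(filter_first = TRUE)`
gives the other order. The metapopulation contrast pools individuals into
two super-populations rather than averaging breed-level estimates, which
is what gives the environment contrast its power at small per-breed
sample sizes.

Negative per-locus estimates are retained: they are an expected property
of the estimator near zero differentiation, and discarding them would
bias window sums upward.

## The simulator and what it does (not) emulate

`simulate_dataset()` draws ancestral frequencies $p \sim U(0.05, 0.95)$,
per-breed frequencies from the Balding–Nichols distribution
$\mathrm{Beta}\!\left(p\frac{1-F}{F}, (1-p)\frac{1-F}{F}\right)$, and
genotypes as independent Hardy–Weinberg draws. The default configuration
mirrors the study design the pipeline was built around: four island
breeds (two wet-adapted, two dry-adapted; $n$ = 60/61/64/39), two ~120-Mb
autosomes, 1% missingness, and per-breed drift coefficients of 0.05–0.10
(a single ancestral gene pool with island isolation; the stronger drift
for the second breed mimics the most isolated population). SNP positions
occupy distinct cells of a 5-kb grid, which enforces the minimum spacing
real arrays have and keeps positions unique.

Injected signals are deliberately simple:

* **Sweeps** shift the target metapopulation's frequencies by $\delta$
  away from the ancestral majority allele, clipped to $[0.01, 0.99]$.
  Shifting toward the *farther* boundary is what preserves the full
  wet/dry differential when the ancestral frequency sits near an edge;
  shifting toward the nearer boundary would clip most of the signal away
  for extreme frequencies.
* **Tracts** copy one breed-shared haplotype over both chromosomes of a
  carrier fraction of the breed, forcing homozygosity across the interval
  while approximately preserving allele frequencies — a detector target,
  not a pedigree-inbreeding model.

The simulator has no linkage disequilibrium outside injected tracts, no
recombination map, no ascertainment bias, and no genotyping-error model.
Passing recovery tests therefore shows that the detectors find the
signals they are defined to find under clean conditions at realistic
scale; it does not show robustness to array ascertainment or LD
structure in real panels.

## Problem sizes used in the validation suite

The recovery suite runs 100 replicates of the four-breed design at
30,000 SNPs over two 125-Mb autosomes with $n = 40$ per breed, one sweep
($\delta = 0.6$, 1 Mb) and one 2.5-Mb tract (carrier fraction 0.85), and
requires both signals to be recovered in at least 95% of replicates.
Oracle-equivalence checks use $10^4$ random loci (Weir–Cockerham, to
$10^{-12}$) and 1000 random chromosomes of up to 300 SNPs (ROH detector,
exact agreement). These sizes give stable pass/fail behaviour while
keeping a full run of the suite at desk scale.

## Known limitations

* Windowed FST thresholds are percentile-based; with few windows (small
  simulated genomes) the 99.95th percentile approaches the maximum and
  the scan warns.
* The PLINK text dialect (.ped/.map) does not encode allele order, so a
  text round-trip reproduces genotype codes only up to A1/A2 orientation;
  every downstream statistic is allele-label invariant, and the binary
  dialect round-trips bit-exactly.
* Non-autosomal chromosomes are dropped on input; the pipeline is
  autosome-only by construction, matching the $L_{aut}$ convention of
  $F_{ROH}$.
* Neighbor-net, model-based clustering and gene annotation are out of
  scope; the distance matrices are exported in standard formats for the
  external tools that do those jobs.

## A worked example

```{r example, eval = FALSE}
cfg <- run_config(
  sim = sim_config(
    seed = 99, n_snps = 6000L,
    sweeps = list(list(chrom = "1", start_bp = 60e6, end_bp = 61e6,
                       target_group = "wet", delta = 0.7)),
    roh_tracts = list(list(population = "MAJ", chrom = "2",
                           start_bp = 40e6, end_bp = 45e6,
                           carrier_fraction = 0.9))),
  out_dir = "demo_run", seed = 99)
manifest <- run_pipeline(cfg)
read.delim("demo_run/roh_islands.tsv")
read.delim("demo_run/fst_significant_windows.tsv")
```

The same workflow is available from a shell through the launcher in
`inst/cli/rohfst` (subcommands `simulate`, `qc`, `diversity`, `roh`,
`roh-islands`, `fst-scan`, `distances`, `mds`, `run-all`).
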