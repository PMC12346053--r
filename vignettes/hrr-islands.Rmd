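---
title: "Heterozygosity-rich regions, islands and their significance in herd-structured genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterozygosity-rich regions, islands and their significance in herd-structured genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrrscan)
```

## The problem

Runs of homozygosity (ROHs) — long autozygous stretches of consecutive
homozygous SNPs — are a standard window on inbreeding in livestock. Their
mirror image, heterozygosity-rich regions (HRRs, also called ROHet or HER),
are contiguous stretches of heterozygous calls in one animal. Where HRRs from
many animals pile up on a chromosome they form an HRR island (HRRI), and a
natural question is whether such islands mark balancing selection (for
example heterozygote advantage at immunity or fertility loci), or merely
regions where inbreeding never took hold.

`hrrscan` implements the full analysis chain for SNP-array genotypes from a
population structured into herds: run detection, island calling, a
permutation null for island significance, chromosome-level saturation
statistics, a windowed Tajima's D scan, and a repeat-element coverage
comparison between island classes. Because array data of this kind is often
held in restricted depositories, the package also ships a herd-structured
genotype simulator so that every stage is testable — and the whole analysis
reproducible — without access to any real animal data.

## Run detection: the consecutive-runs method

A run is detected per animal and chromosome by scanning the ordered markers,
without any sliding window. A run

* extends over consecutive markers whose call matches the target state
  (heterozygous for HRR; either homozygote for ROH),
* tolerates at most `max_missing` missing calls (default 1) and
  `max_opposite` opposite calls (default 0, as in the study design) in its
  interior,
* is broken by an inter-marker gap above `max_gap_bp` (default 1 Mb),
* never starts or ends on a non-target call, and
* is accepted when it carries at least `min_snps` target SNPs **and** spans
  at least `min_length_bp`, where length is `end_bp − start_bp` of the first
  and last run SNP. This length convention is the one under which published
  island coordinate pairs reproduce their printed kb lengths exactly.

The standard parameterizations are `hrr_params(50000)` and
`hrr_params(250000)` (5 heterozygous SNPs minimum) and `roh_params()`
(10 homozygous SNPs, 250 kb).

One design point deserves a precise statement. A naive "extend until a
tolerance is exceeded, then restart after the break" scan is not well defined
when `max_missing > 0`: a rejected short candidate can hide a longer valid
window that starts inside it. `detect_runs` therefore uses *greedy-by-start
with maximal extension*: standing at the leftmost eligible target SNP, it
takes the furthest end reachable within the budgets; an accepted run moves
the cursor past its end (runs of one animal never overlap), a rejected
candidate advances the cursor by one target SNP. The test suite proves this
equal to exhaustive enumeration of all maximal budget-satisfying windows on
hundreds of random instances.

```{r runs-demo}
fx <- emit_fixture("mini-island")
runs <- detect_all_runs(fx$dataset, hrr_params())
head(runs, 3)
```

## Islands and their support

`snp_incidence()` converts runs into a per-marker track: the fraction of a
group's animals with at least one run covering the marker.
`call_islands()` turns a track into islands — maximal stretches of
consecutive markers with incidence at or above a threshold; two stretches
separated by even one sub-threshold marker stay separate. The default
criterion is a fixed threshold of 0.4, with a top-quantile mode (0.999 by
default) as an alternative; both mirror criteria used in the HRR literature,
which has no single convention. Island *support* is the peak (not mean)
incidence among member SNPs — the reading under which published island
support values behave — and island boundaries are member SNP positions, not
midpoints.

## The permutation null

Herd-specific islands could be artifacts of herd structure, so significance
is judged against a null in which animal labels carry no herd information:

1. animals are shuffled into groups (by default herd-sized, so nobody idles;
   a "groups of sixty" mode reproduces designs where a few animals stay out),
2. per group the incidence track is rebuilt *from the precomputed runs* —
   a run belongs to the animal, so permutation changes incidence only and
   `detect_runs` is never re-executed (the suite verifies this by mocking),
3. islands are re-called at the same threshold and matched to each observed
   island by largest base-pair overlap,
4. matched supports are aggregated per group index across replicates,
   mirroring reports that print one value per permuted herd regardless of
   the number of permutations.

Two p-values are reported. `p_mwu` is the exact Mann-Whitney comparison of
the observed support against the per-group permuted supports; with one
observed value against at most six group values its two-sided floor is
2/7 ≈ 0.29, so it can flag nothing at conventional levels — it is retained
for comparability. The primary statistic is the empirical permutation p,
`(1 + #{permuted support ≥ observed}) / (1 + #permuted)`, over the full
matched distribution. An island matched in fewer than `min_matched_groups`
(default 3) permuted groups is flagged *not evaluable* rather than given a
p-value — with discrete support grids and a calling threshold, absence of
matches means the null distribution cannot be formed, not that the island is
significant. `mwu_exact()` itself enumerates all rank assignments for pooled
sizes up to 20 (exact under ties, unlike the classical tables) and falls
back to the tie-corrected normal approximation above that.

## Genome summaries

* `herd_mean_se()`: arithmetic mean and `sd/sqrt(n)` across herds — the
  convention verified against printed per-herd table cells.
* `class_counts()` / `class_proportions()`: run-length spectra in half-open
  Mb classes (0.05–0.2–0.4–0.8–1.6–∞ for the 50 kb scan; starting at 0.25
  for the 250 kb scan).
* `chromosome_rank()`: for chromosome *i*, `(N_i/T) / (L_i/L_genome)` — its
  share of runs over its share of genome length; 1 means proportional
  saturation, and chromosomes more than 2 SD from the mean rank are flagged.
* `extended_het_coefficient()`: per animal, total HRR length divided by the
  SNP-covered autosome length (the sum over chromosomes of last-minus-first
  SNP position — the only computable reading of "autosomes covered by SNP").
  It is the heterozygous analogue of the F_ROH inbreeding coefficient.
* `rank_correlations()`: Pearson and Spearman (midranks) between run share
  and length share, p-values from the t approximation.

## Tajima's D scan

`scan_tajima()` tiles each chromosome with 100 kb frames anchored at
position 0 (half-open, so every SNP falls in exactly one window) and treats
the 2N genotype alleles as sequences: per window, S is the number of
segregating sites, π the mean pairwise difference computed from per-site
allele frequencies, and `D = (π − S/a1) / sqrt(e1·S + e2·S(S−1))` with the
textbook constants; windows with S = 0 are flagged undefined rather than
zero. Per chromosome the SD of all defined D values sets a `3·SD` threshold
and windows above it are flagged — the positive-tail reading consistent with
a near-zero-mean D distribution, where strongly positive D marks candidate
balancing selection. No demographic correction is applied; D here is a
ranking device, not a calibrated test. Missing calls shrink a site's allele
count in π; the constants use the full 2N, which at array-scale missingness
(<1%) is a negligible approximation.

## Repeat-element coverage

`element_fraction()` intersects an island with LINE/SINE/simple-repeat/LTR
intervals (BED input, converted from 0-based half-open to the package's
1-based convention): intervals are merged per type first, so the fraction —
overlap bp over island bp — is invariant to fragmentation and order, and a
fully covered island scores exactly 1. `compare_enrichment()` applies the
exact Mann-Whitney test to per-island fractions of the two island classes.
The coverage-fraction definition is an interpretation of "length fraction per
kb" normalizations seen in the literature, chosen because published values
approach 0.87 for LINEs, which only a fraction-of-length reading produces.

## The simulator

`simulate_dataset()` generates the study conditions the pipeline targets:

* six herds of 57/85/73/44/58/54 cows and 48,108 autosomal markers allocated
  over the 29 bovine autosomes proportionally to ARS-UCD chromosome lengths,
  with gamma(shape 4) inter-marker spacing so the 1 Mb gap rule is exercised;
* an ancestral MAF spectrum uniform on (0.01, 0.5) with a 10% rare fraction
  below 0.01 (half of it strictly monomorphic), matching a ~10% loss at a
  MAF 0.01 filter;
* Balding–Nichols herd differentiation: each herd's frequency is drawn from
  `Beta(p(1−F)/F, (1−p)(1−F)/F)` around ancestral `p`, with `F = 0.05`
  inside the 0.003–0.12 pairwise band reported for such herds, and
  Hardy–Weinberg genotypes within herd (verified by chi-square
  goodness-of-fit in the suite);
* genotyping missingness 0.005 (rate > 0.99);
* planted heterozygote islands at the study's island coordinates, widened to
  at least 400 kb so each tract holds ≥ 5 array SNPs. A cow of an elevated
  herd expresses the island — becomes heterozygous across the tract — with
  probability `h` set to the printed herd support; cows of other herds
  express it with a `baseline_h` derived from the printed whole-population
  support by removing the elevated herds' contribution. Expression is
  tract-level (markers are independent everywhere else): with independent
  per-marker heterozygosity, run coverage — and hence island support — would
  sit far below `h`, and no threshold-0.4 island could ever be recovered at
  h = 0.6; tract-level expression makes support ≈ h, which is what the
  recovery criterion and the printed support values describe;
* planted multi-Mb ROH tracts: carriers (half of the listed herds' members)
  homozygous for one shared haplotype.

What the simulator does **not** emulate: linkage disequilibrium outside
planted tracts (the analysis consumes genotype states, not haplotypes),
pedigree structure, array ascertainment bias, and genotype-intensity noise.
Consequently background run counts are far lower than in real Holstein data
(HRRs arise only from chance heterozygote stretches), absolute run counts
and the coefficient of extended heterozygosity are not comparable to
real-data values, and passing tests demonstrate correctness of the
machinery, not biological realism of the background.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout (PLINK MAP convention); BED
  input is converted on read. Island/run length is `end − start`.
* Display rounding is half-up (`round_half_up()`), matching fixed-precision
  tables; internal values are full precision.
* Pseudo-phenotype labels are opaque strings, never parsed as numbers —
  permutation designs deliberately use labels that collide with genotype
  software's numeric phenotype codes.
* MAF uses non-missing alleles only; QC order is autosomes → marker
  missingness → individual missingness → MAF, and QC is idempotent.
* Two accepted runs separated by a single disallowed call remain separate
  (no post-merge); ties in island matching resolve to the first candidate.
* All randomness flows from one master seed; permutation replicates derive
  per-replicate streams by counter, so any replicate is reproducible in
  isolation, and RNG state of the caller is restored.
* Problem sizes in the shipped tests and acceptance script: the full-scale
  synthetic study (371 cows × 48,108 SNPs) with 200 permutation replicates;
  the uniformity property uses 360 cows × 8,000 SNPs with ~650 background
  islands × 200 replicates; recovery uses 100 seeded replicates of a
  30-cow, 120-SNP herd. These sizes keep each property battery in the
  minutes range while leaving the statistics stable.

## Known limitations

* The empirical permutation p is discrete; with coarse support grids (small
  groups) it is conservative near the calling threshold, where tied permuted
  supports push p toward 1. The uniformity property in the suite therefore
  uses groups of 60 and a threshold well inside the incidence distribution.
* The Mann-Whitney p against six aggregated group values is structurally
  floored at 2/7 and should not be used for significance calls; it is
  reported for table compatibility only.
* The published table cells the aggregation conventions were verified
  against contain small internal inconsistencies (two island lengths off by
  0.1–2 kb from their own coordinates, one mean apparently truncated); the
  suite asserts only the self-consistent cells.
* Tajima's D on array SNPs inherits ascertainment bias; the 3·SD rule ranks
  windows within a chromosome and makes no absolute claim.
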