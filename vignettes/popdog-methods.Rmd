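---
title: "Methods: models, estimators and design choices in popdog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in popdog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

popdog analyses multi-population biallelic SNP-array panels of the kind
produced by high-density genotyping chips in livestock and companion-animal
genetics: a few dozen populations (breeds), roughly a dozen genotyped
individuals each, and on the order of 10^5 autosomal SNPs at an average
density of about 12.5 SNPs per 200 kb. This vignette documents the models
and estimators, the tunable parameters, and the design decisions made where
the published conventions leave the details open.

```{r setup}
library(popdog)
```

## The genotype panel and its conventions

A `genotype_panel` stores an individuals-by-SNPs matrix of dosage codes in
{0, 1, 2, NA} counting copies of `allele_b`, together with the SNP map and
population labels. Conventions:

* `allele_b` is the **minor** allele, so allele frequencies used by MAF
  bookkeeping and the F_ST machinery refer to a consistent orientation.
  Ties at frequency exactly 0.5 are broken lexicographically for
  determinism. Every estimator downstream is algebraically invariant to
  this orientation (substituting p with 1 - p leaves MSG and MSP
  unchanged), so the choice is bookkeeping, not substance.
* Positions are 1-based, as in PLINK MAP/BIM files, and every interval the
  package emits (ROH segments, scan windows, regions) is 1-based inclusive.
* The PLINK text reader derives the minor allele from the data it reads;
  a written panel whose stored `allele_b` happens to be the major allele
  at some SNP is therefore read back with the orientation flipped there
  (dosage x becomes 2 - x). The binary dialect stores both alleles in the
  BIM file and round-trips bit-exactly.
* Population labels come from the PED/FAM family-ID column; a two-column
  sidecar TSV (`individual<TAB>population`) overrides them, because
  consortium-distributed files vary in how they use that column.

Quality control applies the conventional chip thresholds as defaults:
SNPs with MAF < 0.01 or call rate < 90% and then individuals with call
rate < 95% are removed, in that order, with individual call rates computed
on the pre-filter SNP set (`qc_panel()`).

## The F_ST estimator

`per_snp_fst()` implements the ANOVA-style (mean-square) multi-population
estimator. With s populations, n_i allele copies sampled from population i,
and p_i the sample frequency of the reference allele:

* MSG = sum_i n_i p_i (1 - p_i) / sum_i (n_i - 1) — within-population mean
  square;
* MSP = sum_i n_i (p_i - pbar)^2 / (s - 1), pbar = sum n_i p_i / sum n_i —
  between-population mean square;
* n_c = (sum n_i - sum n_i^2 / sum n_i) / (s - 1) — sample size corrected
  for variance across populations;
* F_ST = (MSP - MSG) / (MSP + (n_c - 1) MSG).

Two analytic limits pin the implementation down: a fixed difference
(p = 1 vs 0) gives exactly 1, and identical frequencies give the raw value
-1/(n_c - 1), which truncates to 0 in reported summaries. The published
rendering of the within-population denominator is typographically ambiguous
between sum(n_i) and sum(n_i - 1); the package defaults to sum(n_i - 1),
which makes MSG the usual unbiased within-population variance component,
and exposes the alternative through `msg_denom = "n"` so both readings can
be compared on the same data.

Three reporting rules matter:

* **Truncation.** Negative raw values are meaningless as variance
  proportions and are set to 0 — but only in reported summaries
  (`fst_reported`, `pairwise_fst_matrix()`). The raw signed values are kept
  for the selection scan, because truncating before computing genome-wide
  moments would bias both the mean and the standard deviation used for
  standardization.
* **Informative SNPs.** SNPs monomorphic across the compared populations
  are 0/0 and are excluded from pairwise means rather than counted as 0.
* **Sample sizes.** n_i is counted in allele copies (2 x called
  individuals), per SNP, so missingness enters the estimator through the
  sizes rather than through imputation.

## The d_i selection scan

For breed i the per-SNP statistic is

d_i = sum over j != i of (F_ST^ij - E[F_ST^ij]) / sd[F_ST^ij],

where the moments are each pair's mean and population standard deviation
(divisor N) of the **raw** per-SNP F_ST over all scan SNPs. Large d_i marks
SNPs where breed i diverges from the other breeds jointly, the signature of
breed-specific selection. Implementation decisions:

* SNPs where any constituent pair is undefined are dropped from that
  breed's track (flagged `NA`), never zero-filled; silent imputation would
  shrink real signals.
* Windows tile each autosome on a fixed 200-kb grid anchored at position 1.
  A fixed grid is deterministic and makes region merging well defined;
  windows with fewer than 6 defined SNPs are discarded, which at the
  emulated density (mean 12.5 SNPs/window) removes only the sparse tail.
* Outliers are called per breed at the empirical 99.5th percentile of that
  breed's retained window means, computed as the linear-interpolation
  (type 7) quantile with ties at the threshold included. On small scans
  this discretizes: a scan of m windows calls ceiling(0.005 m) windows, so
  at 250 windows per breed the realized neutral call rate is 0.8% rather
  than 0.5%; with thousands of windows the discrepancy vanishes. Scans
  with fewer than 20 windows warn that the threshold is unstable.
* Grid-adjacent called windows merge into regions (`merge_regions()`), so
  a 650-window call set can land in a smaller number of contiguous
  candidate regions.
* Group contrasts (`group_contrast_scan()`) pool populations into a focal
  and a background group and re-estimate the pair moments from the
  two-group track itself rather than reusing breed-level moments: the
  contrast asks about divergence of the pooled groups, whose genome-wide
  F_ST distribution differs from any single pair's.

## Runs of homozygosity

`detect_roh()` is the scanning-window vote: a 50-SNP window slides one SNP
at a time; a window is homozygous-eligible when it has at most 1
heterozygous and at most 5 missing calls; a SNP is in-ROH when at least 5%
(`hit_fraction`) of the windows covering it are eligible; maximal in-ROH
runs become segments when they span at least 200 kb and 25 SNPs. Window
size, het/missing allowances and the 200-kb minimum follow the conventional
chip settings for dog-genome panels, where strong LD up to 100 kb makes
shorter homozygous tracts uninformative; the vote threshold and SNP minimum
follow the scanning tool's documented defaults scaled to the 50-SNP window
and are exposed as arguments. The scan runs on an LD-pruned set
(r^2 >= 0.8 removed) so that a single over-represented haplotype block
cannot fake a long run. Chromosomes with fewer SNPs than one window yield
no calls by construction. The test suite re-checks every emitted segment
against an exhaustive re-implementation of the vote.

## Linkage disequilibrium

`pairwise_r2()` computes the squared Pearson correlation of genotype
dosages (composite LD) over individuals with both SNPs called — no phasing
and no EM haplotype frequencies — for all same-chromosome pairs within
500 kb, with no r^2 floor. Zero-variance SNPs yield undefined correlations
and those pairs are skipped. Note the finite-sample floor: independent SNPs
give E[r^2] of about 1/(n-1), so with 12 individuals the background is
roughly 0.09, which is why LD-extent comparisons should use equal sample
sizes across populations.

The LD-extent summary r^2_0.3 — the distance at which mean r^2 decays to
0.3 — is extracted from 10-kb binned means after isotonic (monotone
non-increasing) smoothing, by linear interpolation between the flanking bin
midpoints. Isotonic regression plus interpolation is deterministic and
free of tuning constants, unlike curve fitting. A curve that never exceeds
the threshold returns 0; one that never falls below returns the maximum
distance flagged `censored`.

`ld_prune()` is the greedy windowed scan used to prepare structure and ROH
SNP sets: within each 50-SNP window, while any pair has r^2 at or above the
cutoff, the lower-MAF member is removed (ties: the later position). The
removal rule is stated explicitly because published pipelines name only the
cutoffs.

## Diversity indices

Per population: proportion of polymorphic SNPs (on a cohort-level
MAF > 0.1 subset, so that rare cohort variants do not inflate breed-level
polymorphism), observed and expected heterozygosity (h_e = 2p(1-p) from
sample frequencies), rarefaction allelic richness, and a method-of-moments
inbreeding coefficient per individual,
f = (O_hom - E_hom) / (L - E_hom), with the small-sample n/(n-1) correction
in the expected homozygosity. Allelic richness standardizes to g allele
copies by the hypergeometric identity
a_r = sum_a [1 - C(N - N_a, g) / C(N, g)]; it is monotone in g and bounded
by 2 for biallelic loci, which is why printed chip-panel values above 2 can
only arise from multi-allelic coding artifacts and are not reproduced here.
The default g is twice the smallest per-population sample size, mirroring
rarefaction to the largest common sample.

Identity-by-state distances use allele-sharing counts with het-het pairs
sharing 2 copies (the PLINK convention), giving distance
1 - shared/(2 x jointly called). The "1 - Dst" distance named in chip-panel
studies is not defined beyond its name; IBS allele-sharing similarity is
the documented assumption here.

## Structure summaries

PCA standardizes each SNP column by its 2p mean and sqrt(2p(1-p)) scale
(the GRM model used by the common PCA tools), mean-imputes missing entries
as 0 after centering, and eigendecomposes the individual covariance.
Neighbor-joining trees are built from 1 - IBS distances with the classic
Saitou-Nei agglomeration via `ape`; NJ is exact on additive matrices, which
the tests exploit by recovering random additive trees bit-for-bit. Negative
branch lengths, possible on non-additive input, are clamped to zero with
the deficit moved to the sibling edge (standard practice), and the clamp
count is recorded. Tie-breaking follows `ape`'s deterministic order rather
than any file-order behavior of older tools, preferring reproducibility.

## ABBA-BABA D-statistics

`d_statistic()` is the frequency-based four-taxon test:
D = sum[(1-p1) p2 p3 (1-pO) - p1 (1-p2) p3 (1-pO)] /
sum[(1-p1) p2 p3 (1-pO) + p1 (1-p2) p3 (1-pO)] over map-ordered SNPs, with
a delete-one block jackknife over contiguous 300-SNP blocks for the
Z-score. Population allele frequencies (not single pseudo-haploid
samples) are used because the panels carry population samples; 300-SNP
blocks comfortably exceed the LD extent at the emulated density. D is +1
on a pure ABBA site, 0 when P1 and P2 have identical frequency tracks, and
flips sign when P1 and P2 are swapped.

## The simulator: what it emulates, and what it does not

`simulate_panel()` provides ground truth for every stage:

1. SNP positions uniform per chromosome (so window SNP counts vary, which
   the >= 6-SNP rule must handle), ancestral frequencies
   Uniform(0.05, 0.95);
2. population frequencies from the Balding-Nichols Beta distribution
   p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F), whose parameter F equals the
   expected ANOVA-style F_ST — giving an analytic recovery target;
3. per population, `founders_per_pop` founder haplotypes drawn site-wise
   from p_k; each individual's two haplotypes are recombinant mosaics of
   the founders with Poisson crossovers (`recomb_rate` per bp);
4. genotype = haplotype sum; i.i.d. missingness.

The random streams are consumed in that fixed order, so one seed
reproduces the panel exactly. The founder mosaic is what creates LD and
autozygosity: two founders force long homozygous tracts (about half of all
individuals copy the same founder chromosome-wide), while a large pool
approaches independent Hardy-Weinberg draws. A finite founder pool of size
f also adds roughly (1-F)/(2f) of extra differentiation beyond the
parametric F, because the pool is itself a sample from the population
frequency; divergence-recovery experiments therefore use
`founders_per_pop = 100`, at least the number of sampled copies, so the
Beta parameter is the recovery target to within sampling error.

Defaults are fixed at the emulated study scale: 12 individuals per
population (the equalized breed sample size), 12.5 SNPs per 200 kb,
F = 0.1 (typical of reported between-breed differentiation, which spans
roughly 0.01-0.35), 1 cM/Mb recombination, 20 founders (moderate
within-breed LD), 2% missingness, and 2 chromosomes of 25 Mb for
desk-scale runs — the scan statistics are per-window, so chromosome count
scales the number of windows, not the per-window behavior. The test suite
and the acceptance script use 10-breed, 12-per-breed panels over
2 x 25 Mb (about 2,400 retained windows) for scan calibration, ~5,000-SNP
two-population panels for F_ST recovery, and 10,000-SNP quartets for
D-statistics.

Planted selection shifts the focal population's frequency by `freq_shift`
(clipped to [0.02, 0.98]) inside target intervals before genotypes are
drawn; `plant_selection()` does the same post hoc, regenerating the focal
population's genotypes in the interval as independent Bernoulli haplotype
draws at the shifted frequency. That regeneration does not preserve LD
inside the interval — irrelevant for the frequency-based scan statistics,
but a caveat for any haplotype-based use.

The quartet simulator models introgression at the frequency level
(p2' = (1-a) p2 + a p3) on a fixed four-taxon topology with branch drift
F = 0.2 and outgroup drift 0.3, matching the scale of reported
between-breed and dog-wolf differentiation.

What the simulator does **not** emulate: mutation processes, realistic
recombination maps, demographic history (bottlenecks, expansions),
ascertainment bias of chip SNP selection, genotyping error, or sex
chromosomes (autosomes only). Passing tests therefore demonstrate that the
estimators recover known truth under the stated sampling models — not that
chip data are free of ascertainment or batch artifacts.

## Degenerate inputs and numerical conventions

* F = 1 in the simulator is rejected (degenerate Beta); F = 0 collapses to
  the ancestral frequency exactly.
* SNPs with zero calls have no estimable frequency and are excluded from
  heterozygosity and richness means; populations with zero calls at a SNP
  enter the frequency table with n_i = 0 and are handled downstream.
* A pair of individuals with no jointly called SNPs has no defined IBS
  distance and raises an error rather than returning a placeholder.
* Pairs with zero F_ST variance are excluded from the scan with a warning;
  an all-equal window distribution puts every window at the threshold and
  calls them all (degenerate by construction).
* All randomized tests and the acceptance script run under fixed seeds;
  the pipeline writes the seed and all realized thresholds into its JSON
  manifest.

## Known limitations

* The scan's empirical-percentile call is relative: it always calls
  roughly 0.5% of windows, so it ranks rather than tests, and the
  discretization noted above inflates the rate on small scans.
* Mean-of-ratios averaging of per-SNP F_ST (the convention followed here)
  is slightly downward-biased relative to ratio-of-means averaging; the
  divergence-recovery checks bound this empirically within +/- 0.03 of the
  simulated F at the study scale.
* The d_i moments treat SNPs as exchangeable; strong local LD makes
  neighboring window means correlated, which the empirical percentile
  absorbs only partially.
* Haplotype-based statistics (iHS, XPEHH), admixture-proportion models and
  migration-graph fitting are out of scope, as are VCF input, imputation
  and assembly liftover.
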