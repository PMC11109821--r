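---
title: "Population-genomic viability metrics: models, parameters and design"
author: "ovipop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genomic viability metrics: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovipop)
```

## Scope

`ovipop` assembles the standard toolkit for judging the genetic viability of
small, bottlenecked populations — wild sheep are the motivating system —
from a multi-sample SNP call set plus a few side channels (per-chromosome
coverage, a per-base conservation track, an mtDNA alignment). The package
covers:

* shared-drift estimation with outgroup-f3 and f4 statistics,
* population structure summaries (1−f3 distances, classical MDS,
  neighbor-joining trees with chunked-bootstrap support),
* within-population diversity (individual heterozygosity, pairwise-1−f3
  diversity, mtDNA π, autosome/chrX ratios),
* inbreeding via runs of homozygosity (ROH) and their dating,
* sample QC (coverage-based genetic sexing, pseudo-haploid kinship and
  pruning), and
* GERP-weighted relative mutation load.

Every stage has a matching synthetic-data generator with known truth, so the
whole pipeline can be validated by parameter recovery without any external
data.

## The statistics and their assumptions

### Outgroup-f3 and f4

For per-population alternate-allele frequencies $o, a, b$ at a site,

$$f_3(O; A, B) = \mathrm{E}\,[(o - a)(o - b)],$$

estimated as the mean over usable sites. With $O$ an outgroup to both $A$
and $B$, $f_3$ measures the shared drift of $A$ and $B$ since their common
ancestor with $O$: larger values mean a closer relationship, and $1 - f_3$
behaves as a distance. $f_4(A, B; C, D) = \mathrm{E}[(a-b)(c-d)]$ is zero in
expectation when the tree $((A,B),(C,D))$ holds without gene flow across the
central edge, so its Z score tests treeness.

A site enters a statistic only when every argument population has at least
one observed allele there (complete cases per statistic, which mirrors
"include all SNPs" behavior while skipping undefined terms). Standard errors
come from a weighted delete-one-block jackknife (blocks weighted by their
site counts, so a short trailing block is handled correctly); the default
blocks are 5 Mb physical windows, a scale chosen to exceed typical linkage
disequilibrium. An optional small-sample correction subtracts the target's
sampling-noise term $\hat h_O / n_O$ per site; it is **off** by default —
the distances are used comparatively, and the correction requires a diploid
(two-allele) target — and both modes are exposed.

### Distances, MDS, NJ and bootstrap

The pairwise matrix $D[p,q] = 1 - f_3(O; p, q)$ feeds `stats::cmdscale`
(classical MDS; axis signs are fixed deterministically so repeated runs
agree) and a neighbor-joining implementation written here so that its
behavior is fully pinned down: Saitou–Nei Q-criterion, standard
branch-length formulas, ties broken by the lexicographically lowest label
pair, and negative branch lengths clamped to zero with the deficit moved to
the sister branch of the same join (path lengths between the joined
clusters are preserved; support counting is unaffected). On additive
matrices the result is exact, which the tests verify against an exhaustive
topology-enumeration/least-squares oracle for up to six taxa and against
`ape::nj`.

Bootstrap uncertainty follows the chunk scheme of the genotype data: sites
are cut into consecutive chunks of 30,000 SNPs (the final partial chunk kept),
chunks are resampled with replacement, and each replicate distance matrix is
rebuilt from the resampled concatenation. Support for an internal edge is
the percentage of replicate trees containing the same leaf bipartition.
Rooting adds the outgroup at a constant distance of 1 to every ingroup
label — the natural convention for 1−f3 distances, where the outgroup's
self-comparison fixes the scale — and roots on its pendant edge.

### Diversity

Individual heterozygosity is the fraction of heterozygous calls among
callable sites; it estimates π per site directly from called genotypes and
assumes those calls are accurate (low-coverage genotype-likelihood
machinery is out of scope here, and the generator produces exact
genotypes). Population diversity for low-coverage cohorts uses the mean of
pairwise $1 - f_3(O; i, j)$ over member individuals, each treated as its own
"population".

mtDNA π divides the average pairwise difference count by a single site
count $L$: a site is included when it is non-missing in at least two
sequences and carries at most two distinct bases, inclusion is decided once
for the whole alignment, and a pair's missing sites contribute zero
differences. The alternative per-pair-$L$ normalization (each pair divided
by its own joint coverage) is available via `perPairL = TRUE`; the single-L
reading is the default because it matches the usual cohort-level formula,
but with patchy missingness it understates per-pair divergence, which is
exactly when the switch is useful.

Under equal male and female effective sizes there are three X chromosomes
per four autosome copies, so the autosomal/chrX diversity ratio has neutral
expectation $4/3$ (reported as 1.33); smaller male effective size pushes the
ratio toward 1. `autosomeXRatio()` reports both the observed ratio and this
expectation.

### Runs of homozygosity

`callRoh()` re-implements the sliding-window scheme popularized by PLINK:
50-SNP windows tolerate at most 1 heterozygote and 5 missing calls; a SNP is
ROH-eligible when at least 5% of the windows covering it pass; eligible runs
are split at inter-SNP gaps over 1,000 kb, trimmed to their outermost
homozygous SNPs, and reported when they contain ≥ 30 SNPs, span ≥ 500 kb and
average ≤ 30 kb per SNP. The first four parameters are the cited tool's
published settings for > 500 kb segments; window-missing, the 5% hit
threshold and the gap are that tool's documented defaults, since only
non-default flags are usually reported. Segment boundaries are reported at
the outermost homozygous SNP positions, not extrapolated midpoints, so the
planted-tract recovery tests bound the boundary error by the local SNP
spacing.

$F_\mathrm{ROH}$ divides the summed segment length by the autosomal genome
size; the denominator is the caller's choice, and autosomes-only is the
default recommendation here (chrX hemizygosity in males would contaminate
the numerator, and unplaced scaffolds inflate the denominator), passed
explicitly as `autosomalGenomeBp`. Segment lengths are binned into the four
half-open classes [0.5, 1), [1, 2), [2, 3), [3, 5) Mb plus an overflow
class. The expected age of the inbreeding event behind segments of length
$L$ Mb is

$$g = \frac{100}{2 r L}$$

generations, with $r$ the recombination rate in cM/Mb (default 1.5) and a
3-year generation interval for conversion to years; `inbreedingTime()`
returns the unrounded value, its nearest integer, and years as $g \times$
generation time. For mean segment lengths 0.63 and 0.82 Mb this clock gives
53 and 41 generations (≈ 159 and 122 years).

### Genetic sexing (Rx)

For each autosome $i$, $r_i = \mathrm{depth}(X)/\mathrm{depth}(i)$;
$R_x$ is the mean of the $r_i$ and its standard error is
$\mathrm{sd}(r_i)/\sqrt{n}$, so the uncertainty reflects variance among
autosomes rather than read-level noise. Per-autosome ratios (not one pooled
ratio) are used precisely so that this variance is defined. In an ideal
assembly $R_x$ would be 1 (XX) or 0.5 (XY); real ungulate assemblies
attenuate apparent chrX coverage, with observed cluster means nearer 0.74
and 0.42, hence the assignment thresholds: XX when $R_x - 1.96\,SE > 0.65$,
XY when $R_x + 1.96\,SE < 0.5$, otherwise unassigned. `kmeansThresholds()`
(Lloyd's algorithm with deterministic farthest-point seeding) is advisory —
it reports the empirical cluster means and midpoint cutoffs for operator
review, but assignment always uses the configured thresholds. The coverage
generator simulates exactly this attenuated data model (expected
$R_x$ 0.74/0.42 at Poisson depth), because the thresholds are meaningless
against an idealized 1.0/0.5 simulation: with a male X at exactly half
coverage the XY rule could never clear its strict inequality.

### Kinship from pseudo-haploid mismatch

Each genome is reduced to one uniformly drawn allele per site
(`pseudoHaploidize`), and for a pair of samples $P_0$ is the fraction of
jointly observed sites that disagree, averaged over 1 Mb windows (the
cited kinship method's convention; the window mean also damps local
artifacts). Within a population, $P_0$ is normalized by the population
median — the typical unrelated pair — and $\theta = 1 - P_0^{norm}$
estimates the kinship coefficient: 0.5 for identical genomes, 0.25 / 0.125
/ 0.0625 for first/second/third degree, 0 for unrelated. Pairs are
classified by the midpoints $(\theta_1+\theta_2)/2$ of adjacent rungs
(0.375, 0.1875, 0.09375, 0.03125). Third degree extends the cited tool's
second-degree ceiling with the natural $\theta = 0.0625$ rung; at 50k SNPs
the sampling noise of $\theta$ (≈ 0.01) sits well inside the 0.03 half-width
of the third-degree bin, which is why the recovery tests can demand ≥ 95%
accuracy. `pruneRelatives()` greedily drops the sample with the most
close-kin links (ties: lower coverage, then id) until none remain.

### Relative mutation load

Conserved regions are maximal runs of consecutive track positions with
score strictly above 4 (rejected-substitution units); each region's score
$g_i$ is its per-base mean (max and sum would also be defensible; the mean
makes the load a weighted mean, see below). With the outgroup's homozygous
allele defining the ancestral state (heterozygous or missing outgroup sites
are dropped and counted), a sample's derived-allele count in region $i$ is
$n_i$ (1 per heterozygous, 2 per homozygous-derived site) and

$$\mathrm{RML} = \frac{\sum_i n_i\, g_i}{N}, \qquad N = \sum_i n_i .$$

With $N$ the conserved-region total, RML is a weighted mean of the $g_i$
and is bounded by their range — that is the default and the reading under
which the statistic is interpretable as "how conserved are the positions
where this genome carries derived alleles". Counting every derived allele
genome-wide in $N$ instead (exposed as `genomeWideN = TRUE`) makes RML an
absolute burden measure that also scales with how many derived alleles fall
in conserved sequence at all.

## The synthetic generator: what it emulates, what it does not

`simConfig()` defines the reference design: ten ingroup populations plus a
strongly diverged outgroup on a fixed tree mirroring the wild/domestic
sheep clades, three diploid samples per population, 50,000 SNPs over five
30-Mb autosomes, ancestral allele frequencies uniform on (0.05, 0.95).
Branch drift uses the Balding–Nichols model: given parent frequency $p$ and
drift $F$, the child frequency is
$\mathrm{Beta}\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$, which has
mean $p$ and variance $F p (1-p)$ — exactly the frequency covariance
structure that f-statistics measure, at a fraction of the cost of a
forward simulation. Genotypes are binomial(2, p) draws; planted relatives
are built by explicit per-site gamete transmission (degree 0 duplicates a
genome; degrees 1–3 chain meioses), so expected kinship coefficients are
exact. Planted ROH duplicate one sampled allele per site inside the target
interval; coverage profiles are Poisson with the attenuated chrX model
above; the conservation track draws one score level per region with small
per-base jitter; mtDNA evolves by infinite-sites mutation along a star (or
user-supplied) tree, for which $\mathrm{E}[\pi] = 2m/L$.

Deliberately **not** emulated: linkage disequilibrium and recombination
(sites are exchangeable given the tree — fine for f-statistics and kinship
means, but it makes jackknife/bootstrap uncertainty on synthetic data
conservative rather than realistic), sequencing error and genotype
uncertainty (calls are exact, so heterozygosity recovery is cleaner than on
low-coverage data), ascertainment bias, and selection. Passing recovery
tests therefore demonstrates correctness of the estimators on their own
statistical model, not robustness to the messiness of real sequencing data.

## Numerical and design choices

* **Site filters.** Biallelic SNPs passing QUAL ≥ 20, QD ≥ 2, SOR ≤ 3,
  FS ≤ 60, MQ ≥ 40, MQRankSum > −12.5, ReadPosRankSum > −8; per-site mean
  depth (INFO/DP over the sample count) within [4, 16] inclusive; MAF ≥
  0.05 over all samples; two-sided exact Hardy–Weinberg p ≥ 0.001 on
  genotype counts pooled across non-outgroup samples (plain exact test, no
  mid-p). Multiallelic records are dropped, never split. A missing
  annotation skips its test unless listed in `required`. Filtering is
  idempotent.
* **Depth semantics.** Whether the published 4–16× window applies per
  sample or per site is genuinely ambiguous in the field's method sections;
  the per-site mean was chosen and is documented here so results are
  reproducible either way via `filterConfig()`.
* **HWE test.** Written in-house (enumeration over heterozygote counts
  conditional on allele counts) and verified against an independent
  enumeration oracle; worth noting that 10 all-heterozygous diploids give
  p ≈ 0.007, i.e. such a site survives a 0.001 threshold until the cohort
  is about twice that size.
* **Determinism.** Every stochastic operation takes a seed; the pipeline
  funnels one root seed to all stages and re-running an identical
  configuration reproduces every output byte-for-byte. Output tables carry
  a hash of the configuration.
* **Degenerate inputs.** All-removed filters warn and return an empty
  matrix rather than erroring; chromosomes shorter than one ROH window are
  skipped with a warning; zero-depth autosomes are dropped from Rx; a
  population of clones (median $P_0 = 0$) and a sample with no derived
  alleles in conserved regions are explicit errors.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulation sizes are the package's
reference working points: 50,000 SNPs for f4 null calibration (100–200
tree-concordant replicates) and kinship recovery (30–100 seeds), 20-Mb
chromosomes at ~1 SNP/kb with planted 0.6/1.5/2.5/4-Mb tracts for ROH
recovery, 26 autosomes at 2× Poisson depth for sexing (100 seeds), 60
conserved regions × 200 derived alleles for load comparisons, and
5 × 10-kb star alignments for mtDNA π. These sizes keep every recovery rate
comfortably away from its threshold under the generator's default noise
levels.

## Known limitations

* Heterozygosity from called genotypes replaces genotype-likelihood
  estimation; on genuinely low-coverage data the two differ, and coverage
  matching/downsampling is out of scope.
* The f3/f4 machinery assumes the block scheme exceeds the correlation
  length of the data; on real genomes with long-range LD the 5-Mb default
  may need widening.
* NJ support values inherit the bootstrap's chunk-exchangeability
  assumption; they are not a substitute for model-based phylogenetics.
* GERP scores are consumed, not computed, and must already be on the
  working assembly's coordinates.
* The mtDNA module computes π only; haplogroup assignment and network
  construction are out of scope.
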