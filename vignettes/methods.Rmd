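---
title: "Methods: diversity, structure, core collections and fingerprints from SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, structure, core collections and fingerprints from SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

heveacore characterises a germplasm collection from a diploid,
biallelic SNP panel. This vignette documents the statistical models and
algorithms, the parameters that matter, the numerical conventions, and
the choices made where more than one defensible design existed. It is
written for a reader who wants to audit or extend the package, not just
run it.

## Genotype coding and filtering

All computation happens on a samples × loci matrix of alternate-allele
dosages: `0` = 0/0, `1` = 0/1, `2` = 1/1, `9` = missing. Half-calls
(e.g. `0/.`) are conservatively coded missing, and multi-allelic VCF
records are rejected rather than silently recoded — split them upstream
if they matter.

Two filter families exist and deliberately use different inequalities:

* **Calling filters** (`filter_samples()`, `filter_variants()`) keep a
  record when it is *at or inside* the threshold: depth ≥ 20 (below
  that the single genotype call is masked to `9`, not the whole locus
  dropped), per-locus missingness ≤ 10%, minor-allele frequency ≥ 5%.
  Depth masking precedes the locus-level rules, so a low-depth locus
  can fail on missingness after masking. Whether a depth rule should
  mask genotypes or drop loci is genuinely ambiguous in common pipeline
  descriptions; masking is the less destructive reading and is the one
  implemented.
* **Panel-design filters** (`select_panel_loci()`) are a screen for
  building a marker panel and use strict inequalities: MAF > 0.3,
  missing fraction < 0.5, then a minimum physical spacing of 2 Mb
  enforced greedily left-to-right within each chromosome (a locus is
  kept only if ≥ 2 Mb beyond the last kept locus). Greedy scanning is
  the simplest deterministic reading of "evenly spaced"; it is not an
  optimal spacing algorithm and is not meant to be.

The default sample filter (missingness > 0.999) removes only samples
with no usable calls at all — the classic fully-failed library — while
leaving everything else to the locus-level rules.

Allele frequencies are always estimated over non-missing alleles;
missing genotypes are never imputed.

## Diversity statistics

For alternate-allele frequency $p$ (and $q = 1-p$):

$$He = 2pq, \qquad PIC = 1 - (p^2 + q^2) - 2p^2q^2,
\qquad \pi = \frac{n_{ref}\,n_{alt}}{\binom{n}{2}} = \frac{n}{n-1}\,He$$

with $n = n_{ref} + n_{alt}$ called alleles. He carries no small-sample
correction while π is the average pairwise difference among called
alleles — this is the only combination under which the biallelic maxima
are He = 0.5000 exactly and π = 0.5013 at 195 fully-called heterozygous
diploids, which is how the two conventions can be told apart in
published tables. Statistics are computed at full precision and rounded
only for reporting (4 decimals by convention).

Group summaries (`population_summary()`) re-estimate frequencies within
each group, average statistics unweighted across loci, and append a
`Mean` row that is the unweighted mean of the group values (not the
pooled collection value). Retention of a core subset is
`100 · core / original` per statistic and group; values above 100% are
expected when redundant accessions are removed, because pruning clones
pushes frequencies toward intermediate values.

## The admixture model and Evanno ΔK

Individual $i$ has ancestry proportions $q_i$ over $K$ source
populations with per-locus allele frequencies $p_l$; the two allele
draws at a locus are independent Bernoulli($\sum_k q_{ik} p_{lk}$), and
missing genotypes contribute nothing. `fit_admixture()` maximises this
likelihood by EM from a seeded random start (Dirichlet(1) rows for Q,
uniform P). The log-likelihood is non-decreasing every iteration — the
test suite asserts this on every fitted trace — and mixture frequencies
are clamped to $[10^{-9}, 1-10^{-9}]$ for numerical safety.

Classical germplasm studies run STRUCTURE's MCMC here (typically 10⁵
burn-in plus 10⁵ sweeps, five runs per K). The package instead uses the
maximum-likelihood EM fit, for three reasons: it is deterministic given
a seed, it is orders of magnitude faster at desk scale, and the Evanno
statistic only needs a per-run model-fit score, for which the maximised
log-likelihood serves as a proxy for STRUCTURE's estimated
ln P(X|K). This is a proxy, not the same quantity; whether the two
plateau at the same K on any particular real data set cannot be checked
without that data set. On synthetic two-subpopulation panels of the
package's default shape the selection behaviour is exercised directly
in the tests.

`evanno_delta_k()` computes, over replicate scores per K:
$L'(K) = \bar L(K) - \bar L(K-1)$,
$|L''(K)| = |L'(K+1) - L'(K)|$, and
$\Delta K = |L''(K)| / \mathrm{sd}(L(K))$, defined only at interior K.
A zero replicate standard deviation makes ΔK undefined (`NA` with a
warning) rather than infinite; perfectly linear mean scores leave
`best_k` flagged `NA`.

Defaults: `fit_admixture()` runs to |ΔL| < 10⁻⁶ within 2000
iterations. `admixture_scan()` — the replicate-grid driver — uses
looser per-fit settings (500 iterations, tol 10⁻⁴): ΔK depends on
between-K differences in log-likelihood that are orders of magnitude
larger than the EM tail, and the looser setting selects the same K
while keeping a full K = 1..5 × 5-replicate scan under ~20 s for a
195 × 99 panel. Replicate seeds are derived deterministically from the
master seed by a stage-name hash, so any single replicate can be
reproduced in isolation.

## Distances, trees and group assignment

The pairwise distance is 1 − IBS: one minus the proportion of alleles
identical by state over loci called in both samples. It is
parameter-free and standard for SNP panels; the package makes no claim
that it matches any particular legacy software's internal distance,
which published methods sections often leave unstated. Pairs sharing no
called locus are an error rather than a guess.

`neighbor_joining()` is the classical Saitou–Nei algorithm: join the
pair minimising $Q(i,j) = (n-2)d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$,
with the standard branch-length formulas, ties broken by the smallest
(row, column) index pair. NJ is exact on additive matrices, which the
tests exploit: on random additive 8-taxon matrices the recovered tree's
path distances must match the input to 10⁻⁹ and the topology must match
the generating tree. Negative branch lengths (possible on non-additive
data) are clamped to zero at export with the raw values retained in an
attribute.

`assign_groups()` cuts the tree into k groups by removing k − 1
internal branches. The obvious rule — cut the longest internal
branches — turned out to be fragile in development: on simulated
two-subpopulation panels at F_ST ≈ 0.15 the longest internal NJ edge
frequently isolates a 2-sample outlier clade even though an edge
inducing the true two-population split is present in the tree. The
package therefore scores each internal edge by *length × number of leaf
pairs separated* ($\ell \cdot n_{below}(n - n_{below})$) and cuts the
top k − 1. This preserves the "two major groups" semantics, is
deterministic (ties by edge index), degrades gracefully (pendant edges
are used only when internal ones run out, so k = n yields singletons),
and recovers the simulated split reliably in the recovery tests. A tree
whose branch lengths are all ≈ 0 (clonal collection) is flagged
degenerate and yields a single group.

PCA uses the variance-standardised convention: dosage $g$ at a locus
with frequency $p$ becomes $(g - 2p)/\sqrt{2p(1-p)}$; missing entries
are zeroed after centring (i.e. set to the locus mean); monomorphic
loci are dropped. Explained variance is $100\,\lambda_c/\sum\lambda$.

## Core collections

Counts are allocated per cluster as
`max(1, round_half_up(ratio × size))` — the 1-per-group floor keeps
small clusters represented at low ratios. Published core-bank tables
sometimes print counts that no single rounding rule reproduces; the
rule here is documented as the package's choice, auditable and
deliberately simple, rather than an attempt to reverse-engineer any
particular study's arithmetic.

Within each cluster, `stepwise_core_sample()` implements stepwise
clustering: find the closest remaining pair, drop the member with the
smaller mean distance to the other remaining samples (the more
redundant one), repeat. Ties — equal pair distances or equal means —
resolve by sample order, so the procedure is fully deterministic and
needs no seed. On clone-containing fixtures duplicates are provably
eliminated before unique genotypes (a clone's closest pair is its twin,
and the twin is the most redundant sample by construction). The greedy
procedure is not globally optimal; the tests pin it to the exhaustive
max–min-distance subset on a 6-sample fixture, not in general.

`recommend_ratio()` returns the smallest ratio at which every group
retains at least `min_retention` (default 0.95) of He, PIC *and* π
against its own 100% baseline, falling back with a warning to the
best-retaining ratio when none qualifies. The 0.95 default is
conservative: cluster-stratified stepwise cores typically retain
> 100%.

## Fingerprints

`select_fingerprint_loci()` operationalises "highly differentiated
fingerprint SNPs" as a greedy set-cover: start from the highest-PIC
locus, repeatedly add the locus that most reduces the number of sample
pairs whose partial codes are still identical (ties: higher PIC, then
locus order), stop when all pairs are resolved or `n_max` (default 20,
the customary fingerprint length) loci are chosen. Residual unresolved
pairs — genuine clones — are reported, never hidden.

Codes concatenate dosage digits in locus order over the alphabet
{0, 1, 2, 9}. Collision auditing defaults to *strict* missing handling
(a `9` matches only another `9`); the *lenient* policy, where `9` is a
wildcard, is available because an unreadable digit arguably fails to
prove two accessions distinct. Strict is the default because it matches
the operational reading — two printed codes either are or are not the
same string.

QR payloads are plain `"<id>|<code>"` strings; the pipe is reserved, so
ids containing it are rejected. No checksum is added (codes are short
and the id is redundant with the registry). Rendering the payload to an
image is delegated to any standard QR encoder; the payload string is
the artifact the package tests.

## The synthetic-data generator

`simulate_panel()` emulates the statistical structure the analysis
assumes: two (or more) subpopulations of configurable size diverged
under the Balding–Nichols model — per locus an ancestral frequency
$p \sim U(\text{maf\_floor}, 1-\text{maf\_floor})$ and per
subpopulation $p_k \sim \mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ —
optional symmetric-Dirichlet admixture, genotypes
$\mathrm{Binomial}(2, \sum_k q_{ik}p_{lk})$, MCAR missingness, and
optionally a fixed number of fully-missing samples (the failed-library
case). Positions are uniform-random, strictly increasing on one
synthetic chromosome, long enough to exercise the 2 Mb spacing filter.

Defaults mirror the motivating collection's shape: subpopulations of
169 and 26, 99 loci, 3% missingness. Two defaults are judgment calls
the user should know about. `fst = 0.05` encodes the reading that the
collection's two groups are weakly diverged ("diversity not high", low
differentiation); no published estimate exists for the real material,
so F_ST must be treated as a free parameter, and the recovery tests
deliberately run at 0.1–0.2 where the structure signal is realistic for
clearly separated germplasm groups. `maf_floor = 0.1` reflects that
real panels are pre-screened for informative markers; it keeps most
simulated loci above the 5% frequency filter.

What the generator does **not** emulate — and therefore what passing
tests do *not* demonstrate about real data: linkage disequilibrium
(loci are independent), selection, genotyping error correlated with
genotype, non-random missingness, multi-allelic sites, and indel
variants (real panels sometimes include small indels scored as
biallelic markers; the simulator treats every locus as a generic
biallelic variant). Recovery results on this generator are
best-case-structure results.

Ground truth (subpopulation labels, ancestry matrix, ancestral and
per-population frequencies) round-trips through TSV at ≥ 12 decimals,
so recovery tests can be run against files as well as in-memory
objects.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed, and compound drivers
(`admixture_scan()`, `run_all()`) derive per-stage seeds from a master
seed by hashing the stage name, so stages are reproducible
independently of execution order. `run_all()` writes every intermediate
in a standard text format (VCF v4.2, TSV, Newick, JSON) plus a manifest
with MD5 checksums; re-running an identical configuration reproduces
all artifacts byte-for-byte, which the test suite asserts.

The test suite sizes its simulations for a single desk CPU: recovery
properties use 99-locus panels with 90–200 samples and 20 seeds where a
distributional claim is made (median ARI, median Q-RMSE, ΔK hit rate),
and brute-force oracles run at 6–10 samples or 8 taxa where exhaustive
enumeration is cheap. These sizes are the package's choice of a
convincing-but-quick validation scale, and all thresholds asserted in
tests (ARI ≥ 0.9, Q-RMSE ≤ 0.15, ΔK hit rate ≥ 18/20) were fixed
before the corresponding conditions were run.

## Known limitations

* The EM log-likelihood is a proxy for STRUCTURE's marginal-likelihood
  estimate; ΔK selections can differ on real data.
* 1 − IBS is a pseudo-metric; the triangle inequality is checked
  empirically on fixtures, not guaranteed.
* Greedy spacing, greedy fingerprint selection and stepwise elimination
  are all locally optimal heuristics, pinned to exhaustive search only
  on small fixtures.
* The biallelic PIC/He formulas are used throughout; multi-allelic
  markers are out of scope.
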