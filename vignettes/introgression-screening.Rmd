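---
title: "Detecting recent pig introgression in wild boar: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recent pig introgression in wild boar: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boarmix)
```

## The problem

European wild boar and domestic pigs are two forms of *Sus scrofa* with
recent shared ancestry and ongoing gene flow. A wild-living animal may
carry domestic ancestry from an old backcross chain (expected domestic
fraction 0.5 in an F1, 0.25 in a BC1, 0.125 in a BC2, ...) or be an
escaped, near-pure pig living feral. Screening for such introgression
from SNP-array genotypes is statistically delicate: the forms are only
moderately differentiated, local breeds differ strongly from commercial
lines, and any single analysis (one marker panel, one geographic scope,
one clustering) produces idiosyncratic calls. `boarmix` implements a
consensus protocol: many analyses, each individually conventional, whose
weighted agreement defines a hybrid.

## Data model and quality control

Genotypes are stored as B-allele dosages (0/1/2, `NA` missing) with
locus and sample registries; PLINK text PED/MAP is the interchange
format, and dataset merging harmonizes allele coding (swaps and strand
flips resolved when unambiguous; palindromic A/T and C/G loci with
inconsistent coding are dropped, since a swap cannot be told from a
strand flip there).

QC follows the usual chip workflow, in a fixed order:

* **Call rate.** Samples with call rate ≤ 0.9 are removed first, then
  loci with ≥ 10 % missingness among the retained samples. The order
  matters (a bad sample can push loci over the missingness cutoff) and
  is therefore fixed and tested.
* **Relatedness.** PI_HAT is the method-of-moments IBD estimate from
  IBS counts and sample allele frequencies. Pairs with PI_HAT ≥ 0.45
  — the expected 0.5 of first-order relatives minus a noise margin — are
  resolved greedily: highest PI_HAT first, dropping the member with the
  lower call rate (ties: lexicographically larger id), but never
  emptying a population when the alternative removal would not.
  Finite-sample correction factors are omitted; the estimator is
  validated on simulated duplicates (PI_HAT = 1), parent–offspring pairs
  (≈ 0.5) and unrelated pairs (≈ 0).
* **Equalization.** Unequal sample sizes bias diversity, F_ST and
  cluster inference, so populations are randomly downsampled to at most
  25 with a seeded RNG.

Monomorphic loci pass QC: they carry no ancestry signal but belong in
the polymorphic-locus accounting of the diversity report.

## Diversity and differentiation

Per cluster we report the polymorphic-locus count, mean expected
heterozygosity `2p(1−p)`, mean observed heterozygote fraction and the
minor-allele-frequency mean and SD. Means run over the whole panel, so
monomorphic loci contribute zero (a polymorphic-only MAF is available by
flag); the small-sample `2n/(2n−1)` He correction is off by default.

Pairwise differentiation uses the Weir–Cockerham (1984) θ estimator
with the standard two-population variance components (unequal sample
sizes, observed heterozygosity) combined across loci as a ratio of sums,
restricted to loci polymorphic within the pair. Small negative multilocus
values are reported as computed. θ was chosen over AMOVA-style
estimators deliberately: it is closed-form, testable by hand at a single
locus, and calibrated against the generator (below). Before
differentiation analyses, loci in strong linkage disequilibrium are
pruned by sliding-window genotype correlation (window 50 SNPs, step 5,
removing the smaller-MAF member of any pair with r² > 0.5; ties remove
the later map position). One PLINK-style sweep is not exactly
idempotent, so sweeps repeat until no locus is removed — the output is
then a fixed point, which makes the operation order-deterministic and
repeat-stable.

Within-group F_ST distributions (e.g. among-wild vs among-domestic) are
compared by a two-sided Mann–Whitney test; the p-value is exact for
small untied samples and otherwise uses the normal approximation, and
the reported statistic is the tie-corrected normal-approximation z (a
rank test has no t statistic; published tables sometimes label this z
differently).

## PCA and the informative marker panel

PCA runs on the mean-imputed, column-centered dosage matrix via SVD;
missingness is low after QC, so mean imputation is a mild, standard
choice. No variance scaling is applied by default, keeping loadings
interpretable as allele-frequency contrasts; each component is oriented
so its largest-magnitude loading is positive, which makes results
invariant to sample order. The first component of a combined wild +
domestic PCA is the form axis, and the 983 loci with the largest
absolute PC1 loadings form the reduced "1 K" panel (ties broken by locus
id). Whether informativeness should be read off one or several
components is genuinely open; the axis is therefore a parameter, with
PC1 the default. On simulated data the panel must both enrich
between-form frequency differences and reproduce the full-panel
wild/domestic assignment for ≥ 99 % of samples — the property the
reduced-panel design relies on.

PCA also supplies an explicit candidate-hybrid rule (the visual
"position between the clouds" reading made reproducible): each wild
sample's PC1 score is projected onto the segment from the wild reference
centroid (t = 0) to the domestic centroid (t = 1), and t ≥ 0.10 flags a
candidate — the same 10 % threshold the ancestry caller uses, for
internal consistency. The projection is affine-invariant in the scores.

## Ancestry decomposition

The likelihood is the STRUCTURE/ADMIXTURE binomial mixture:
`g_il ~ Binomial(2, Σ_k q_ik f_kl)` over called cells, with π clamped to
`[1e-9, 1 − 1e-9]` and binomial constants dropped. Optimization is plain
alternating EM — multiplicative updates on Q and F, guaranteed monotone
in the log-likelihood, which the fit asserts per iteration — rather than
quasi-Newton block relaxation; monotonicity and bit-reproducibility
(dataset, K, seed, cap, tolerance) were judged worth more than the
acceleration, and F is clamped to `[1e-6, 1 − 1e-6]` for numerical
safety. Initialization is a seeded flat-Dirichlet Q and uniform F; an
explicit initialization can be supplied (used by the equivariance
tests). Cluster labels are canonicalized by descending total Q mass, and
a best-permutation matcher (exhaustive over K!) aligns fitted labels with
any reference for evaluation.

K is selected by masked-cell cross-validation: called cells are
partitioned into folds (10 by default), each fold is masked and
predicted as `2π̂`, and the mean squared dosage error, averaged over
folds, scores K; the minimum wins, ties to the smaller K. Masking cells
rather than whole samples keeps every sample in every fit, which is the
convention for ancestry models. The K grid is capped at
min(30, samples − 1).

## The consensus classifier

Each analysis contributes per-sample calls: a sample is called in one
analysis when its summed domestic-cluster ancestry is **strictly above
10 %** ("more than 10 %"), clusters having been typed wild or domestic
by comparing mean ancestry over wild- vs domestic-labeled reference
samples. Analyses focusing on the sample's own geographic area carry
weight 1.0, other-area and whole-sample analyses 0.8, and a sample is a
consensus hybrid when the weighted fraction of calling analyses among
those covering it reaches **at least 30 %**. The "weighted fraction of
covering analyses" reading is one consistent formalization of a rule
often stated loosely (should uncovered analyses count in the
denominator? is the weight on the numerator only?); it is the one
implemented, and the worked arithmetic (1.0/3.4 = 0.294 → no;
1.8/3.4 = 0.529 → yes) is frozen in tests. Samples whose per-analysis
domestic fraction ever reaches 0.75 are additionally flagged near-pure
domestic — feral pigs sampled as wild, which always also exceed the
hybrid threshold.

Tallies report per-country hybrid counts and one-decimal percentages
over wild-labeled samples plus a grand total. The east/west comparison
aggregates countries by a representative longitude against a reference
meridian (default 14°E), recomputing percentages from pooled counts
rather than averaging country percentages. One representative longitude
per country is a simplification — samples carry no coordinates — and
countries straddling the meridian (Slovenia) follow their configured
default, which places them east.

## The synthetic generator

The generator produces the study design the screen assumes, with full
truth:

* **Frequencies.** Balding–Nichols: ancestral p ~ Uniform(0.05, 0.95);
  a population at divergence c draws Beta(p(1−c)/c, (1−p)(1−c)/c).
  Pairwise Weir–Cockerham θ between two populations approximates the
  mean of their c values, giving direct F_ST control without a
  coalescent simulator. Divergence is hierarchical: each form (wild,
  domestic) drifts from the shared ancestor at 0.05–0.06, clusters
  drift within their form at 0.03–0.22, reproducing the observed
  structure of continental chip surveys — wild–wild differentiation
  from a few percent to ~0.3 with a strongly drifted Near-East-like
  cluster, wild–domestic differentiation ~0.1–0.25, and observed
  heterozygosities in the 0.15–0.35 band.
* **Genotypes.** `g ~ Binomial(2, q·f)` with uniform missingness (5 %
  by default, matching a post-QC chip dataset). Hybrids take mixture
  ancestry rows (1−q_dom, q_dom) over one wild and one domestic source:
  F1 0.5, BC1 0.25, BC2 0.125, a 0.05 low-admixture class below the
  calling threshold, and feral pigs at 0.9. Drawing hybrid genotypes
  from mixture frequencies rather than simulating recombining
  chromosomes is deliberate: the analyses are unlinked-SNP methods, so
  linkage realism buys nothing (LD-pruning tests use constructed
  correlated loci instead).
* **Relatives.** Parent–offspring pairs are synthesized by drawing one
  allele per locus from each of two same-cluster parents, exercising the
  relatedness QC path (PI_HAT ≈ 0.5).

Two presets exist. `default_scenario_config()` mirrors a continent-wide
sampling design: 8 wild + 8 domestic clusters capped at 25 samples,
hybrids spanning q_dom 0.05–0.5, two ferals, 5 % missingness, two
related pairs. `pipeline_scenario_config()` is the end-to-end evaluation
design: 3 wild + 2 domestic clusters of 25, the same hybrid ladder,
5,000 loci — sized so the full five-analysis screen runs in a few
minutes on one CPU. Everything is bit-reproducible from (config, seed).

What passing tests on this generator shows — and what it does not: the
generator matches the analyses' own assumptions (unlinked loci, binomial
genotypes, discrete source clusters), so end-to-end sensitivity ≥ 0.95
for q_dom ≥ 0.25 and a false-positive rate ≤ 0.05 on pure wild
demonstrate internal correctness of the chain, not field performance on
ascertained chips, bottlenecked demographies or continuous clines, none
of which are modeled.

## Numerical choices and degenerate inputs

* π clamped at 1e-9, F at 1e-6; EM trace asserted non-decreasing to
  within −1e-8 (floating point).
* EM stops when the log-likelihood gain drops below `tol` (1e-6 for
  final fits; 1e-4 to 1e-5 for cross-validation folds, where ranking —
  not convergence — is the goal) or at `max_iter`; a capped,
  non-converged fit is returned flagged, never an error.
* Ties are deterministic everywhere: marker ranking by locus id,
  relatedness removal by sample id, LD pruning by map position, K
  selection by smaller K.
* Degenerate inputs error early with names: constant matrices in PCA,
  empty datasets after QC, uncovered samples in the consensus, missing
  longitudes in the regional split, K above the sample count.

## Problem sizes used in validation

The validation suite runs desk-scale versions of each claim: oracle
comparisons on matrices up to 6×10 (exact to 1e-9); F_ST calibration at
5,000 loci and n = 50 + 50 (θ within 0.03 of the generating c, |θ| <
0.01 under the null); ancestry recovery across 20 seeded K = 2–3
scenarios of 1,000–5,000 loci and 20–50 samples (best-of-3-seeds RMSE <
0.05); cross-validated K correct in ≥ 80 % of 10 two-cluster replicates;
and the end-to-end screen on the 5-cluster, 5,000-locus design. These
sizes are the package's own validation design and are deliberately far
below chip scale; the algorithms themselves are vectorized (the EM step
is four dense matrix products) and handle tens of thousands of loci
comfortably.

## Known limitations

* Supervised ancestry, linked-site models and phased haplotypes are out
  of scope, as are hybrid generation-class assignment and breed
  attribution.
* The binomial model ignores inbreeding within clusters; strongly
  inbred reference panels will inflate apparent admixture noise.
* PI_HAT omits finite-sample corrections; with very few samples,
  frequency estimation error biases the estimates (the QC default of
  ≥ 50 usable loci and population-scale panels keeps this minor).
* One longitude per country is a coarse regional assignment.
* The generator's realism caveats above apply to every
  simulation-based guarantee.
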