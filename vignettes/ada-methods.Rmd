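---
title: "Adaptive combination of P-values for rare-variant association: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive combination of P-values for rare-variant association: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-variant association tests are essentially powerless for variants with
minor allele frequency (MAF) below 1%: the expected allele counts in any
realistic case-control sample are in the single digits.  Region-based tests
therefore pool evidence across the variants of a gene or functional unit.
Burden tests collapse dosages into one genetic score per subject before
testing, which works well when most pooled variants are causal and act in
the same direction, but loses power quickly as neutral variants dilute the
score or as deleterious and protective effects cancel.

The ADA test implemented here takes the opposite route: it tests each site
first, then combines the per-site P-values -- weighted, direction-stratified,
and *truncated* so that sites whose P-values look like noise contribute
nothing.  Because no single truncation threshold suits every genetic
architecture, the threshold is chosen adaptively from a candidate grid, and
the selection is paid for honestly inside a permutation scheme.

## Per-site evidence

For site $i$, allele counts are cross-tabulated on chromosomes: $a_i$ minor
alleles among $2n_A$ case chromosomes versus $c_i$ among $2n_U$ control
chromosomes.  Conditioning on both margins gives the hypergeometric null,
and we use the two-sided **mid-P** Fisher exact value: the probability of
all tables strictly less probable than the observed one plus half the
probability of tables exactly as probable.  Mid-P removes about half of the
conservatism of the classical exact test for discrete data, and its null
expectation is exactly 1/2, which matters when many small-count tables are
combined.  Equality of table probabilities is decided with a relative
tolerance of $10^{-12}$: equiprobable tables arise systematically from the
symmetry of the hypergeometric likelihood, and exact floating-point
comparison would misclassify them.  A site where only one table is
attainable (monomorphic in the analysed sample) gets $p_i = 1$ and direction
"tied", so it contributes nothing downstream; keeping such sites instead of
deleting them simplifies bookkeeping without changing any statistic.

Each site also carries:

* a **direction**: deleterious-inclined if its minor-allele frequency is
  higher in cases, protective-inclined if higher in controls, tied if equal;
* a **Madsen-Browning weight**
  $w_i = 1/\sqrt{n_U\,\hat q_i(1-\hat q_i)}$ with
  $\hat q_i = (m_i+1)/(2n_U+2)$, the add-one smoothed control frequency
  ($m_i$ = minor alleles among the $n_U$ controls).  Variants rare in
  controls get large weights; the smoothing keeps the weight finite even
  when controls carry no or only reference alleles.

The 2x2 tables are built on allele counts, not carrier counts, because the
weight is defined on allele counts and the two layers should use one
convention.

## The ADA statistic

Given candidate truncation thresholds $\theta_1 < \dots < \theta_J$ (default
$J = 11$: $0.10, 0.11, \dots, 0.20$), the deleterious and protective
significance scores at threshold $j$ are

$$S^D_j = \sum_i \mathbf 1(\text{del}_i)\,\mathbf 1(p_i < \theta_j)\,
          w_i(-\ln p_i), \qquad
  S^P_j = \sum_i \mathbf 1(\text{prot}_i)\,\mathbf 1(p_i < \theta_j)\,
          w_i(-\ln p_i),$$

and the per-threshold statistic is $S_j = \max(S^D_j, S^P_j)$.  Fisher's
combination would use $-2\ln p$; the factor 2 rescales every observed and
permuted statistic identically and cancels in permutation ranks, so it is
omitted.  The max over directions lets the test react to whichever effect
direction dominates the region; the alternative sum $S^D_j + S^P_j$ is
available (`statistic_mode = "sum"`) but only helps when deleterious and
protective variants are comparably numerous, which empirical mutation
spectra make unlikely -- hence max is the default.  The truncation uses a
strict inequality $p_i < \theta_j$, and tied sites are excluded outright.

Thresholds below 0.10 are not in the default grid because single
rare-variant tests are underpowered and a stringent cutoff would discard
causal signal; thresholds above 0.20 mostly admit neutral noise.  The
widened grid $0.05, \dots, 0.25$ is kept as a robustness check and changes
power only marginally (the package's paired grid comparison asserts the
difference stays under five percentage points).

## Two-layer permutation

Variant sites in a region are linked, so the null distribution of $S_j$ is
obtained by permuting phenotype labels with the case/control counts fixed.
Weights, directions and mid-P values are recomputed inside every
permutation, because all three depend on which subjects are labelled
controls; freezing them at their observed values (available as
`recompute_weights = FALSE` for comparison) would test a subtly different
null.  With $B$ permutations:

* observed per-threshold P-value:
  $p_j = \bigl(1 + \#\{b: S_j^{(b)} \ge S_j\}\bigr)/(B+1)$ -- the add-one
  estimator keeps P-values positive and valid, and ties count against the
  observed statistic (conservative);
* each permuted sample's $p_j^{(b)}$ is its rank among the $B$ permuted
  statistics only (leave-observed-out; both conventions are valid, this one
  keeps the permutation layer self-contained);
* minP layer: $\text{minP} = \min_j p_j$ for the observed sample and each
  permutation, and the **adjusted P-value** is
  $\bigl(1 + \#\{b: \text{minP}^{(b)} \le \text{minP}\}\bigr)/(B+1)$.

Allowing every permuted sample its own optimal threshold is what makes the
adaptive search valid: the observed minimum is compared against minima
obtained under the same search.  The adjusted P-value lives in
$[1/(B+1),\,1]$, so $B$ bounds the attainable significance.

All permutations in one test invocation come from a single RNG stream
seeded by the `seed` argument and restored afterwards; results are
bit-reproducible given the seed.  (A per-permutation seeding contract for
parallel execution was considered and dropped -- the package runs
single-threaded, and one stream is simpler to reason about.)

For tiny samples `exhaustive = TRUE` replaces random permutations by the
complete enumeration of case/control assignments, which the test suite uses
to check the estimator layer against an independent brute-force oracle.

## Comparators

Five burden-style comparators run under the same engine, sharing each
replicate's permutations so power comparisons are paired:

* **sigma-MidP**: $\sum_i w_i(-2\ln p_i)$ over sites with unequal
  case/control minor-allele counts -- the un-truncated ancestor of ADA;
* **T1 / T5**: per-subject minor-allele counts over variants with pooled
  MAF < 1% (resp. 5%); statistic = case-control difference in mean score,
  two-tailed via $|{\cdot}|$ (the classical right-tailed versions lose all
  power against protective regions, so both tails are used throughout);
* **WS**: Madsen-Browning rank sum of per-subject weighted scores, weights
  recomputed per permutation, two-tailed on the deviation from the null
  expectation $n_A(n+1)/2$;
* **VT**: for every candidate threshold $t$ in the sorted distinct observed
  MAFs, a two-sample z-score of the mean-score difference using variants
  with MAF $\le t$, standardised by the pooled per-subject score variance;
  statistic $\max_t |z(t)|$.  (With "$< t$" over the same candidate set the
  largest-MAF site could never enter any score; "$\le t$" spans every
  collapsing rule the data admit and matches the original variable-threshold
  construction.)

SKAT-type kernel tests are deliberately out of scope: they are not burden
tests, have their own analytic P-value machinery, and a faithful
re-implementation would be a package of its own.

## Data handling

Genotypes arrive as VCF (split per alternate allele) or as a tab-delimited
dosage matrix, with a two-column phenotype table.  Subjects with any
missing genotype are dropped -- per-site 2x2 tables must be complete, and
imputing rare-variant genotypes would manufacture evidence.  Dosages are
re-polarised to the pooled-sample minor allele, since every formula is
written in minor-allele counts.  Variants with pooled MAF above 5% are
excluded before testing (`maf_filter`); the boundary is kept (retain
MAF $\le 0.05$), and the filter is applied to each analysed sample, which
in simulations means after case-control sampling.

## The synthetic haplotype pool

The simulation machinery emulates coalescent-simulated chromosome pools
(10,000 chromosomes by default) with two properties the tests are actually
sensitive to:

1. **a rare-dominated frequency spectrum**: population MAFs are drawn
   log-uniformly (density $\propto 1/x$) on $[5\times10^{-5}, 0.05]$, the
   neutral-spectrum shape, so most sites are rare;
2. **local linkage**: sites are partitioned into blocks (mean size 10,
   Poisson-distributed) and within a block each haplotype's allele
   indicators share a latent Gaussian factor with correlation 0.5.  This
   makes neighbouring rare variants positively dependent -- the reason
   permutation rather than independence-based combination is needed --
   while leaving every column marginally an independent Bernoulli(MAF)
   sample across haplotypes, so realised pool frequencies are exactly
   binomial around their targets.

What the generator does **not** reproduce: realistic recombination maps and
long-range LD decay, population demography, selection at linked sites, and
the empirical HapMap-CEU haplotype structure of coalescent simulators.
Calibration results (type-I error) are insensitive to this -- permutation
tests are valid under any genotype distribution -- but absolute power
numbers shift by a few points relative to coalescent haplotypes, which is
why the package's power checks carry wider tolerances (about ten percentage
points) than its calibration checks.

Disease status follows a multiplicative penetrance
$P(\text{affected}) = \min\bigl(1, f_0 \prod_j \text{GRR}_j^{g_j}\bigr)$
over the causal-site dosages $g_j$, with baseline penetrance $f_0 = 1\%$;
the clip at 1 keeps extreme multi-carrier genotypes valid.  Effect sizes
are parameterised by a per-variant population attributable risk:
$\text{GRR} = 1 + \text{PAR}/((1-\text{PAR})\cdot\text{MAF})$ for
deleterious sites and the reciprocal for protective ones, so rarer causal
variants get larger effects at fixed PAR.  This reciprocal construction is
asymmetric on the odds-ratio scale -- a deleterious variant is strictly
easier to detect than a protective variant of equal MAF and PAR -- and the
test suite verifies that inequality exactly from the penetrance model.
Causal sites (d of them, `ceiling(d * r_isk / 100)` deleterious) are drawn
among sites with population MAF below 1%, the rare-variant convention.
Case-control samples draw chromosome pairs with replacement until 500 cases
and 500 controls accumulate; under the null (all GRR = 1) affection is
independent of genotype, and the sampler draws both strata directly --
the same distribution without the rejection loop.

## Problem sizes and numerical choices

The package's heavy checks run at desk scale, chosen as the largest sizes a
single-CPU session handles comfortably: type-I error from 20 pools x 100
replicates (2,000 tests) at $B = 1000$, power from 20 pools x 25 replicates
(500 tests), with the d = 20 preset (~400 neutral sites, the largest region
in the preset ladder, where neutral-noise robustness matters most).  At
2,000 null replicates the three-standard-error acceptance band around 0.05
is about $\pm 0.015$.  The permutation engine exploits two invariances:
pooled per-site allele totals are fixed under label permutation, so mid-P
values and weights are precomputed as lookup tables indexed by the case
count (sites with equal totals share a table), and genotype matrices are
stored subject-major sparse, so accumulating one permutation's counts costs
only the nonzero dosages of its cases.

Degenerate inputs are defined, not special-cased away: monomorphic sites
carry $p = 1$ and no direction; a region with no variant under the MAF
filter warns and reports adjusted P = 1; an all-tied region gives the
sigma-MidP statistic 0 and P = 1; a disease model whose case quota is
unreachable stops at a draw cap with a diagnostic rather than looping
forever.  Ties in permutation ranks always count against significance.
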