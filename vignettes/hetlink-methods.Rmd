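---
title: "Methods: intercross GBS markers, F2 linkage maps and QTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intercross GBS markers, F2 linkage maps and QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetlink)
```

## The mapping design

`hetlink` targets a cross design that sidesteps the usual obstacle to
linkage mapping in highly heterozygous, inbreeding-depressed species: a
single heterozygous F1 individual is *selfed*, and its F2 progeny are
genotyped by GBS.  At any biallelic SNP where the F1 is heterozygous, the
F2 segregates 1:2:1 (hh : hk : kk) and both alleles are informative in
both directions — an *intercross* (hk×hk) marker.  Because the grandparents
are not genotyped, which homozygote is called `AA` versus `BB` is an
arbitrary per-group convention; the package resolves it consistently within
each linkage group (coupling phase along a maximum-LOD spanning tree) and
reports the flip applied per marker.  Every sign statement about additive
effects is therefore relative to that convention, exactly as in any F2
analysis without grandparental genotypes.

## Marker calling

GBS yields sparse, depth-limited calls, and its characteristic artefact is
**heterozygote undercalling**: a true heterozygote sampled by `D` reads
shows only one allele with probability `2^(1-D)` and is miscalled
homozygous.  The calling filters are therefore depth-first:

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 6 | calls with known depth below this are masked missing |
| `min_site_completeness` | 0.75 | fraction of progeny called, per site |
| `min_sample_completeness` | 0.75 | fraction of sites called, per progeny |
| `maf_min` | 0.10 | minor allele frequency among called progeny alleles |
| `min_presence` | 0.40 | fraction of progeny with any call |
| `alpha_seg` | 0.01 | level of the 1:2:1 goodness-of-fit test |

Depth masking happens *before* completeness is computed, so a depth-failed
call counts as missing for every later rule; this is the stricter of the
possible orderings and is idempotent (re-filtering a filtered table changes
nothing).  MAF is computed from progeny only, since segregation is a progeny
property.  A site whose progenitor call is missing is rejected rather than
imputed — progenitor heterozygosity is the defining condition of an
intercross marker, not something to guess.  The 1:2:1 test uses the
asymptotic χ² distribution with 2 df (`p = exp(-χ²/2)`), without continuity
correction; at family sizes of several hundred the approximation is
excellent, and the test suite verifies the realised type-I error at
n = 424 against its nominal 1%.

## Two-point linkage and map construction

The recombination fraction between two intercross markers is estimated by
EM on the 9-class joint genotype likelihood of an F2 pair; the
double-heterozygote class is a mixture of 0- and 2-recombinant gamete
pairs, and its expected recombinant count `2r²/((1-r)² + r²)` is the only
non-trivial E-step term.  The EM runs unconstrained on [0, 1] from two
starts (0.25 and 0.75): a maximum above 0.5 is the repulsion phase, for
which r̂ = 1 − r*.  Individuals missing at either marker contribute only
marginal terms that cancel from the likelihood ratio, so pairs are
effectively estimated from jointly-called individuals; pairs with fewer
than 10 are flagged unreliable.  The tests hold the EM to a brute-force
grid-plus-golden-section maximisation of the directly-coded likelihood to
|Δr| ≤ 1e-4.

Grouping is single-linkage clustering at linkage LOD ≥ 10 — deliberately
conservative, since spurious joins are costlier than split groups at this
marker density.  Ordering within a group proceeds in three stages:

1. greedy seriation on two-point r̂ (extend whichever map end has the
   nearest unplaced marker);
2. `n_rounds` (default 3) of deterministic local search — all 2-opt segment
   reversals, then all single-marker insertions, first-improvement — scored
   by the multipoint likelihood of the observed genotypes under a Markov
   chain along the order (interval r from the two-point estimates; with
   complete data this objective *is* the profile multipoint likelihood,
   because the F2 chain factorises over adjacent pairs);
3. interval-by-interval refinement of the recombination fractions against
   the full hidden-Markov likelihood, then Kosambi transformation
   d = 25·ln[(1+2r)/(1−2r)] of the refined intervals.

The output order is canonical — smaller physical coordinate first where
physical data exist, lexicographic first marker otherwise — so reversing
the input marker list cannot change the result.

Curation removes markers with segregation p ≤ 1e-5 (severe distortion
destabilises both grouping and ordering), collapses duplicate loci
(identical call vectors with missing as a wildcard; the most complete
marker represents the set), and prunes by **nearest-neighbour stress**.
Stress here is defined as the mean absolute difference between a marker's
map distance to each of its two nearest neighbours and the corresponding
two-point Kosambi distance; a marker whose genotypes carry errors inflates
its apparent recombination with *both* neighbours, so its stress rises
while its neighbours' does not.  Markers above 2.5 cM are removed worst
first, with positions re-fitted after each removal.  This stress formula is
this package's own operational definition: the commercial mapping tool
that popularised the 2.5 cM rule does not publish its formula, so ours is
declared rather than inferred, and the threshold is exposed as a parameter.

Map statistics follow the conventions of published linkage maps: total
length (1 decimal), mean inter-marker distance (2 decimals), Mb/cM
(3 decimals), largest gap, genome coverage (mean per-group physical span
over chromosome length), and a per-group Spearman rank correlation between
genetic and physical positions as the collinearity check.

## Genotype probabilities and single-trait QTL scans

Missing and error-prone genotypes are handled by the standard F2 hidden
Markov model: latent genotypes form a Markov chain with transitions from
the inverse-Kosambi of inter-position distances, observed calls emit
through a symmetric error model (`error_prob`, default 1e-4), and missing
calls emit uniformly.  Forward–backward gives posterior 3-vectors on a grid
containing every marker plus pseudomarkers every `step_cM` (default 1 cM).

Interval mapping fits, at each grid position, a three-genotype-class model
by EM with the posterior probabilities as mixture weights: a Gaussian
mixture with common variance for normal traits, per-class Bernoulli
penetrances for binary traits (fitted by EM on penetrances, not logistic
regression).  `LOD = log10(L1/L0)` against the no-QTL null.  EM stops at a
relative log-likelihood change below 1e-8 or 1000 iterations; peak ties
break toward the smaller cM.  Composite interval mapping conditions both
models on cofactor markers' posterior-expected additive and dominance codes
(`x_add = P(BB) − P(AA)`, `x_dom = P(AB)`), excluding cofactors within
10 cM of the tested position; cofactors are chosen by forward selection on
residual sum of squares with a BIC stopping rule and a cap of 3 — a small
cap because the trait architectures this design resolves rarely support
more, and each cofactor costs 2 df.

Effects are read off the class means as a = (μ_BB − μ_AA)/2 and
d = μ_AB − (μ_AA + μ_BB)/2 (positive a: the B-labelled allele raises the
trait), and R² = 1 − 10^(−2·LOD/n) with n the phenotyped individuals in
the scan (missing phenotypes are dropped per scan).  Genome-wide
significance comes from permutation of trait values (default 1000
permutations, α = 0.05, empirical quantile of per-permutation genome-wide
maxima, seeded and reproducible).  Support intervals are the contiguous run
around the peak within `drop` (1.5 or 1.8) LOD of the maximum, with
physical bounds from the nearest genotyped markers at or outside the ends;
intervals hitting a group boundary are flagged truncated.

## Joint two-trait scan and causal model selection

The joint scan fits, at each position, the bivariate fixed-effects model
with trait main effects, cofactor additive/dominance effects per trait,
tested-position effects per trait, and an unstructured 2×2 residual
covariance Σ.  Cofactors are placed every 1.51 cM snapped to the nearest
marker and deduplicated (on a dense map that approaches one cofactor per
marker; the snapping rule is this package's own, stated because
grid-snapping conventions differ between implementations), and cofactors
within 50 cM of the tested position are excluded.  Σ is re-estimated from
residuals with the REML divisor inside an iterative GLS loop (cap 1000
iterations); with complete cases and the same design for both traits the
GLS update coincides with per-trait least squares, so the loop converges
immediately — the iteration cap matters only for the general contract.
The profile reported is −log10 p of the 4-df Wald test that all four
tested-position effects vanish; its threshold converts a genome-wide
α = 0.05 through the Li–Ji effective number of tests, M_eff =
Σ [I(λ_i ≥ 1) + (λ_i − ⌊λ_i⌋)] over eigenvalues of the per-group marker
score correlation matrices, summed across groups (genome-wide rather than
per-chromosome summation, the more conservative reading).  Eigenvalues are
rounded at 1e-8 before the floor to keep the formula's discontinuity away
from numerical noise.  Peaks above threshold are selected greedily by
significance subject to ≥ 30 cM separation, refitted jointly under the
simplified multi-locus model, and backward-eliminated until every retained
locus passes its joint test; per-trait effects and drop-one
explained-variance fractions are reported.

The causal model selection test compares four Gaussian structures for two
traits sharing a QTL — causal (Q→T1→T2), reactive (Q→T2→T1), independent
(Q→T1, Q→T2), and full (Q→T1, {Q,T1}→T2) — by maximum likelihood, AIC and
BIC.  Each QTL term is a 3-class mean (3 parameters) and each regression a
single residual variance, giving 7/7/8/9 parameters; causal and reactive
are exact mirrors under trait swap, which the tests assert to 1e-10.  The
non-penalised AIC/BIC form is implemented; penalised variants of the same
family of tests are out of scope.

## The simulator: what it emulates and what it does not

`simulate_f2()` generates latent genotypes by a Markov (no-interference)
chain over marker intervals with F2 transition matrices from the inverse
map function (Kosambi by default), so marginals are exactly (¼, ½, ¼) and
the progenitor is heterozygous everywhere.  `apply_gbs_noise()` draws a
read depth per call from a negative binomial, undercalls heterozygotes with
probability `2^(1-D)` (resolving to the sampled allele's homozygote —
equivalently a fair coin, by symmetry), emits zero-depth calls as missing,
and adds independent extra missingness (default 2%).  `simulate_traits()`
builds quantitative traits as μ + Σ(a·x_add + d·x_dom) + ε, fully dominant
binary traits as carrier indicators, and causal chains (T2 = β·T1 + noise)
for model-selection scenarios.

The depth model default is negative binomial with mean 12 and size 8
(variance/mean = 2.5).  Under it roughly 10% of calls fall below the
depth-6 filter and about 0.4% of retained heterozygote calls are
undercalled, so both GBS artefacts are active while a site's completeness
(~0.88) sits clear of the 0.75 threshold — a mid-depth GBS library.  A
lower mean (8 or less) pushes per-call missingness past 25% and the 75%
completeness filter then removes essentially every site; that regime is
reachable through `depth_mean`/`depth_size` but is not a sensible default
for a pipeline whose filters assume a usable library.  Setting
`depth_size = Inf` gives constant depth, which the tests use to verify the
closed-form undercall rate `2^(1-D)` exactly.

What the simulator does **not** emulate: crossover interference beyond
what Kosambi's transition probabilities imply (the chain is Markov, so
simulated multi-locus interference is weaker than in real meioses),
reference-alignment bias, paralog collapse (a real source of spurious
heterozygosity), allele-specific sequencing error, and linked or epistatic
trait architectures beyond additive/dominance terms plus causal chains.
Passing tests therefore demonstrate correctness of the estimators under
the stated model, not robustness to artefacts outside it.

## Numerical choices and degenerate inputs

- Two-point EM: tolerance 1e-10 on r, 500 iterations, two starts; r clamped
  to [1e-12, 1−1e-12] to keep the E-step finite.
- Ordering objective clamps interval r to [1e-6, 0.499]; interval
  refinement uses Brent search on [1e-6, 0.499] at tolerance 1e-5 cM-scale.
- Mixture EMs clamp penetrances to [1e-9, 1−1e-9] and variances to ≥ 1e-12;
  log-densities floor at 1e-300 before logging.
- `kosambi(0.5)` is an error (infinite distance), not a clamp.
- A group of one marker maps trivially at 0 cM; an empty thresholded joint
  profile returns an empty QTL list, not an error; a binary trait with a
  single class, a zero-variance CMST trait, or all sites removed by filters
  are hard errors with actionable messages.
- All stochastic entry points (simulation, permutations) take explicit
  seeds; a simulation config without a seed is rejected.

## Problem sizes used by the packaged checks

The test suite exercises the pipeline at the design's family size
(n = 424) but keeps marker panels compact: the end-to-end check simulates
19 linkage groups × 10 markers under full GBS noise and requires 19 groups
back, ≥ 95% of groups ordered correctly up to reversal, and a fully
penetrant dominant QTL localised inside its 1.8-LOD support interval.
Calibration checks use 20,000 simulated markers for the segregation filter
and a 3-group map with a 400-permutation threshold against 200 fresh null
scans for the genome-wide false-positive rate; CMST model selection is
scored over 100 replicates at n = 424.  These sizes are the package's
choices for routine verification; all of them scale up by changing the
simulation configs.

## Known limitations

- No interference models (chi-square/gamma renewal) in mapping or
  simulation; distances assume the Kosambi relation pairwise.
- Dominant (3:1) markers are not recovered; only co-dominant intercross
  markers are mapped, which matches the design's information content but
  discards some sites a mixed-marker mapper would keep.
- The joint scan handles exactly two traits (pairs are the unit of the
  causal analysis); more traits mean more pairs, not one larger model.
- Genotype likelihoods (PL/GL fields) are not modelled; depth is the only
  per-call quality signal.
- The N.N. stress statistic is an operational surrogate (see above), so
  pruning decisions near the 2.5 cM threshold can differ from tools using
  a proprietary definition.
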