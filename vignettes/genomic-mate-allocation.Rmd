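---
title: "Genomic mate allocation with dominance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic mate allocation with dominance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a purebred pig nucleus, selection decides *which* animals become parents,
but mate allocation decides *which pairs* are actually mated. Breeding values
(the transmissible, additive part of merit) are all that matters for
long-term response, yet the performance of the immediate offspring also
depends on dominance: the interaction of the two alleles an offspring
receives at each locus. Because a mating fixes which allelic combinations can
occur, the expected *total genetic value* of a litter is mate-specific. With
genome-wide SNP genotypes on the candidate parents, both the additive and the
dominance contributions of every prospective mating can be predicted, and the
set of matings can be chosen to maximise either expected breeding value
(`u`) or expected total genetic value (`g`).

`matealloc` implements that full chain: quality control of SNP data,
variance-component estimation with dominance and inbreeding depression,
conversion to marker effects, prediction of all candidate matings, and exact
optimisation of the mating set.

## Models

### Animal-level variance components

Three single-trait linear mixed models are supported:

* **Model A** (pedigree): `y = X b + Z u + e`, `u ~ N(0, A sigma2_A)`, with
  `A` the numerator relationship matrix (tabular method).
* **Model G** (genomic additive): `y = X b + f b_f + Z u + Z pe + e`,
  `u ~ N(0, G sigma2_A)`, where `f` is genomic inbreeding — the proportion
  of homozygous SNP calls per animal — and its coefficient `b_f` is the
  inbreeding-depression parameter. The permanent-environmental term is used
  only for repeated-record (maternal) traits.
* **Model GD** adds a dominance-deviation term `v ~ N(0, D sigma2_D)`.

`G` is VanRaden's matrix `M M' / (2 sum p_k q_k)`, with `M` coding genotypes
AA/Aa/aa as `2 - 2p`, `1 - 2p`, `-2p`; `D` follows the dominance-deviation
parameterisation, `W W' / sum (2 p_k q_k)^2` with codes `-2q^2`, `2pq`,
`-2p^2`. In this parameterisation breeding values and dominance deviations
are orthogonal under Hardy-Weinberg equilibrium, so adding the dominance
term barely moves the additive estimate. Allele frequencies are the
*observed post-QC frequencies*, computed once, frozen in the genotype
container and reused by every downstream consumer; mixing frequency sets
across stages silently breaks the marker-level equivalences, which is why
the container makes the freeze explicit.

Including `f` as a covariate is what identifies *directional* dominance: a
nonzero mean of dominance effects appears phenotypically as a linear effect
of genome-wide homozygosity (inbreeding depression), and omitting the
covariate inflates the estimated dominance variance. For reporting, the
coefficient is also rescaled to "per 10% inbreeding" (`b/10`).

### REML

Variance components are estimated by EM-REML in the phenotypic-covariance
parameterisation `V = sum_j Z_j K_j Z_j' sigma2_j + I sigma2_e`. The EM
update is the classical fixed point; its restricted log-likelihood is
non-decreasing, and the implementation *asserts* this every iteration.
Because EM slows near the optimum, `method = "ai"` takes an
average-information step first and falls back to EM whenever that step would
leave the parameter space or decrease the restricted likelihood — so the
monotonicity guarantee is preserved while convergence typically drops from
hundreds of iterations to a dozen. Asymptotic standard errors come from the
inverse average-information matrix at convergence, with first-order delta
propagation to heritability and variance ratios; this is an
information-matrix approximation to the exact sampling-variance treatment
sometimes used for variance proportions.

Working in `V`-form has a second advantage: a genomic relationship matrix
centered at observed allele frequencies is exactly singular (the vector of
ones lies in its null space), which breaks MME formulations that need
`K^{-1}` but is harmless here. Blending `K* = w K + (1 - w) I` with
`w = 0.95` is still applied by default before REML for numerical stability,
matching common practice. Note that fitting data whose true covariance is
`K` under the blended `K*` rescales the estimate by roughly `1/w` (+5% at
`w = 0.95`); the parameter-recovery tests therefore estimate under the
unblended matrices, which the `V`-form handles exactly, while the pipeline
default remains blended.

Numerical choices: convergence is declared when the maximum relative
parameter change falls below `tol` (default `1e-8`; the pipeline uses
`1e-6`, ample for three-significant-figure reporting); variances are floored
at `1e-8 * var(y)` and a component pinned at the floor for 50 iterations is
reported as a boundary estimate; the AIC counts only variance components as
parameters (`AIC = -2 logL_R + 2 k`), since fixed effects are identical
across the genomic models for a trait. Comparing model A with the genomic
models by AIC is reproduced as is conventional, although their fixed-effect
structures differ by the inbreeding covariate, so that comparison should be
read qualitatively.

### Marker effects and progeny prediction

Given `sigma2_A`, `sigma2_D` from model GD, marker-level variances follow
`sigma2_d = sigma2_D / sum (2pq)^2` and
`sigma2_a = (sigma2_A - sum[2pq (q - p)^2] sigma2_d) / sum 2pq`, and the
equivalent SNP-BLUP model `y = X b + f b_f + K a + T d* + e` (K coded
1/0/-1, T coded 0/1/0) is solved by dense mixed-model equations. The
centered dominance effects are shifted back by `d = d* - b_f/m`, and allele
substitution effects are `alpha = a + d (q - p)`. GEBVs use the centered
coding `sum (count - 2p) alpha`; the uncentered alternative shifts every
animal by the same constant and cannot change a ranking or an allocation.
With a purely additive model and unblended `G`, the animal-level and
marker-level predictions coincide to machine precision — an identity the
test suite checks at `1e-6`.

For a candidate mating, single-locus progeny genotype probabilities follow
from random gamete transmission (`P(AA) = (c_s/2)(c_d/2)` etc. for parental
allele counts `c`). Expected progeny total genetic value and breeding value
are

* `g_hat = sum_k [P(AA) a_k + P(Aa) d_k + P(aa)(-a_k)]`
* `u_hat = sum_k [P(AA)(2-2p) + P(Aa)(1-2p) + P(aa)(-2p)] alpha_k`

Loci with a missing parental genotype are skipped for that pair. With
complete genotypes `u_hat` is exactly the parental GEBV average, so
selecting matings on `u_hat` is equivalent to truncation selection of
parents on GEBV — the useful consequence is that any benefit of allocating
on `g_hat` is attributable to dominance, not to a different selection
intensity.

### Allocation

Choosing `n` matings to optimise the summed expected progeny value, with at
most one boar per sow and at most `c` sows per boar, is a linear program on
a transportation polytope; its vertices are integral, so the LP optimum is a
valid 0/1 mating plan. The solver is an exact successive-shortest-path
min-cost-flow routine (implemented in C++): a source feeds each boar with
capacity `c`, each sow passes capacity 1 to the sink, and `n` units are
routed at minimum cost. Since the total number of matings is fixed, the
values are shifted to non-negative costs without changing the optimum;
maximisation and minimisation (for traits where lower is better, such as
age at 100 kg or backfat) differ only by a sign. The result is
deterministic for a fixed input ordering; among exactly tied optima the
plan returned is the one the augmenting-path order produces, which is
stable but not otherwise canonical.

The boar-capacity constraint is implemented as an inequality (`<= c`)
together with an equality on the total number of matings. A formulation
with per-boar equalities would force every preselected boar to full use,
which contradicts the observed behaviour of such plans (a few boars used
lightly); with the inequality the number of boars actually used is an
outcome, not an input.

Plans are compared by `Delta_U` and `Delta_G`: the mean `u_hat` (or
`g_hat`) of the selected matings minus the mean over all candidate matings,
reported in trait units and in genetic standard deviations
(`/ sqrt(sigma2_A)`). Both quantities are reported for both plans. By
construction the `g`-optimised plan can only do better on `Delta_G` and the
`u`-optimised plan on `Delta_U`; the scientific question is the size of the
`Delta_G` advantage relative to the `Delta_U` sacrifice, which at a
dominance/additive ratio near 0.2 is a visible gain for a ~2% sacrifice.

## The simulator

`sim_config()` + `simulate_population()` generate the data structure the
analysis assumes: founder boars and sows with binomial (Hardy-Weinberg)
genotypes at independent loci, frequencies uniform on the configured range;
one generation of random boar x sow matings producing full-sib litters by
explicit gamete sampling; per-SNP additive effects `a_k ~ N(0, sigma2_a)`
and dominance effects `d_k ~ N(-b/m, sigma2_d)` with the marker variances
obtained by inverting the conversion formulas at the observed frequencies,
so the animal-level variances are the configured ones by construction.
Inbreeding depression is induced *only* through the nonzero mean of the
dominance effects — no `f` covariate is simulated — so recovering `b` from
the fitted covariate is a genuine test of the identification argument, not
bookkeeping. Fixed effects are a single categorical batch factor with
normal level values; a permanent-environmental effect and repeated records
are available for maternal-trait layouts.

Default parameters are the reference trait configuration for age at 100 kg
(variances 16.26 / 3.31 / 42.80 days², dominance/additive ratio 0.20,
depression 4.29 days per 10% homozygosity) and a herd of 30 boars x 150
sows x 2 litters of 8, i.e. ~2400 genotyped offspring — a desk-scale
analogue of a nucleus population. Normal distributions for marker effects
are a modelling choice (the estimation theory does not prescribe one).

What the simulator deliberately omits: linkage disequilibrium and linked
loci, multi-generation selection, genotyping error, crossbreeding, and
maternal common-litter environments. Passing tests on these data therefore
demonstrate correctness of the estimators and the allocation machinery
under the model's own assumptions, not robustness to the violations real
data exhibit (LD between causal variants and markers being the most
consequential).

## Problem sizes used in the checks

The automated checks run at sizes chosen for a desktop: parameter recovery
uses 20 replicates of 200 full-sib litters of 12 (n = 2400, 600 SNPs) with
unblended matrices; the GBLUP/SNP-BLUP equivalence uses 300 animals x 1000
SNPs; allocation exactness is verified against brute-force enumeration on
grids up to 4 boars x 6 sows; the allocation comparison uses 20 replicates
of ~360 offspring with marker effects from SNP-BLUP at the generating
variance components. The acceptance script runs the full pipeline once
(simulation through allocation of 600 matings among 120 preselected boars
and all genotyped sows, capacity 15) and reports only quantities it
computes in that run.

## Known limitations

* Dense linear algebra throughout; intended for desk-scale problems
  (a few thousand animals / equations), not national evaluations.
* Single-trait only; no selection index over multiple traits.
* The AI-matrix standard errors are asymptotic and can be optimistic for
  variance components near zero.
* Mate allocation ignores inbreeding of the planned litters and genetic
  diversity of the boar team; it optimises expected progeny merit only.
* The pedigree A matrix uses the plain tabular method (no sparse-inverse
  shortcuts), adequate for the pedigree depths used here.
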