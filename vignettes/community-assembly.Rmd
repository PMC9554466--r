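---
title: "Inferring assembly processes of abundant and rare soil fungi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring assembly processes of abundant and rare soil fungi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This package implements a complete inference chain for asking which
ecological processes — selection along environmental gradients, dispersal
limitation, homogenizing dispersal, or drift — structure soil fungal
metacommunities, and whether those processes differ between the abundant
minority of taxa and the rare majority. The chain starts from an ASV
count table and sample metadata and ends with variance attributions of
pairwise community divergence to spatial and environmental predictors.
Because the questions are answered through null models, permutation
tests and nonlinear model fits whose behavior is easy to get subtly
wrong, the package also ships a synthetic metacommunity generator with
known, switchable assembly processes; every inferential step is
validated against data whose truth is known.

## The data model

A `community_table` is a samples x taxa matrix of read counts. The
intended workflow fixes the preprocessing order: taxa with fewer than 8
total reads are discarded (`filter_low_count_taxa()`), then every sample
is rarefied to a common depth — 9,080 reads by default — by exact
subsampling without replacement (`rarefy_table()`). Rarefaction before
filtering would re-introduce sampling-depth artifacts into the
low-count filter, so the order filter-then-rarefy is asserted in the
pipeline. The rarefaction depth N later doubles as the community size
of the neutral model, so it is carried by the table rather than asked
of the user twice.

Taxa are classified at two levels from relative abundances
(`classify_local()`, `classify_regional()`): locally, a taxon above 1%
of a sample's reads is abundant and below 0.01% rare; regionally, the
unweighted mean of per-sample relative abundances over all samples
(zeros included) is compared against 0.1% (abundant) and 0.005%
(rare). All four inequalities are strict; boundary values fall to
intermediate. A taxon absent from a sample carries no local label —
an undetected taxon has no local abundance to classify. All
downstream subcommunity analyses operate on the regional abundant and
regional rare subsets.

## Niche breadth

Levins' niche breadth treats the samples as resource states:
B = 1 / sum over samples of p_j^2, with p_j the proportion of the
taxon's reads in sample j. B runs from 1 (a point niche) to the number
of samples (perfectly even use) and is invariant to rescaling, so
computing it on rarefied counts or on relative abundances differs only
through rounding; we use rarefied counts. The community-level value
Bcom is the within-sample abundance-weighted mean of the B values of
the taxa present, with weights renormalized over the analyzed subset so
that abundant-subcommunity Bcom and rare-subcommunity Bcom are each
internally coherent.

## The abundance-based null model and the beta-deviation

The central statistic is the standardized effect size of Bray-Curtis
beta-diversity. For each of `reps` (default 999) replicates, every
sample is rebuilt by (a) drawing its observed richness S_k distinct
taxa from the regional pool, sequentially without replacement, with
probabilities proportional to regional abundance, and (b) giving each
drawn taxon one read and allocating the remaining N_k - S_k reads
multinomially with pool-proportional probabilities. Per-sample richness
and total abundance are therefore preserved exactly, with no rejection
loop; a rejection-sampling alternative (`method = "rejection"`)
re-draws full multinomials until every drawn taxon is represented, for
sensitivity analysis. The two allocators differ only in how the
guaranteed single read enters and agree closely at sequencing depths;
the seeded allocator is the default because its cost is deterministic.

For every sample pair, deviation = (observed Bray-Curtis − null mean) /
null SD. Deviations far above zero indicate dispersal limitation or
heterogeneous selection; far below zero, homogenizing dispersal or
homogeneous selection; near zero, stochastic assembly.

Two numerical points deserve note. First, when the regional pool is
estimated from the observed table itself (the standard field practice
and our default), each sample contributes 1/n of the pool, which
imparts a small negative bias of order 1/n to the deviations; with 90
samples this is negligible, but the `pool` argument accepts the true
pool when one is known (as in calibration studies, where the
self-consistency check — data generated by the null process must score
approximately N(0,1) — is run against the generating pool). Second,
pairs whose null ensemble is degenerate (zero SD) are reported as `NA`
with a warning rather than as infinities.

## The Sloan neutral community model

Under neutral immigration at rate m into local communities of N reads,
a taxon with metacommunity mean relative abundance p has local relative
abundance distributed Beta(N m p, N m (1 − p)), and its expected
occurrence frequency is the probability mass above the detection limit
d: freq(p) = 1 − I_d(N m p, N m (1 − p)), the complement of the
regularized incomplete beta function. We take d = 1/N — one read at the
rarefied depth — as the detection limit. `fit_ncm()` estimates m by
bounded scalar least squares on untransformed frequencies
(multi-start at 0.01/0.1/0.5 plus a golden-section pass, tolerance
1e-8) and reports R² = 1 − SSres/SStot, which can be negative when the
neutral curve fits worse than the mean frequency; an R² below 0.3
triggers a warning that the migration-rate estimate is unreliable,
because occurrence frequencies then constrain m only weakly.
Subcommunity fits pass the full table's rarefaction depth as `N`, since
the taxon's relative abundance is defined against the whole community.

The parameter-recovery oracle `simulate_sloan_community()` draws local
relative abundances from the model's own beta marginal and applies the
model's own detection rule (present iff the local proportion exceeds
d), with binomial read counts clamped to at least one read for detected
taxa. Simulating reads as plain binomial draws instead smooths the hard
detection limit and inflates the recovered m by roughly a third — an
estimator property worth knowing when interpreting published m values.
Even with detection-consistent simulation, a small upward bias (about
+0.03 at m = 0.3, N = 9,080) remains because the mean relative
abundance of near-limit taxa is computed from detected reads only.

## Distances, distance-decay, and permutation inference

Bray-Curtis dissimilarities come from `vegan::vegdist`; geographic
distances are haversine great-circle distances on a 6,371 km sphere;
environmental distances are Euclidean on z-scored covariates, entered
per variable so that forward selection can prune them. Before any
regression, covariates are pruned greedily until no pair exceeds
|Pearson r| = 0.6, dropping within each offending pair the variable
with the higher mean absolute correlation (a keep-list can override).

The distance-decay relationship is the OLS slope of similarity
(1 − Bray-Curtis) against distance over all sample pairs, reported per
km and per 1,000 km. Because pairs sharing a sample are not
independent, the naive OLS p-value is optimistic; we therefore also
report a permutation p obtained by jointly permuting the similarity
matrix's sample labels, and the same label-permutation scheme (with the
+1 correction, two-sided) underlies the Mantel test and the MRM
coefficient tests. PERMANOVA is delegated to `vegan::adonis2`.

## MRM, variation partitioning, hierarchical partitioning, path analysis

Multiple regression on distance matrices unfolds each matrix's lower
triangle (column-major; for three samples the pair order is (2,1),
(3,1), (3,2)) and fits OLS; coefficient significance comes from
refitting under response-label permutations. Forward selection adds, at
each step, the candidate with the largest R² gain if its permutation p
is below alpha = 0.05, breaking ties by name order so runs are
reproducible; an empty selection is a legitimate outcome and is
propagated honestly — the variation partitioning then attributes zero
variance to the environment rather than refitting the full candidate
set, which would report overfit noise as signal.

Two-set variation partitioning computes pure and shared fractions from
the three R² values (full, space-only, environment-only). The shared
fraction can be negative (a suppression effect) and is never clipped.
Hierarchical partitioning averages each predictor group's R² increment
over all entry orders, computed exactly over all subsets (at most five
groups); contributions sum to the full-model R² to 1e-10 by
construction, and this identity is asserted in the tests rather than
assumed.

The path model is a recursive (acyclic, observed-variable) system fit
equation-by-equation with OLS on standardized variables, so every
coefficient is a standardized path coefficient and a single-parent
child's coefficient equals the Pearson correlation. Direct, indirect
and total effects on the terminal outcome are obtained by path tracing;
total = direct + indirect holds algebraically. This replaces
covariance-based SEM deliberately: for the saturated recursive
structures used here the point estimates coincide, while latent
variables and global fit indices (chi-square, CFI, GFI, RMSEA) are out
of scope. Variables enter on the pairwise (distance) scale, consistent
with a pairwise response; the nominal OLS standard errors are therefore
optimistic, which is flagged in the output documentation — effect
decomposition, not hypothesis testing, is the purpose of this module.

## The synthetic metacommunity generator

`simulate_covariates()` emulates the study design the pipeline targets:
30 sites along a ~2,500 km desert transect, three 10 x 10 m quadrats
per site (90 samples), four vegetation types, soil (SM, pH, TSN, SAN,
TSP, TOC), climate (MAT, MAP, PET, aridity = 1 − MAP/PET with the
aridity index held in the dryland band 0.03–0.32) and plant covariates
(PLC, SLA, LCN, LNP, PHight, Cwidth, richness), plus a plant
composition table. One latent environmental axis drives everything:
it correlates with transect position at `env_spatial_corr` (default
0.7 — desert environments are strongly but not perfectly spatially
structured), and every covariate loads on it at 0.75, which keeps
covariate pairs near the pruning threshold (so the collinearity step is
actually exercised) while each remains an honest proxy of the axis.

`simulate_metacommunity()` draws a lognormal regional pool
(meanlog 0, sdlog 2.5 — chosen so the regionally abundant class is a
minority of taxa, under 15%, holding most reads, as in real fungal
communities), filters it per sample by a Gaussian niche factor on the
environmental axis raised to `selection_strength`, optionally by an
exponential dispersal kernel around each taxon's home site, and then
realizes reads through Dirichlet-multinomial drift. The drift
concentration is N·m/(1−m): m = 1 is the exact mass-effect limit in
which local communities are multinomial samples of the pool — i.e. the
null model's own generative process, the only regime in which
beta-deviations are expected to center on zero — while small m gives
drift-dominated assembly. The default m = 0.05 reflects weak
immigration plausible for dispersal-limited desert fungi and, usefully,
spreads the abundant tail across the occurrence-frequency transition so
that the neutral model is identifiable per subcommunity. The default
niche breadth (`niche_sd` 0.4 on an axis spanning roughly five units)
keeps pairwise dissimilarities of selected taxa away from saturation at
1, where the deviation-environment gradient would be lost.

`mixed_scenario()` constructs the study's headline contrast in one
table: the abundant tail of the SAD (top decile of pool abundance)
assembles neutrally with drift, while the remaining rare taxa track the
environment deterministically under strong selection
(`selection_strength` 6). Selection redistributes composition within
the rare block but does not transfer its biomass to the abundant block
(each block keeps its pool share of every sample's expected reads), and
drift is applied to the neutral block only — drift is part of the
neutral process being contrasted, not of selection. On this generator
the pipeline reproduces, at the default seed and across seeds, the
qualitative pattern the method suite is meant to detect: the neutral
model fits the abundant subcommunity better than the rare one,
community niche breadth is higher for abundant taxa, and the pure
environmental fraction of beta-deviation variance is larger for rare
taxa.

What the generator does not emulate: taxonomy and guild structure,
phylogenetic relatedness, sequence-level error, compositional biases of
PCR, temporal dynamics, and plant-fungus feedbacks; covariates are
Gaussian with a single shared latent axis rather than the messier
dependence structure of real soil data. Passing tests on this generator
therefore validate the statistical machinery and its calibration, not
the ecological conclusions one would draw from any particular real
dataset.

## Problem sizes and numerical choices in the test suite

The self-calibration of the null model uses 200 trials of a 20-sample
by 50-taxon fixture at 299 replicates; sampler correctness is checked
against exhaustive enumeration of ordered draws on a 5-taxon pool with
10,000 draws; neutral-model recovery uses 20 replicate fits at the full
design size (90 samples, 1,000 taxa, depth 9,080); permutation-test
calibration uses 500 null runs per test at 99 permutations; scenario
checks run the full pipeline at 299 null replicates. Tolerances follow
the statistic's own sampling noise: algebraic identities at 1e-10,
quadrature agreement at 1e-6, calibration bands of ±0.02 around the
nominal 0.05 rejection rate.

## Known limitations

- Beta-deviations inherit a small negative bias when the pool is
  estimated from few samples (order 1/n).
- The migration-rate estimate of the neutral fit is biased upward by a
  few hundredths at sequencing depths, and unreliable whenever R² is
  low; both conditions are flagged.
- MRM-family inference treats pairs as exchangeable under label
  permutations, which is correct for the global null but, as in the
  field's standard practice, the reported R² values are descriptive,
  not unbiased effect sizes.
- The path model's analytic p-values ignore pair non-independence and
  should be read as descriptive.
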