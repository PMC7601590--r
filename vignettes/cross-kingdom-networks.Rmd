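---
title: "Cross-kingdom co-occurrence analysis of rumen fungi and bacteria"
author: "ruminet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-kingdom co-occurrence analysis of rumen fungi and bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

`ruminet` implements the statistical stages that follow ASV calling in a
paired-amplicon study of the rumen: twelve fistulated steers in a 3x3
crossover graze pure alfalfa (PA), alfalfa with the anti-bloat surfactant
Alfasure (AA) or an alfalfa-sainfoin mix (AS) after a shared alfalfa-hay
baseline, and each rumen sample is sequenced twice - an ITS library for
the anaerobic fungi (phylum Neocallimastigomycota) and a 16S library for
the bacteria.  The questions are the ones this design supports: how diet
and frothy bloat shift fungal diversity and composition, which fungal and
bacterial ASVs co-occur or exclude each other across kingdoms, which fungi
act as network hubs, and which individual ASVs respond to the diet/bloat
combination.

Everything is exercisable without the original reads because the package
ships a generator that emulates the design (below).  All stages consume
two `count_table`s (samples x taxa integer counts plus taxonomy lineages)
and a metadata table (steer, period, treatment, dichotomized bloat
status).

```{r, eval = FALSE}
library(ruminet)
ds <- generate_dataset(synth_config(seed = 1))
fun <- preprocess_table(ds$fungal, 7000, 0.5,
                        taxonomy_keep = "Neocallimastigomycota")
bac <- preprocess_table(ds$bacterial, 25000, 0.5)
net <- conet(fun, bac, seed = 1)
find_hubs(net, k = 4)
```

# Preprocessing

Fungal and bacterial tables are processed independently, mirroring their
separate libraries.  The fungal table is first restricted to lineages
containing `Neocallimastigomycota` (case-sensitive substring at any
rank), then each table is rarefied - 7,000 reads per sample for fungi,
25,000 for bacteria, drawn without replacement; samples below the target
are dropped with a warning rather than kept unrarefied, because the
downstream diversity comparison requires equal depth.  A prevalence
filter follows rarefaction: a taxon is kept when present (count > 0) in
at least `ceiling(f * n)` samples, with `f = 0.5` defining network nodes
and `f = 0.1` the differential-abundance candidates.  The ordering -
filter after rarefaction - is a package choice; the alternative order
changes little but would let never-rarefied singletons set prevalence.

CLR analysis needs strictly positive compositions, so zeros are imputed
by a Bayesian-multiplicative rule before the transform: in sample *j*
with total *n~j~*, a zero cell of taxon *i* becomes
*t~i~* s / (*n~j~* + s), where the prior weight *t~i~* is the taxon's
mean relative abundance over the samples where it occurs (renormalized
across taxa) and the prior strength *s* defaults to 1.  Observed
proportions are then shrunk by the common factor 1 - (sum of imputed
mass), so ratios among observed taxa - the quantities CLR works on - are
untouched.  An imputed value that would reach the sample's smallest
observed proportion is repeatedly multiplied by 0.65 with a warning;
with *s* = 1 this cannot trigger, but it protects the configurable-prior
case.  The CLR transform itself is ln *x* minus the row mean of ln *x*;
rows of the result sum to zero to 1e-9 and the composition's scale drops
out.

# Diversity

Chao1 uses the classic estimator S~obs~ + F1^2^/(2 F2) and switches to
the bias-corrected S~obs~ + F1(F1-1)/2 when no doubletons exist (the
always-bias-corrected form is available via `bias_corrected = TRUE`).
Shannon is -sum p ln p in natural log by default, with a configurable
base since the original base is not fixed by convention.

Baseline-vs-treatment comparisons pair samples by steer, averaging a
steer's replicates within a phase, and use a Wilcoxon signed-rank test
implemented in-package: zero differences dropped, midranks for ties,
and the two-sided p from exact enumeration of the signed-rank
distribution up to 25 effective pairs (a convolution over the 2^n sign
assignments, which remains exact under ties, where the textbook tables do
not apply); beyond that the tie-corrected normal approximation is used,
without continuity correction.  Bloat vs no-bloat within AS compares
different steers and therefore uses the rank-sum test.  The fungal-vs-
bacterial diversity association is Spearman's rho with an exact
permutation p for n <= 9 and the t approximation otherwise.

# Ordination

`rda()` is a direct least-squares implementation of redundancy analysis:
the response (CLR matrix) is column-centred, the constraint dummy-coded
and centred, R^2^ is the fitted-to-total trace ratio, and the adjusted
value is 1 - (1 - R^2^)(n-1)/(n-1-p).  With a `condition` design both
response and constraint are residualized on it first (partial RDA, used
for "variance explained by hub fungi adjusted for diet and bloat"), and
the permutation test then permutes those reduced-model residuals
(Freedman-Lane); otherwise rows are permuted freely.  Matched-steer
structure is deliberately not used to restrict permutations by default.
A constraint that becomes collinear after residualization is an error
naming the dropped columns rather than a silent drop.

PERMANOVA on Bray-Curtis distances is delegated to `vegan::adonis2`
behind `permanova()`; the test-suite cross-checks it against the direct
Gower sums-of-squares partition and against the MANOVA trace pseudo-F on
Euclidean coordinates.  Pairwise ADONIS comparisons run two-group models
on sample subsets, each with its own permutation run and optional BH
correction across the family.

# The co-occurrence network

For every fungus x bacterium pair (inter-kingdom pairs only - the
questions concern cross-kingdom structure), four association measures
are computed on relative abundances: Spearman (Pearson of midranks),
Kendall tau-b, Bray-Curtis across samples, and a symmetrized
Kullback-Leibler divergence of the across-sample-normalized profiles.
The KLD pseudocount is 1% of each profile's mean: it must scale with the
profile, because an absolute epsilon lets a single sample in which both
taxa happen to be absent dominate the divergence with an unbounded
log-ratio.

The null model is a ReBoot-style permutation (default 1,000 iterations):
the two taxa are shuffled independently across samples, and - for the
correlation measures - each sample's composition is re-closed with the
shuffled values in place, so the part of a correlation that mere closure
would produce for this pair is absorbed into the null.  A bootstrap over
samples (default 1,000 resamples) yields the score's sampling
distribution; the measure-specific p-value is the two-sided probability
of the null mean under a Gaussian with the bootstrap mean and SD.
Direction is the sign of the observed correlation, or, for
dissimilarities, the side of the null mean the observed value falls on
(above: mutual exclusion; below: co-presence; exactly at it: none).

Per pair, measures are partitioned by direction; the majority direction
defines the edge's supporting set (a 2-2 tie cannot reach the support
threshold and yields no edge).  Supporting p-values are merged with
Brown's method - Fisher's statistic referred to a scaled chi-square whose
moments account for the dependence between measures.  The required
covariance of the -2 ln p statistics is estimated empirically from the
null-like bulk of candidate pairs (those with every per-measure p above
0.05): pairs with genuine signal make all four p-values small together
and would inflate the estimate towards total dependence, whereas Brown's
method is defined in terms of the covariance under the null.  BH
correction is applied across all candidate pairs, and an edge is retained
when at least three measures support it, its merged q is below 0.05 and
every supporting observed score lies inside its bootstrap 95% CI.  All
three thresholds are arguments.

Stratified networks subset the grazing samples by bloat status (baseline
samples carry no bloat score and are excluded), re-applying the 50%
prevalence filter per stratum.  Hubs are the top-4 nodes by degree per
network (ties broken by the summed |z| of incident merged p-values, then
by ID, with ties through the k-th place reported in full), and the hub
set of a study is the union across the overall and the two stratified
networks.

# Differential abundance

Per taxon passing the 10% prevalence filter, a permutation ANOVA
associates the CLR abundance with the diet/bloat combination
(`BASELINE`, `PA.B`, `AA.NB`, `AS.B`, `AS.NB` under the default bloat
pattern) while treating steer as a blocking factor: the F statistic comes
from the additive two-way least-squares fit, and the null from permuting
the response within each steer's samples - a permutation-exact treatment
of the repeated-measures structure that avoids a variance-component fit.
An exact mode enumerates all within-block permutations for small designs
and anchors the test suite.  BH correction runs across taxa; flagged taxa
(q < 0.05) get matched-pairs Wilcoxon follow-ups against baseline per
diet/bloat combination and a rank-sum comparison of bloat within AS, with
BH within each contrast.  Permutations default to 4,999 for analysis runs
and 199 in the tests.

# The synthetic generator

`synth_config()` defaults encode the trial: 12 steers, three 4-steer
groups rotating through PA/AA/AS over three periods behind a baseline
occasion; four missed samplings (1 PA, 2 AA, 1 AS) leaving 44 samples;
PA steers all bloating, AA none, AS half; 30 fungal and 120 bacterial
taxa; per-sample totals lognormal around 110k (ITS) and 55k (16S) reads
so rarefaction occasionally drops a sample.  Latent log-abundance of
taxon *t* in sample *s* is

base~t~ + treatment shift + steer effect + sum~k~ L~tk~ f~ks~ + noise,

with counts multinomial at the drawn depth from the within-kingdom
softmax.  Planted structure enters through the factors *f*: each of the
5 hub fungi carries loading +1.5 on its own standard-normal factor and
each of its 8 bacterial partners sign x 1.5 on the same factor, 80% of
signs negative.  Treatment effects are per-taxon log-fold shifts drawn
for a configurable fraction of taxa; `null_dataset()` zeroes both
couplings and shifts.

Three generator choices deserve their rationale:

* **Coupled taxa sit in the interquartile range of baseline abundance.**
  Closure makes relative abundances sum to one, so a coupled taxon that
  dominates its kingdom would drag every other taxon along with its
  factor swings and the planted edges would no longer be the dataset's
  dominant cross-kingdom structure.
* **Steer effects are small (SD 0.1 vs residual 0.3).**  The network
  stage assumes exchangeable samples: its bootstrap is iid over samples,
  so strong within-steer clustering shrinks the effective sample size and
  makes rank-correlation p-values anti-conservative.  In this trial diet,
  not animal identity, dominated composition; users simulating strong
  individual signatures should expect a higher false-edge rate.
* **Composition skew (base SD 1.5)** matches the span of ASV relative
  abundances typically left after a 50% prevalence filter (roughly three
  orders of magnitude).

What passing tests on this generator do **not** show: real data carry
taxonomy-assignment error, depth-confounded batch structure, and
interaction topologies richer than disjoint hub-partner stars; none of
these are emulated.

A structural caveat worth stating explicitly, because it shapes the
recovery benchmarks: when 40 of 120 bacterial taxa swing by a factor of
e^±3^, closure transmits those swings to every other taxon's relative
abundance, and the ensemble (correctly) reports the induced
relative-abundance associations as edges.  Against a planted-edge truth
table these count as false positives, so planted-edge "precision" and
the recovered exclusion fraction understate the method's specificity -
the type-I experiment on `null_dataset()`, where no couplings exist at
all, is the cleaner control and retains well under 5% of candidate
pairs.

# Numerical and interface choices

* Seeds: every resampling function takes an explicit seed; the pipeline
  derives per-stage seeds from one master seed, and identical
  configuration reproduces byte-identical outputs (`manifest.json`
  records stage seeds, parameters and output MD5 hashes).
* Permutation p-values use the (1 + exceedances)/(B + 1) convention with
  a relative tolerance on F comparisons; exact enumerations report the
  plain fraction including the identity.
* p-values entering Brown's merge are clamped to [1e-300, 1] so a
  numerically-zero p cannot produce NaN.
* Degenerate inputs: zero-variance profiles yield `NA` scores and drop
  that measure for the pair; all-zero samples are errors in distance
  computations; an empty network is a valid result (hub extraction warns
  and returns an empty set).
* The test suite runs the network stage at 200 permutations/bootstraps,
  the blocked ANOVA at 199 permutations and the full pipeline at 30
  fungal x 120 bacterial taxa; analysis defaults are 1,000/1,000/4,999.
* The orchestration surface is `run_pipeline()` plus plain TSV / JSON /
  GraphML stage outputs (and a thin `Rscript` wrapper in
  `inst/scripts/run_pipeline.R`), so any stage can be audited or re-run
  in isolation.

# Known limitations

* The Gauss-curve p-value construction inherits the original ensemble
  method's asymmetry (null mean against bootstrap spread); it has no
  exactness guarantee and is sensitive to bootstrap-SD underestimation
  under clustered sampling designs.
* Compositional closure means "association" is always association of
  relative abundances; absolute-abundance claims need spike-ins or flow
  counts this pipeline does not model.
* The blocked permutation ANOVA treats steer as exchangeable within
  block; carry-over effects between periods are not modelled.
* Brown's covariance estimate needs enough null-like pairs (>= 30); tiny
  candidate sets fall back to the all-pairs estimate.
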