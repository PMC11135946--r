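---
title: "Models and methods behind chronodate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chronodate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chronodate implements Bayesian node dating of a fixed, rooted, binary
species topology, together with the machinery that surrounds dating in
deep-time studies of bacterial lineages such as the ammonia oxidizers:
sequential (two-step) calibration propagation, clock-model choice by
marginal likelihood, gene-verticality screening with the
delta-log-likelihood (dLL) statistic, and genomic-content convergence and
association statistics. This vignette describes the models, the defaults
and why they were chosen, the numerical decisions, and what the synthetic
validation does and does not establish.

## The dating model

Ages are in Ma at every user-facing boundary; internally the sampler works
in units of 100 Ma, the common practice in clock dating, so that rates
(substitutions/site/100 Ma) and ages have comparable magnitudes.

**Likelihood.** Two interchangeable likelihood modes are exposed:

* *exact*: Felsenstein pruning over site patterns under a closed-form
  substitution model — JC or equal-input (F81) nucleotide, HKY with its
  analytic transition probabilities, or the equal-input (Poisson+F) amino
  acid model. Gaps and ambiguity codes are marginalized as fully uncertain
  states. Analytic branch-length gradients are computed by a joint
  post-order/pre-order pass.
* *approximate*: a second-order expansion of the exact log-likelihood
  around the maximum-likelihood branch lengths `bhat`
  (`l(b) ~ l0 + g'(b-bhat) + (b-bhat)'H(b-bhat)/2`). This is the standard
  approximate-likelihood device for genome-scale dating: the expensive
  data structure is compressed once into `(bhat, g, H)` and every MCMC
  iteration evaluates a quadratic form. The Hessian comes from forward
  differences of the analytic gradient, symmetrized, and projected to be
  negative semi-definite (eigenvalues clipped at `-1e-8`) — branches whose
  ML estimate sits on a box bound can otherwise leave a direction of
  positive curvature that would make the surrogate likelihood unbounded.

The package simulates with the same closed-form transition probabilities
it infers with, so the generator is the exact twin of the inference model.
The equal-input amino-acid model was preferred over empirical matrices
(LG and relatives) precisely to keep this twin property self-contained;
the substitution-model identity is irrelevant to the correctness
properties being validated.

**Branch-length optimization.** L-BFGS-B with analytic gradients, run in
two phases: first under a conservative upper bound (2 substitutions/site),
then released. A cold start under a wide box can otherwise throw several
branches at once onto the saturation plateau of the likelihood, where the
surface is jointly flat and neither gradient steps nor coordinate moves
recover. A gradient-guided coordinate polish (golden-section search on any
branch whose gradient exceeds 0.1 and that is not boundary-optimal)
finishes the fit; the conditional likelihood in a single branch length is
unimodal, so the 1-D search is plateau-immune.

**Calibrations.** Node-age constraints are soft bounds, proper densities
on (0, Inf):

* *joint* `[tL, tU]`: uniform plateau carrying mass `1-pL-pU`, continuous
  power-law tails carrying `pL` below and `pU` above (default 0.025 each —
  the conventional soft-bound tail mass; the underlying study states
  bounds, not tail masses, so the mass is exposed as a parameter);
* *min*: power ramp with mass `pL` below `tL` and a heavy Pareto tail
  (shape 2 by default) above — a minimum constrains only weakly from
  above, mirroring how fossil minima are treated;
* *max*: uniform on `(0, tU)` with a power-decay tail above — the
  root-maximum style of constraint;
* *fitted densities* (lognormal, gamma, skew-normal, zero-truncated
  normal) for propagated second-step priors.

**Node-age prior.** Uncalibrated interior nodes follow the birth–death
kernel density conditional on the root age (complete sampling; the
`lambda = mu` and `mu = 0` limits are closed forms). Calibrated nodes take
their calibration density as their marginal prior — replacing, not
multiplying, the kernel. This construction is what makes prior recovery
exact: with the likelihood off, a calibrated node's marginal matches its
calibration density up to the truncation induced by parent/child ordering.
Users should still place calibrations whose bulk respects the ordering:
heavily overlapping calibrations on adjacent nodes will interact, exactly
as they do in standard dating tools.

**Clock models.** Strict (one rate), independent lognormal rates (IR;
branch rates iid lognormal with mean-preserving log-mean
`log m - sigma2/2`), and autocorrelated rates (AR; geometric Brownian
motion along the tree, child branch log-rate normal around the parent's
with drift `-sigma2 dt/2` and variance `sigma2 dt`, `dt` the branch
duration in 100 Ma). Both relaxed clocks are mean-rate identifiable by
construction. Hyperpriors: gamma on the mean rate (default shape 2, mean
0.02/100 Ma — a slow, conserved-marker scale that keeps deep branches away
from saturation on multi-Ga trees) and gamma on `sigma2` (default shape 1,
mean 0.5).

**Sampler.** Metropolis-within-Gibbs:

* node ages — random-walk proposals reflected inside the (oldest child,
  parent) interval, per-node step sizes; uncalibrated nodes additionally
  receive independence proposals from the birth–death kernel truncated to
  the same interval (closed-form CDF and inverse), which keeps ages
  decorrelated when the likelihood term is weak (prior-only runs, low
  stepping-stone rungs);
* branch rates — multiplicative random walks alternating with
  independence proposals from the conditional rate prior;
* hyperparameters — log-scale random walks, refreshed three times per
  sweep (they touch only the prior, so the extra updates are nearly free);
* a non-centered `sigma2` move for relaxed clocks that holds the
  standardized log-rate increments fixed and rescales them with the
  proposed `sigma2`; in increment coordinates the rate-prior terms cancel
  and the acceptance reduces to `beta dlogL + dlog p(sigma2) +
  log(sigma2'/sigma2)`. Without this move, `sigma2` and the rate vector
  mix an order of magnitude more slowly under the AR model;
* a whole-tree scale move (ages x c, rates / c) with Jacobian
  `c^(n_ages - n_rates - 1)`, which travels along the rate–time ridge.

Step sizes are auto-tuned toward 20–40% acceptance during burn-in
(default 25% of iterations). The root must carry a max, joint or fitted
calibration; the sampler refuses to run otherwise, since the time scale
would be unidentified from sequence data alone.

## Sequential calibration propagation

The two-step strategy dates a calibration-rich analysis first, fits a
parametric density to each shared node's posterior ages, and imposes those
densities — together with the second analysis' own fossils — as
independent marginal priors in the second step. Candidate families are
lognormal, gamma, skew-normal and zero-truncated normal, fitted by maximum
likelihood; the winner minimizes the Kolmogorov–Smirnov distance to the
sample (AIC is reported as a diagnostic). The four families cover
right-skewed, symmetric and bounded posterior shapes; which families the
original analyses used is not stated anywhere we know of, so the set is a
package choice. Near-symmetric posteriors are genuinely ambiguous between
lognormal, gamma and skew-normal — the families then agree to within the
KS resolution, so the ambiguity is inconsequential for the propagated
prior.

Fitted densities are truncated at the second step's root maximum (a
propagated prior must not push mass above the root bound) and correlations
between first-step nodes are deliberately discarded — the method's stated
simplification, and its main caveat: jointly tight first-step posteriors
enter the second step slightly over-confident.

The package's validation checks the property that justifies the method:
on a partitioned dataset with overlapping calibrated nodes, two-step
posterior means agree with a joint single-run analysis to within a few
percent of the root age.

## Clock-model selection

Marginal likelihoods are estimated by stepping-stone sampling over power
posteriors `p(D|theta)^beta p(theta)` with K = 8 rungs spaced as quantiles
of Beta(0.3, 1) (crowding rungs near the prior, where the integrand
changes fastest). The Monte Carlo error propagates each rung's weight
variance with an autocorrelation-corrected effective sample size; a rung
whose ESS stays below 50 after two chain-length doublings aborts the
estimate rather than returning a silently unreliable number. Stepping
stone was chosen over the harmonic mean (unstable) and thermodynamic
integration (needs dense rungs). The Bayes-factor verdict thresholds
`|log BF|` at 1.15 (BF about 3.2, "substantial" on the usual scale); the
threshold is a declared convention, configurable.

## Gene-verticality screening

`dLL = max_topology l(gene) - l(gene | species topology)`, both terms with
branch lengths re-optimized under the same substitution model; model
parameters are shared between the two terms so the score isolates
topology. Search is exhaustive for up to 7 taxa and NNI hill-climbing
otherwise. Ties in the gene ranking break lexicographically by gene name
for reproducibility.

The *gene-removal* protocol sorts genes by dLL and repeatedly drops the
two most discordant, re-dating the concatenate each time (the step size
and the floor — default 6 retained genes — are parameters). The *sliding
window* protocol keeps the gene count fixed at k (default 10; 6, 8, 10 and
12 are the standard choices) and slides along the dLL ranking one gene at
a time. Both record the tracked clades' posterior ages and their age gap,
so the gap can be read against gene verticality. Screening re-dates many
times, so it runs the dating chain at shortened settings; trajectories
need relative, not publication-grade, precision.

One point of record: the protocol description in the source methods says
the window "uses every ten genes" while the accompanying figure sweeps
k = 6, 8, 10, 12; the package makes k a parameter with default 10.

## Genomic-content statistics

* Manhattan distance on binary gene presence/absence = number of families
  present in exactly one genome of the pair ("metabolic dissimilarity").
* Mash-style nucleotide distance: bottom-s MinHash (s = 1000, k = 21 —
  conventional sketching defaults) of canonical k-mers hashed with a
  splitmix64 finalizer truncated to 53 bits (exactly representable in
  doubles); Jaccard estimated from the merged sketch; distance
  `-log(2j/(1+j))/k`, with sketch-disjoint pairs capped at a declared
  maximum.
* Non-metric MDS by Kruskal stress-1 majorization (vegan's monoMDS
  engine), seeded.
* The convergence permutation test z-normalizes each distance matrix over
  its off-diagonal entries (rank normalization is available behind a
  flag), takes `T = mean normalized metabolic distance over A x B pairs -
  mean normalized nucleotide distance over A x B pairs`, and permutes
  genome identities jointly in both matrices — preserving each matrix's
  internal structure while breaking the group–metric linkage. One-sided
  add-one p-value; small T is the convergence signal. The exact
  normalization and permutation unit of the original analysis are not
  stated; these are the package's declared choices.
* The association battery runs, per gene family and group contrast,
  two-sided Fisher's exact test of presence against membership, Pearson
  correlation against the focal (marker) gene's column, and Pagel's
  lambda phylogenetic-signal test with a likelihood-ratio p-value
  (phytools' engine), with Benjamini–Hochberg correction within each test
  family. Binary traits are fed to the lambda test as 0/1 continuous
  values — the common pragmatic usage; the D-statistic for binary traits
  is a documented alternative, not the default. All three tests and their
  pass flags are reported; final curation is left to the user.

## The synthetic-data generator

Every validation input is generated with known ground truth:

* *timetrees*: conditioned on the tip count and root age, the non-root
  node ages are drawn iid from the birth–death kernel given the root age
  and splits attached to uniformly chosen open lineages. This conditioned
  construction (rather than forward simulation plus rescaling) was chosen
  deliberately: it is the exact generative counterpart of the dating
  engine's node-age prior, so prior-recovery and simulation-based
  calibration checks compare like with like, and the Yule special case has
  a closed-form order-statistic distribution to test against.
* *branch rates*: strict, IR or AR exactly as the inference models define
  them.
* *alignments*: evolved site-iid with the inference models' transition
  probabilities.
* *discordant ("transferred") gene families*: evolved on NNI-perturbed
  topologies. NNI moves are guaranteed to change the unrooted topology (a
  pivot at the root would merely re-root, so there the move exchanges
  grandchildren across the root); ages are re-drawn only where an
  interchange breaks the ordering. Incongruence by NNI rather than
  explicit donor/recipient transfer simulation is sufficient because dLL
  screening only needs topological discordance, and the move count gives a
  tunable discordance dial.
* *calibrations*: joint bounds at `(1 +/- 0.2) x true age`, minimum bounds
  at 0.8 x true (the purple-sulfur-bacteria-minimum style), maximum bounds
  at 1.2 x true (the root-maximum style) — all bracketing the truth by
  construction.
* *gene content*: focal columns Bernoulli with presence probability
  shifted by group membership (`p_in = (1-e)p0 + e`); background columns a
  symmetric two-state Markov chain along the tree (phylogenetic signal
  only).

Default simulation scale for validation: 5–24 tips, 150–2,000 sites per
gene, 7–16 gene families — sized so that every end-to-end protocol runs in
minutes on one core. The default mean rate of 0.02 substitutions/site/100
Ma keeps root-to-tip paths below about 0.6 substitutions on 3-Ga trees;
hotter settings push deep branches into saturation, where branch lengths
(and hence everything downstream) are only weakly identified — that regime
is a property of the data, not of the implementation, and the validation
deliberately avoids claiming anything about it.

What passing these checks shows: the sampler targets its stated posterior
(prior recovery, simulation-based calibration), the approximate likelihood
is a faithful stand-in at realistic curvature, the screening and
sequential protocols behave as designed when their assumptions hold. What
it does not show: robustness to model misspecification (real alignments
are not site-iid draws from JC or equal-input models; real rate variation
is not exactly lognormal), to topology error in the fixed species tree, or
to calibrations that do not bracket the truth. Those questions need real
data and sensitivity analyses, not this generator.

## Validation protocol sizes

The shipped checks use: prior recovery at 20,000+ retained draws;
parameter recovery over twenty replicates of 16-tip/2,000-site
strict-clock data with three bracketing calibrations; simulation-based
calibration over fifty reduced replicates (6 tips, 150 sites);
approximate-vs-exact agreement on a 10-tip instance; dLL against the
exhaustive 15-topology oracle on twenty 5-taxon genes; screening recovery
over ten replicates of a 10 congruent + 6 discordant mixture on a planted
1,200-Ma age gap, with the removal floor set at 10 genes so that the
recorded trajectory spans exactly the removal of the discordant block;
sequential-vs-joint agreement on a partitioned 12-tip dataset;
clock-model recovery over ten 16-tip, 1,200-site IR datasets at
sigma2 = 1 — the large-variance regime where the IR/AR contrast carries
real information (expected |log BF| of roughly 1.5–15; fewer branches or
weaker rate variance leave many datasets genuinely ambiguous between the
two clocks, which is a property of the models, not of the estimator); and
the content-statistics oracles
(exhaustive Fisher enumeration, brute-force BH, exact-set Jaccard,
permutation size and power). `scripts/acceptance.R` re-runs the same
pipeline at slightly reduced replicate counts and writes the resulting
numbers as JSON.

## Known limitations

* The species topology is fixed; topology error propagates silently into
  ages.
* Fitted sequential priors are independent marginals; step-1 posterior
  correlations are discarded.
* The birth–death prior assumes complete extant sampling (no sampling
  fraction parameter).
* Pagel's lambda on 0/1 traits is a continuous approximation.
* The approximate likelihood degrades when the posterior visits branch
  lengths far from `bhat` (very weak data); the exact mode exists for
  exactly that situation.
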