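---
title: "Detecting shifts in acoustic allometry with multi-optima OU models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting shifts in acoustic allometry with multi-optima OU models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomshift)
```

## The scientific problem

Across frogs, the dominant frequency of the male advertisement call
scales negatively with body size: bigger frogs call lower. The question
this package addresses is whether that allometric constraint has ever
been escaped — whether particular clades have moved to a new optimum
intercept, or a new slope, of the size–frequency relationship — and if
so, where on the phylogeny those escapes happened.

The model is a multi-optima Ornstein–Uhlenbeck (OU) regression on a
time-calibrated phylogeny. Let $y_i$ be the natural-log mean dominant
frequency (log Hz) of species $i$ and $x_i$ its natural-log mean male
snout–vent length (log mm). The adaptive landscape is a *regime
painting*: $K$ shift points on branches partition every root-to-tip
lineage into segments, each assigned to one of $K+1$ regimes, with
regime 0 the ancestral regime at the root. Each regime $k$ carries an
optimum intercept $\theta_k$ and a body-size slope $\beta_k$; the trait
tracks the (time-varying) optimum under stabilizing selection of
strength $\alpha$ with diffusion variance $\sigma^2$.

The expected value at tip $i$ is a Hansen-weighted mixture of the
regimes its lineage visited:

$$E[y_i] = \sum_k W_{ik}(\alpha)\,(\theta_k + \beta_k x_i)
  \;+\; d_i^\top\beta_{site} + (x_i d_i)^\top\beta_{int},$$

where a lineage segment of regime $k$ spanning times $[t_0, t_1]$
contributes $e^{-\alpha(T_i - t_1)} - e^{-\alpha(T_i - t_0)}$ to
$W_{ik}$, the residual weight $e^{-\alpha T_i}$ falls to the root regime
(the root state is fixed at the root optimum, which gives a proper
Brownian-motion limit as $\alpha \to 0$), and $d_i$ holds dummy codes
for the calling site (aquatic, terrestrial, arboreal; terrestrial is the
reference level). Three model forms are fitted: (a) size only, (b) size
plus site, (c) size plus site plus the site-by-size interaction. Site
and interaction coefficients are global — only $\theta$ and the size
slope shift between regimes, which is the granularity at which the
per-regime estimates are reported.

The tip covariance is the standard OU form with measurement error:
$V_{ij} = \tfrac{\sigma^2}{2\alpha}
e^{-\alpha(T_i + T_j - 2 s_{ij})}(1 - e^{-2\alpha s_{ij}})$ with
$s_{ij}$ the depth of the most recent common ancestor, plus the
per-species observation variance of $y$ on the diagonal. Below
$\alpha = 10^{-8}$ the analytic Brownian limit $\sigma^2 s_{ij}$ is
used. The likelihood is the exact dense multivariate normal evaluated
through a Cholesky factor.

## Priors and the reversible-jump sampler

Priors follow the conventions of Bayesian multi-optima OU regression:
every slope-type coefficient has a normal prior with mean 0 and sd 0.2;
every optimum has a normal prior centred on the mean observed log
response with sd 1.5 times its standard deviation; the number of shifts
$K$ is by default uniform on $\{0, \dots, 200\}$ (capped at the number
of branches), with a conditional Poisson available; a shift's branch is
chosen with probability proportional to branch length and its position
is uniform along the branch, with at most one shift per branch;
$\alpha$ and $\sigma^2$ have bounded log-uniform priors (defaults span
unit-depth trees — rescale the bounds for trees in absolute time
units).

Because the one-shift-per-branch restriction makes branch sets
non-independent, the configuration prior is normalized exactly with
elementary symmetric polynomials $e_K$ of the branch lengths, computed
once per tree in log space. This makes the marginal prior on $K$
*exactly* the chosen $K$ prior — verifiable by the package's data-free
("no data") runs, which mirror the prior-predictive check of running
the estimation with the likelihood disabled (`power = 0`) and
confirming the a-priori mean number of shifts.

The reversible-jump sampler mixes: birth (prior-draw proposals for the
new regime's $\theta, \beta$, so proposal densities cancel and the
Jacobian is 1), death, relocation of a shift, random-walk updates of
optima and slopes, and log-scale multiplier updates of $\alpha$ and
$\sigma^2$ (probabilities 0.15 / 0.15 / 0.10 / 0.60 split across the
parameter moves). Two additional moves address ridges that plain
random walks traverse slowly: a joint multiplier on
$(\alpha, \sigma^2)$ that moves along the constant-stationary-variance
ridge, and a shear on one regime's $(\beta_k, \theta_k)$ along
$\theta + \beta \bar{x}_k$. Random-walk step sizes adapt toward an
acceptance rate of 0.3 during burn-in only and are frozen afterwards,
so the retained samples come from a fixed transition kernel. Every
chain is bit-reproducible from its integer seed. Correctness is tested
two ways: with the likelihood disabled the sampler must reproduce every
prior marginal (Kolmogorov–Smirnov distance < 0.05 at 10,000 samples),
and on a 4-tip tree with $K_{max} = 1$ its stationary $P(K = 1)$ must
match a brute-force enumeration in which $\theta, \beta$ are
integrated analytically and the shift position by quadrature.

## Detection settings

The package default ($K$ uniform, wide $\alpha$ bounds) is the most
transparent choice for prior checks, but two empirical properties of
the posterior at moderate sample sizes (n in the low hundreds) matter
for *detection*:

* Under a uniform $K$ prior the posterior honestly spreads over many
  weak-shift configurations (there is no complexity penalty beyond the
  Occam factor), diluting per-branch posterior probabilities.
* The weak-selection region $\alpha \to 0$ is a near-degenerate basin:
  a clade-level offset can be absorbed as Brownian drift, and a chain
  that enters this basin cannot propose its way out, because escaping
  requires raising $\alpha$ and adding the shift simultaneously. This
  is the familiar OU identifiability problem: a phylogenetic half-life
  $\ln 2/\alpha$ much longer than the tree height is statistically
  indistinguishable from Brownian motion.

The documented *detection settings* therefore use a conditional
Poisson prior on $K$ with rate 2 (a conservative expectation that most
lineages share the ancestral allometry) and a log-uniform $\alpha$
bounded below at a half-life of about 1.4 tree heights
($\alpha \in [0.5, 100]$ on a unit-depth tree). Fits additionally
start from a data-informed state (`init = "informed"`): ordinary
least-squares residual contrasts seed up to three disjoint candidate
shifts, $\alpha$ starts at a half-life of half the tree depth, and
chains after the first jitter all starting parameters. A heuristic
start only shortens the transient — chains remain free to discard
seeded shifts, and the Gelman–Rubin diagnostic below is computed
across dispersed chains.

## Convergence, summaries, and filters

Convergence is assessed with the potential scale reduction factor
(between- versus within-chain variance) on the per-branch shift indicators (the quantities that define
the result) and on $K$, $\alpha$, $\sigma^2$, and the log-likelihood,
with effective sample sizes from Geyer's initial-positive-sequence
estimator. The verdict is "converged" when every monitored $R < 1.1$.
Branches never sampled with a shift have zero variance and are reported
as $R = 1$ by convention.

Post-burn-in samples are pooled across chains. A branch's posterior
probability is the fraction of pooled samples containing a shift on it;
under one-shift-per-branch these probabilities sum exactly to the
posterior mean of $K$. The *supported set* applies two filters: posterior
probability at least 0.7, and more than 3 species in the shifted clade
(`min_clade = 4`); supported sets at 0.5 and 0.9 are reported alongside.
Regime parameter summaries are marginal over all samples whose
configuration contains the given shift — not only the modal
configuration — which uses every relevant sample at the cost of mixing
slightly different configurations. A regime's "mean age" is the mean
age of the internal nodes of the shifted clade including its stem node;
this is one of several defensible conventions and is flagged as such.

## Model comparison

Marginal likelihoods are estimated by stepping-stone sampling along the
power-posterior ladder $\beta_t = (t/(T-1))^{1/0.3}$ (default 20 rungs),
each rung's chain starting from the previous rung's end state. The
estimator's Monte-Carlo standard error combines per-rung delta-method
variances discounted by the autocorrelation-corrected effective sample
size. Bayes factors are reported on the natural scale with $2\ln BF$
alongside; BF > 10 is flagged as strong support. The estimator is
validated against the closed-form normal–normal marginal on a conjugate
toy (agreement within 3 SE, invariant to doubling the rungs).

## Phylogenetic ANCOVA corroboration

Every supported shift is re-tested in a null-hypothesis framework: a
PGLS under pure Brownian motion comparing a full model (separate
intercept and slope for the focal clade; 4 parameters) with a reduced
model (one intercept and slope for all species; 2 parameters) by an
F-ratio test, $F = [(RSS_r - RSS_f)/2]\,/\,[RSS_f/(n-4)]$. The response
and design are whitened by a triangular factor of the BM covariance;
any factor with $C = LL^\top$ yields identical sums of squares. Mean
sums of squares are $RSS/(n-p)$. On a star tree the procedure reduces
exactly to ordinary ANCOVA, and its type-I error on a fixed 100-tip
tree is nominal (0.05 ± 0.02 over 1,000 null simulations). Note the
corroboration deliberately uses the size-only regression, not the full
covariate set.

## The synthetic-data generator

`sim_config()` / `simulate_dataset()` emulate the structure of the
empirical data: a Yule tree rescaled to unit depth; log body size by
Brownian motion (root 4 log mm ≈ 55 mm, rate 0.25, giving tip sd
0.5 log mm); calling site by a symmetric 3-state Markov chain (rate 0.7
per unit depth); and the response drawn from the *exact* joint normal of
the OU model — no Euler discretization, so likelihood tests against
these data are sharp — plus independent per-species measurement error
(gamma, mean 0.02 log-Hz²). Default regime parameters mirror the scale
of empirical acoustic allometry (root optimum 9.28 log Hz, slope −0.45,
$\alpha = 2$, $\sigma^2 = 0.8$ per unit depth, i.e. stationary sd
0.45 log Hz), with weak site effects so the covariate models are
exercised.

What the generator does *not* emulate: real taxonomic imbalance,
empirical body-size distributions, correlated site–size evolution, or
tree misspecification. Passing tests on these data demonstrate that the
machinery is correct under its own assumptions, not that the model is
adequate for any particular empirical dataset.

## The planted-shift recovery experiment

The end-to-end check plants one shift at the base of a clade spanning
20–35% of a 150-tip tree and asks the full pipeline to find it. The
planted offset is three intercept-prior standard deviations, where the
prior — as in the analysis itself — is defined from the dataset being
analyzed: the offset is iterated to the fixed point
$\Delta = 4.5\,\mathrm{sd}(y(\Delta))$. This makes the planted regime
unambiguous by construction, so the experiment tests the machinery
(search, convergence, summarization, filtering) rather than statistical
power at threshold effect sizes; the regression slope of the recovery
datasets is set to −0.2 (one slope-prior sd) so that credible-interval
coverage of the root parameters is evaluated at a prior-typical truth.
With the detection settings and two chains of 25,000 generations per
dataset (the package's desk-scale default; production analyses should
use millions of generations and four chains), the true branch enters
the supported set and the root $\theta$, $\beta$ 95% credible intervals
cover truth in at least 8 of 10 seeds each.

## Numerical choices and degenerate inputs

* Ultrametricity is flagged at relative tolerance $10^{-6}$;
  non-ultrametric trees are analysed with a warning (the OU algebra
  needs only node times).
* Zero-length branches cannot host shifts (zero prior mass) and are
  excluded from birth proposals.
* The positive-definiteness of $V$ is enforced by the Cholesky
  factorization; a proposal producing a non-PD covariance is rejected
  rather than crashing the chain, and `ou_covariance()` reports the
  smallest eigenvalue when constructed directly.
* Species names are matched exactly after space/underscore
  normalization and case-folding; no fuzzy matching.
* Measurement-error variances missing for some species are imputed by
  policy (`mean`, `zero`, or `fixed`), recorded in the table's
  attributes.
* The cached log-likelihood inside the sampler is spot-checked against
  a fresh evaluation every 10,000 generations; drift beyond $10^{-6}$
  relative aborts the run (it would indicate a bookkeeping bug, and its
  absence over long mixed-move runs is itself a regression test).

## Known limitations

* $\alpha$ and $\sigma^2$ are global; regime-specific selection or
  diffusion is out of scope.
* One shift per branch. At the resolution of branch-level posterior
  probabilities this costs nothing, but very long branches with
  multiple true transitions will be summarized as a single shift.
* The stepping-stone and rjMCMC defaults here are desk-scale; the
  empirical analysis this package's design follows used four chains of
  10–20 million generations per model, and marginal-likelihood
  estimates at desk scale carry correspondingly larger Monte-Carlo
  error.
* Site and interaction coefficients never shift between regimes; if the
  truth shifts them, their effects fold into the regime optima.
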