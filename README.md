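# allomshift

Bayesian detection of adaptive shifts in evolutionary allometry on
phylogenies — built around the question of *allometric escape* in frog
acoustics: most frogs obey a shared scaling of call dominant frequency
with body size (bigger frogs call lower), but particular clades appear
to have jumped to a new optimum or slope of that relationship. The
package finds such shifts, quantifies their support, and corroborates
them with a frequentist phylogenetic ANCOVA.

## The model

Log dominant frequency `y` (log Hz) is regressed on log male body size
`x` (log mm) and calling site (aquatic / terrestrial / arboreal) under
a multi-optima Ornstein–Uhlenbeck process on a time-calibrated tree.
A configuration of `K` shift points on branches paints every lineage
into `K + 1` regimes, each with its own optimum intercept `θ_k` and
size slope `β_k`; selection strength `α` and diffusion `σ²` are global,
and per-species measurement error enters the covariance diagonal. The
expected tip value is the Hansen-weighted mixture

    E[y_i] = Σ_k W_ik(α) (θ_k + β_k x_i) + site terms,

and the likelihood is the exact multivariate normal with covariance
`V_ij = σ²/(2α) · exp(−α(T_i+T_j−2s_ij)) · (1 − exp(−2α s_ij))`.
Shift number, locations, and magnitudes are sampled by reversible-jump
MCMC; model forms (a) size, (b) size + site, (c) size + site +
site×size are compared by stepping-stone marginal likelihoods and Bayes
factors (BF > 10 = strong support); convergence is checked with
Gelman–Rubin R on branch shift probabilities; shifts with posterior
probability ≥ 0.7 subtending ≥ 4 species form the supported set; each
supported clade is re-tested by a Brownian-motion PGLS F-ratio test
(full model: own intercept and slope for the clade, 4 parameters;
reduced: 2).

## Worked example

Simulate a 60-tip dataset with one strong planted shift (offset 4.71
log Hz at the base of a 14-species clade, branch 80 of the simulated
tree), fit the size-only model with the detection settings, and
summarize:

```r
library(allomshift)

phy <- simulate_tree(sim_config(n_tips = 60, seed = 42))
cfg <- sim_config(n_tips = 60, tree = phy, shifts = shift_config(80, 0),
                  params = regime_params(theta = c(9.28, 13.99),
                                         beta_size = c(-0.2, -0.2),
                                         alpha = 2, sigma2 = 0.8),
                  seed = 42)
sim <- simulate_traits(phy, cfg)
pr  <- allom_priors(sim$table, K_prior = "poisson", K_lambda = 2,
                    alpha_prior  = list(type = "loguniform", min = 0.5, max = 100),
                    sigma2_prior = list(type = "loguniform", min = 1e-3, max = 10))
ch  <- run_analysis(phy, sim$table, model_spec("a"), pr,
                    n_chains = 2, seed = 1, generations = 20000,
                    thinning = 20, init = "informed")
gelman_r(ch)
summarize_shifts(ch, phy)
pancova(phy, sim$table, 80)
```

Output from this exact run:

```
Gelman-Rubin diagnostics: converged (threshold 1.1 )
  scalar R: K 1.004, alpha 1.007, sigma2 1.001, loglik 1.022
  scalar ESS: K 164, alpha 38, sigma2 55, loglik 27
  max branch R: 1.015 over 102 branches with sampled shifts
Posterior shift summary over 1500 pooled samples
  posterior mean K: 2.702
  supported shifts (pp >= 0.7 , >= 4 species): 80
    regime branch pp n_species theta_median theta_lo theta_hi beta_median
1     root     NA NA        46        8.702    7.608    9.618    -0.05510
2 shift_80     80  1        14       11.330   10.017   13.372     0.08208
Phylogenetic ANCOVA F-ratio test: F( 2 , 56 ) = 4.782 , p = 0.0121
```

The planted branch is recovered with posterior probability 1.00 and
passes the 4-species clade filter; the root regime's optimum (truth
9.28) and slope (truth −0.2) fall inside their 95% credible intervals;
and the pANCOVA corroborates the shift under the null-hypothesis test
(F-ratio between the 4-parameter full model and the 2-parameter reduced
model, p = 0.012). The shifted regime's own optimum (median 11.3,
planted 13.99) is shrunk toward the intercept prior, which is centred
on the overall mean log frequency — the planted value sits nearly three
prior standard deviations out.

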