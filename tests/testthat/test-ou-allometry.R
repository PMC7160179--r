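test_that("Hansen weights reproduce the hand-evaluated lineage integral", {
  # lineage of depth 2 with a shift at time 1, alpha = 1:
  # residual root weight e^-2; old regime e^-1 - e^-2; new regime 1 - e^-1
  phy <- ape::read.tree(text = "(A:2,B:2);")
  cfg <- shift_config(which(phy$tip.label == "A"), 0.5)
  W <- hansen_weights(phy, paint(phy, cfg), alpha = 1)
  expect_equal(W[1, ], c(exp(-2) + exp(-1) - exp(-2), 1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(W[1, 2], 0.6321206, tolerance = 1e-6)
  expect_equal(W[2, ], c(1, 0))
  expect_equal(rowSums(W), c(1, 1), tolerance = 1e-12)
})

test_that("weight rows sum to one and saturate correctly in alpha", {
  phy <- simulate_tree(sim_config(n_tips = 15, seed = 2))
  cfg <- rand_config(phy, 3, seed = 6)
  p <- paint(phy, cfg)
  for (alpha in c(0, 1e-6, 0.5, 2, 50)) {
    W <- hansen_weights(phy, p, alpha)
    expect_true(all(abs(rowSums(W) - 1) < 1e-10), info = paste("alpha", alpha))
    expect_true(all(W > -1e-12))
  }
  # alpha = 0: all weight on the root regime
  expect_equal(hansen_weights(phy, p, 0)[, 1], rep(1, 15))
  # very large alpha: all weight on each tip's terminal regime, with
  # alpha scaled so the shortest terminal regime segment saturates
  last_seg <- vapply(1:15, function(tp) {
    s <- p$segments[p$segments$tip == tp, ]
    s$t1[nrow(s)] - s$t0[nrow(s)]
  }, numeric(1))
  a_big <- 40 / min(last_seg)
  Wbig <- hansen_weights(phy, p, a_big)
  expect_equal(Wbig[cbind(1:15, p$tip_regime + 1)], rep(1, 15),
               tolerance = 1e-8)
})

test_that("OU covariance matches closed forms and the BM limit", {
  # single lineage, t = 1, alpha = 1, sigma2 = 2: V = 1 - e^-2
  phy1 <- ape::read.tree(text = "(A:1,B:1000);")
  V1 <- ou_covariance(phy1, 1, 2)
  expect_equal(V1[1, 1], 1 - exp(-2), tolerance = 1e-10)
  expect_equal(V1[1, 1], 0.8647, tolerance = 1e-4)

  phy <- tree3()
  # alpha below the threshold: exactly sigma2 * shared path lengths
  S <- unname(ape::vcv.phylo(phy))
  expect_equal(ou_covariance(phy, 0, 1.7), 1.7 * S, tolerance = 1e-12)
  # general alpha: entrywise closed form
  a <- 0.5
  V <- ou_covariance(phy, a, 1)
  tipd <- diag(S)
  Vb <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    Vb[i, j] <- 1 / (2 * a) * exp(-a * (tipd[i] + tipd[j] - 2 * S[i, j])) *
      (1 - exp(-2 * a * S[i, j]))
  expect_equal(V, Vb, tolerance = 1e-12)
  # measurement error adds to the diagonal only
  Vme <- ou_covariance(phy, a, 1, me = c(0.1, 0.2, 0.3))
  expect_equal(Vme - V, diag(c(0.1, 0.2, 0.3)), tolerance = 1e-12)
})

test_that("log-likelihood reproduces scalar normal densities", {
  phy1 <- ape::read.tree(text = "(A:1,B:1000);")
  tab <- trait_table(c("A", "B"), c(0, 0), c(0, 0),
                     rep("terrestrial", 2), c(0, 0))
  pars <- regime_params(0, 0, alpha = 1, sigma2 = 2)
  ll <- ou_loglik(phy1, tab, model_spec("a"), shift_config(), pars)
  # B is essentially at stationarity (var 1) with y = 0; A has var 1-e^-2
  vA <- 1 - exp(-2)
  expect_equal(ll, -0.5 * log(2 * pi * vA) - 0.5 * log(2 * pi),
               tolerance = 1e-6)
  expect_equal(-0.5 * log(2 * pi * vA), -0.8463, tolerance = 1e-4)
  # adding ME to bring A's variance to 1 gives the unit normal density
  tab2 <- tab; tab2$me_var <- c(exp(-2), 0)
  ll2 <- ou_loglik(phy1, tab2, model_spec("a"), shift_config(), pars)
  expect_equal(ll2, -0.5 * log(2 * pi) * 2, tolerance = 1e-6)
})

test_that("log-likelihood equals the dense brute-force oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(4:8, 1)
    phy <- if (seed %% 3 == 0) ape::rtree(n) else ape::rcoal(n)
    K <- sample(0:2, 1)
    cfg <- if (K == 0) shift_config() else rand_config(phy, K, seed)
    form <- c("a", "b", "c")[1 + seed %% 3]
    spec <- model_spec(form)
    pars <- rand_params(K, spec, seed)
    tab <- rand_table(phy, seed)
    expect_equal(ou_loglik(phy, tab, spec, cfg, pars),
                 oracle_loglik(phy, tab, spec, cfg, pars),
                 tolerance = 1e-8, info = paste("seed", seed, "form", form))
  }
})

test_that("BM limit matches an independent Brownian-motion fit", {
  skip_if_not_installed("phytools")
  set.seed(42)
  phy <- ape::rcoal(25)
  y <- as.numeric(ape::rTraitCont(phy, "BM", sigma = 0.6, root.value = 2))
  fit <- phytools::brownie.lite(phy, setNames(y, phy$tip.label))
  tab <- trait_table(phy$tip.label, y, rep(0, 25),
                     rep("terrestrial", 25), rep(0, 25))
  pars <- regime_params(theta = fit$a.single, beta_size = 0,
                        alpha = 0, sigma2 = fit$sig2.single)
  ll <- ou_loglik(phy, tab, model_spec("a"), shift_config(), pars)
  expect_equal(ll, fit$logL1, tolerance = 1e-6)
})

test_that("likelihood is invariant to regime relabeling", {
  phy <- simulate_tree(sim_config(n_tips = 10, seed = 4))
  cfg <- rand_config(phy, 2, seed = 3)
  spec <- model_spec("a")
  pars <- rand_params(2, spec, seed = 9)
  ll1 <- ou_loglik(phy, rand_table(phy, 5), spec, cfg, pars)
  # present the same shifts in reverse order; paint() canonicalizes by
  # preorder, so permuting the *input* order must not change anything
  cfg_r <- shift_config(rev(cfg$branch), rev(cfg$position))
  ll2 <- ou_loglik(phy, rand_table(phy, 5), spec, cfg_r, pars)
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("adding measurement error lowers a zero-residual tip's density", {
  phy1 <- ape::read.tree(text = "(A:1,B:1);")
  tab0 <- trait_table(c("A", "B"), c(0, 0), c(0, 0),
                      rep("terrestrial", 2), c(0, 0))
  tab1 <- tab0; tab1$me_var <- c(0.5, 0)
  pars <- regime_params(0, 0, alpha = 1, sigma2 = 1)
  ll0 <- ou_loglik(phy1, tab0, model_spec("a"), shift_config(), pars)
  ll1 <- ou_loglik(phy1, tab1, model_spec("a"), shift_config(), pars)
  expect_lt(ll1, ll0)   # wider variance, zero residual: lower peak density
})
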