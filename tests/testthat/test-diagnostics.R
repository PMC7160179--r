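test_that("PSRF is 1 for identical chains and large for separated ones", {
  phy <- simulate_tree(sim_config(n_tips = 10, seed = 1))
  sim <- simulate_traits(phy, sim_config(n_tips = 10, seed = 1))
  pr <- allom_priors(sim$table, K_max = 5)
  tr <- run_chain(phy, sim$table, model_spec("a"), pr,
                  generations = 4000, thinning = 10, seed = 1)
  dup <- gelman_r(list(tr, tr))
  expect_true(all(abs(dup$scalar_r - 1) < 1e-8, na.rm = TRUE))
  expect_equal(dup$verdict, "converged")

  # direct evaluation of the PSRF on separated normal samples
  set.seed(2)
  r_far <- allomshift:::psrf(list(rnorm(500, 0, 1), rnorm(500, 5, 1)))
  expect_gt(r_far, 1.1)
  r_same <- allomshift:::psrf(list(rnorm(2000), rnorm(2000)))
  expect_lt(r_same, 1.1)
})

test_that("chains from the same posterior converge below 1.1", {
  cfg <- sim_config(n_tips = 40, shifts = shift_config(), seed = 6)
  phy <- simulate_tree(cfg)
  sim <- simulate_traits(phy, cfg)
  ch <- run_analysis(phy, sim$table, model_spec("a"),
                     detection_priors(sim$table), n_chains = 2, seed = 3,
                     generations = 30000, thinning = 15,
                     init = "informed")
  dg <- gelman_r(ch)
  expect_equal(dg$verdict, "converged")
  expect_true(all(dg$scalar_r < 1.1))
  expect_true(all(dg$scalar_ess > 0))
  expect_true(all(dg$scalar_ess <= 2 * ch$traces[[1]]$n_samples))
})

test_that("gelman_r enforces its preconditions", {
  phy <- simulate_tree(sim_config(n_tips = 10, seed = 1))
  sim <- simulate_traits(phy, sim_config(n_tips = 10, seed = 1))
  pr <- allom_priors(sim$table, K_max = 2)
  tr <- run_chain(phy, sim$table, model_spec("a"), pr,
                  generations = 2000, thinning = 10, seed = 1)
  expect_error(gelman_r(list(tr)), "at least 2 chains")
  short <- run_chain(phy, sim$table, model_spec("a"), pr,
                     generations = 1000, thinning = 200, seed = 1)
  expect_error(gelman_r(list(short, short)), "at least 10")
})

test_that("shift summaries apply the support and clade-size filters", {
  phy <- simulate_tree(sim_config(n_tips = 30, seed = 12))
  sim <- simulate_traits(phy, sim_config(n_tips = 30, seed = 12))
  pr <- allom_priors(sim$table, K_max = 10)
  ch <- run_analysis(phy, sim$table, model_spec("a"), pr, n_chains = 2,
                     seed = 9, generations = 6000, thinning = 10)
  sm <- summarize_shifts(ch, phy)
  # the sum of branch probabilities is exactly the posterior mean K
  kbar <- mean(unlist(lapply(ch$traces, function(tr)
    allomshift:::post_burnin(tr)$K)))
  expect_equal(sm$mean_K, kbar, tolerance = 1e-12)
  # pooling order cannot matter
  sm_rev <- summarize_shifts(list(ch$traces[[2]], ch$traces[[1]]), phy)
  expect_equal(sm_rev$pp, sm$pp)
  expect_equal(sort(sm_rev$supported), sort(sm$supported))
  # supported sets are nested across thresholds and respect min_clade
  expect_true(all(sm$supported_09 %in% sm$supported))
  expect_true(all(sm$supported %in% sm$supported_05))
  idx <- allomshift:::tree_index(phy)
  if (length(sm$supported))
    expect_true(all(vapply(sm$supported, function(b)
      length(idx$tips_below[[b]]), integer(1)) >= 4))
  expect_true(all(sm$pp >= 0 & sm$pp <= 1))
})

test_that("boundary support values honour the threshold exactly", {
  # synthetic traces: branch 9 in 69% of samples, branch 12 in 100%
  phy <- simulate_tree(sim_config(n_tips = 8, seed = 5))
  template <- run_chain(phy,
                        simulate_traits(phy, sim_config(n_tips = 8,
                                                        seed = 5))$table,
                        model_spec("a"),
                        allom_priors(theta_mean = 8, theta_sd = 1,
                                     K_max = 3),
                        generations = 1000, thinning = 10, seed = 1,
                        burnin = 0)
  n <- template$n_samples
  idx <- allomshift:::tree_index(phy)
  big <- setdiff(which(vapply(idx$tips_below, length, integer(1)) >= 4),
                 idx$root)
  b_always <- big[1]; b_069 <- big[2]
  for (i in seq_len(n)) {
    br <- b_always
    if (i <= round(0.69 * n)) br <- c(br, b_069)
    template$samples$shift_branch[[i]] <- br
    template$samples$shift_pos[[i]] <- rep(0.5, length(br))
    template$samples$theta[[i]] <- rep(8, length(br) + 1)
    template$samples$beta_size[[i]] <- rep(0, length(br) + 1)
    template$samples$K[i] <- length(br)
  }
  sm <- summarize_shifts(list(template), phy, pp_threshold = 0.7)
  expect_equal(sm$pp[b_always], 1)
  expect_equal(sm$pp[b_069], 0.69)
  expect_true(b_always %in% sm$supported)
  expect_false(b_069 %in% sm$supported)     # 0.69 < 0.7 excluded
  # a clade of 3 or fewer species is filtered even at pp = 1
  small <- which(vapply(idx$tips_below, length, integer(1)) %in% 2:3)[1]
  for (i in seq_len(n)) {
    template$samples$shift_branch[[i]] <- small
    template$samples$shift_pos[[i]] <- 0.5
    template$samples$theta[[i]] <- c(8, 9)
    template$samples$beta_size[[i]] <- c(0, 0)
    template$samples$K[i] <- 1L
  }
  sm2 <- summarize_shifts(list(template), phy, pp_threshold = 0.7)
  expect_equal(sm2$pp[small], 1)
  expect_false(small %in% sm2$supported)
})

test_that("annotated trees carry branch probabilities as node labels", {
  phy <- simulate_tree(sim_config(n_tips = 12, seed = 3))
  sim <- simulate_traits(phy, sim_config(n_tips = 12, seed = 3))
  pr <- allom_priors(sim$table, K_max = 5)
  ch <- run_analysis(phy, sim$table, model_spec("a"), pr, n_chains = 2,
                     seed = 2, generations = 3000, thinning = 10)
  sm <- summarize_shifts(ch, phy)
  tf <- tempfile(fileext = ".nwk")
  write_annotated_tree(sm, phy, tf)
  back <- ape::read.tree(tf)
  expect_equal(length(back$node.label), phy$Nnode)
})
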