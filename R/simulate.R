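# Synthetic data with known ground truth, emulating the structure of the
# empirical inputs: an ultrametric tree, a Brownian-motion log body-size
# predictor, a 3-state calling-site covariate evolving by a symmetric
# Markov chain, and a log dominant-frequency response drawn from the
# exact multi-optima OU joint normal plus independent measurement error.

#' Simulation configuration
#'
#' Defaults describe the conditions the generator emulates: a Yule
#' tree rescaled to unit depth; a root regime with optimum 9.28 log Hz and
#' body-size slope -0.45 (the scale of empirical acoustic allometry in
#' frogs); OU selection strength 2 and diffusion variance 0.8 per unit
#' depth (stationary sd 0.45 log Hz); a body-size predictor with root
#' 4 log mm (~55 mm) and BM rate 0.25 (tip sd 0.5 log mm); weak global
#' site and site-by-size effects so models "b" and "c" are exercised;
#' and gamma-distributed per-species measurement-error variances with
#' mean 0.02 log-Hz^2.
#'
#' @param n_tips Number of tip species (>= 4).
#' @param tree `"yule"` or a fixed `phylo` object (used as-is).
#' @param birth Yule speciation rate (shape only; depth is rescaled).
#' @param depth Tree depth after rescaling (time units).
#' @param shifts A [shift_config()] of true shifts (`branch` ids refer to
#'   the simulated tree), or an integer K to place K random shifts on
#'   branches with probability proportional to branch length.
#' @param params A [regime_params()] with `K + 1` optima/slopes; defaults
#'   as above for K = 0.
#' @param x_root,x_rate Root value and BM rate of log body size.
#' @param site_rate Transition rate of the symmetric 3-state calling-site
#'   chain, per unit depth.
#' @param me Either `list(model = "gamma", shape =, mean =)` or
#'   `list(model = "fixed", value =)` for per-species measurement-error
#'   variances; `value = 0` gives error-free data.
#' @param seed Integer seed; every simulation product is reproducible
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tips = 150L, tree = "yule", birth = 1,
                       depth = 1, shifts = shift_config(),
                       params = NULL, x_root = 4, x_rate = 0.25,
                       site_rate = 0.7,
                       me = list(model = "gamma", shape = 2, mean = 0.02),
                       seed = 1L) {
  stopifnot(n_tips >= 4L, birth > 0, depth > 0, x_rate > 0,
            site_rate > 0)
  if (is.numeric(shifts) && length(shifts) == 1L)
    shifts <- list(random_K = as.integer(shifts))
  if (is.null(params)) {
    K <- if (inherits(shifts, "shift_config")) shifts$K
         else shifts$random_K
    params <- regime_params(theta = rep(9.28, K + 1L),
                            beta_size = rep(-0.45, K + 1L),
                            alpha = 2, sigma2 = 0.8,
                            beta_site = c(0.1, -0.1),
                            beta_inter = c(0.05, -0.05))
  }
  structure(list(n_tips = as.integer(n_tips), tree = tree, birth = birth,
                 depth = depth, shifts = shifts, params = params,
                 x_root = x_root, x_rate = x_rate, site_rate = site_rate,
                 me = me, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an ultrametric tree
#'
#' Pure-birth (Yule) tree with `n_tips` tips, rescaled so every
#' root-to-tip depth equals `config$depth`. A fixed `phylo` supplied in
#' the config is passed through unchanged.
#'
#' @param config A [sim_config()].
#' @return A `phylo` with the `"ultrametric"` attribute set.
#' @export
simulate_tree <- function(config) {
  if (inherits(config$tree, "phylo")) return(validate_tree(config$tree))
  set.seed(config$seed)
  phy <- ape::rphylo(config$n_tips, birth = config$birth, death = 0)
  d <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * (config$depth / d)
  phy$tip.label <- sprintf("sp%04d", seq_len(config$n_tips))
  validate_tree(phy)
}

# random shift placement: branches sampled without replacement with
# probability proportional to length, positions uniform
random_shifts <- function(phy, K) {
  idx <- tree_index(phy)
  if (K > nrow(idx$edge)) stop("more shifts than branches")
  e <- sample(nrow(idx$edge), K, prob = idx$elen)
  shift_config(idx$edge[e, 2L], stats::runif(K))
}

#' Simulate traits under the multi-optima OU allometric model
#'
#' Log body size evolves by Brownian motion; calling site by a symmetric
#' 3-state Markov chain; the log-frequency response is drawn from the
#' exact multivariate normal implied by the regime painting (mean from
#' Hansen weights, covariance from the OU process) with independent
#' measurement-error noise added per species. Sampling from the exact
#' joint normal avoids any time-discretization error, so likelihood-based
#' tests against these data are sharp.
#'
#' @param phy A `phylo`, typically from [simulate_tree()].
#' @param config A [sim_config()].
#' @return A list: `table` (a `trait_table`; `me_var` holds the true
#'   observation variances), `truth` (true shift config, painting, params,
#'   expected means), `tree`.
#' @export
simulate_traits <- function(phy, config) {
  set.seed(config$seed + 1L)
  n <- ape::Ntip(phy)
  shifts <- if (inherits(config$shifts, "shift_config")) config$shifts
            else random_shifts(phy, config$shifts$random_K)
  params <- config$params
  if (length(params$theta) != shifts$K + 1L)
    stop("params imply ", length(params$theta) - 1L,
         " shifts but config has ", shifts$K)

  x <- as.numeric(ape::rTraitCont(phy, model = "BM",
                                  sigma = sqrt(config$x_rate),
                                  root.value = config$x_root))
  site <- as.character(ape::rTraitDisc(phy, model = "ER",
                                       k = 3L, rate = config$site_rate,
                                       states = SITE_LEVELS,
                                       root.value = 1L))

  me_var <- switch(config$me$model,
    gamma = stats::rgamma(n, shape = config$me$shape,
                          scale = config$me$mean / config$me$shape),
    fixed = rep(config$me$value, n),
    stop("unknown me model ", config$me$model))

  painting <- paint(phy, shifts)
  W <- hansen_weights(phy, painting, params$alpha)
  D <- cbind(aquatic = as.numeric(site == "aquatic"),
             arboreal = as.numeric(site == "arboreal"))
  mu <- ou_mean(W, x, params, D)
  V <- ou_covariance(phy, params$alpha, params$sigma2, me = 0)
  y <- mu + as.vector(t(chol(V)) %*% stats::rnorm(n)) +
    stats::rnorm(n, 0, sqrt(me_var))

  table <- trait_table(phy$tip.label, log_df = y, log_size = x,
                       site = site, me_var = me_var)
  list(table = table,
       truth = list(shifts = shifts, params = params,
                    painting = painting, expected_mean = mu,
                    tip_regime = painting$tip_regime,
                    seed = config$seed),
       tree = phy)
}

#' Simulate a complete dataset and optionally write it to disk
#'
#' Runs [simulate_tree()] and [simulate_traits()] and, when `dir` is
#' given, writes the same formats the readers consume: `tree.nwk`
#' (Newick), `traits.csv` (raw scale: Hz and mm), and `truth.json`.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory (created if missing).
#' @return The [simulate_traits()] result, invisibly when writing.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  phy <- simulate_tree(config)
  sim <- simulate_traits(phy, config)
  if (is.null(dir)) return(sim)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tree(phy, file.path(dir, "tree.nwk"))
  raw <- data.frame(species = sim$table$species,
                    dominant_frequency_hz = exp(sim$table$log_df),
                    svl_mm = exp(sim$table$log_size),
                    calling_site = as.character(sim$table$site),
                    me_var = sim$table$me_var)
  write_traits(raw, file.path(dir, "traits.csv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(shift_branch = truth$shifts$branch,
         shift_position = truth$shifts$position,
         theta = truth$params$theta,
         beta_size = truth$params$beta_size,
         beta_site = truth$params$beta_site,
         beta_inter = truth$params$beta_inter,
         alpha = truth$params$alpha, sigma2 = truth$params$sigma2,
         seed = config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(sim)
}
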