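# Reversible-jump MCMC over shift configurations and regime parameters.
#
# The trans-dimensional bookkeeping follows the standard prior-draw birth
# scheme: a birth draws the new regime's optimum and slope from their
# priors, so those densities cancel from the acceptance ratio and the
# Jacobian is 1. The configuration prior "branch chosen proportional to
# length, one shift per branch" is normalized exactly with elementary
# symmetric polynomials e_K of the branch lengths (computed once per tree
# in log space), so the marginal prior on K is exactly the K prior.

# log elementary symmetric polynomials e_0..e_kmax of lengths (log scale)
log_esp <- function(log_len, kmax) {
  le <- c(0, rep(-Inf, kmax))           # le[k+1] = log e_k
  for (ll in log_len) {
    hi <- 2:(kmax + 1L)
    prev <- le[hi - 1L] + ll
    le[hi] <- pmax(le[hi], prev) +
      log1p(exp(-abs(le[hi] - prev)))
    le[is.nan(le)] <- -Inf
  }
  le
}

# painting quantities the sampler needs, with regimes in *state order*
# (regime j = j-th shift of the current state; no canonicalization)
paint_light <- function(idx, branch, pos) {
  K <- length(branch)
  node_regime <- integer(idx$n_all)
  if (K) {
    eidx <- idx$edge_of[branch]
    shift_on_edge <- integer(nrow(idx$edge))
    shift_on_edge[eidx] <- seq_len(K)
    for (i in seq_len(nrow(idx$edge))) {
      s <- shift_on_edge[i]
      node_regime[idx$edge[i, 2L]] <-
        if (s > 0L) s else node_regime[idx$edge[i, 1L]]
    }
    shift_time <- idx$depth[idx$parent[branch]] + pos * idx$elen[eidx]
    src <- node_regime[idx$parent[branch]]
  } else {
    shift_time <- numeric(0); src <- integer(0)
  }
  list(tip_regime = node_regime[seq_len(idx$n_tip)],
       shift_branch = branch, shift_time = shift_time,
       shift_src_regime = src, n_regimes = K + 1L)
}

default_control <- function() {
  list(move_probs = c(birth = 0.15, death = 0.15, relocate = 0.10,
                      theta = 0.15, beta = 0.075, slide = 0.075,
                      alpha = 0.075, relax = 0.075, sigma2 = 0.15),
       theta_step = NULL,      # defaults to 0.5 * theta prior sd
       beta_step = NULL,       # defaults to 0.5 * slope prior sd
       alpha_step = 0.6, sigma2_step = 0.6, relax_step = 0.4,
       slide_step = NULL,      # defaults to beta_step
       adapt_interval = 200L, adapt_target = 0.3,
       check_interval = 10000L)
}

#' Data-informed starting state for the sampler
#'
#' Builds a heuristic initial state: ordinary least squares gives starting
#' intercept and slope; branches whose clades show a strong contrast in
#' the OLS residuals (Welch-type statistic above `t_threshold`, clade size
#' between `min_clade` and half the tips) seed initial shifts, greedily
#' and disjointly, largest contrast first; `alpha` starts at a phylogenetic
#' half-life of half the tree depth and `sigma2` at the value whose
#' stationary variance matches the residual variance. A heuristic start
#' only shortens the transient — the stationary distribution is
#' unaffected — but it avoids the slowly-mixing basin where a weak-
#' selection state must discover shifts through prior-draw births.
#'
#' @param phy A `phylo` object.
#' @param table A `trait_table` aligned to `phy`.
#' @param max_shifts Maximum number of seeded shifts.
#' @param t_threshold Residual-contrast statistic required to seed a
#'   shift.
#' @param min_clade Smallest clade size considered.
#' @return An `init` list for [run_chain()].
#' @export
informed_init <- function(phy, table, max_shifts = 3L, t_threshold = 3,
                          min_clade = 4L) {
  idx <- tree_index(phy)
  n <- idx$n_tip
  fit <- stats::lm(table$log_df ~ table$log_size)
  r <- stats::residuals(fit)
  sizes <- vapply(idx$tips_below, length, integer(1))
  cand <- setdiff(which(sizes >= min_clade & sizes <= n %/% 2L), idx$root)
  tstat <- vapply(cand, function(b) {
    inb <- idx$tips_below[[b]]
    a <- r[inb]; o <- r[-inb]
    se <- sqrt(stats::var(a) / length(a) + stats::var(o) / length(o))
    if (!is.finite(se) || se == 0) return(0)
    abs(mean(a) - mean(o)) / se
  }, numeric(1))
  ord <- cand[order(tstat, decreasing = TRUE)]
  tstat <- tstat[order(tstat, decreasing = TRUE)]
  picked <- integer(0)
  for (i in seq_along(ord)) {
    if (length(picked) >= max_shifts || tstat[i] < t_threshold) break
    b <- ord[i]
    overlap <- any(vapply(picked, function(p)
      length(intersect(idx$tips_below[[p]], idx$tips_below[[b]])) > 0,
      logical(1)))
    if (!overlap) picked <- c(picked, b)
  }
  depth <- max(idx$tip_depth)
  alpha0 <- log(2) / (0.5 * depth)
  theta0 <- unname(stats::coef(fit)[1L])
  beta0 <- unname(stats::coef(fit)[2L])
  theta <- c(theta0, vapply(picked, function(b)
    theta0 + mean(r[idx$tips_below[[b]]]), numeric(1)))
  list(branch = picked, pos = rep(0.5, length(picked)),
       theta = theta, beta_size = rep(beta0, length(picked) + 1L),
       alpha = alpha0,
       sigma2 = max(stats::var(r), 1e-4) * 2 * alpha0)
}

#' Run one reversible-jump MCMC chain
#'
#' Samples the joint posterior of the shift configuration (number,
#' branches, positions) and the regime parameters under the multi-optima
#' OU allometric regression. Move mix: birth / death / relocate of shifts
#' plus random-walk updates of optima and slopes and log-scale multiplier
#' updates of `alpha` and `sigma2`. Random-walk step sizes adapt toward
#' their target acceptance rate during burn-in only and are frozen
#' afterwards, preserving detailed balance for the retained samples.
#'
#' @param phy A `phylo` object.
#' @param table A `trait_table` aligned to `phy` (see [reconcile()]).
#' @param spec A [model_spec()].
#' @param priors An [allom_priors()].
#' @param generations Number of MCMC generations.
#' @param thinning Record every `thinning`-th generation.
#' @param seed Integer RNG seed; traces are bit-reproducible given the
#'   seed.
#' @param burnin Fraction of generations treated as burn-in (adaptation
#'   window; downstream summaries drop these samples).
#' @param power Likelihood power (1 = posterior, 0 = prior-only run as in
#'   the no-data prior check; intermediate values are used by the
#'   stepping-stone ladder).
#' @param init Optional initial state: a list with any of `branch`, `pos`,
#'   `theta`, `beta_size`, `beta_site`, `beta_inter`, `alpha`, `sigma2`.
#' @param control List of sampler controls; see `default_control` in the
#'   package source (move probabilities, step sizes, adaptation interval).
#' @param quiet Suppress progress messages.
#' @return An object of class `allom_trace`.
#' @export
run_chain <- function(phy, table, spec, priors, generations = 100000L,
                      thinning = 100L, seed = 1L, burnin = 0.25,
                      power = 1, init = NULL, control = list(),
                      quiet = TRUE) {
  stopifnot(inherits(priors, "allom_priors"), inherits(spec, "model_spec"),
            generations >= thinning, burnin >= 0, burnin < 1)
  ctl <- utils::modifyList(default_control(), control)
  if (is.null(ctl$theta_step)) ctl$theta_step <- 0.5 * priors$theta_sd
  if (is.null(ctl$beta_step))
    ctl$beta_step <- 0.5 * max(priors$slope_sd, 1e-3)
  if (is.null(ctl$slide_step)) ctl$slide_step <- ctl$beta_step
  set.seed(seed)

  idx <- tree_index(phy)
  n <- idx$n_tip
  if (nrow(table) != n) stop("table rows must match tree tips")
  y <- table$log_df; x <- table$log_size
  me <- ifelse(is.na(table$me_var), 0, table$me_var)
  D <- site_dummies(table)
  S <- shared_path_matrix(idx$phy)
  use_lik <- power > 0

  fx <- priors$fixed
  K_max <- min(priors$K_max, nrow(idx$edge))
  log_elen <- log(idx$elen)
  le <- log_esp(log_elen[is.finite(log_elen)], K_max)
  # zero-length branches can never host a shift (prior mass zero)
  eligible <- which(idx$elen > 0)

  beta_fixed <- !is.null(fx$beta_size)
  alpha_fixed <- !is.null(fx$alpha)
  sigma2_fixed <- !is.null(fx$sigma2)
  site_fixed <- !is.null(fx$beta_site)
  inter_fixed <- !is.null(fx$beta_inter)

  # --- initial state ----------------------------------------------------
  st <- list(branch = integer(0), pos = numeric(0),
             theta = stats::rnorm(1, priors$theta_mean, priors$theta_sd),
             beta = if (beta_fixed) fx$beta_size
                    else stats::rnorm(1, 0, priors$slope_sd),
             beta_site = if (!spec$has_site) NULL
                         else if (site_fixed) fx$beta_site
                         else stats::rnorm(2, 0, priors$slope_sd),
             beta_inter = if (!spec$has_inter) NULL
                          else if (inter_fixed) fx$beta_inter
                          else stats::rnorm(2, 0, priors$slope_sd),
             alpha = if (alpha_fixed) fx$alpha
                     else sample_prior_positive(priors$alpha_prior),
             sigma2 = if (sigma2_fixed) fx$sigma2
                      else sample_prior_positive(priors$sigma2_prior))
  if (identical(init, "informed")) init <- informed_init(idx$phy, table)
  if (!is.null(init)) for (nm in names(init)) {
    key <- if (nm == "beta_size") "beta" else nm
    st[[key]] <- init[[nm]]
  }
  # keep starting values inside bounded prior support
  clamp <- function(x, spec) if (spec$type == "loguniform")
    min(max(x, spec$min), spec$max) else x
  if (!alpha_fixed) st$alpha <- clamp(st$alpha, priors$alpha_prior)
  if (!sigma2_fixed) st$sigma2 <- clamp(st$sigma2, priors$sigma2_prior)
  st$branch <- as.integer(st$branch)
  K <- length(st$branch)
  if (length(st$theta) != K + 1L)
    st$theta <- c(st$theta,
                  stats::rnorm(K + 1L - length(st$theta),
                               priors$theta_mean, priors$theta_sd))
  if (length(st$beta) != K + 1L)
    st$beta <- if (beta_fixed) rep(fx$beta_size, K + 1L)
               else c(st$beta, stats::rnorm(K + 1L - length(st$beta),
                                            0, priors$slope_sd))

  # --- cached quantities -------------------------------------------------
  params_of <- function(st)
    list(theta = st$theta, beta_size = st$beta,
         beta_site = if (spec$has_site) st$beta_site,
         beta_inter = if (spec$has_inter) st$beta_inter)
  recompute_mu <- function(st, W)
    ou_mean(W, x, params_of(st), D)
  make_chol <- function(G, sigma2) {
    V <- sigma2 * G
    diag(V) <- diag(V) + me
    tryCatch(chol(V), error = function(e) NULL)
  }
  lp_config <- function(branch) {
    K <- length(branch)
    log_dprior_K(K, priors) +
      (if (K) sum(log_elen[idx$edge_of[branch]]) else 0) - le[K + 1L]
  }
  lp_params <- function(st) {
    lp <- log_dprior_theta(st$theta, priors)
    if (!beta_fixed) lp <- lp + log_dprior_slope(st$beta, priors)
    if (spec$has_site && !site_fixed)
      lp <- lp + log_dprior_slope(st$beta_site, priors)
    if (spec$has_inter && !inter_fixed)
      lp <- lp + log_dprior_slope(st$beta_inter, priors)
    if (!alpha_fixed)
      lp <- lp + log_dprior_positive(st$alpha, priors$alpha_prior)
    if (!sigma2_fixed)
      lp <- lp + log_dprior_positive(st$sigma2, priors$sigma2_prior)
    lp
  }
  loglik_of <- function(mu, R) if (use_lik) mvn_loglik_chol(y - mu, R) else 0

  pl <- paint_light(idx, st$branch, st$pos)
  G <- ou_cov_from_S(S, st$alpha, 1)
  R <- make_chol(G, st$sigma2)
  if (is.null(R)) stop("initial covariance not positive definite")
  W <- hansen_weights_fast(idx, pl, st$alpha)
  mu <- recompute_mu(st, W)
  cur <- list(st = st, pl = pl, G = G, R = R, W = W, mu = mu,
              ll = loglik_of(mu, R),
              lp = lp_params(st) + lp_config(st$branch))

  # --- move machinery ----------------------------------------------------
  mp <- ctl$move_probs
  if (beta_fixed && !spec$has_site && !spec$has_inter) mp["beta"] <- 0
  if (beta_fixed) mp["slide"] <- 0
  if (alpha_fixed) mp["alpha"] <- 0
  if (sigma2_fixed) mp["sigma2"] <- 0
  if (alpha_fixed || sigma2_fixed) mp["relax"] <- 0
  if (K_max == 0L) mp[c("birth", "death", "relocate")] <- 0
  mp <- mp / sum(mp)
  move_names <- names(mp)
  prop_n <- acc_n <- stats::setNames(numeric(length(mp)), move_names)

  n_keep <- generations %/% thinning
  tr <- list(gen = integer(n_keep), K = integer(n_keep),
             alpha = numeric(n_keep), sigma2 = numeric(n_keep),
             loglik = numeric(n_keep), logprior = numeric(n_keep),
             shift_branch = vector("list", n_keep),
             shift_pos = vector("list", n_keep),
             theta = vector("list", n_keep),
             beta_size = vector("list", n_keep),
             beta_site = vector("list", n_keep),
             beta_inter = vector("list", n_keep))
  keep_i <- 0L
  burn_gens <- floor(burnin * generations)
  window_acc <- stats::setNames(numeric(length(mp)), move_names)
  window_prop <- window_acc

  free_edges <- function(branch)
    if (length(branch)) setdiff(eligible, idx$edge_of[branch]) else eligible

  for (gen in seq_len(generations)) {
    mv <- sample(move_names, 1L, prob = mp)
    prop_n[mv] <- prop_n[mv] + 1; window_prop[mv] <- window_prop[mv] + 1
    st <- cur$st
    K <- length(st$branch)
    accepted <- FALSE

    if (mv == "birth") {
      free <- free_edges(st$branch)
      if (K < K_max && length(free)) {
        lf <- idx$elen[free]
        e_new <- if (length(free) == 1L) free else
          sample(free, 1L, prob = lf)
        b_new <- idx$edge[e_new, 2L]
        p_new <- stats::runif(1)
        th_new <- stats::rnorm(1, priors$theta_mean, priors$theta_sd)
        be_new <- if (beta_fixed) fx$beta_size
                  else stats::rnorm(1, 0, priors$slope_sd)
        ns <- st
        ns$branch <- c(st$branch, b_new); ns$pos <- c(st$pos, p_new)
        ns$theta <- c(st$theta, th_new); ns$beta <- c(st$beta, be_new)
        npl <- paint_light(idx, ns$branch, ns$pos)
        nW <- hansen_weights_fast(idx, npl, st$alpha)
        nmu <- recompute_mu(ns, nW)
        nll <- loglik_of(nmu, cur$R)
        nlp <- lp_params(ns) + lp_config(ns$branch)
        lq_f <- log(idx$elen[e_new] / sum(lf)) +
          stats::dnorm(th_new, priors$theta_mean, priors$theta_sd,
                       log = TRUE) +
          (if (beta_fixed) 0
           else stats::dnorm(be_new, 0, priors$slope_sd, log = TRUE))
        lq_r <- -log(K + 1)
        la <- power * (nll - cur$ll) + (nlp - cur$lp) + lq_r - lq_f
        if (is.finite(la) && log(stats::runif(1)) < la) {
          cur$st <- ns; cur$pl <- npl; cur$W <- nW; cur$mu <- nmu
          cur$ll <- nll; cur$lp <- nlp
          accepted <- TRUE
        }
      }
    } else if (mv == "death") {
      if (K > 0L) {
        j <- if (K == 1L) 1L else sample.int(K, 1L)
        ns <- st
        ns$branch <- st$branch[-j]; ns$pos <- st$pos[-j]
        ns$theta <- st$theta[-(j + 1L)]; ns$beta <- st$beta[-(j + 1L)]
        npl <- paint_light(idx, ns$branch, ns$pos)
        nW <- hansen_weights_fast(idx, npl, st$alpha)
        nmu <- recompute_mu(ns, nW)
        nll <- loglik_of(nmu, cur$R)
        nlp <- lp_params(ns) + lp_config(ns$branch)
        free_new <- free_edges(ns$branch)
        e_old <- idx$edge_of[st$branch[j]]
        lq_f <- -log(K)
        lq_r <- log(idx$elen[e_old] / sum(idx$elen[free_new])) +
          stats::dnorm(st$theta[j + 1L], priors$theta_mean,
                       priors$theta_sd, log = TRUE) +
          (if (beta_fixed) 0
           else stats::dnorm(st$beta[j + 1L], 0, priors$slope_sd,
                             log = TRUE))
        la <- power * (nll - cur$ll) + (nlp - cur$lp) + lq_r - lq_f
        if (is.finite(la) && log(stats::runif(1)) < la) {
          cur$st <- ns; cur$pl <- npl; cur$W <- nW; cur$mu <- nmu
          cur$ll <- nll; cur$lp <- nlp
          accepted <- TRUE
        }
      }
    } else if (mv == "relocate") {
      if (K > 0L) {
        j <- if (K == 1L) 1L else sample.int(K, 1L)
        avail <- c(free_edges(st$branch), idx$edge_of[st$branch[j]])
        la_len <- idx$elen[avail]
        e_new <- if (length(avail) == 1L) avail else
          sample(avail, 1L, prob = la_len)
        ns <- st
        ns$branch[j] <- idx$edge[e_new, 2L]
        ns$pos[j] <- stats::runif(1)
        npl <- paint_light(idx, ns$branch, ns$pos)
        nW <- hansen_weights_fast(idx, npl, st$alpha)
        nmu <- recompute_mu(ns, nW)
        nll <- loglik_of(nmu, cur$R)
        nlp <- lp_params(ns) + lp_config(ns$branch)
        # proposal ratio l_old/l_new cancels the config-prior ratio
        la <- power * (nll - cur$ll) + (nlp - cur$lp) +
          log(idx$elen[idx$edge_of[st$branch[j]]]) - log(idx$elen[e_new])
        if (is.finite(la) && log(stats::runif(1)) < la) {
          cur$st <- ns; cur$pl <- npl; cur$W <- nW; cur$mu <- nmu
          cur$ll <- nll; cur$lp <- nlp
          accepted <- TRUE
        }
      }
    } else if (mv == "theta") {
      k <- if (K == 0L) 1L else sample.int(K + 1L, 1L)
      dth <- stats::rnorm(1, 0, ctl$theta_step)
      ns <- st; ns$theta[k] <- st$theta[k] + dth
      nmu <- cur$mu + cur$W[, k] * dth
      nll <- loglik_of(nmu, cur$R)
      dlp <- stats::dnorm(ns$theta[k], priors$theta_mean, priors$theta_sd,
                          log = TRUE) -
             stats::dnorm(st$theta[k], priors$theta_mean, priors$theta_sd,
                          log = TRUE)
      la <- power * (nll - cur$ll) + dlp
      if (is.finite(la) && log(stats::runif(1)) < la) {
        cur$st <- ns; cur$mu <- nmu; cur$ll <- nll; cur$lp <- cur$lp + dlp
        accepted <- TRUE
      }
    } else if (mv == "beta") {
      # choose uniformly among all free slope-type coefficients
      n_slope <- if (beta_fixed) 0L else K + 1L
      n_site <- if (spec$has_site && !site_fixed) 2L else 0L
      n_inter <- if (spec$has_inter && !inter_fixed) 2L else 0L
      tot <- n_slope + n_site + n_inter
      if (tot > 0L) {
        pick <- if (tot == 1L) 1L else sample.int(tot, 1L)
        db <- stats::rnorm(1, 0, ctl$beta_step)
        ns <- st
        if (pick <= n_slope) {
          k <- pick
          ns$beta[k] <- st$beta[k] + db
          old <- st$beta[k]; new <- ns$beta[k]
          nmu <- cur$mu + x * cur$W[, k] * db
        } else if (pick <= n_slope + n_site) {
          jj <- pick - n_slope
          ns$beta_site[jj] <- st$beta_site[jj] + db
          old <- st$beta_site[jj]; new <- ns$beta_site[jj]
          nmu <- cur$mu + D[, jj] * db
        } else {
          jj <- pick - n_slope - n_site
          ns$beta_inter[jj] <- st$beta_inter[jj] + db
          old <- st$beta_inter[jj]; new <- ns$beta_inter[jj]
          nmu <- cur$mu + x * D[, jj] * db
        }
        nll <- loglik_of(nmu, cur$R)
        dlp <- stats::dnorm(new, 0, priors$slope_sd, log = TRUE) -
               stats::dnorm(old, 0, priors$slope_sd, log = TRUE)
        la <- power * (nll - cur$ll) + dlp
        if (is.finite(la) && log(stats::runif(1)) < la) {
          cur$st <- ns; cur$mu <- nmu; cur$ll <- nll
          cur$lp <- cur$lp + dlp
          accepted <- TRUE
        }
      }
    } else if (mv == "slide") {
      # shear along the intercept-slope ridge of one regime: beta_k and
      # theta_k trade off through the regime's weighted mean body size,
      # so moving both keeps the fitted means nearly unchanged
      if (!beta_fixed) {
        k <- if (K == 0L) 1L else sample.int(K + 1L, 1L)
        wk <- cur$W[, k]
        sw <- sum(wk)
        xbar <- if (sw > 1e-12) sum(wk * x) / sw else mean(x)
        db <- stats::rnorm(1, 0, ctl$slide_step)
        ns <- st
        ns$beta[k] <- st$beta[k] + db
        ns$theta[k] <- st$theta[k] - db * xbar
        nmu <- cur$mu + db * wk * (x - xbar)
        nll <- loglik_of(nmu, cur$R)
        dlp <- stats::dnorm(ns$beta[k], 0, priors$slope_sd, log = TRUE) -
               stats::dnorm(st$beta[k], 0, priors$slope_sd, log = TRUE) +
               stats::dnorm(ns$theta[k], priors$theta_mean, priors$theta_sd,
                            log = TRUE) -
               stats::dnorm(st$theta[k], priors$theta_mean, priors$theta_sd,
                            log = TRUE)
        la <- power * (nll - cur$ll) + dlp
        if (is.finite(la) && log(stats::runif(1)) < la) {
          cur$st <- ns; cur$mu <- nmu; cur$ll <- nll
          cur$lp <- cur$lp + dlp
          accepted <- TRUE
        }
      }
    } else if (mv == "alpha") {
      a_new <- st$alpha * exp(ctl$alpha_step * stats::rnorm(1))
      dlp <- log_dprior_positive(a_new, priors$alpha_prior) -
             log_dprior_positive(st$alpha, priors$alpha_prior)
      if (is.finite(dlp)) {
        nG <- ou_cov_from_S(S, a_new, 1)
        nR <- make_chol(nG, st$sigma2)
        if (!is.null(nR)) {
          nW <- hansen_weights_fast(idx, cur$pl, a_new)
          ns <- st; ns$alpha <- a_new
          nmu <- recompute_mu(ns, nW)
          nll <- loglik_of(nmu, nR)
          la <- power * (nll - cur$ll) + dlp + log(a_new) - log(st$alpha)
          if (is.finite(la) && log(stats::runif(1)) < la) {
            cur$st <- ns; cur$G <- nG; cur$R <- nR; cur$W <- nW
            cur$mu <- nmu; cur$ll <- nll; cur$lp <- cur$lp + dlp
            accepted <- TRUE
          }
        }
      }
    } else if (mv == "relax") {
      # joint multiplier on (alpha, sigma2): travels along the ridge where
      # selection strength and diffusion trade off at fixed stationary
      # variance sigma2 / (2 alpha)
      eps <- ctl$relax_step * stats::rnorm(1)
      a_new <- st$alpha * exp(eps)
      s_new <- st$sigma2 * exp(eps)
      dlp <- log_dprior_positive(a_new, priors$alpha_prior) -
             log_dprior_positive(st$alpha, priors$alpha_prior) +
             log_dprior_positive(s_new, priors$sigma2_prior) -
             log_dprior_positive(st$sigma2, priors$sigma2_prior)
      if (is.finite(dlp)) {
        nG <- ou_cov_from_S(S, a_new, 1)
        nR <- make_chol(nG, s_new)
        if (!is.null(nR)) {
          nW <- hansen_weights_fast(idx, cur$pl, a_new)
          ns <- st; ns$alpha <- a_new; ns$sigma2 <- s_new
          nmu <- recompute_mu(ns, nW)
          nll <- loglik_of(nmu, nR)
          la <- power * (nll - cur$ll) + dlp + 2 * eps
          if (is.finite(la) && log(stats::runif(1)) < la) {
            cur$st <- ns; cur$G <- nG; cur$R <- nR; cur$W <- nW
            cur$mu <- nmu; cur$ll <- nll; cur$lp <- cur$lp + dlp
            accepted <- TRUE
          }
        }
      }
    } else if (mv == "sigma2") {
      s_new <- st$sigma2 * exp(ctl$sigma2_step * stats::rnorm(1))
      dlp <- log_dprior_positive(s_new, priors$sigma2_prior) -
             log_dprior_positive(st$sigma2, priors$sigma2_prior)
      if (is.finite(dlp)) {
        nR <- make_chol(cur$G, s_new)
        if (!is.null(nR)) {
          ns <- st; ns$sigma2 <- s_new
          nll <- loglik_of(cur$mu, nR)
          la <- power * (nll - cur$ll) + dlp + log(s_new) - log(st$sigma2)
          if (is.finite(la) && log(stats::runif(1)) < la) {
            cur$st <- ns; cur$R <- nR; cur$ll <- nll
            cur$lp <- cur$lp + dlp
            accepted <- TRUE
          }
        }
      }
    }

    if (accepted) {
      acc_n[mv] <- acc_n[mv] + 1; window_acc[mv] <- window_acc[mv] + 1
    }

    # adapt random-walk step sizes during burn-in only
    if (gen <= burn_gens && gen %% ctl$adapt_interval == 0L) {
      for (m in c("theta", "beta", "slide", "alpha", "sigma2", "relax")) {
        if (window_prop[m] >= 10) {
          rate <- window_acc[m] / window_prop[m]
          fac <- exp(0.6 * (rate - ctl$adapt_target))
          key <- paste0(m, "_step")
          ctl[[key]] <- max(1e-6, min(1e3, ctl[[key]] * fac))
        }
      }
      window_acc[] <- 0; window_prop[] <- 0
    }

    # integrity spot-check of the cached likelihood
    if (use_lik && gen %% ctl$check_interval == 0L) {
      ref <- mvn_loglik_chol(y - recompute_mu(cur$st, cur$W), cur$R)
      if (abs(ref - cur$ll) > 1e-6 * max(1, abs(ref)))
        stop("internal error: cached log-likelihood drifted")
      cur$ll <- ref
    }

    if (gen %% thinning == 0L) {
      keep_i <- keep_i + 1L
      s <- cur$st
      tr$gen[keep_i] <- gen
      tr$K[keep_i] <- length(s$branch)
      tr$alpha[keep_i] <- s$alpha
      tr$sigma2[keep_i] <- s$sigma2
      tr$loglik[keep_i] <- cur$ll
      tr$logprior[keep_i] <- cur$lp
      tr$shift_branch[[keep_i]] <- s$branch
      tr$shift_pos[[keep_i]] <- s$pos
      tr$theta[[keep_i]] <- s$theta
      tr$beta_size[[keep_i]] <- s$beta
      tr$beta_site[keep_i] <- list(s$beta_site)
      tr$beta_inter[keep_i] <- list(s$beta_inter)
    }
    if (!quiet && gen %% 50000L == 0L)
      message("gen ", gen, " K=", length(cur$st$branch),
              " ll=", round(cur$ll, 2))
  }

  structure(list(samples = tr, n_samples = n_keep,
                 generations = generations, thinning = thinning,
                 burnin = burnin, seed = seed, power = power,
                 spec = spec, priors = priors,
                 n_tip = n, n_edge = nrow(idx$edge),
                 tree_hash = hash_tree(idx$phy),
                 acceptance = data.frame(move = move_names,
                                         proposed = as.numeric(prop_n),
                                         accepted = as.numeric(acc_n)),
                 steps = ctl[c("theta_step", "beta_step", "slide_step",
                               "alpha_step", "sigma2_step", "relax_step")]),
            class = "allom_trace")
}

#' @export
print.allom_trace <- function(x, ...) {
  cat("allom_trace:", x$n_samples, "samples (thinning", x$thinning,
      ", burn-in", paste0(100 * x$burnin, "%"), ", seed", x$seed, ")\n")
  post <- post_burnin(x)
  cat("  posterior mean K:", round(mean(post$K), 3),
      " mean log-lik:", round(mean(post$loglik), 2), "\n")
  invisible(x)
}

# post-burn-in sample indices / subset
post_burnin_idx <- function(trace)
  which(trace$samples$gen > trace$burnin * trace$generations)

post_burnin <- function(trace) {
  i <- post_burnin_idx(trace)
  lapply(trace$samples, function(v) if (is.list(v)) v[i] else v[i])
}

hash_tree <- function(phy) {
  tf <- tempfile(fileext = ".nwk")
  on.exit(unlink(tf))
  ape::write.tree(phy, tf)
  unname(tools::md5sum(tf))
}

#' Run several independent chains
#'
#' Runs `n_chains` chains with consecutive seeds (`seed`, `seed + 1`, ...)
#' and collects them for convergence assessment. A single chain is allowed
#' but flagged, since the Gelman-Rubin diagnostic needs at least two.
#'
#' @inheritParams run_chain
#' @param n_chains Number of chains (default 4).
#' @param init Starting state as in [run_chain()]; with `"informed"`,
#'   chains after the first jitter the starting parameters (optima by
#'   half a prior sd, selection strength by up to a factor 2, shift
#'   positions resampled) so starting points are dispersed while every
#'   chain remains free to keep or discard the seeded shifts.
#' @param ... Passed on to [run_chain()].
#' @return An object of class `allom_chains`: list of `allom_trace` plus
#'   shared metadata.
#' @export
run_analysis <- function(phy, table, spec, priors, n_chains = 4L,
                         seed = 1L, init = NULL, ...) {
  informed <- identical(init, "informed")
  if (informed) init <- informed_init(phy, table)
  traces <- lapply(seq_len(n_chains), function(i) {
    ci <- init
    if (informed && i > 1L) {
      set.seed(seed + i - 1L)
      m <- length(ci$branch)
      ci$theta <- ci$theta + stats::rnorm(m + 1L, 0, 0.5 * priors$theta_sd)
      ci$beta_size <- ci$beta_size +
        stats::rnorm(m + 1L, 0, 0.5 * priors$slope_sd)
      ci$alpha <- ci$alpha * exp(stats::runif(1, -0.7, 0.7))
      ci$sigma2 <- ci$sigma2 * exp(stats::runif(1, -0.7, 0.7))
      if (m) ci$pos <- stats::runif(m)
    }
    run_chain(phy, table, spec, priors, seed = seed + i - 1L,
              init = ci, ...)
  })
  structure(list(traces = traces, n_chains = n_chains,
                 single_chain = n_chains < 2L,
                 tree_hash = traces[[1L]]$tree_hash,
                 spec = spec),
            class = "allom_chains")
}

#' @export
print.allom_chains <- function(x, ...) {
  cat("allom_chains:", x$n_chains, "chains, model", x$spec$form, "\n")
  if (x$single_chain)
    cat("  note: single chain; cross-chain convergence not assessable\n")
  for (tr in x$traces) print(tr)
  invisible(x)
}
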