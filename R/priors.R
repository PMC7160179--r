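#' Prior specification for the shift model
#'
#' Defaults follow the conventions of Bayesian multi-optima OU regression:
#' every slope-type coefficient (body-size slopes, site offsets, site-size
#' interactions) gets a zero-centred normal prior with sd 0.2; each regime
#' optimum gets a normal prior centred on the mean of the observed log
#' response with sd 1.5 times its standard deviation; the number of shifts
#' K is uniform on `{0, ..., K_max}` with `K_max = 200` (a conditional
#' Poisson is available as an option); shift locations fall on branches
#' with probability proportional to branch length, position uniform along
#' the branch; `alpha` and `sigma2` get bounded log-uniform priors.
#'
#' @param table Optional `trait_table` used to centre the optimum prior
#'   (mean of `log_df`) and scale it (1.5 x sd of `log_df`). Supply
#'   `theta_mean`/`theta_sd` directly for data-free runs.
#' @param theta_mean,theta_sd Optimum prior centre and sd; override the
#'   table-derived values.
#' @param slope_sd Sd of the zero-mean normal prior on all slope-type
#'   coefficients.
#' @param K_max Maximum number of shifts.
#' @param K_prior `"uniform"` or `"poisson"` (conditional Poisson truncated
#'   to `{0..K_max}`; set `K_lambda`).
#' @param K_lambda Rate of the conditional Poisson K prior.
#' @param alpha_prior,sigma2_prior Lists: `list(type = "loguniform", min =,
#'   max =)` or `list(type = "halfnormal", sd =)` (alpha only). Defaults
#'   span unit-depth trees; rescale the bounds for trees measured in, e.g.,
#'   millions of years.
#' @param fixed Named list of parameters to hold fixed (excluded from both
#'   sampling and the prior): any of `alpha`, `sigma2`, `beta_size`
#'   (scalar, shared by all regimes), `beta_site`, `beta_inter`.
#' @return A list of class `allom_priors`.
#' @export
allom_priors <- function(table = NULL, theta_mean = NULL, theta_sd = NULL,
                         slope_sd = 0.2, K_max = 200L,
                         K_prior = c("uniform", "poisson"), K_lambda = NULL,
                         alpha_prior = list(type = "loguniform",
                                            min = 1e-3, max = 1e3),
                         sigma2_prior = list(type = "loguniform",
                                             min = 1e-4, max = 1e2),
                         fixed = list()) {
  K_prior <- match.arg(K_prior)
  if (!is.null(table)) {
    if (is.null(theta_mean)) theta_mean <- mean(table$log_df)
    if (is.null(theta_sd)) theta_sd <- 1.5 * stats::sd(table$log_df)
  }
  if (is.null(theta_mean) || is.null(theta_sd))
    stop("supply either a trait table or theta_mean and theta_sd")
  if (K_prior == "poisson" && is.null(K_lambda))
    stop("K_prior 'poisson' needs K_lambda")
  stopifnot(theta_sd > 0, slope_sd >= 0, K_max >= 0)
  bad <- setdiff(names(fixed),
                 c("alpha", "sigma2", "beta_size", "beta_site", "beta_inter"))
  if (length(bad)) stop("unknown fixed parameters: ",
                        paste(bad, collapse = ", "))
  structure(list(theta_mean = theta_mean, theta_sd = theta_sd,
                 slope_sd = slope_sd, K_max = as.integer(K_max),
                 K_prior = K_prior, K_lambda = K_lambda,
                 alpha_prior = alpha_prior, sigma2_prior = sigma2_prior,
                 fixed = fixed),
            class = "allom_priors")
}

log_dprior_theta <- function(x, pr)
  sum(stats::dnorm(x, pr$theta_mean, pr$theta_sd, log = TRUE))

log_dprior_slope <- function(x, pr)
  sum(stats::dnorm(x, 0, pr$slope_sd, log = TRUE))

log_dprior_K <- function(k, pr) {
  if (k < 0 || k > pr$K_max) return(-Inf)
  switch(pr$K_prior,
    uniform = -log(pr$K_max + 1),
    poisson = {
      kk <- 0:pr$K_max
      stats::dpois(k, pr$K_lambda, log = TRUE) -
        log(sum(stats::dpois(kk, pr$K_lambda)))
    })
}

log_dprior_positive <- function(x, spec) {
  if (spec$type == "loguniform") {
    if (x < spec$min || x > spec$max) return(-Inf)
    -log(x) - log(log(spec$max / spec$min))
  } else if (spec$type == "halfnormal") {
    if (x < 0) return(-Inf)
    log(2) + stats::dnorm(x, 0, spec$sd, log = TRUE)
  } else stop("unknown prior type ", spec$type)
}

sample_prior_positive <- function(spec) {
  if (spec$type == "loguniform")
    exp(stats::runif(1, log(spec$min), log(spec$max)))
  else abs(stats::rnorm(1, 0, spec$sd))
}
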