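#' Hansen regime weights
#'
#' Under an Ornstein-Uhlenbeck process with selection strength `alpha`, the
#' expected tip value is a convex combination of the regime optima its
#' lineage has visited. For tip i with depth `T_i` and a lineage segment in
#' regime k spanning times `[t0, t1]` (from the root), the segment
#' contributes `exp(-alpha (T_i - t1)) - exp(-alpha (T_i - t0))` to
#' `W[i, k]`; the residual weight `exp(-alpha T_i)` goes to the root regime
#' (the root state is fixed at the root-regime optimum). At `alpha = 0`
#' all weight falls on the root regime.
#'
#' @param phy A `phylo` object.
#' @param painting A `regime_painting` from [paint()].
#' @param alpha Selection strength, `>= 0` (per unit branch-length time).
#' @return An `n_tip x n_regimes` matrix with rows summing to 1.
#' @export
hansen_weights <- function(phy, painting, alpha) {
  stopifnot(inherits(painting, "regime_painting"), alpha >= 0)
  n_tip <- ape::Ntip(phy)
  tipd <- ape::node.depth.edgelength(phy)[seq_len(n_tip)]
  seg <- painting$segments
  W <- matrix(0, n_tip, painting$n_regimes)
  w <- exp(-alpha * (tipd[seg$tip] - seg$t1)) -
       exp(-alpha * (tipd[seg$tip] - seg$t0))
  for (s in seq_len(nrow(seg)))
    W[seg$tip[s], seg$regime[s] + 1L] <-
      W[seg$tip[s], seg$regime[s] + 1L] + w[s]
  W[, 1L] <- W[, 1L] + exp(-alpha * tipd)
  W
}

# Fast Hansen weights used inside the sampler: scatter/gather over the
# shift set instead of per-segment aggregation. For each shift j at time
# tau_j with source regime s_j, every descendant tip i receives
# g = exp(-alpha (T_i - tau_j)) added to regime s_j and subtracted from
# regime j; the terminal regime of each tip receives the base weight 1.
# Algebraically identical to hansen_weights() on the same painting.
hansen_weights_fast <- function(idx, painting, alpha) {
  n_tip <- idx$n_tip
  K <- painting$n_regimes - 1L
  W <- matrix(0, n_tip, K + 1L)
  W[cbind(seq_len(n_tip), painting$tip_regime + 1L)] <- 1
  for (j in seq_len(K)) {
    tips <- idx$tips_below[[painting$shift_branch[j]]]
    g <- exp(-alpha * (idx$tip_depth[tips] - painting$shift_time[j]))
    cb_new <- cbind(tips, j + 1L)
    cb_src <- cbind(tips, painting$shift_src_regime[j] + 1L)
    W[cb_new] <- W[cb_new] - g
    W[cb_src] <- W[cb_src] + g
  }
  W
}

#' Ornstein-Uhlenbeck tip covariance with measurement error
#'
#' For tips i, j with depths `T_i`, `T_j` and MRCA depth `s_ij`,
#' `V_ij = sigma2 / (2 alpha) * exp(-alpha (T_i + T_j - 2 s_ij)) *
#' (1 - exp(-2 alpha s_ij))`; the per-tip measurement-error variance is
#' added to the diagonal. Below `alpha = 1e-8` the analytic Brownian-motion
#' limit `sigma2 * s_ij` is used.
#'
#' @param phy A `phylo` object.
#' @param alpha Selection strength (`>= 0`).
#' @param sigma2 Diffusion variance (`> 0`), per unit time.
#' @param me Per-tip measurement-error variances (scalar or length
#'   `n_tip`); default 0.
#' @param S Optional precomputed shared path-length matrix
#'   ([shared_path_matrix()]); supplied by callers that hold one.
#' @return The `n_tip x n_tip` covariance matrix.
#' @export
ou_covariance <- function(phy, alpha, sigma2, me = 0, S = NULL) {
  stopifnot(alpha >= 0, sigma2 > 0)
  if (is.null(S)) S <- shared_path_matrix(phy)
  V <- ou_cov_from_S(S, alpha, sigma2)
  diag(V) <- diag(V) + me
  ev <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    stop("OU covariance is not positive definite (smallest eigenvalue ",
         format(ev), ")")
  V
}

ALPHA_BM_LIMIT <- 1e-8

ou_cov_from_S <- function(S, alpha, sigma2) {
  if (alpha < ALPHA_BM_LIMIT) return(sigma2 * S)
  tipd <- diag(S)
  D <- outer(tipd, tipd, "+") - 2 * S
  sigma2 / (2 * alpha) * exp(-alpha * D) * (1 - exp(-2 * alpha * S))
}

#' Model forms for the allometric regression
#'
#' * `"a"`: log frequency ~ log size (per-regime optimum and slope);
#' * `"b"`: adds global calling-site offsets;
#' * `"c"`: adds global site-by-size interaction slopes.
#'
#' Site and interaction coefficients do not shift across regimes; only the
#' optimum intercept and the body-size slope are regime-specific.
#'
#' @param form One of `"a"`, `"b"`, `"c"`.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(form = c("a", "b", "c")) {
  form <- match.arg(form)
  structure(list(form = form,
                 has_site = form %in% c("b", "c"),
                 has_inter = form == "c"),
            class = "model_spec")
}

# site dummy matrix (non-reference levels), rows aligned to table
site_dummies <- function(table) {
  D <- cbind(aquatic = as.numeric(table$site == "aquatic"),
             arboreal = as.numeric(table$site == "arboreal"))
  rownames(D) <- NULL
  D
}

#' Per-regime parameter set
#'
#' @param theta Numeric length K+1: optimum intercept per regime (log Hz).
#' @param beta_size Numeric length K+1: body-size slope per regime.
#' @param alpha Selection strength (`>= 0`).
#' @param sigma2 Diffusion variance (`> 0`).
#' @param beta_site Length-2 site offsets (aquatic, arboreal), models b/c.
#' @param beta_inter Length-2 site-by-size slopes, model c only.
#' @return A list of class `regime_params`.
#' @export
regime_params <- function(theta, beta_size, alpha, sigma2,
                          beta_site = NULL, beta_inter = NULL) {
  if (length(theta) != length(beta_size))
    stop("theta and beta_size must have the same length (K + 1)")
  stopifnot(alpha >= 0, sigma2 > 0)
  structure(list(theta = as.numeric(theta),
                 beta_size = as.numeric(beta_size),
                 beta_site = if (!is.null(beta_site)) as.numeric(beta_site),
                 beta_inter = if (!is.null(beta_inter)) as.numeric(beta_inter),
                 alpha = alpha, sigma2 = sigma2),
            class = "regime_params")
}

# expected tip values given weights and covariates
ou_mean <- function(W, x, params, D) {
  mu <- as.vector(W %*% params$theta) + x * as.vector(W %*% params$beta_size)
  if (!is.null(params$beta_site))
    mu <- mu + as.vector(D %*% params$beta_site)
  if (!is.null(params$beta_inter))
    mu <- mu + as.vector((x * D) %*% params$beta_inter)
  mu
}

# Gaussian log density given a Cholesky factor (upper triangular R'R = V)
mvn_loglik_chol <- function(resid, R) {
  z <- backsolve(R, resid, transpose = TRUE)
  -0.5 * length(resid) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z * z)
}

#' Multi-optima OU log-likelihood
#'
#' Exact log-likelihood of the tip data under the multi-optima OU
#' allometric regression: the response vector is multivariate normal with
#' mean `W (theta + beta_size * x)` plus global site terms, and covariance
#' [ou_covariance()] including measurement error.
#'
#' @param phy A `phylo` object.
#' @param table A `trait_table` aligned to `phy` tip order (see
#'   [reconcile()]); `NA` measurement errors are treated as 0.
#' @param spec A [model_spec()].
#' @param config A [shift_config()].
#' @param params A [regime_params()] consistent with `spec` and `config`.
#' @return The log-likelihood in nats.
#' @export
ou_loglik <- function(phy, table, spec, config, params) {
  if (length(params$theta) != config$K + 1L)
    stop("params imply ", length(params$theta) - 1L, " shifts, config has ",
         config$K)
  if (spec$has_site && is.null(params$beta_site))
    stop("model ", spec$form, " needs beta_site")
  if (spec$has_inter && is.null(params$beta_inter))
    stop("model c needs beta_inter")
  if (!spec$has_site) params$beta_site <- NULL
  if (!spec$has_inter) params$beta_inter <- NULL
  idx <- tree_index(phy)
  if (nrow(table) != idx$n_tip)
    stop("table rows must match tree tips")
  painting <- paint_idx(idx, config)
  W <- hansen_weights_fast(idx, painting, params$alpha)
  me <- ifelse(is.na(table$me_var), 0, table$me_var)
  V <- ou_covariance(idx$phy, params$alpha, params$sigma2, me)
  D <- site_dummies(table)
  mu <- ou_mean(W, table$log_size, params, D)
  R <- chol(V)
  mvn_loglik_chol(table$log_df - mu, R)
}
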