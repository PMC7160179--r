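# Convergence diagnostics and posterior shift summarization.

# potential scale reduction factor across chains (classic between/within
# form on the full sequences, floored at 1 so identically-sampled chains
# report exactly 1; the finite-sample correction otherwise dips below it)
psrf <- function(x) {
  n <- min(lengths(x))
  if (n < 4L) return(NA_real_)
  seqs <- lapply(x, function(v) v[seq_len(n)])
  means <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  max(1, sqrt(((n - 1) / n * W + B / n) / W))
}

# Geyer initial-positive-sequence effective sample size for one series
ess_ips <- function(v) {
  n <- length(v)
  if (n < 4L || stats::var(v) == 0) return(n)
  rho <- stats::acf(v, lag.max = min(n - 2L, 200L), plot = FALSE,
                    demean = TRUE)$acf[, 1L, 1L][-1L]
  m <- length(rho) %/% 2L
  gam <- rho[2 * seq_len(m) - 1L] + rho[2 * seq_len(m)]
  pos <- which(gam <= 0)
  if (length(pos)) gam <- gam[seq_len(pos[1L] - 1L)]
  max(1, n / (1 + 2 * sum(pmax(gam, 0))))
}

# per-chain, post-burn-in shift indicator series for every branch
branch_indicator_series <- function(traces) {
  n_edge <- traces[[1L]]$n_edge
  lapply(traces, function(tr) {
    ps <- post_burnin(tr)
    mat <- matrix(0L, length(ps$gen), tr$n_tip + tr$n_edge + 1L)
    for (i in seq_along(ps$shift_branch)) {
      b <- ps$shift_branch[[i]]
      if (length(b)) mat[i, b] <- 1L
    }
    mat    # columns indexed by branch child-node id
  })
}

#' Gelman-Rubin convergence diagnostics across chains
#'
#' Computes the potential scale reduction factor (split-chain PSRF) for
#' the per-branch shift posterior probabilities — each branch's shift
#' indicator series compared within and between chains — and for the
#' scalar quantities K, `alpha`, `sigma2`, and the log-likelihood, plus
#' effective sample sizes for the scalars. The verdict is `"converged"`
#' when every monitored R is below `r_threshold`.
#'
#' Branches on which no chain ever places a shift have zero variance
#' everywhere; their R is reported as 1 with a note, following the
#' convention that an identically-sampled quantity is trivially converged.
#'
#' @param chains An `allom_chains` object or list of `allom_trace`.
#' @param r_threshold Convergence threshold on R (default 1.1).
#' @return An object of class `allom_diagnostics`.
#' @export
gelman_r <- function(chains, r_threshold = 1.1) {
  traces <- if (inherits(chains, "allom_chains")) chains$traces else chains
  if (length(traces) < 2L)
    stop("need at least 2 chains for the Gelman-Rubin diagnostic")
  n_post <- vapply(traces, function(tr) length(post_burnin_idx(tr)),
                   integer(1))
  if (any(n_post < 10L))
    stop("need at least 10 post-burn-in samples per chain")

  ind <- branch_indicator_series(traces)
  any_shift <- which(Reduce(`+`, lapply(ind, colSums)) > 0)
  branch_r <- rep(1, ncol(ind[[1L]]))
  note <- "branches never sampled with a shift are reported as R = 1"
  for (b in any_shift)
    branch_r[b] <- psrf(lapply(ind, function(m) as.numeric(m[, b])))
  const <- setdiff(seq_along(branch_r), any_shift)

  scalars <- c("K", "alpha", "sigma2", "loglik")
  scalar_r <- scalar_ess <- stats::setNames(numeric(4), scalars)
  for (q in scalars) {
    series <- lapply(traces, function(tr) as.numeric(post_burnin(tr)[[q]]))
    scalar_r[q] <- psrf(series)
    scalar_ess[q] <- sum(vapply(series, ess_ips, numeric(1)))
  }
  scalar_r[!is.finite(scalar_r) &
             vapply(scalars, function(q)
               all(vapply(traces, function(tr)
                 stats::var(post_burnin(tr)[[q]]) == 0, logical(1))),
               logical(1))] <- 1

  all_r <- c(branch_r[any_shift], scalar_r)
  converged <- all(is.finite(all_r)) && all(all_r < r_threshold)
  structure(list(branch_r = branch_r, monitored_branches = any_shift,
                 constant_branches = const, note = note,
                 scalar_r = scalar_r, scalar_ess = scalar_ess,
                 r_threshold = r_threshold,
                 verdict = if (converged) "converged" else "not converged"),
            class = "allom_diagnostics")
}

#' @export
print.allom_diagnostics <- function(x, ...) {
  cat("Gelman-Rubin diagnostics:", x$verdict,
      "(threshold", x$r_threshold, ")\n")
  cat("  scalar R:",
      paste(names(x$scalar_r), round(x$scalar_r, 3), collapse = ", "), "\n")
  cat("  scalar ESS:",
      paste(names(x$scalar_ess), round(x$scalar_ess), collapse = ", "), "\n")
  if (length(x$monitored_branches))
    cat("  max branch R:",
        round(max(x$branch_r[x$monitored_branches]), 3), "over",
        length(x$monitored_branches), "branches with sampled shifts\n")
  invisible(x)
}

#' Summarize posterior shift support
#'
#' Pools post-burn-in samples across chains and computes, per branch, the
#' posterior probability of a shift (fraction of pooled samples with a
#' shift on that branch). The supported set applies two filters: posterior
#' probability at least `pp_threshold`, and at least `min_clade` tip
#' species in the shifted clade (the default 4 excludes shifts subtending
#' three or fewer species). Supported sets at thresholds 0.5 and 0.9 are
#' reported alongside. Regime parameter summaries are marginal over all
#' samples whose configuration contains the given shift.
#'
#' @param chains An `allom_chains` object or list of `allom_trace`.
#' @param phy The `phylo` the chains were run on.
#' @param pp_threshold Posterior-probability support threshold.
#' @param min_clade Minimum number of tip species a supported shift must
#'   subtend.
#' @param ci Credible-interval mass for regime parameter summaries.
#' @return An object of class `allom_shift_summary`.
#' @export
summarize_shifts <- function(chains, phy, pp_threshold = 0.7,
                             min_clade = 4L, ci = 0.95) {
  traces <- if (inherits(chains, "allom_chains")) chains$traces else chains
  idx <- tree_index(phy)
  post <- lapply(traces, post_burnin)
  n_samp <- sum(vapply(post, function(p) length(p$gen), integer(1)))
  if (n_samp == 0L) stop("no post-burn-in samples")

  n_nodes <- idx$n_all
  pp_count <- numeric(n_nodes)
  for (p in post) {
    tb <- unlist(p$shift_branch)
    if (length(tb)) {
      tc <- tabulate(tb, nbins = n_nodes)
      pp_count <- pp_count + tc
    }
  }
  pp <- pp_count / n_samp
  n_below <- vapply(seq_len(n_nodes), function(b)
    length(idx$tips_below[[b]]), integer(1))

  sel_at <- function(thr) {
    b <- which(pp >= thr & n_below >= min_clade)
    b[b != idx$root]
  }
  supported <- sel_at(pp_threshold)

  qlo <- (1 - ci) / 2; qhi <- 1 - qlo
  summ_vec <- function(v)
    c(median = stats::median(v),
      lo = unname(stats::quantile(v, qlo)),
      hi = unname(stats::quantile(v, qhi)))

  # root regime: marginal over all samples
  th_root <- unlist(lapply(post, function(p)
    vapply(p$theta, `[`, numeric(1), 1L)))
  be_root <- unlist(lapply(post, function(p)
    vapply(p$beta_size, `[`, numeric(1), 1L)))

  root_n <- if (length(supported)) {
    cfg <- shift_config(supported, rep(0, length(supported)))
    sum(paint_idx(idx, cfg)$tip_regime == 0L)
  } else idx$n_tip
  regime_rows <- list(data.frame(
    regime = "root", branch = NA_integer_,
    pp = NA_real_, n_species = root_n,
    theta_median = summ_vec(th_root)[1L], theta_lo = summ_vec(th_root)[2L],
    theta_hi = summ_vec(th_root)[3L],
    beta_median = summ_vec(be_root)[1L], beta_lo = summ_vec(be_root)[2L],
    beta_hi = summ_vec(be_root)[3L],
    mean_age = NA_real_, stringsAsFactors = FALSE))

  for (b in supported) {
    th <- unlist(lapply(post, function(p) {
      out <- numeric(0)
      for (i in seq_along(p$shift_branch)) {
        j <- match(b, p$shift_branch[[i]])
        if (!is.na(j)) out <- c(out, p$theta[[i]][j + 1L])
      }
      out
    }))
    be <- unlist(lapply(post, function(p) {
      out <- numeric(0)
      for (i in seq_along(p$shift_branch)) {
        j <- match(b, p$shift_branch[[i]])
        if (!is.na(j)) out <- c(out, p$beta_size[[i]][j + 1L])
      }
      out
    }))
    sv_t <- summ_vec(th); sv_b <- summ_vec(be)
    regime_rows[[length(regime_rows) + 1L]] <- data.frame(
      regime = paste0("shift_", b), branch = b, pp = pp[b],
      n_species = n_below[b],
      theta_median = sv_t[1L], theta_lo = sv_t[2L], theta_hi = sv_t[3L],
      beta_median = sv_b[1L], beta_lo = sv_b[2L], beta_hi = sv_b[3L],
      mean_age = regime_mean_age(idx, b), stringsAsFactors = FALSE)
  }
  regimes <- do.call(rbind, regime_rows)
  rownames(regimes) <- NULL

  branch_tbl <- data.frame(
    branch = seq_len(n_nodes), pp = pp, n_species = n_below,
    stringsAsFactors = FALSE)
  branch_tbl <- branch_tbl[branch_tbl$branch != idx$root &
                             branch_tbl$pp > 0, , drop = FALSE]
  rownames(branch_tbl) <- NULL

  structure(list(branch_pp = branch_tbl, pp = pp,
                 supported = supported,
                 supported_05 = sel_at(0.5), supported_09 = sel_at(0.9),
                 pp_threshold = pp_threshold, min_clade = min_clade,
                 regimes = regimes,
                 mean_K = sum(pp[seq_len(n_nodes) != idx$root]),
                 n_samples = n_samp,
                 tip_labels = lapply(supported, function(b)
                   idx$phy$tip.label[idx$tips_below[[b]]])),
            class = "allom_shift_summary")
}

# mean age of the internal nodes inside the shifted clade (including its
# stem node); ages measured back from the deepest tip. This is one of
# several defensible conventions for a regime's "mean age"; it is stated
# in the vignette.
regime_mean_age <- function(idx, b) {
  total <- max(idx$tip_depth)
  # collect all internal descendants of b (including b itself)
  all_nodes <- b
  repeat {
    kids <- idx$edge[idx$edge[, 1L] %in% all_nodes, 2L]
    new <- setdiff(kids[kids > idx$n_tip], all_nodes)
    if (!length(new)) break
    all_nodes <- c(all_nodes, new)
  }
  internal <- all_nodes[all_nodes > idx$n_tip]
  if (!length(internal)) return(NA_real_)
  mean(total - idx$depth[internal])
}

#' @export
print.allom_shift_summary <- function(x, ...) {
  cat("Posterior shift summary over", x$n_samples, "pooled samples\n")
  cat("  posterior mean K:", round(x$mean_K, 3), "\n")
  cat("  supported shifts (pp >=", x$pp_threshold, ", >=", x$min_clade,
      "species):", if (length(x$supported))
        paste(x$supported, collapse = ", ") else "none", "\n")
  print(x$regimes, digits = 4)
  invisible(x)
}

#' Write a Newick tree annotated with branch shift probabilities
#'
#' Internal-node labels carry the posterior shift probability of the
#' branch subtending the node (rounded to 4 digits); the full per-branch
#' table should be taken from the summary object itself, since Newick
#' node labels cannot annotate terminal branches.
#'
#' @param summary An `allom_shift_summary`.
#' @param phy The tree the summary refers to.
#' @param path Output path.
#' @export
write_annotated_tree <- function(summary, phy, path) {
  n_tip <- ape::Ntip(phy)
  labs <- format(round(summary$pp[(n_tip + 1L):(n_tip + phy$Nnode)], 4L))
  phy$node.label <- labs
  ape::write.tree(phy, path)
  invisible(path)
}
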