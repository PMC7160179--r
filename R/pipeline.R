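# End-to-end orchestration: read inputs, run chains per model, compute
# diagnostics, marginal likelihoods, shift summaries, and pANCOVA
# corroboration, writing every artifact plus a run manifest to one
# directory. The command-line wrapper in inst/scripts/allomshift is a
# thin veneer over these functions.

#' Fit the full shift-detection analysis and write a run directory
#'
#' For each requested model form: runs `n_chains` reversible-jump chains,
#' checks convergence with [gelman_r()], summarizes shifts with
#' [summarize_shifts()], and (optionally) estimates the marginal
#' likelihood by [stepping_stone()]. Models are then compared by
#' [compare_models()], and every supported shift of the best model is
#' corroborated by [pancova()]. All results are written under `out_dir`
#' together with a manifest (seeds, priors, settings, input hashes).
#'
#' @param tree_file,trait_file Input paths ([read_tree()],
#'   [read_traits()]); alternatively pass `phy` and `table` directly.
#' @param phy,table In-memory inputs (override the file arguments).
#' @param models Character subset of `c("a", "b", "c")`.
#' @param out_dir Output directory (created).
#' @param seed Base seed; chain i of model m uses consecutive seeds.
#' @param generations,thinning,n_chains,burnin Chain settings.
#' @param me_policy Measurement-error imputation policy ([impute_me()]);
#'   `"auto"` uses `"mean"` when any variances are observed, else
#'   `"zero"`.
#' @param priors An [allom_priors()]; by default derived from the data.
#' @param marginal `TRUE` to run stepping-stone marginal likelihoods.
#' @param rungs,gens_per_rung Stepping-stone settings.
#' @param pp_threshold,min_clade,bf_threshold Reporting thresholds.
#' @param quiet Suppress progress output.
#' @return A list with all result objects and `out_dir`, invisibly.
#' @export
fit_pipeline <- function(tree_file = NULL, trait_file = NULL,
                         phy = NULL, table = NULL,
                         models = c("a"), out_dir, seed = 1L,
                         generations = 100000L, thinning = 100L,
                         n_chains = 4L, burnin = 0.25,
                         me_policy = "auto", priors = NULL,
                         marginal = FALSE, rungs = 10L,
                         gens_per_rung = 5000L,
                         pp_threshold = 0.7, min_clade = 4L,
                         bf_threshold = 10, quiet = TRUE) {
  models <- match.arg(models, c("a", "b", "c"), several.ok = TRUE)
  if (is.null(phy)) {
    phy <- read_tree(tree_file)
    raw <- read_traits(trait_file)
    rec <- reconcile(phy, raw)
    phy <- rec$tree; table <- rec$table
  } else if (is.null(table)) stop("supply both phy and table")
  if (me_policy == "auto")
    me_policy <- if (any(!is.na(table$me_var))) "mean" else "zero"
  table <- impute_me(table, me_policy)
  if (is.null(priors)) priors <- allom_priors(table)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  per_model <- list()
  mls <- list()
  for (m in models) {
    spec <- model_spec(m)
    chains <- run_analysis(phy, table, spec, priors,
                           n_chains = n_chains, seed = seed,
                           generations = generations,
                           thinning = thinning, burnin = burnin,
                           quiet = quiet)
    diag <- if (n_chains >= 2L) gelman_r(chains) else NULL
    summ <- summarize_shifts(chains, phy, pp_threshold = pp_threshold,
                             min_clade = min_clade)
    ml <- if (marginal)
      stepping_stone(phy, table, spec, priors, rungs = rungs,
                     gens_per_rung = gens_per_rung,
                     seed = seed + 500L) else NULL
    write_model_outputs(out_dir, m, chains, diag, summ, ml, phy)
    per_model[[m]] <- list(chains = chains, diagnostics = diag,
                           summary = summ, marginal = ml)
    if (!is.null(ml)) mls[[m]] <- ml
  }

  bf <- if (length(mls) >= 2L) compare_models(mls, bf_threshold) else NULL
  if (!is.null(bf))
    jsonlite::write_json(
      list(estimates = as.list(bf$estimates), best = bf$best,
           threshold = bf$threshold, pairs = bf$table),
      file.path(out_dir, "bayes_factors.json"), auto_unbox = TRUE,
      digits = NA, dataframe = "rows")

  best <- if (!is.null(bf)) bf$best else models[[1L]]
  summ_best <- per_model[[best]]$summary
  panc <- list()
  for (b in summ_best$supported) {
    res <- tryCatch(pancova(phy, table, b), error = function(e) e)
    if (!inherits(res, "error")) panc[[as.character(b)]] <- res
  }
  if (length(panc)) {
    ptab <- do.call(rbind, lapply(names(panc), function(b) {
      r <- panc[[b]]
      data.frame(branch = as.integer(b), F = r$F, df1 = r$df1,
                 df2 = r$df2, p_value = r$p_value,
                 rss_full = r$table$ss[1L], rss_reduced = r$table$ss[2L])
    }))
    utils::write.csv(ptab, file.path(out_dir, "pancova.csv"),
                     row.names = FALSE)
  }

  verdicts <- vapply(per_model, function(pm)
    if (is.null(pm$diagnostics)) "single chain" else
      pm$diagnostics$verdict, character(1))
  manifest <- list(
    package_version = as.character(utils::packageVersion("allomshift")),
    seed = seed, models = models, generations = generations,
    thinning = thinning, n_chains = n_chains, burnin = burnin,
    me_policy = me_policy,
    priors = priors[c("theta_mean", "theta_sd", "slope_sd", "K_max",
                      "K_prior")],
    pp_threshold = pp_threshold, min_clade = min_clade,
    bf_threshold = bf_threshold,
    tree_hash = per_model[[1L]]$chains$tree_hash,
    n_species = ape::Ntip(phy),
    convergence = as.list(verdicts),
    best_model = best,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(models = per_model, bayes_factors = bf,
                 pancova = panc, manifest = manifest,
                 out_dir = out_dir))
}

write_model_outputs <- function(out_dir, m, chains, diag, summ, ml, phy) {
  for (i in seq_along(chains$traces))
    write_trace(chains$traces[[i]],
                file.path(out_dir,
                          sprintf("model_%s_chain%d.tsv", m, i)))
  if (!is.null(diag))
    jsonlite::write_json(
      list(verdict = diag$verdict, scalar_r = as.list(diag$scalar_r),
           scalar_ess = as.list(diag$scalar_ess),
           max_branch_r = if (length(diag$monitored_branches))
             max(diag$branch_r[diag$monitored_branches]) else 1),
      file.path(out_dir, sprintf("model_%s_diagnostics.json", m)),
      auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(mean_K = summ$mean_K, supported = summ$supported,
         supported_05 = summ$supported_05,
         supported_09 = summ$supported_09,
         pp_threshold = summ$pp_threshold, min_clade = summ$min_clade),
    file.path(out_dir, sprintf("model_%s_shifts.json", m)),
    auto_unbox = TRUE, digits = NA)
  utils::write.table(summ$regimes,
                     file.path(out_dir, sprintf("model_%s_regimes.tsv", m)),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_annotated_tree(summ, phy,
                       file.path(out_dir, sprintf("model_%s_pp.nwk", m)))
  if (!is.null(ml))
    jsonlite::write_json(
      list(form = ml$form, estimate = ml$estimate, se = ml$se,
           rungs = ml$rungs, gens_per_rung = ml$gens_per_rung,
           ladder = ml$ladder),
      file.path(out_dir, sprintf("model_%s_marginal.json", m)),
      auto_unbox = TRUE, digits = NA)
}

#' Write a chain trace as a delimited samples file
#'
#' One row per retained sample: generation, K, alpha, sigma2,
#' log-likelihood, log-prior, and JSON-serialized shift set and
#' per-regime parameters.
#'
#' @param trace An `allom_trace`.
#' @param path Output path (tab-separated).
#' @export
write_trace <- function(trace, path) {
  s <- trace$samples
  js <- function(v) vapply(v, function(x)
    as.character(jsonlite::toJSON(x, digits = NA)), character(1))
  df <- data.frame(gen = s$gen, K = s$K, alpha = s$alpha,
                   sigma2 = s$sigma2, loglik = s$loglik,
                   logprior = s$logprior,
                   shift_branch = js(s$shift_branch),
                   shift_pos = js(s$shift_pos),
                   theta = js(s$theta), beta_size = js(s$beta_size),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
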