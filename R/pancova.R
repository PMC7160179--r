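# Phylogenetic ANCOVA under Brownian motion: a full model giving the
# focal clade its own intercept and body-size slope versus a reduced
# model with one intercept and slope for all species, compared by an
# F-ratio test on GLS residual sums of squares.

#' Fit the full and reduced PGLS models for a candidate clade
#'
#' Both models are generalized least squares fits of log dominant
#' frequency on log body size under the Brownian-motion covariance
#' (shared path lengths). The response and design are premultiplied by
#' the inverse of a triangular (Cholesky) factor of the covariance and
#' fitted by ordinary least squares; residual sums of squares are reported
#' in the transformed space, where they are invariant to the choice of
#' factor. The full model has 4 parameters (intercept and slope for the
#' focal clade, another pair for the remaining species); the reduced
#' model has 2.
#'
#' @param phy A `phylo` object.
#' @param table A `trait_table` aligned to `phy` tip order.
#' @param clade Tip labels (or tip indices) of the focal clade, or a
#'   single internal node id whose descendants define it. Must be
#'   monophyletic with at least 2 members and at least 2 non-members.
#' @param require_monophyly Set `FALSE` to allow an arbitrary tip set as
#'   the focal group.
#' @return A list with elements `full` and `reduced` (each with `p`,
#'   `rss`, `coef`), `n`, and the membership vector.
#' @export
pgls_fit <- function(phy, table, clade, require_monophyly = TRUE) {
  n <- ape::Ntip(phy)
  if (nrow(table) != n) stop("table rows must match tree tips")
  if (is.character(clade)) {
    tips <- match(clade, phy$tip.label)
    if (anyNA(tips)) stop("clade tips not in tree: ",
                          paste(clade[is.na(tips)], collapse = ", "))
  } else if (length(clade) == 1L && clade > n) {
    idx <- tree_index(phy)
    tips <- idx$tips_below[[clade]]
  } else {
    tips <- as.integer(clade)
  }
  if (length(tips) < 2L) stop("focal clade needs at least 2 tips")
  if (n - length(tips) < 2L)
    stop("focal clade leaves fewer than 2 background species; ",
         "design would be singular")
  if (require_monophyly && length(tips) < n) {
    mrca <- if (length(tips) == 1L) tips else ape::getMRCA(phy, tips)
    below <- tree_index(phy)$tips_below[[mrca]]
    if (!setequal(below, tips))
      stop("focal tip set is not monophyletic (MRCA subtends ",
           length(below), " tips)")
  }
  g <- as.numeric(seq_len(n) %in% tips)
  y <- table$log_df
  x <- table$log_size
  C <- shared_path_matrix(phy)
  R <- chol(C)
  ty <- backsolve(R, y, transpose = TRUE)
  tX_full <- backsolve(R, cbind(1, x, g, g * x), transpose = TRUE)
  tX_red <- backsolve(R, cbind(1, x), transpose = TRUE)
  fit_f <- stats::lm.fit(tX_full, ty)
  fit_r <- stats::lm.fit(tX_red, ty)
  if (fit_f$rank < 4L) stop("full-model design is singular")
  list(full = list(p = 4L, rss = sum(fit_f$residuals^2),
                   coef = stats::setNames(fit_f$coefficients,
                     c("intercept", "slope", "clade_intercept",
                       "clade_slope"))),
       reduced = list(p = 2L, rss = sum(fit_r$residuals^2),
                      coef = stats::setNames(fit_r$coefficients,
                        c("intercept", "slope"))),
       n = n, membership = g)
}

#' F-ratio test between nested GLS models
#'
#' `F = [(RSS_r - RSS_f) / (p_f - p_r)] / [RSS_f / (n - p_f)]` with a
#' p-value from the F distribution on `(p_f - p_r, n - p_f)` degrees of
#' freedom. Mean sums of squares are `RSS / (n - p)` per model.
#'
#' @param rss_full,rss_reduced Residual sums of squares of the nested
#'   models (full must not exceed reduced).
#' @param p_full,p_reduced Parameter counts (`p_full > p_reduced`).
#' @param n Number of species.
#' @return Object of class `pancova_result` with the model table
#'   (`df`, `ss`, `mss`), `F`, `df1`, `df2`, `p_value`.
#' @export
f_ratio <- function(rss_full, p_full, rss_reduced, p_reduced, n) {
  stopifnot(p_full > p_reduced, n > p_full)
  if (rss_full > rss_reduced * (1 + 1e-12))
    stop("nesting violated: full-model RSS exceeds reduced-model RSS")
  df1 <- p_full - p_reduced
  df2 <- n - p_full
  Fstat <- max(0, (rss_reduced - rss_full) / df1) / (rss_full / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  tab <- data.frame(
    model = c("full", "reduced"),
    df = c(p_full, p_reduced),
    ss = c(rss_full, rss_reduced),
    mss = c(rss_full / (n - p_full), rss_reduced / (n - p_reduced)),
    F = c(Fstat, NA), p_value = c(p, NA),
    stringsAsFactors = FALSE)
  structure(list(table = tab, F = Fstat, df1 = df1, df2 = df2,
                 p_value = p, n = n),
            class = "pancova_result")
}

#' @export
print.pancova_result <- function(x, ...) {
  cat("Phylogenetic ANCOVA F-ratio test: F(", x$df1, ",", x$df2, ") =",
      round(x$F, 3), ", p =", format.pval(x$p_value, digits = 3), "\n")
  print(x$table, digits = 7)
  invisible(x)
}

#' Phylogenetic ANCOVA for a candidate shifted clade
#'
#' Convenience wrapper: fits the full and reduced PGLS models with
#' [pgls_fit()] and applies [f_ratio()].
#'
#' @inheritParams pgls_fit
#' @return A `pancova_result`, with the fits attached as
#'   `attr(, "fits")`.
#' @export
pancova <- function(phy, table, clade, require_monophyly = TRUE) {
  fits <- pgls_fit(phy, table, clade, require_monophyly)
  res <- f_ratio(fits$full$rss, fits$full$p,
                 fits$reduced$rss, fits$reduced$p, fits$n)
  attr(res, "fits") <- fits
  res
}
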