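#' Read a species trait table
#'
#' Expects a delimited text file with header
#' `species,dominant_frequency_hz,svl_mm,calling_site,me_var` where
#' `dominant_frequency_hz` is the species mean dominant call frequency (Hz),
#' `svl_mm` the mean male snout-vent length (mm), `calling_site` one of
#' `aquatic`, `terrestrial`, `arboreal`, and `me_var` an optional
#' observation-error variance of log dominant frequency (log-Hz^2; may be
#' empty/NA). Values are kept on the raw scale here; logs are taken by
#' [trait_table()] / [reconcile()].
#'
#' @param path Path to a CSV or TSV file (delimiter guessed from extension).
#' @param sep Field delimiter; default guessed (`","` unless the extension
#'   is `.tsv`/`.txt`).
#' @return A data frame of raw trait rows.
#' @export
read_traits <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("species", "dominant_frequency_hz", "svl_mm", "calling_site")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("trait table is missing columns: ", paste(miss, collapse = ", "))
  if (!"me_var" %in% names(raw)) raw$me_var <- NA_real_
  raw
}

#' Write a raw trait table
#' @param raw Data frame as returned by [read_traits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traits <- function(raw, path) {
  utils::write.csv(raw, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Calling-site factor levels (terrestrial is the reference level)
#' @export
SITE_LEVELS <- c("terrestrial", "aquatic", "arboreal")

#' Build a trait table on the analysis scale
#'
#' Constructs the per-species table used by the model: natural-log dominant
#' frequency (log Hz), natural-log body size (log mm), calling site as a
#' factor with `terrestrial` as the reference level, and the per-species
#' measurement-error variance of the log response. Natural logarithms are
#' used throughout; note an optimum intercept is the expected log frequency
#' at log size 0 (a 1 mm animal), so intercepts sit well above observed
#' log frequencies when slopes are negative.
#'
#' @param species Character vector of species names.
#' @param log_df Numeric, natural log of mean dominant frequency (log Hz).
#' @param log_size Numeric, natural log of mean male SVL (log mm).
#' @param site Character or factor with values in
#'   `c("terrestrial","aquatic","arboreal")`.
#' @param me_var Numeric, observation-error variance of `log_df`
#'   (log-Hz^2), `NA` when unknown.
#' @return A `data.frame` of class `trait_table`.
#' @export
trait_table <- function(species, log_df, log_size, site,
                        me_var = rep(NA_real_, length(species))) {
  species <- as.character(species)
  site <- as.character(site)
  bad <- setdiff(unique(site), SITE_LEVELS)
  if (length(bad))
    stop("unknown calling-site categories: ", paste(bad, collapse = ", "))
  if (!all(is.finite(log_df)) || !all(is.finite(log_size)))
    stop("log_df and log_size must be finite")
  if (any(!is.na(me_var) & me_var < 0)) stop("me_var must be >= 0")
  if (anyDuplicated(species))
    stop("duplicate species in trait table")
  out <- data.frame(species = species, log_df = as.numeric(log_df),
                    log_size = as.numeric(log_size),
                    site = factor(site, levels = SITE_LEVELS),
                    me_var = as.numeric(me_var),
                    stringsAsFactors = FALSE)
  class(out) <- c("trait_table", "data.frame")
  out
}

# exact matching after underscore/space normalization and case-folding
normalize_species <- function(x) tolower(gsub("[ _]+", "_", trimws(x)))

#' Reconcile a tree and a raw trait table
#'
#' Prunes the tree to the species shared with the trait table (exact name
#' match after space/underscore normalization and case-folding), log-
#' transforms the traits, and orders the table to the pruned tree's tip
#' order. Names dropped on either side are reported via `message()` and
#' returned.
#'
#' @param phy A `phylo` object.
#' @param raw Raw trait rows from [read_traits()], or an existing
#'   `trait_table` (already on the log scale).
#' @return A list with elements `tree` (pruned `phylo`), `table`
#'   (`trait_table` in tip order), `dropped_tips`, `dropped_rows`.
#' @export
reconcile <- function(phy, raw) {
  stopifnot(inherits(phy, "phylo"))
  if (inherits(raw, "trait_table")) {
    tab <- raw
  } else {
    if (any(raw$dominant_frequency_hz <= 0) || any(raw$svl_mm <= 0))
      stop("frequencies and body sizes must be positive to log-transform")
    tab <- trait_table(raw$species, log(raw$dominant_frequency_hz),
                       log(raw$svl_mm), raw$calling_site, raw$me_var)
  }
  key_tip <- normalize_species(phy$tip.label)
  key_tab <- normalize_species(tab$species)
  if (anyDuplicated(key_tab))
    stop("trait species not unique after name normalization")
  keep <- intersect(key_tip, key_tab)
  if (length(keep) == 0L) stop("no species shared between tree and traits")
  if (length(keep) < 4L)
    stop("only ", length(keep), " species shared; need at least 4")
  dropped_tips <- phy$tip.label[!key_tip %in% keep]
  dropped_rows <- tab$species[!key_tab %in% keep]
  if (length(dropped_tips))
    message("dropping ", length(dropped_tips), " tips without traits: ",
            paste(utils::head(dropped_tips, 5L), collapse = ", "),
            if (length(dropped_tips) > 5L) ", ...")
  if (length(dropped_rows))
    message("dropping ", length(dropped_rows), " trait rows not in tree: ",
            paste(utils::head(dropped_rows, 5L), collapse = ", "),
            if (length(dropped_rows) > 5L) ", ...")
  pruned <- if (length(dropped_tips))
    ape::drop.tip(phy, dropped_tips) else phy
  ord <- match(normalize_species(pruned$tip.label), key_tab)
  tab <- tab[ord, , drop = FALSE]
  tab$species <- pruned$tip.label   # adopt tree spelling
  rownames(tab) <- NULL
  class(tab) <- c("trait_table", "data.frame")
  list(tree = validate_tree(pruned), table = tab,
       dropped_tips = dropped_tips, dropped_rows = dropped_rows)
}

#' Fill in missing measurement-error variances
#'
#' Species lacking an intraspecific variance estimate receive one according
#' to `policy`: the mean of the observed variances, zero, or a fixed value.
#' The policy is recorded in the `"me_policy"` attribute.
#'
#' @param table A `trait_table`.
#' @param policy `"mean"`, `"zero"`, or `"fixed"`.
#' @param value Variance used when `policy = "fixed"`.
#' @return The completed `trait_table`.
#' @export
impute_me <- function(table, policy = c("mean", "zero", "fixed"),
                      value = NULL) {
  policy <- match.arg(policy)
  miss <- is.na(table$me_var)
  fill <- switch(policy,
    mean = {
      if (all(miss))
        stop("policy 'mean' needs at least one observed me_var; ",
             "use policy 'zero' or 'fixed'")
      mean(table$me_var[!miss])
    },
    zero = 0,
    fixed = {
      if (is.null(value) || !is.finite(value) || value < 0)
        stop("policy 'fixed' needs a finite non-negative 'value'")
      value
    })
  table$me_var[miss] <- fill
  attr(table, "me_policy") <-
    list(policy = policy, fill = fill, n_imputed = sum(miss))
  table
}
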