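#' Construct a shift configuration
#'
#' A shift configuration places `K` adaptive-regime shifts on branches of
#' the tree. Each shift lives on one branch — identified by the node at the
#' tipward end of the branch, the usual edge labelling — at a fractional
#' position along the branch measured from its rootward end. At most one
#' shift per branch is allowed; everything tipward of a shift belongs to
#' the new regime until overridden by a more tipward shift.
#'
#' @param branch Integer vector of node ids (the child node of each shift
#'   branch). May be empty for the no-shift configuration.
#' @param position Numeric vector in `[0, 1]`, same length as `branch`;
#'   defaults to 0 (shift at the rootward end of the branch).
#' @return An object of class `shift_config`.
#' @export
shift_config <- function(branch = integer(0),
                         position = rep(0, length(branch))) {
  branch <- as.integer(branch)
  position <- as.numeric(position)
  if (length(branch) != length(position))
    stop("branch and position must have the same length")
  if (anyDuplicated(branch))
    stop("at most one shift per branch: duplicated branch id ",
         branch[duplicated(branch)][1L])
  if (length(position) && (any(position < 0) || any(position > 1)))
    stop("positions must lie in [0, 1]")
  structure(list(branch = branch, position = position,
                 K = length(branch)),
            class = "shift_config")
}

#' @export
print.shift_config <- function(x, ...) {
  cat("shift_config with K =", x$K, "shifts\n")
  if (x$K)
    print(data.frame(branch = x$branch, position = x$position))
  invisible(x)
}

#' Serialize a shift configuration to JSON
#'
#' Branches are written as the tip-label sets that define them (all tips
#' descending from the branch's child node), so the file is portable across
#' node numberings.
#'
#' @param config A `shift_config`.
#' @param phy The `phylo` object the configuration refers to.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @export
write_shift_config <- function(config, phy, path = NULL) {
  idx <- tree_index(phy)
  shifts <- lapply(seq_len(config$K), function(j) {
    b <- config$branch[j]
    list(clade = idx$phy$tip.label[idx$tips_below[[b]]],
         position = config$position[j])
  })
  js <- jsonlite::toJSON(shifts, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a shift configuration from JSON
#' @param path Path or JSON string from [write_shift_config()].
#' @param phy The `phylo` object to resolve clades against.
#' @export
read_shift_config <- function(path, phy) {
  shifts <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  branch <- vapply(shifts, function(s) {
    tips <- match(unlist(s$clade), phy$tip.label)
    if (anyNA(tips)) stop("clade tips not all present in tree")
    if (length(tips) == 1L) tips else ape::getMRCA(phy, tips)
  }, integer(1))
  pos <- vapply(shifts, function(s) as.numeric(s$position), numeric(1))
  shift_config(branch, pos)
}

#' Paint a tree with the regimes implied by a shift configuration
#'
#' Produces, for every tip, the ordered sequence of regime segments along
#' its root-to-tip lineage. Regime 0 is the ancestral (root) regime; shift
#' regimes are numbered 1..K in preorder of their branches, so paintings
#' are stable under reordering of the shift set.
#'
#' @param phy A `phylo` object.
#' @param config A `shift_config`.
#' @return An object of class `regime_painting`: a list with `segments`
#'   (data frame with columns `tip`, `regime`, `t0`, `t1`, times measured
#'   from the root), `tip_regime` (terminal regime per tip),
#'   `node_regime` (regime in force at each node), `shift_branch`,
#'   `shift_position`, `shift_time`, `shift_src_regime` (canonically
#'   ordered), and `n_regimes` (= K + 1).
#' @export
paint <- function(phy, config) {
  idx <- tree_index(phy)
  paint_idx(idx, config)
}

# painting against a prebuilt tree_index (internal fast path entry)
paint_idx <- function(idx, config) {
  n_tip <- idx$n_tip
  K <- config$K
  if (K && any(idx$edge_of[config$branch] == 0L))
    stop("shift branch not found in tree (root or unknown node)")
  # canonical order: preorder of the shift edges (cladewise edge rows)
  ord <- if (K) order(idx$edge_of[config$branch]) else integer(0)
  branch <- config$branch[ord]
  pos <- config$position[ord]
  eidx <- idx$edge_of[branch]
  shift_time <- idx$depth[idx$parent[branch]] + pos * idx$elen[eidx]

  # regime in force at each node (value just below the node)
  node_regime <- integer(idx$n_all)
  shift_on_edge <- integer(nrow(idx$edge))   # 0 = none, else regime id
  shift_on_edge[eidx] <- seq_len(K)
  for (i in seq_len(nrow(idx$edge))) {
    pa <- idx$edge[i, 1L]; ch <- idx$edge[i, 2L]
    s <- shift_on_edge[i]
    node_regime[ch] <- if (s > 0L) s else node_regime[pa]
  }
  src_regime <- node_regime[idx$parent[branch]]

  # per-tip segments: regime changes exactly at the shift points on the path
  seg_tip <- integer(0); seg_reg <- integer(0)
  seg_t0 <- numeric(0); seg_t1 <- numeric(0)
  on_path <- if (K) lapply(seq_len(K), function(j) idx$tips_below[[branch[j]]])
             else list()
  tip_events <- vector("list", n_tip)
  for (j in seq_len(K))
    for (tp in on_path[[j]])
      tip_events[[tp]] <- rbind(tip_events[[tp]],
                                c(shift_time[j], j))
  for (tp in seq_len(n_tip)) {
    ev <- tip_events[[tp]]
    Tt <- idx$tip_depth[tp]
    if (is.null(ev)) {
      times <- numeric(0); regs <- integer(0)
    } else {
      o <- order(ev[, 1L])
      times <- ev[o, 1L]; regs <- as.integer(ev[o, 2L])
    }
    bounds <- c(0, times, Tt)
    regimes <- c(0L, regs)
    keep <- bounds[-1L] > bounds[-length(bounds)] | length(bounds) == 2L
    seg_tip <- c(seg_tip, rep(tp, sum(keep)))
    seg_reg <- c(seg_reg, regimes[keep])
    seg_t0 <- c(seg_t0, bounds[-length(bounds)][keep])
    seg_t1 <- c(seg_t1, bounds[-1L][keep])
  }
  structure(list(
    segments = data.frame(tip = seg_tip, regime = seg_reg,
                          t0 = seg_t0, t1 = seg_t1),
    tip_regime = node_regime[seq_len(n_tip)],
    node_regime = node_regime,
    shift_branch = branch, shift_position = pos,
    shift_time = shift_time, shift_src_regime = src_regime,
    n_regimes = K + 1L), class = "regime_painting")
}

#' Number of tip species in each regime
#'
#' Counts the tips whose terminal lineage segment lies in each regime of a
#' shift configuration. Counts sum to the number of tips.
#'
#' @param phy A `phylo` object.
#' @param config A `shift_config`.
#' @return Named integer vector, names `"0"`..`"K"` (regime ids).
#' @export
regime_species_count <- function(phy, config) {
  p <- paint(phy, config)
  cnt <- tabulate(p$tip_regime + 1L, nbins = p$n_regimes)
  names(cnt) <- as.character(seq_len(p$n_regimes) - 1L)
  cnt
}
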