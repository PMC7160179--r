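#' Read a rooted, branch-length-bearing phylogeny
#'
#' Reads a tree from a Newick or Nexus file and validates that it can carry
#' a time-calibrated comparative analysis: rooted, with branch lengths, and
#' uniquely labelled tips. Ultrametricity is assessed (all root-to-tip path
#' lengths equal within a relative tolerance of 1e-6) and attached as an
#' attribute; non-ultrametric trees are accepted with a warning since the
#' Ornstein-Uhlenbeck machinery only needs node heights, not equal tip
#' depths.
#'
#' @param path Path to the tree file.
#' @param format `"newick"` or `"nexus"`; by default guessed from the file
#'   extension (`.nex`/`.nexus`/`.tre` with a NEXUS header is Nexus,
#'   everything else Newick).
#' @return An object of class `phylo` with attribute `"ultrametric"`
#'   (logical).
#' @export
read_tree <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    first <- toupper(substr(readLines(path, n = 1L, warn = FALSE), 1L, 6L))
    format <- if (ext %in% c("nex", "nexus") || identical(first, "#NEXUS"))
      "nexus" else "newick"
  }
  phy <- switch(format,
    newick = ape::read.tree(path),
    nexus  = ape::read.nexus(path))
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L)
      stop("file contains ", length(phy), " trees; expected exactly one")
    phy <- phy[[1L]]
  }
  validate_tree(phy)
}

#' Write a phylogeny to Newick or Nexus
#'
#' @param phy A `phylo` object.
#' @param path Output path.
#' @param format `"newick"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_tree <- function(phy, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  switch(format,
    newick = ape::write.tree(phy, file = path),
    nexus  = ape::write.nexus(phy, file = path))
  invisible(path)
}

#' Validate a phylogeny for comparative analysis
#'
#' @param phy A `phylo` object.
#' @return `phy` with the `"ultrametric"` attribute set.
#' @export
validate_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object")
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths; a time-calibrated tree is required")
  if (anyNA(phy$edge.length) || any(phy$edge.length < 0))
    stop("tree has missing or negative branch lengths")
  if (!ape::is.rooted(phy))
    stop("tree is unrooted; root it before analysis")
  dup <- phy$tip.label[duplicated(phy$tip.label)]
  if (length(dup))
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "))
  depths <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
  span <- max(depths)
  attr(phy, "ultrametric") <-
    span > 0 && (max(depths) - min(depths)) <= 1e-6 * span
  if (!attr(phy, "ultrametric"))
    warning("tree is not ultrametric; proceeding (OU model does not require it)")
  phy
}

#' Is the tree ultrametric (within relative tolerance 1e-6)?
#' @param phy A `phylo` object.
#' @return Logical.
#' @export
is_ultrametric <- function(phy) {
  ul <- attr(phy, "ultrametric")
  if (!is.null(ul)) return(ul)
  depths <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
  span <- max(depths)
  span > 0 && (max(depths) - min(depths)) <= 1e-6 * span
}

# Precompute the traversal structures every downstream module needs:
# node depths (time from root), per-edge descendant tip sets, per-tip
# root-to-tip edge paths, and a cladewise (preorder) edge ordering.
# Kept internal; all public functions accept a plain `phylo`.
tree_index <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  phy <- ape::reorder.phylo(phy, "cladewise")
  n_tip <- ape::Ntip(phy)
  n_node <- phy$Nnode
  n_all <- n_tip + n_node
  root <- n_tip + 1L
  edge <- phy$edge
  elen <- phy$edge.length
  depth <- ape::node.depth.edgelength(phy)

  parent <- integer(n_all)
  edge_of <- integer(n_all)          # edge index whose child is the node
  parent[edge[, 2L]] <- edge[, 1L]
  edge_of[edge[, 2L]] <- seq_len(nrow(edge))

  # tips below every edge (indexed by edge child), via postorder accumulation
  tips_below <- vector("list", n_all)
  for (i in seq_len(n_tip)) tips_below[[i]] <- i
  po <- ape::reorder.phylo(phy, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    ch <- po[i, 2L]; pa <- po[i, 1L]
    tips_below[[pa]] <- c(tips_below[[pa]], tips_below[[ch]])
  }

  # root-to-tip paths as ordered vectors of child-node ids
  paths <- vector("list", n_tip)
  for (i in seq_len(n_tip)) {
    p <- integer(0)
    nd <- i
    while (nd != root) {
      p <- c(nd, p)
      nd <- parent[nd]
    }
    paths[[i]] <- p
  }

  list(phy = phy, n_tip = n_tip, n_node = n_node, n_all = n_all,
       root = root, edge = edge, elen = elen, depth = depth,
       tip_depth = depth[seq_len(n_tip)], parent = parent,
       edge_of = edge_of, tips_below = tips_below, paths = paths,
       total_length = sum(elen))
}

# Shared path-length matrix (depth of the MRCA of each tip pair); this is
# the unit-rate Brownian-motion covariance.
shared_path_matrix <- function(phy) {
  unname(ape::vcv.phylo(phy))
}
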