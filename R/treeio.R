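# Tree input, validation, polytomy resolution and extraction of the
# ordered coalescent times consumed by the likelihood.

#' Read an ultrametric phylogeny from a Newick file
#'
#' Reads a rooted tree with branch lengths (time units) and validates that
#' it is ultrametric: all root-to-tip path lengths must agree within
#' `tolerance * tree depth`.  Empirical chronograms carry rounding noise,
#' hence the relative tolerance (default `1e-4`).
#'
#' @param path Path to a Newick file (branch lengths required; internal
#'   node labels are ignored).  If the file contains several trees only
#'   the first is returned, with a warning.
#' @param tolerance Relative ultrametricity tolerance: the maximum
#'   root-to-tip depth discrepancy allowed, as a fraction of tree depth.
#' @return An [ape::phylo] object with attributes `binary` (logical) and
#'   `depth_discrepancy` (largest root-to-tip difference found).
#' @seealso [coalescent_times()], [resolve_polytomies()], [write_newick()]
#' @export
read_newick <- function(path, tolerance = 1e-4) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop("unparseable Newick in '", path,
                                          "': ", conditionMessage(e)))
  if (is.null(tr)) stop("unparseable Newick in '", path, "'")
  if (inherits(tr, "multiPhylo")) {
    warning("file contains ", length(tr), " trees; using the first")
    tr <- tr[[1]]
  }
  validate_tree(tr, tolerance = tolerance)
}

#' Validate a phylogeny for coalescent analysis
#'
#' Checks that a tree has branch lengths, no negative branch lengths, and
#' is ultrametric within a relative tolerance.  Used by [read_newick()];
#' exported so trees built in memory can be validated the same way.
#'
#' @param tree An [ape::phylo] object.
#' @inheritParams read_newick
#' @return The tree, with attributes `binary` and `depth_discrepancy` set.
#' @export
validate_tree <- function(tree, tolerance = 1e-4) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  n <- ape::Ntip(tree)
  h <- ape::node.depth.edgelength(tree)   # root-to-node path lengths
  tip_h <- h[seq_len(n)]
  disc <- max(tip_h) - min(tip_h)
  depth <- max(tip_h)
  if (depth <= 0) stop("tree has zero depth")
  if (disc > tolerance * depth)
    stop(sprintf(paste0("not ultrametric: root-to-tip depths differ by %g ",
                        "(relative %.3g, tolerance %.3g)"),
                 disc, disc / depth, tolerance))
  attr(tree, "binary") <- ape::is.binary(tree)
  attr(tree, "depth_discrepancy") <- disc
  tree
}

#' Write a phylogeny to a Newick file
#'
#' @param tree An [ape::phylo] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Resolve polytomies with arbitrarily small internode distances
#'
#' Replaces every multifurcation of degree d by d - 2 random bifurcations
#' separated by `epsilon` time units, the standard treatment for
#' contentious nodes in empirical chronograms.  Because the internode-
#' distance likelihood depends only on the waiting times between nodes,
#' the (random) order of resolution does not affect downstream
#' log-likelihoods.  Tip depths are preserved exactly: each new node is
#' placed `epsilon` below the node it subdivides and the child branches
#' absorb the difference, so total root-to-tip depths change by at most
#' `epsilon * (d - 2)` only in the degenerate case where a child branch is
#' shorter than the accumulated offset (an error is raised instead).
#'
#' Zero-length internal branches already present in the tree (tied node
#' depths) are spaced out by `epsilon` as well, since they are polytomies
#' in all but representation.
#'
#' @param tree An [ape::phylo] object, possibly with multifurcations.
#' @param epsilon Spacing between successive resolved nodes (> 0); default
#'   `1e-6` time units.
#' @param seed Optional integer seed controlling the random resolution.
#' @return A binary [ape::phylo] object.
#' @examples
#' star <- ape::read.tree(text = "(A:1,B:1,C:1);")
#' tr <- resolve_polytomies(star, epsilon = 1e-6, seed = 1)
#' coalescent_times(tr)$internode  # one internode distance of 1e-6
#' @export
resolve_polytomies <- function(tree, epsilon = 1e-6, seed = NULL) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  has_zero_internal <- {
    internal_child <- tree$edge[, 2] > ape::Ntip(tree)
    any(internal_child & tree$edge.length == 0)
  }
  if (ape::is.rooted(tree) && ape::is.binary(tree) && !has_zero_internal)
    return(tree)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::multi2di(tree, random = TRUE)
  n <- ape::Ntip(tr)
  root <- n + 1L
  h <- ape::node.depth.edgelength(tr)       # heights measured from root
  newh <- h
  tr <- ape::reorder.phylo(tr, "cladewise") # parents before children
  # nodes introduced by the resolution sit on zero-length edges; stack the
  # nodes of each resolved polytomy at epsilon, 2*epsilon, ... below it,
  # regardless of the random topology chosen, so that every resolution
  # yields the same multiset of internode distances
  nnode_tot <- n + tr$Nnode
  cluster <- seq_len(nnode_tot)             # polytomy each new node hangs on
  spent <- integer(nnode_tot)               # epsilons used under a polytomy
  for (i in seq_len(nrow(tr$edge))) {
    par <- tr$edge[i, 1]; child <- tr$edge[i, 2]
    if (child > n && tr$edge.length[i] == 0) {
      cl <- cluster[par]
      cluster[child] <- cl
      spent[cl] <- spent[cl] + 1L
      newh[child] <- h[cl] + spent[cl] * epsilon
    } else if (child > n) {
      newh[child] <- max(h[child], newh[par])
    }                                        # tips keep their height
  }
  len <- newh[tr$edge[, 2]] - newh[tr$edge[, 1]]
  if (any(len < 0))
    stop("epsilon too large: a branch is shorter than the accumulated ",
         "resolution offset")
  tr$edge.length <- len
  tr
}

#' Extract ordered coalescent times from an ultrametric tree
#'
#' Computes the sufficient statistic of the internode-distance likelihood:
#' the depths (time before present) `t_1 > t_2 > ... > t_{n-1}` of the
#' n - 1 internal nodes of a binary ultrametric tree with n tips, numbered
#' from the root towards the tips, and the n - 2 internode distances
#' `g_j = t_{j-1} - t_j` (during `g_j` exactly j lineages exist).  The
#' terminal interval `t_{n-1}` - the time between the most recent node and
#' the present - is stored separately: it is not a waiting time between
#' cladogenesis events and is excluded from the likelihood (it is used by
#' the gamma statistic, however).
#'
#' The present is taken as the maximum root-to-tip depth, so trees that
#' are ultrametric only within tolerance are handled gracefully.
#'
#' @param tree A binary, ultrametric [ape::phylo] object with at least 3
#'   tips (resolve multifurcations first with [resolve_polytomies()]).
#' @return An object of class `"coalescent_times"`: a list with elements
#'   `n` (tip count), `node_depths` (decreasing, length n - 1),
#'   `internode` (lengths `g_2 ... g_{n-1}`), `terminal` (excluded
#'   terminal interval `t_{n-1}`) and `depth` (root depth `t_1`).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' coalescent_times(tr)
#' @export
coalescent_times <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (!ape::is.rooted(tree) || !ape::is.binary(tree))
    stop("tree has polytomies (or an unrooted basal trichotomy); use ",
         "resolve_polytomies() first")
  n <- ape::Ntip(tree)
  if (n < 3) stop("need at least 3 tips (no usable internode distance)")
  h <- ape::node.depth.edgelength(tree)
  present <- max(h[seq_len(n)])
  depths <- sort(present - h[(n + 1):(n + tree$Nnode)], decreasing = TRUE)
  as_coalescent_times(depths)
}

#' Build coalescent times from a vector of node depths
#'
#' Low-level constructor used by [coalescent_times()] and by simulation
#' code that generates node depths directly (e.g. Yule internode intervals
#' drawn as independent exponentials).
#'
#' @param node_depths Numeric vector of the n - 1 internal node depths
#'   (time before present); order is irrelevant, ties are kept.
#' @return A `"coalescent_times"` object (see [coalescent_times()]).
#' @export
as_coalescent_times <- function(node_depths) {
  depths <- sort(as.numeric(node_depths), decreasing = TRUE)
  m <- length(depths)
  if (m < 2) stop("need at least 2 node depths (3 tips)")
  if (any(depths < 0)) stop("node depths must be >= 0")
  structure(list(
    n = m + 1L,
    node_depths = depths,
    internode = -diff(depths),          # g_2 ... g_{n-1}
    terminal = depths[m],
    depth = depths[1]
  ), class = "coalescent_times")
}

#' @export
print.coalescent_times <- function(x, ...) {
  cat("Coalescent times of", x$n, "sampled species\n")
  cat("  root depth t_1        =", format(x$depth), "\n")
  cat("  internode distances   =", x$n - 2L, "(g_2 ... g_{n-1})\n")
  cat("  terminal interval     =", format(x$terminal),
      "(excluded from the likelihood)\n")
  invisible(x)
}
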