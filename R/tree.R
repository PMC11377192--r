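#' Read a time-calibrated ultrametric tree from newick
#'
#' Thin, validating wrapper around [ape::read.tree()]. The tree is the central
#' data structure of the package: a rooted phylogeny with branch lengths in
#' millions of years (Myr) and node ages measured backwards from the present
#' (tips at age 0, in Ma). All likelihood functions in the package adopt this
#' convention so that ages line up with paleo-curve axes.
#'
#' @param text newick string (exactly one of `text`/`file`).
#' @param file path to a newick file.
#' @param tol relative ultrametricity tolerance: all tip ages must lie within
#'   `tol * crown age` of zero. Trees failing this are accepted here but
#'   rejected by the likelihood functions; set `check_ultrametric = TRUE`
#'   to reject at read time.
#' @param check_ultrametric reject non-ultrametric trees immediately.
#' @return an object of class `phylo`.
#' @export
read_time_tree <- function(text = NULL, file = NULL, tol = 1e-6,
                           check_ultrametric = FALSE) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  tree <- if (!is.null(text)) ape::read.tree(text = text) else
    ape::read.tree(file = file)
  if (is.null(tree)) stop("newick parse error")
  if (is.null(tree$edge.length)) stop("branch lengths are required")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree$tip.label <- trimws(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (ape::Ntip(tree) == 1)
    warning("single-tip tree: root is non-bifurcating")
  if (check_ultrametric && !is_time_ultrametric(tree, tol))
    stop("tree is not ultrametric within tolerance ", tol)
  tree
}

#' Node ages in Ma before present
#'
#' Ages for all nodes (tips first, then internal nodes, in `phylo` node
#' numbering). The deepest tip defines the present (age 0); for an
#' ultrametric tree all tips have age ~0 and the root age is the crown age.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return numeric vector of length `Ntip + Nnode`.
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Crown age of a tree (Ma)
#' @param tree a `phylo` object.
#' @export
crown_age <- function(tree) {
  node_ages(tree)[ape::Ntip(tree) + 1L]
}

is_time_ultrametric <- function(tree, tol = 1e-6) {
  ages <- node_ages(tree)
  ca <- ages[ape::Ntip(tree) + 1L]
  if (ca <= 0) return(TRUE)
  max(abs(ages[seq_len(ape::Ntip(tree))])) <= tol * ca
}

assert_time_tree <- function(tree, tol = 1e-6, bifurcating = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a `phylo` tree")
  if (is.null(tree$edge.length)) stop("branch lengths are required")
  if (!is_time_ultrametric(tree, tol))
    stop("tree is not ultrametric within tolerance ", tol)
  if (bifurcating && !ape::is.binary(tree))
    stop("tree must be fully bifurcating for this operation")
  invisible(tree)
}

#' Branching times (internal node ages), descending
#'
#' @param tree ultrametric `phylo`.
#' @param tol ultrametricity tolerance (relative to crown age).
#' @return numeric vector of internal-node ages in Ma, sorted descending;
#'   length equals the number of internal nodes.
#' @export
branching_ages <- function(tree, tol = 1e-6) {
  assert_time_tree(tree, tol, bifurcating = FALSE)
  ages <- node_ages(tree)
  sort(ages[(ape::Ntip(tree) + 1L):length(ages)], decreasing = TRUE)
}

#' Uniformly subsample tree tips
#'
#' Retains a uniformly sampled subset of tips (rounded half up), suppresses
#' the resulting degree-2 nodes and merges branch lengths, so the result is
#' again ultrametric with the pairwise divergence times of the retained tips
#' unchanged. This mirrors the robustness check of randomly subsampling a
#' phylogeny to a fraction of its taxa.
#'
#' @param tree a `phylo` object.
#' @param fraction proportion of tips to keep, in (0, 1].
#' @param seed integer RNG seed.
#' @return pruned `phylo`.
#' @export
subsample_tips <- function(tree, fraction, seed) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- ape::Ntip(tree)
  m <- floor(n * fraction + 0.5)  # round half up
  if (m < 2) stop("fraction leaves fewer than 2 tips")
  if (m == n) return(tree)
  keep <- with_seed(seed, sample(tree$tip.label, m))
  ape::keep.tip(tree, keep)
}

#' All tips descending from the MRCA of a tip subset
#'
#' @param tree a `phylo` object.
#' @param tips character vector of tip labels (nonempty).
#' @return character vector of all tip labels in the MRCA's subtree
#'   (a superset of `tips`).
#' @export
clade_mrca_tips <- function(tree, tips) {
  tips <- trimws(tips)
  if (length(tips) == 0) stop("empty tip subset")
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (length(unique(tips)) == 1) return(unique(tips))
  node <- ape::getMRCA(tree, tips)
  tree$tip.label[tips_under(tree, node)]
}

# all node indices (tips and internal) in the subtree rooted at `node`,
# including `node` itself
nodes_under <- function(tree, node) {
  out <- node
  stack <- node
  children <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    kids <- children[[as.character(v)]]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > ape::Ntip(tree)])
  }
  out
}

# tip indices under a node (the node itself if it is a tip)
tips_under <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  children <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    kids <- children[[as.character(v)]]
    tipkids <- kids[kids <= ntip]
    out <- c(out, tipkids)
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}

#' Clade definition
#'
#' A named clade with its tip set and sampling fraction f (the proportion of
#' the clade's true species that are present in the tree).
#'
#' @param name clade name.
#' @param tips character vector of tip labels (nonempty).
#' @param sampling_fraction f in (0, 1].
#' @export
clade_def <- function(name, tips, sampling_fraction = 1) {
  tips <- trimws(tips)
  stopifnot(length(tips) >= 1, sampling_fraction > 0, sampling_fraction <= 1)
  structure(list(name = name, tips = tips,
                 sampling_fraction = sampling_fraction),
            class = "clade_def")
}

#' Read clade definitions from TSV
#'
#' Expects columns `clade`, `tip`, `sampling_fraction` (one row per tip).
#'
#' @param path TSV path.
#' @param tree optional tree to validate tip labels against.
#' @return list of [clade_def()] objects.
#' @export
read_clade_defs <- function(path, tree = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("clade", "tip", "sampling_fraction")
  if (!all(need %in% names(df)))
    stop("clade TSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$clade), function(d)
    clade_def(d$clade[1], d$tip, d$sampling_fraction[1]))
  if (!is.null(tree)) {
    for (cl in out) {
      bad <- setdiff(cl$tips, trimws(tree$tip.label))
      if (length(bad))
        stop("clade '", cl$name, "' has tips absent from tree: ",
             paste(bad, collapse = ", "))
    }
  }
  out
}
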