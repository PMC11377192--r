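# Forward birth-death tree simulation with time-varying rates, incomplete
# sampling, and an optional single rate shift. Time runs forward from the
# crown (s = 0) to the present (s = T); rate functions take the AGE
# a = T - s in Ma before present, matching the likelihood convention.

# Simulate one lineage forward from time s0 to `end` by thinning against the
# constant bound `rmax`. Returns a nested-list subtree:
#   list(len, kids = NULL|list(a, b), status = "extant"|"extinct"|"open")
# "open" leaves are lineages still alive at `end` (used for the two-phase
# shift simulator). `counter` guards against runaway lineage counts.
sim_lineage <- function(s0, end, lam, mu, rmax, T_total, counter, max_lineages) {
  s <- s0
  repeat {
    if (counter$n > max_lineages) stop("lineage cap exceeded")
    s <- s + stats::rexp(1, rmax)
    if (s >= end)
      return(list(len = end - s0, kids = NULL, status = "open"))
    a <- T_total - s
    l <- lam(a); m <- mu(a)
    if (stats::runif(1) * rmax < l + m) {
      if (stats::runif(1) * (l + m) < l) {      # speciation
        counter$n <- counter$n + 1L
        k1 <- sim_lineage(s, end, lam, mu, rmax, T_total, counter, max_lineages)
        k2 <- sim_lineage(s, end, lam, mu, rmax, T_total, counter, max_lineages)
        return(list(len = s - s0, kids = list(k1, k2), status = NA))
      } else {                                  # extinction
        return(list(len = s - s0, kids = NULL, status = "extinct"))
      }
    }
  }
}

# convert nested-list tree to newick; labels open/extant leaves with `prefix`
subtree_newick <- function(node, prefix, counter) {
  if (is.null(node$kids)) {
    if (identical(node$status, "extinct")) {
      counter$x <- counter$x + 1L
      lab <- paste0("x", counter$x)
    } else {
      counter$t <- counter$t + 1L
      lab <- paste0(prefix, counter$t)
    }
    return(paste0(lab, ":", format(node$len, digits = 17)))
  }
  paste0("(", subtree_newick(node$kids[[1]], prefix, counter), ",",
         subtree_newick(node$kids[[2]], prefix, counter), "):",
         format(node$len, digits = 17))
}

# collect references to "open" leaves (environments are mutated in place via
# indices paths); returns list of integer paths into the nested structure
open_paths <- function(node, path = integer(0)) {
  if (is.null(node$kids)) {
    if (identical(node$status, "open")) return(list(path))
    return(list())
  }
  c(open_paths(node$kids[[1]], c(path, 1L)),
    open_paths(node$kids[[2]], c(path, 2L)))
}

get_node <- function(root, path) {
  for (i in path) root <- root$kids[[i]]
  root
}

set_node <- function(root, path, value) {
  if (length(path) == 0) return(value)
  root$kids[[path[1]]] <- set_node(root$kids[[path[1]]], path[-1], value)
  root
}

# build rate functions from (rate0, dependency); dependency = NULL gives a
# constant rate, otherwise rate(a) = rate0 * exp(coef * curve(a))
make_rate_fun <- function(rate0, dependency = NULL, coef_name = "alpha") {
  if (is.null(dependency)) return(function(a) rep(rate0, length(a)))
  curve <- dependency$curve
  cf <- dependency[[coef_name]] %||% dependency$coef %||% 0
  if (inherits(curve, "paleo_curve")) {
    function(a) rate0 * exp(cf * eval_curve(curve, a))
  } else if (is.function(curve)) {
    function(a) rate0 * exp(cf * curve(a))
  } else stop("dependency$curve must be a paleo_curve or a function")
}

# prune a simulated full tree to extant, f-sampled tips, conditioning on at
# least one sampled survivor in EACH crown daughter (so crown age is kept)
prune_simulated <- function(root, T_total, f, shift_prefix = NULL) {
  cnt <- new.env(); cnt$t <- 0L; cnt$x <- 0L
  # root has two crown daughters; write each separately to track sides
  n1 <- subtree_newick(root$kids[[1]], "t", cnt)
  side1_max <- cnt$t
  n2 <- subtree_newick(root$kids[[2]], "t", cnt)
  tr <- ape::read.tree(text = paste0("(", n1, ",", n2, ");"))
  # extant = tip whose root-to-tip depth equals the full simulation span
  depth <- ape::node.depth.edgelength(tr)[seq_len(ape::Ntip(tr))]
  extant <- tr$tip.label[startsWith(tr$tip.label, "t") &
                           abs(depth - T_total) < 1e-8 * max(T_total, 1)]
  if (length(extant) < 2) return(NULL)
  sampled <- extant[stats::runif(length(extant)) <= f]
  idx <- as.integer(sub("^t", "", sampled))
  if (!any(idx <= side1_max) || !any(idx > side1_max)) return(NULL)
  ape::keep.tip(tr, sampled)
}

#' Simulate a reconstructed birth-death tree
#'
#' Forward simulation from two crown lineages under a (possibly
#' environment- or time-dependent) birth-death process, run to a fixed crown
#' age; extinct lineages are pruned and each extant tip is retained
#' independently with probability `f`. Simulation is repeated (rejection
#' sampling) until at least one sampled survivor remains on each side of the
#' crown, so the returned tree has exactly the requested crown age. Rates
#' may depend exponentially on a paleo-curve:
#' `lambda(a) = lambda0 * exp(alpha * env(a))` with `a` the age in Ma.
#'
#' @param lambda0 base speciation rate (/Myr), > 0 unless a pure 2-tip tree
#'   is intended.
#' @param mu0 base extinction rate (/Myr), >= 0.
#' @param crown_age_ma stopping crown age T (Ma).
#' @param f sampling fraction in (0, 1].
#' @param seed integer RNG seed.
#' @param lambda_dep,mu_dep optional `list(curve =, coef =)` giving the
#'   exponential dependence of each rate on a [smooth_curve()] object (or
#'   plain function of age).
#' @param max_rejections,max_lineages rejection-sampling guards.
#' @return `list(tree, truth)` where `truth` records the generating
#'   parameters and seed (sufficient to re-simulate identically).
#' @export
simulate_bd_tree <- function(lambda0, mu0 = 0, crown_age_ma, f = 1, seed,
                             lambda_dep = NULL, mu_dep = NULL,
                             max_rejections = 1000, max_lineages = 20000) {
  stopifnot(lambda0 >= 0, mu0 >= 0, f > 0, f <= 1, crown_age_ma > 0)
  lam <- make_rate_fun(lambda0, lambda_dep, "coef")
  mu <- make_rate_fun(mu0, mu_dep, "coef")
  grid <- seq(0, crown_age_ma, length.out = 512)
  rmax <- max(lam(grid) + mu(grid)) * 1.0001
  with_seed(seed, {
    for (try in seq_len(max_rejections)) {
      cnt <- new.env(); cnt$n <- 2L
      root <- if (rmax <= 0) {
        list(len = 0, kids = list(
          list(len = crown_age_ma, kids = NULL, status = "open"),
          list(len = crown_age_ma, kids = NULL, status = "open")), status = NA)
      } else {
        k1 <- sim_lineage(0, crown_age_ma, lam, mu, rmax, crown_age_ma,
                          cnt, max_lineages)
        k2 <- sim_lineage(0, crown_age_ma, lam, mu, rmax, crown_age_ma,
                          cnt, max_lineages)
        list(len = 0, kids = list(k1, k2), status = NA)
      }
      tr <- prune_simulated(root, crown_age_ma, f)
      if (!is.null(tr)) {
        return(list(
          tree = tr,
          truth = list(lambda0 = lambda0, mu0 = mu0,
                       crown_age_ma = crown_age_ma, f = f, seed = seed,
                       lambda_dep = lambda_dep, mu_dep = mu_dep,
                       rejections = try - 1L)))
      }
    }
    stop("no surviving sampled crown after ", max_rejections, " attempts")
  })
}

#' Simulate a birth-death tree with a single clade rate shift
#'
#' Two-phase forward simulation: the process runs at base rates from the
#' crown until `shift_age_ma`; one lineage alive at that moment is chosen
#' uniformly at random and it (with all its descendants) continues with
#' rates multiplied by `multiplier`, while all other lineages continue at
#' base rates. This emulates a single k-fold increase in diversification
#' rate in one clade. Truth records the shifted clade's sampled tips.
#'
#' @inheritParams simulate_bd_tree
#' @param shift_age_ma age of the shift (Ma before present), within
#'   (0, crown_age_ma).
#' @param multiplier rate multiplier (> 0) applied to both lambda and mu.
#' @return `list(tree, truth)`; `truth$shift_tips` holds the labels of
#'   sampled tips descending from the shifted lineage.
#' @export
simulate_rate_shift_tree <- function(lambda0, mu0 = 0, crown_age_ma,
                                     shift_age_ma, multiplier, f = 1, seed,
                                     max_rejections = 1000,
                                     max_lineages = 20000) {
  stopifnot(multiplier > 0, shift_age_ma > 0, shift_age_ma < crown_age_ma)
  lam <- function(a) rep(lambda0, length(a))
  mu <- function(a) rep(mu0, length(a))
  s_shift <- crown_age_ma - shift_age_ma
  rbase <- (lambda0 + mu0) * 1.0001
  rshift <- rbase * multiplier
  with_seed(seed, {
    for (try in seq_len(max_rejections)) {
      cnt <- new.env(); cnt$n <- 2L
      phase1 <- function() {
        if (rbase <= 0)
          list(len = s_shift, kids = NULL, status = "open")
        else sim_lineage(0, s_shift, lam, mu, rbase, crown_age_ma,
                         cnt, max_lineages)
      }
      root <- list(len = 0, kids = list(phase1(), phase1()), status = NA)
      paths <- open_paths(root)
      if (length(paths) == 0) next  # no lineage alive at shift time
      focal <- sample.int(length(paths), 1)
      ok <- TRUE
      for (i in seq_along(paths)) {
        mult <- if (i == focal) multiplier else 1
        lam2 <- function(a) lambda0 * mult
        mu2 <- function(a) mu0 * mult
        r2 <- if (i == focal) rshift else rbase
        sub <- tryCatch({
          if (r2 <= 0) list(len = crown_age_ma - s_shift, kids = NULL,
                            status = "open")
          else sim_lineage(s_shift, crown_age_ma, lam2, mu2, r2,
                           crown_age_ma, cnt, max_lineages)
        }, error = function(e) e)
        if (inherits(sub, "error")) { ok <- FALSE; break }
        stub <- get_node(root, paths[[i]])
        sub$len <- sub$len + stub$len
        # tag the focal subtree's leaves so shifted tips can be recovered
        if (i == focal) sub <- tag_leaves(sub)
        root <- set_node(root, paths[[i]], sub)
      }
      if (!ok) next
      tr <- prune_simulated_tagged(root, crown_age_ma, f)
      if (!is.null(tr)) {
        shift_tips <- grep("^s", tr$tree$tip.label, value = TRUE)
        return(list(
          tree = tr$tree,
          truth = list(lambda0 = lambda0, mu0 = mu0,
                       crown_age_ma = crown_age_ma,
                       shift_age_ma = shift_age_ma, multiplier = multiplier,
                       f = f, seed = seed, shift_tips = shift_tips,
                       rejections = try - 1L)))
      }
    }
    stop("no valid shifted tree after ", max_rejections, " attempts")
  })
}

# mark all non-extinct leaves of a subtree as "shifted"
tag_leaves <- function(node) {
  if (is.null(node$kids)) {
    if (!identical(node$status, "extinct")) node$status <- "shifted"
    return(node)
  }
  node$kids <- lapply(node$kids, tag_leaves)
  node
}

subtree_newick_tagged <- function(node, counter) {
  if (is.null(node$kids)) {
    lab <- if (identical(node$status, "extinct")) {
      counter$x <- counter$x + 1L; paste0("x", counter$x)
    } else if (identical(node$status, "shifted")) {
      counter$t <- counter$t + 1L; paste0("s", counter$t)
    } else {
      counter$t <- counter$t + 1L; paste0("t", counter$t)
    }
    return(paste0(lab, ":", format(node$len, digits = 17)))
  }
  paste0("(", subtree_newick_tagged(node$kids[[1]], counter), ",",
         subtree_newick_tagged(node$kids[[2]], counter), "):",
         format(node$len, digits = 17))
}

prune_simulated_tagged <- function(root, T_total, f) {
  cnt <- new.env(); cnt$t <- 0L; cnt$x <- 0L
  n1 <- subtree_newick_tagged(root$kids[[1]], cnt)
  side1_max <- cnt$t
  n2 <- subtree_newick_tagged(root$kids[[2]], cnt)
  tr <- ape::read.tree(text = paste0("(", n1, ",", n2, ");"))
  depth <- ape::node.depth.edgelength(tr)[seq_len(ape::Ntip(tr))]
  extant <- tr$tip.label[!startsWith(tr$tip.label, "x") &
                           abs(depth - T_total) < 1e-8 * max(T_total, 1)]
  if (length(extant) < 2) return(NULL)
  sampled <- extant[stats::runif(length(extant)) <= f]
  idx <- as.integer(sub("^[ts]", "", sampled))
  if (!any(idx <= side1_max) || !any(idx > side1_max)) return(NULL)
  list(tree = ape::keep.tip(tr, sampled))
}
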