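# Forward simulators for continuous traits (BM, OU), binary characters, and
# phylogenetic path-analysis datasets with known truth.

# preorder edge indices (parent before child)
preorder_edges <- function(tree) {
  tree2 <- ape::reorder.phylo(tree, "cladewise")
  match(paste(tree2$edge[, 1], tree2$edge[, 2]),
        paste(tree$edge[, 1], tree$edge[, 2]))
}

#' Paint the edges of a clade (MRCA subtree) with a regime or multiplier
#'
#' Returns a vector over tree edges (in `tree$edge` order): `base` everywhere
#' and `value` on every edge inside the MRCA subtree of `tips` (stem edge
#' excluded).
#'
#' @param tree `phylo`.
#' @param tips tip labels defining the clade.
#' @param value value painted within the clade.
#' @param base background value.
#' @export
paint_clade <- function(tree, tips, value, base = 1) {
  out <- rep(base, nrow(tree$edge))
  labs <- clade_mrca_tips(tree, tips)
  node <- if (length(labs) == 1) match(labs, tree$tip.label) else
    ape::getMRCA(tree, labs)
  inside <- nodes_under(tree, node)
  sel <- tree$edge[, 1] %in% inside  # edges whose parent is in the subtree
  out[sel] <- value
  out
}

#' Simulate multivariate Brownian-motion traits with clade-specific rates
#'
#' Independent BM per dimension from a root value of 0: the increment along
#' a branch has variance `sigma2 * multiplier(branch) * length`. Clade
#' multipliers emulate clade-structured evolutionary rates.
#'
#' @param tree `phylo` with branch lengths (Myr).
#' @param sigma2 base diffusion rate (> 0), trait units^2 / Myr.
#' @param dims number of independent trait dimensions.
#' @param clade_multipliers optional named list `clade name -> list(tips,
#'   multiplier)`; multipliers must be > 0 and apply to all branches in the
#'   clade's MRCA subtree.
#' @param seed integer RNG seed.
#' @return `list(traits, truth)`: `traits` is a tips x dims matrix with
#'   rownames = tip labels.
#' @export
simulate_traits_bm <- function(tree, sigma2, dims = 1,
                               clade_multipliers = NULL, seed) {
  stopifnot(sigma2 >= 0, dims >= 1)
  mult <- rep(1, nrow(tree$edge))
  for (cm in clade_multipliers %||% list()) {
    if (cm$multiplier <= 0) stop("clade multiplier must be > 0")
    pm <- paint_clade(tree, cm$tips, cm$multiplier, base = NA)
    mult[!is.na(pm)] <- pm[!is.na(pm)]
  }
  ntot <- ape::Ntip(tree) + tree$Nnode
  with_seed(seed, {
    x <- matrix(0, ntot, dims)
    for (e in preorder_edges(tree)) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      sd_e <- sqrt(sigma2 * mult[e] * tree$edge.length[e])
      x[ch, ] <- x[p, ] + stats::rnorm(dims, 0, sd_e)
    }
    traits <- x[seq_len(ape::Ntip(tree)), , drop = FALSE]
    rownames(traits) <- tree$tip.label
    colnames(traits) <- paste0("V", seq_len(dims))
    list(traits = traits,
         truth = list(sigma2 = sigma2, dims = dims,
                      clade_multipliers = clade_multipliers, seed = seed,
                      edge_multiplier = mult))
  })
}

#' Simulate an Ornstein-Uhlenbeck trait under a regime painting
#'
#' Exact branch-by-branch OU transition sampling: along a branch of length t
#' in regime r, `x_child ~ N(theta_r + (x_parent - theta_r) e^{-alpha t},
#' sigma2 (1 - e^{-2 alpha t}) / (2 alpha))`. With `alpha = 0` the process
#' degenerates to Brownian motion. The root starts at the root regime's
#' optimum.
#'
#' @param tree `phylo`.
#' @param regimes integer/character vector over edges (in `tree$edge` order)
#'   giving each branch's regime id; every branch must be painted.
#' @param root_regime regime id governing the root state.
#' @param alpha selection strength (/Myr), >= 0.
#' @param sigma2 diffusion (> 0).
#' @param theta named vector of per-regime optima.
#' @param seed integer RNG seed.
#' @return `list(traits, truth)`; `traits` is a named numeric tip vector.
#' @export
simulate_traits_ou <- function(tree, regimes, root_regime, alpha, sigma2,
                               theta, seed) {
  stopifnot(alpha >= 0, sigma2 > 0)
  if (length(regimes) != nrow(tree$edge)) stop("every branch must be painted")
  if (anyNA(regimes)) stop("unpainted branch (NA regime)")
  bad <- setdiff(unique(as.character(regimes)), names(theta))
  if (length(bad)) stop("no optimum for regime(s): ",
                        paste(bad, collapse = ", "))
  ntot <- ape::Ntip(tree) + tree$Nnode
  with_seed(seed, {
    x <- rep(NA_real_, ntot)
    x[ape::Ntip(tree) + 1L] <- theta[[as.character(root_regime)]]
    for (e in preorder_edges(tree)) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      t <- tree$edge.length[e]
      th <- theta[[as.character(regimes[e])]]
      if (alpha == 0) {
        m <- x[p]; v <- sigma2 * t
      } else {
        w <- exp(-alpha * t)
        m <- th + (x[p] - th) * w
        v <- sigma2 * (1 - w^2) / (2 * alpha)
      }
      x[ch] <- stats::rnorm(1, m, sqrt(v))
    }
    traits <- x[seq_len(ape::Ntip(tree))]
    names(traits) <- tree$tip.label
    list(traits = traits,
         truth = list(alpha = alpha, sigma2 = sigma2, theta = theta,
                      root_regime = root_regime, regimes = regimes,
                      seed = seed))
  })
}

#' Simulate a binary character by a 2-state Markov chain
#'
#' Continuous-time 2-state simulation along the tree; the root state is drawn
#' from the stationary distribution unless fixed. Emulates a binary
#' biogeographic background (e.g. Andean vs extra-Andean occurrence).
#'
#' @param tree `phylo`.
#' @param q01 rate 0 -> 1 (/Myr), >= 0.
#' @param q10 rate 1 -> 0 (/Myr), >= 0.
#' @param root_state optional fixed root state (0/1); required if both rates
#'   are zero.
#' @param seed integer RNG seed.
#' @return `list(states, truth)`; `states` is a named 0/1 tip vector.
#' @export
simulate_binary_character <- function(tree, q01, q10, root_state = NULL,
                                      seed) {
  stopifnot(q01 >= 0, q10 >= 0)
  if (q01 + q10 == 0 && is.null(root_state))
    stop("both rates zero: a root state must be given")
  # 2-state transition probability over time t
  p_stay <- function(from, t) {
    q <- q01 + q10
    if (q == 0) return(1)
    pi1 <- q01 / q
    if (from == 0) (1 - pi1) + pi1 * exp(-q * t) else
      pi1 + (1 - pi1) * exp(-q * t)
  }
  ntot <- ape::Ntip(tree) + tree$Nnode
  with_seed(seed, {
    x <- rep(NA_integer_, ntot)
    x[ape::Ntip(tree) + 1L] <- if (!is.null(root_state)) as.integer(root_state)
      else stats::rbinom(1, 1, q01 / (q01 + q10))
    for (e in preorder_edges(tree)) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      stay <- p_stay(x[p], tree$edge.length[e])
      x[ch] <- if (stats::runif(1) <= stay) x[p] else 1L - x[p]
    }
    states <- x[seq_len(ape::Ntip(tree))]
    names(states) <- tree$tip.label
    list(states = states,
         truth = list(q01 = q01, q10 = q10, root_state = root_state,
                      seed = seed))
  })
}
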