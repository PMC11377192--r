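# Forward DEC simulation: anagenetic dispersal/extirpation along branches
# (Gillespie, stratified rates) and cladogenetic range inheritance at nodes
# using the same event set and weights as the likelihood.

# one anagenetic trajectory from a_start (older) to a_end (younger);
# a lineage hitting the null (empty) range is re-drawn from the branch
# start (conditioning each lineage on being observed), up to `max_tries`
sim_branch_ranges <- function(state, a_start, a_end, space, params, Qs,
                              max_tries = 200) {
  for (try in seq_len(max_tries)) {
    st <- state
    a <- a_start
    dead <- FALSE
    while (a > a_end + 1e-12) {
      s <- stratum_at(params, a)
      rates <- Qs[[s]][st, ]
      tot <- -Qs[[s]][st, st]
      # stay until the next stratum boundary below `a`
      bnd <- if (is.null(params$strata_ma)) a_end else {
        b <- params$strata_ma
        inner <- b[b < a - 1e-12 & b > a_end]
        if (length(inner)) max(inner) else a_end
      }
      if (tot <= 0) { a <- bnd; next }
      wait <- stats::rexp(1, tot)
      if (a - wait <= bnd) { a <- bnd; next }
      a <- a - wait
      probs <- pmax(rates, 0); probs[st] <- 0
      st <- sample.int(space$n_states, 1, prob = probs)
      if (length(space$states[[st]]) == 0) { dead <- TRUE; break }
    }
    if (!dead) return(st)
  }
  NA_integer_
}

#' Forward-simulate tip ranges under DEC
#'
#' Simulates anagenetic dispersal/extirpation along each branch and
#' cladogenetic range inheritance at each node, with the same event set and
#' weights as [dec_loglik()]. Trajectories hitting the null (empty) range
#' are rejected and the whole simulation redrawn, conditioning on ranges
#' being observed at all tips.
#'
#' @param tree ultrametric bifurcating `phylo`.
#' @param space a [range_state_space()].
#' @param params a [dec_params()].
#' @param root_range character vector of area codes for the root (nonempty);
#'   `NULL` draws uniformly from the allowed states.
#' @param seed RNG seed.
#' @param max_rejections rejection cap (high extirpation rates reject often).
#' @return `list(tip_ranges, node_states, truth)`; `tip_ranges` is a named
#'   list of area-code vectors.
#' @export
simulate_ranges_dec <- function(tree, space, params, root_range = NULL,
                                seed, max_rejections = 1000) {
  assert_time_tree(tree)
  setup <- dec_setup(space, params)
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  children <- split(tree$edge[, 2], tree$edge[, 1])
  root_idx <- if (!is.null(root_range)) {
    range_indices(space, list(root_range))
  } else NA_integer_
  allowed <- which(lengths(space$states) > 0)
  with_seed(seed, {
    for (try in seq_len(max_rejections)) {
      st <- rep(NA_integer_, ntot)  # state on arrival at each node
      st[ntip + 1L] <- if (is.na(root_idx))
        allowed[sample.int(length(allowed), 1)] else root_idx
      ok <- TRUE
      preorder <- unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1])
      for (v in preorder) {
        sc <- setup$clado[[st[v]]]
        pick <- sample.int(nrow(sc), 1, prob = sc[, "weight"])
        daughters <- sc[pick, c("left", "right")]
        kids <- children[[as.character(v)]]
        for (ci in 1:2) {
          res <- sim_branch_ranges(daughters[ci], ages[v], ages[kids[ci]],
                                   space, params, setup$Qs)
          if (is.na(res)) { ok <- FALSE; break }
          st[kids[ci]] <- res
        }
        if (!ok) break
      }
      if (ok) {
        tip_ranges <- lapply(seq_len(ntip), function(i)
          space$areas[space$states[[st[i]]]])
        names(tip_ranges) <- tree$tip.label
        return(list(tip_ranges = tip_ranges, node_states = st,
                    truth = list(params = params, root_range = root_range,
                                 seed = seed, rejections = try - 1L)))
      }
    }
    stop("excessive rejection: lineages keep hitting the null range")
  })
}
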