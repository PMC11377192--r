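# Time-stratified dispersal-extinction-cladogenesis (DEC, optional +J):
# state space over subsets of areas, anagenetic rate matrices from d, e and
# per-stratum dispersal multipliers raised to the power w, cladogenetic
# range inheritance, pruning likelihood, ML fitting, and marginal ancestral
# range probabilities.

#' Build a DEC range state space
#'
#' States are all nonempty subsets of the areas up to `max_size`, plus the
#' null (empty) range, which is reachable anagenetically (absorbing) but
#' excluded from cladogenesis, tips, and the root.
#'
#' @param areas character vector of area codes (<= 9 recommended).
#' @param max_size maximum range size (default `min(5, length(areas))`).
#' @return object of class `range_state_space`: `areas`, `max_size`,
#'   `states` (list of integer area-index vectors; state 1 is the null
#'   range), `labels` (e.g. "AB"), `n_states`.
#' @export
range_state_space <- function(areas, max_size = min(5L, length(areas))) {
  stopifnot(length(areas) >= 1, max_size >= 1, max_size <= length(areas))
  A <- length(areas)
  states <- list(integer(0))
  for (k in seq_len(max_size))
    states <- c(states, utils::combn(A, k, simplify = FALSE))
  labels <- vapply(states, function(s)
    if (length(s) == 0) "0" else paste(areas[s], collapse = ""), character(1))
  structure(list(areas = areas, max_size = max_size, states = states,
                 labels = labels, n_states = length(states)),
            class = "range_state_space")
}

#' DEC parameters
#'
#' @param d dispersal rate (/Myr), >= 0.
#' @param e extirpation rate (/Myr), >= 0.
#' @param j founder-event (jump) weight, >= 0; 0 gives classic DEC.
#' @param w exponent applied to the dispersal multipliers, in [0, 3].
#' @param multipliers optional per-stratum list of area x area multiplier
#'   matrices (values conventionally in [0.00001, 1]); NULL means all 1.
#' @param strata_ma optional vector of stratum boundary ages (Ma), e.g.
#'   `c(34, 20, 15, 5, 0)` for the four-stratum scheme 34-20, 20-15, 15-5,
#'   5-0 Ma; NULL for a single stratum.
#' @export
dec_params <- function(d, e, j = 0, w = 1, multipliers = NULL,
                       strata_ma = NULL) {
  stopifnot(d >= 0, e >= 0, j >= 0, w >= 0, w <= 3)
  if (!is.null(strata_ma)) {
    strata_ma <- sort(unique(as.numeric(strata_ma)), decreasing = TRUE)
    ns <- length(strata_ma) - 1
    if (ns < 1) stop("need at least two stratum boundaries")
    if (!is.null(multipliers) && length(multipliers) != ns)
      stop("need one multiplier matrix per stratum")
  }
  structure(list(d = d, e = e, j = j, w = w, multipliers = multipliers,
                 strata_ma = strata_ma),
            class = "dec_params")
}

# stratum index for an age (1 = oldest); single stratum when strata_ma NULL
stratum_at <- function(params, age) {
  if (is.null(params$strata_ma)) return(1L)
  b <- params$strata_ma
  idx <- findInterval(-age, -b, rightmost.closed = TRUE)
  max(1L, min(idx, length(b) - 1L))
}

#' Anagenetic DEC rate matrix for one stratum
#'
#' Dispersal into area a from range R has rate
#' `sum_{b in R} d * m_s(b, a)^w`; extirpation of any occupied area has
#' rate `e` (loss from a single-area range leads to the absorbing null
#' range). Rows sum to zero.
#'
#' @param space a [range_state_space()].
#' @param params a [dec_params()].
#' @param stratum stratum index (1 = oldest).
#' @return dense rate matrix (n_states x n_states).
#' @export
build_q <- function(space, params, stratum = 1L) {
  ns <- space$n_states
  A <- length(space$areas)
  m <- if (!is.null(params$multipliers)) params$multipliers[[stratum]] else
    matrix(1, A, A)
  mw <- m^params$w
  Q <- matrix(0, ns, ns, dimnames = list(space$labels, space$labels))
  key <- vapply(space$states, paste, character(1), collapse = ",")
  idx_of <- function(s) match(paste(s, collapse = ","), key)
  for (i in seq_len(ns)) {
    R <- space$states[[i]]
    if (length(R) == 0) next  # null range is absorbing
    if (length(R) < space$max_size) {
      for (a in setdiff(seq_len(A), R)) {
        rate <- params$d * sum(mw[R, a])
        if (rate > 0) {
          jx <- idx_of(sort(c(R, a)))
          Q[i, jx] <- Q[i, jx] + rate
        }
      }
    }
    for (a in R) {
      jx <- idx_of(setdiff(R, a))
      Q[i, jx] <- Q[i, jx] + params$e
    }
    Q[i, i] <- -sum(Q[i, -i])
  }
  Q
}

# cladogenetic scenario table for one parent state index: matrix with columns
# (left state, right state, weight); weights not yet normalized
clado_scenarios <- function(space, parent_idx, j = 0) {
  R <- space$states[[parent_idx]]
  key <- vapply(space$states, paste, character(1), collapse = ",")
  idx_of <- function(s) match(paste(sort(s), collapse = ","), key)
  out <- list()
  if (length(R) == 0) return(NULL)
  if (length(R) == 1) {
    out[[length(out) + 1]] <- c(parent_idx, parent_idx, 1)  # narrow sympatry
  } else {
    for (a in R) {
      ia <- idx_of(a)
      # subset sympatry (both orders)
      out[[length(out) + 1]] <- c(parent_idx, ia, 1)
      out[[length(out) + 1]] <- c(ia, parent_idx, 1)
      # vicariance (both orders); remainder must respect max_size (it does,
      # being a subset of R)
      ir <- idx_of(setdiff(R, a))
      out[[length(out) + 1]] <- c(ia, ir, 1)
      out[[length(out) + 1]] <- c(ir, ia, 1)
    }
  }
  if (j > 0) {
    A <- length(space$areas)
    for (a in setdiff(seq_len(A), R)) {
      ia <- idx_of(a)
      out[[length(out) + 1]] <- c(parent_idx, ia, j)
      out[[length(out) + 1]] <- c(ia, parent_idx, j)
    }
  }
  mat <- do.call(rbind, out)
  colnames(mat) <- c("left", "right", "weight")
  # collapse duplicated (left, right) scenarios (vicariance on 2-area
  # ranges is generated once per lost area, i.e. twice)
  mat[!duplicated(mat[, c("left", "right"), drop = FALSE]), , drop = FALSE]
}

# transition matrix over a branch segment set: branch runs from child age
# a_child up to parent age a_parent; returns P such that
# L_parent_side = P %*% L_child (conditional likelihoods flow tip -> root)
branch_transition <- function(space, params, Qs, a_child, a_parent) {
  if (a_parent <= a_child + 1e-12) return(diag(space$n_states))
  if (is.null(params$strata_ma)) {
    return(as.matrix(Matrix::expm(Qs[[1]] * (a_parent - a_child))))
  }
  b <- params$strata_ma
  cuts <- sort(unique(c(a_child, a_parent, b[b > a_child & b < a_parent])))
  P <- diag(space$n_states)
  # propagate upward (young -> old): P_total = P_oldest ... P_youngest
  for (i in seq_len(length(cuts) - 1)) {
    lo <- cuts[i]; hi <- cuts[i + 1]
    s <- stratum_at(params, (lo + hi) / 2)
    P <- as.matrix(Matrix::expm(Qs[[s]] * (hi - lo))) %*% P
  }
  P
}

dec_setup <- function(space, params) {
  ns_strata <- if (is.null(params$strata_ma)) 1L else
    length(params$strata_ma) - 1L
  Qs <- lapply(seq_len(ns_strata), function(s) build_q(space, params, s))
  clado <- lapply(seq_len(space$n_states), function(i)
    clado_scenarios(space, i, params$j))
  list(Qs = Qs, clado = clado)
}

range_indices <- function(space, tip_ranges) {
  key <- vapply(space$states, paste, character(1), collapse = ",")
  vapply(tip_ranges, function(r) {
    ia <- sort(match(r, space$areas))
    if (anyNA(ia)) stop("unknown area code in tip range")
    if (length(ia) == 0) stop("tip range must be nonempty")
    ix <- match(paste(ia, collapse = ","), key)
    if (is.na(ix)) stop("tip range exceeds max range size")
    ix
  }, integer(1))
}

# core pruning pass; returns per-node conditional likelihood vectors
# (state of the node on arrival, i.e. before its own cladogenesis) plus the
# per-node log scaling factors
dec_prune <- function(tree, tip_idx, space, params, setup) {
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  ages <- node_ages(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  Ls <- vector("list", ntot)
  logscale <- numeric(ntot)
  postorder <- rev(unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1]))
  for (i in seq_len(ntip)) {
    v <- numeric(space$n_states)
    v[tip_idx[i]] <- 1
    Ls[[i]] <- v
  }
  for (v in postorder) {
    kids <- children[[as.character(v)]]
    if (length(kids) != 2) stop("DEC requires a bifurcating tree")
    up <- lapply(kids, function(ch) {
      P <- branch_transition(space, params, setup$Qs, ages[ch], ages[v])
      drop(P %*% Ls[[ch]])
    })
    L <- numeric(space$n_states)
    for (s in seq_len(space$n_states)) {
      sc <- setup$clado[[s]]
      if (is.null(sc)) next
      wsum <- sum(sc[, "weight"])
      L[s] <- sum(sc[, "weight"] * up[[1]][sc[, "left"]] *
                    up[[2]][sc[, "right"]]) / wsum
    }
    sc_max <- max(L)
    if (sc_max <= 0) {
      logscale[v] <- -Inf
      Ls[[v]] <- L
    } else {
      Ls[[v]] <- L / sc_max
      logscale[v] <- log(sc_max) + sum(logscale[kids])
    }
  }
  list(L = Ls, logscale = logscale, root = ntip + 1L)
}

#' DEC log-likelihood
#'
#' Pruning-algorithm likelihood of the tip ranges under the (optionally
#' time-stratified, optionally +J) DEC model. Branch transition matrices are
#' matrix exponentials multiplied segment-wise across stratum boundaries;
#' at each internal node the allowed cladogenetic scenarios (narrow
#' sympatry, subset sympatry, vicariance, and founder-event jumps weighted
#' by `j` when `j > 0`) are normalized per parent state. The root state is
#' weighted uniformly over allowed (non-null) states.
#'
#' @param tree ultrametric bifurcating `phylo`.
#' @param tip_ranges named list (by tip label) of character vectors of area
#'   codes, or a named character vector of comma/empty-separated codes.
#' @param space a [range_state_space()].
#' @param params a [dec_params()].
#' @return log-likelihood.
#' @export
dec_loglik <- function(tree, tip_ranges, space, params) {
  assert_time_tree(tree)
  tip_ranges <- normalize_ranges(tip_ranges, tree)
  tip_idx <- range_indices(space, tip_ranges)
  setup <- dec_setup(space, params)
  pr <- dec_prune(tree, tip_idx, space, params, setup)
  rootL <- pr$L[[pr$root]]
  allowed <- which(lengths(space$states) > 0)
  lik <- mean(rootL[allowed])
  if (lik <= 0 || !is.finite(pr$logscale[pr$root])) return(-Inf)
  log(lik) + pr$logscale[pr$root]
}

normalize_ranges <- function(tip_ranges, tree) {
  if (is.character(tip_ranges))
    tip_ranges <- lapply(tip_ranges, function(s)
      strsplit(gsub(" ", "", s), ",")[[1]])
  if (is.null(names(tip_ranges)) ||
      !all(tree$tip.label %in% names(tip_ranges)))
    stop("tip_ranges must be named and cover all tips")
  tip_ranges[tree$tip.label]
}

#' Fit DEC parameters by maximum likelihood
#'
#' Bounded ML over the requested free parameters (d, e on the log scale;
#' j in [0, 3]; w in [0, 3]) with multiple starts.
#'
#' @param tree ultrametric bifurcating `phylo`.
#' @param tip_ranges see [dec_loglik()].
#' @param space a [range_state_space()].
#' @param free character subset of `c("d", "e", "j", "w")`.
#' @param init a [dec_params()] giving fixed values and starting values.
#' @param starts number of optimization starts.
#' @param seed RNG seed for start jitter.
#' @return object of class `dec_fit`: `params`, `logL`, `k`, `aicc`,
#'   `n_tips`.
#' @export
fit_dec <- function(tree, tip_ranges, space, free = c("d", "e"),
                    init = dec_params(d = 0.01, e = 0.01), starts = 3,
                    seed = 1) {
  stopifnot(length(free) >= 1, all(free %in% c("d", "e", "j", "w")))
  tip_ranges <- normalize_ranges(tip_ranges, tree)
  to_opt <- function(p) vapply(free, function(nm)
    if (nm %in% c("d", "e")) log(max(p[[nm]], 1e-8)) else p[[nm]],
    numeric(1))
  from_opt <- function(v) {
    p <- init
    for (i in seq_along(free)) {
      nm <- free[i]
      p[[nm]] <- if (nm %in% c("d", "e")) exp(v[i]) else
        min(max(v[i], 0), 3)
    }
    p
  }
  negll <- function(v) {
    p <- from_opt(v)
    -tryCatch(dec_loglik(tree, tip_ranges, space, p),
              error = function(e) -Inf)
  }
  v0 <- to_opt(init)
  jit <- with_seed(seed, lapply(seq_len(max(starts - 1, 0)), function(i)
    v0 + stats::rnorm(length(v0), 0, 1)))
  best <- NULL
  for (v in c(list(v0), jit)) {
    res <- if (length(free) == 1) {
      tryCatch(stats::optim(v, negll, method = "Brent",
                            lower = v - 8, upper = v + 8),
               error = function(e) NULL)
    } else {
      tryCatch(stats::optim(v, negll, method = "Nelder-Mead",
                            control = list(maxit = 500, reltol = 1e-8)),
               error = function(e) NULL)
    }
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all DEC optimization starts failed")
  k <- length(free)
  n <- ape::Ntip(tree)
  logL <- -best$value
  structure(list(params = from_opt(best$par), logL = logL, k = k,
                 n_tips = n,
                 aicc = -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)),
            class = "dec_fit")
}

#' @export
print.dec_fit <- function(x, ...) {
  cat(sprintf("dec_fit: d=%.4g e=%.4g j=%.3g w=%.3g logL=%.4f AICc=%.3f\n",
              x$params$d, x$params$e, x$params$j, x$params$w, x$logL,
              x$aicc))
  invisible(x)
}

#' Marginal ancestral range probabilities
#'
#' Standard two-pass computation: tip-to-root conditional likelihoods
#' (pruning), then root-to-tip back-propagation through both the
#' cladogenetic scenario weights and the branch transition matrices. Each
#' node's marginal is over its state "on arrival" (below its own
#' cladogenetic event); probabilities at every node sum to 1.
#'
#' @inheritParams dec_loglik
#' @return matrix (nodes x states; rows = internal node numbers in `phylo`
#'   numbering, root first) of marginal probabilities.
#' @export
ancestral_ranges <- function(tree, tip_ranges, space, params) {
  assert_time_tree(tree)
  tip_ranges <- normalize_ranges(tip_ranges, tree)
  tip_idx <- range_indices(space, tip_ranges)
  setup <- dec_setup(space, params)
  pr <- dec_prune(tree, tip_idx, space, params, setup)
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  ages <- node_ages(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  U <- vector("list", ntot)
  prior <- ifelse(lengths(space$states) > 0, 1, 0)
  prior <- prior / sum(prior)
  U[[pr$root]] <- prior
  preorder <- unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1])
  marg <- matrix(0, tree$Nnode, space$n_states,
                 dimnames = list((ntip + 1L):ntot, space$labels))
  for (v in preorder) {
    kids <- children[[as.character(v)]]
    ups <- lapply(kids, function(ch) {
      P <- branch_transition(space, params, setup$Qs, ages[ch], ages[v])
      list(P = P, Lup = drop(P %*% pr$L[[ch]]))
    })
    for (ci in 1:2) {
      ch <- kids[ci]; other <- ups[[3 - ci]]$Lup
      # U at the top of the child branch (state assigned to this daughter)
      Utop <- numeric(space$n_states)
      for (s in seq_len(space$n_states)) {
        if (U[[v]][s] == 0) next
        sc <- setup$clado[[s]]
        if (is.null(sc)) next
        wsum <- sum(sc[, "weight"])
        mine <- sc[, c("left", "right")[ci]]
        oth <- sc[, c("left", "right")[3 - ci]]
        contrib <- U[[v]][s] * sc[, "weight"] * other[oth] / wsum
        Utop <- Utop + as.numeric(
          tapply(contrib, factor(mine, levels = seq_len(space$n_states)),
                 sum, default = 0))
      }
      P <- ups[[ci]]$P
      U[[ch]] <- drop(crossprod(P, Utop))
      tot <- sum(U[[ch]])
      if (tot > 0) U[[ch]] <- U[[ch]] / tot
    }
  }
  for (v in (ntip + 1L):ntot) {
    post <- U[[v]] * pr$L[[v]]
    marg[v - ntip, ] <- post / sum(post)
  }
  marg
}
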