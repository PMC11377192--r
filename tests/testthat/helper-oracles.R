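# Independent oracles and small fixtures used across the suite. These are
# deliberately written as brute-force / closed-form computations that share
# no code with the package internals they check.

# closed-form constant-rate birth-death likelihood on a reconstructed tree
# (crown-age + both-crown-lineages-survival conditioning, sampling f),
# using the analytic E(t) and high-precision quadrature of the log-flow
const_bd_oracle <- function(tree, lam, mu, f) {
  T <- crown_age(tree)
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  r <- lam - mu
  E <- function(t) 1 - f * r / (f * lam + (lam * (1 - f) - mu) * exp(-r * t))
  g <- function(t) -(lam + mu) + 2 * lam * E(t)
  s <- sum(mapply(function(a, b)
    stats::integrate(g, a, b, rel.tol = 1e-13)$value,
    ages[tree$edge[, 2]], ages[tree$edge[, 1]]))
  s + ntip * log(f) + (ntip - 1) * log(lam) - (log(lam) + 2 * log(1 - E(T)))
}

# dense multivariate-normal log density (independent of package internals)
mvn_logdens <- function(y, mu, S) {
  n <- length(y)
  as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(S, logarithm = TRUE)$modulus +
                       t(y - mu) %*% solve(S, y - mu)))
}

# brute-force d-separation: X and Y d-separated by Z in a DAG given as a
# 2-column edge matrix over `vertices`. Enumerates all undirected paths and
# applies the blocking rules (collider logic with descendants).
bf_dsep <- function(vertices, edges, x, y, z) {
  if (nrow(edges) == 0) return(TRUE)
  nbr <- function(v) unique(c(edges[edges[, 1] == v, 2],
                              edges[edges[, 2] == v, 1]))
  desc <- function(v) {
    out <- character(0); stack <- v
    while (length(stack)) {
      cur <- stack[[1]]; stack <- stack[-1]
      ch <- edges[edges[, 1] == cur, 2]
      ch <- setdiff(ch, out)
      out <- c(out, ch); stack <- c(stack, ch)
    }
    out
  }
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == y) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
    for (w in setdiff(nbr(v), path)) walk(c(path, w))
  }
  walk(x)
  if (!length(paths)) return(TRUE)
  is_edge <- function(a, b) any(edges[, 1] == a & edges[, 2] == b)
  for (p in paths) {
    if (length(p) == 2) return(FALSE)  # direct edge: never blocked
    blocked <- FALSE
    for (i in 2:(length(p) - 1)) {
      a <- p[i - 1]; v <- p[i]; b <- p[i + 1]
      collider <- is_edge(a, v) && is_edge(b, v)
      if (collider) {
        if (!(v %in% z) && !any(desc(v) %in% z)) { blocked <- TRUE; break }
      } else {
        if (v %in% z) { blocked <- TRUE; break }
      }
    }
    if (!blocked) return(FALSE)
  }
  TRUE
}

# a small reproducible ultrametric tree fixture; deterministically scans
# seeds until the realized size is near the target (the birth-death tip
# count has high variance)
fixture_tree <- function(n_target = 30, seed = 5, crown = 10) {
  for (s in seed + 0:50) {
    tr <- simulate_bd_tree(log(n_target / 2) / crown, 0,
                           crown_age_ma = crown, f = 1, seed = s)$tree
    if (ape::Ntip(tr) >= 0.7 * n_target && ape::Ntip(tr) <= 1.5 * n_target)
      return(tr)
  }
  stop("no fixture tree of suitable size found")
}

# a young subclade (crown age below `max_rel_age` of the tree's crown age)
# with at least `min_tips` tips — a late-burst painting target
fixture_young_clade <- function(tree, min_tips = 6, max_rel_age = 0.5) {
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  cand <- (ntip + 2L):(ntip + tree$Nnode)
  cand <- cand[ages[cand] <= max_rel_age * max(ages)]
  sizes <- vapply(cand, function(v)
    length(macroevopaths:::tips_under(tree, v)), integer(1))
  cand <- cand[sizes >= min_tips]
  if (!length(cand)) stop("no young clade in fixture tree")
  best <- cand[which.max(vapply(cand, function(v)
    length(macroevopaths:::tips_under(tree, v)), integer(1)))]
  tree$tip.label[macroevopaths:::tips_under(tree, best)]
}

# a genuine subclade (tips under an internal node) of roughly the requested
# relative size
fixture_clade <- function(tree, frac = 0.3) {
  ntip <- ape::Ntip(tree)
  sizes <- vapply((ntip + 2L):(ntip + tree$Nnode), function(v)
    length(macroevopaths:::tips_under(tree, v)), integer(1))
  target <- max(2, round(frac * ntip))
  node <- (ntip + 2L):(ntip + tree$Nnode)
  best <- node[which.min(abs(sizes - target))]
  tree$tip.label[macroevopaths:::tips_under(tree, best)]
}

# brute-force DEC likelihood on a 2- or 3-tip tree by enumerating all
# internal-node states and cladogenetic scenarios; transition probabilities
# from the Kolmogorov forward ODE (deSolve), independent of Matrix::expm
bf_transition <- function(Q, t) {
  ns <- nrow(Q)
  out <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    sol <- deSolve::ode(y = as.numeric(seq_len(ns) == i),
                        times = c(0, t),
                        func = function(tt, y, p) list(drop(y %*% Q)),
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
    out[i, ] <- sol[2, -1]
  }
  out
}

bf_dec_loglik_3tip <- function(tree, tip_idx, space, params) {
  # tree assumed "((A,B),C);"-shaped with node ages from the tree
  Q <- build_q(space, params, 1)
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  kids_of <- function(v) tree$edge[tree$edge[, 1] == v, 2]
  clado <- lapply(seq_len(space$n_states), function(i)
    macroevopaths:::clado_scenarios(space, i, params$j))
  allowed <- which(lengths(space$states) > 0)
  Pcache <- new.env()
  Pt <- function(t) {
    key <- format(t, digits = 12)
    if (is.null(Pcache[[key]])) Pcache[[key]] <- bf_transition(Q, t)
    Pcache[[key]]
  }
  # enumerate states recursively
  lik_node <- function(v, state) {
    if (v <= ntip) return(as.numeric(state == tip_idx[v]))
    sc <- clado[[state]]
    if (is.null(sc)) return(0)
    kids <- kids_of(v)
    tot <- 0
    for (r in seq_len(nrow(sc))) {
      lks <- vapply(1:2, function(ci) {
        top <- sc[r, ci]
        ch <- kids[ci]
        P <- Pt(ages[v] - ages[ch])
        sum(vapply(seq_len(space$n_states), function(s2)
          P[top, s2] * lik_node(ch, s2), numeric(1)))
      }, numeric(1))
      tot <- tot + sc[r, "weight"] * lks[1] * lks[2]
    }
    tot / sum(sc[, "weight"])
  }
  log(mean(vapply(allowed, function(s) lik_node(root, s), numeric(1))))
}

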