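#' DR statistic (inverse equal-splits tip speciation rate)
#'
#' For tip i with root-to-tip edges indexed j = 1 (terminal) ... N_i
#' (root-adjacent) of lengths l_j, the equal-splits measure is
#' `ES_i = sum_j l_j * 2^-(j-1)` and `DR_i = 1 / ES_i` (units /Myr). DR is a
#' fast per-tip proxy for the speciation rate that allows high variance
#' among tips.
#'
#' @param tree ultrametric bifurcating `phylo`, >= 2 tips.
#' @return named numeric vector of DR values (one per tip, all > 0).
#' @export
dr_statistic <- function(tree) {
  assert_time_tree(tree)
  ntip <- ape::Ntip(tree)
  parent_of <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- ntip + 1L
  es <- vapply(seq_len(ntip), function(i) {
    v <- i; w <- 1; acc <- 0
    while (v != root) {
      acc <- acc + elen[v] * w
      w <- w / 2
      v <- parent_of[v]
    }
    acc
  }, numeric(1))
  if (any(es <= 0)) stop("zero-length root-to-tip path")
  stats::setNames(1 / es, tree$tip.label)
}

#' Phylogenetic ridge regression: per-branch and per-tip trait rates
#'
#' Regresses tip trait values on the tips x branches incidence matrix L
#' (L[i, b] = length of branch b if b lies on the root-to-tip-i path, else
#' 0), solving, per trait axis,
#' `min_beta ||y - y_root - L beta||^2 + penalty * ||beta||^2`,
#' where `y_root` is the GLS root estimate under Brownian motion. The
#' coefficient `beta_b` is branch b's evolutionary rate for that axis; a
#' tip's rate is the Euclidean norm across axes of its terminal-branch
#' coefficients (a single scalar per trait space, as required downstream).
#'
#' The `"auto"` penalty is chosen by generalized cross-validation over a log
#' grid spanning `1e-6 ... 1e3` times `tr(L'L)/n_branches` (recorded in the
#' output); this is a deterministic, reproducible choice of shrinkage.
#'
#' @param tree ultrametric bifurcating `phylo`.
#' @param traits matrix (species x axes) or numeric vector; rownames/names
#'   must match tip labels; no missing values.
#' @param penalty positive ridge penalty, 0 (unpenalized; an error is raised
#'   if the system is singular), or `"auto"`.
#' @return list with `branch_rates` (branches x axes, rows in `tree$edge`
#'   order), `tip_rates` (named vector), `penalty` (the value used), and
#'   `root` (per-axis root estimates).
#' @export
ridge_rates <- function(tree, traits, penalty = "auto") {
  assert_time_tree(tree)
  if (is.null(dim(traits))) traits <- cbind(V1 = traits)
  if (is.null(rownames(traits))) stop("traits must be named by species")
  if (anyNA(traits)) stop("traits contain missing values")
  miss <- setdiff(tree$tip.label, rownames(traits))
  if (length(miss)) stop("traits missing for: ", paste(miss, collapse = ", "))
  traits <- traits[tree$tip.label, , drop = FALSE]
  ntip <- ape::Ntip(tree)
  nb <- nrow(tree$edge)
  # incidence matrix of branch lengths on root-to-tip paths
  L <- matrix(0, ntip, nb)
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of <- match(seq_len(ntip + tree$Nnode), tree$edge[, 2])
  root <- ntip + 1L
  for (i in seq_len(ntip)) {
    v <- i
    while (v != root) {
      e <- edge_of[v]
      L[i, e] <- tree$edge.length[e]
      v <- parent_of[v]
    }
  }
  # GLS root estimate under BM
  V <- bm_vcv(tree)[tree$tip.label, tree$tip.label]
  Vi1 <- solve(V, rep(1, ntip))
  root_est <- drop(crossprod(Vi1, traits)) / sum(Vi1)
  root_est <- matrix(root_est, nrow = 1)
  Yc <- sweep(traits, 2, root_est)
  LtL <- crossprod(L)
  scale_pen <- sum(diag(LtL)) / nb
  solve_ridge <- function(lam) {
    A <- LtL + diag(lam, nb)
    beta <- solve(A, crossprod(L, Yc))
    beta
  }
  if (identical(penalty, "auto")) {
    grid <- scale_pen * 10^seq(-6, 3, length.out = 19)
    gcv <- vapply(grid, function(lam) {
      A <- LtL + diag(lam, nb)
      Ainv_Lt <- solve(A, t(L))
      H <- L %*% Ainv_Lt
      edf <- sum(diag(H))
      res <- Yc - H %*% Yc
      sum(res^2) / (1 - edf / ntip)^2
    }, numeric(1))
    lam <- grid[which.min(gcv)]
  } else if (is.numeric(penalty) && penalty == 0) {
    if (rcond_sym(LtL) < 1e-12)
      stop("system singular with penalty = 0 on this tree")
    lam <- 0
  } else {
    stopifnot(is.numeric(penalty), penalty > 0)
    lam <- penalty
  }
  beta <- solve_ridge(lam)
  colnames(beta) <- colnames(traits)
  term_edge <- edge_of[seq_len(ntip)]
  tip_rates <- sqrt(rowSums(beta[term_edge, , drop = FALSE]^2))
  names(tip_rates) <- tree$tip.label
  list(branch_rates = beta, tip_rates = tip_rates, penalty = lam,
       root = drop(root_est))
}

rcond_sym <- function(A) {
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' Randomization test for elevated rates in a focal clade
#'
#' Observed statistic: mean absolute tip rate within the clade. Null:
#' the same statistic on random tip subsets of equal size. Two-tailed
#' p-value with add-one correction:
#' `p = (1 + 2 * min(#{null >= obs}, #{null <= obs})) / (reps + 1)`,
#' capped at 1.
#'
#' @param tip_rates named numeric vector of per-tip rates.
#' @param clade a [clade_def()] or character vector of tip labels
#'   (>= 2 tips, fewer than all tips).
#' @param reps number of random subsets (a warning is issued below 100).
#' @param seed integer RNG seed.
#' @return list with `p_value`, `observed`, `null_mean`, `effect_size`
#'   (observed / null mean).
#' @export
rate_shift_test <- function(tip_rates, clade, reps = 1000, seed = 1) {
  tips <- if (inherits(clade, "clade_def")) clade$tips else clade
  tips <- intersect(tips, names(tip_rates))
  n <- length(tips)
  if (n < 2 || n >= length(tip_rates))
    stop("focal clade must have >= 2 and < all tips")
  if (reps < 100) warning("reps < 100 gives coarse p-value resolution")
  obs <- mean(abs(tip_rates[tips]))
  null <- with_seed(seed, vapply(seq_len(reps), function(i)
    mean(abs(sample(tip_rates, n))), numeric(1)))
  p <- min(1, (1 + 2 * min(sum(null >= obs), sum(null <= obs))) / (reps + 1))
  list(p_value = p, observed = obs, null_mean = mean(null),
       effect_size = obs / mean(null))
}
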