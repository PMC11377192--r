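# Brownian-motion and multi-optimum Ornstein-Uhlenbeck (Hansen) model
# fitting on single trait axes, with BIC / pBIC comparison of a priori
# regime hypotheses (e.g. a single Andean shift vs a core-clade shift vs
# multiple pollinator shifts).

#' Regime painting for OU hypotheses
#'
#' A map from branches to selective regimes. Regime ids are recoded to
#' contiguous integers 0..m-1 (order of first appearance, root regime
#' first).
#'
#' @param tree `phylo`.
#' @param regimes vector over edges (in `tree$edge` order); every branch
#'   must be painted.
#' @param root_regime regime governing the root state.
#' @return object of class `regime_painting`: `edge_regime` (integer 0-based
#'   codes), `root_regime` (code), `levels`, `m`.
#' @export
regime_painting <- function(tree, regimes, root_regime) {
  if (length(regimes) != nrow(tree$edge)) stop("every branch must be painted")
  if (anyNA(regimes)) stop("unpainted branch (NA regime)")
  lev <- unique(c(as.character(root_regime), as.character(regimes)))
  structure(list(edge_regime = match(as.character(regimes), lev) - 1L,
                 root_regime = 0L, levels = lev, m = length(lev)),
            class = "regime_painting")
}

#' Paint a single-shift hypothesis (background + one clade regime)
#'
#' @param tree `phylo`.
#' @param shift_tips tips whose MRCA subtree gets the shifted regime.
#' @return a [regime_painting()] with m = 2 (or m = 1 if the clade spans
#'   the whole tree).
#' @export
paint_shift <- function(tree, shift_tips) {
  reg <- paint_clade(tree, shift_tips, "shift", base = "bg")
  if (all(reg == "shift")) return(regime_painting(tree, reg, "shift"))
  regime_painting(tree, reg, "bg")
}

#' Fit Brownian motion to a trait vector
#'
#' ML under `y ~ N(mu0 * 1, sigma2 * V)` with V the shared-path-length (BM)
#' covariance; closed-form GLS estimates (ML variance, divisor n).
#'
#' @param tree ultrametric `phylo`.
#' @param y named numeric trait vector covering all tips.
#' @return object of class `bm_fit`: `sigma2`, `root`, `logL`, `k` (= 2),
#'   `degenerate` (TRUE when y has zero variance).
#' @export
fit_bm <- function(tree, y) {
  assert_time_tree(tree, bifurcating = FALSE)
  y <- y[tree$tip.label]
  if (anyNA(y)) stop("y must be complete and named by tip label")
  n <- length(y)
  V <- bm_vcv(tree)[tree$tip.label, tree$tip.label]
  R <- chol(V)
  z1 <- backsolve(R, rep(1, n), transpose = TRUE)
  zy <- backsolve(R, y, transpose = TRUE)
  mu0 <- sum(z1 * zy) / sum(z1^2)
  resid <- zy - mu0 * z1
  s2 <- sum(resid^2) / n
  degenerate <- s2 <= .Machine$double.eps * max(1, stats::var(y))
  logL <- if (degenerate) Inf else
    -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(R))) + n)
  structure(list(sigma2 = s2, root = mu0, logL = logL, k = 2,
                 degenerate = degenerate),
            class = "bm_fit")
}

# OU mean design (weight matrix W over regimes, tips x m) and correlation
# structure for an ultrametric tree with the root at the root regime's
# optimum: for tips i, j with MRCA at time t_a from the root (depth) and
# tree height T, V_ij = sigma2/(2 alpha) * exp(-alpha * d_ij) *
# (1 - exp(-2 alpha * t_a)), d_ij = 2 (T - t_a).
ou_structure <- function(tree, painting, alpha) {
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  T <- max(ages)
  m <- painting$m
  W <- matrix(0, ntip, m)
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of <- match(seq_len(ntip + tree$Nnode), tree$edge[, 2])
  root <- ntip + 1L
  for (i in seq_len(ntip)) {
    v <- i
    while (v != root) {
      e <- edge_of[v]
      r <- painting$edge_regime[e] + 1L
      # segment from age a_parent to a_child; weight in Hansen mean:
      # exp(-alpha * a_child) - exp(-alpha * a_parent)
      W[i, r] <- W[i, r] +
        (exp(-alpha * ages[v]) - exp(-alpha * ages[parent_of[v]]))
      v <- parent_of[v]
    }
    W[i, painting$root_regime + 1L] <- W[i, painting$root_regime + 1L] +
      exp(-alpha * T)
  }
  Vbm <- bm_vcv(tree)  # shared path length = depth of MRCA
  ta <- Vbm
  if (alpha == 0) {
    V0 <- ta  # BM limit of V / sigma2
  } else {
    dij <- 2 * (T - ta)
    V0 <- exp(-alpha * dij) * (1 - exp(-2 * alpha * ta)) / (2 * alpha)
  }
  list(W = W, V0 = V0[tree$tip.label, tree$tip.label])
}

# profile logL over (theta, sigma2) given alpha
ou_profile <- function(tree, y, painting, alpha) {
  n <- length(y)
  st <- ou_structure(tree, painting, alpha)
  R <- tryCatch(chol(st$V0), error = function(e) NULL)
  if (is.null(R)) return(list(logL = -Inf))
  Zw <- backsolve(R, st$W, transpose = TRUE)
  zy <- backsolve(R, y, transpose = TRUE)
  XtX <- crossprod(Zw)
  if (rcond_sym(XtX) < 1e-14) {
    # collinear regime weights (e.g. alpha ~ 0 makes non-root columns ~ 0):
    # drop near-null columns, keep root regime
    keep <- sqrt(diag(XtX)) > 1e-10 * max(sqrt(diag(XtX)))
    keep[painting$root_regime + 1L] <- TRUE
    Zw <- Zw[, keep, drop = FALSE]
    XtX <- crossprod(Zw)
    theta_full <- rep(NA_real_, painting$m)
  } else keep <- rep(TRUE, painting$m)
  theta <- solve(XtX, crossprod(Zw, zy))
  resid <- zy - Zw %*% theta
  s2 <- sum(resid^2) / n
  if (s2 <= 0) return(list(logL = -Inf))
  logL <- -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(R))) + n)
  th <- rep(NA_real_, painting$m)
  th[keep] <- drop(theta)
  list(logL = logL, sigma2 = s2, theta = th)
}

#' Fit a multi-optimum OU (Hansen) model
#'
#' ML fit of an Ornstein-Uhlenbeck model with regime-specific optima painted
#' on branches: the expected tip value is a weighted combination of the
#' optima (weights decaying exponentially with selection strength along each
#' root-to-tip path; the root sits at the root regime's optimum), and the
#' covariance is the non-stationary OU covariance for ultrametric trees.
#' Optima are profiled by GLS and sigma2 analytically; alpha is optimized on
#' the log scale, with the alpha -> 0 limit handled analytically
#' (continuation to BM).
#'
#' @param tree ultrametric `phylo`.
#' @param y named trait vector.
#' @param painting a [regime_painting()].
#' @param alpha optional fixed alpha (skips optimization).
#' @param alpha_range log10 search range for alpha (/Myr).
#' @return object of class `ou_fit`: `alpha`, `sigma2`, `theta` (named by
#'   regime level), `logL`, `k`, `m`, `n`, `bic`.
#' @export
fit_ou <- function(tree, y, painting, alpha = NULL,
                   alpha_range = c(-4, 2)) {
  assert_time_tree(tree, bifurcating = FALSE)
  y <- y[tree$tip.label]
  if (anyNA(y)) stop("y must be complete and named by tip label")
  n <- length(y)
  if (is.null(alpha)) {
    # profile over log10(alpha), compare with the BM limit alpha = 0
    obj <- function(la) -ou_profile(tree, y, painting, 10^la)$logL
    opt <- stats::optimize(obj, interval = alpha_range, tol = 1e-6)
    cand_alpha <- 10^opt$minimum
    p_opt <- ou_profile(tree, y, painting, cand_alpha)
    p_bm <- ou_profile(tree, y, painting, 0)
    if (p_bm$logL > p_opt$logL + 1e-9) {
      alpha <- 0; prof <- p_bm
    } else {
      alpha <- cand_alpha; prof <- p_opt
    }
  } else {
    prof <- ou_profile(tree, y, painting, alpha)
  }
  if (!is.finite(prof$logL))
    stop("OU likelihood degenerate for this painting/trait")
  theta <- prof$theta
  names(theta) <- painting$levels
  m <- painting$m
  k <- 2 + m
  structure(list(alpha = alpha, sigma2 = prof$sigma2, theta = theta,
                 logL = prof$logL, k = k, m = m, n = n,
                 bic = -2 * prof$logL + k * log(n),
                 painting = painting),
            class = "ou_fit")
}

#' @export
print.ou_fit <- function(x, ...) {
  cat(sprintf("ou_fit: m=%d regimes, alpha=%.4g, sigma2=%.4g, logL=%.4f\n",
              x$m, x$alpha, x$sigma2, x$logL))
  cat("  theta:", paste(names(x$theta), format(x$theta, digits = 4),
                        sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Compare OU/BM fits by BIC or pBIC
#'
#' `BIC = -2 logL + k ln n` with `k = 2 + m` (alpha, sigma2, m optima);
#' `pBIC = BIC + 2 ln C(edges, m - 1)`, additionally penalizing the number
#' of possible placements of the m - 1 shifts on the tree's edges
#' (a deterministic multiplicity correction, labelled "pBIC(config-count)").
#' For m = 1 the two criteria coincide.
#'
#' @param fits list of `ou_fit` (and/or `bm_fit`, treated as m = 1 with
#'   k = 2) objects on the same data.
#' @param n number of tips (consistency-checked against ou fits).
#' @param edges number of tree edges.
#' @param penalty `"pBIC"` (default) or `"BIC"`.
#' @return data.frame ranked ascending by the chosen criterion.
#' @export
compare_ou <- function(fits, n, edges, penalty = c("pBIC", "BIC")) {
  penalty <- match.arg(penalty)
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (inherits(f, "bm_fit")) {
      m <- 1L; k <- 2L; logL <- f$logL
    } else {
      if (!is.null(f$n) && f$n != n) stop("inconsistent n across fits")
      m <- f$m; k <- f$k; logL <- f$logL
    }
    bic <- -2 * logL + k * log(n)
    pbic <- bic + 2 * lchoose(edges, m - 1)
    data.frame(model = names(fits)[i] %||% paste0("model", i),
               m = m, k = k, logL = logL, BIC = bic, pBIC = pbic,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  crit <- if (penalty == "pBIC") tab$pBIC else tab$BIC
  tab <- tab[order(crit), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab
}
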