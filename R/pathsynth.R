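# Phylogenetic path analysis: causal-model DAGs, Shipley d-separation basis
# sets, mixed continuous/binary phylogenetic regressions, Fisher's C, CICc
# ranking and conditional model averaging.

#' Define a causal model (DAG)
#'
#' @param name model label.
#' @param edges character vector of `"A->B"` edges (or 2-column matrix).
#' @param vertices vertex set; default is the union of edge endpoints plus
#'   the standard variables `BG, climR, vegR, florR, SR`.
#' @return object of class `causal_model`: `name`, `vertices`, `edges`
#'   (2-column character matrix, possibly 0 rows).
#' @export
causal_model <- function(name, edges,
                         vertices = c("BG", "climR", "vegR", "florR", "SR")) {
  if (is.character(edges)) {
    parts <- strsplit(gsub(" ", "", edges), "->", fixed = TRUE)
    if (length(edges) && any(lengths(parts) != 2))
      stop("edges must look like 'A->B'")
    edges <- if (length(edges)) do.call(rbind, parts) else
      matrix(character(0), 0, 2)
  }
  edges <- matrix(as.character(edges), ncol = 2)
  vertices <- unique(c(vertices, as.vector(edges)))
  if (anyDuplicated(vertices)) stop("duplicate vertices")
  m <- structure(list(name = name, vertices = vertices, edges = edges),
                 class = "causal_model")
  topo_order(m)  # errors on cycles
  m
}

# topological order with lexicographic tie-break (deterministic)
topo_order <- function(model) {
  v <- sort(model$vertices)
  edges <- model$edges
  indeg <- stats::setNames(integer(length(v)), v)
  for (i in seq_len(nrow(edges))) indeg[edges[i, 2]] <- indeg[edges[i, 2]] + 1L
  out <- character(0)
  remaining <- v
  while (length(remaining)) {
    free <- remaining[indeg[remaining] == 0]
    if (!length(free)) stop("cyclic model: ", model$name)
    nxt <- sort(free)[1]
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
    ch <- edges[edges[, 1] == nxt, 2]
    for (c2 in ch) indeg[c2] <- indeg[c2] - 1L
  }
  out
}

parents_of <- function(model, v) unique(model$edges[model$edges[, 2] == v, 1])

#' Shipley d-separation basis of a causal model
#'
#' One conditional-independence claim per non-adjacent vertex pair: the
#' claim's response is the pair member later in topological order
#' (lexicographic tie-break), and the conditioning set is the union of both
#' members' parents minus the pair itself.
#'
#' @param model a [causal_model()].
#' @return list of claims `list(x, y, given)` with `y` the response;
#'   deterministic order.
#' @export
dsep_basis <- function(model) {
  ord <- topo_order(model)
  v <- ord
  adj <- paste(model$edges[, 1], model$edges[, 2])
  claims <- list()
  for (i in seq_along(v)) for (jj in seq_along(v)) {
    if (jj <= i) next
    a <- v[i]; b <- v[jj]  # b later in topological order
    if (paste(a, b) %in% adj || paste(b, a) %in% adj) next
    given <- setdiff(union(parents_of(model, a), parents_of(model, b)),
                     c(a, b))
    claims[[length(claims) + 1]] <- list(x = a, y = b, given = sort(given))
  }
  claims
}

#' Phylogenetic GLS regression with Pagel's lambda
#'
#' GLS under residual covariance `sigma2 [lambda V* + (1 - lambda) I]`,
#' where V* is the Brownian-motion covariance scaled to unit diagonal;
#' lambda is estimated by bounded ML on [0, 1] (profiled via the
#' eigendecomposition of V*), interpolating between star-tree independence
#' (0) and full Brownian structure (1). Coefficient p-values are two-sided
#' t-tests on n - p degrees of freedom.
#'
#' @param y named numeric response over all tips.
#' @param X predictor data.frame/matrix (rownames = species) or NULL for an
#'   intercept-only model; an intercept is always added.
#' @param tree ultrametric `phylo` covering all species.
#' @param lambda optional fixed lambda (skips estimation).
#' @return object of class `pgls_fit`: `coefficients` (data.frame with
#'   estimate, se, t, p), `lambda`, `sigma2`, `logL`, `n`, `df_residual`.
#' @export
pgls_lambda <- function(y, X = NULL, tree, lambda = NULL) {
  sp <- tree$tip.label
  y <- y[sp]
  if (anyNA(y)) stop("y must cover all tips")
  n <- length(y)
  Xm <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(X)) {
    X <- as.data.frame(X)[sp, , drop = FALSE]
    if (anyNA(X)) stop("X must cover all tips")
    Xm <- cbind(Xm, as.matrix(X))
  }
  p <- ncol(Xm)
  if (n <= p + 2) stop("need n > p + 2")
  V <- bm_vcv(tree)[sp, sp]
  V <- V / mean(diag(V))  # unit diagonal (ultrametric: constant diagonal)
  eg <- eigen(V, symmetric = TRUE)
  U <- eg$vectors; dv <- eg$values
  ty <- crossprod(U, y); tX <- crossprod(U, Xm)
  fit_at <- function(lam) {
    w <- lam * dv + (1 - lam)
    if (any(w <= 0)) return(list(logL = -Inf))
    sw <- 1 / sqrt(w)
    Xs <- tX * sw; ys <- ty * sw
    XtX <- crossprod(Xs)
    if (rcond_sym(XtX) < 1e-12) stop("singular design")
    beta <- solve(XtX, crossprod(Xs, ys))
    res <- ys - Xs %*% beta
    s2 <- sum(res^2) / n
    logL <- -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n)
    list(logL = logL, beta = beta, s2 = s2, XtX = XtX)
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(function(l) -fit_at(l)$logL, c(0, 1), tol = 1e-8)
    lambda <- opt$minimum
    # check the boundaries explicitly (optimize avoids the endpoints)
    for (lb in c(0, 1))
      if (fit_at(lb)$logL > fit_at(lambda)$logL) lambda <- lb
  }
  ft <- fit_at(lambda)
  se <- sqrt(diag(solve(ft$XtX)) * ft$s2 * n / (n - p))
  tval <- drop(ft$beta) / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  structure(list(
    coefficients = data.frame(term = colnames(Xm), estimate = drop(ft$beta),
                              se = se, t = tval, p = pval,
                              stringsAsFactors = FALSE, row.names = NULL),
    lambda = lambda, sigma2 = ft$s2, logL = ft$logL, n = n,
    df_residual = n - p), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("pgls_fit: n=%d lambda=%.3f logL=%.3f\n", x$n, x$lambda,
              x$logL))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Firth-penalized logistic regression with a phylogenetic random effect
#'
#' Logistic regression of a binary response with Firth's Jeffreys-prior
#' penalty (guaranteeing finite estimates under separation), plus an
#' optional phylogenetic random effect approximated by a single variance
#' component `s2` on V* (the unit-diagonal Brownian covariance): the latent
#' effect b ~ N(0, s2 V*) enters the linear predictor and is integrated out
#' by Laplace approximation; `s2` is chosen on a coarse profile grid
#' including 0, at which the model reduces to plain Firth logistic
#' regression. Wald p-values.
#'
#' @param y named 0/1 response over all tips (both classes present).
#' @param X predictors (rownames = species); an intercept is added.
#' @param tree ultrametric `phylo`; `NULL` (or `s2_grid = 0`) drops the
#'   phylogenetic component.
#' @param s2_grid candidate variance components (default `c(0, 0.25, 1)`).
#' @return object of class `phylo_logistic_fit`: `coefficients` (estimate,
#'   se, z, p), `s2`, `converged`.
#' @export
phylo_logistic <- function(y, X, tree = NULL, s2_grid = c(0, 0.25, 1)) {
  sp <- if (!is.null(tree)) tree$tip.label else names(y)
  y <- y[sp]
  if (anyNA(y)) stop("y must cover all species")
  if (length(unique(y)) < 2) stop("response has a single class")
  n <- length(y)
  Xm <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(X)) {
    X <- as.data.frame(X)[sp, , drop = FALSE]
    Xm <- cbind(Xm, as.matrix(X))
  }
  p <- ncol(Xm)
  if (n <= p + 2) stop("need n > p + 2")
  Vs <- if (!is.null(tree)) {
    V <- bm_vcv(tree)[sp, sp]; V / mean(diag(V))
  } else NULL
  if (is.null(Vs)) s2_grid <- 0
  fit_at <- function(s2) {
    # joint penalized IRLS over (beta, b); b absorbed via generalized ridge
    use_re <- s2 > 0
    Z <- if (use_re) diag(n) else NULL
    Kinv <- if (use_re) solve(Vs + diag(1e-8, n)) / s2 else NULL
    beta <- rep(0, p); b <- rep(0, n)
    for (it in 1:100) {
      eta <- drop(Xm %*% beta) + if (use_re) b else 0
      mu <- 1 / (1 + exp(-eta))
      Wd <- pmax(mu * (1 - mu), 1e-10)
      # Firth adjustment via hat diagonal of the fixed-effect part
      XW <- Xm * Wd
      Finf <- crossprod(Xm, XW)
      h <- rowSums((Xm %*% solve(Finf)) * XW)
      ystar <- y + h * (0.5 - mu)
      score_b <- if (use_re) (ystar - mu - h * (0.5 - mu)) else NULL
      # working response update
      grad_beta <- crossprod(Xm, ystar - mu)
      if (use_re) {
        # block update: beta given b, then b given beta (penalized)
        Hbb <- diag(Wd) + Kinv
        b_new <- solve(Hbb, (y - mu) + Wd * b)
        b <- drop(b_new)
        eta <- drop(Xm %*% beta) + b
        mu <- 1 / (1 + exp(-eta))
        Wd <- pmax(mu * (1 - mu), 1e-10)
        XW <- Xm * Wd
        Finf <- crossprod(Xm, XW)
        h <- rowSums((Xm %*% solve(Finf)) * XW)
        ystar <- y + h * (0.5 - mu)
        grad_beta <- crossprod(Xm, ystar - mu)
      }
      step <- solve(Finf + diag(1e-10, p), grad_beta)
      beta <- beta + drop(step)
      if (max(abs(step)) < 1e-8) break
    }
    eta <- drop(Xm %*% beta) + if (use_re) b else 0
    mu <- 1 / (1 + exp(-eta))
    Wd <- pmax(mu * (1 - mu), 1e-10)
    Finf <- crossprod(Xm, Xm * Wd)
    # Firth-penalized log-likelihood (+ Laplace terms for the random effect)
    ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12))) +
      0.5 * determinant(Finf, logarithm = TRUE)$modulus
    if (use_re) {
      Hbb <- diag(Wd) + Kinv
      ll <- ll - 0.5 * drop(crossprod(b, Kinv %*% b)) -
        0.5 * determinant(Hbb, logarithm = TRUE)$modulus -
        0.5 * determinant(s2 * Vs, logarithm = TRUE)$modulus -
        0.5 * n * log(2 * pi) + 0.5 * n * log(2 * pi)
    }
    list(beta = beta, se = sqrt(diag(solve(Finf))), ll = as.numeric(ll),
         converged = it < 100, s2 = s2)
  }
  fits <- lapply(s2_grid, fit_at)
  best <- fits[[which.max(vapply(fits, function(f) f$ll, numeric(1)))]]
  z <- best$beta / best$se
  structure(list(
    coefficients = data.frame(term = colnames(Xm), estimate = best$beta,
                              se = best$se, z = z,
                              p = 2 * stats::pnorm(-abs(z)),
                              stringsAsFactors = FALSE, row.names = NULL),
    s2 = best$s2, converged = best$converged),
    class = "phylo_logistic_fit")
}

#' Fit a causal model by phylogenetic d-separation
#'
#' Each basis claim `X _||_ Y | Z` (Y the topologically later member) is
#' tested by regressing Y on X and Z — [pgls_lambda()] when Y is
#' continuous, [phylo_logistic()] when Y is the binary `BG` — and taking
#' the p-value of X's coefficient. Fisher's `C = -2 sum ln p_i` is compared
#' to a chi-squared distribution with `2k` df (k claims), and
#' `CICc = C + 2 q n / (n - 1 - q)` with q the number of edges (by default;
#' configurable to edges + vertices). Per-edge path coefficients come from
#' regressing each vertex on its parents.
#'
#' @param model a [causal_model()].
#' @param data data.frame with rownames = species and columns covering the
#'   model's vertices; `BG` binary 0/1, other variables continuous
#'   (z-scored internally once).
#' @param tree ultrametric `phylo`.
#' @param q_count `"edges"` (default) or `"edges_plus_vertices"`.
#' @param binary_vars variables treated as binary (default `"BG"`).
#' @return object of class `path_fit`: `stats` (k, C, df, p, q, n, CICc),
#'   `claims` (per-claim p-values), `edge_coefficients` (data.frame with
#'   from, to, estimate, se).
#' @export
fit_path_model <- function(model, data, tree,
                           q_count = c("edges", "edges_plus_vertices"),
                           binary_vars = "BG") {
  q_count <- match.arg(q_count)
  pd <- prepare_path_data(data, tree, binary_vars)
  claims <- dsep_basis(model)
  k <- length(claims)
  claim_p <- numeric(k)
  # predictors (including binary BG) are z-scored so every reported
  # coefficient is on the standardized scale
  std_cols <- function(d) {
    for (v in names(d))
      if (stats::sd(d[[v]]) > 0) d[[v]] <- as.numeric(scale(d[[v]]))
    d
  }
  for (i in seq_along(claims)) {
    cl <- claims[[i]]
    preds <- c(cl$x, cl$given)
    Xd <- std_cols(pd$data[, preds, drop = FALSE])
    if (cl$y %in% binary_vars) {
      f <- phylo_logistic(pd$data[[cl$y]], Xd, tree)
    } else {
      f <- pgls_lambda(stats::setNames(pd$data[[cl$y]], rownames(pd$data)),
                       Xd, tree)
    }
    claim_p[i] <- f$coefficients$p[match(cl$x, f$coefficients$term)]
  }
  C <- if (k) -2 * sum(log(pmax(claim_p, 1e-300))) else 0
  pC <- if (k) stats::pchisq(C, df = 2 * k, lower.tail = FALSE) else 1
  q <- nrow(model$edges) +
    if (q_count == "edges_plus_vertices") length(model$vertices) else 0
  n <- nrow(pd$data)
  if (n - 1 - q <= 0) stop("n - 1 - q <= 0: CICc undefined")
  cicc <- C + 2 * q * n / (n - 1 - q)
  # per-edge coefficients: regress each vertex on its parents
  ec <- list()
  for (v in unique(model$edges[, 2])) {
    pa <- parents_of(model, v)
    Xd <- std_cols(pd$data[, pa, drop = FALSE])
    f <- if (v %in% binary_vars) phylo_logistic(pd$data[[v]], Xd, tree) else
      pgls_lambda(stats::setNames(pd$data[[v]], rownames(pd$data)), Xd, tree)
    for (pv in pa) {
      r <- f$coefficients[match(pv, f$coefficients$term), ]
      ec[[length(ec) + 1]] <- data.frame(from = pv, to = v,
                                         estimate = r$estimate, se = r$se,
                                         stringsAsFactors = FALSE)
    }
  }
  edge_co <- if (length(ec)) do.call(rbind, ec) else
    data.frame(from = character(0), to = character(0),
               estimate = numeric(0), se = numeric(0))
  structure(list(
    model = model,
    stats = data.frame(model = model$name, k = k, C = C, df = 2 * k,
                       p = pC, q = q, n = n, CICc = cicc,
                       stringsAsFactors = FALSE),
    claims = data.frame(
      x = vapply(claims, `[[`, character(1), "x"),
      y = vapply(claims, `[[`, character(1), "y"),
      given = vapply(claims, function(cl)
        paste(cl$given, collapse = "+"), character(1)),
      p = claim_p, stringsAsFactors = FALSE),
    edge_coefficients = edge_co), class = "path_fit")
}

prepare_path_data <- function(data, tree, binary_vars = "BG") {
  data <- as.data.frame(data)
  if (is.null(rownames(data)) && "species" %in% names(data)) {
    rownames(data) <- data$species
    data$species <- NULL
  }
  miss <- setdiff(tree$tip.label, rownames(data))
  if (length(miss)) stop("data missing species: ", paste(miss, collapse = ", "))
  data <- data[tree$tip.label, , drop = FALSE]
  if (anyNA(data)) stop("incomplete rows in path data")
  for (v in names(data)) {
    if (v %in% binary_vars) {
      if (length(unique(data[[v]])) < 2)
        stop("binary variable '", v, "' has a single class")
    } else if (stats::sd(data[[v]]) > 0) {
      data[[v]] <- as.numeric(scale(data[[v]]))
    }
  }
  list(data = data)
}

#' Rank causal models by CICc and average the supported set
#'
#' Models are sorted by CICc; relative likelihood `exp(-dCICc/2)` is
#' normalized into CICc weights. Models with `dCICc <` the threshold form
#' the averaging set; each edge's averaged coefficient is the
#' weight-renormalized mean over the averaging-set models containing that
#' edge (conditional averaging), with 95% CIs from Buckland-style
#' model-averaged standard errors
#' `se = sum_m w_m sqrt(se_m^2 + (b_m - b_bar)^2)`.
#'
#' @param models list of [causal_model()]s.
#' @param data,tree as in [fit_path_model()].
#' @param threshold dCICc threshold for the averaging set (default 2).
#' @param ... passed to [fit_path_model()].
#' @return object of class `path_ranking`: `ranking` (data.frame with k, C,
#'   p, q, CICc, dCICc, rel_lik, weight), `averaged` (from, to, estimate,
#'   se, ci_lower, ci_upper), `fits`.
#' @export
rank_and_average <- function(models, data, tree, threshold = 2, ...) {
  stopifnot(length(models) >= 1)
  fits <- lapply(models, fit_path_model, data = data, tree = tree, ...)
  tab <- do.call(rbind, lapply(fits, function(f) f$stats))
  tab$dCICc <- tab$CICc - min(tab$CICc)
  tab$rel_lik <- exp(-tab$dCICc / 2)
  tab$weight <- tab$rel_lik / sum(tab$rel_lik)
  ord <- order(tab$CICc)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  rownames(tab) <- NULL
  avg_idx <- which(tab$dCICc < threshold)
  w <- tab$weight[avg_idx]; w <- w / sum(w)
  all_edges <- unique(do.call(rbind, lapply(fits[avg_idx], function(f)
    f$edge_coefficients[, c("from", "to")])))
  avg <- NULL
  if (!is.null(all_edges) && nrow(all_edges)) {
    rows <- lapply(seq_len(nrow(all_edges)), function(i) {
      e <- all_edges[i, ]
      est <- se <- ww <- numeric(0)
      for (mi in seq_along(avg_idx)) {
        ecs <- fits[[avg_idx[mi]]]$edge_coefficients
        hit <- which(ecs$from == e$from & ecs$to == e$to)
        if (length(hit)) {
          est <- c(est, ecs$estimate[hit]); se <- c(se, ecs$se[hit])
          ww <- c(ww, w[mi])
        }
      }
      ww <- ww / sum(ww)
      bbar <- sum(ww * est)
      se_avg <- sum(ww * sqrt(se^2 + (est - bbar)^2))
      data.frame(from = e$from, to = e$to, estimate = bbar, se = se_avg,
                 ci_lower = bbar - 1.96 * se_avg,
                 ci_upper = bbar + 1.96 * se_avg,
                 stringsAsFactors = FALSE)
    })
    avg <- do.call(rbind, rows)
  }
  structure(list(ranking = tab, averaged = avg, fits = fits,
                 averaging_set = tab$model[avg_idx]),
            class = "path_ranking")
}

#' @export
print.path_ranking <- function(x, ...) {
  cat("Phylogenetic path analysis: CICc ranking\n")
  print(x$ranking[, c("model", "k", "C", "p", "q", "CICc", "dCICc",
                      "weight")], digits = 4)
  cat("Averaging set:", paste(x$averaging_set, collapse = ", "), "\n")
  invisible(x)
}

#' The default set of 11 causal models
#'
#' Increasingly complex hypotheses for the dependence of speciation rate
#' (SR) on biogeographic background (BG) and the rates of climatic-niche
#' (climR), vegetative-trait (vegR), and floral-trait (florR) evolution:
#' models 1-4 are single direct effects; 5-10 add the biogeography ->
#' climatic-niche link and trait cascades; model 11 is the full model in
#' which BG drives climR, climR drives SR and both trait rates, the trait
#' rates affect SR, and BG retains a direct SR effect.
#'
#' @return named list of 11 [causal_model()]s.
#' @export
default_model_set <- function() {
  specs <- list(
    m01_BG       = "BG->SR",
    m02_climR    = "climR->SR",
    m03_vegR     = "vegR->SR",
    m04_florR    = "florR->SR",
    m05_chain    = c("BG->climR", "climR->SR"),
    m06_direct   = c("BG->climR", "BG->SR"),
    m07_both     = c("BG->climR", "climR->SR", "BG->SR"),
    m08_cascade  = c("BG->climR", "climR->vegR", "climR->florR",
                     "climR->SR"),
    m09_traits   = c("BG->climR", "climR->vegR", "climR->florR",
                     "vegR->SR", "florR->SR"),
    m10_combined = c("BG->climR", "climR->vegR", "climR->florR",
                     "climR->SR", "vegR->SR", "florR->SR"),
    m11_full     = c("BG->climR", "BG->SR", "climR->SR", "climR->vegR",
                     "climR->florR", "vegR->SR", "florR->SR"))
  out <- lapply(names(specs), function(nm) causal_model(nm, specs[[nm]]))
  stats::setNames(out, names(specs))
}
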