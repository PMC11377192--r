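test_that("causal models validate and order deterministically", {
  m <- causal_model("m", c("BG->climR", "climR->SR"))
  expect_setequal(m$vertices, c("BG", "climR", "vegR", "florR", "SR"))
  expect_error(causal_model("cyc", c("A->B", "B->A"), vertices = c("A", "B")),
               "cyclic")
  expect_identical(macroevopaths:::topo_order(m),
                   macroevopaths:::topo_order(m))
})

test_that("d-separation basis has one claim per non-adjacent pair", {
  one <- causal_model("one", "BG->SR")
  expect_length(dsep_basis(one), 9)
  # complete DAG on 5 vertices: no claims
  v <- c("a", "b", "c", "d", "e")
  full <- causal_model("full", apply(utils::combn(v, 2), 2, function(p)
    paste0(p[1], "->", p[2])), vertices = v)
  expect_length(dsep_basis(full), 0)
  chain <- causal_model("chain", c("BG->climR", "climR->SR"),
                        vertices = c("BG", "climR", "SR"))
  b <- dsep_basis(chain)
  expect_length(b, 1)
  expect_equal(b[[1]], list(x = "BG", y = "SR", given = "climR"))
})

test_that("every basis claim is a true d-separation (exhaustive small DAGs)", {
  # all DAGs on 4 (and a fixed-order exhaustive family on 5) vertices
  check_model <- function(v, pairs, mask) {
    edges <- pairs[mask, , drop = FALSE]
    m <- causal_model("x", if (nrow(edges))
      paste0(edges[, 1], "->", edges[, 2]) else character(0), vertices = v)
    claims <- dsep_basis(m)
    expect_length(claims, choose(length(v), 2) - nrow(edges))
    for (cl in claims)
      expect_true(bf_dsep(v, edges, cl$x, cl$y, cl$given))
  }
  v4 <- c("a", "b", "c", "d")
  p4 <- t(utils::combn(v4, 2))
  for (code in 0:(2^6 - 1))
    check_model(v4, p4, as.logical(intToBits(code)[1:6]))
  v5 <- c("a", "b", "c", "d", "e")
  p5 <- t(utils::combn(v5, 2))
  set.seed(1)
  for (code in sample(0:(2^10 - 1), 200))
    check_model(v5, p5, as.logical(intToBits(code)[1:10]))
})

test_that("removing an edge never shrinks the claim count", {
  m11 <- default_model_set()$m11_full
  k_full <- length(dsep_basis(m11))
  for (i in seq_len(nrow(m11$edges))) {
    sub <- causal_model("sub", apply(m11$edges[-i, , drop = FALSE], 1,
                                     paste, collapse = "->"))
    expect_gte(length(dsep_basis(sub)), k_full)
  }
})

test_that("PGLS with Pagel's lambda matches OLS on a star tree and a dense GLS oracle", {
  star <- ape::read.tree(text = paste0(
    "(", paste(paste0("s", 1:12, ":1"), collapse = ","), ");"))
  set.seed(4)
  y <- stats::setNames(rnorm(12), star$tip.label)
  X <- data.frame(x = rnorm(12), row.names = star$tip.label)
  f <- pgls_lambda(y, X, star, lambda = 0.5)  # any lambda: V* = I
  ols <- stats::lm(y ~ X$x)
  expect_equal(f$coefficients$estimate, unname(stats::coef(ols)),
               tolerance = 1e-8)
  # exact linear signal
  y2 <- stats::setNames(2 * X$x, star$tip.label)
  f2 <- pgls_lambda(y2, X, star, lambda = 0)
  expect_equal(f2$coefficients$estimate[2], 2, tolerance = 1e-8)
  # dense-GLS oracle at fixed lambda on a real tree; profile optimality
  tr <- fixture_tree(20, seed = 3)
  n <- ape::Ntip(tr)
  yy <- simulate_traits_bm(tr, 1, dims = 1, seed = 5)$traits[, 1]
  xx <- data.frame(x = rnorm(n), row.names = tr$tip.label)
  V <- ape::vcv(tr)[tr$tip.label, tr$tip.label]
  V <- V / mean(diag(V))
  for (lam in c(0, 0.5, 1)) {
    ours <- pgls_lambda(yy, xx, tr, lambda = lam)
    S <- lam * V + (1 - lam) * diag(n)
    Xm <- cbind(1, xx[tr$tip.label, ])
    b <- solve(t(Xm) %*% solve(S, Xm), t(Xm) %*% solve(S, yy))
    expect_equal(ours$coefficients$estimate, drop(b), tolerance = 1e-6)
    r <- yy - Xm %*% b
    s2 <- drop(t(r) %*% solve(S, r)) / n
    expect_equal(ours$logL, mvn_logdens(yy, drop(Xm %*% b), s2 * S),
                 tolerance = 1e-6)
  }
  fhat <- pgls_lambda(yy, xx, tr)
  for (lam in c(0, 0.5, 1))
    expect_gte(fhat$logL, pgls_lambda(yy, xx, tr, lambda = lam)$logL - 1e-8)
})

test_that("Firth logistic handles no-association and complete separation", {
  star <- ape::read.tree(text = paste0(
    "(", paste(paste0("s", 1:8, ":1"), collapse = ","), ");"))
  y <- stats::setNames(c(0, 1, 0, 1, 0, 1, 0, 1), star$tip.label)
  X <- data.frame(x = c(1, 1, -1, -1, 1, 1, -1, -1),
                  row.names = star$tip.label)
  f <- phylo_logistic(y, X, star)
  expect_lt(abs(f$coefficients$estimate[2]), 0.2)
  ys <- stats::setNames(c(0, 0, 0, 0, 1, 1, 1, 1), star$tip.label)
  Xs <- data.frame(x = c(-1, -1, -1, -1, 1, 1, 1, 1),
                   row.names = star$tip.label)
  fs <- phylo_logistic(ys, Xs, star)
  expect_true(is.finite(fs$coefficients$estimate[2]))
  expect_gt(fs$coefficients$estimate[2], 0)
  # permutation invariance
  perm <- sample(star$tip.label)
  fp <- phylo_logistic(ys[perm], Xs[perm, , drop = FALSE], star)
  expect_equal(fp$coefficients$estimate, fs$coefficients$estimate,
               tolerance = 1e-6)
  expect_error(phylo_logistic(stats::setNames(rep(1, 8), star$tip.label),
                              X, star), "single class")
})

test_that("Fisher's C, its p-value, and CICc follow the formulas", {
  C <- -2 * sum(log(c(0.5, 0.5)))
  expect_equal(C, 2.773, tolerance = 1e-3)
  expect_equal(stats::pchisq(C, 4, lower.tail = FALSE), 0.596,
               tolerance = 1e-3)
  expect_equal(0 + 2 * 5 * 100 / (100 - 1 - 5), 10.638, tolerance = 1e-3)
  # through the fitting interface: a saturated model has C = 0
  tr <- fixture_tree(30, seed = 12)
  pd <- make_ppa_dataset(tr, default_model_set()$m11_full,
                         coefs = stats::setNames(
                           rep(0.5, 7),
                           apply(default_model_set()$m11_full$edges, 1,
                                 paste, collapse = "->")),
                         seed = 3)$data
  v <- c("BG", "climR", "vegR", "florR", "SR")
  full <- causal_model("full", apply(utils::combn(v, 2), 2, function(p)
    paste0(p[1], "->", p[2])), vertices = v)
  ff <- fit_path_model(full, pd, tr)
  expect_equal(ff$stats$C, 0)
  expect_equal(ff$stats$p, 1)
  n <- ff$stats$n
  expect_equal(ff$stats$CICc, 2 * 10 * n / (n - 1 - 10), tolerance = 1e-10)
})

test_that("default model set: 11 acyclic models, single-effect claim counts", {
  ms <- default_model_set()
  expect_length(ms, 11)
  for (m in ms) expect_s3_class(m, "causal_model")
  for (i in 1:4) {
    expect_equal(nrow(ms[[i]]$edges), 1)
    expect_length(dsep_basis(ms[[i]]), 9)
  }
  expect_equal(nrow(ms$m11_full$edges), 7)
})

test_that("CICc ranking weights normalize and averaging degenerates correctly", {
  tr <- fixture_tree(40, seed = 2, crown = 15)
  chain <- default_model_set()$m05_chain
  pd <- make_ppa_dataset(tr, chain,
                         coefs = c("BG->climR" = 0.8, "climR->SR" = 0.8),
                         sigma = c(BG = 1, climR = 0.6, vegR = 1,
                                   florR = 1, SR = 0.6),
                         seed = 8)$data
  # two structurally identical models: equal weights, averaged = single fit
  rk <- rank_and_average(list(a = chain, b = chain), pd, tr)
  expect_equal(rk$ranking$weight, c(0.5, 0.5), tolerance = 1e-9)
  single <- fit_path_model(chain, pd, tr)$edge_coefficients
  merged <- merge(rk$averaged, single, by = c("from", "to"))
  expect_equal(merged$estimate.x, merged$estimate.y, tolerance = 1e-9)
  expect_equal(sum(rk$ranking$weight), 1, tolerance = 1e-9)
  expect_equal(rk$ranking$rel_lik[1], 1)
})

test_that("structure recovery: the generating chain wins the CICc ranking", {
  ms <- default_model_set()
  cand <- list(chain = ms$m05_chain, bg_only = ms$m01_BG,
               clim_only = ms$m02_climR)
  wins <- 0; reps <- 12
  for (i in seq_len(reps)) {
    tr <- fixture_tree(100, seed = 2300 + i, crown = 25)
    pd <- make_ppa_dataset(tr, ms$m05_chain,
                           coefs = c("BG->climR" = 0.8, "climR->SR" = 0.8),
                           sigma = c(BG = 1, climR = 0.6, vegR = 1,
                                     florR = 1, SR = 0.6),
                           seed = i)$data
    rk <- rank_and_average(cand, pd, tr)
    if (rk$ranking$model[1] == "m05_chain") wins <- wins + 1
  }
  expect_gte(wins / reps, 0.8)
})
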