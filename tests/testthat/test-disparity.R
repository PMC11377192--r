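test_that("Gower distance follows the typed per-trait rules", {
  df <- data.frame(leaf_area = c(10, 20), margin = c("entire", "toothed"),
                   row.names = c("sp1", "sp2"))
  D <- gower_distance(df, c("cont", "nom"))
  expect_equal(D["sp1", "sp2"], 1)  # (10/10 + 1)/2
  same <- gower_distance(df[c(1, 1), ], c("cont", "nom"))
  expect_equal(same[1, 2], 0)
  # single continuous trait: rank-identical to Euclidean
  x <- data.frame(v = c(0, 1, 4, 9), row.names = paste0("s", 1:4))
  D1 <- gower_distance(x, "cont")
  expect_equal(D1 * 9, abs(outer(x$v, x$v, "-")), ignore_attr = TRUE)
  # symmetry, zero diagonal, [0,1]
  set.seed(1)
  mix <- data.frame(a = rnorm(8), b = sample(letters[1:3], 8, TRUE),
                    c = rbinom(8, 1, 0.5), d = sample(1:4, 8, TRUE))
  Dm <- gower_distance(mix, c("cont", "nom", "bin", "ord"))
  expect_equal(Dm, t(Dm))
  expect_true(all(diag(Dm) == 0))
  expect_true(all(Dm >= 0 & Dm <= 1))
  # missing values excluded pairwise; all-missing pair errors
  mix2 <- mix; mix2$a[1] <- NA
  expect_silent(gower_distance(mix2, c("cont", "nom", "bin", "ord")))
  solo <- data.frame(a = c(1, NA), b = c(NA, 2))
  expect_error(gower_distance(solo, c("cont", "cont")), "comparable")
})

test_that("Gower agrees with an independent implementation", {
  skip_if_not_installed("cluster")
  set.seed(7)
  df <- data.frame(a = rnorm(12), b = runif(12),
                   c = factor(sample(c("x", "y", "z"), 12, TRUE)))
  D <- gower_distance(df, c("cont", "cont", "nom"))
  Do <- as.matrix(cluster::daisy(df, metric = "gower"))
  expect_equal(unname(D), unname(Do), tolerance = 1e-10)
})

test_that("ordination: PCA variance accounting and PCoA coordinate recovery", {
  # collinear points: one axis explains everything
  line <- cbind(x = 1:10, y = 2 * (1:10))
  rownames(line) <- paste0("s", 1:10)
  ms <- ordinate(line, "PCA")
  expect_equal(ms$var_explained[1], 1, tolerance = 1e-8)
  expect_equal(sum(ordinate(matrix(rnorm(40), 10, 4,
    dimnames = list(paste0("s", 1:10), NULL)), "PCA")$var_explained), 1,
    tolerance = 1e-9)
  # PCoA of Euclidean distances reproduces the configuration
  set.seed(2)
  pts <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("s", 1:12), NULL))
  rec <- ordinate(as.matrix(dist(pts)), "PCoA")
  expect_lt(max(abs(as.matrix(dist(rec$scores[, 1:2])) -
                      as.matrix(dist(pts)))), 1e-6)
  expect_true(all(diff(rec$var_explained) <= 1e-12))
  # axes orthogonal
  G <- crossprod(scale(rec$scores, scale = FALSE))
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("PCoA on Gower distances reproduces them after correction", {
  set.seed(3)
  df <- data.frame(a = rnorm(10), b = sample(c("u", "v"), 10, TRUE),
                   c = rbinom(10, 1, 0.4), row.names = paste0("s", 1:10))
  D <- gower_distance(df, c("cont", "nom", "bin"))
  ms <- ordinate(D, "PCoA", correction = "cailliez")
  Dr <- as.matrix(dist(ms$scores))
  # after the Cailliez constant, distances are inflated additively;
  # compare against the corrected target
  cstar <- if (ms$correction == "cailliez")
    mean((Dr - D)[upper.tri(D)]) else 0
  rel_err <- norm(Dr - (D + cstar * (1 - diag(nrow(D)))), "F") / norm(D, "F")
  expect_lt(rel_err, 1e-6)
})

test_that("clade disparity equals the pairwise definition and the variance identity", {
  expect_equal(clade_disparity(cbind(c(a = 0, b = 2))), 4)
  expect_equal(clade_disparity(cbind(c(a = 0, b = 1, c = 2))), 2)
  expect_equal(clade_disparity(cbind(c(a = 1, b = 1, c = 1))), 0)
  set.seed(4)
  sc <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("s", 1:10), NULL))
  pair_mean <- mean(as.matrix(dist(sc))[upper.tri(diag(10))]^2)
  expect_equal(clade_disparity(sc), pair_mean, tolerance = 1e-10)
  expect_equal(clade_disparity(sc), 2 * sum(apply(sc, 2, var)),
               tolerance = 1e-10)
  expect_error(clade_disparity(sc, c("s1", "nope")), "missing")
})

test_that("Bhattacharyya coefficient: identity, disjointness, hand case", {
  set.seed(5)
  x <- rnorm(200)
  expect_equal(bhattacharyya_coef(x, x), 1, tolerance = 1e-12)
  expect_equal(bhattacharyya_coef(rnorm(100), rnorm(100) + 100), 0)
  xa <- c(rep(0.5, 5), rep(1.5, 5))
  xb <- c(rep(0.5, 8), rep(1.5, 2))
  expect_equal(bhattacharyya_coef(xa, xb, breaks = c(0, 1, 2)),
               sqrt(0.4) + sqrt(0.1), tolerance = 1e-12)
  expect_equal(round(bhattacharyya_coef(xa, xb, breaks = c(0, 1, 2)), 3),
               0.949)
})

test_that("rarefied disparity separates distinct clades and not identical ones", {
  tr <- fixture_tree(40, seed = 5)
  clade <- fixture_clade(tr, 0.4)
  rest <- setdiff(tr$tip.label, clade)
  set.seed(6)
  sc <- cbind(rnorm(ape::Ntip(tr), 0, 0.1))
  rownames(sc) <- tr$tip.label
  sc[clade, 1] <- rnorm(length(clade), 0, 10)  # far larger disparity
  clades <- list(clade_def("fast", clade), clade_def("slow", rest))
  rd <- rarefied_disparity(sc, clades, n = 4, reps = 100, seed = 2)
  expect_equal(dim(rd$distributions), c(100, 2))
  # identical clades overlap fully; scale-separated clades overlap far less
  rd2 <- rarefied_disparity(sc, list(clade_def("a", clade),
                                     clade_def("b", clade)),
                            n = 4, reps = 100, seed = 3)
  expect_gt(rd2$pairwise$bc[1], 0.6)
  expect_lt(rd$pairwise$bc[1], rd2$pairwise$bc[1] - 0.2)
  expect_identical(rd$pairwise$distinct, rd$pairwise$bc < 0.05)
  expect_error(rarefied_disparity(sc, list(clade_def("tiny", clade[1:3])),
                                  n = 4, reps = 10, seed = 1), "smaller")
})

test_that("DTT normalizes at the root and is scale invariant", {
  tr <- fixture_tree(30, seed = 5)
  sc <- simulate_traits_bm(tr, 1, dims = 2, seed = 9)$traits
  d <- dtt(tr, sc, sims = 30, seed = 3)
  expect_equal(d$observed[1], 1)
  expect_true(all(d$observed >= 0))
  d10 <- dtt(tr, sc * 10, sims = 30, seed = 3)
  expect_equal(d$observed, d10$observed, tolerance = 1e-10)
  expect_equal(d$mdi, d10$mdi, tolerance = 1e-10)
})

test_that("a late-burst clade pushes DTT above the BM null (positive MDI)", {
  tr <- fixture_tree(35, seed = 7)
  clade <- fixture_young_clade(tr)
  hits <- 0; reps <- 15
  for (i in seq_len(reps)) {
    sc <- simulate_traits_bm(tr, 0.02, dims = 2,
                             clade_multipliers = list(
                               list(tips = clade, multiplier = 20)),
                             seed = 700 + i)$traits
    d <- dtt(tr, sc, sims = 40, seed = i)
    if (d$mdi > 0) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})
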