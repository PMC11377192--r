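test_that("birth-death simulator honours degenerate and deterministic cases", {
  s <- simulate_bd_tree(0, 0, crown_age_ma = 7, f = 1, seed = 1)
  expect_equal(ape::Ntip(s$tree), 2)
  expect_equal(unname(s$tree$edge.length), c(7, 7))
  a <- simulate_bd_tree(0.2, 0.05, crown_age_ma = 10, f = 0.8, seed = 42)
  b <- simulate_bd_tree(0.2, 0.05, crown_age_ma = 10, f = 0.8, seed = 42)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_true(macroevopaths:::is_time_ultrametric(a$tree))
  expect_equal(crown_age(a$tree), 10, tolerance = 1e-9)
})

test_that("pure-birth tip counts match the Yule expectation", {
  # E[N | 2 crown lineages, no extinction, no conditioning beyond survival]
  # = 2 exp(lambda T); with lambda T = 1.2 the survival conditioning is
  # negligible for mu = 0
  lam <- 0.2; T <- 6
  n <- vapply(1:300, function(i)
    ape::Ntip(simulate_bd_tree(lam, 0, T, f = 1, seed = 1000 + i)$tree),
    numeric(1))
  expected <- 2 * exp(lam * T)
  se <- stats::sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - expected), 4 * se + 0.05 * expected)
})

test_that("rate-shift simulator elevates diversification in the shifted clade", {
  hits <- 0; reps <- 40
  for (i in seq_len(reps)) {
    s <- simulate_rate_shift_tree(0.16, 0, 20, shift_age_ma = 10,
                                  multiplier = 3, f = 1, seed = 500 + i)
    dr <- dr_statistic(s$tree)
    inside <- names(dr) %in% s$truth$shift_tips
    if (sum(inside) >= 2 && sum(!inside) >= 2 &&
        stats::median(dr[inside]) > stats::median(dr[!inside]))
      hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("BM trait simulator matches closed-form variances", {
  tr <- read_time_tree(text = "(A:3,B:3);")
  d <- vapply(1:800, function(i) {
    x <- simulate_traits_bm(tr, sigma2 = 2, dims = 1, seed = i)$traits
    x["A", 1] - x["B", 1]
  }, numeric(1))
  # Var(x_A - x_B) = 2 sigma2 t = 12
  expect_lt(abs(stats::var(d) - 12) / 12, 0.2)
  z <- simulate_traits_bm(tr, sigma2 = 0, dims = 2, seed = 1)$traits
  expect_true(all(z == 0))
})

test_that("clade rate multipliers inflate within-clade variance", {
  tr <- fixture_tree(30, seed = 5)
  clade <- fixture_clade(tr, 0.4)
  hits <- 0; reps <- 30
  for (i in seq_len(reps)) {
    x <- simulate_traits_bm(tr, 0.1, dims = 1,
                            clade_multipliers = list(
                              list(tips = clade, multiplier = 10)),
                            seed = 900 + i)$traits
    inside <- rownames(x) %in% clade
    if (stats::var(x[inside, 1]) > stats::var(x[!inside, 1]))
      hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("OU simulator reaches stationary moments and the BM limit", {
  tr <- fixture_tree(40, seed = 8)
  reg <- rep("r", nrow(tr$edge))
  # strong selection: stationary mean theta, variance sigma2 / (2 alpha)
  alpha <- 5; sigma2 <- 2
  x <- unlist(lapply(1:40, function(i)
    simulate_traits_ou(tr, reg, "r", alpha, sigma2, c(r = 5),
                       seed = 200 + i)$traits))
  expect_lt(abs(mean(x) - 5), 0.1)
  expect_lt(abs(stats::var(x) - sigma2 / (2 * alpha)) / (sigma2 / (2 * alpha)),
            0.3)
  # alpha = 0 equals the BM distribution (same seed, same draws)
  ou0 <- simulate_traits_ou(tr, reg, "r", 0, 1.5, c(r = 0), seed = 77)$traits
  bm <- simulate_traits_bm(tr, 1.5, dims = 1, seed = 77)$traits[, 1]
  expect_equal(unname(ou0), unname(bm), tolerance = 1e-12)
  # sigma2 -> 0 converges deterministically to theta
  tiny <- simulate_traits_ou(tr, reg, "r", 5, 1e-12, c(r = 3), seed = 1)$traits
  expect_lt(max(abs(tiny - 3)), 1e-3)
  expect_error(simulate_traits_ou(tr, rep(NA, nrow(tr$edge)), "r", 1, 1,
                                  c(r = 0), seed = 1), "unpainted")
})

test_that("binary character simulation respects rates and stationarity", {
  tr <- fixture_tree(30, seed = 4)
  all0 <- simulate_binary_character(tr, 0, 0, root_state = 0, seed = 1)
  expect_true(all(all0$states == 0))
  freq <- mean(unlist(lapply(1:40, function(i)
    simulate_binary_character(tr, 0.5, 0.5, seed = 300 + i)$states)))
  expect_lt(abs(freq - 0.5), 0.1)
  a <- simulate_binary_character(tr, 0.2, 0.1, seed = 9)
  b <- simulate_binary_character(tr, 0.2, 0.1, seed = 9)
  expect_identical(a$states, b$states)
})

test_that("DEC forward simulation responds to dispersal rate", {
  tr <- fixture_tree(25, seed = 6)
  space <- range_state_space(c("A", "B", "C"), max_size = 3)
  fixed <- simulate_ranges_dec(tr, space, dec_params(0, 0),
                               root_range = "A", seed = 1)
  expect_true(all(vapply(fixed$tip_ranges, identical, logical(1), y = "A")))
  mean_size <- vapply(c(0.01, 0.05, 0.2), function(d) {
    mean(unlist(lapply(1:8, function(i)
      lengths(simulate_ranges_dec(tr, space, dec_params(d, 0),
                                  root_range = "A",
                                  seed = 40 + i)$tip_ranges))))
  }, numeric(1))
  expect_true(all(diff(mean_size) > 0))
  a <- simulate_ranges_dec(tr, space, dec_params(0.05, 0.02),
                           root_range = "A", seed = 3)
  b <- simulate_ranges_dec(tr, space, dec_params(0.05, 0.02),
                           root_range = "A", seed = 3)
  expect_identical(a$tip_ranges, b$tip_ranges)
})

test_that("paleo curve generator produces the advertised shapes", {
  flat <- make_paleo_curve("linear", list(intercept = 3, slope = 0), 20)
  expect_true(all(flat$value == 3))
  sine <- make_paleo_curve("sinusoid",
                           list(mean = 0, amplitude = 1, period = 5),
                           span_ma = 20, step_ma = 0.5)
  v1 <- sine$value[sine$age_ma == 17]
  v2 <- sine$value[sine$age_ma == 12]
  expect_lt(abs(v1 - v2), 1e-9)
  up <- make_paleo_curve("logistic_uplift",
                         list(height = 4, midpoint_ma = 10, scale_ma = 2),
                         span_ma = 30, step_ma = 0.1)
  # ordered oldest -> youngest, so values must be nondecreasing along rows
  expect_true(all(diff(up$value) >= -1e-12))
  # matches the closed-form logistic
  expect_equal(up$value, 4 / (1 + exp((up$age_ma - 10) / 2)),
               tolerance = 1e-12)
})

test_that("PPA generator recovers independence and chain coefficients", {
  tr <- fixture_tree(80, seed = 12, crown = 20)
  null_model <- causal_model("null", character(0))
  nd <- make_ppa_dataset(tr, null_model, coefs = numeric(0), lambda = 0,
                         seed = 2)$data
  ols <- summary(stats::lm(SR ~ climR + vegR + florR + BG, data = nd))
  expect_true(all(abs(ols$coefficients[-1, "Estimate"]) < 0.4))
  # chain with residual sd 0.6 so each child has ~unit variance and the
  # standardized fitted coefficient is comparable to the generating one
  chain <- causal_model("chain", c("BG->climR", "climR->SR"))
  slopes <- vapply(1:25, function(i) {
    d <- make_ppa_dataset(tr, chain,
                          coefs = c("BG->climR" = 0.8, "climR->SR" = 0.8),
                          lambda = 0.5,
                          sigma = c(BG = 1, climR = 0.6, vegR = 1,
                                    florR = 1, SR = 0.6),
                          seed = 600 + i)$data
    ec <- fit_path_model(chain, d, tr)$edge_coefficients
    ec$estimate[ec$from == "climR" & ec$to == "SR"]
  }, numeric(1))
  expect_lt(abs(stats::median(slopes) - 0.8), 0.15)
})
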