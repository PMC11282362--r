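# GLS/PGLS, naive OLS, Poisson GEE and Pagel's lambda estimation.

test_that("identity-covariance GLS reproduces ordinary least squares", {
  f <- fit_gls(c(0, 0, 1, 1), c(1, 2, 3, 5), diag(4))
  expect_equal(f$slope, 2.5)
  expect_equal(f$intercept, 1.5)

  n <- fit_naive_ols(c(0, 0, 1, 1), c(1, 2, 3, 5))
  expect_equal(n$slope, 2.5)

  set.seed(8)
  x <- rbinom(20, 1, 0.5)
  y <- rnorm(20)
  expect_equal(fit_gls(x, y, diag(20))$slope, fit_naive_ols(x, y)$slope,
               tolerance = 1e-10)
})

test_that("a perfect linear relationship gives the exact slope and p near zero", {
  tr <- random_tree(12, 1)
  V <- covariance_matrix(tr, covariance_spec("brownian"))
  x <- rep(c(0, 1), 6)
  y <- 3 + 2 * x
  f <- fit_gls(x, y, V)
  expect_equal(f$slope, 2, tolerance = 1e-8)
  expect_lt(f$p_value, 1e-10)
})

test_that("fit_gls matches the closed-form matrix oracle on random instances", {
  for (seed in 1:20) {
    tr <- random_tree(8, seed)
    V <- covariance_matrix(tr, covariance_spec("brownian"))
    set.seed(seed + 100)
    x <- rbinom(8, 1, 0.5)
    if (length(unique(x)) < 2) x[1:2] <- c(0, 1)
    y <- rnorm(8)
    f <- fit_gls(x, y, V)
    o <- gls_oracle(x, y, V)
    expect_equal(c(f$intercept, f$slope), unname(o), tolerance = 1e-8)
  }
})

test_that("fit_gls agrees with an independent GLS implementation", {
  skip_if_not_installed("nlme")
  # ultrametric tree: nlme correlation structures assume equal variances,
  # which holds for Brownian covariance only when tip depths are equal
  set.seed(42)
  tr <- ape::rcoal(25)
  V <- covariance_matrix(tr, covariance_spec("brownian"))
  set.seed(43)
  x <- rbinom(25, 1, 0.5)
  y <- drop(t(chol(V)) %*% rnorm(25)) + 0.5 * x
  d <- data.frame(x = x, y = y, sp = tr$tip.label)
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corBrownian(1, tr, form = ~sp),
                 method = "ML")
  f <- fit_gls(setNames(x, tr$tip.label), setNames(y, tr$tip.label), V)
  expect_equal(f$slope, unname(coef(g)[2]), tolerance = 1e-6)
  expect_equal(f$intercept, unname(coef(g)[1]), tolerance = 1e-6)
})

test_that("degenerate designs are rejected and shifts only move the intercept", {
  tr <- random_tree(10, 5)
  V <- covariance_matrix(tr, covariance_spec("brownian"))
  expect_error(fit_gls(rep(1, 10), rnorm(10), V), "constant")
  expect_error(fit_gls(rbinom(10, 1, 0.5), rep(2, 10), V), "constant")

  set.seed(6)
  x <- c(rep(0, 5), rep(1, 5))
  y <- rnorm(10)
  f1 <- fit_gls(x, y, V)
  f2 <- fit_gls(x, y + 7, V)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-10)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-10)
  expect_equal(f2$intercept - f1$intercept, 7, tolerance = 1e-8)
})

test_that("fit_pgls delegates correctly across covariance specifications", {
  tr <- make_balanced_tree(5)
  set.seed(9)
  x <- setNames(rbinom(32, 1, 0.5), tr$tip.label)
  y <- setNames(rnorm(32, 10), tr$tip.label)

  ident <- fit_pgls(x, y, tr, covariance_spec("identity"))
  naive <- fit_naive_ols(x, y)
  expect_equal(ident$slope, naive$slope, tolerance = 1e-8)

  lam1 <- fit_pgls(x, y, tr, covariance_spec("pagel_lambda", 1))
  bm <- fit_pgls(x, y, tr, covariance_spec("brownian"))
  expect_equal(lam1$slope, bm$slope, tolerance = 1e-12)
  expect_equal(lam1$p_value, bm$p_value, tolerance = 1e-12)
})

test_that("profiled and fixed-parameter code paths agree on identical covariance", {
  tr <- make_balanced_tree(6)
  set.seed(12)
  V <- covariance_matrix(tr, covariance_spec("brownian"))
  y <- setNames(drop(t(chol(V)) %*% rnorm(64)), tr$tip.label)
  x <- setNames(rbinom(64, 1, 0.5), tr$tip.label)
  prof <- fit_pgls(x, y, tr, covariance_spec("pagel_lambda", "estimate"))
  fixed <- fit_pgls(x, y, tr, covariance_spec("pagel_lambda",
                                              prof$cov_param))
  expect_equal(prof$slope, fixed$slope, tolerance = 1e-6)
})

test_that("pgls detects the simulated negative effect of the predictor", {
  tr <- make_balanced_tree(6)
  neg <- 0
  for (i in seq_len(50)) {
    st <- simulate_traits(tr, sim_params(r = 0.05, m = 1, c = 1, p = 0,
                                         seed = 900 + i))
    x <- st$x_obs
    if (length(unique(x)) < 2) next
    f <- fit_pgls(x, st$y_true[tr$tip.label], tr,
                  covariance_spec("brownian"))
    neg <- neg + (f$slope < 0)
  }
  expect_gte(neg / 50, 0.9)
})

test_that("poisson GEE with identity correlation equals classic Poisson IRLS", {
  star <- ape::stree(40, "star")
  star$edge.length <- rep(1, 40)
  star$tip.label <- paste0("t", 1:40)
  set.seed(14)
  x <- rbinom(40, 1, 0.5)
  y <- rpois(40, exp(1 + 0.4 * x))
  f <- fit_poisson_gee(setNames(x, star$tip.label),
                       setNames(y, star$tip.label), star)
  g <- stats::glm(y ~ x, family = stats::poisson)
  expect_equal(f$slope, unname(coef(g)[2]), tolerance = 1e-6)
  expect_equal(f$intercept, unname(coef(g)[1]), tolerance = 1e-6)
  expect_true(f$converged)
})

test_that("constant counts give slope zero and intercept log k", {
  tr <- make_balanced_tree(4)
  x <- setNames(rep(c(0, 1), 8), tr$tip.label)
  y <- setNames(rep(7, 16), tr$tip.label)
  f <- fit_poisson_gee(x, y, tr)
  expect_equal(f$slope, 0, tolerance = 1e-8)
  expect_equal(f$intercept, log(7), tolerance = 1e-8)

  expect_error(fit_poisson_gee(x, y + 0.5, tr), "integer")
})

test_that("power is monotone in the effect size for brownian PGLS", {
  tr <- make_balanced_tree(6)
  r <- 0.05
  rate <- function(cc) {
    hits <- 0
    n <- 0
    for (i in seq_len(200)) {
      st <- simulate_traits(tr, sim_params(r = r, m = 1, c = cc, p = 0,
                                           seed = 3000 + i))
      p <- tryCatch(fit_pgls(st$x_obs, st$y_true[tr$tip.label], tr,
                             covariance_spec("brownian"))$p_value,
                    error = function(e) NA_real_)
      if (!is.na(p)) {
        n <- n + 1
        hits <- hits + (p < 0.05)
      }
    }
    hits / n
  }
  r0 <- rate(0)
  r1 <- rate(0.5)
  r2 <- rate(1)
  expect_lte(r0, r1 + 0.02)
  expect_lte(r1, r2 + 0.02)
  expect_gt(r2, r0)
})

test_that("pagel's lambda is recovered for Brownian traits and destroyed by shuffling", {
  tr <- make_balanced_tree(7)
  V <- covariance_matrix(tr, covariance_spec("brownian"))
  ch <- t(chol(V))
  lams <- lams_shuf <- numeric(5)
  for (i in 1:5) {
    set.seed(20 + i)
    y <- setNames(drop(ch %*% rnorm(128)), tr$tip.label)
    est <- estimate_pagel_lambda(y, tr)
    lams[i] <- est$lambda
    expect_gte(est$loglik, est$loglik_0 - 1e-6)
    expect_gte(est$loglik, est$loglik_1 - 1e-6)
    y_shuf <- setNames(sample(y), tr$tip.label)
    lams_shuf[i] <- estimate_pagel_lambda(y_shuf, tr)$lambda
  }
  expect_gte(median(lams), 0.9)
  expect_lte(median(lams_shuf), 0.1)
  expect_error(estimate_pagel_lambda(rep(1, 128), tr), "constant")
})

test_that("lambda estimate agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- make_balanced_tree(6)
  V <- covariance_matrix(tr, covariance_spec("brownian"))
  set.seed(31)
  y <- setNames(drop(t(chol(0.6 * V + 0.4 * diag(diag(V)))) %*% rnorm(64)),
                tr$tip.label)
  mine <- estimate_pagel_lambda(y, tr)$lambda
  ref <- phytools::phylosig(tr, y, method = "lambda")$lambda
  expect_equal(mine, ref, tolerance = 0.05)
})
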