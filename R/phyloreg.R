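# Parametric comparative regression: GLS/PGLS under phylogenetic covariance
# structures, naive OLS, Poisson regression with a phylogenetic working
# correlation fitted by generalized estimating equations, and Pagel's lambda
# signal estimation.

fit_result <- function(method, slope, intercept, p_value, cov_param = NA_real_,
                       dispersion = NA_real_, n, converged = TRUE) {
  structure(list(method = method, slope = unname(slope),
                 intercept = unname(intercept), p_value = unname(p_value),
                 cov_param = cov_param, dispersion = dispersion,
                 n = n, converged = converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<%s>  slope = %.6g  p = %.4g  n = %d%s\n", x$method, x$slope,
              x$p_value, x$n, if (x$converged) "" else "  [not converged]"))
  if (!is.na(x$cov_param))
    cat(sprintf("  covariance parameter = %.4g\n", x$cov_param))
  invisible(x)
}

# Core GLS machinery. V is factorized once per call via a Cholesky
# decomposition of the jittered matrix (never explicitly inverted).
gls_core <- function(X, y, V) {
  n <- length(y)
  Vj <- V + diag(1e-10 * sum(diag(V)) / n, n)
  ch <- tryCatch(chol(Vj), error = function(e)
    stop("covariance matrix is numerically singular", call. = FALSE))
  # whiten: solve t(ch) %*% z = . ; then OLS on whitened data
  wy <- backsolve(ch, y, transpose = TRUE)
  wX <- backsolve(ch, X, transpose = TRUE)
  XtX <- crossprod(wX)
  beta <- tryCatch(solve(XtX, crossprod(wX, wy)), error = function(e)
    stop("degenerate design: predictor columns are collinear", call. = FALSE))
  r <- wy - wX %*% beta
  rss <- sum(r^2)
  sigma2 <- rss / n # ML estimate
  logdet <- 2 * sum(log(diag(ch)))
  loglik <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(beta = drop(beta), sigma2 = sigma2, loglik = loglik)
}

#' Generalized least squares with an explicit covariance matrix
#'
#' Fits `y = b0 + b1 x + e`, `e ~ N(0, sigma2 V)`, by maximum likelihood.
#' The slope p-value comes from a likelihood-ratio test against the
#' intercept-only model with the same `V`, referred to a chi-squared
#' distribution with one degree of freedom.
#'
#' @param x Binary (0/1) or numeric predictor over tips; must not be constant.
#' @param y Numeric response over tips.
#' @param V Symmetric positive definite covariance matrix conformable with
#'   `x` and `y`. A tiny diagonal jitter (`1e-10 * mean(diag(V))`) is added
#'   before factorization.
#' @return A `fit_result` with slope, intercept and LRT p-value.
#' @export
fit_gls <- function(x, y, V) {
  if (!is.matrix(V) || nrow(V) != ncol(V)) stop_arg("`V` must be square")
  if (length(x) != length(y) || length(y) != nrow(V))
    stop_arg("x, y and V must be conformable")
  if (length(y) < 3) stop_arg("need at least 3 observations")
  if (!is.null(names(x)) && !is.null(rownames(V))) {
    x <- align_to_tips(x, rownames(V), "x")
    y <- align_to_tips(y, rownames(V), "y")
  }
  if (length(unique(x)) < 2)
    stop_arg("degenerate design: predictor is constant")
  if (length(unique(as.numeric(y))) < 2)
    stop_arg("response is constant across tips")
  X1 <- cbind(1, as.numeric(x))
  X0 <- matrix(1, length(y), 1)
  alt <- gls_core(X1, as.numeric(y), V)
  null <- gls_core(X0, as.numeric(y), V)
  lrt <- max(0, 2 * (alt$loglik - null$loglik))
  fit_result("gls", slope = alt$beta[2], intercept = alt$beta[1],
             p_value = pchisq(lrt, df = 1, lower.tail = FALSE),
             n = length(y))
}

#' Ordinary least squares ignoring phylogeny
#'
#' The naive baseline: every species treated as an independent sample. Slope
#' p-value is the usual two-sided t-test.
#'
#' @inheritParams fit_gls
#' @return A `fit_result`.
#' @export
fit_naive_ols <- function(x, y) {
  if (length(unique(x)) < 2)
    stop_arg("degenerate design: predictor is constant")
  x <- as.numeric(x)
  y <- as.numeric(y)
  fit <- lm(y ~ x)
  co <- summary(fit)$coefficients
  fit_result("naive_ols", slope = co[2, 1], intercept = co[1, 1],
             p_value = co[2, 4], n = length(y))
}

# Profile the free covariance parameter of a spec over its legal range,
# maximizing the GLS log-likelihood for a given design matrix. Returns the
# best (parameter, loglik).
profile_cov_param <- function(X, y, tree, model) {
  if (model == "pagel_lambda") {
    Vb <- covariance_matrix(tree, covariance_spec("brownian"))
    d <- diag(Vb)
    make_V <- function(lam) {
      V <- Vb * lam
      diag(V) <- d
      V
    }
    lower <- 0
    upper <- 1
  } else { # martins_hansen
    D <- patristic_distances(tree)
    Tmax <- max(D)
    make_V <- function(alpha) exp(-alpha * D)
    lower <- 1e-4 / Tmax
    upper <- 50 / Tmax
  }
  obj <- function(par) gls_core(X, y, make_V(par))$loglik
  opt <- optimize(obj, c(lower, upper), maximum = TRUE, tol = 1e-6)
  cand <- c(opt$maximum, lower, upper)
  ll <- c(opt$objective, obj(lower), obj(upper))
  best <- which.max(ll)
  list(parameter = cand[best], loglik = ll[best], make_V = make_V)
}

#' Phylogenetic generalized least squares
#'
#' GLS regression of tip response on tip predictor with residual covariance
#' built from the tree under a chosen evolutionary model. When the
#' specification's parameter is `"estimate"`, Pagel's `lambda` (on `[0, 1]`)
#' or the Martins-Hansen `alpha` (on `[1e-4/T, 50/T]`, `T` the tree depth in
#' patristic distance) is profiled by bounded likelihood maximization. The
#' likelihood-ratio p-value re-profiles the parameter under both the null
#' (intercept-only) and alternative models, so the test does not inherit the
#' alternative's estimate.
#'
#' @param x,y Tip predictor and response, named by tip label or in tip order.
#' @param tree A `phylo` whose tips match `x`/`y`.
#' @param spec A [covariance_spec()].
#' @return A `fit_result`; `cov_param` records the fitted/fixed parameter.
#' @export
fit_pgls <- function(x, y, tree, spec = covariance_spec("brownian")) {
  stopifnot(inherits(tree, "phylo"), inherits(spec, "covariance_spec"))
  x <- align_to_tips(x, tree$tip.label, "x")
  y <- align_to_tips(y, tree$tip.label, "y")
  if (length(unique(x)) < 2)
    stop_arg("degenerate design: predictor is constant")
  if (length(unique(as.numeric(y))) < 2)
    stop_arg("response is constant across tips")
  n <- length(y)
  X1 <- cbind(1, as.numeric(x))
  X0 <- matrix(1, n, 1)
  yv <- as.numeric(y)
  if (identical(spec$parameter, "estimate")) {
    alt <- profile_cov_param(X1, yv, tree, spec$model)
    null <- profile_cov_param(X0, yv, tree, spec$model)
    beta <- gls_core(X1, yv, alt$make_V(alt$parameter))$beta
    lrt <- max(0, 2 * (alt$loglik - null$loglik))
    fit_result(paste0("pgls_", spec$model),
               slope = beta[2], intercept = beta[1],
               p_value = pchisq(lrt, df = 1, lower.tail = FALSE),
               cov_param = alt$parameter, n = n)
  } else {
    V <- covariance_matrix(tree, spec)
    res <- fit_gls(as.numeric(x), yv, V)
    res$method <- paste0("pgls_", spec$model)
    res$cov_param <- if (is.null(spec$parameter)) NA_real_ else spec$parameter
    res
  }
}

#' Poisson regression with phylogenetic working correlation (GEE)
#'
#' Log-link Poisson regression of a count response on a binary predictor,
#' fitted by generalized estimating equations with working correlation
#' `R = D^{-1/2} V D^{-1/2}` derived from the Brownian covariance `V`
#' (`D = diag(V)`). The update iterates
#' `beta <- beta + (t(Delta) W^-1 Delta)^-1 t(Delta) W^-1 (y - mu)` with
#' `mu = exp(X beta)`, `Delta = A X`, `W = A^{1/2} R A^{1/2}`, `A = diag(mu)`,
#' to relative tolerance 1e-8 (at most 100 iterations). The dispersion
#' `phi` is estimated from the generalized Pearson statistic (residuals
#' whitened by the working covariance, reducing to the usual Pearson sum when
#' `R` is the identity) and scales the model-based variance of the Wald z
#' statistic for the slope.
#'
#' @param x Binary tip predictor (not constant).
#' @param y_counts Non-negative integer response over tips.
#' @param tree A `phylo`.
#' @return A `fit_result`; `dispersion` carries `phi`, `converged` is `FALSE`
#'   on divergence (never an error).
#' @export
fit_poisson_gee <- function(x, y_counts, tree) {
  stopifnot(inherits(tree, "phylo"))
  x <- align_to_tips(x, tree$tip.label, "x")
  y <- align_to_tips(y_counts, tree$tip.label, "y_counts")
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop_arg("`y_counts` must be non-negative integers")
  if (length(unique(x)) < 2)
    stop_arg("degenerate design: predictor is constant")
  n <- length(y)
  V <- covariance_matrix(tree, covariance_spec("brownian"))
  R <- cov2cor(V)
  X <- cbind(1, as.numeric(x))
  y <- as.numeric(y)
  beta <- c(log(max(mean(y), 1e-8)), 0)
  converged <- FALSE
  U <- NULL
  mu <- NULL
  for (iter in seq_len(100)) {
    eta <- pmin(drop(X %*% beta), 30)
    mu <- exp(eta)
    A <- pmax(mu, 1e-10)
    sa <- sqrt(A)
    W <- R * tcrossprod(sa) # A^{1/2} R A^{1/2}
    W <- W + diag(1e-10 * mean(diag(W)), n)
    ch <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(ch)) break
    Delta <- X * A # diag(A) %*% X
    wD <- backsolve(ch, Delta, transpose = TRUE)
    wr <- backsolve(ch, y - mu, transpose = TRUE)
    U <- crossprod(wD)
    step <- tryCatch(solve(U, crossprod(wD, wr)), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    beta <- beta + drop(step)
    if (max(abs(step)) <= 1e-8 * max(1, max(abs(beta)))) {
      converged <- TRUE
      break
    }
  }
  if (is.null(U) || is.null(mu)) {
    return(fit_result("pglm_poisson", NA_real_, NA_real_, NA_real_,
                      n = n, converged = FALSE))
  }
  # dispersion from the generalized Pearson statistic: residuals whitened by
  # the working covariance W, so phi is consistent under correlated residuals
  # (with R = identity this is the usual Pearson sum over mu)
  eta <- pmin(drop(X %*% beta), 30)
  mu <- exp(eta)
  sa <- sqrt(pmax(mu, 1e-10))
  W <- R * tcrossprod(sa)
  W <- W + diag(1e-10 * mean(diag(W)), n)
  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(ch)) {
    return(fit_result("pglm_poisson", beta[2], beta[1], NA_real_,
                      n = n, converged = FALSE))
  }
  wD <- backsolve(ch, X * pmax(mu, 1e-10), transpose = TRUE)
  U <- crossprod(wD)
  wr <- backsolve(ch, y - mu, transpose = TRUE)
  phi <- sum(wr^2) / max(n - 2, 1)
  vb <- tryCatch(phi * solve(U), error = function(e) NULL)
  if (is.null(vb) || vb[2, 2] <= 0) {
    return(fit_result("pglm_poisson", beta[2], beta[1], NA_real_,
                      dispersion = phi, n = n, converged = FALSE))
  }
  z <- beta[2] / sqrt(vb[2, 2])
  fit_result("pglm_poisson", slope = beta[2], intercept = beta[1],
             p_value = 2 * pnorm(-abs(z)), dispersion = phi, n = n,
             converged = converged)
}

#' Estimate Pagel's lambda for a tip trait
#'
#' Maximum-likelihood `lambda` under an intercept-only Brownian model whose
#' off-diagonal covariances are scaled by `lambda`; bounded optimization on
#' `[0, 1]` including both endpoints. `lambda` near 1 indicates trait
#' covariance tracking shared ancestry (strong phylogenetic signal); near 0, a
#' star-like absence of signal.
#'
#' @param y Tip trait values (must vary), named by tip label or in tip order.
#' @param tree A `phylo`.
#' @return A list with `lambda`, its `loglik`, and `loglik_0`/`loglik_1` at
#'   the boundaries.
#' @export
estimate_pagel_lambda <- function(y, tree) {
  stopifnot(inherits(tree, "phylo"))
  y <- as.numeric(align_to_tips(y, tree$tip.label, "y"))
  if (length(unique(y)) < 2) stop_arg("`y` is constant across tips")
  n <- length(y)
  X0 <- matrix(1, n, 1)
  prof <- profile_cov_param(X0, y, tree, "pagel_lambda")
  list(lambda = prof$parameter, loglik = prof$loglik,
       loglik_0 = gls_core(X0, y, prof$make_V(0))$loglik,
       loglik_1 = gls_core(X0, y, prof$make_V(1))$loglik)
}
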