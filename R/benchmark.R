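# Sensitivity/specificity benchmarking: sweep simulator parameters, run every
# method on each simulated dataset, and summarize false/true positive rates.

bench_methods <- c("naive", "pgls_bm", "pgls_lambda", "pgls_mh",
                   "pgls_grafen", "pglm_poisson", "wilcoxon", "bootstrap")

#' Define a benchmark grid
#'
#' The default grid mirrors the headline synthetic control: a depth-8 balanced
#' tree (256 tips), flip probability calibrated so that on average 8
#' evolutionary events innovate a positive predictor, effect sizes
#' `c in {0, m/2, m}` (the null `c = 0` is always included), occlusion
#' probabilities `p in {0, 0.2, 0.4, 0.6, 0.8}`, reversible predictor
#' dynamics, and 100 replicates per cell.
#'
#' @param tree A fixed `phylo` reused across replicates, or a function
#'   `function(seed)` returning a fresh tree per replicate (the convention for
#'   birth-death topologies).
#' @param c_values Effect sizes; must contain 0.
#' @param p_values Occlusion probabilities.
#' @param m Characteristic loss magnitude.
#' @param target_innovations Mean innovation count to which `r` is calibrated
#'   (ignored when `r` is given).
#' @param r Optional fixed flip probability.
#' @param reversible Logical flag(s) for predictor dynamics.
#' @param replicates Replicates per grid cell (>= 1).
#' @param alpha Nominal test level in (0, 1).
#' @param base_seed Integer; per-cell seeds are derived from it by hashing the
#'   grid coordinates, so any cell is reproducible in isolation.
#' @param y0 Root response value.
#' @return A `benchmark_grid` list.
#' @export
benchmark_grid <- function(tree = make_balanced_tree(8),
                           c_values = c(0, 0.5, 1),
                           p_values = c(0, 0.2, 0.4, 0.6, 0.8),
                           m = 1, target_innovations = 8, r = NULL,
                           reversible = TRUE, replicates = 100,
                           alpha = 0.05, base_seed = 1, y0 = 100) {
  if (!0 %in% c_values)
    stop_arg("`c_values` must contain 0: the null is always benchmarked")
  if (!is_count(replicates) || replicates < 1)
    stop_arg("`replicates` must be a positive integer")
  if (alpha <= 0 || alpha >= 1) stop_arg("`alpha` must lie in (0, 1)")
  structure(list(tree = tree, c_values = c_values, p_values = p_values,
                 m = m, target_innovations = target_innovations, r = r,
                 reversible = reversible, replicates = replicates,
                 alpha = alpha, base_seed = as.integer(base_seed), y0 = y0),
            class = "benchmark_grid")
}

# Fit one method to one simulated dataset; never throws.
run_one_method <- function(method, tree, x, y, seed) {
  res <- tryCatch(switch(method,
    naive = fit_naive_ols(x, y),
    pgls_bm = fit_pgls(x, y, tree, covariance_spec("brownian")),
    pgls_lambda = fit_pgls(x, y, tree, covariance_spec("pagel_lambda",
                                                       "estimate")),
    pgls_mh = fit_pgls(x, y, tree, covariance_spec("martins_hansen",
                                                   "estimate")),
    pgls_grafen = fit_pgls(x, y, tree, covariance_spec("grafen", 1)),
    pglm_poisson = fit_poisson_gee(x, round(y), tree),
    wilcoxon = {
      ct <- extract_contrasts(tree, propagate_states(tree, x, y))
      wt <- wilcoxon_signed_rank(ct$diff)
      fit_result("wilcoxon", slope = mean(ct$diff), intercept = NA_real_,
                 p_value = wt$p_value, n = nrow(ct))
    },
    bootstrap = {
      ct <- extract_contrasts(tree, propagate_states(tree, x, y))
      bt <- bootstrap_mean_test(ct$diff, B = 2000, seed = seed)
      fit_result("bootstrap", slope = mean(ct$diff), intercept = NA_real_,
                 p_value = bt$p_value, n = nrow(ct))
    }
  ), error = function(e) NULL)
  if (is.null(res)) {
    res <- fit_result(method, NA_real_, NA_real_, NA_real_, n = NA_integer_,
                      converged = FALSE)
  }
  res
}

#' Run every method over a benchmark grid
#'
#' For each grid cell and replicate: obtain the tree (fixed, or freshly
#' simulated for function-valued tree specs), evolve the traits, occlude the
#' predictor, and fit every requested method on the observed tips. Failures
#' (e.g. an all-negative observed predictor after heavy occlusion) are
#' recorded with `converged = FALSE`, never dropped.
#'
#' @param grid A [benchmark_grid()].
#' @param methods Character vector drawn from `naive`, `pgls_bm`,
#'   `pgls_lambda`, `pgls_mh`, `pgls_grafen`, `pglm_poisson`, `wilcoxon`,
#'   `bootstrap`.
#' @return A data frame with one record per (cell, replicate, method).
#' @export
run_benchmark_grid <- function(grid, methods = c("naive", "pgls_bm",
                                                 "pglm_poisson")) {
  stopifnot(inherits(grid, "benchmark_grid"))
  bad <- setdiff(methods, bench_methods)
  if (length(bad))
    stop_arg("unknown method id(s): ", paste(bad, collapse = ", "),
             " (available: ", paste(bench_methods, collapse = ", "), ")")
  fixed_tree <- !is.function(grid$tree)
  cal_tree <- if (fixed_tree) grid$tree else grid$tree(grid$base_seed)
  records <- list()
  for (rev in unique(grid$reversible)) {
    r_use <- if (!is.null(grid$r)) grid$r else
      calibrate_r(cal_tree, grid$target_innovations, reversible = rev,
                  seed = mix_seed(grid$base_seed, "calibrate", rev))
    for (cc in grid$c_values) for (pp in grid$p_values) {
      for (rep_i in seq_len(grid$replicates)) {
        cell_seed <- mix_seed(grid$base_seed, cc, pp, rev, rep_i)
        tree <- if (fixed_tree) grid$tree else grid$tree(cell_seed)
        params <- sim_params(r = r_use, m = grid$m, c = cc, p = pp,
                             reversible = rev, y0 = grid$y0,
                             seed = cell_seed)
        states <- simulate_traits(tree, params)
        y_tip <- states$y_true[tree$tip.label]
        for (method in methods) {
          fit <- run_one_method(method, tree, states$x_obs, y_tip,
                                seed = mix_seed(cell_seed, method))
          records[[length(records) + 1L]] <- data.frame(
            c = cc, p = pp, reversible = rev, r = r_use,
            replicate = rep_i, method = method,
            slope = fit$slope, p_value = fit$p_value,
            cov_param = fit$cov_param, converged = fit$converged
          )
        }
      }
    }
  }
  do.call(rbind, records)
}

#' Summarize rejection rates per grid cell and method
#'
#' The rate is the fraction of converged replicates with `p_value < alpha`;
#' cells with `c = 0` are false-positive (specificity) cells, cells with
#' `c > 0` true-positive (sensitivity) cells. Non-converged replicate counts
#' are reported, and excluded from the denominator.
#'
#' @param records Output of [run_benchmark_grid()].
#' @param alpha Test level.
#' @return A data frame of cells with `rate`, `type`, `n_converged`,
#'   `n_total`.
#' @export
summarize_rates <- function(records, alpha = 0.05) {
  if (!nrow(records)) stop_arg("`records` is empty")
  key <- interaction(records$c, records$p, records$reversible,
                     records$method, drop = TRUE)
  out <- lapply(split(records, key), function(d) {
    ok <- d$converged & !is.na(d$p_value)
    data.frame(c = d$c[1], p = d$p[1], reversible = d$reversible[1],
               method = d$method[1],
               type = if (d$c[1] == 0) "FP" else "TP",
               rate = if (any(ok)) mean(d$p_value[ok] < alpha) else NA_real_,
               n_converged = sum(ok), n_total = nrow(d))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$method, res$c, res$p), ]
}
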