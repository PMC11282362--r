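# Nonparametric and clade-blocked analyses: recursive sibling contrasts with
# Wilcoxon / bootstrap tests, the Scheirer-Ray-Hare two-way rank test with a
# Kruskal-Wallis fallback, and clade-mean normalization.

np_test <- function(method, statistic, p_value, n_units, note = NULL) {
  structure(list(method = method, statistic = unname(statistic),
                 p_value = unname(p_value), n_units = n_units, note = note),
            class = "np_test")
}

#' @export
print.np_test <- function(x, ...) {
  cat(sprintf("<%s>  statistic = %.6g  p = %.4g  n = %d\n", x$method,
              x$statistic, x$p_value, x$n_units))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Propagate tip states to internal nodes
#'
#' Recursive labelling over immediate children: an internal node's predictor
#' is 1 iff every child's predictor is 1 (otherwise 0), and its response is
#' the mean of its children's responses. Applied in postorder, so labels flow
#' from the tips to the root.
#'
#' @param tree A `phylo`.
#' @param x Binary tip predictor (observed values), named or in tip order.
#' @param y Numeric tip response, named or in tip order.
#' @return A `trait_labels` list with `x` and `y` over all nodes (indexed by
#'   ape node number) and the tree.
#' @export
propagate_states <- function(tree, x, y) {
  stopifnot(inherits(tree, "phylo"))
  x <- align_to_tips(x, tree$tip.label, "x")
  y <- align_to_tips(y, tree$tip.label, "y")
  if (anyNA(x) || anyNA(y)) stop_arg("tip labels must be complete (no NA)")
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  X <- rep(NA_real_, n_all)
  Y <- rep(NA_real_, n_all)
  X[seq_len(n_tip)] <- as.numeric(x)
  Y[seq_len(n_tip)] <- as.numeric(y)
  post <- ape::reorder.phylo(tree, "postorder")
  parents <- unique(post$edge[, 1])
  for (a in parents) {
    ch <- post$edge[post$edge[, 1] == a, 2]
    X[a] <- as.numeric(all(X[ch] == 1))
    Y[a] <- mean(Y[ch])
  }
  structure(list(x = X, y = Y, tree = tree), class = "trait_labels")
}

#' Extract sibling contrasts in the predictor
#'
#' For every internal node whose immediate children are not unanimous in the
#' predictor, records one contrast: the mean response among children with
#' `X = 1` minus the mean among children with `X = 0` (multifurcations are
#' averaged within each predictor value). Each contrast uses a disjoint child
#' set, so contrasts are drawn from phylogenetically separate clades.
#'
#' @param tree A `phylo`.
#' @param labels A `trait_labels` object from [propagate_states()].
#' @return A data frame (`parent_node`, `y_plus`, `y_minus`, `diff`) ordered
#'   by node id; zero rows when no diverse sibling set exists.
#' @export
extract_contrasts <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"), inherits(labels, "trait_labels"))
  n_tip <- length(tree$tip.label)
  out <- list()
  for (a in sort(unique(tree$edge[, 1]))) {
    ch <- tree$edge[tree$edge[, 1] == a, 2]
    xs <- labels$x[ch]
    if (length(unique(xs)) < 2) next
    out[[length(out) + 1L]] <- data.frame(
      parent_node = a,
      y_plus = mean(labels$y[ch[xs == 1]]),
      y_minus = mean(labels$y[ch[xs == 0]])
    )
  }
  if (!length(out)) {
    return(data.frame(parent_node = integer(0), y_plus = numeric(0),
                      y_minus = numeric(0), diff = numeric(0)))
  }
  res <- do.call(rbind, out)
  res$diff <- res$y_plus - res$y_minus
  res
}

# Exact two-sided signed-rank p-value by convolution over the 2^n equally
# likely sign assignments. Ranks may be half-integers (average ranks under
# ties), so the grid is doubled.
signed_rank_exact_p <- function(ranks, W) {
  s <- as.integer(round(2 * ranks))
  total <- sum(s)
  f <- numeric(total + 1)
  f[1] <- 1
  for (si in s) {
    g <- f
    idx <- (si + 1):(total + 1)
    g[idx] <- g[idx] + f[seq_len(total + 1 - si)]
    f <- g
  }
  f <- f / sum(f)
  w2 <- as.integer(round(2 * W))
  p_le <- sum(f[seq_len(w2 + 1)])
  p_ge <- sum(f[(w2 + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test of zero median difference
#'
#' Two-sided matched-pairs test on a list of differences. Zeros are dropped
#' and ties receive average ranks. For up to 25 nonzero differences the p
#' comes from the exact null distribution (enumeration of all sign
#' assignments via convolution); beyond that, a normal approximation with
#' continuity and tie corrections is used.
#'
#' @param diffs Numeric vector of differences.
#' @return An `np_test`; if all differences are zero the result carries
#'   `p_value = 1` and a `note`, not an error.
#' @export
wilcoxon_signed_rank <- function(diffs) {
  diffs <- as.numeric(diffs)
  diffs <- diffs[!is.na(diffs)]
  nz <- diffs[diffs != 0]
  n <- length(nz)
  if (n == 0) {
    return(np_test("wilcoxon_signed_rank", 0, 1, 0,
                   note = "all differences are zero"))
  }
  r <- rank(abs(nz))
  W <- sum(r[nz > 0])
  if (n <= 25) {
    p <- signed_rank_exact_p(r, W)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  np_test("wilcoxon_signed_rank", W, p, n)
}

#' Bootstrap percentile test for a nonzero mean difference
#'
#' Resamples the difference list with replacement `B` times to build the
#' sampling distribution of the mean; the two-sided p-value is twice the
#' smaller tail fraction at zero (with an add-one correction so the smallest
#' reportable p is about `2/B`), capped at 1.
#'
#' @param diffs Numeric vector of at least 2 differences.
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @return An `np_test` with the observed mean as statistic.
#' @export
bootstrap_mean_test <- function(diffs, B = 10000, seed = 1) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2) stop_arg("need at least 2 differences")
  if (!is_count(B) || B < 100) stop_arg("`B` must be an integer >= 100")
  set.seed(seed)
  n <- length(diffs)
  bm <- colMeans(matrix(sample(diffs, n * B, replace = TRUE), nrow = n))
  p_lo <- (sum(bm <= 0) + 1) / (B + 1)
  p_hi <- (sum(bm >= 0) + 1) / (B + 1)
  np_test("bootstrap_mean", mean(diffs), min(1, 2 * min(p_lo, p_hi)), n)
}

#' Scheirer-Ray-Hare two-way rank test
#'
#' Rank-based two-factor test generalizing Kruskal-Wallis: all responses are
#' ranked together (average ranks for ties), sums of squares are taken from a
#' sequential two-way ANOVA on the ranks, and each effect's statistic is
#' `H = SS_effect / (SS_total / (N - 1))`, referred to a chi-squared
#' distribution with (levels - 1) degrees of freedom. Used here with the
#' feature of interest as `group` and top-level clade (see [assign_clades()])
#' as `block`. With a single block level the group statistic reduces exactly
#' to Kruskal-Wallis.
#'
#' @param y Numeric response.
#' @param group Factor of interest (>= 2 levels present).
#' @param block Blocking factor (e.g. clade).
#' @return An `np_test` for the group effect; block and interaction
#'   statistics, when estimable, are attached as `attr(res, "effects")`.
#' @export
srh_test <- function(y, group, block) {
  y <- as.numeric(y)
  group <- factor(group)
  block <- factor(block)
  if (nlevels(droplevels(group)) < 2)
    stop_arg("`group` has a single level; use kruskal_wallis() within ",
             "the one clade instead")
  if (length(unique(c(length(y), length(group), length(block)))) != 1)
    stop_arg("y, group and block must have equal length")
  N <- length(y)
  r <- rank(y)
  ss_total <- sum((r - mean(r))^2)
  if (ss_total == 0) return(np_test("scheirer_ray_hare", 0, 1, N))
  ms_total <- ss_total / (N - 1)
  form <- if (nlevels(droplevels(block)) > 1) r ~ group + block + group:block
          else r ~ group
  an <- anova(lm(form))
  get_h <- function(term) {
    if (!term %in% rownames(an)) return(NULL)
    ss <- an[term, "Sum Sq"]
    df <- an[term, "Df"]
    if (is.na(ss) || df < 1) return(NULL)
    h <- ss / ms_total
    list(H = h, df = df, p = pchisq(h, df, lower.tail = FALSE))
  }
  g <- get_h("group")
  res <- np_test("scheirer_ray_hare", g$H, g$p, N)
  attr(res, "effects") <- list(group = g, block = get_h("block"),
                               interaction = get_h("group:block"))
  res
}

#' Kruskal-Wallis rank test
#'
#' Wrapper around [stats::kruskal.test()] (standard tie-corrected H with a
#' chi-squared p-value) returning the package's test container; a constant
#' response yields `H = 0, p = 1` rather than an undefined statistic.
#'
#' @param y Numeric response.
#' @param group Factor with at least 2 levels present.
#' @return An `np_test`.
#' @export
kruskal_wallis <- function(y, group) {
  y <- as.numeric(y)
  group <- droplevels(factor(group))
  if (nlevels(group) < 2) stop_arg("`group` must have at least 2 levels")
  if (length(unique(y)) == 1)
    return(np_test("kruskal_wallis", 0, 1, length(y)))
  kt <- kruskal.test(y, group)
  np_test("kruskal_wallis", kt$statistic, kt$p.value, length(y))
}

#' Subtract clade means from a response
#'
#' Centers the response within each clade, removing clade-level baselines
#' (e.g. systematically different organelle gene counts in different
#' supergroups) before a subsequent regression.
#'
#' @param y Numeric response named by tip label (or aligned with `clades`).
#' @param clades Tip -> clade assignment, as from [assign_clades()].
#' @return The adjusted response; each clade of the output has mean zero.
#' @export
clade_normalize <- function(y, clades) {
  if (!is.null(names(y)) && !is.null(names(clades))) {
    missing <- setdiff(names(y), names(clades))
    if (length(missing))
      stop_arg("no clade assigned for: ", paste(head(missing, 5),
                                                collapse = ", "))
    clades <- clades[names(y)]
  } else if (length(y) != length(clades)) {
    stop_arg("`y` and `clades` must have equal length")
  }
  y - ave(as.numeric(y), as.character(clades))
}
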