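# Feature screening for trait tables: per-(feature, value) binarization,
# positive-subtree restriction, influence filtering, PLM + Poisson PGLM fits,
# Bonferroni correction and significance-profile coding.

norm_species <- function(x) tolower(gsub("\\s+", " ", trimws2(as.character(x))))

check_trait_table <- function(table) {
  need <- c("species", "feature", "value")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop_arg("trait table must be a data frame with columns ",
             paste(need, collapse = ", "))
  table
}

#' Binarize one feature value of a trait table
#'
#' Species carrying `positive_value` for the feature are coded 1; species
#' carrying any *other observed* value are coded 0; species for which the
#' feature is missing are reported as undefined and excluded downstream — a
#' missing observation is never coded as a negative. Sweeping every observed
#' value of every feature as the positive case generates the hypothesis set.
#'
#' @param table Long-format trait table (`species`, `feature`, `value`);
#'   `NA` values count as missing.
#' @param feature Feature (column `feature`) to binarize.
#' @param positive_value The value treated as positive; must occur.
#' @return A list with `x` (named 0/1 vector over species with an observed
#'   value) and `undefined` (species in the table lacking this feature).
#' @export
binarize_feature <- function(table, feature, positive_value) {
  table <- check_trait_table(table)
  rows <- table[table$feature == feature & !is.na(table$value), , drop = FALSE]
  if (!nrow(rows)) stop_arg("feature has no observed values: ", feature)
  if (!positive_value %in% rows$value)
    stop_arg("value ", positive_value, " never observed for feature ",
             feature)
  x <- setNames(as.numeric(rows$value == positive_value), rows$species)
  x <- x[!duplicated(names(x))]
  all_species <- unique(table$species)
  list(x = x, undefined = setdiff(all_species, names(x)))
}

#' Restrict an analysis to the positive subtree
#'
#' Guards against clade-definition artifacts (a feature that is only defined
#' within one clade trivially "correlating" with that clade's response
#' baseline): the tree is cut down to the subtree rooted at the most recent
#' common ancestor of all positive-labelled species, and species outside it
#' are dropped from the predictor.
#'
#' @param tree A `phylo`.
#' @param predictor Named 0/1 vector with at least one positive.
#' @return A list with the restricted `tree` and `predictor`, and the MRCA
#'   `node`.
#' @export
restrict_to_positive_subtree <- function(tree, predictor) {
  stopifnot(inherits(tree, "phylo"))
  pos <- names(predictor)[predictor == 1]
  pos <- intersect(pos, tree$tip.label)
  if (!length(pos)) stop_arg("no positive-labelled species on the tree")
  node <- mrca_node(tree, pos)
  sub <- extract_subtree(tree, node)
  keep <- intersect(names(predictor), sub$tip.label)
  list(tree = sub, predictor = predictor[keep], node = node)
}

#' Influence filter against small-number artifacts
#'
#' If either predictor class has at most two distinct response values, every
#' distinct response value in that class must be backed by at least
#' `min_obs` observations — otherwise the result would hinge on a handful of
#' observations (e.g. a lone count of 12 against many counts of 13) and the
#' (feature, value) pair is discarded. Classes with three or more distinct
#' response values are not subject to the rule.
#'
#' @param predictor 0/1 vector; both classes must be non-empty.
#' @param response Numeric response aligned with `predictor`.
#' @param min_obs Minimum observations per distinct response value when the
#'   rule triggers (default 6).
#' @param both_classes If `TRUE`, a triggering class imposes the count
#'   requirement on the response values of both classes, not just its own.
#' @return A list with `keep` (logical) and `reason` (string or `NA`).
#' @export
influence_filter <- function(predictor, response, min_obs = 6,
                             both_classes = FALSE) {
  if (length(predictor) != length(response))
    stop_arg("predictor and response must be aligned")
  for (cls in c(0, 1)) {
    if (!any(predictor == cls)) stop_arg("empty predictor class: ", cls)
  }
  for (cls in c(0, 1)) {
    vals <- response[predictor == cls]
    counts <- table(vals)
    if (length(counts) <= 2) {
      check <- if (both_classes) table(response) else counts
      if (any(check < min_obs)) {
        return(list(keep = FALSE, reason = sprintf(
          "class %d has %d distinct response value(s) and value %s has only %d observation(s) (< %d)",
          cls, length(counts), names(check)[which.min(check)], min(check),
          min_obs)))
      }
    }
  }
  list(keep = TRUE, reason = NA_character_)
}

#' Code a pair of p-values into a significance profile
#'
#' Per method: `"**"` if `p < alpha / n_tests` (Bonferroni-robust), `"*"` if
#' `p < alpha` without correction, `"-"` otherwise; the two codes are joined
#' as `"plm/pglm"`.
#'
#' @param p_plm,p_pglm P-values from the linear and Poisson fits.
#' @param alpha Nominal level.
#' @param n_tests Bonferroni denominator (number of hypotheses tested).
#' @return A profile string such as `"**/*"`.
#' @export
significance_profile <- function(p_plm, p_pglm, alpha = 0.05, n_tests = 1) {
  if (n_tests < 1) stop_arg("`n_tests` must be >= 1")
  code <- function(p) {
    if (is.na(p)) return("-")
    if (p < alpha / n_tests) "**" else if (p < alpha) "*" else "-"
  }
  paste(code(p_plm), code(p_pglm), sep = "/")
}

#' Screen every (feature, value) pair of a trait table
#'
#' The full analysis pipeline applied to each candidate hypothesis:
#' binarize ([binarize_feature()]), drop undefined species, restrict to the
#' positive subtree ([restrict_to_positive_subtree()]), apply the influence
#' filter ([influence_filter()]), then fit PLM (Brownian PGLS) and Poisson
#' PGLM ([fit_poisson_gee()], on responses rounded to counts) and code the
#' significance profile with a Bonferroni denominator equal to the number of
#' pairs actually fitted (unless `n_tests` overrides it). Species names in
#' the table, response and tree are reconciled after whitespace/case
#' normalization; unmatched species are dropped with a message.
#'
#' @param table Long-format trait table (`species`, `feature`, `value`).
#' @param response Named numeric vector of per-species counts, or a data
#'   frame with columns `species` and `count`.
#' @param tree A `phylo` over the species.
#' @param alpha Nominal level for the profiles.
#' @param n_tests Optional fixed Bonferroni denominator.
#' @param min_class Minimum species per predictor class for a fit (default 3).
#' @return A data frame of `feature_result` rows sorted by the smaller of the
#'   two p-values; filtered/failed pairs carry `filtered = TRUE`, a `reason`,
#'   and no profile. The Bonferroni denominator used is attached as
#'   `attr(res, "n_tests")`.
#' @export
screen_features <- function(table, response, tree, alpha = 0.05,
                            n_tests = NULL, min_class = 3) {
  table <- check_trait_table(table)
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(response)) {
    if (!all(c("species", "count") %in% names(response)))
      stop_arg("response data frame needs columns species, count")
    response <- setNames(response$count, response$species)
  }
  table$species <- norm_species(table$species)
  names(response) <- norm_species(names(response))
  tree$tip.label <- norm_species(tree$tip.label)
  usable <- intersect(tree$tip.label, names(response))
  unmatched <- setdiff(union(unique(table$species), names(response)),
                       tree$tip.label)
  if (length(unmatched))
    message(length(unmatched),
            " species not matched to the tree were dropped")
  pairs <- unique(table[!is.na(table$value), c("feature", "value")])
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    feat <- pairs$feature[i]
    val <- pairs$value[i]
    row <- data.frame(feature = feat, positive_value = val,
                      subtree_node = NA_integer_, n_pos = NA_integer_,
                      n_neg = NA_integer_, slope_plm = NA_real_,
                      p_plm = NA_real_, slope_pglm = NA_real_,
                      p_pglm = NA_real_, filtered = TRUE,
                      reason = NA_character_, profile = NA_character_)
    res <- tryCatch({
      bin <- binarize_feature(table, feat, val)
      x <- bin$x[intersect(names(bin$x), usable)]
      if (sum(x == 1) < 1) stop("no positive species on the tree")
      restr <- restrict_to_positive_subtree(tree, x)
      x <- restr$predictor
      sub <- ape::keep.tip(restr$tree, names(x))
      y <- response[sub$tip.label]
      x <- x[sub$tip.label]
      row$subtree_node <- restr$node
      row$n_pos <- sum(x == 1)
      row$n_neg <- sum(x == 0)
      if (row$n_pos < min_class || row$n_neg < min_class)
        stop("fewer than ", min_class, " species in a predictor class")
      filt <- influence_filter(x, y)
      if (!filt$keep) stop("influence filter: ", filt$reason)
      plm <- fit_pgls(x, y, sub, covariance_spec("brownian"))
      pglm <- fit_poisson_gee(x, round(y), sub)
      row$slope_plm <- plm$slope
      row$p_plm <- plm$p_value
      row$slope_pglm <- pglm$slope
      row$p_pglm <- pglm$p_value
      row$filtered <- FALSE
      row
    }, error = function(e) {
      row$reason <- conditionMessage(e)
      row
    })
    rows[[i]] <- res
  }
  res <- do.call(rbind, rows)
  fitted <- !res$filtered
  denom <- if (!is.null(n_tests)) n_tests else max(1, sum(fitted))
  res$profile[fitted] <- mapply(significance_profile, res$p_plm[fitted],
                                res$p_pglm[fitted],
                                MoreArgs = list(alpha = alpha,
                                                n_tests = denom))
  ord <- order(ifelse(fitted, pmin(res$p_plm, res$p_pglm, na.rm = TRUE), Inf))
  res <- res[ord, ]
  rownames(res) <- NULL
  attr(res, "n_tests") <- denom
  res
}

#' Build a synthetic trait table with one planted effect
#'
#' Generates the end-to-end screening fixture: a predictor feature planted on
#' a known clade drives faster response loss (`c > 0`) via
#' [evolve_response_given_x()], while `n_decoys` decoy features mark random
#' clades that have no influence on the response. Used to verify that
#' [screen_features()] recovers a planted signal and loses it under label
#' shuffling.
#'
#' @param tree A `phylo`.
#' @param m,c,y0 Response evolution parameters (see [sim_params()]).
#' @param n_decoys Number of decoy features.
#' @param seed Integer seed.
#' @return A list with `table` (long-format trait table), `response` (named
#'   counts), `planted_feature`, and the planted `node`.
#' @export
synth_screen_dataset <- function(tree, m = 2, c = 2, y0 = 100, n_decoys = 10,
                                 seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  planted <- plant_innovation(tree, seed = mix_seed(seed, "plant"),
                              min_tips = 16, max_frac = 0.5)
  states <- evolve_response_given_x(tree, planted$x, m = m, c = c, y0 = y0,
                                    seed = mix_seed(seed, "response"))
  y <- round(states$y_true[tree$tip.label])
  tabs <- list(data.frame(species = tree$tip.label, feature = "planted",
                          value = ifelse(planted$x == 1, "yes", "no")))
  for (k in seq_len(n_decoys)) {
    decoy <- plant_innovation(tree, seed = mix_seed(seed, "decoy", k),
                              min_tips = 8, max_frac = 0.5)
    tabs[[k + 1L]] <- data.frame(species = tree$tip.label,
                                 feature = paste0("decoy_", k),
                                 value = ifelse(decoy$x == 1, "yes", "no"))
  }
  list(table = do.call(rbind, tabs), response = y,
       planted_feature = "planted", node = planted$node)
}
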