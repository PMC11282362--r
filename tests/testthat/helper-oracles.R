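# Independent brute-force oracles and fixture builders shared by the tests.
# Every oracle is written from the definition, not from the implementation.

# Random tree with branch lengths, seeded.
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- round(tr$edge.length, 6)
  tr
}

# Path from the root to a node, as a vector of node numbers (root first).
root_path <- function(tree, node) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  path <- node
  root <- length(tree$tip.label) + 1L
  while (node != root) {
    node <- parent[node]
    path <- c(node, path)
  }
  path
}

# Brute-force Brownian covariance: for each pair of tips, sum the lengths of
# the branches shared by their root paths.
brownian_oracle <- function(tree) {
  n <- length(tree$tip.label)
  edge_len <- setNames(tree$edge.length, tree$edge[, 2])
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(n), function(i) root_path(tree, i))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[i]], paths[[j]])
    shared <- setdiff(shared, length(tree$tip.label) + 1L) # drop the root
    V[i, j] <- sum(edge_len[as.character(shared)])
  }
  V
}

# Brute-force patristic distances via root paths.
patristic_oracle <- function(tree) {
  n <- length(tree$tip.label)
  edge_len <- setNames(tree$edge.length, tree$edge[, 2])
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(n), function(i) root_path(tree, i))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    sym <- c(setdiff(paths[[i]], paths[[j]]), setdiff(paths[[j]], paths[[i]]))
    D[i, j] <- sum(edge_len[as.character(sym)])
  }
  D
}

# MRCA by intersecting root paths.
mrca_oracle <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  common <- Reduce(intersect, lapply(idx, function(i) root_path(tree, i)))
  common[length(common)]
}

# Closed-form GLS estimate via explicit matrix inversion.
gls_oracle <- function(x, y, V) {
  X <- cbind(1, x)
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y)
}

# Exact two-sided signed-rank p-value by direct enumeration of all 2^n sign
# assignments (feasible for n <= 12).
signed_rank_enum_p <- function(diffs) {
  nz <- diffs[diffs != 0]
  n <- length(nz)
  r <- rank(abs(nz))
  W_obs <- sum(r[nz > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- drop(signs %*% r)
  p_le <- mean(W_all <= W_obs + 1e-12)
  p_ge <- mean(W_all >= W_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# Two-way rank ANOVA by explicit sums of squares for a balanced layout.
srh_oracle_balanced <- function(y, group, block) {
  r <- rank(y)
  N <- length(y)
  gmean <- tapply(r, group, mean)
  bmean <- tapply(r, block, mean)
  ng <- table(group)
  nb <- table(block)
  ss_group <- sum(ng * (gmean - mean(r))^2)
  ss_total <- sum((r - mean(r))^2)
  ss_group / (ss_total / (N - 1))
}

# Small MediaWiki-style XML dump written to a temp file.
write_fixture_dump <- function(pages) {
  path <- tempfile(fileext = ".xml")
  body <- vapply(seq_along(pages), function(i) {
    sprintf("<page><title>%s</title><revision><text>%s</text></revision></page>",
            names(pages)[i], pages[[i]])
  }, "")
  writeLines(c(
    '<mediawiki xmlns="http://www.mediawiki.org/xml/export-0.10/">',
    body, "</mediawiki>"), path)
  path
}

fixture_dump_3pages <- function() {
  write_fixture_dump(c(
    Cuscuta = paste0("Cuscuta is a parasitic plant of the morning glory ",
                     "family, a [[Parasitism|parasite]] twining around ",
                     "[[Clover]] and other hosts."),
    Chlamydomonas = paste0("Chlamydomonas is a single-celled green alga ",
                           "related to [[Volvox]]; it is not parasitic."),
    Quercus = "Oaks are large trees of the Northern Hemisphere."
  ))
}
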