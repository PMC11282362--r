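# Tree construction, Newick I/O, covariance structures and tree queries.

test_that("balanced trees have the forced shape", {
  t0 <- make_balanced_tree(0)
  expect_s3_class(t0, "phylo")
  expect_equal(length(t0$tip.label), 1L)

  t8 <- make_balanced_tree(8)
  expect_equal(length(t8$tip.label), 256L)
  expect_equal(nrow(t8$edge), 510L)

  t3 <- make_balanced_tree(3, branch_length = 1)
  depths <- ape::node.depth.edgelength(t3)[seq_len(8)]
  expect_equal(unname(depths), rep(3, 8))

  expect_error(make_balanced_tree(-1), "non-negative")
  expect_error(make_balanced_tree(3, branch_length = 0), "positive")
})

test_that("birth-death simulation is seeded, conditioned and ultrametric when pure-birth", {
  y <- simulate_birth_death_tree(16, birth = 1, death_nu = 0, seed = 7)
  expect_equal(length(y$tip.label), 16L)
  d <- ape::node.depth.edgelength(y)[seq_len(16)]
  expect_lt(max(d) - min(d), 1e-8)

  a <- simulate_birth_death_tree(64, birth = 1, death_nu = 0.5, seed = 1)
  b <- simulate_birth_death_tree(64, birth = 1, death_nu = 0.5, seed = 1)
  expect_identical(write_newick(a), write_newick(b))
  expect_equal(length(a$tip.label), 64L)

  expect_error(simulate_birth_death_tree(16, birth = 1, death_nu = 1),
               "smaller than")
})

test_that("mean tip count at a fixed time matches the analytic birth-death expectation", {
  birth <- 1
  death <- 0.3
  t_max <- 1.5
  set.seed(42)
  counts <- replicate(200, {
    tr <- phylosieve:::bd_forward(birth, death, t_max = t_max)
    if (is.null(tr)) 0 else length(tr$tip.label)
  })
  expected <- 2 * exp((birth - death) * t_max) # two initial lineages
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("newick reading honours the absent-length dialect and validates input", {
  tr <- read_newick("(A:1,B:1):0;")
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(sort(tr$edge.length), c(1, 1))

  bare <- read_newick("((A,B),C);")
  expect_null(bare$edge.length)

  expect_error(read_newick("((A,B),A);"), "duplicate")
  expect_error(read_newick("((A,B;"), "parse|parenth")
})

test_that("newick round-trips preserve topology, labels and lengths", {
  for (seed in 1:5) {
    tr <- random_tree(50, seed)
    back <- read_newick(write_newick(tr))
    expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE))
  }
})

test_that("brownian covariance matches hand values and the path-sum oracle", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  V <- covariance_matrix(tr, covariance_spec("brownian"))
  expect_equal(V["A", "A"], 2)
  expect_equal(V["B", "B"], 2)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["C", "C"], 2)
  expect_equal(V["A", "C"], 0)

  for (seed in 1:5) {
    tr <- random_tree(20, seed)
    V <- covariance_matrix(tr, covariance_spec("brownian"))
    O <- brownian_oracle(tr)
    expect_equal(V[rownames(O), colnames(O)], O, tolerance = 1e-12)
  }
})

test_that("covariance transforms behave as defined", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  V0 <- covariance_matrix(tr, covariance_spec("pagel_lambda", 0))
  expect_equal(unname(V0), diag(c(2, 2, 2)))

  # lambda = 1 is exactly brownian
  tr2 <- random_tree(15, 3)
  expect_equal(covariance_matrix(tr2, covariance_spec("pagel_lambda", 1)),
               covariance_matrix(tr2, covariance_spec("brownian")))

  # martins-hansen approaches the identity as alpha grows
  t3 <- make_balanced_tree(3)
  D <- patristic_distances(t3)
  Vmh <- covariance_matrix(t3, covariance_spec("martins_hansen", 50 / max(D)))
  expect_lt(max(abs(Vmh[upper.tri(Vmh)])), 1e-6)
  expect_equal(unname(diag(Vmh)), rep(1, 8))

  # all models yield symmetric PSD matrices
  specs <- list(covariance_spec("brownian"),
                covariance_spec("pagel_lambda", 0.5),
                covariance_spec("martins_hansen", 0.7),
                covariance_spec("grafen", 1),
                covariance_spec("identity"))
  for (seed in 1:3) {
    tr3 <- random_tree(12, seed + 10)
    for (sp in specs) {
      V <- covariance_matrix(tr3, sp)
      expect_equal(V, t(V))
      expect_gt(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
                -1e-9)
    }
  }

  expect_error(covariance_spec("pagel_lambda", 1.5), "lambda")
  expect_error(covariance_spec("martins_hansen", -1), "alpha")
})

test_that("grafen heights follow the descendant-tip-count definition", {
  tr <- read_newick("((A,B),(C,(D,E)));")
  V <- covariance_matrix(tr, covariance_spec("grafen", 1))
  # root height 1; MRCA(A,B) height (2-1)/4; MRCA(C,D,E) height (3-1)/4
  expect_equal(V["A", "B"], 1 - 1 / 4)
  expect_equal(V["C", "D"], 1 - 2 / 4)
  expect_equal(V["D", "E"], 1 - 1 / 4)
  expect_equal(unname(diag(V)), rep(1, 5))
})

test_that("patristic distances match hand values, the oracle and the brownian identity", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  D <- patristic_distances(tr)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)

  star <- ape::stree(6, "star")
  star$edge.length <- rep(1, 6)
  Ds <- patristic_distances(star)
  expect_true(all(Ds[upper.tri(Ds)] == 2))

  for (seed in 6:8) {
    tr <- random_tree(15, seed)
    D <- patristic_distances(tr)
    expect_equal(D, patristic_oracle(tr)[rownames(D), colnames(D)],
                 tolerance = 1e-10)
    V <- covariance_matrix(tr, covariance_spec("brownian"))
    ident <- outer(diag(V), diag(V), "+") - 2 * V
    expect_equal(D, ident, tolerance = 1e-10)
  }
})

test_that("mrca matches the root-path intersection oracle", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(mrca_node(tr, "A"), 1L)
  expect_equal(mrca_node(tr, c("A", "C")), 4L) # root
  expect_error(mrca_node(tr, c("A", "Z")), "unknown")

  for (seed in 1:5) {
    tr <- random_tree(20, seed)
    set.seed(seed)
    tips <- sample(tr$tip.label, 4)
    expect_equal(mrca_node(tr, tips), mrca_oracle(tr, tips))
  }
})

test_that("extract_subtree preserves structure and matches the descendant oracle", {
  tr <- random_tree(20, 2)
  expect_identical(extract_subtree(tr, 21L), tr) # root

  tip_tree <- extract_subtree(tr, 3L)
  expect_equal(length(tip_tree$tip.label), 1L)
  expect_equal(tip_tree$tip.label, tr$tip.label[3])

  node <- mrca_node(tr, tr$tip.label[c(4, 9)])
  sub <- extract_subtree(tr, node)
  expect_setequal(sub$tip.label,
                  tr$tip.label[phylosieve:::descendant_tips(tr, node)])
  expect_error(extract_subtree(tr, 999), "unknown node")
})

test_that("clade assignment partitions the tips by child of the root", {
  tr <- read_newick("((A,B),C,(D,E));") # trifurcating root
  cl <- assign_clades(tr)
  expect_equal(length(unique(cl)), 3L)

  t8 <- make_balanced_tree(8)
  cl8 <- assign_clades(t8)
  expect_equal(as.integer(sort(table(cl8))), c(128L, 128L))

  for (seed in 1:3) {
    tr <- random_tree(25, seed)
    cl <- assign_clades(tr)
    expect_setequal(names(cl), tr$tip.label)   # exhaustive
    expect_false(any(cl == ""))                 # every tip assigned once
  }
})
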