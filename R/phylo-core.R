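# Tree construction, Newick I/O and phylogenetic covariance structures.
# Trees are ape "phylo" objects throughout: tips 1..Ntip, root Ntip+1,
# polytomies allowed, edge lengths optional (absent, not zero, when unknown).

#' Build a balanced bifurcating tree with uniform branch lengths
#'
#' Constructs the fully symmetric tree used as the reference topology in the
#' synthetic control studies: `2^depth` tips, every branch of the same length,
#' so that all root-to-tip paths have length `depth * branch_length`.
#'
#' @param depth Non-negative integer; number of bifurcations from root to tip.
#'   `depth = 0` gives a single-tip tree.
#' @param branch_length Positive branch length applied to every edge.
#' @return An object of class `phylo` with tips labelled `t1..t{2^depth}`.
#' @examples
#' tr <- make_balanced_tree(3)
#' ape::Ntip(tr)  # 8
#' @export
make_balanced_tree <- function(depth, branch_length = 1) {
  if (!is_count(depth)) stop_arg("`depth` must be a non-negative integer")
  if (!is.numeric(branch_length) || branch_length <= 0)
    stop_arg("`branch_length` must be a positive real")
  if (depth == 0) return(single_tip_tree("t1", edge_len = 0))
  phy <- ape::stree(2^depth, type = "balanced")
  phy$edge.length <- rep(branch_length, nrow(phy$edge))
  phy$tip.label <- paste0("t", seq_len(2^depth))
  phy
}

# A phylo with one tip; used for degenerate subtrees.
single_tip_tree <- function(label, edge_len = NULL) {
  phy <- list(edge = matrix(c(2L, 1L), 1, 2), Nnode = 1L, tip.label = label)
  if (!is.null(edge_len)) phy$edge.length <- edge_len
  class(phy) <- "phylo"
  phy
}

#' Simulate a birth-death phylogeny conditioned on a tip count
#'
#' Forward (Gillespie) simulation of a linear birth-death process started from
#' two lineages, with exponential waiting times between events; the simulation
#' stops the moment the number of extant lineages reaches `n_tips`. Extinct
#' lineages are pruned and unary nodes suppressed, so the returned tree has
#' exactly `n_tips` tips, all extant at the stopping time. Runs ending in total
#' extinction are discarded and redrawn, up to 1000 retries.
#'
#' @param n_tips Number of extant tips required (>= 2).
#' @param birth Speciation rate (> 0).
#' @param death_nu Extinction rate `nu` (>= 0, strictly less than `birth`).
#' @param seed Integer seed; the same seed always yields the same tree.
#' @return A rooted `phylo` with branch lengths, tips labelled `t1..tn`.
#' @export
simulate_birth_death_tree <- function(n_tips, birth = 1, death_nu = 0, seed = 1) {
  if (!is_count(n_tips) || n_tips < 2)
    stop_arg("`n_tips` must be an integer >= 2")
  if (!is.numeric(birth) || birth <= 0) stop_arg("`birth` must be positive")
  if (!is.numeric(death_nu) || death_nu < 0)
    stop_arg("`death_nu` must be non-negative")
  if (death_nu >= birth)
    stop_arg("`death_nu` must be smaller than `birth` so that ", n_tips,
             " extant tips are eventually reached")
  set.seed(seed)
  for (attempt in seq_len(1000)) {
    res <- bd_forward(birth, death_nu, n_tips = n_tips)
    if (!is.null(res)) return(res)
  }
  stop("birth-death simulation went extinct in all 1000 retries; ",
       "increase `birth` relative to `death_nu`")
}

# Forward birth-death simulation. Exactly one of n_tips / t_max must be given;
# consumes the current RNG stream. Returns NULL on total extinction.
bd_forward <- function(birth, death, n_tips = NULL, t_max = NULL) {
  parent <- c(NA_integer_, NA_integer_)
  t_start <- c(0, 0)
  t_end <- c(NA_real_, NA_real_)
  status <- c("alive", "alive") # alive / split / dead
  t <- 0
  repeat {
    alive <- which(status == "alive")
    na <- length(alive)
    if (na == 0L) return(NULL)
    if (!is.null(n_tips) && na == n_tips) {
      # stop at the event that reached n_tips; if no event has happened yet
      # (n_tips = 2), advance by one waiting time so branches have length
      if (t == 0) t <- rexp(1, na * (birth + death))
      break
    }
    dt <- rexp(1, na * (birth + death))
    if (!is.null(t_max) && t + dt > t_max) {
      t <- t_max
      break
    }
    t <- t + dt
    lin <- if (na == 1L) alive else alive[sample.int(na, 1L)]
    if (runif(1) < birth / (birth + death)) {
      status[lin] <- "split"
      t_end[lin] <- t
      parent <- c(parent, lin, lin)
      t_start <- c(t_start, t, t)
      t_end <- c(t_end, NA_real_, NA_real_)
      status <- c(status, "alive", "alive")
    } else {
      status[lin] <- "dead"
      t_end[lin] <- t
    }
  }
  t_end[status == "alive"] <- t
  bd_to_phylo(parent, t_start, t_end, status)
}

# Prune extinct lineages, suppress unary nodes, and emit a phylo.
bd_to_phylo <- function(parent, t_start, t_end, status) {
  n <- length(parent)
  has_alive <- status == "alive"
  for (i in rev(seq_len(n))) {
    if (has_alive[i] && !is.na(parent[i])) has_alive[parent[i]] <- TRUE
  }
  if (!any(has_alive)) return(NULL)
  kids_of <- function(i) which(!is.na(parent) & parent == i & has_alive)
  counter <- new.env()
  counter$k <- 0L
  # returns newick fragment without trailing length
  build <- function(i, extra = 0) {
    len <- t_end[i] - t_start[i] + extra
    if (status[i] == "alive") {
      counter$k <- counter$k + 1L
      return(sprintf("t%d:%.10g", counter$k, len))
    }
    ch <- kids_of(i)
    if (length(ch) == 1L) return(build(ch, extra = len))
    sprintf("(%s):%.10g", paste(vapply(ch, build, ""), collapse = ","), len)
  }
  roots <- which(is.na(parent) & has_alive)
  if (length(roots) == 2L) {
    txt <- sprintf("(%s,%s);", build(roots[1]), build(roots[2]))
  } else {
    # only one initial lineage survived: root at its first surviving split
    i <- roots
    while (status[i] == "split" && length(kids_of(i)) == 1L) i <- kids_of(i)
    if (status[i] == "alive") return(NULL) # single surviving tip: degenerate
    ch <- kids_of(i)
    txt <- sprintf("(%s);", paste(vapply(ch, build, ""), collapse = ","))
  }
  ape::read.tree(text = txt)
}

#' Read / write Newick strings
#'
#' Thin, validating wrappers around [ape::read.tree()] and [ape::write.tree()].
#' Branch lengths are optional; when a tree has none, lengths are recorded as
#' absent (not zero). Duplicate tip labels and malformed strings raise parse
#' errors naming the offending token.
#'
#' @param text A Newick string.
#' @return `read_newick`: a `phylo`; `write_newick`: a Newick string.
#' @export
read_newick <- function(text) {
  phy <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop_arg("could not parse Newick string (check parentheses): ",
             substr(text, 1, 60))
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup))
    stop_arg("duplicate tip label(s) in Newick string: ",
             paste(dup, collapse = ", "))
  if (any(phy$tip.label == "")) stop_arg("empty tip label in Newick string")
  phy
}

#' @param tree A `phylo`.
#' @rdname read_newick
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Substitute unit branch lengths when none are recorded
#'
#' Taxonomy-derived trees often carry no branch length information. For
#' covariance models that need lengths, every branch is assigned the same
#' default length (with a message), mirroring the practice of re-running
#' analyses with branch length estimates removed.
#'
#' @param tree A `phylo`.
#' @param default Length given to every branch when none are present.
#' @param quiet Suppress the substitution message.
#' @return A `phylo` that is guaranteed to carry branch lengths.
#' @export
ensure_branch_lengths <- function(tree, default = 1, quiet = FALSE) {
  if (is.null(tree$edge.length)) {
    if (!quiet)
      message("tree has no branch lengths; substituting length ", default,
              " on every branch")
    tree$edge.length <- rep(default, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) stop_arg("negative branch length in tree")
  tree
}

#' Specify a phylogenetic covariance model
#'
#' @param model One of `"brownian"`, `"identity"`, `"pagel_lambda"`,
#'   `"martins_hansen"`, `"grafen"`.
#' @param parameter Free parameter of the model: Pagel's `lambda` in `[0, 1]`,
#'   Martins-Hansen decay rate `alpha > 0`, or Grafen's `rho > 0` (default 1).
#'   For `pagel_lambda` and `martins_hansen` the string `"estimate"` requests
#'   maximum-likelihood profiling inside [fit_pgls()].
#' @return A `covariance_spec` object.
#' @export
covariance_spec <- function(model = c("brownian", "identity", "pagel_lambda",
                                      "martins_hansen", "grafen"),
                            parameter = NULL) {
  model <- match.arg(model)
  if (model %in% c("brownian", "identity")) {
    if (!is.null(parameter))
      stop_arg(model, " covariance carries no free parameter")
  } else if (identical(parameter, "estimate")) {
    if (model == "grafen")
      stop_arg("rho is not profiled; give a fixed value for grafen")
  } else {
    if (is.null(parameter)) {
      parameter <- switch(model, pagel_lambda = 1, martins_hansen = NULL,
                          grafen = 1)
      if (is.null(parameter))
        stop_arg("martins_hansen needs `parameter` (alpha > 0 or \"estimate\")")
    }
    if (!is.numeric(parameter) || length(parameter) != 1)
      stop_arg("`parameter` must be a single number or \"estimate\"")
    if (model == "pagel_lambda" && (parameter < 0 || parameter > 1))
      stop_arg("lambda must lie in [0, 1]")
    if (model == "martins_hansen" && parameter <= 0)
      stop_arg("alpha must be positive")
    if (model == "grafen" && parameter <= 0)
      stop_arg("rho must be positive")
  }
  structure(list(model = model, parameter = parameter),
            class = "covariance_spec")
}

#' Phylogenetic covariance matrix among tips
#'
#' Builds the tip covariance (or correlation) matrix implied by a covariance
#' specification:
#' * `brownian`: \eqn{V_{ij}} equals the branch length shared by the
#'   root-to-tip paths of `i` and `j` (so \eqn{V_{ii}} is the root-to-tip
#'   distance), the covariance of Brownian characters;
#' * `pagel_lambda`: Brownian off-diagonals multiplied by `lambda`, diagonal
#'   unchanged;
#' * `martins_hansen`: correlation \eqn{\exp(-\alpha d_{ij})} with
#'   \eqn{d_{ij}} the patristic distance;
#' * `grafen`: Brownian rule applied after replacing branch lengths by
#'   differences of Grafen node heights (proportional to descendant tip counts,
#'   root height 1) raised to the power `rho` — usable without measured branch
#'   lengths;
#' * `identity`: no phylogenetic structure (star phylogeny).
#'
#' Trees lacking branch lengths get unit lengths substituted (see
#' [ensure_branch_lengths()]), except under `grafen`/`identity` which ignore
#' them.
#'
#' @param tree A `phylo` with at least 2 tips.
#' @param spec A [covariance_spec()] with a fixed (not `"estimate"`) parameter.
#' @return A symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
covariance_matrix <- function(tree, spec = covariance_spec("brownian")) {
  stopifnot(inherits(tree, "phylo"), inherits(spec, "covariance_spec"))
  if (length(tree$tip.label) < 2) stop_arg("tree must have at least 2 tips")
  if (identical(spec$parameter, "estimate"))
    stop_arg("cannot build a matrix for parameter = \"estimate\"; ",
             "use fit_pgls() to profile it")
  switch(spec$model,
    identity = {
      V <- diag(length(tree$tip.label))
      dimnames(V) <- list(tree$tip.label, tree$tip.label)
      V
    },
    brownian = ape::vcv(ensure_branch_lengths(tree)),
    pagel_lambda = {
      V <- ape::vcv(ensure_branch_lengths(tree))
      d <- diag(V)
      V <- V * spec$parameter
      diag(V) <- d
      V
    },
    martins_hansen = {
      D <- patristic_distances(tree)
      exp(-spec$parameter * D)
    },
    grafen = {
      phy <- ape::compute.brlen(tree, method = "Grafen",
                                power = spec$parameter)
      ape::vcv(phy)
    }
  )
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips (zero on
#' the diagonal). Trees without branch lengths get unit lengths substituted.
#'
#' @inheritParams covariance_matrix
#' @return A symmetric matrix with tip-label dimnames.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  stats::cophenetic(ensure_branch_lengths(tree))
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree A `phylo`.
#' @param tips Character vector of tip labels (or integer tip numbers).
#' @return The ape node number of the MRCA; for a single tip, that tip's own
#'   number.
#' @export
mrca_node <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tips) == 0) stop_arg("`tips` must be non-empty")
  if (is.character(tips)) {
    idx <- match(tips, tree$tip.label)
    if (anyNA(idx))
      stop_arg("unknown tip label(s): ",
               paste(tips[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(tips)
    if (any(idx < 1 | idx > length(tree$tip.label)))
      stop_arg("tip numbers out of range")
  }
  idx <- unique(idx)
  if (length(idx) == 1) return(idx)
  ape::getMRCA(tree, idx)
}

#' Extract the subtree rooted at a node
#'
#' Branch lengths below the node are preserved. Extracting at the root returns
#' the tree unchanged; extracting at a tip returns a single-tip tree.
#'
#' @param tree A `phylo`.
#' @param root_node An ape node number present in the tree.
#' @return A `phylo`.
#' @export
extract_subtree <- function(tree, root_node) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  if (!is_count(root_node) || root_node < 1 || root_node > n_all)
    stop_arg("unknown node: ", root_node)
  root_node <- as.integer(root_node)
  if (root_node <= n_tip) {
    return(single_tip_tree(tree$tip.label[root_node],
                           edge_len = if (is.null(tree$edge.length)) NULL else 0))
  }
  if (root_node == n_tip + 1L) return(tree)
  ape::extract.clade(tree, root_node)
}

#' Assign each tip to a top-level clade
#'
#' Partitions the tips by which child-of-root subtree contains them — the
#' blocking variable used when deep-branching clades are treated as separate
#' baselines (e.g. the first branches after the common eukaryotic ancestor).
#'
#' @param tree A rooted `phylo`.
#' @return A named character vector, tip label -> clade id (`"clade_<node>"`).
#' @export
assign_clades <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  if (n_tip == 1) return(setNames("clade_1", tree$tip.label))
  root <- n_tip + 1L
  children <- tree$edge[tree$edge[, 1] == root, 2]
  out <- character(n_tip)
  for (ch in children) {
    if (ch <= n_tip) {
      out[ch] <- paste0("clade_", ch)
    } else {
      out[descendant_tips(tree, ch)] <- paste0("clade_", ch)
    }
  }
  setNames(out, tree$tip.label)
}

# Tip numbers below a node (the node itself if it is a tip).
descendant_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  todo <- node
  tips <- integer(0)
  edge <- tree$edge
  while (length(todo)) {
    ch <- edge[edge[, 1] %in% todo, 2]
    tips <- c(tips, ch[ch <= n_tip])
    todo <- ch[ch > n_tip]
  }
  sort(tips)
}
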