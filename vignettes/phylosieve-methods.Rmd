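---
title: "Methods: comparative analysis of eroding traits with biased observations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of eroding traits with biased observations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phylosieve asks a question that recurs across broad-scale comparative
biology: which organismal features are associated with a response that only
ever *decreases* over evolutionary time — the canonical example being the
number of genes retained in mitochondrial or plastid DNA — when the
phylogeny is broad, branch lengths are often unknown, a few clades dominate
the sample, and the predictor is observed sparsely, with absences that may
be missing records rather than true negatives? Because several textbook
assumptions of comparative methods fail at once here, the package pairs
every analysis tool with a simulator that generates data under exactly
these difficulties, so that specificity and sensitivity can be measured
rather than assumed.

## The generative model

Evolution runs from root to tips on a rooted phylogeny (balanced trees with
uniform branch lengths, or birth–death trees simulated forward with
speciation rate `birth` and extinction rate `death_nu`, conditioned on a
tip count). The root starts with predictor $X = 0$ and response $Y = y_0$.
Along each branch from ancestor $a$ to descendant $d$ with length
$t_{a,d}$:

* the binary predictor flips with probability $r$: reversibly
  ($X_d = 1 - X_a$) or irreversibly ($X_d = 1$), the latter modelling
  adaptations such as parasitism that are effectively never lost;
* the response is inherited minus a decrement
  $dY = t_{a,d}\,u$, with $u \sim U(0, m)$ when $X_a = 0$ and
  $u \sim U(c, m + c)$ when $X_a = 1$; negative values are clipped to zero.

So the predictor influences the *rate* of loss, not a target value: an
Ornstein–Uhlenbeck picture of stabilizing selection toward an optimum is
deliberately not used, because gene loss is monotone, often irreversible,
and driven by many influences beyond the predictor. $c = 0$ is the null
(no relationship); $c = m$ doubles-and-shifts the loss rate and is the
reference "true effect" in the tests.

Observation error is one-way: a tip with true $X = 1$ is reported as $0$
with probability $p$; true negatives are always reported faithfully. This
mimics trait databases in which positive records are trustworthy but
absence of a record is uninformative.

Parameter conventions, chosen once:

* `y0 = 100` — arbitrary; it only matters through how often the zero floor
  is hit, so it is set far above `m` times the tree depth and the floor is
  effectively never reached in the shipped settings.
* `m = 1` — the loss scale; slope magnitudes scale with it but test
  statistics and p-values are invariant to joint rescaling of `m`, `c` and
  `y0`, so nothing in the benchmarks depends on this choice.
* `r` is not set directly in benchmarks: it is calibrated by bisection so
  that the Monte-Carlo mean number of 0→1 innovations matches a target
  (8 on the 256-tip tree, after the reference benchmark design), within
  10%. The search brackets from below, where the innovation count is
  monotone in `r`.
* Draws are seeded; occlusion consumes a seed derived from the evolution
  seed, so one history can be re-occluded at several `p`.
* `dY` draws one uniform per branch and multiplies by branch length; a
  per-unit-time compounding alternative is not implemented because the
  branch-scaled form is the stated model.
* Polytomies need no special casing: the branch rule applies independently
  to each child branch.

What the generator does *not* emulate: systematically missing-not-at-random
sampling tied to the predictor–response relationship itself, clade-specific
loss-rate regimes beyond those induced by the predictor, discreteness of
the response during evolution (the simulator keeps $Y$ continuous and
rounds only where counts are required), and real taxonomic uncertainty in
the tree. Passing benchmarks therefore show robustness to sparse, biased,
non-Gaussian data on a known tree — not to a misspecified topology.

## Parametric models

`fit_gls()` fits $y = \beta_0 + \beta_1 x + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2 V)$ by maximum likelihood, with $V$ built
from the tree by `covariance_matrix()`:

* **brownian** — shared root-to-MRCA path length, the Brownian-motion
  covariance;
* **pagel_lambda** — Brownian off-diagonals scaled by $\lambda \in [0,1]$;
* **martins_hansen** — correlation $\exp(-\alpha d_{ij})$ in patristic
  distance, the OU-derived structure;
* **grafen** — Brownian rule on branch lengths derived from node heights
  proportional to descendant tip counts (raised to power $\rho$), usable
  for taxonomy trees without measured lengths;
* **identity** — the naive star phylogeny.

Numerical choices: $V$ receives a diagonal jitter of
$10^{-10}\,\mathrm{tr}(V)/n$ and is factorized by Cholesky decomposition
(never inverted explicitly). Trees lacking branch lengths get unit lengths
substituted, with a message — mirroring the common practice of re-running
analyses with branch length estimates removed.

The slope p-value is a likelihood-ratio statistic against the
intercept-only model with the same covariance structure, referred to
$\chi^2_1$. When $\lambda$ or $\alpha$ is estimated, it is re-profiled
under *both* the null and the alternative model (an honest profile LRT):
fixing the null's parameter at the alternative's estimate inflates test
size, and the chosen convention is validated by the null-calibration tests.
$\lambda$ is profiled on $[0,1]$; $\alpha$ on $[10^{-4}/T,\,50/T]$ with $T$
the maximum patristic distance, the range in which the correlation spans
essentially-Brownian to essentially-independent. ML (not REML) likelihoods
are used throughout; the choice is validated by the same calibration.

`fit_poisson_gee()` is the Poisson phylogenetic GLM: log-link regression
fitted by generalized estimating equations with working correlation
$R = D^{-1/2} V D^{-1/2}$ from the Brownian $V$. The update iterates
$\beta \leftarrow \beta + (\Delta' W^{-1} \Delta)^{-1} \Delta' W^{-1}
(y - \mu)$ with $\mu = e^{X\beta}$, $\Delta = A X$,
$W = A^{1/2} R A^{1/2}$, $A = \mathrm{diag}(\mu)$, to relative tolerance
$10^{-8}$ or 100 iterations; with $R = I$ this is exactly classic Poisson
IRLS, which the tests verify against `glm()`. The slope test is a Wald z
with model-based variance scaled by a dispersion $\hat\varphi$ taken from
the *generalized* Pearson statistic — residuals whitened by $W$ — rather
than the raw Pearson sum: with strongly correlated residuals the raw sum
absorbs the shared component into the intercept and understates the
variance, which simulation showed inflates the null rejection rate well
above nominal; the whitened form restores calibration and reduces to the
raw sum when $R = I$. A normal reference is used for the z statistic (no
phylogenetic degrees-of-freedom correction); the convention is judged by
simulated size, not by its asymptotic pedigree.

The predictor is coded 0/1 without standardization, so the PLM slope reads
directly as the average inferred change in the response when an organism
has the property.

`estimate_pagel_lambda()` profiles $\lambda$ under an intercept-only model,
reporting the maximum-likelihood signal strength of a single trait.

## Nonparametric sibling contrasts

`propagate_states()` labels internal nodes recursively from the tips over
*immediate children*: predictor 1 only if every child is 1, response equal
to the mean of the children. (An alternative reading — averaging over all
descendant tips — changes the weighting on unbalanced trees; the
children-mean is implemented because the labelling is defined recursively,
and the choice is recorded here deliberately.) Every internal node whose
children disagree in the predictor contributes one contrast
$Y^{+} - Y^{-}$ (means within each predictor value across polytomies), so
contrasts come from disjoint, phylogenetically separate clades. The
contrast list feeds either

* an exact Wilcoxon signed-rank test — zeros dropped, average ranks for
  ties, the exact null distribution computed by convolution over all sign
  assignments for up to 25 nonzero differences (the grid is doubled so
  half-integer ranks stay exact), a tie- and continuity-corrected normal
  approximation beyond; or
* a bootstrap percentile test of the mean difference, two-sided by
  doubling the smaller tail (matching the Wilcoxon convention; the
  one-sided alternative is not used), with an add-one correction so the
  smallest reportable p is about $2/B$.

## Clade blocking

Deep-branching clades can carry different response baselines for reasons
unrelated to the predictor. Two complementary devices are provided:
`srh_test()`, the Scheirer–Ray–Hare two-way rank test with the feature as
group and the child-of-root clade (`assign_clades()`) as block — computed
from a sequential two-way ANOVA on average ranks with
$H = SS_{\mathrm{effect}} / (SS_{\mathrm{total}}/(N-1))$ against
$\chi^2$; with a single block it reduces exactly to Kruskal–Wallis, which
is also exposed directly for single-clade features. No additional tie
adjustment is applied beyond using the empirical $SS_{\mathrm{total}}$ of
the average ranks. And `clade_normalize()`, which subtracts each clade's
mean response before a subsequent PLM fit.

## The benchmark harness

`benchmark_grid()` fixes the study design: by default the 256-tip balanced
tree, `r` calibrated to 8 innovations, $c \in \{0, m/2, m\}$,
$p \in \{0, 0.2, 0.4, 0.6, 0.8\}$, reversible dynamics, 100 replicates per
cell at $\alpha = 0.05$. Balanced-tree cells reuse one fixed tree;
function-valued tree specifications draw a fresh (e.g. birth–death) tree
per replicate. Per-cell seeds are hashed from the base seed and the grid
coordinates, so any cell is reproducible in isolation. Replicates where a
method fails — most commonly a constant observed predictor after heavy
occlusion — are recorded as non-converged and excluded from the rate
denominator, with the exclusion counted and visible, a conservative and
explicit convention. `summarize_rates()` reports the fraction of converged
replicates with $p < \alpha$ per cell: a false-positive rate where $c = 0$,
a true-positive rate otherwise.

The shipped tests run reduced but honest versions of the headline studies:
null calibration with 300 replicates on the 128-tip tree, occlusion power
with 100 replicates on the 256-tip tree, nonparametric comparisons with
200 replicates, and 20-seed screening studies — sizes chosen so the whole
suite re-runs in minutes while keeping binomial error small relative to
the margins being asserted.

## Screening trait tables

`screen_features()` sweeps every observed value of every feature as the
"positive" case and applies, in order: binarization with missing values
kept *undefined* (never coded as negatives); restriction to the subtree
rooted at the MRCA of the positive species — the guard against
clade-definition artifacts, where a trait defined only within one clade
(palms among plants, say) would otherwise "correlate" with that clade's
baseline; an influence filter; PLM (Brownian PGLS) and Poisson PGLM fits;
and Bonferroni-coded significance profiles (`**` robust to correction,
`*` nominal only, `-` neither, joined as `plm/pglm`).

The influence filter guards against results that hinge on a handful of
observations: if either predictor class has at most two distinct response
values, every distinct value in that class must have at least 6
observations. Two readings of the rule were possible; the implemented one
applies the count requirement within the triggering class (the reading
consistent with the motivating artifact, where a single low count in the
positive class drives a spurious hit), with the both-classes variant
available behind a flag. A class with a single constant response value also
triggers the rule, being at least as degenerate as a two-valued one. The
Bonferroni denominator is the number of hypotheses actually fitted after
filtering (logged on the result), overridable when a fixed denominator is
preferred.

Species names are reconciled across table, response and tree by exact match
after whitespace and case normalization; fuzzy matching is out of scope.

## Semi-automated curation

`scan_articles()` searches a MediaWiki-style XML dump for a regular
expression and reports each occurrence with a ±300-character context
window (configurable). Candidate terms are taken from wiki link markup
within the snippet, falling back to capitalized multi-word spans — a
stated heuristic, since "interesting text" has no canonical definition.
`render_review_html()` emits a self-contained review page (checkboxes per
term, manual entry, a compile button producing one comma-separated list);
the selection step is manual by design — the tool accelerates curation, it
does not replace judgement. `parse_selection_list()` reads the compiled
list back. No network access and no language-model extraction are
involved.

## Known limitations

* The GLS p-values assume the $\chi^2_1$ reference for the LRT; residuals
  from the loss process are not Gaussian, and the justification is the
  simulated calibration, not theory.
* Power at heavy occlusion is real but modest: with half of the positive
  observations hidden, the reference effect ($c = m$, 8 innovations,
  256 tips) is detected in slightly under half of replicates — the
  benchmark exists precisely to make that number visible before
  interpreting a screen.
* The GEE working correlation is always Brownian-derived; mis-specification
  costs efficiency, though the sandwich-free scaled variance keeps size
  approximately nominal in the shipped settings.
* Clade blocking uses only the first branching below the root; finer
  hierarchical structure (random-slope mixed models and the like) is out
  of scope.
* The birth–death simulator conditions on reaching a tip count and prunes
  extinct lineages; it does not implement time-calibrated or serially
  sampled trees.
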