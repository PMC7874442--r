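---
title: "Modelling pangenome gene turnover from genome intersections"
author: "pangloss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pangenome gene turnover from genome intersections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangloss)
```

## The problem

Closely related bacteria and archaea differ substantially in gene content:
a cluster of N genomes carries a pangenome whose gene commonality
distribution $g_k$ (the number of gene families present in exactly k of
the N genomes) is universally U-shaped — a cloud of rare genes on the
left, a conserved core on the right. `pangloss` implements a framework in
which the turnover rates that shape this distribution are inferred not
from $g_k$ itself but from *genome intersections*: $I_k$, the number of
genes shared by a chosen set of k genomes, and its uniform average
$\langle I \rangle_k$ over all $\binom{N}{k}$ subsets.

The model pictures gene content evolving by stochastic gain and loss
along the cluster's phylogeny. Under two idealising assumptions — genes
are acquired from an effectively infinite external pool (every gain is a
brand-new family), and gain balances loss so genome size is constant
(together, "IGP-CGS") — the intersection of a genome set spanning total
tree distance D decays exponentially per gene class:

$$ I(D) = \sum_i x_i e^{-\lambda_i D}, $$

where $x_i$ is the class size and $\lambda_i = P^-_i / x_i$ its per-gene
loss rate. Averaging over the distribution $P(D_k)$ of spanning-subtree
distances for each k gives the model curve $\langle I \rangle_k$, and an
exact inclusion–exclusion identity converts intersections to
commonality:

$$ g_k = \sum_{n=k}^{N} (-1)^{n-k} \binom{n}{k} \binom{N}{n}
   \langle I \rangle_n . $$

This identity is purely combinatorial — it holds for any binary
presence/absence matrix, with no model content — and it is the package's
workhorse: fits performed on one statistic can be judged on another. The
framework's central diagnostic is an asymmetry: IGP-CGS fits to
$\langle I \rangle_k$ match intersections and the core well but
*overestimate singletons*, whereas direct fits to $g_k$ match the
U-shape but underestimate turnover rates and *overestimate the core*.
Either a finite gene pool (families can be regained) or net gene loss
(genomes shrink) removes the singleton excess, and the package's
simulator produces both regimes so the diagnostic can be studied under
controlled conditions.

## Exact transforms and numerical hygiene

The coefficients $\binom{n}{k}\binom{N}{n}$ reach $\sim 3\times 10^9$ at
N = 20 and the series alternates, so naive floating-point evaluation can
destroy the small $g_k$ by catastrophic cancellation. The package
therefore keeps two paths:

* **Empirical path (exact).** For data, $\langle I \rangle_n$ is a
  rational number $S_n / \binom{N}{n}$ whose numerator
  $S_n = \sum_m g_m \binom{m}{n}$ is an integer. The transform collapses
  to $g_k = \sum_n (-1)^{n-k} \binom{n}{k} S_n$, evaluated in exact
  integer arithmetic (doubles are exact below $2^{53}$; at N = 20 with
  $\le 10^5$ families every term stays below $\sim 10^{15}$). The round
  trip intersections → commonality → intersections is an identity, and
  the test suite asserts it bit-exactly.
* **Model path (compensated).** Model-predicted profiles are floats, so
  the alternating sum uses Kahan-compensated summation; the residual
  error is of order $N \cdot \mathrm{ulp}(\max |{\rm term}|)$, i.e.
  $\lesssim 10^{-2}$ genes at N = 20 for genome-sized inputs, negligible
  against the $g_k$ being predicted. Materially negative $g_k$ beyond
  tolerance triggers a warning, since no consistent matrix can produce
  them.

The fixation probability $F(S) = S/(1 - e^{-S})$ has a removable
singularity at S = 0 and is evaluated by its series
$1 + S/2 + S^2/12$ for $|S| < 10^{-5}$. The selection coefficient is
carried for completeness in the rate decomposition
$P^+ = \alpha F(S)$, $P^- = \beta F(-S)$; the framework infers loss
rates only and makes no attempt to estimate S, $\alpha$ or $\beta$ from
data.

## Tree machinery

$D_k$ for a genome subset is the total branch length of the tree pruned
to that subset, with the stem above the subset's most recent common
ancestor removed — a single genome spans distance 0, which is what makes
$\langle I \rangle_1$ equal the mean genome size. Exact distributions
$P(D_k)$ are built by a full $2^N$ sweep using per-edge leaf bitsets
(an edge contributes to a subset's spanning length iff the subset
intersects the clade below the edge without being contained in it),
capped at N = 20 ($\sim 10^6$ subsets); larger trees fall back to seeded
uniform subset sampling. Two independent oracles guard this machinery in
the tests: explicit prune-and-sum on every subset of small trees, and
the closed form for the mean,
$\sum_e \ell_e [1 - (\binom{a_e}{k} + \binom{N-a_e}{k})/\binom{N}{k}]$
with $a_e$ leaves below edge e.

Branch lengths of closely related genomes are systematically
underestimated where homologous recombination is frequent; the package
exposes a user-supplied multiplicative rescaling (default 1) rather than
deriving a correction. Dataset-selection checks report the maximum
pairwise leaf distance against a 0.1 substitutions/site threshold; the
"more than two typical pairwise distances" criterion has no standard
operational definition, so the number of modes of the pairwise-distance
density is reported as an advisory metric only, never as a hard filter.

## The simulator

`simulate_pangenome()` runs an exact Gillespie scheme along the tree:
waiting times $\tau = -\ln(r)/a_0$ with $a_0$ the total event rate, each
event choosing a class and gain-versus-loss in proportion to its rate; a
loss removes a uniformly chosen resident gene of the class; the state is
copied to each child at internal nodes. Three regimes:

* **IGP-CGS** — gains mint globally unique new families (the new-family
  counter is shared across lineages by reference, so "new" means new to
  the whole simulated clade); $P^+_i = P^-_i$ holds the size constant on
  average.
* **FGP-CGS** — each class draws gains from a finite pool of $L_i$
  families. The default draw is uniform over pool members currently
  absent from the genome, so every gain adds exactly one gene and the
  constant-size balance stays exact; a "draw-any, no-op if present" mode
  is available as a config-visible alternative.
* **IGP-VGS** — gain and loss need not balance. The gain rate is held
  constant along a branch (acquisition pressure comes from outside the
  genome), while the loss rate tracks the class's current content,
  $P^-_i(t) = \lambda_i n_i(t)$ with $\lambda_i$ fixed at
  $P^-_i(0)/x_i$, since deletion attempts scale with the number of
  resident genes. This is a deliberate design choice: holding the
  *total* loss rate constant while a class shrinks drives the fast class
  extinct within a fraction of a branch at realistic parameter ratios,
  leaving effectively one-class data, whereas size-proportional loss
  relaxes each class towards the equilibrium
  $x_i^{eq} = (P^+_i/P^-_i)\, x_i$ and preserves the two-exponential
  structure that makes the regime comparable to real clusters. Under
  constant genome size the two conventions coincide.

All randomness flows from one stream seeded per simulation and consumed
in a fixed preorder edge traversal, so a (tree, parameters, seed) triple
reproduces its matrix bit-for-bit. R's base generator has no cheap
independent substreams, so per-branch streams were not used; determinism
is guaranteed within this traversal rather than across hypothetical
alternative traversals.

Classes evolve independently and the unit of evolution is a single gene:
no multi-gene transfer events, no duplication or de novo birth, no
within-population polymorphism, no fluctuating selection.

## Study conditions emulated by the generator

The empirical setting the synthetic data emulates is a cluster of up to
20 closely related prokaryotic genomes. The defaults are fixed once:

* **Tree**: a 20-leaf Yule topology rescaled to total branch length 7.
  The anchor is the framework's own demonstration regime (x = 4500,
  $\lambda = 1/3$), in which the simulated cluster retains a visible
  core of hundreds of genes; that requires total spanned distance of
  order 5–8. Smaller examples use 8-leaf Yule trees.
* **Reference parameters**: two classes with $x = (3730, 749)$ and
  $\lambda = (0.04, 1.98)$ — the inferred values for the *E. coli*-like
  cluster, with the fast class turning over ~50× faster and holding
  ~17% of the genes. The three-class variant uses sizes
  2250/1500/750 with $\lambda$ = 0.005/0.1/2.
* **Regime knobs**: finite pools at 3× (slow) and 9× (fast) the class
  sizes; varying-size gain:loss ratios 1.26 (slow) and 0.16 (fast).

What the synthetic data does *not* contain: orthology-inference noise,
annotation artefacts, gene-length or functional-category structure,
lineage-specific rate variation, and correlated multi-gene events. A
passing suite therefore demonstrates the internal consistency of the
estimator and the reality of the core/singleton asymmetry under the
model's own generative assumptions — not that real clusters satisfy
those assumptions.

## Fitting

All three statistics ($\langle I \rangle_k$, $g_k$, $J_k$) are linear in
the class sizes $x_i$, so the least-squares fit profiles the sizes out:
for each candidate decay vector $\lambda$, the sizes solve a
non-negative least-squares problem, and a Nelder–Mead search (golden
section for one class) runs over $\log \lambda$ only. Multistart uses a
seeded Latin hypercube of 32 points over
$\lambda \in [10^{-4}, 10^2]$; the three-class fit is additionally
warm-started from the two-class optimum, which enforces nested-model
monotonicity of the achievable $R^2$. Multi-exponential fitting is
notoriously multimodal, hence the generous start set.

The default objective is ordinary least squares on the linear scale over
all k with no weighting and no constraint tying $\sum_i x_i$ to the
observed mean genome size (the k = 1 point enters the loss like any
other); a log-scale objective is available by configuration and refines
the full parameter vector from the linear-scale solution. During the
search the exact $P(D_k)$ is compressed by moment-matched binning to at
most 256 support points per k (each bin keeps its total weight and
weighted mean D); the relative error this induces in
$\langle e^{-\lambda D} \rangle$ is second order,
$\sim (\lambda \Delta D)^2/8$ per bin, far below simulation noise. Final
reported curves and $R^2$ are always evaluated on the uncompressed
distributions.

Goodness of fit is $R^2 = 1 - SS_{res}/SS_{tot}$ with the adjusted
variant $1 - (1 - R^2)(n-1)/(n-p-1)$ computed at n = N points per
statistic and p = 2 × (number of classes). Model selection between two
and three classes prefers the higher adjusted $R^2$, with a
fewer-parameters tie-break, and flags three-class solutions as
degenerate when the smallest class holds < 1% of the genes or two decay
rates sit within a ratio of 0.9–1.1 (both thresholds configurable) —
the situations in which a nominal three-class fit has collapsed to two
classes.

## A worked example

```{r example, eval = FALSE}
tr <- generate_random_tree(20, seed = 1)
tr <- rescale_tree(tr, 7 / sum(tr$edge.length))
dd <- distance_distributions(tr)

sp <- sim_params(x = c(3730L, 749L), loss = c(3730, 749) * c(0.04, 1.98))
pm <- simulate_pangenome(tr, sp, seed = 101)

fit <- fit_model(pm, dd, fit_config("meanI", n_classes = 2))
fit$classes     # recovered sizes and decay rates
fit$r_squared   # ~0.9999 at these conditions
fit$errors      # core / singleton diagnostic errors
```

## Problem sizes and runtime choices

The shipped experiments use 20-leaf trees (exact $P(D_k)$ enumeration,
$2^{20}$ subsets, a second or two), genomes of ~4.5k genes, 200
replicates for simulator-versus-theory comparisons, and 3–5 seeds for
recovery and asymmetry experiments; a full two-class fit takes a few
seconds. These sizes were chosen so the complete analysis reruns
comfortably on a laptop while keeping Monte-Carlo standard errors small
compared with the tolerances being tested.

## Known limitations

* The decay law for $I_k(D)$ is taken as given; its derivation (and the
  separation of selection from raw deletion rates) is outside the
  package's scope, as is any estimation of S, $\alpha$, $\beta$.
* Fits are point estimates; no confidence intervals or likelihood-based
  uncertainty is provided.
* Exact subset enumeration is capped at 20 genomes; beyond that,
  sampled distance distributions introduce (controlled, seeded) noise.
* The finite-pool "absent-only" gain rule is one of several defensible
  readings of a finite gene pool; the alternative draw-any rule is
  provided but the two converge only for pools well above genome size.
* Empirical mean intersections weight all $\binom{N}{k}$ subsets
  uniformly; the tree enters only the model side through $P(D_k)$.
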