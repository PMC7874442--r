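# pangloss

Gene gain/loss dynamics of prokaryotic pangenomes: exact
intersection–commonality transforms, Gillespie simulation of gene content
evolution along phylogenies, and multi-class exponential-decay fitting of
gene turnover rates.

## What it is for

For a cluster of N closely related bacterial or archaeal genomes, the gene
commonality distribution g_k — the number of gene families present in
exactly k genomes — is universally U-shaped: a cloud of rare genes, a
shell, and a conserved core. `pangloss` is for researchers who want to
infer the *gene turnover rates* behind that shape. Instead of fitting the
U-shape directly, the framework works with genome intersections: under an
infinite external gene pool and constant genome size (IGP-CGS), the number
of genes shared by a genome set spanning total tree distance D decays as

    I(D) = Σ_i x_i · exp(−λ_i · D)

with class sizes x_i and per-gene loss rates λ_i (λ = P⁻/x). Averaging
over the spanning-distance distribution P(D_k) of all C(N,k) subsets gives
the model's mean intersection ⟨I⟩_k, and the exact inclusion–exclusion
identity

    g_k = Σ_{n=k..N} (−1)^(n−k) · C(n,k) · C(N,n) · ⟨I⟩_n

links intersections to commonality with no model assumptions at all. The
package provides:

* exact, integer-arithmetic transforms between ⟨I⟩_k, g_k and the
  cumulative J_k (and their inverses), safe against the catastrophic
  cancellation the alternating series invites at N = 20;
* spanning-subtree distance machinery on `ape` trees (exact 2^N
  enumeration up to 20 leaves, seeded sampling beyond);
* a Gillespie simulator of gene content evolution along a tree with 1–3
  gene classes under IGP-CGS, finite-pool (FGP-CGS) and varying-genome-size
  (IGP-VGS) regimes;
* least-squares fitting of (x_i, λ_i) to any of the three statistics, with
  variable projection, seeded multistart, adjusted-R² model selection and
  degeneracy detection;
* the core/singleton diagnostic: fits to intersections overestimate
  singletons while fits to commonality overestimate the core whenever the
  data violate the infinite-pool or constant-size assumptions.

## A worked example

```r
library(pangloss)

# a 20-leaf cluster tree (Yule topology, total branch length 7)
tr <- generate_random_tree(20, seed = 1)
tr <- rescale_tree(tr, 7 / sum(tr$edge.length))
dd <- distance_distributions(tr)          # exact P(D_k), all 2^20 subsets

# simulate two gene classes at the E. coli-like reference parameters
sp <- sim_params(x = c(3730L, 749L), loss = c(3730, 749) * c(0.04, 1.98))
pm <- simulate_pangenome(tr, sp, seed = 101)

# fit a two-class model to the mean intersections
fit <- fit_model(pm, dd, fit_config("meanI", n_classes = 2))
print(fit)
```

```
Gene turnover model fit [meanI, 2 class(es)]
Gene turnover classes (2):
 label      size      decay
  slow 3734.6015 0.03832001
  fast  731.7776 2.00002831
R^2 = 0.999999  adj R^2 = 0.999998
core error = -0.000  singleton error = +0.003
```

The fitted `size`/`decay` columns recover the simulation's true classes
(3730 genes at λ = 0.04; 749 genes at λ = 1.98) to within a few percent
from a single simulated cluster; `core error` and `singleton error` are
the signed relative errors (model − data)/data on g_N and g_1, the two
ends of the U-shaped distribution. Swapping `"meanI"` for
`"commonality"` or `"cumulative"` fits g_k or J_k instead; simulating
with `regime = "fgp-cgs"` (finite gene pools) or `regime = "igp-vgs"`
(net gene loss) reproduces the characteristic diagnostic asymmetry
between those fits.

The toy three-genome example {a,b,c}/{b,c,d}/{c,d,e} runs through the
same machinery exactly: ⟨I⟩ = (3, 5/3, 1), g = (2, 2, 1), J = (2, 4, 5).

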