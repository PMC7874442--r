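# Shared fixtures and independent brute-force oracles.

toy_newick <- "((A:1,B:1):1,C:2);"
toy_tree <- function() read_tree(toy_newick)

# three genomes {a,b,c}, {b,c,d}, {c,d,e}
toy_matrix <- function() {
  m <- matrix(c(1, 0, 0,
                1, 1, 0,
                1, 1, 1,
                0, 1, 1,
                0, 0, 1),
              nrow = 5, byrow = TRUE,
              dimnames = list(letters[1:5], c("G1", "G2", "G3")))
  pangenome_matrix(m)
}

# 20-leaf Yule topology rescaled to total length 7: the synthetic stand-in
# for a closely related genome cluster used in the recovery experiments
study_tree <- function(seed) {
  tr <- generate_random_tree(20, branching_rate = 1, seed = seed)
  rescale_tree(tr, 7 / sum(tr$edge.length))
}

# reference two-class parameter set (E. coli-like cluster)
ref_sizes <- c(3730, 749)
ref_decay <- c(0.04, 1.98)

# oracle: spanning length by pruning the tree to the subset and summing
# the remaining branch lengths (ape handles stem suppression)
oracle_spanning <- function(tree, subset) {
  if (length(subset) < 2L) return(0)
  sum(ape::keep.tip(tree, subset)$edge.length)
}

# oracle: mean intersection by direct enumeration of all k-subsets
oracle_mean_intersections <- function(pm) {
  inc <- pm$incidence
  N <- ncol(inc)
  vapply(seq_len(N), function(k) {
    subs <- utils::combn(N, k)
    mean(apply(subs, 2, function(cols)
      sum(rowSums(inc[, cols, drop = FALSE]) == k)))
  }, numeric(1))
}

# oracle: closed-form mean spanning distance of a uniform k-subset,
# summing each edge's probability of being on the spanning subtree
oracle_mean_distance <- function(tree, k) {
  N <- length(tree$tip.label)
  below <- pangloss:::edge_leaf_masks(tree)
  a <- vapply(below$mask, function(m)
    sum(bitwAnd(as.integer(m), as.integer(2^(seq_len(N) - 1))) != 0),
    numeric(1))
  sum(below$length *
        (1 - (choose(a, k) + choose(N - a, k)) / choose(N, k)))
}

random_binary_matrix <- function(N, n_fam, seed) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(N * n_fam, 1, runif(1, 0.2, 0.8)), n_fam, N)
    m[rowSums(m) == 0, sample.int(N, 1)] <- 1
  })
  colnames(m) <- paste0("g", seq_len(N))
  pangenome_matrix(m)
}
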