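test_that("Newick reading validates structure and round-trips", {
  tr <- toy_tree()
  expect_equal(length(tr$tip.label), 3)
  expect_equal(sum(tr$edge.length), 5)
  expect_error(read_tree("((A:1,A:1):1,C:2);"), "duplicate")
  expect_error(read_tree("((A:1,B):1,C:2);"), "length")
  expect_error(read_tree("(('A':1,B:1):1,C:2);"), "quoted")
  rt <- read_tree(write_tree(tr))
  expect_equal(sort(rt$tip.label), sort(tr$tip.label))
  expect_equal(sum(rt$edge.length), 5)
})

test_that("rescaling multiplies branch lengths and spanning distances", {
  tr <- toy_tree()
  expect_equal(rescale_tree(tr, 1)$edge.length, tr$edge.length)
  tr2 <- rescale_tree(tr, 2)
  expect_equal(sum(tr2$edge.length), 10)
  expect_equal(spanning_length(tr2, c("A", "C")),
               2 * spanning_length(tr, c("A", "C")))
  expect_error(rescale_tree(tr, 0), "positive")
  expect_error(rescale_tree(tr, -3), "positive")
})

test_that("spanning length prunes to the subset and drops the stem", {
  tr <- toy_tree()
  expect_equal(spanning_length(tr, "A"), 0)
  expect_equal(spanning_length(tr, c("A", "C")), 4)
  expect_equal(spanning_length(tr, c("A", "B")), 2)
  expect_equal(spanning_length(tr, c("A", "B", "C")), 5)
  expect_error(spanning_length(tr, c("A", "Z")), "unknown leaf")
})

test_that("per-edge spanning formula equals prune-and-sum on all subsets", {
  for (seed in c(2, 9)) {
    n <- c(5, 8)[match(seed, c(2, 9))]
    tr <- generate_random_tree(n, seed = seed)
    tips <- tr$tip.label
    for (s in seq_len(2^n - 1)) {
      subset <- tips[bitwAnd(s, 2^(seq_len(n) - 1)) != 0]
      expect_equal(spanning_length(tr, subset),
                   oracle_spanning(tr, subset), tolerance = 1e-12)
    }
  }
})

test_that("exact distance distributions enumerate all subsets per k", {
  tr <- toy_tree()
  dd <- distance_distributions(tr)
  expect_equal(sort(dd$levels[[2]]$D), c(2, 4, 4))
  expect_equal(dd$levels[[2]]$weight, rep(1 / 3, 3))
  expect_equal(dd$levels[[3]]$D, 5)
  expect_equal(dd$levels[[1]]$D, rep(0, 3))
  # per-k weights always sum to 1
  for (k in 1:3) expect_equal(sum(dd$levels[[k]]$weight), 1)
})

test_that("exact distribution means match the closed per-edge form", {
  for (seed in c(1, 4)) {
    tr <- generate_random_tree(7, seed = seed)
    dd <- distance_distributions(tr)
    means <- vapply(dd$levels, function(l) sum(l$D * l$weight), numeric(1))
    oracle <- vapply(1:7, function(k) oracle_mean_distance(tr, k),
                     numeric(1))
    expect_equal(means, oracle, tolerance = 1e-12)
    # stochastic dominance: mean spanning distance grows with k
    expect_true(all(diff(means) > 0))
  }
})

test_that("sampled distance distributions converge to the exact ones", {
  tr <- generate_random_tree(10, seed = 3)
  exact <- distance_distributions(tr)
  samp <- distance_distributions(tr, mode = "sample",
                                 sample_size = 4000L, seed = 7)
  for (k in c(2, 5, 9)) {
    m_exact <- sum(exact$levels[[k]]$D * exact$levels[[k]]$weight)
    d <- samp$levels[[k]]$D
    se <- stats::sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - m_exact), 3 * se + 1e-12)
  }
  expect_error(distance_distributions(tr, max_exact_n = 8), "sample")
})

test_that("random Yule trees are seeded and scale with branching rate", {
  t1 <- generate_random_tree(8, seed = 1)
  t2 <- generate_random_tree(8, seed = 1)
  expect_identical(write_tree(t1), write_tree(t2))
  expect_equal(length(t1$tip.label), 8)
  expect_true(all(t1$edge.length > 0))
  expect_error(generate_random_tree(1), ">= 2")
  # mean pairwise distance scales as 1/branching_rate
  mpd <- function(rate) mean(vapply(1:60, function(s) {
    tr <- generate_random_tree(6, branching_rate = rate, seed = 1000 + s)
    d <- ape::cophenetic.phylo(tr)
    mean(d[upper.tri(d)])
  }, numeric(1)))
  expect_equal(mpd(1) / mpd(2), 2, tolerance = 0.25)
})

test_that("leaf subsampling preserves spanning distances of kept leaves", {
  tr <- generate_random_tree(10, seed = 5)
  expect_identical(subsample_leaves(tr, max_n = 20), tr)
  big <- generate_random_tree(25, seed = 6)
  sub <- subsample_leaves(big, max_n = 20, seed = 2)
  expect_equal(length(sub$tip.label), 20)
  expect_true(all(sub$tip.label %in% big$tip.label))
  pick <- sub$tip.label[c(1, 5, 11)]
  expect_equal(spanning_length(sub, pick), spanning_length(big, pick),
               tolerance = 1e-12)
})

test_that("cluster selection criteria flag shallow trees", {
  rep_toy <- check_cluster_criteria(toy_tree())
  expect_true(rep_toy$pass)
  expect_equal(rep_toy$max_pairwise_distance, 4)
  star <- read_tree("(A:0.01,B:0.01,C:0.01,D:0.01);")
  rep_star <- check_cluster_criteria(star)
  expect_false(rep_star$pass)
  expect_equal(rep_star$max_pairwise_distance, 0.02)
  two <- read_tree("(A:0.3,B:0.5);")
  expect_equal(check_cluster_criteria(two)$max_pairwise_distance, 0.8)
})

test_that("tree-averaged model curve reduces correctly at k = 1", {
  tr <- toy_tree()
  dd <- distance_distributions(tr)
  cls <- gene_classes(100, 0.1)
  mc <- mean_intersection_curve(cls, dd)
  expect_equal(mc$values[1], 100)
  expect_equal(mc$values[2], 100 * (exp(-0.2) + 2 * exp(-0.4)) / 3,
               tolerance = 1e-12)
  expect_equal(mc$values[3], 100 * exp(-0.5), tolerance = 1e-12)
  # no loss: flat curve at the total genome size
  flat <- mean_intersection_curve(gene_classes(c(60, 40), c(0, 0)), dd)
  expect_equal(flat$values, rep(100, 3))
  # non-increasing in k
  two <- mean_intersection_curve(gene_classes(c(80, 20), c(0.05, 1)), dd)
  expect_true(all(diff(two$values) <= 0))
})
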