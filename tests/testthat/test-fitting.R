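# small tree + exact distance distributions shared across fitting tests
fit_fixture <- local({
  tr <- generate_random_tree(8, branching_rate = 2, seed = 21)
  dd <- distance_distributions(tr)
  list(tree = tr, dists = dd)
})

test_that("goodness of fit matches the R-squared definitions", {
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 3), 1)$r_squared, 1)
  obs <- c(4, 7, 1, 8)
  g0 <- goodness_of_fit(rep(mean(obs), 4), obs, 1)
  expect_equal(g0$r_squared, 0)
  g <- goodness_of_fit(c(1, 2, 4), c(1, 2, 3), 1)
  expect_equal(g$r_squared, 0.5)
  expect_equal(g$adj_r_squared, 0.0)
  expect_error(goodness_of_fit(c(1, 2), c(3, 3), 1), "undefined")
  expect_error(goodness_of_fit(1:3, 1:4, 1), "mismatch")
})

test_that("noise-free single-class curves are recovered essentially exactly", {
  truth <- gene_classes(4500, 1 / 3)
  prof <- mean_intersection_curve(truth, fit_fixture$dists)
  f <- fit_model(prof, fit_fixture$dists, fit_config(n_classes = 1))
  expect_equal(f$classes$size, 4500, tolerance = 1e-6)
  expect_equal(f$classes$decay, 1 / 3, tolerance = 1e-6)
  expect_gt(f$r_squared, 1 - 1e-12)
})

test_that("noise-free two-class curves are recovered to high precision", {
  truth <- gene_classes(ref_sizes, ref_decay)
  prof <- mean_intersection_curve(truth, fit_fixture$dists)
  f <- fit_model(prof, fit_fixture$dists,
                 fit_config(n_classes = 2, seed = 3))
  expect_equal(f$classes$size, gene_classes(ref_sizes, ref_decay)$size,
               tolerance = 1e-4)
  expect_equal(f$classes$decay, gene_classes(ref_sizes, ref_decay)$decay,
               tolerance = 1e-4)
  expect_gt(f$r_squared, 1 - 1e-9)
})

test_that("all three statistics can serve as the fitting target", {
  truth <- gene_classes(c(800, 200), c(0.05, 1.2))
  pred <- predict_statistics(truth, fit_fixture$dists)
  for (stat in c("meanI", "commonality", "cumulative")) {
    obs <- switch(stat, meanI = pred$meanI, commonality = pred$g,
                  cumulative = pred$g)  # J derived from g internally
    f <- fit_model(obs, fit_fixture$dists,
                   fit_config(stat, n_classes = 2, seed = 2))
    expect_gt(f$r_squared, 0.999)
    expect_equal(sum(f$classes$size), 1000, tolerance = 0.05)
  }
})

test_that("model curves chain through the exact transform", {
  # 4-leaf star with equal tips: D_k = k * t for k >= 2
  star <- read_tree("(A:0.5,B:0.5,C:0.5,D:0.5);")
  dd <- distance_distributions(star)
  cls <- gene_classes(1000, 0.4)
  pred <- predict_statistics(cls, dd)
  expect_equal(pred$meanI$values,
               c(1000, 1000 * exp(-0.4 * c(2, 3, 4) * 0.5)),
               tolerance = 1e-12)
  # independent alternating-sum evaluation of the commonality
  I <- pred$meanI$values
  g_oracle <- vapply(1:4, function(k)
    sum(vapply(k:4, function(n)
      (-1)^(n - k) * choose(n, k) * choose(4, n) * I[n], numeric(1))),
    numeric(1))
  expect_equal(pred$g$counts, g_oracle, tolerance = 1e-9)
  expect_equal(pred$J, cumsum(g_oracle), tolerance = 1e-9)
  # no decay concentrates everything in the core
  frozen <- predict_statistics(gene_classes(500, 0), dd)
  expect_equal(frozen$g$counts, c(0, 0, 0, 500), tolerance = 1e-9)
})

test_that("nested models never fit worse and selection prefers parsimony", {
  truth3 <- gene_classes(c(2250, 1500, 750) / 10, c(0.005, 0.1, 2))
  prof <- mean_intersection_curve(truth3, fit_fixture$dists)
  f1 <- fit_model(prof, fit_fixture$dists, fit_config(n_classes = 1))
  cmp <- compare_class_counts(prof, fit_fixture$dists,
                              fit_config(seed = 4))
  expect_lt(cmp$fit2$r_squared, 1)
  expect_gte(cmp$fit2$r_squared, f1$r_squared)
  expect_gte(round(cmp$fit3$r_squared, 10), round(cmp$fit2$r_squared, 10))
  # two-class truth: the third class is redundant and flagged degenerate,
  # so selection falls back to two classes
  prof2 <- mean_intersection_curve(gene_classes(c(900, 100), c(0.02, 1)),
                                   fit_fixture$dists)
  cmp2 <- compare_class_counts(prof2, fit_fixture$dists,
                               fit_config(seed = 5))
  expect_equal(cmp2$selection$selected, "2-class")
})

test_that("degeneracy detection flags collapsed three-class solutions", {
  tiny <- gene_classes(c(1000, 0.5, 500), c(0.01, 0.5, 2))
  flags <- pangloss:::degeneracy_flags(tiny)
  expect_true(flags$tiny_class)
  near <- gene_classes(c(500, 500, 500), c(0.1, 0.105, 2))
  expect_true(pangloss:::degeneracy_flags(near)$near_equal_decay)
  clean <- gene_classes(c(500, 500), c(0.1, 2))
  expect_false(pangloss:::degeneracy_flags(clean)$degenerate)
})

test_that("log-scale objective refines without breaking recovery", {
  truth <- gene_classes(c(800, 200), c(0.05, 1.2))
  prof <- mean_intersection_curve(truth, fit_fixture$dists)
  f <- fit_model(prof, fit_fixture$dists,
                 fit_config(n_classes = 2, scale = "log", seed = 6))
  expect_gt(f$r_squared, 0.9999)
  expect_equal(sum(f$classes$size), 1000, tolerance = 0.02)
})
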