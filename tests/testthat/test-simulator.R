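test_that("simulation parameters enforce regime invariants", {
  p <- sim_params(x = c(100, 50), loss = c(10, 20))
  expect_equal(p$gain, p$loss)  # CGS forces P+ = P-
  expect_equal(p$labels, c("slow", "fast"))
  expect_error(sim_params(x = c(10, 10, 10, 10), loss = rep(1, 4)),
               "1 to 3")
  expect_error(sim_params(x = 10, loss = 1, regime = "fgp-cgs"),
               "pool size")
  expect_error(sim_params(x = 10, loss = 1, regime = "fgp-cgs", pool = 5),
               ">= initial")
  expect_error(sim_params(x = 10, loss = 1, gain = 2), "igp-vgs")
  vgs <- sim_params(x = 10, loss = 1, regime = "igp-vgs", gain = 3)
  expect_equal(vgs$gain, 3)
})

test_that("waiting times are exponential with rate a0", {
  expect_equal(draw_waiting_time(4, r = 1), 0)
  expect_equal(draw_waiting_time(4, r = exp(-2)), 0.5)
  expect_identical(draw_waiting_time(0), Inf)
  taus <- withr::with_seed(1, replicate(1e4, draw_waiting_time(2.5)))
  se <- stats::sd(taus) / sqrt(length(taus))
  expect_lt(abs(mean(taus) - 1 / 2.5), 3 * se)
})

test_that("branch evolution honours degenerate inputs", {
  params <- sim_params(x = 50, loss = 10)
  st <- pangloss:::new_state(params)
  expect_identical(pangloss:::evolve_branch(st, 0, params)$n, st$n)
  none <- sim_params(x = 50, loss = 0)
  expect_identical(pangloss:::evolve_branch(
    pangloss:::new_state(none), 5, none)$n, none$x)
  # loss on an empty class is a silent no-op
  empty <- sim_params(x = 0L, loss = 5)
  out <- withr::with_seed(1, pangloss:::evolve_branch(
    pangloss:::new_state(empty), 2, empty))
  expect_gte(out$n[1], 0)
})

test_that("gain-only growth is Poisson and overlap decays exponentially", {
  grow <- sim_params(x = 100L, loss = 0, regime = "igp-vgs", gain = 30)
  sizes <- withr::with_seed(2, replicate(150, {
    pangloss:::evolve_branch(pangloss:::new_state(grow), 1, grow)$n[1]
  }))
  se <- stats::sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - 130), 3 * se)
  # single-class CGS: expected overlap with the start x * exp(-lambda t)
  params <- sim_params(x = 500L, loss = 50)  # lambda = 0.1
  ov <- withr::with_seed(3, replicate(150, {
    st <- pangloss:::evolve_branch(pangloss:::new_state(params), 2, params)
    sum(st$genes[[1]][seq_len(st$n[1])] <= 500)
  }))
  se <- stats::sd(ov) / sqrt(length(ov))
  expect_lt(abs(mean(ov) - 500 * exp(-0.2)), 3 * se)
})

test_that("pangenome simulation is deterministic and respects zero rates", {
  tr <- generate_random_tree(6, seed = 4)
  p <- sim_params(x = c(60, 30), loss = c(3, 12))
  m1 <- simulate_pangenome(tr, p, seed = 9)
  m2 <- simulate_pangenome(tr, p, seed = 9)
  expect_identical(m1$incidence, m2$incidence)
  expect_identical(m1$classes, m2$classes)
  frozen <- simulate_pangenome(tr, sim_params(x = c(40, 10),
                                              loss = c(0, 0)), seed = 1)
  expect_identical(commonality_counts(frozen)$counts, c(0, 0, 0, 0, 0, 50))
})

test_that("finite pools bound the pangenome and converge to infinite pools", {
  tr <- generate_random_tree(6, seed = 8)
  pool <- c(30L, 40L)
  p <- sim_params(x = c(20, 20), loss = c(4, 10), regime = "fgp-cgs",
                  pool = pool)
  pm <- simulate_pangenome(tr, p, seed = 3)
  expect_lte(nrow(pm$incidence), sum(pool))
  expect_true(all(table(pm$classes)[c("slow", "fast")] <= pool |
                    is.na(table(pm$classes)[c("slow", "fast")])))
  # a huge pool behaves like the infinite-pool regime
  tr2 <- generate_random_tree(8, seed = 2)
  big <- sim_params(x = c(200, 100), loss = c(10, 40), regime = "fgp-cgs",
                    pool = c(20000L, 10000L))
  igp <- sim_params(x = c(200, 100), loss = c(10, 40))
  g_fgp <- rowMeans(sapply(1:10, function(s) commonality_counts(
    simulate_pangenome(tr2, big, seed = s))$counts))
  g_igp <- rowMeans(sapply(1:10, function(s) commonality_counts(
    simulate_pangenome(tr2, igp, seed = 100 + s))$counts))
  expect_lt(max(abs(g_fgp - g_igp)) / max(g_igp), 0.15)
})

test_that("net gene loss shrinks genomes along the tree", {
  tr <- generate_random_tree(8, seed = 5)
  p <- sim_params(x = 400L, loss = 40, regime = "igp-vgs", gain = 10)
  sizes <- sapply(1:12, function(s) {
    pm <- simulate_pangenome(tr, p, seed = s)
    mean(colSums(pm$incidence))
  })
  # sign test: every replicate's mean leaf genome is below the root size
  expect_true(all(sizes < 400))
})

test_that("random matrix fixture follows its occupancy law", {
  core <- random_matrix_fixture(5, 40, occupancy_law = 5, seed = 1)
  expect_identical(commonality_counts(core)$counts, c(0, 0, 0, 0, 40))
  single <- random_matrix_fixture(5, 40, occupancy_law = 1, seed = 1)
  expect_identical(commonality_counts(single)$counts, c(40, 0, 0, 0, 0))
  unif <- random_matrix_fixture(6, 1200, seed = 2)
  g <- commonality_counts(unif)$counts
  se <- sqrt(1200 * (1 / 6) * (5 / 6))
  expect_true(all(abs(g - 200) < 3 * se))
  expect_error(random_matrix_fixture(4, 10, occupancy_law = 9), "1..N")
})
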