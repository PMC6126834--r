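test_that("total LD score sums r2 within the window plus self-count", {
  v <- toy_variants(3, pos = c(1000, 11000, 21000))
  ld <- toy_ld(c("v1", "v1"), c("v2", "v3"), c(0.3, 0.2),
               c(1000, 1000), c(11000, 21000))
  s <- total_ld_score(v, ld, window_bp = 1e6)
  expect_equal(s, c(1.5, 1.3, 1.2))  # 1 + sum of r2 with partners

  # partner beyond the window contributes nothing
  far <- toy_ld("v1", "v3", 0.9, 1000, 2002000)
  s2 <- total_ld_score(toy_variants(3, pos = c(1000, 11000, 2002000)), far, 1e6)
  expect_equal(s2, c(1, 1, 1))
})

test_that("total LD score equals brute-force oracle on random fixtures", {
  set.seed(42)
  for (rep in 1:3) {
    n <- 20
    v <- toy_variants(n, pos = sort(sample(1:3e6, n)))
    cmb <- utils::combn(n, 2)
    pick <- sample(ncol(cmb), 40)
    ld <- toy_ld(v$variant_id[cmb[1, pick]], v$variant_id[cmb[2, pick]],
                 runif(40), v$pos[cmb[1, pick]], v$pos[cmb[2, pick]])
    s <- total_ld_score(v, ld, window_bp = 5e5)
    want <- vapply(v$variant_id, total_ld_oracle, numeric(1),
                   ld_pairs = ld, window_bp = 5e5)
    expect_equal(s, unname(want))
  }
})

test_that("pruning retains a lone variant everywhere and respects the LD window", {
  v1 <- toy_variants(1)
  pr <- random_prune(v1, NULL, n_sets = 10, seed = 1)
  expect_true(all(vapply(pr$replicate_sets, identical, logical(1), "v1")))

  # far apart: both retained despite high r2
  v2 <- toy_variants(2, pos = c(1000, 2001000))
  ld <- toy_ld("v1", "v2", 0.9, 1000, 2001000)
  pr2 <- random_prune(v2, ld, n_sets = 5, seed = 1)
  expect_true(all(lengths(pr2$replicate_sets) == 2))
})

test_that("conflicting pair: each replicate keeps exactly one, both orders occur", {
  v <- toy_variants(2, pos = c(1000, 11000))
  ld <- toy_ld("v1", "v2", 0.5, 1000, 11000)
  picks <- character(0)
  for (seed in 1:40) {
    pr <- random_prune(v, ld, n_sets = 1, seed = seed)
    expect_length(pr$replicate_sets[[1]], 1)
    picks <- c(picks, pr$replicate_sets[[1]])
  }
  # brute force over the two orderings: each variant wins under one of the
  # two equally likely permutations, so both must appear across seeds
  expect_setequal(unique(picks), c("v1", "v2"))
  frac <- mean(picks == "v1")
  expect_gt(frac, 0.2); expect_lt(frac, 0.8)
})

test_that("pruning is sound (exhaustive scan), reproducible, and maximal on zero LD", {
  set.seed(42)
  cfg <- sim_config(n_variants = 600, seed = 11)
  sim <- simulate_variants(cfg)
  pr <- random_prune(sim$variants, sim$ld_pairs, n_sets = 10, seed = 5)
  for (s in pr$replicate_sets)
    expect_equal(prune_violations(s, sim$ld_pairs, 0.2, 1e6), 0)

  pr2 <- random_prune(sim$variants, sim$ld_pairs, n_sets = 10, seed = 5)
  expect_identical(pr$replicate_sets, pr2$replicate_sets)
  pr3 <- random_prune(sim$variants, sim$ld_pairs, n_sets = 2, seed = 6)
  expect_false(identical(pr$replicate_sets[[1]], pr3$replicate_sets[[1]]))

  # no-LD universe: everything retained in every replicate
  cfg0 <- sim_config(n_variants = 200, n_blocks = 200, seed = 3)
  sim0 <- simulate_variants(cfg0)
  expect_equal(nrow(sim0$ld_pairs), 0)
  pr0 <- random_prune(sim0$variants, sim0$ld_pairs, n_sets = 3, seed = 1)
  expect_true(all(lengths(pr0$replicate_sets) == 200))

  expect_error(random_prune(sim0$variants, sim0$ld_pairs, n_sets = 0), "n_sets")
})

test_that("disjoint mode yields mutually disjoint replicates", {
  cfg <- sim_config(n_variants = 400, seed = 12)
  sim <- simulate_variants(cfg)
  pr <- random_prune(sim$variants, sim$ld_pairs, n_sets = 3, seed = 2,
                     disjoint = TRUE)
  for (i in 1:2) for (j in (i + 1):3)
    expect_length(intersect(pr$replicate_sets[[i]], pr$replicate_sets[[j]]), 0)
})

test_that("prune replicates round-trip through a manifest directory", {
  cfg <- sim_config(n_variants = 300, seed = 4)
  sim <- simulate_variants(cfg)
  pr <- random_prune(sim$variants, sim$ld_pairs, n_sets = 3, seed = 9)
  d <- withr::local_tempdir()
  write_prune_replicates(pr, d)
  pr2 <- read_prune_replicates(d)
  expect_identical(pr2$replicate_sets, pr$replicate_sets)
  expect_equal(pr2$seeds, pr$seeds)
  expect_equal(pr2$params$r2_max, pr$params$r2_max)
})

test_that("ld_window includes the lead, applies the inclusive threshold, spans members", {
  v <- toy_variants(6, pos = c(1000, 2000, 3000, 4000, 5000, 6000))
  # no partners
  w0 <- ld_window("v1", v, NULL)
  expect_equal(w0$members, "v1")
  expect_equal(w0$start, w0$end)

  ld <- toy_ld(rep("v3", 3), c("v1", "v2", "v5"), c(0.85, 0.79, 0.8),
               rep(3000, 3), c(1000, 2000, 5000))
  w <- ld_window("v3", v, ld, r2_min = 0.8)
  expect_setequal(w$members, c("v3", "v1", "v5"))  # 0.79 excluded, 0.80 included
  expect_equal(w$start, 1000)
  expect_equal(w$end, 5000)
  expect_error(ld_window("nope", v, ld), "not in table")
})
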