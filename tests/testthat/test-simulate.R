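test_that("config validation catches infeasible fractions", {
  expect_error(sim_config(roadmap_fractions = c(a = 0.6, b = 0.5)), "sum")
  expect_error(sim_config(lambda = 0.9), "lambda")
  expect_error(sim_config(beta = c("eqtl:all" = -0.1)), ">= 0")
  expect_error(sim_config(pi1 = c("eqtl:all" = 1.2)), "pi1")
})

test_that("singleton blocks produce a zero-LD universe with unit total LD", {
  cfg <- sim_config(n_variants = 500, n_blocks = 500, seed = 5)
  sim <- simulate_variants(cfg)
  expect_equal(nrow(sim$ld_pairs), 0)
  expect_true(all(sim$variants$total_ld == 1))
})

test_that("emitted LD pairs are consistent with loadings and in-window", {
  cfg <- sim_config(n_variants = 800, seed = 6)
  sim <- simulate_variants(cfg)
  expect_true(all(sim$ld_pairs$r2 >= 0 & sim$ld_pairs$r2 <= 1))
  expect_true(all(sim$ld_pairs$distance <= 1e6))
  i <- match(sim$ld_pairs$id_a, sim$variants$variant_id)
  j <- match(sim$ld_pairs$id_b, sim$variants$variant_id)
  expect_equal(sim$ld_pairs$r2, (sim$loading[i] * sim$loading[j])^2)
  # and total_ld equals the sum over listed pairs
  s <- total_ld_score(sim$variants, sim$ld_pairs)
  expect_equal(sim$variants$total_ld, s)
})

test_that("tissue sharing fraction is realized near its design value", {
  cfg <- sim_config(n_variants = 20000, tissues = c("a", "b", "c"),
                    eqtl_fraction = 0.03, sharing = 0.10, seed = 42)
  sim <- simulate_variants(cfg)
  ab <- overlap_fraction(sim$sets[["eqtl:a"]], sim$sets[["eqtl:b"]])
  ac <- overlap_fraction(sim$sets[["eqtl:a"]], sim$sets[["eqtl:c"]])
  # binomial sd on 600-member sets is ~0.012
  expect_gt(mean(c(ab, ac)), 0.06)
  expect_lt(mean(c(ab, ac)), 0.14)

  cfg1 <- sim_config(n_variants = 2000, tissues = c("a", "b"), sharing = 1,
                     seed = 42)
  sim1 <- simulate_variants(cfg1)
  expect_setequal(sim1$sets[["eqtl:a"]]$variant_ids,
                  sim1$sets[["eqtl:b"]]$variant_ids)
})

test_that("null simulation gives uniform p-values, unit mean chi-squared and lambda 1", {
  cfg <- sim_config(n_variants = 50000, seed = 42)
  sim <- simulate_variants(cfg)
  st <- simulate_gwas(sim, "t")
  expect_equal(mean(st$z2), 1, tolerance = 0.05)
  # KS on a thinned subsample (one variant per block, independent nulls)
  first <- !duplicated(sim$block)
  ks <- suppressWarnings(stats::ks.test(st$p[first], "punif"))
  expect_gt(ks$p.value, 0.001)
  reps <- random_prune(sim$variants, sim$ld_pairs, seed = 1)
  expect_equal(gc_lambda(st, sim$variants, reps)$lambda_gc, 1, tolerance = 0.05)
})

test_that("moment identity: class mean chi-squared is lambda * (1 + beta)", {
  cfg <- sim_config(n_variants = 60000, eqtl_fraction = 0.05,
                    beta = c("eqtl:all" = 0.2), seed = 42)
  sim <- simulate_variants(cfg)
  st <- simulate_gwas(sim, "t")
  inset <- st$variant_id %in% sim$sets[["eqtl:all"]]$variant_ids
  # Monte-Carlo SE of the mean difference ~ sqrt(2*1.44/3000) ~ 0.031
  expect_equal(mean(st$z2[inset]) - mean(st$z2[!inset]), 0.2,
               tolerance = 3 * 0.031)

  # pi1 < 1: only that fraction of the class carries the effect
  cfg2 <- sim_config(n_variants = 60000, eqtl_fraction = 0.05,
                     beta = c("eqtl:all" = 1.0), pi1 = c("eqtl:all" = 0.5),
                     seed = 43)
  sim2 <- simulate_variants(cfg2)
  st2 <- simulate_gwas(sim2, "t")
  inset2 <- st2$variant_id %in% sim2$sets[["eqtl:all"]]$variant_ids
  expect_equal(mean(st2$z2[inset2]) - mean(st2$z2[!inset2]), 0.5,
               tolerance = 0.12)
})

test_that("genomic inflation is injected multiplicatively", {
  cfg <- sim_config(n_variants = 60000, lambda = 1.10, seed = 44)
  sim <- simulate_variants(cfg)
  st <- simulate_gwas(sim, "t")
  reps <- random_prune(sim$variants, sim$ld_pairs, seed = 2)
  expect_equal(gc_lambda(st, sim$variants, reps)$lambda_gc, 1.10,
               tolerance = 0.04)
})

test_that("fixtures regenerate byte-identically under the same seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_fixture("tiny", d1, seed = 9)
  make_fixture("tiny", d2, seed = 9)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in setdiff(files, "manifest.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("tiny fixture loads through the readers with zero dropped rows", {
  d <- withr::local_tempdir()
  fx <- make_fixture("tiny", d, seed = 10)
  g <- read_gwas(file.path(d, "gwas_trait1.tsv"))
  expect_equal(attr(g, "n_dropped"), 0L)
  expect_equal(nrow(g), 2000)
  v <- read_variant_table(file.path(d, "variants.tsv"))
  expect_equal(nrow(v), 2000)
  ld <- read_ld_pairs(file.path(d, "ld_pairs.tsv"))
  expect_equal(nrow(ld), nrow(fx$sim$ld_pairs))
  eq <- read_eqtl_table(file.path(d, "eqtl_table.tsv"))
  expect_setequal(names(eq$sets), c("eqtl:adipose", "eqtl:blood"))
  expect_setequal(eq$sets[["eqtl:adipose"]]$variant_ids,
                  fx$sim$sets[["eqtl:adipose"]]$variant_ids)
})
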