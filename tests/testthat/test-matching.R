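test_that("exact twins are matched one-to-one and controls never intersect targets", {
  n <- 40
  v <- data.frame(variant_id = paste0("v", 1:n), chrom = "chr1",
                  pos = 1:n * 1000,
                  maf = rep(seq(0.05, 0.45, length.out = n / 2), 2),
                  is_genic = TRUE,
                  tss_distance = rep(seq(1000, 50000, length.out = n / 2), 2),
                  total_ld = 1, stringsAsFactors = FALSE)
  target <- annotation_set("eqtl:adipose", v$variant_id[1:(n / 2)])
  ctl <- match_controls(target, v, seed = 42)
  expect_length(ctl$variant_ids, n / 2)
  expect_length(intersect(ctl$variant_ids, target$variant_ids), 0)
  expect_length(attr(ctl, "unmatched"), 0)
  expect_equal(ctl$label, "control:adipose")
})

test_that("candidates with expression association below 1e-4 are excluded outright", {
  v <- toy_variants(4)
  v$maf <- 0.2; v$tss_distance <- 10000
  target <- annotation_set("eqtl:adipose", "v1")
  expr <- c(v2 = 1e-5, v3 = 2e-4)   # v2 excluded, v3 allowed
  ctl <- match_controls(target, v, pool = c("v2", "v3"), expression_p = expr,
                        seed = 1)
  expect_equal(ctl$variant_ids, "v3")
  expect_equal(attr(ctl, "n_excluded_expression"), 1)
})

test_that("empty strata are reported as unmatched without failing", {
  v <- toy_variants(4)
  v$maf <- c(0.05, 0.45, 0.45, 0.45)  # target v1 isolated in its MAF bin
  v$tss_distance <- 10000
  target <- annotation_set("eqtl:adipose", "v1")
  ctl <- match_controls(target, v, seed = 1)
  expect_length(ctl$variant_ids, 0)
  expect_equal(attr(ctl, "unmatched"), "v1")
  expect_error(match_controls(target, v, pool = character(0)), "empty")
})

test_that("matched controls reproduce the target MAF histogram when strata are full", {
  set.seed(42)
  cfg <- sim_config(n_variants = 8000, tissues = "adipose",
                    eqtl_fraction = 0.05, sharing = 1, seed = 19)
  sim <- simulate_variants(cfg)
  target <- sim$sets[["eqtl:adipose"]]
  ctl <- match_controls(target, sim$variants,
                        pool = setdiff(sim$variants$variant_id,
                                       target$variant_ids),
                        expression_p = sim$expression_p, seed = 42)
  d <- matching_diagnostics(target, ctl, sim$variants)
  full <- attr(ctl, "unmatched")
  # nearly all strata populated at this density; histograms agree up to
  # the unmatched remainder
  expect_lt(length(full) / length(target$variant_ids), 0.05)
  expect_lt(max(abs(d$maf_counts$target - d$maf_counts$control)),
            0.05 * length(target$variant_ids))
  # matching proxies balanced; rank tests not significant
  p_maf <- d$rank_tests$p[d$rank_tests$variable == "maf"]
  p_dist <- d$rank_tests$p[d$rank_tests$variable == "tss_distance"]
  expect_gt(p_maf, 0.01)
  expect_gt(p_dist, 0.01)
})

test_that("diagnostics flag an inflated total-LD target and pass a self-comparison", {
  v <- toy_variants(200, pos = 1:200 * 1000)
  set.seed(42)
  v$total_ld <- 1 + rexp(200)
  a <- annotation_set("eqtl:adipose", v$variant_id[1:100])
  same <- matching_diagnostics(a, a, v)
  expect_true(all(same$rank_tests$p == 1))

  v2 <- v
  v2$total_ld[1:100] <- v2$total_ld[1:100] + 2   # targets carry extra LD
  b <- annotation_set("control:adipose", v$variant_id[101:200])
  d <- matching_diagnostics(a, b, v2)
  expect_lt(d$rank_tests$p[d$rank_tests$variable == "total_ld"], 1e-6)
})

test_that("matching is deterministic under a fixed seed and supports ratio > 1", {
  set.seed(1)
  cfg <- sim_config(n_variants = 3000, tissues = "adipose",
                    eqtl_fraction = 0.02, sharing = 1, seed = 23)
  sim <- simulate_variants(cfg)
  target <- sim$sets[["eqtl:adipose"]]
  pool <- setdiff(sim$variants$variant_id, target$variant_ids)
  c1 <- match_controls(target, sim$variants, pool = pool, seed = 99)
  c2 <- match_controls(target, sim$variants, pool = pool, seed = 99)
  expect_identical(c1$variant_ids, c2$variant_ids)
  c3 <- match_controls(target, sim$variants, pool = pool, seed = 100)
  expect_false(identical(c1$variant_ids, c3$variant_ids))

  c2x <- match_controls(target, sim$variants, pool = pool, ratio = 2, seed = 7)
  expect_gt(length(c2x$variant_ids), length(c1$variant_ids))
})
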