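make_design_fixture <- function(n = 400, seed = 1) {
  set.seed(seed)
  v <- toy_variants(n, pos = seq_len(n) * 1000)
  v$total_ld <- 1 + rexp(n)
  eqtl <- sample(v$variant_id, n / 4)
  ctl <- sample(setdiff(v$variant_id, eqtl), n / 4)
  prom <- sample(v$variant_id, n / 5)
  sets <- list(
    "eqtl:all" = annotation_set("eqtl:all", eqtl),
    "control:all" = annotation_set("control:all", ctl),
    "roadmap:active_promoter" = annotation_set("roadmap:active_promoter", prom))
  st <- toy_stats(v, runif(n))
  list(v = v, sets = sets, st = st)
}

test_that("design matrix has indicator coding, scope filtering and product interactions", {
  fx <- make_design_fixture()
  spec <- design_spec(c("eqtl:all", "roadmap:active_promoter", "total_ld"),
                      interactions = list(c("eqtl:all", "roadmap:active_promoter")))
  d <- build_design(fx$v, fx$st, fx$v$variant_id, fx$sets, spec)
  X <- d$X
  expect_equal(sum(X[, "eqtl_all"]), length(fx$sets[["eqtl:all"]]$variant_ids))
  expect_true(all(X[, "eqtl_all"] %in% 0:1))
  expect_equal(X[, "eqtl_all_x_roadmap_active_promoter"],
               X[, "eqtl_all"] * X[, "roadmap_active_promoter"],
               ignore_attr = TRUE)

  spec2 <- design_spec(c("eqtl:all", "total_ld"), scope = "eqtl_controls")
  d2 <- build_design(fx$v, fx$st, fx$v$variant_id, fx$sets, spec2)
  expect_equal(nrow(d2$X), 200)   # 100 eqtl + 100 controls of 400 variants

  # a term constant within the replicate is an error naming it
  few <- fx$sets[["eqtl:all"]]$variant_ids[1:5]
  expect_error(
    build_design(fx$v, fx$st, few, fx$sets,
                 design_spec(c("eqtl:all", "total_ld"))),
    "eqtl:all")
})

test_that("design_spec validates terms and interactions", {
  expect_error(design_spec(c("a", "a")), "duplicate")
  expect_error(design_spec("a", interactions = list(c("a", "b"))), "undeclared")
  expect_error(design_spec("a", interactions = list("a")), "pairs")
})

test_that("single-indicator OLS equals the difference of group means", {
  fx <- make_design_fixture(seed = 7)
  spec <- design_spec("eqtl:all")
  d <- build_design(fx$v, fx$st, fx$v$variant_id, fx$sets, spec)
  fit <- fit_chisq_glm(d)
  flagged <- d$X[, "eqtl_all"] == 1
  expect_equal(fit$beta[fit$term == "eqtl:all"],
               mean(d$y[flagged]) - mean(d$y[!flagged]), tolerance = 1e-12)
  expect_equal(fit$beta[fit$term == "(Intercept)"], mean(d$y[!flagged]),
               tolerance = 1e-12)

  # constant response: intercept only, zero slope
  d$y <- rep(3, length(d$y))
  fit0 <- fit_chisq_glm(d)
  expect_equal(fit0$beta, c(3, 0), tolerance = 1e-12)
})

test_that("OLS residuals are orthogonal to every design column and collinearity is reported", {
  fx <- make_design_fixture(seed = 3)
  spec <- design_spec(c("eqtl:all", "roadmap:active_promoter", "total_ld"))
  d <- build_design(fx$v, fx$st, fx$v$variant_id, fx$sets, spec)
  fit <- fit_chisq_glm(d)
  beta <- fit$beta
  res <- d$y - d$X %*% beta
  expect_lt(max(abs(crossprod(d$X, res))), 1e-8)

  X <- cbind(1, x = rnorm(50), y = 0)
  X[, 3] <- X[, 2] * 2
  colnames(X) <- c("(Intercept)", "x", "x2")
  expect_error(fit_chisq_glm(X, rnorm(50)), "collinear")
})

test_that("simulated additive chi-squared model is recovered within 3 SE", {
  set.seed(42)
  cfg <- sim_config(n_variants = 30000, eqtl_fraction = 0.05,
                    beta = c("eqtl:all" = 0.2), beta_ld = 0.05, seed = 202)
  sim <- simulate_variants(cfg)
  st <- simulate_gwas(sim, "t")
  spec <- design_spec(c("eqtl:all", "total_ld"))
  d <- build_design(sim$variants, st, sim$variants$variant_id, sim$sets, spec)
  fit <- fit_chisq_glm(d)
  b_eqtl <- fit[fit$term == "eqtl:all", ]
  b_ld <- fit[fit$term == "total_ld", ]
  expect_lt(abs(b_eqtl$beta - 0.2), 3 * b_eqtl$se)
  expect_lt(abs(b_ld$beta - 0.05), 3 * b_ld$se)
})

test_that("meta-analysis combines replicate fits by mean and inverse variance", {
  one <- function(beta, se) data.frame(term = "x", beta = beta, se = se,
                                       p = 0.5, stringsAsFactors = FALSE)
  m <- meta_analyze(replicate(10, one(0.18, 0.04), simplify = FALSE))
  expect_equal(m$beta_bar, 0.18)
  expect_equal(m$beta_ivw, 0.18)
  expect_equal(m$se_meta, 0.04 / sqrt(10), tolerance = 1e-12)
  expect_lte(m$ci_low, m$beta_bar); expect_gte(m$ci_high, m$beta_bar)

  m2 <- meta_analyze(list(one(0.1, 0.05), one(0.2, 0.05)))
  expect_equal(m2$beta_bar, 0.15)
  expect_equal(m2$beta_ivw, 0.15)

  expect_error(meta_analyze(list(one(1, 1), data.frame(term = "y", beta = 1,
                                                       se = 1, p = 1))),
               "disagree")
})

test_that("inverse-variance pooling agrees with metafor fixed-effect model", {
  skip_if_not_installed("metafor")
  set.seed(42)
  betas <- rnorm(10, 0.2, 0.05)
  ses <- runif(10, 0.03, 0.08)
  fits <- lapply(1:10, function(i)
    data.frame(term = "x", beta = betas[i], se = ses[i], p = 0.5))
  m <- meta_analyze(fits)
  rf <- metafor::rma(yi = betas, sei = ses, method = "FE")
  expect_equal(m$beta_ivw, as.numeric(rf$beta), tolerance = 1e-8)
  expect_equal(m$se_meta, rf$se, tolerance = 1e-8)
  expect_equal(m$p, rf$pval, tolerance = 1e-8)
})

test_that("meta coefficient of a lone indicator matches group-mean differences across replicates", {
  set.seed(42)
  cfg <- sim_config(n_variants = 4000, eqtl_fraction = 0.1,
                    beta = c("eqtl:all" = 0.5), seed = 77)
  sim <- simulate_variants(cfg)
  st <- simulate_gwas(sim, "t")
  reps <- random_prune(sim$variants, sim$ld_pairs, n_sets = 5, seed = 8)
  fit <- fit_replicates(sim$variants, st, reps, sim$sets, design_spec("eqtl:all"))
  z2 <- st$z2; names(z2) <- st$variant_id
  diffs <- vapply(reps$replicate_sets, function(ids) {
    e <- ids %in% sim$sets[["eqtl:all"]]$variant_ids
    mean(z2[ids[e]]) - mean(z2[ids[!e]])
  }, numeric(1))
  expect_equal(fit$beta_bar[fit$term == "eqtl:all"], mean(diffs),
               tolerance = 1e-10)
})

test_that("interaction scan keeps main effects and reduces to the base fit when empty", {
  set.seed(42)
  cfg <- sim_config(n_variants = 3000, eqtl_fraction = 0.1,
                    roadmap_fractions = c(active_promoter = 0.3),
                    beta = c("eqtl:all" = 0.4), seed = 31)
  sim <- simulate_variants(cfg)
  st <- simulate_gwas(sim, "t")
  reps <- random_prune(sim$variants, sim$ld_pairs, n_sets = 3, seed = 5)
  base <- design_spec(c("eqtl:all", "roadmap:active_promoter", "total_ld"))

  sc <- interaction_scan(sim$variants, st, reps, sim$sets, base,
                         eqtl_terms = "eqtl:all",
                         with_terms = c("roadmap:active_promoter", "total_ld"))
  expect_true(all(c("eqtl:all", "roadmap:active_promoter",
                    "eqtl:all x roadmap:active_promoter",
                    "eqtl:all x total_ld") %in% sc$term))

  plain <- fit_replicates(sim$variants, st, reps, sim$sets, base)
  sc0 <- interaction_scan(sim$variants, st, reps, sim$sets, base,
                          eqtl_terms = character(0), with_terms = character(0))
  expect_equal(sc0$beta_bar, plain$beta_bar)
  expect_equal(sc0$p, plain$p)
})
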