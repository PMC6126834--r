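#' Simulation configuration
#'
#' Declares the statistical structure of a synthetic GWAS-plus-annotation
#' data set: a variant map organised in LD blocks, tissue-tagged eQTL sets
#' with a controlled pairwise sharing fraction, chromatin-state categories,
#' and association z-scores whose variance is inflated on annotated variants
#' so the linear-in-chi-squared enrichment model is correctly specified.
#'
#' Within a block, the z-score of variant i loads on a shared block factor
#' with loading l_i, giving pairwise correlation l_i l_j and hence pairwise
#' LD r-squared (l_i l_j)^2; the squared loadings are drawn from the Beta
#' distribution given by `loading_beta`. Across blocks LD is zero.
#'
#' @param n_variants Number of variants.
#' @param n_blocks Number of LD blocks (default `n_variants / 20`, i.e. a
#'   mean block size of 20 variants, spanning tens of kb at the default
#'   spacing -- the scale of common LD blocks).
#' @param loading_beta Shape parameters of the Beta distribution of squared
#'   block-factor loadings. The default `c(10, 10)` centres squared
#'   loadings at 0.5, so within-block pairwise r-squared centres near 0.25:
#'   most block-mate pairs conflict at the r-squared 0.2 pruning threshold
#'   while an appreciable minority do not, as in real tag-SNP panels.
#' @param maf_range Uniform range of minor allele frequencies.
#' @param tissues Tissue names.
#' @param eqtl_fraction Per-tissue eQTL fraction of the variant universe.
#' @param sharing Expected pairwise overlap fraction between tissue eQTL
#'   sets (default 0.10); implemented by drawing every tissue's set from a
#'   common eQTL-prone pool of size `eqtl_fraction * n / sharing`.
#' @param roadmap_fractions Named fractions of variants per chromatin-state
#'   category (mutually exclusive; must sum to < 1).
#' @param genic_fraction Fraction of genic variants (the complement feeds
#'   the intergenic genomic-control estimate).
#' @param beta Named vector of enrichment coefficients on the expected
#'   chi-squared scale, keyed by annotation label (e.g.
#'   `c("eqtl:adipose" = 0.2)`).
#' @param beta_ld Coefficient of `total_ld - 1` in the expected chi-squared.
#' @param pi1 Named vector, per annotation label: fraction of the label's
#'   variants carrying its effect (default 1 = all members).
#' @param lambda Genomic inflation factor (>= 1) multiplying every
#'   variant's z variance.
#' @param traits Trait names for [simulate_gwas()] / [make_fixture()].
#' @param seed Master seed; every downstream draw is derived from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_variants = 20000,
                       n_blocks = round(n_variants / 20),
                       loading_beta = c(10, 10),
                       maf_range = c(0.01, 0.5),
                       tissues = c("adipose", "epidermal", "lcl", "blood"),
                       eqtl_fraction = 0.02,
                       sharing = 0.10,
                       roadmap_fractions = c(active_promoter = 0.03,
                                             weak_promoter = 0.03,
                                             strong_enhancer = 0.04,
                                             weak_enhancer = 0.05),
                       genic_fraction = 0.5,
                       beta = numeric(0),
                       beta_ld = 0,
                       pi1 = numeric(0),
                       lambda = 1,
                       traits = "trait1",
                       seed = 1L) {
  stopifnot(n_variants >= 1, n_blocks >= 1, n_blocks <= n_variants,
            lambda >= 1, eqtl_fraction >= 0, eqtl_fraction <= 1,
            sharing > 0, sharing <= 1, genic_fraction >= 0, genic_fraction <= 1)
  if (sum(roadmap_fractions) >= 1)
    stop("roadmap category fractions must sum to < 1 (they are exclusive)")
  if (any(beta < 0)) stop("enrichment coefficients must be >= 0")
  if (any(pi1 < 0 | pi1 > 1)) stop("pi1 values must lie in [0, 1]")
  structure(list(n_variants = n_variants, n_blocks = n_blocks,
                 loading_beta = loading_beta, maf_range = maf_range,
                 tissues = tissues, eqtl_fraction = eqtl_fraction,
                 sharing = sharing, roadmap_fractions = roadmap_fractions,
                 genic_fraction = genic_fraction, beta = beta,
                 beta_ld = beta_ld, pi1 = pi1, lambda = lambda,
                 traits = traits, seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic seed splitting: every stage gets its own stream derived
# from the master seed, so adding a stage never shifts another's draws.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 48271L + h) %% 2147483563L + 1L
}

#' Simulate the variant map, LD structure and annotations
#'
#' Places variants in LD blocks on synthetic chromosomes, emits all
#' within-block pairwise r-squared as an LD-pairs table, computes total LD
#' scores, assigns MAF, TSS distance (log-normal with median 25 kb, so the
#' proximal/distal split is non-degenerate), genic status, per-tissue eQTL
#' sets with the configured sharing structure, chromatin-state categories,
#' and per-variant minimum expression-association p-values (strong for
#' eQTL-prone variants, uniform otherwise).
#'
#' @param config A `sim_config`.
#' @return List with `variants` (variant table), `ld_pairs`, `sets` (named
#'   list of `annotation_set`s: `eqtl:<tissue>`, `eqtl:all`,
#'   `roadmap:<category>`), `expression_p` (named vector), `block` (integer
#'   block index per variant), `loading` (block-factor loadings), `config`.
#' @export
simulate_variants <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_variants
  set.seed(derive_seed(config$seed, "variants"))

  # blocks: near-equal sizes, laid out consecutively on 22 chromosomes
  base <- n %/% config$n_blocks
  sizes <- rep(base, config$n_blocks)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  block <- rep(seq_len(config$n_blocks), sizes)

  n_chrom <- min(22L, config$n_blocks)
  chrom_of_block <- rep(seq_len(n_chrom), length.out = config$n_blocks)
  chrom <- paste0("chr", chrom_of_block[block])

  # positions: 0.5-5 kb within-block spacing, >= 2 Mb gaps between blocks
  spacing <- round(stats::runif(n, 500, 5000))
  pos <- numeric(n)  # double: many blocks per chromosome exceed integer range
  for (cb in split(seq_len(n), chrom_of_block[block])) {
    off <- cumsum(spacing[cb])
    gap <- (match(block[cb], unique(block[cb])) - 1L) * 2e6
    pos[cb] <- off + gap + 1
  }

  l2 <- stats::rbeta(n, config$loading_beta[1], config$loading_beta[2])
  loading <- sqrt(l2)

  variants <- data.frame(
    variant_id = sprintf("rs%06d", seq_len(n)),
    chrom = chrom, pos = pos,
    maf = stats::runif(n, config$maf_range[1], config$maf_range[2]),
    is_genic = stats::runif(n) < config$genic_fraction,
    tss_distance = round(stats::rlnorm(n, meanlog = log(25000), sdlog = 1.5)),
    total_ld = NA_real_,
    stringsAsFactors = FALSE)

  ld_pairs <- block_ld_pairs(variants, block, loading)
  variants$total_ld <- total_ld_score(variants, ld_pairs, window_bp = 1e6)

  # tissue eQTL sets drawn from a common eQTL-prone pool: with per-tissue
  # size m and pool size m / sharing, the expected pairwise overlap
  # fraction between two tissue sets is `sharing`
  m <- round(n * config$eqtl_fraction)
  sets <- list()
  expression_p <- stats::runif(n)
  names(expression_p) <- variants$variant_id
  if (m > 0 && length(config$tissues)) {
    pool_size <- min(n, round(m / config$sharing))
    pool <- sample(variants$variant_id, pool_size)
    expression_p[pool] <- 10^stats::runif(pool_size, -12, -5)
    for (ts in config$tissues) {
      ids <- sample(pool, m)
      sets[[paste0("eqtl:", ts)]] <-
        annotation_set(paste0("eqtl:", ts), ids, provenance = "simulated")
    }
    all_ids <- unique(unlist(lapply(sets, `[[`, "variant_ids")))
    sets[["eqtl:all"]] <- annotation_set("eqtl:all", all_ids,
                                         provenance = "union of tissues")
  }

  # mutually exclusive chromatin-state categories
  rf <- config$roadmap_fractions
  if (length(rf)) {
    cat_draw <- sample(c(names(rf), "none"), n, replace = TRUE,
                       prob = c(rf, 1 - sum(rf)))
    for (cat in names(rf)) {
      sets[[paste0("roadmap:", cat)]] <-
        annotation_set(paste0("roadmap:", cat),
                       variants$variant_id[cat_draw == cat],
                       provenance = "simulated track")
    }
  }

  list(variants = variants, ld_pairs = ld_pairs, sets = sets,
       expression_p = expression_p, block = block, loading = loading,
       config = config)
}

# All within-block pairs with r2 = (l_i l_j)^2, in the pairwise LD dialect.
block_ld_pairs <- function(variants, block, loading) {
  per_block <- split(seq_len(nrow(variants)), block)
  per_block <- per_block[lengths(per_block) > 1]
  if (!length(per_block)) {
    return(data.frame(id_a = character(), pos_a = integer(),
                      id_b = character(), pos_b = integer(),
                      r2 = numeric(), distance = numeric(),
                      stringsAsFactors = FALSE))
  }
  cmb <- lapply(per_block, function(ix) utils::combn(ix, 2L))
  a <- unlist(lapply(cmb, function(m) m[1, ]), use.names = FALSE)
  b <- unlist(lapply(cmb, function(m) m[2, ]), use.names = FALSE)
  data.frame(id_a = variants$variant_id[a], pos_a = variants$pos[a],
             id_b = variants$variant_id[b], pos_b = variants$pos[b],
             r2 = (loading[a] * loading[b])^2,
             distance = abs(variants$pos[b] - variants$pos[a]),
             stringsAsFactors = FALSE)
}

#' Simulate GWAS summary statistics over a variant map
#'
#' Draws per-variant z-scores jointly within each LD block (correlation
#' l_i l_j, matching the emitted pairwise r-squared), with variance
#' sigma^2_i = lambda * (1 + sum_k beta_k x_ik eta_ik + beta_ld *
#' (total_ld_i - 1)), where x_ik is membership of annotation class k and
#' eta_ik is a Bernoulli(pi1_k) non-null indicator (default all 1). Null
#' variants have marginal z ~ N(0, lambda), so their two-sided p-values are
#' uniform at lambda = 1 and uniformly deflected at lambda > 1, which the
#' genomic-control stage must undo.
#'
#' @param sim Output of [simulate_variants()].
#' @param trait Trait name.
#' @param seed Seed for this trait's draws; defaults to a stream derived
#'   from the master seed and the trait name.
#' @return Association table (`variant_id`, `p`, `z2`, `trait`) with the
#'   non-null indicator matrix in attribute `"nonnull"`.
#' @export
simulate_gwas <- function(sim, trait = sim$config$traits[1], seed = NULL) {
  config <- sim$config
  n <- nrow(sim$variants)
  if (is.null(seed)) seed <- derive_seed(config$seed, paste0("gwas:", trait))
  set.seed(seed)

  effect <- numeric(n)
  nonnull <- list()
  for (k in names(config$beta)) {
    if (config$beta[[k]] == 0) next
    if (!k %in% names(sim$sets))
      stop("enrichment coefficient for unknown annotation: ", k)
    x <- sim$variants$variant_id %in% sim$sets[[k]]$variant_ids
    p1 <- if (k %in% names(config$pi1)) config$pi1[[k]] else 1
    eta <- x & (stats::runif(n) < p1)
    effect <- effect + config$beta[[k]] * eta
    nonnull[[k]] <- eta
  }
  if (config$beta_ld != 0)
    effect <- effect + config$beta_ld * (sim$variants$total_ld - 1)
  sigma2 <- config$lambda * (1 + effect)
  if (any(sigma2 <= 0)) stop("non-positive z variance; check coefficients")

  u <- stats::rnorm(max(sim$block))[sim$block]
  e <- stats::rnorm(n)
  z <- sqrt(sigma2) * (sim$loading * u + sqrt(1 - sim$loading^2) * e)
  z2 <- z^2
  p <- pmax(p_from_chisq(z2), 1e-300)
  out <- data.frame(variant_id = sim$variants$variant_id, p = p, z2 = z2,
                    trait = trait, stringsAsFactors = FALSE)
  attr(out, "nonnull") <- nonnull
  out
}

#' Genome-wide-significant, LD-independent lead variants
#'
#' Orders variants by association p-value and greedily retains a variant as
#' a locus lead iff it passes the significance threshold and no
#' already-retained lead within `window_bp` has r-squared >= `r2_max` with
#' it; leads are therefore LD-independent under the pruning threshold.
#'
#' @param stats Association table.
#' @param variants Variant table.
#' @param ld_pairs Pairwise LD table.
#' @param p_threshold Genome-wide significance threshold.
#' @param r2_max,window_bp Independence criteria for leads.
#' @return data.frame with columns `variant_id`, `chrom`, `pos`, `p`.
#' @export
significant_loci <- function(stats, variants, ld_pairs, p_threshold = 5e-8,
                             r2_max = 0.2, window_bp = 1e6) {
  sig <- stats[stats$p < p_threshold, , drop = FALSE]
  sig <- sig[order(sig$p), , drop = FALSE]
  adj <- build_conflict_graph(variants, ld_pairs, r2_max, window_bp)
  idx <- match(sig$variant_id, variants$variant_id)
  retained <- logical(nrow(variants))
  leads <- integer(0)
  for (v in idx) {
    if (is.na(v)) next
    nb <- adj[[v]]
    if (is.null(nb) || !any(retained[nb])) {
      retained[v] <- TRUE
      leads <- c(leads, v)
    }
  }
  data.frame(variant_id = variants$variant_id[leads],
             chrom = variants$chrom[leads], pos = variants$pos[leads],
             p = stats$p[match(variants$variant_id[leads], stats$variant_id)],
             stringsAsFactors = FALSE)
}

#' Write a complete synthetic input directory
#'
#' Generates a full set of pipeline inputs in exactly the formats the
#' readers consume: variant table, LD pairs, per-trait GWAS summary
#' statistics (SNP/CHR/BP/P/N), an eQTL table (SNP/gene/tissue/tss_dist/fdr),
#' chromatin-state BED4 tracks, matched-control annotation-set files, an
#' expression-association p table, a template id list, a
#' genome-wide-significant loci list, and a JSON manifest recording the
#' configuration and seed. Regenerating with the same seed is byte-identical.
#'
#' Two scales are predefined: `"tiny"` (2,000 variants, 2 tissues, 1 trait;
#' seconds, for unit tests) and `"desk"` (100,000 variants, 4 tissues,
#' 2 traits, eQTL enrichment injected on the first trait; a couple of
#' minutes, for end-to-end runs).
#'
#' @param scale `"tiny"` or `"desk"`, or pass a full `sim_config` as
#'   `config`.
#' @param dir Output directory (created).
#' @param seed Master seed (overrides the config's).
#' @param config Optional `sim_config` replacing the scale presets.
#' @return Invisibly, a list with the in-memory objects (`sim`, `gwas`,
#'   `controls`, `loci`, `paths`).
#' @export
make_fixture <- function(scale = c("tiny", "desk"), dir, seed = 1L,
                         config = NULL) {
  if (is.null(config)) {
    scale <- match.arg(scale)
    config <- switch(scale,
      tiny = sim_config(n_variants = 2000,
                        tissues = c("adipose", "blood"),
                        eqtl_fraction = 0.05,
                        beta = c("eqtl:adipose" = 0.3, "eqtl:blood" = 0.3),
                        traits = "trait1", seed = seed),
      desk = sim_config(n_variants = 100000,
                        eqtl_fraction = 0.02,
                        beta = c("eqtl:adipose" = 0.2, "eqtl:epidermal" = 0.2,
                                 "eqtl:lcl" = 0.2, "eqtl:blood" = 0.2),
                        traits = c("trait1", "trait2"), seed = seed))
  } else {
    config$seed <- as.integer(seed)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_variants(config)
  v <- sim$variants

  paths <- list(variants = file.path(dir, "variants.tsv"),
                ld = file.path(dir, "ld_pairs.tsv"),
                eqtl = file.path(dir, "eqtl_table.tsv"),
                bed = file.path(dir, "roadmap.bed"),
                template = file.path(dir, "template.txt"),
                expression = file.path(dir, "expression_p.tsv"),
                manifest = file.path(dir, "manifest.json"))
  write_variant_table(v, paths$variants)
  data.table::fwrite(
    data.frame(SNP_A = sim$ld_pairs$id_a, BP_A = sim$ld_pairs$pos_a,
               SNP_B = sim$ld_pairs$id_b, BP_B = sim$ld_pairs$pos_b,
               R2 = sim$ld_pairs$r2),
    paths$ld, sep = "\t", quote = FALSE)
  writeLines(v$variant_id, paths$template)

  # eQTL table: gene ids are synthetic; fdr drawn below the designation cut
  set.seed(derive_seed(config$seed, "eqtl_table"))
  eqtl_rows <- do.call(rbind, lapply(config$tissues, function(ts) {
    ids <- sim$sets[[paste0("eqtl:", ts)]]$variant_ids
    vr <- match(ids, v$variant_id)
    data.frame(SNP = ids, gene = paste0("G", vr), tissue = ts,
               tss_dist = v$tss_distance[vr],
               fdr = signif(stats::runif(length(ids), 0, 0.01), 4),
               stringsAsFactors = FALSE)
  }))
  data.table::fwrite(eqtl_rows, paths$eqtl, sep = "\t", quote = FALSE)

  # chromatin-state BED4: one 1-bp half-open interval per member variant
  bed_rows <- do.call(rbind, lapply(names(config$roadmap_fractions), function(cat) {
    ids <- sim$sets[[paste0("roadmap:", cat)]]$variant_ids
    vr <- match(ids, v$variant_id)
    vr <- vr[order(v$chrom[vr], v$pos[vr])]
    data.frame(chrom = v$chrom[vr], start = v$pos[vr] - 1L, end = v$pos[vr],
               name = cat, stringsAsFactors = FALSE)
  }))
  utils::write.table(bed_rows, paths$bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  data.table::fwrite(
    data.frame(SNP = names(sim$expression_p), min_p = sim$expression_p),
    paths$expression, sep = "\t", quote = FALSE)

  # matched controls per tissue, drawn from the non-eQTL pool
  controls <- list()
  all_eqtl <- sim$sets[["eqtl:all"]]$variant_ids
  for (ts in config$tissues) {
    set <- sim$sets[[paste0("eqtl:", ts)]]
    ctl <- match_controls(set, v, pool = setdiff(v$variant_id, all_eqtl),
                          expression_p = sim$expression_p,
                          seed = derive_seed(config$seed, paste0("controls:", ts)))
    controls[[ctl$label]] <- ctl
    p <- file.path(dir, paste0("control_", ts, ".txt"))
    write_annotation_set(ctl, p)
    paths[[paste0("control_", ts)]] <- p
  }
  if (length(controls)) {
    ctl_all <- annotation_set("control:all",
                              unique(unlist(lapply(controls, `[[`, "variant_ids"))),
                              provenance = "union of tissue controls")
    controls[["control:all"]] <- ctl_all
    paths$control_all <- file.path(dir, "control_all.txt")
    write_annotation_set(ctl_all, paths$control_all)
  }

  gwas <- list()
  for (tr in config$traits) {
    st <- simulate_gwas(sim, trait = tr)
    p <- file.path(dir, paste0("gwas_", tr, ".tsv"))
    vr <- match(st$variant_id, v$variant_id)
    data.table::fwrite(
      data.frame(SNP = st$variant_id, CHR = v$chrom[vr], BP = v$pos[vr],
                 P = st$p, N = 10000L),
      p, sep = "\t", quote = FALSE)
    gwas[[tr]] <- st
    paths[[paste0("gwas_", tr)]] <- p
  }

  loci <- significant_loci(gwas[[1]], v, sim$ld_pairs)
  paths$loci <- file.path(dir, "loci.tsv")
  data.table::fwrite(loci, paths$loci, sep = "\t", quote = FALSE)

  jsonlite::write_json(
    list(scale = if (is.null(config$scale)) NA else config$scale,
         config = unclass(config), seed = config$seed,
         files = lapply(paths, basename)),
    paths$manifest, auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(sim = sim, gwas = gwas, controls = controls, loci = loci,
                 paths = paths, config = config))
}
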