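#' Select matched control variants
#'
#' Draws control variants for a target annotation set from a candidate pool,
#' matching on the two standard confounder proxies: minor allele frequency
#' (fixed-width bins, default 2%) and distance to TSS (deciles of
#' log10(1 + distance), pool-based cut points). Candidates showing any
#' evidence of association with expression (minimum expression-association
#' p-value below `expression_p_max`) are excluded outright, whatever their
#' match quality. Controls are drawn without replacement, up to `ratio` per
#' target variant, from the target variant's (MAF bin, distance bin)
#' stratum; targets whose stratum is exhausted are reported as unmatched
#' rather than failing the run.
#'
#' @param target An `annotation_set` (e.g. one tissue's eQTLs).
#' @param variants Variant table covering target and pool (`maf`,
#'   `tss_distance` needed).
#' @param pool Character vector of candidate ids; defaults to all variants
#'   not in `target`. Must be disjoint from the target.
#' @param expression_p Named numeric vector: per-variant minimum
#'   expression-association p across genes; absent variants are treated as
#'   p = 1 (no evidence).
#' @param expression_p_max Exclusion threshold.
#' @param maf_bin_width MAF bin width (fraction).
#' @param dist_bins Number of TSS-distance quantile bins.
#' @param ratio Controls drawn per target variant.
#' @param seed Integer seed; draws are deterministic given it.
#' @param label Label for the returned set.
#' @return An `annotation_set` of controls with attributes `"unmatched"`
#'   (target ids with an exhausted stratum) and `"n_excluded_expression"`.
#' @export
match_controls <- function(target, variants, pool = NULL, expression_p = NULL,
                           expression_p_max = 1e-4, maf_bin_width = 0.02,
                           dist_bins = 10, ratio = 1, seed = 1L,
                           label = NULL) {
  stopifnot(inherits(target, "annotation_set"))
  tids <- intersect(target$variant_ids, variants$variant_id)
  if (is.null(pool)) pool <- setdiff(variants$variant_id, tids)
  if (!length(pool)) stop("empty control pool")
  if (length(intersect(pool, tids)))
    stop("pool must be disjoint from the target set")

  expr_p <- rep(1, length(pool))
  names(expr_p) <- pool
  if (!is.null(expression_p)) {
    common <- intersect(pool, names(expression_p))
    expr_p[common] <- expression_p[common]
  }
  excluded <- pool[expr_p < expression_p_max]
  pool <- setdiff(pool, excluded)

  vr <- match(c(tids, pool), variants$variant_id)
  maf <- variants$maf[vr]
  dist <- variants$tss_distance[vr]
  names(maf) <- names(dist) <- c(tids, pool)

  maf_bin <- floor(maf / maf_bin_width)
  ld <- log10(1 + dist)
  # quantile cut points from the pool, so bins reflect candidate availability
  qs <- stats::quantile(ld[pool], probs = seq(0, 1, length.out = dist_bins + 1),
                        na.rm = TRUE, names = FALSE)
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  dist_bin <- findInterval(ld, qs, rightmost.closed = TRUE)
  stratum <- paste(maf_bin, dist_bin, sep = "/")
  names(stratum) <- c(tids, pool)

  set.seed(seed)
  # pre-shuffled per-stratum pools; drawing = popping from the front
  pool_by_stratum <- lapply(split(pool, stratum[pool]),
                            function(v) if (length(v) > 1) sample(v) else v)
  chosen_list <- vector("list", length(tids))
  unmatched <- character(0)
  i <- 0L
  for (tv in sample(tids)) {  # random target order so stratum exhaustion is unbiased
    st <- stratum[tv]
    avail <- pool_by_stratum[[st]]
    if (is.null(avail) || length(avail) == 0) {
      unmatched <- c(unmatched, tv)
      next
    }
    take <- min(ratio, length(avail))
    i <- i + 1L
    chosen_list[[i]] <- avail[seq_len(take)]
    pool_by_stratum[[st]] <- avail[-seq_len(take)]
  }
  chosen <- unlist(chosen_list)
  out <- annotation_set(
    label %||% sub("^eqtl:", "control:", target$label),
    chosen,
    provenance = sprintf("matched to %s on MAF (%.0f%% bins) and log10 TSS distance (%d bins), ratio %g, seed %d",
                         target$label, 100 * maf_bin_width, dist_bins, ratio, seed))
  attr(out, "unmatched") <- unmatched
  attr(out, "n_excluded_expression") <- length(excluded)
  out
}

#' Diagnostics for a matched-control set
#'
#' Per-bin counts of target and controls on the matching proxies, and
#' two-sample rank tests (Mann-Whitney) comparing MAF, TSS distance and
#' total LD score between target and controls. eQTLs typically carry more
#' total LD than their matched counterparts even when MAF and distance are
#' balanced, so the total-LD comparison is the one worth watching.
#'
#' @param target,controls `annotation_set`s.
#' @param variants Variant table (with `total_ld` for the LD comparison).
#' @param maf_bin_width MAF bin width for the count table.
#' @return List with `maf_counts` (data.frame bin/target/control) and
#'   `rank_tests` (data.frame variable/p).
#' @export
matching_diagnostics <- function(target, controls, variants,
                                 maf_bin_width = 0.02) {
  stopifnot(inherits(target, "annotation_set"), inherits(controls, "annotation_set"))
  if (!length(target$variant_ids) || !length(controls$variant_ids))
    stop("both sets must be nonempty")
  tv <- variants[variants$variant_id %in% target$variant_ids, , drop = FALSE]
  cv <- variants[variants$variant_id %in% controls$variant_ids, , drop = FALSE]
  bins <- sort(unique(floor(c(tv$maf, cv$maf) / maf_bin_width)))
  maf_counts <- data.frame(
    maf_bin_low = bins * maf_bin_width,
    target = vapply(bins, function(b) sum(floor(tv$maf / maf_bin_width) == b), integer(1)),
    control = vapply(bins, function(b) sum(floor(cv$maf / maf_bin_width) == b), integer(1)))
  cmp <- function(a, b) {
    if (all(is.na(a)) || all(is.na(b))) return(NA_real_)
    mann_whitney(a[!is.na(a)], b[!is.na(b)])$p
  }
  rank_tests <- data.frame(
    variable = c("maf", "tss_distance", "total_ld"),
    p = c(cmp(tv$maf, cv$maf),
          cmp(tv$tss_distance, cv$tss_distance),
          cmp(tv$total_ld, cv$total_ld)))
  list(maf_counts = maf_counts, rank_tests = rank_tests)
}
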