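#' Convert two-sided p-values to 1-df chi-squared statistics
#'
#' Recovers the association chi-squared from a two-sided p-value by squaring
#' the standard-normal quantile of the half p-value:
#' chi2 = (Phi^-1(p/2))^2. Strictly decreasing in p; [p_from_chisq()] is its
#' inverse.
#'
#' @param p Two-sided p-values in (0, 1].
#' @return Chi-squared statistics (1 df), same length as `p`.
#' @examples
#' chisq_from_p(0.05)        # 3.8415
#' p_from_chisq(chisq_from_p(0.05))
#' @export
chisq_from_p <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  stats::qnorm(p / 2)^2
}

#' @rdname chisq_from_p
#' @param z2 Chi-squared statistics (1 df), >= 0.
#' @export
p_from_chisq <- function(z2) {
  if (any(is.na(z2)) || any(z2 < 0)) stop("z2 must be >= 0")
  stats::pchisq(z2, df = 1, lower.tail = FALSE)
}

# Median of the 1-df chi-squared distribution (~0.4549364), from the
# quantile function rather than a hard-coded constant.
chisq1_median <- function() stats::qchisq(0.5, df = 1)

#' Intergenic genomic-control factor, median of medians
#'
#' For each pruning replicate, takes the median chi-squared over the
#' replicate's intergenic members; the genomic-control lambda is the median
#' of those per-replicate medians divided by the median of the null 1-df
#' chi-squared distribution. Computing the factor across the same
#' near-independent sets that the downstream models use keeps the correction
#' representative of those sets.
#'
#' @param stats Association table with columns `variant_id`, `z2`.
#' @param variants Variant table with `variant_id`, `is_genic`.
#' @param replicates A `prune_replicates` object.
#' @return An object of class `gc_factor`: list with `lambda_gc`,
#'   `per_replicate_medians`, `n_intergenic_per_replicate`.
#' @export
gc_lambda <- function(stats, variants, replicates) {
  stopifnot(inherits(replicates, "prune_replicates"))
  intergenic <- variants$variant_id[!variants$is_genic]
  z2 <- stats$z2
  names(z2) <- stats$variant_id
  meds <- numeric(length(replicates$replicate_sets))
  ns <- integer(length(meds))
  for (i in seq_along(meds)) {
    ids <- intersect(replicates$replicate_sets[[i]], intergenic)
    ids <- ids[ids %in% names(z2)]
    if (!length(ids))
      stop("replicate ", i, " contains no intergenic variants with statistics")
    ns[i] <- length(ids)
    meds[i] <- stats::median(z2[ids])
  }
  structure(list(lambda_gc = stats::median(meds) / chisq1_median(),
                 per_replicate_medians = meds,
                 n_intergenic_per_replicate = ns),
            class = "gc_factor")
}

#' @export
print.gc_factor <- function(x, ...) {
  cat(sprintf("<gc_factor> lambda_gc = %.4f (%d replicates, intergenic n %s)\n",
              x$lambda_gc, length(x$per_replicate_medians),
              paste(range(x$n_intergenic_per_replicate), collapse = "-")))
  invisible(x)
}

#' Apply genomic control to association statistics
#'
#' Divides every chi-squared by `lambda_gc` and regenerates the p-values
#' from the corrected statistics, so all downstream quantities (Q-Q curves,
#' fold enrichment, pi1, rank tests, models) see corrected values. A factor
#' of 1 is a no-op; the rank order of p-values is always preserved.
#'
#' @param stats Association table with columns `p`, `z2`.
#' @param gc A `gc_factor`, or a bare positive number.
#' @return The corrected association table.
#' @export
apply_gc <- function(stats, gc) {
  lambda <- if (inherits(gc, "gc_factor")) gc$lambda_gc else as.numeric(gc)
  if (!is.finite(lambda) || lambda <= 0) stop("lambda_gc must be > 0")
  stats$z2 <- stats$z2 / lambda
  stats$p <- p_from_chisq(stats$z2)
  stats
}

#' Serialize a genomic-control factor to JSON
#'
#' @param x A `gc_factor`.
#' @param path Output path.
#' @export
write_gc_factor <- function(x, path) {
  stopifnot(inherits(x, "gc_factor"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
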