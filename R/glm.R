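#' Design specification for the chi-squared general linear model
#'
#' Declares which covariates enter the model of per-variant association
#' chi-squared: annotation indicators (eQTL per tissue, matched controls,
#' chromatin-state categories, genic status) named by their annotation-set
#' labels, the continuous `total_ld` covariate, and optional interaction
#' terms given as pairs of declared main terms. `scope` selects the rows:
#' the full analysis template, or only eQTLs and their matched controls (so
#' controls become the reference level and the eQTL indicator measures the
#' eQTL-vs-control contrast directly).
#'
#' @param terms Character vector of main-effect terms (annotation labels
#'   and/or `"total_ld"`, `"is_genic"`). No duplicates.
#' @param interactions List of length-2 character vectors; each element must
#'   reference declared main terms.
#' @param scope `"full"` or `"eqtl_controls"`.
#' @param center_total_ld Center total LD at 1 (its floor) so the intercept
#'   is the expected chi-squared of an unannotated LD-free variant.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(terms, interactions = list(),
                        scope = c("full", "eqtl_controls"),
                        center_total_ld = TRUE) {
  scope <- match.arg(scope)
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("duplicate terms in design")
  for (ia in interactions) {
    if (length(ia) != 2) stop("interactions must be pairs of terms")
    bad <- setdiff(ia, terms)
    if (length(bad))
      stop("interaction references undeclared term(s): ", paste(bad, collapse = ", "))
  }
  structure(list(terms = terms, interactions = interactions, scope = scope,
                 center_total_ld = center_total_ld),
            class = "design_spec")
}

term_name <- function(ia) paste(ia, collapse = " x ")

# Sanitize annotation labels etc. into syntactic design-matrix column names.
col_name <- function(x) gsub("[^A-Za-z0-9_.]", "_", x)

#' Build the design matrix and response for one pruning replicate
#'
#' One row per replicate variant in scope; 0/1 indicator coding for
#' annotation terms, `total_ld` passed through numerically (optionally
#' centered at 1), interactions as elementwise products of their parents'
#' columns.
#'
#' @param variants Variant table.
#' @param stats Association table (`variant_id`, `z2`).
#' @param replicate_ids Character vector of variant ids in the replicate.
#' @param sets Named list of `annotation_set`s supplying indicator terms.
#' @param spec A `design_spec`.
#' @return List with `X` (model matrix incl. intercept), `y` (chi-squared
#'   response), `ids` (row variant ids), `term_map` (display name for each
#'   non-intercept column).
#' @export
build_design <- function(variants, stats, replicate_ids, sets, spec) {
  stopifnot(inherits(spec, "design_spec"))
  ids <- intersect(replicate_ids, intersect(variants$variant_id, stats$variant_id))
  if (!length(ids)) stop("replicate has no variants with statistics")

  in_scope <- if (spec$scope == "eqtl_controls") {
    scope_sets <- sets[grepl("^(eqtl|control):", vapply(sets, `[[`, "", "label"))]
    if (!length(scope_sets)) stop("eqtl_controls scope but no eqtl:/control: sets")
    ids %in% unique(unlist(lapply(scope_sets, `[[`, "variant_ids")))
  } else rep(TRUE, length(ids))
  ids <- ids[in_scope]
  if (!length(ids)) stop("no variants in scope for this replicate")

  vrow <- match(ids, variants$variant_id)
  srow <- match(ids, stats$variant_id)
  y <- stats$z2[srow]

  cols <- list()
  display <- character(0)
  for (tm in spec$terms) {
    x <- if (tm == "total_ld") {
      tl <- variants$total_ld[vrow]
      if (anyNA(tl)) stop("total_ld missing for some in-scope variants")
      if (spec$center_total_ld) tl - 1 else tl
    } else if (tm == "is_genic") {
      as.numeric(variants$is_genic[vrow])
    } else {
      if (!tm %in% names(sets)) stop("no annotation set for term: ", tm)
      as.numeric(ids %in% sets[[tm]]$variant_ids)
    }
    cols[[col_name(tm)]] <- x
    display <- c(display, tm)
  }
  for (ia in spec$interactions) {
    cols[[col_name(term_name(ia))]] <-
      cols[[col_name(ia[1])]] * cols[[col_name(ia[2])]]
    display <- c(display, term_name(ia))
  }
  X <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  const <- which(apply(X[, -1, drop = FALSE], 2, function(v) length(unique(v)) == 1))
  if (length(const))
    stop("constant design column(s) within replicate: ",
         paste(display[const], collapse = ", "))
  names(display) <- colnames(X)[-1]
  list(X = X, y = y, ids = ids, term_map = display)
}

#' Fit the chi-squared general linear model
#'
#' Ordinary least squares (Gaussian family, identity link) of the 1-df
#' association chi-squared on the design; per-term two-sided p-values from
#' the t statistic. Chi-squared responses are right-skewed and
#' heteroskedastic, so these standard errors are the conventional, slightly
#' optimistic ones; `robust = TRUE` switches to heteroskedasticity-consistent
#' (HC1) standard errors.
#'
#' @param design Output of [build_design()], or a bare numeric matrix (then
#'   `y` must be given).
#' @param y Response vector when `design` is a bare matrix.
#' @param robust Use HC1 sandwich standard errors.
#' @return data.frame with columns `term`, `beta`, `se`, `p`, and attribute
#'   `n` (rows used).
#' @export
fit_chisq_glm <- function(design, y = NULL, robust = FALSE) {
  if (is.list(design) && !is.null(design$X)) {
    X <- design$X; y <- design$y
    term_map <- design$term_map
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    term_map <- stats::setNames(colnames(X), colnames(X))
  }
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop("need more rows than columns")
  qx <- qr(X)
  if (qx$rank < k) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):k]]
    hit <- dropped %in% names(term_map)
    dropped[hit] <- term_map[dropped[hit]]
    stop("rank-deficient design; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  XtX_inv <- solve(crossprod(X))
  if (robust) {
    meat <- crossprod(X * as.vector(res))
    vc <- XtX_inv %*% meat %*% XtX_inv * n / (n - k)
  } else {
    s2 <- sum(res^2) / (n - k)
    vc <- XtX_inv * s2
  }
  se <- sqrt(diag(vc))
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = n - k, lower.tail = FALSE)
  terms <- colnames(X)
  terms[terms %in% names(term_map)] <- term_map[terms[terms %in% names(term_map)]]
  out <- data.frame(term = terms, beta = as.numeric(beta), se = se, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n") <- n
  out
}

#' Meta-analyse per-replicate model fits
#'
#' Combines the per-replicate coefficients of each term across the pruning
#' replicates: the reported effect size `beta_bar` is the plain mean of the
#' replicate coefficients; significance comes from fixed-effect
#' inverse-variance pooling of the replicate (beta, SE) pairs, with the 95%
#' confidence interval from the pooled standard error around the pooled
#' estimate. Replicates overlap by construction, so the pooled standard
#' error understates the true sampling error and the meta p-values are
#' anti-conservative; this mirrors the replicate-averaging convention the
#' procedure follows and is reported as-is, not corrected.
#'
#' @param fits List of per-replicate fit tables from [fit_chisq_glm()];
#'   every replicate must contain every term.
#' @return An object of class `enrichment_fit`: data.frame with one row per
#'   term (`term`, `beta_bar`, `beta_ivw`, `se_meta`, `ci_low`, `ci_high`,
#'   `p`) plus per-replicate coefficient matrix in attribute
#'   `"replicate_beta"` and per-replicate n in attribute `"n"`.
#' @export
meta_analyze <- function(fits) {
  if (!length(fits)) stop("no replicate fits")
  terms <- fits[[1]]$term
  for (f in fits) {
    miss <- setdiff(terms, f$term)
    extra <- setdiff(f$term, terms)
    if (length(miss) || length(extra))
      stop("replicate fits disagree on terms: ",
           paste(c(miss, extra), collapse = ", "))
  }
  B <- sapply(fits, function(f) f$beta[match(terms, f$term)])
  S <- sapply(fits, function(f) f$se[match(terms, f$term)])
  if (is.null(dim(B))) { B <- matrix(B, nrow = length(terms)); S <- matrix(S, nrow = length(terms)) }
  w <- 1 / S^2
  beta_ivw <- rowSums(B * w) / rowSums(w)
  se_meta <- sqrt(1 / rowSums(w))
  z <- beta_ivw / se_meta
  out <- data.frame(term = terms,
                    beta_bar = rowMeans(B),
                    beta_ivw = beta_ivw,
                    se_meta = se_meta,
                    ci_low = beta_ivw - stats::qnorm(0.975) * se_meta,
                    ci_high = beta_ivw + stats::qnorm(0.975) * se_meta,
                    p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "replicate_beta") <- B
  attr(out, "replicate_se") <- S
  attr(out, "n") <- vapply(fits, function(f)
    as.numeric(attr(f, "n", exact = TRUE) %||% NA_real_), numeric(1))
  class(out) <- c("enrichment_fit", "data.frame")
  out
}

#' @export
print.enrichment_fit <- function(x, ...) {
  cat(sprintf("<enrichment_fit> %d terms over %d replicates\n",
              nrow(x), ncol(attr(x, "replicate_beta"))))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Fit the model on every replicate and meta-analyse
#'
#' Convenience wrapper: [build_design()] + [fit_chisq_glm()] per replicate,
#' then [meta_analyze()].
#'
#' @inheritParams build_design
#' @param replicates A `prune_replicates` object.
#' @param robust Passed to [fit_chisq_glm()].
#' @return An `enrichment_fit`.
#' @export
fit_replicates <- function(variants, stats, replicates, sets, spec,
                           robust = FALSE) {
  stopifnot(inherits(replicates, "prune_replicates"))
  fits <- lapply(replicates$replicate_sets, function(ids)
    fit_chisq_glm(build_design(variants, stats, ids, sets, spec), robust = robust))
  meta_analyze(fits)
}

#' Interaction scan: eQTL-by-annotation effect modification
#'
#' Extends a base design with eQTL-by-chromatin-state and (optionally)
#' eQTL-by-total-LD interaction terms, fits on every replicate, and
#' meta-analyses. A significant interaction means the eQTL excess of
#' association differs inside that category; the total-LD interaction
#' captures enrichment attributable to the eQTLs beyond their LD-tagging
#' power. Main effects are always retained.
#'
#' @inheritParams fit_replicates
#' @param eqtl_terms Character vector of eQTL main terms to interact.
#' @param with_terms Character vector of terms to interact them with
#'   (chromatin-state labels, `"total_ld"`, ...); must be in the base spec.
#' @param base_spec A `design_spec` holding the main effects.
#' @return An `enrichment_fit` including the interaction rows.
#' @export
interaction_scan <- function(variants, stats, replicates, sets, base_spec,
                             eqtl_terms, with_terms, robust = FALSE) {
  stopifnot(inherits(base_spec, "design_spec"))
  inter <- list()
  for (e in eqtl_terms) for (w in with_terms) inter <- c(inter, list(c(e, w)))
  spec <- design_spec(base_spec$terms, interactions = c(base_spec$interactions, inter),
                      scope = base_spec$scope,
                      center_total_ld = base_spec$center_total_ld)
  fit_replicates(variants, stats, replicates, sets, spec, robust = robust)
}

#' Write an enrichment fit as TSV
#'
#' One row per term with the meta-analysed columns followed by the
#' per-replicate coefficients (`beta_r1`, `beta_r2`, ...).
#'
#' @param x An `enrichment_fit`.
#' @param path Output path.
#' @export
write_enrichment_fit <- function(x, path) {
  stopifnot(inherits(x, "enrichment_fit"))
  B <- attr(x, "replicate_beta")
  tab <- cbind(as.data.frame(x),
               stats::setNames(as.data.frame(B),
                               paste0("beta_r", seq_len(ncol(B)))))
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE)
  invisible(path)
}
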