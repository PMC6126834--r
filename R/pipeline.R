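#' Run the full stratified-enrichment pipeline on an input directory
#'
#' Orchestrates ingest, LD pruning, intergenic genomic control, stratified
#' Q-Q / fold-enrichment curves, Mann-Whitney comparisons, pi1 estimation,
#' the chi-squared general linear model with the interaction scan, and the
#' locus-overlap analysis, for every trait found in the directory. The
#' directory layout is the one [make_fixture()] writes (and any real data
#' arranged the same way): `variants.tsv`, `ld_pairs.tsv`, `template.txt`,
#' `eqtl_table.tsv`, `roadmap.bed`, `control_<tissue>.txt`,
#' `gwas_<trait>.tsv`, optional `loci.tsv`.
#'
#' Annotation terms whose indicator would be constant inside some pruning
#' replicate (e.g. a category with no in-scope members) are dropped from the
#' model with a message rather than aborting the stage.
#'
#' @param dir Input directory.
#' @param out_dir Optional output directory; when given, result tables are
#'   written as TSV/JSON alongside a manifest.
#' @param n_sets Number of pruning replicates.
#' @param r2_max,window_bp Pruning parameters.
#' @param prune_seed Seed for the pruning permutations.
#' @param fdr_max eQTL designation threshold when reading the eQTL table.
#' @param tss_threshold Proximal/distal split (bp).
#' @param scope Model scope for the main fit (`"eqtl_controls"` keeps
#'   matched controls as the reference level).
#' @param interactions Run the eQTL-by-category interaction scan.
#' @param overlap_K,overlap_N Baseline counts for the locus-overlap ratio
#'   (annotation-represented and total independent genomic loci). Defaults:
#'   K = eQTLs in the template, N = mean pruning-replicate size (the
#'   in-universe count of near-independent variants).
#' @return An object of class `stratenrich_results`: nested list with
#'   `gc`, `fits`, `interaction`, `per_set` (curves/tests per trait and
#'   set), `overlap`, `summary` (the cross-trait summary table), `log`.
#' @export
run_enrichment_pipeline <- function(dir, out_dir = NULL, n_sets = 10,
                                    r2_max = 0.2, window_bp = 1e6,
                                    prune_seed = 1L, fdr_max = 0.01,
                                    tss_threshold = 25000,
                                    scope = "eqtl_controls",
                                    interactions = TRUE,
                                    overlap_K = NULL, overlap_N = NULL) {
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- ingest ----------------------------------------------------------
  inp <- stage("ingest", {
    variants <- read_variant_table(file.path(dir, "variants.tsv"))
    ld_pairs <- read_ld_pairs(file.path(dir, "ld_pairs.tsv"))
    template <- readLines(file.path(dir, "template.txt"))
    eqtl <- read_eqtl_table(file.path(dir, "eqtl_table.tsv"), fdr_max = fdr_max)
    sets <- eqtl$sets
    bed_path <- file.path(dir, "roadmap.bed")
    if (file.exists(bed_path))
      sets <- c(sets, read_bed_annotations(bed_path, variants))
    for (f in list.files(dir, pattern = "^control_.*\\.txt$", full.names = TRUE)) {
      s <- read_annotation_set(f)
      sets[[s$label]] <- s
    }
    if (length(sets) == 0) stop("no annotation sets found")
    tissues <- sub("^eqtl:", "", grep("^eqtl:", names(sets), value = TRUE))
    tissues <- setdiff(tissues, "all")
    if (!"eqtl:all" %in% names(sets) && length(tissues)) {
      ids <- unique(unlist(lapply(sets[paste0("eqtl:", tissues)], `[[`, "variant_ids")))
      sets[["eqtl:all"]] <- annotation_set("eqtl:all", ids, "union of tissues")
    }
    r <- restrict_to_template(variants, stats = NULL, template = template,
                              sets = sets)
    variants <- r$variants; sets <- r$sets
    if (anyNA(variants$total_ld))
      variants$total_ld <- total_ld_score(variants, ld_pairs, window_bp)
    pd <- assign_proximal_distal(variants, threshold = tss_threshold)
    sets$proximal <- pd$proximal; sets$distal <- pd$distal
    gwas_files <- list.files(dir, pattern = "^gwas_.*\\.tsv$", full.names = TRUE)
    if (!length(gwas_files)) stop("no gwas_<trait>.tsv files in ", dir)
    list(variants = variants, ld_pairs = ld_pairs, sets = sets,
         tissues = tissues, gwas_files = gwas_files)
  })
  note("ingest: %d variants, %d LD pairs, %d annotation sets, %d GWAS",
       nrow(inp$variants), nrow(inp$ld_pairs), length(inp$sets),
       length(inp$gwas_files))

  # ---- pruning ---------------------------------------------------------
  replicates <- stage("prune",
    random_prune(inp$variants, inp$ld_pairs, r2_max = r2_max,
                 window_bp = window_bp, n_sets = n_sets, seed = prune_seed))
  note("prune: %d replicates, sizes %s", n_sets,
       paste(range(lengths(replicates$replicate_sets)), collapse = "-"))

  results <- list(replicates = replicates, gc = list(), fits = list(),
                  interaction = list(), per_set = list(), overlap = NULL,
                  log = NULL)

  roadmap_terms <- grep("^roadmap:", names(inp$sets), value = TRUE)
  eqtl_terms <- paste0("eqtl:", inp$tissues)

  loci_path <- file.path(dir, "loci.tsv")
  loci <- if (file.exists(loci_path))
    data.table::fread(loci_path, data.table = FALSE) else NULL

  summary_rows <- list()
  for (gf in inp$gwas_files) {
    trait <- sub("^gwas_(.*)\\.tsv$", "\\1", basename(gf))

    stats <- stage(paste0("gwas:", trait), {
      st <- read_gwas(gf, trait = trait)
      restrict_to_template(inp$variants, st, inp$variants$variant_id)$stats
    })

    gc <- stage(paste0("gc:", trait),
                gc_lambda(stats, inp$variants, replicates))
    note("gc[%s]: lambda = %.4f", trait, gc$lambda_gc)
    stats <- apply_gc(stats, gc)
    results$gc[[trait]] <- gc

    # per-set curves, rank tests, pi1 (full, unpruned variant set)
    z2 <- stats$z2; names(z2) <- stats$variant_id
    p <- stats$p; names(p) <- stats$variant_id
    for (ts in inp$tissues) {
      el <- paste0("eqtl:", ts); cl <- paste0("control:", ts)
      if (!cl %in% names(inp$sets)) next
      eids <- intersect(inp$sets[[el]]$variant_ids, stats$variant_id)
      cids <- intersect(inp$sets[[cl]]$variant_ids, stats$variant_id)
      if (!length(eids) || !length(cids)) next
      res <- stage(paste0("curves:", trait, ":", ts), list(
        qq = qq_points(p[eids]),
        fold = fold_enrichment(p[eids], p[cids]),
        mw = mann_whitney(z2[eids], z2[cids]),
        pi1_eqtl = estimate_pi1(p[eids]),
        pi1_control = estimate_pi1(p[cids])))
      results$per_set[[trait]][[ts]] <- res
    }

    # chi-squared GLM, meta-analysed over replicates; drop terms that are
    # constant in some replicate instead of failing the stage
    fit <- stage(paste0("glm:", trait), {
      terms <- c(eqtl_terms, roadmap_terms, "total_ld")
      spec <- design_spec(terms, scope = scope)
      fit_with_usable_terms(inp$variants, stats, replicates, inp$sets, spec, note)
    })
    results$fits[[trait]] <- fit

    if (interactions) {
      results$interaction[[trait]] <- stage(paste0("interaction:", trait), {
        base_terms <- intersect(c(eqtl_terms, roadmap_terms, "total_ld"),
                                c(fit$term, "total_ld"))
        usable_eqtl <- intersect(eqtl_terms, base_terms)
        usable_with <- intersect(c(roadmap_terms, "total_ld"), base_terms)
        inter <- list()
        for (e in usable_eqtl) for (w in usable_with)
          inter <- c(inter, list(c(e, w)))
        spec <- design_spec(base_terms, interactions = inter, scope = scope)
        fit_with_usable_terms(inp$variants, stats, replicates, inp$sets,
                              spec, note)
      })
    }

    for (ts in names(results$per_set[[trait]])) {
      r <- results$per_set[[trait]][[ts]]
      el <- paste0("eqtl:", ts)
      brow <- match(el, fit$term)
      summary_rows[[paste(trait, ts)]] <- data.frame(
        trait = trait, set = el,
        pi1 = r$pi1_eqtl$pi1,
        mw_neglog10_p = -log10(r$mw$p),
        beta_bar = if (is.na(brow)) NA_real_ else fit$beta_bar[brow],
        glm_p = if (is.na(brow)) NA_real_ else fit$p[brow],
        stringsAsFactors = FALSE)
    }

    # locus overlap, first trait with loci available
    if (!is.null(loci) && nrow(loci) && is.null(results$overlap) &&
        "eqtl:all" %in% names(inp$sets)) {
      results$overlap <- stage("overlap", {
        ov <- overlap_loci(loci, inp$sets[["eqtl:all"]], inp$variants,
                           inp$ld_pairs)
        K <- overlap_K %||% length(inp$sets[["eqtl:all"]]$variant_ids)
        N <- overlap_N %||% round(mean(lengths(replicates$replicate_sets)))
        c(ov, list(summary = enrichment_ratio(ov$k_overlapping, ov$n_loci,
                                              K, N)))
      })
      note("overlap[%s]: %d/%d loci", trait, results$overlap$k_overlapping,
           results$overlap$n_loci)
    }
  }

  results$summary <- if (length(summary_rows))
    do.call(rbind, c(summary_rows, list(make.row.names = FALSE)))
  else data.frame()
  results$log <- log
  class(results) <- "stratenrich_results"

  if (!is.null(out_dir)) write_results(results, out_dir)
  results
}

# Fit dropping terms (mains or interactions) that come back constant or
# collinear within some replicate.
fit_with_usable_terms <- function(variants, stats, replicates, sets, spec,
                                  note = message) {
  repeat {
    ok <- tryCatch(
      fit_replicates(variants, stats, replicates, sets, spec),
      error = function(e) e)
    if (!inherits(ok, "error")) return(ok)
    msg <- conditionMessage(ok)
    m <- regmatches(msg, regexec(
      "(constant design column\\(s\\) within replicate|collinear term\\(s\\)): (.*)$",
      msg))[[1]]
    if (length(m) < 3) stop(ok)
    bad <- trimws(strsplit(m[3], ",")[[1]])
    bad_inter <- bad[grepl(" x ", bad, fixed = TRUE)]
    bad_main <- setdiff(bad, bad_inter)
    keep_terms <- setdiff(spec$terms, bad_main)
    keep_inter <- Filter(function(ia)
      !term_name(ia) %in% bad_inter && all(ia %in% keep_terms),
      spec$interactions)
    if (identical(keep_terms, spec$terms) &&
        length(keep_inter) == length(spec$interactions)) stop(ok)
    if (!length(keep_terms)) stop(ok)
    note("glm: dropping degenerate term(s): %s", paste(bad, collapse = ", "))
    spec <- design_spec(keep_terms, interactions = keep_inter,
                        scope = spec$scope,
                        center_total_ld = spec$center_total_ld)
  }
}

#' Cross-trait summary table
#'
#' One row per trait and eQTL set with the three enrichment measures: the
#' estimated proportion of non-null associations (pi1), the -log10
#' Mann-Whitney p-value for the chi-squared difference between the set and
#' its matched controls, and the meta-analysed model coefficient with its
#' p-value. These are the coordinates (and glyph sizes) of the standard
#' cross-trait enrichment scatter.
#'
#' @param results A `stratenrich_results` object.
#' @param path Optional path to also write the table as TSV.
#' @return data.frame with columns `trait`, `set`, `pi1`, `mw_neglog10_p`,
#'   `beta_bar`, `glm_p`.
#' @export
summary_table <- function(results, path = NULL) {
  stopifnot(inherits(results, "stratenrich_results"))
  tab <- results$summary
  if (!is.null(path))
    data.table::fwrite(tab, path, sep = "\t", quote = FALSE, na = "NA")
  tab
}

#' @export
print.stratenrich_results <- function(x, ...) {
  cat("<stratenrich_results>\n")
  cat("  traits:", paste(names(x$gc), collapse = ", "), "\n")
  for (tr in names(x$gc))
    cat(sprintf("  lambda_gc[%s] = %.4f\n", tr, x$gc[[tr]]$lambda_gc))
  if (NROW(x$summary)) {
    cat("  summary:\n")
    print.data.frame(x$summary, digits = 3)
  }
  invisible(x)
}

# Persist the result tables; large intermediates stay in memory.
write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (tr in names(results$gc))
    write_gc_factor(results$gc[[tr]], file.path(out_dir, paste0("gc_", tr, ".json")))
  for (tr in names(results$fits))
    write_enrichment_fit(results$fits[[tr]],
                         file.path(out_dir, paste0("glm_", tr, ".tsv")))
  for (tr in names(results$interaction))
    write_enrichment_fit(results$interaction[[tr]],
                         file.path(out_dir, paste0("interaction_", tr, ".tsv")))
  if (!is.null(results$overlap)) {
    write_overlap_detail(results$overlap, file.path(out_dir, "overlap_detail.tsv"))
    jsonlite::write_json(unclass(results$overlap$summary),
                         file.path(out_dir, "overlap_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (NROW(results$summary))
    summary_table(results, file.path(out_dir, "summary.tsv"))
  writeLines(results$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}
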