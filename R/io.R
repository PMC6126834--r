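#' Read GWAS summary statistics
#'
#' Reads a tab- or whitespace-delimited summary-statistics file with a header
#' and returns one association record per retained row. Rows with a missing
#' variant id or an unparseable / out-of-range p-value (p <= 0 or p > 1) are
#' dropped and counted; exact zeros, common in large GWAS exports where the
#' true p underflows double precision, are clamped to `p_floor` with a
#' warning rather than dropped, so top hits survive ingestion.
#'
#' @param path Path to the summary-statistics file.
#' @param column_map Named list mapping the roles `snp`, `chrom`, `pos`, `p`,
#'   `n` to column names in the file. Only `snp` and `p` are mandatory.
#' @param trait Trait name stored with each record.
#' @param p_floor Clamping floor for p = 0 entries.
#' @return A `data.frame` with columns `variant_id`, `p`, `z2` (the 1-df
#'   chi-squared recovered from the two-sided p), `trait`, plus `chrom`,
#'   `pos`, `n` when mapped. Attribute `n_dropped` counts discarded rows.
#' @seealso [chisq_from_p()]
#' @export
read_gwas <- function(path,
                      column_map = list(snp = "SNP", chrom = "CHR", pos = "BP",
                                        p = "P", n = "N"),
                      trait = "trait", p_floor = 1e-300) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = TRUE)
  if (nrow(dt) == 0L) stop("empty GWAS file: ", path)
  for (role in c("snp", "p")) {
    col <- column_map[[role]]
    if (is.null(col) || !col %in% names(dt))
      stop("GWAS file is missing mandated column '", col %||% role,
           "' (role: ", role, ")")
  }
  p <- suppressWarnings(as.numeric(dt[[column_map$p]]))
  id <- as.character(dt[[column_map$snp]])

  clamped <- !is.na(p) & p == 0
  if (any(clamped)) {
    warning(sum(clamped), " rows with p = 0 clamped to ", p_floor)
    p[clamped] <- p_floor
  }
  keep <- !is.na(p) & p > 0 & p <= 1 & !is.na(id) & nzchar(id)
  n_dropped <- sum(!keep)

  out <- data.frame(variant_id = id[keep], p = p[keep], stringsAsFactors = FALSE)
  for (role in c("chrom", "pos", "n")) {
    col <- column_map[[role]]
    if (!is.null(col) && col %in% names(dt)) out[[role]] <- dt[[col]][keep]
  }
  out$z2 <- chisq_from_p(out$p)
  out$trait <- trait
  attr(out, "n_dropped") <- n_dropped
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an eQTL table
#'
#' Tab-delimited table with columns `SNP`, `gene`, `tissue`, `tss_dist`,
#' `fdr` (configurable names). Returns the table plus per-tissue
#' `annotation_set`s of the variants designated at `fdr_max`.
#'
#' @param path Path to the eQTL TSV.
#' @param fdr_max Designation threshold; rows with `fdr` above it are kept in
#'   the table but excluded from the per-tissue sets.
#' @param registry Optional `annotation_registry` for the `eqtl:<tissue>` labels.
#' @return A list with elements `table` (data.frame) and `sets` (named list
#'   of `annotation_set`, one per tissue).
#' @export
read_eqtl_table <- function(path, fdr_max = 0.01, registry = NULL) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("SNP", "gene", "tissue", "tss_dist", "fdr")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("eQTL table missing column(s): ", paste(miss, collapse = ", "))
  sets <- lapply(split(dt, dt$tissue), function(d) {
    keep <- d$SNP[d$fdr <= fdr_max]
    annotation_set(paste0("eqtl:", d$tissue[1]), keep,
                   provenance = paste0("designated at FDR <= ", fdr_max),
                   registry = registry)
  })
  names(sets) <- paste0("eqtl:", names(sets))
  list(table = dt, sets = sets)
}

#' Annotate variants with BED intervals
#'
#' Reads a BED file (0-based, half-open intervals; BED4's fourth column gives
#' the category) and returns one `annotation_set` per category containing the
#' variants falling inside that category's intervals. A 1-based variant
#' position P lies inside \[start, end) iff start <= P - 1 < end; the
#' coordinate conversion lives here and nowhere else.
#'
#' @param path Path to a BED3/BED4 file.
#' @param variants Variant table with columns `variant_id`, `chrom`, `pos`.
#' @param label_prefix Prefix applied to BED names to form labels
#'   (default `"roadmap:"`). BED3 files get the single label
#'   `paste0(label_prefix, "all")`.
#' @param registry Optional `annotation_registry`.
#' @return Named list of `annotation_set`s, one per BED name.
#' @export
read_bed_annotations <- function(path, variants, label_prefix = "roadmap:",
                                 registry = NULL) {
  bed <- utils::read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED file needs at least 3 columns: ", path)
  names(bed)[1:3] <- c("chrom", "start", "end")
  bed$name <- if (ncol(bed) >= 4) as.character(bed[[4]]) else "all"
  if (any(bed$start > bed$end))
    stop("BED interval with start > end at line ",
         which(bed$start > bed$end)[1])
  unknown <- setdiff(unique(bed$chrom), unique(variants$chrom))
  if (length(unknown)) {
    warning("skipping BED intervals on unknown chromosome(s): ",
            paste(unknown, collapse = ", "))
    bed <- bed[!bed$chrom %in% unknown, , drop = FALSE]
  }
  v_gr <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos, width = 1L))
  out <- lapply(split(bed, bed$name), function(b) {
    # BED 0-based half-open [start, end) -> 1-based closed [start+1, end]
    b_gr <- GenomicRanges::GRanges(b$chrom,
                                   IRanges::IRanges(b$start + 1L, b$end))
    hit <- IRanges::overlapsAny(v_gr, b_gr)
    annotation_set(paste0(label_prefix, b$name[1]), variants$variant_id[hit],
                   provenance = paste0("BED ", basename(path)),
                   registry = registry)
  })
  names(out) <- paste0(label_prefix, names(out))
  out
}

#' Read pairwise LD
#'
#' Reads the common pairwise dialect (columns `SNP_A`, `BP_A`, `SNP_B`,
#' `BP_B`, `R2`; extra columns ignored). Pairs are unordered; absent pairs
#' are treated as r-squared 0 throughout the package.
#'
#' @param path Path to the LD-pairs TSV.
#' @return data.frame with columns `id_a`, `pos_a`, `id_b`, `pos_b`, `r2`,
#'   `distance`.
#' @export
read_ld_pairs <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("SNP_A", "BP_A", "SNP_B", "BP_B", "R2")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("LD file missing column(s): ", paste(miss, collapse = ", "))
  if (any(dt$R2 < 0 | dt$R2 > 1)) stop("R2 outside [0, 1] in ", path)
  data.frame(id_a = as.character(dt$SNP_A), pos_a = dt$BP_A,
             id_b = as.character(dt$SNP_B), pos_b = dt$BP_B,
             r2 = dt$R2, distance = abs(dt$BP_B - dt$BP_A),
             stringsAsFactors = FALSE)
}

#' Write / read the variant table
#'
#' The variant table is an ordinary data.frame with one row per variant and
#' the documented column order `variant_id`, `chrom`, `pos`, `maf`,
#' `is_genic`, `tss_distance`, `total_ld` (the last two may be `NA`).
#' Persisted as TSV; round-trips exactly.
#'
#' @param variants Variant table.
#' @param path File path.
#' @export
write_variant_table <- function(variants, path) {
  cols <- c("variant_id", "chrom", "pos", "maf", "is_genic", "tss_distance",
            "total_ld")
  miss <- setdiff(cols, names(variants))
  for (m in miss) variants[[m]] <- NA
  data.table::fwrite(variants[, cols], path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  v <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE,
                         na.strings = "NA")
  v$variant_id <- as.character(v$variant_id)
  v$chrom <- as.character(v$chrom)
  stopifnot(all(v$pos >= 1), all(v$maf >= 0 & v$maf <= 0.5, na.rm = TRUE))
  v
}

#' Restrict variants and statistics to a template
#'
#' High-quality variant templates (the common, well-imputed variants shared
#' by all GWAS in a project) define the analysis universe. This drops
#' variants outside the template and re-projects association statistics and
#' annotation sets onto it; restriction is idempotent.
#'
#' @param variants Variant table.
#' @param stats Optional association table (from [read_gwas()]).
#' @param template Character vector of variant ids, nonempty.
#' @param sets Optional (possibly nested) list of `annotation_set`s to
#'   re-project.
#' @return List with `variants`, `stats`, `sets` restricted to the template.
#' @export
restrict_to_template <- function(variants, stats = NULL, template, sets = NULL) {
  if (!length(template)) stop("empty template")
  keep <- variants$variant_id %in% template
  if (!any(keep)) stop("template does not intersect the variant table")
  variants <- variants[keep, , drop = FALSE]
  rownames(variants) <- NULL
  universe <- variants$variant_id
  if (!is.null(stats)) {
    stats <- stats[stats$variant_id %in% universe, , drop = FALSE]
    rownames(stats) <- NULL
  }
  if (!is.null(sets)) sets <- project_sets(sets, universe)
  list(variants = variants, stats = stats, sets = sets)
}

project_sets <- function(sets, universe) {
  if (inherits(sets, "annotation_set")) {
    sets$variant_ids <- intersect(sets$variant_ids, universe)
    return(sets)
  }
  lapply(sets, project_sets, universe = universe)
}

#' Assign proximal / distal labels by TSS distance
#'
#' Variants at absolute TSS distance at or below the threshold are labelled
#' proximal, above it distal; variants without a TSS distance get neither
#' label. The default 25 kb threshold splits typical cis-eQTL catalogues into
#' two roughly equal halves; `threshold = "median"` picks the median distance
#' so the two categories differ in size by at most one.
#'
#' @param variants Variant table with a `tss_distance` column.
#' @param threshold Base pairs, or the string `"median"`.
#' @return List of two `annotation_set`s, `proximal` and `distal`; the chosen
#'   threshold is stored in attribute `"threshold"`.
#' @export
assign_proximal_distal <- function(variants, threshold = 25000) {
  d <- variants$tss_distance
  if (any(d < 0, na.rm = TRUE)) stop("negative tss_distance")
  has <- !is.na(d)
  if (identical(threshold, "median")) threshold <- stats::median(d[has])
  stopifnot(is.numeric(threshold), threshold >= 0)
  out <- list(
    proximal = annotation_set("proximal",
                              variants$variant_id[has & d <= threshold],
                              provenance = paste0("tss_distance <= ", threshold)),
    distal = annotation_set("distal",
                            variants$variant_id[has & d > threshold],
                            provenance = paste0("tss_distance > ", threshold))
  )
  attr(out, "threshold") <- threshold
  out
}
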