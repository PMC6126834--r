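#' Annotation registry
#'
#' A registry declares the annotation labels a project is allowed to use.
#' Operations that attach labels to variants check against the registry so
#' that typos ("eqtl:adpiose") fail loudly instead of silently creating an
#' empty stratum.
#'
#' Labels follow the convention `class:instance`, e.g. `eqtl:adipose`,
#' `control:adipose`, `roadmap:active_promoter`, plus the bare positional
#' labels `proximal` and `distal`.
#'
#' @param labels Character vector of allowed labels.
#' @return An object of class `annotation_registry`.
#' @examples
#' reg <- annotation_registry(c("eqtl:adipose", "control:adipose", "proximal", "distal"))
#' @export
annotation_registry <- function(labels) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate labels in registry")
  structure(list(labels = labels), class = "annotation_registry")
}

#' Default annotation registry
#'
#' Registry covering the labels used throughout the package: per-tissue eQTL
#' and matched-control sets, the four chromatin-state (Roadmap-style)
#' categories, and the proximal/distal split at the TSS-distance threshold.
#'
#' @param tissues Character vector of tissue names.
#' @param roadmap Character vector of chromatin-state category names.
#' @return An `annotation_registry`.
#' @export
default_registry <- function(tissues = c("adipose", "epidermal", "lcl", "blood"),
                             roadmap = c("active_promoter", "weak_promoter",
                                         "strong_enhancer", "weak_enhancer")) {
  annotation_registry(c(
    paste0("eqtl:", tissues),
    paste0("control:", tissues),
    "eqtl:all", "control:all",
    paste0("roadmap:", roadmap),
    "proximal", "distal"
  ))
}

check_label <- function(label, registry = NULL) {
  if (!is.null(registry)) {
    stopifnot(inherits(registry, "annotation_registry"))
    bad <- setdiff(label, registry$labels)
    if (length(bad))
      stop("label(s) not in registry: ", paste(bad, collapse = ", "))
  }
  invisible(label)
}

#' Construct an annotation set
#'
#' An annotation set is a labelled collection of variant ids (an eQTL set for
#' one tissue, its matched controls, a chromatin-state category, ...), with
#' free-text provenance recording where it came from.
#'
#' @param label Label for the set (checked against `registry` when given).
#' @param variant_ids Character vector of variant ids; de-duplicated.
#' @param provenance Free text (tissue, FDR level, track id, ...).
#' @param registry Optional `annotation_registry` to validate `label` against.
#' @return An object of class `annotation_set`.
#' @examples
#' annotation_set("eqtl:adipose", c("rs1", "rs2"), provenance = "designated at FDR 0.01")
#' @export
annotation_set <- function(label, variant_ids, provenance = "", registry = NULL) {
  check_label(label, registry)
  structure(list(label = as.character(label)[1],
                 variant_ids = unique(as.character(variant_ids)),
                 provenance = paste(provenance, collapse = "; ")),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s: %d variants", x$label, length(x$variant_ids)))
  if (nzchar(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$variant_ids)

#' Combine two annotation sets
#'
#' Set algebra over variant-id sets: used to build consensus sets
#' (intersection of two eQTL catalogues designated at the same FDR), to pool
#' tissues (union), and to exclude multi-tissue "double agent" eQTLs
#' (difference). Provenance strings are concatenated.
#'
#' @param a,b `annotation_set` objects over the same variant universe.
#' @param mode One of `"union"`, `"intersection"`, `"difference"`
#'   (`a` minus `b`).
#' @param label Label for the result; defaults to a descriptive combination.
#' @return An `annotation_set`.
#' @examples
#' a <- annotation_set("eqtl:adipose", c("rs1", "rs2", "rs3"))
#' b <- annotation_set("eqtl:blood", c("rs2", "rs3", "rs4"))
#' length(combine_sets(a, b, "intersection"))  # 2
#' @export
combine_sets <- function(a, b, mode = c("union", "intersection", "difference"),
                         label = NULL) {
  stopifnot(inherits(a, "annotation_set"), inherits(b, "annotation_set"))
  mode <- match.arg(mode)
  ids <- switch(mode,
    union = union(a$variant_ids, b$variant_ids),
    intersection = intersect(a$variant_ids, b$variant_ids),
    difference = setdiff(a$variant_ids, b$variant_ids)
  )
  if (is.null(label))
    label <- paste0(a$label, ".", substr(mode, 1, 5), ".", b$label)
  annotation_set(label, ids,
                 provenance = paste0(mode, "(", a$provenance, " | ", b$provenance, ")"))
}

#' Pairwise overlap fraction between two annotation sets
#'
#' Size of the intersection divided by the mean set size; the statistic used
#' to describe tissue sharing of eQTL sets.
#'
#' @param a,b `annotation_set` objects.
#' @return Numeric scalar in \[0, 1\].
#' @export
overlap_fraction <- function(a, b) {
  n <- length(intersect(a$variant_ids, b$variant_ids))
  n / mean(c(length(a$variant_ids), length(b$variant_ids)))
}

#' Write / read an annotation set as plain text
#'
#' One header line `#label<TAB>provenance`, then one variant id per line.
#' Round-trips exactly.
#'
#' @param x An `annotation_set`.
#' @param path File path.
#' @return `write_annotation_set` returns `path` invisibly;
#'   `read_annotation_set` returns an `annotation_set`.
#' @export
write_annotation_set <- function(x, path) {
  stopifnot(inherits(x, "annotation_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", x$label, "\t", x$provenance), con)
  writeLines(x$variant_ids, con)
  invisible(path)
}

#' @rdname write_annotation_set
#' @export
read_annotation_set <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("not an annotation-set file (missing '#label' header): ", path)
  hdr <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  annotation_set(hdr[1], lines[-1],
                 provenance = if (length(hdr) > 1) hdr[2] else "")
}
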