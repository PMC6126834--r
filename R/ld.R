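#' Total LD score
#'
#' Conventional per-variant total LD score: 1 (the variant's own
#' contribution) plus the sum of r-squared with all partners within
#' `window_bp`. A variant with no listed partners scores exactly 1; pairs
#' missing from the list count as r-squared 0.
#'
#' @param variants Variant table (`variant_id` column), or a character vector
#'   of ids.
#' @param ld_pairs Pairwise LD table from [read_ld_pairs()].
#' @param window_bp Window in base pairs within which partners count.
#' @return Numeric vector of scores (>= 1), aligned with the input ids.
#' @export
total_ld_score <- function(variants, ld_pairs, window_bp = 1e6) {
  ids <- if (is.data.frame(variants)) variants$variant_id else as.character(variants)
  score <- rep(1, length(ids))
  names(score) <- ids
  if (NROW(ld_pairs)) {
    keep <- ld_pairs$distance <= window_bp
    lp <- ld_pairs[keep, , drop = FALSE]
    if (nrow(lp)) {
      add <- tapply(c(lp$r2, lp$r2), c(lp$id_a, lp$id_b), sum)
      common <- intersect(names(add), ids)
      score[common] <- score[common] + add[common]
    }
  }
  unname(score)
}

# Conflict adjacency for pruning: integer adjacency list over the variant
# table for pairs with r2 >= r2_max at distance <= window_bp.
build_conflict_graph <- function(variants, ld_pairs, r2_max, window_bp) {
  n <- nrow(variants)
  idx <- seq_len(n)
  names(idx) <- variants$variant_id
  if (!NROW(ld_pairs)) return(vector("list", n))
  lp <- ld_pairs[ld_pairs$r2 >= r2_max & ld_pairs$distance <= window_bp, , drop = FALSE]
  a <- idx[lp$id_a]; b <- idx[lp$id_b]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  adj <- vector("list", n)
  if (length(a)) {
    edges <- split(c(b, a), c(a, b))
    adj[as.integer(names(edges))] <- lapply(edges, unname)
  }
  adj
}

#' Random LD-based pruning replicates
#'
#' Builds `n_sets` near-independent variant subsets. Each replicate draws a
#' fresh random permutation of the variants (each considered once, i.e.
#' without replacement within the replicate) and greedily retains a variant
#' iff no already-retained variant within `window_bp` has r-squared at or
#' above `r2_max` with it; every replicate is maximal under its own ordering.
#' Replicates are independent draws and generally overlap; with
#' `disjoint = TRUE` later replicates exclude variants retained earlier
#' (they may then be far from maximal, or empty).
#'
#' Per-replicate seeds are derived from `seed` and recorded for exact replay.
#'
#' @param variants Variant table.
#' @param ld_pairs Pairwise LD table; absent pairs mean r-squared 0.
#' @param r2_max Conflict threshold (retained pairs all have r2 < r2_max).
#' @param window_bp Conflict window in base pairs.
#' @param n_sets Number of replicates (>= 1).
#' @param seed Integer master seed.
#' @param disjoint Force replicates to be mutually disjoint.
#' @return An object of class `prune_replicates`: list with
#'   `replicate_sets` (list of character vectors), `seeds`, `params`.
#' @export
random_prune <- function(variants, ld_pairs, r2_max = 0.2, window_bp = 1e6,
                         n_sets = 10, seed = 1L, disjoint = FALSE) {
  if (n_sets < 1) stop("n_sets must be >= 1")
  n <- nrow(variants)
  adj <- build_conflict_graph(variants, ld_pairs, r2_max, window_bp)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_sets)
  taken <- logical(n)  # used only when disjoint
  sets <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    set.seed(rep_seeds[s])
    ord <- sample.int(n)
    retained <- logical(n)
    for (v in ord) {
      if (disjoint && taken[v]) next
      nb <- adj[[v]]
      if (is.null(nb) || !any(retained[nb])) retained[v] <- TRUE
    }
    if (disjoint) taken <- taken | retained
    sets[[s]] <- variants$variant_id[retained]
  }
  structure(list(replicate_sets = sets, seeds = rep_seeds,
                 params = list(r2_max = r2_max, window_bp = window_bp,
                               disjoint = disjoint)),
            class = "prune_replicates")
}

#' @export
print.prune_replicates <- function(x, ...) {
  cat(sprintf("<prune_replicates> %d sets, sizes %s; r2 < %g within %g bp\n",
              length(x$replicate_sets),
              paste(range(lengths(x$replicate_sets)), collapse = "-"),
              x$params$r2_max, x$params$window_bp))
  invisible(x)
}

#' Persist / load pruning replicates
#'
#' One id-list file per replicate plus a JSON manifest recording seeds and
#' parameters.
#'
#' @param x A `prune_replicates` object.
#' @param dir Directory to write into (created if needed).
#' @export
write_prune_replicates <- function(x, dir) {
  stopifnot(inherits(x, "prune_replicates"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("replicate_%02d.txt", seq_along(x$replicate_sets))
  for (i in seq_along(files))
    writeLines(x$replicate_sets[[i]], file.path(dir, files[i]))
  jsonlite::write_json(list(seeds = x$seeds, params = x$params, files = files),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_prune_replicates
#' @export
read_prune_replicates <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  sets <- lapply(file.path(dir, man$files), readLines)
  structure(list(replicate_sets = sets, seeds = man$seeds,
                 params = as.list(man$params)),
            class = "prune_replicates")
}

#' LD window around a lead variant
#'
#' The locus tagged by a genome-wide-significant lead: the lead itself plus
#' every variant in high LD with it (r-squared at or above `r2_min`,
#' inclusive), and the genomic interval spanning those members on the lead's
#' chromosome.
#'
#' @param lead Variant id of the lead; must be present in `variants`.
#' @param variants Variant table.
#' @param ld_pairs Pairwise LD table.
#' @param r2_min High-LD threshold (inclusive).
#' @return List with `lead`, `members` (character vector incl. the lead),
#'   `chrom`, `start`, `end`.
#' @export
ld_window <- function(lead, variants, ld_pairs, r2_min = 0.8) {
  row <- match(lead, variants$variant_id)
  if (is.na(row)) stop("lead variant not in table: ", lead)
  partners <- character(0)
  if (NROW(ld_pairs)) {
    hit_a <- ld_pairs$id_a == lead & ld_pairs$r2 >= r2_min
    hit_b <- ld_pairs$id_b == lead & ld_pairs$r2 >= r2_min
    partners <- c(ld_pairs$id_b[hit_a], ld_pairs$id_a[hit_b])
  }
  members <- unique(c(lead, partners))
  chrom <- variants$chrom[row]
  in_tab <- variants$variant_id %in% members & variants$chrom == chrom
  pos <- variants$pos[in_tab]
  list(lead = lead, members = members, chrom = chrom,
       start = min(pos), end = max(pos))
}
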