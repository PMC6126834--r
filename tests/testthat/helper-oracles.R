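# Independent brute-force oracles and tiny fixture builders shared across
# the suite. Oracles deliberately avoid the code paths they check.

# Exact two-sided Mann-Whitney p by full enumeration of all group labelings.
mw_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- u_of(a, b)
  labelings <- utils::combn(length(pooled), na)
  us <- apply(labelings, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  p_low <- mean(us <= obs)
  p_high <- mean(us >= obs)
  min(1, 2 * min(p_low, p_high))
}

# Two-sided Fisher p by hypergeometric enumeration over all tables with the
# observed margins, summing probabilities <= P(observed) (with the standard
# relative-error guard).
fisher_enum_oracle <- function(k, n, K, N) {
  tot <- k + K
  xs <- max(0, tot - N):min(n, tot)
  prob <- vapply(xs, function(x)
    choose(n, x) * choose(N, tot - x) / choose(n + N, tot), numeric(1))
  p_obs <- prob[match(k, xs)]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Brute-force total LD score: scan every pair involving the variant.
total_ld_oracle <- function(id, ld_pairs, window_bp) {
  s <- 1
  for (i in seq_len(NROW(ld_pairs))) {
    if ((ld_pairs$id_a[i] == id || ld_pairs$id_b[i] == id) &&
        ld_pairs$distance[i] <= window_bp)
      s <- s + ld_pairs$r2[i]
  }
  s
}

# Exhaustive pruning-soundness scan: any retained pair violating the
# (r2 >= r2_max within window) constraint?
prune_violations <- function(set_ids, ld_pairs, r2_max, window_bp) {
  inset <- ld_pairs$id_a %in% set_ids & ld_pairs$id_b %in% set_ids
  sum(inset & ld_pairs$r2 >= r2_max & ld_pairs$distance <= window_bp)
}

# Brute-force BED membership for a single variant against raw intervals.
bed_member_oracle <- function(chrom, pos, bed) {
  any(bed$chrom == chrom & bed$start <= pos - 1 & pos - 1 < bed$end)
}

# Minimal hand-rolled variant table.
toy_variants <- function(n = 6, chrom = "chr1", pos = NULL) {
  data.frame(variant_id = paste0("v", seq_len(n)),
             chrom = chrom,
             pos = if (is.null(pos)) seq_len(n) * 1000 else pos,
             maf = seq(0.05, 0.45, length.out = n),
             is_genic = rep(c(TRUE, FALSE), length.out = n),
             tss_distance = seq(1000, 60000, length.out = n),
             total_ld = 1,
             stringsAsFactors = FALSE)
}

toy_ld <- function(id_a, id_b, r2, pos_a, pos_b) {
  data.frame(id_a = id_a, pos_a = pos_a, id_b = id_b, pos_b = pos_b,
             r2 = r2, distance = abs(pos_b - pos_a),
             stringsAsFactors = FALSE)
}

toy_stats <- function(variants, p) {
  data.frame(variant_id = variants$variant_id, p = p, z2 = chisq_from_p(p),
             trait = "t", stringsAsFactors = FALSE)
}
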