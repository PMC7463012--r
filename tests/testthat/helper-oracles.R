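# Independent oracles used to check the statistical primitives. These stay
# deliberately naive: direct pmf summation and exhaustive table enumeration,
# never the code paths they verify.

# P(X >= k) for X ~ Poisson(lam) by direct summation of the upper-tail pmf.
poisson_tail_oracle <- function(k, lam) {
  if (lam == 0) return(as.numeric(k == 0))
  upper <- ceiling(max(k, lam) + 20 * sqrt(lam + 1) + 60)
  sum(dpois(k:upper, lam))
}

# Two-sided Fisher p-value by exhaustive enumeration of all 2x2 tables with
# the observed margins, summing those no more probable than the observed one
# (minimum-likelihood rule, with the customary 1 + 1e-7 relative tolerance
# on the inclusion threshold).
fisher_oracle <- function(normal_ref, normal_alt, tumor_ref, tumor_alt) {
  r1 <- normal_ref + normal_alt
  r2 <- tumor_ref + tumor_alt
  cref <- normal_ref + tumor_ref
  calt <- normal_alt + tumor_alt
  xs <- max(0, cref - r2):min(r1, cref)
  pr <- dhyper(xs, cref, calt, r1)
  p_obs <- dhyper(normal_ref, cref, calt, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Small hand-buildable count table: one site across the given samples.
one_site_counts <- function(depths, alts, samples = paste0("R", seq_along(depths)),
                            chrom = "chr1", pos = 100L, ref = "A", alt = "T") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             sample = samples, depth = as.integer(depths),
             alt_count = as.integer(alts), stringsAsFactors = FALSE)
}

meta_for <- function(samples, purity = 1, normal = NULL) {
  m <- data.frame(sample = samples, role = "region",
                  purity = rep_len(purity, length(samples)),
                  stringsAsFactors = FALSE)
  if (!is.null(normal)) {
    m <- rbind(m, data.frame(sample = normal, role = "normal", purity = 1))
  } else {
    m <- rbind(m, data.frame(sample = "NORM", role = "normal", purity = 1))
  }
  m
}

simple_pool <- function(depths, alts, pos = seq_along(depths)) {
  data.frame(chrom = "chr1", pos = as.integer(pos), ref = "A", alt = "T",
             depth = as.integer(depths), alt_count = as.integer(alts),
             stringsAsFactors = FALSE)
}
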