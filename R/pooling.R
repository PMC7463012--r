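# In silico read pooling at the count level. Per-site (depth, alt_count)
# pairs are resampled instead of individual reads: keeping each read of a
# site independently with probability f gives depth' ~ Binomial(depth, f)
# and, conditional on depth', alt' ~ Hypergeometric(depth, alt, depth') —
# exactly the law of sampling reads without replacement — so site-level
# detection statistics match read-level (BAM) manipulation.

pool_cols <- c("chrom", "pos", "ref", "alt", "depth", "alt_count")

#' Construct a read pool from a count table
#'
#' A read pool is one sample's per-site `(depth, alt_count)` table, the
#' unit the pooling experiment mixes, thins and upscales.
#'
#' @param counts Long count table, or an existing pool table.
#' @param sample If `counts` is a multi-sample table, the sample to
#'   extract.
#' @param origin Optional origin label (e.g. `"primary"`,
#'   `"metastasis"`) stored as an attribute.
#' @return data.frame `chrom pos ref alt depth alt_count` with attribute
#'   `origin`.
#' @export
read_pool <- function(counts, sample = NULL, origin = NULL) {
  if (!is.null(sample)) {
    counts <- counts[counts$sample == sample, , drop = FALSE]
  }
  missing <- setdiff(pool_cols, names(counts))
  if (length(missing)) {
    stop("pool is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pool <- counts[, pool_cols]
  rownames(pool) <- NULL
  assert_pool(pool)
  attr(pool, "origin") <- origin
  pool
}

assert_pool <- function(pool, arg = "pool") {
  if (!is.data.frame(pool) || !all(pool_cols %in% names(pool))) {
    stop(arg, " must have columns ", paste(pool_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(pool) && (any(pool$alt_count > pool$depth) ||
                     any(pool$depth < 0) || any(pool$alt_count < 0))) {
    stop(arg, ": need 0 <= alt_count <= depth", call. = FALSE)
  }
  invisible(pool)
}

# One without-replacement tranche: keep fraction f of the remaining reads.
thin_once <- function(depth, alt, fraction) {
  d2 <- rbinom(length(depth), depth, fraction)
  a2 <- rhyper(length(depth), m = alt, n = depth - alt, k = d2)
  list(depth = d2, alt = a2)
}

#' Randomly thin a read pool to a fraction of its reads
#'
#' Samples reads without replacement within each site: the retained depth
#' is `Binomial(depth, fraction)` and the retained mutant reads follow the
#' hypergeometric law given that depth, so the expected VAF of every site
#' is preserved.
#'
#' @param pool A read pool (see [read_pool()]).
#' @param fraction Fraction of reads to keep, in `(0, 1]`; 1 returns the
#'   pool unchanged.
#' @param seed Optional integer seed for reproducibility.
#' @return A read pool with thinned `depth` and `alt_count`.
#' @examples
#' p <- data.frame(chrom = "chr1", pos = 1:2, ref = "A", alt = "T",
#'                 depth = c(100L, 80L), alt_count = c(40L, 0L))
#' thin_counts(p, 0.5, seed = 1)
#' @export
thin_counts <- function(pool, fraction, seed = NULL) {
  assert_pool(pool)
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop("domain error: fraction must lie in (0, 1]", call. = FALSE)
  }
  if (fraction == 1) return(pool)
  with_seed_if(seed, {
    th <- thin_once(pool$depth, pool$alt_count, fraction)
    pool$depth <- th$depth
    pool$alt_count <- th$alt
    pool
  })
}

#' Subsample a pool by repeated 10% tranches
#'
#' Draws successive without-replacement tranches, each targeting `step` of
#' the original reads, until the target fraction is reached (a final
#' partial tranche covers any remainder). Because each tranche keeps every
#' remaining read with the appropriate conditional probability, the union
#' of tranches is distributed exactly as a single without-replacement draw
#' of the target fraction.
#'
#' @param pool A read pool.
#' @param target_fraction Total fraction of reads to extract, in `(0, 1]`.
#' @param step Tranche size as a fraction of the original reads.
#'   Default 0.1.
#' @param seed Optional integer seed.
#' @return A read pool holding the union of the tranches.
#' @export
iterative_subsample <- function(pool, target_fraction, step = 0.1,
                                seed = NULL) {
  assert_pool(pool)
  if (!is.numeric(step) || length(step) != 1L || is.na(step) || step <= 0) {
    stop("domain error: step must be > 0", call. = FALSE)
  }
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      is.na(target_fraction) || target_fraction <= 0 || target_fraction > 1) {
    stop("domain error: target_fraction must lie in (0, 1]", call. = FALSE)
  }
  n_full <- floor(target_fraction / step + 1e-9)
  tranches <- rep(step, n_full)
  remainder <- target_fraction - n_full * step
  if (remainder > 1e-9) tranches <- c(tranches, remainder)

  with_seed_if(seed, {
    rem_depth <- pool$depth
    rem_alt <- pool$alt_count
    out_depth <- integer(nrow(pool))
    out_alt <- integer(nrow(pool))
    remaining <- 1
    for (tr in tranches) {
      f <- min(1, tr / remaining)
      th <- thin_once(rem_depth, rem_alt, f)
      out_depth <- out_depth + th$depth
      out_alt <- out_alt + th$alt
      rem_depth <- rem_depth - th$depth
      rem_alt <- rem_alt - th$alt
      remaining <- remaining - tr
      if (remaining <= 1e-12) break
    }
    pool$depth <- out_depth
    pool$alt_count <- out_alt
    pool
  })
}

# Outer-join two pools on site key; absent sites get depth 0.
align_pools <- function(a, b) {
  ka <- site_key(a)
  kb <- site_key(b)
  keys <- union(ka, kb)
  take <- function(pool, k, keys) {
    i <- match(keys, k)
    data.frame(depth = ifelse(is.na(i), 0L, pool$depth[i]),
               alt_count = ifelse(is.na(i), 0L, pool$alt_count[i]))
  }
  src <- rbind(a[, c("chrom", "pos", "ref", "alt")],
               b[, c("chrom", "pos", "ref", "alt")])
  first <- match(keys, c(ka, kb))
  sites <- src[first, , drop = FALSE]
  rownames(sites) <- NULL
  list(sites = sites, a = take(a, ka, keys), b = take(b, kb, keys),
       keys = keys)
}

#' Mix two read pools at a given composition
#'
#' Models pooled DNA from two tumor sites: fraction `(1 - proportion_b) *
#' total_scale` of pool `a`'s reads and `proportion_b * total_scale` of
#' pool `b`'s are drawn without replacement and summed per site. The site
#' universe is the union of both pools' sites (a site absent from one pool
#' contributes zero reads from it); a mutation private to the minor pool is
#' thereby diluted in proportion to its share of the mixture.
#'
#' @param a,b Read pools.
#' @param proportion_b Share of pool `b` in the mixture, in `[0, 1]`.
#' @param total_scale Overall scaling of the mixture's depth; 1 (default)
#'   keeps an equal-coverage mixture at the per-sample sequencing depth.
#' @param seed Optional integer seed.
#' @return A read pool over the union of sites.
#' @export
mix_pools <- function(a, b, proportion_b, total_scale = 1, seed = NULL) {
  assert_pool(a, "a")
  assert_pool(b, "b")
  if (!is.numeric(proportion_b) || length(proportion_b) != 1L ||
      is.na(proportion_b) || proportion_b < 0 || proportion_b > 1) {
    stop("domain error: proportion_b must lie in [0, 1]", call. = FALSE)
  }
  if (total_scale == 1) {
    if (proportion_b == 0) return(a)
    if (proportion_b == 1) return(b)
  }
  fa <- (1 - proportion_b) * total_scale
  fb <- proportion_b * total_scale
  if (fa > 1 || fb > 1) {
    stop("domain error: total_scale too large; a pool cannot contribute ",
         "more than all of its reads (use upscale_pool)", call. = FALSE)
  }
  al <- align_pools(a, b)
  with_seed_if(seed, {
    da <- if (fa > 0) thin_once(al$a$depth, al$a$alt_count, fa) else
      list(depth = 0L, alt = 0L)
    db <- if (fb > 0) thin_once(al$b$depth, al$b$alt_count, fb) else
      list(depth = 0L, alt = 0L)
    out <- al$sites
    out$depth <- da$depth + db$depth
    out$alt_count <- da$alt + db$alt
    out
  })
}

#' Sum two read pools site by site
#'
#' The full combination of both pools' reads — the "onefold" reference
#' coverage for the coverage titration (onefold = the combined depth of
#' the original inputs).
#'
#' @param a,b Read pools.
#' @return A read pool over the union of sites with summed counts.
#' @export
combine_pools <- function(a, b) {
  al <- align_pools(a, b)
  out <- al$sites
  out$depth <- al$a$depth + al$b$depth
  out$alt_count <- al$a$alt_count + al$b$alt_count
  out
}

#' Upscale a read pool by bootstrap resampling
#'
#' Emulates deeper sequencing of the same library: per site, a new depth
#' with expectation `fold * depth` is drawn and reads are resampled with
#' replacement from the observed ones, preserving each site's expected
#' VAF. Bootstrap resampling cannot create reads the original pool never
#' saw, so (unlike true re-sequencing) a site with zero observed mutant
#' reads stays at zero at any fold.
#'
#' @param pool A read pool.
#' @param fold Coverage multiplier, must be > 1 (use [thin_counts()] to go
#'   below the original coverage).
#' @param seed Optional integer seed.
#' @return A read pool with inflated counts.
#' @export
upscale_pool <- function(pool, fold, seed = NULL) {
  assert_pool(pool)
  if (!is.numeric(fold) || length(fold) != 1L || is.na(fold) || fold <= 1) {
    stop("guard error: fold must be > 1; use thin_counts for fold <= 1",
         call. = FALSE)
  }
  with_seed_if(seed, {
    d2 <- rpois(nrow(pool), fold * pool$depth)
    vaf <- ifelse(pool$depth > 0, pool$alt_count / pool$depth, 0)
    a2 <- rbinom(nrow(pool), d2, vaf)
    pool$depth <- d2
    pool$alt_count <- a2
    pool
  })
}

#' Rescale a pool to an arbitrary coverage fold
#'
#' Dispatches to [thin_counts()] for `fold < 1`, returns the pool
#' unchanged at `fold = 1`, and to [upscale_pool()] for `fold > 1`.
#'
#' @param pool A read pool.
#' @param fold Positive coverage multiplier.
#' @param seed Optional integer seed.
#' @return A read pool.
#' @export
scale_pool <- function(pool, fold, seed = NULL) {
  if (!is.numeric(fold) || length(fold) != 1L || is.na(fold) || fold <= 0) {
    stop("domain error: fold must be > 0", call. = FALSE)
  }
  if (fold < 1) {
    thin_counts(pool, fold, seed)
  } else if (fold == 1) {
    pool
  } else {
    upscale_pool(pool, fold, seed)
  }
}

# ---- detection --------------------------------------------------------------

#' Detect mutations in a single pooled sample
#'
#' The sweep detection rule: a site is detected when its coverage reaches
#' `min_depth` and either the hard mutant-read filter (`alt_count >=
#' min_alt`) or the Poisson background genotyper accepts it. The
#' purity-corrected VAF filter is not applied here: the purity of an in
#' silico mixture is undefined.
#'
#' @param pool A read pool.
#' @param cfg A [filter_config()].
#' @param error_rate Background error rate for the genotyper.
#' @return Logical vector, one element per site of `pool`.
#' @export
detect_in_pool <- function(pool, cfg = filter_config(), error_rate = 1e-3) {
  assert_pool(pool)
  lam <- pmax(error_rate, cfg$min_error_rate) * pool$depth
  p <- poisson_tail(pool$alt_count, lam)
  rescued <- p <= cfg$genotype_alpha & pool$alt_count >= 1L
  pool$depth >= cfg$min_depth & (pool$alt_count >= cfg$min_alt | rescued)
}

assert_truth <- function(truth) {
  need <- c("chrom", "pos", "ref", "alt", "origin", "clonality")
  if (!is.data.frame(truth) || !all(need %in% names(truth))) {
    stop("truth must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(truth) == 0L) {
    stop("input error: empty truth table", call. = FALSE)
  }
  if (!all(truth$clonality %in% c("clonal", "subclonal"))) {
    stop("truth clonality must be 'clonal' or 'subclonal'", call. = FALSE)
  }
  invisible(truth)
}

summarize_detection <- function(detected, truth_idx, truth, axis, axis_value,
                                replicate) {
  det <- rep(FALSE, nrow(truth))
  ok <- !is.na(truth_idx)
  det[ok] <- detected[truth_idx[ok]]
  groups <- expand.grid(class = c("clonal", "subclonal"),
                        origin = c(unique(truth$origin), "all"),
                        stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(groups)), function(i) {
    cl <- groups$class[i]
    or <- groups$origin[i]
    sel <- truth$clonality == cl & (or == "all" | truth$origin == or)
    n <- sum(sel)
    if (n == 0L) return(NULL)
    data.frame(axis = axis, axis_value = axis_value, replicate = replicate,
               class = cl, origin = or, n_sites = n,
               n_detected = sum(det[sel]),
               detected_fraction = mean(det[sel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Composition sweep: mix two pools across deciles
#'
#' For every mixing proportion (default every decile from 10% to 90%) and
#' replicate, mixes the two pools, applies the detection rule, and records
#' the fraction of truth mutations detected per clonality class and per
#' origin. Replicate `r` uses seed `base_seed + r`, so the whole sweep is
#' reproducible and each replicate independently so.
#'
#' @param a,b Read pools (e.g. primary tumor and metastasis).
#' @param truth Truth table `chrom pos ref alt origin clonality` labeling
#'   every site to score.
#' @param deciles Mixing proportions of pool `b`. Default
#'   `seq(0.1, 0.9, by = 0.1)`.
#' @param replicates Replicates per proportion. Default 10.
#' @param cfg A [filter_config()].
#' @param error_rate Background error rate for genotyper rescue.
#' @param base_seed Base seed for replicate seed derivation.
#' @return A `detection_summary` data.frame in long format: `axis
#'   axis_value replicate class origin n_sites n_detected
#'   detected_fraction`.
#' @export
composition_sweep <- function(a, b, truth,
                              deciles = seq(0.1, 0.9, by = 0.1),
                              replicates = 10, cfg = filter_config(),
                              error_rate = 1e-3, base_seed = 1L) {
  assert_pool(a, "a")
  assert_pool(b, "b")
  assert_truth(truth)
  res <- list()
  for (p in deciles) {
    for (r in seq_len(replicates)) {
      mixed <- mix_pools(a, b, proportion_b = p,
                         seed = derive_seed(base_seed, r))
      detected <- detect_in_pool(mixed, cfg, error_rate)
      idx <- match(site_key(truth), site_key(mixed))
      res[[length(res) + 1L]] <-
        summarize_detection(detected, idx, truth, "composition", p, r)
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("detection_summary", class(out))
  attr(out, "base_seed") <- base_seed
  out
}

#' Coverage sweep: titrate a pooled sample across coverage folds
#'
#' Thins (fold < 1) or bootstrap-upscales (fold > 1) the pooled input to
#' each coverage fold — onefold being the pooled input's own coverage —
#' and records detected fractions per clonality class and origin, with
#' `replicates` replicates per fold.
#'
#' @param pooled A read pool (typically [combine_pools()] of two inputs).
#' @param truth Truth table as in [composition_sweep()].
#' @param folds Coverage multipliers. Default
#'   `c(0.1, 0.25, 0.5, 1, 2, 5, 10, 30, 100)`.
#' @param replicates Replicates per fold. Default 10.
#' @param cfg A [filter_config()].
#' @param error_rate Background error rate for genotyper rescue.
#' @param base_seed Base seed for replicate seed derivation.
#' @return A `detection_summary` data.frame (axis `coverage_fold`).
#' @export
coverage_sweep <- function(pooled, truth,
                           folds = c(0.1, 0.25, 0.5, 1, 2, 5, 10, 30, 100),
                           replicates = 10, cfg = filter_config(),
                           error_rate = 1e-3, base_seed = 1L) {
  assert_pool(pooled)
  assert_truth(truth)
  if (any(folds <= 0)) {
    stop("domain error: folds must be positive", call. = FALSE)
  }
  res <- list()
  for (f in folds) {
    for (r in seq_len(replicates)) {
      scaled <- scale_pool(pooled, f, seed = derive_seed(base_seed, r))
      detected <- detect_in_pool(scaled, cfg, error_rate)
      idx <- match(site_key(truth), site_key(scaled))
      res[[length(res) + 1L]] <-
        summarize_detection(detected, idx, truth, "coverage_fold", f, r)
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("detection_summary", class(out))
  attr(out, "base_seed") <- base_seed
  out
}

#' Average a detection summary over replicates
#'
#' @param summary A `detection_summary` from [composition_sweep()] or
#'   [coverage_sweep()].
#' @return data.frame `axis axis_value class origin mean_detected se` with
#'   the replicate mean and its standard error.
#' @export
mean_detection <- function(summary) {
  key <- interaction(summary$axis_value, summary$class, summary$origin,
                     drop = TRUE)
  agg <- lapply(split(summary, key), function(d) {
    data.frame(axis = d$axis[1], axis_value = d$axis_value[1],
               class = d$class[1], origin = d$origin[1],
               mean_detected = mean(d$detected_fraction),
               se = stats::sd(d$detected_fraction) /
                 sqrt(nrow(d)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$class, out$origin, out$axis_value), ]
  rownames(out) <- NULL
  out
}
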