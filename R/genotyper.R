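# Poisson background-noise joint genotyper: once a candidate somatic site
# is called in any sample of a patient, every other sample of that patient
# is tested against its own sequencing-error background, rescuing genotypes
# whose mutant-read count is inconsistent with noise alone.

#' Estimate a per-sample background error rate from flanking positions
#'
#' The background model is the per-base rate at which a sample produces
#' non-reference reads at positions that carry no variant ("intermediate
#' regions" flanking the candidate sites). The rate is the pooled ratio
#' `sum(nonref) / sum(depth)` across flanking positions; when no flanking
#' coverage is available, a fallback rate is used.
#'
#' @param flank_counts data.frame with columns `depth` and `nonref_count`
#'   (one row per flanking position); may be empty.
#' @param fallback_rate Rate used when flanking coverage is absent; must lie
#'   in `[0, 0.5)`. Default 1e-3.
#' @param sample_id Optional sample label stored in the model.
#' @return An object of class `background_model`: list with `sample_id`,
#'   `error_rate`, `n_observed_bases`.
#' @examples
#' fl <- data.frame(depth = c(100, 100, 100, 100),
#'                  nonref_count = c(1, 1, 0, 2))
#' estimate_background_rate(fl)$error_rate # 0.01
#' @export
estimate_background_rate <- function(flank_counts = NULL,
                                     fallback_rate = 1e-3,
                                     sample_id = NA_character_) {
  if (!is.numeric(fallback_rate) || is.na(fallback_rate) ||
      fallback_rate < 0 || fallback_rate >= 0.5) {
    stop("config error: fallback_rate must lie in [0, 0.5)", call. = FALSE)
  }
  total_depth <- 0
  total_nonref <- 0
  if (!is.null(flank_counts) && nrow(flank_counts)) {
    if (!all(c("depth", "nonref_count") %in% names(flank_counts))) {
      stop("flank_counts needs columns depth and nonref_count", call. = FALSE)
    }
    if (any(flank_counts$nonref_count > flank_counts$depth) ||
        any(flank_counts$depth < 0) || any(flank_counts$nonref_count < 0)) {
      stop("flank_counts: nonref_count must lie in [0, depth]", call. = FALSE)
    }
    total_depth <- sum(flank_counts$depth)
    total_nonref <- sum(flank_counts$nonref_count)
  }
  if (total_depth > 0) {
    rate <- total_nonref / total_depth
  } else {
    rate <- fallback_rate
  }
  structure(list(sample_id = sample_id,
                 error_rate = rate,
                 n_observed_bases = total_depth),
            class = "background_model")
}

#' Estimate background error rates for several samples at once
#'
#' @param flanks data.frame with columns `sample`, `depth`, `nonref_count`
#'   (positions may also carry `chrom`/`pos`, which are ignored here).
#' @param samples Sample ids to produce models for; samples absent from
#'   `flanks` get the fallback rate.
#' @param fallback_rate See [estimate_background_rate()].
#' @return data.frame `sample, error_rate, n_observed_bases`.
#' @export
estimate_background_rates <- function(flanks, samples = NULL,
                                      fallback_rate = 1e-3) {
  if (is.null(samples)) samples <- unique(flanks$sample)
  models <- lapply(samples, function(s) {
    fl <- flanks[flanks$sample == s, , drop = FALSE]
    estimate_background_rate(fl, fallback_rate, sample_id = s)
  })
  data.frame(sample = samples,
             error_rate = vapply(models, `[[`, numeric(1), "error_rate"),
             n_observed_bases = vapply(models, `[[`, numeric(1),
                                       "n_observed_bases"),
             stringsAsFactors = FALSE)
}

#' Poisson upper-tail probability
#'
#' `P(X >= k)` for `X ~ Poisson(lam)`: the probability that background
#' noise alone produces at least `k` mutant reads when the expected number
#' of error reads is `lam`. `P(X >= 0)` is exactly 1, and the computation
#' is stable for large means (delegated to the regularized incomplete
#' gamma function via [stats::ppois()]).
#'
#' @param k Observed mutant reads (non-negative integer, vectorized).
#' @param lam Expected background mutant reads (>= 0, vectorized).
#' @return `P(X >= k)` per element.
#' @examples
#' poisson_tail(0, 5)   # 1
#' poisson_tail(5, 1)   # ~0.00366
#' poisson_tail(1, 0)   # 0
#' @export
poisson_tail <- function(k, lam) {
  n <- max(length(k), length(lam))
  k <- rep_len(k, n)
  lam <- rep_len(lam, n)
  if (any(is.na(k)) || any(k < 0) || any(k != floor(k))) {
    stop("domain error: k must be a non-negative integer", call. = FALSE)
  }
  if (any(is.na(lam)) || any(lam < 0)) {
    stop("domain error: lam must be >= 0", call. = FALSE)
  }
  ppois(k - 1, lam, lower.tail = FALSE)
}

as_background_df <- function(background, samples) {
  if (inherits(background, "background_model")) {
    background <- data.frame(sample = background$sample_id,
                             error_rate = background$error_rate,
                             stringsAsFactors = FALSE)
  }
  if (is.numeric(background) && length(background) == 1L) {
    return(data.frame(sample = samples, error_rate = background,
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(background) &&
      all(c("sample", "error_rate") %in% names(background))) {
    missing <- setdiff(samples, background$sample)
    if (length(missing)) {
      stop("config error: no background model for sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    return(background)
  }
  stop("background must be a rate, a background_model, or a data.frame ",
       "with columns sample and error_rate", call. = FALSE)
}

#' Joint genotyping by Poisson background test
#'
#' Tests every site x sample in a patient's count table: the expected
#' number of background mutant reads is `lambda = error_rate * depth`
#' (error rates floored at `cfg$min_error_rate`), and the genotype is
#' accepted when `P(X >= alt_count)` under `Poisson(lambda)` is at most
#' `genotype_alpha` and at least one mutant read was observed. Because the
#' input contains every sample of the patient at every candidate site, a
#' site called in one sample is automatically tested in all the others —
#' the joint aspect that rescues low-evidence genotypes.
#'
#' @param counts Long count table.
#' @param background Per-sample error rates: a data.frame
#'   `sample, error_rate`, a single [estimate_background_rate()] model, or
#'   one numeric rate for all samples.
#' @param cfg A [filter_config()]; uses `genotype_alpha`, `min_error_rate`
#'   and (if `bonferroni`) the per-site test count.
#' @return data.frame `chrom pos ref alt sample p_value accepted`.
#' @examples
#' counts <- data.frame(chrom = "chr1", pos = 1000, ref = "G", alt = "A",
#'                      sample = c("R1", "R2"), depth = c(100L, 100L),
#'                      alt_count = c(5L, 0L))
#' joint_genotype(counts, background = 0.01, cfg = filter_config())
#' @export
joint_genotype <- function(counts, background, cfg = filter_config()) {
  assert_counts(counts)
  stopifnot(inherits(cfg, "filter_config"))
  bg <- as_background_df(background, unique(counts$sample))
  rate <- bg$error_rate[match(counts$sample, bg$sample)]
  if (any(is.na(rate))) {
    stop("config error: no background model for sample(s): ",
         paste(unique(counts$sample[is.na(rate)]), collapse = ", "),
         call. = FALSE)
  }
  lam <- pmax(rate, cfg$min_error_rate) * counts$depth
  p <- poisson_tail(counts$alt_count, lam)
  alpha <- cfg$genotype_alpha
  if (cfg$bonferroni) {
    m <- table(site_key(counts))[site_key(counts)]
    alpha <- alpha / as.numeric(m)
  }
  accepted <- p <= alpha & counts$alt_count >= 1L
  data.frame(chrom = counts$chrom, pos = counts$pos, ref = counts$ref,
             alt = counts$alt, sample = counts$sample,
             p_value = p, accepted = accepted,
             stringsAsFactors = FALSE)
}
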