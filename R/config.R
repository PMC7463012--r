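#' Filtering and testing thresholds
#'
#' Bundles the named thresholds that drive every deterministic decision in
#' the pipeline: the somatic hard filters (minimum site coverage and minimum
#' mutant-read support), the purity-corrected VAF floor used when selecting
#' variants for presence heatmaps, the VAF cutoff separating clonal from
#' sub-clonal mutations, and the significance levels of the Poisson joint
#' genotyper and the LOH Fisher test.
#'
#' @param min_depth Minimum site coverage (reads) for a sample-level pass.
#'   Default 50.
#' @param min_alt Minimum mutant reads required in at least one tumor sample
#'   for a site-level pass. Default 5.
#' @param min_corrected_vaf Minimum purity-corrected variant allele frequency
#'   for a sample-level pass. Default 0.05.
#' @param clonal_vaf_threshold VAF at or above which a mutation is called
#'   clonal; below it, sub-clonal. Default 0.10.
#' @param genotype_alpha Significance level of the Poisson background test in
#'   the joint genotyper. Default 0.01.
#' @param loh_alpha Significance level of the LOH Fisher test. Default 0.05.
#' @param min_error_rate Floor applied to per-sample background error rates
#'   before forming the Poisson mean, so that an estimated rate of exactly
#'   zero cannot make a single read genome-wide significant. Default 1e-4.
#' @param bonferroni If `TRUE`, the genotyper divides `genotype_alpha` by the
#'   number of samples tested at each site. Off by default: the genotyper's
#'   role is permissive rescue of known candidate sites within one patient,
#'   not genome-wide discovery.
#' @param bh_correct_loh If `TRUE`, LOH calls use Benjamini-Hochberg adjusted
#'   p-values. Off by default (raw per-site p-values are reported).
#'
#' @return An object of class `filter_config`: a validated named list.
#' @examples
#' cfg <- filter_config()
#' cfg$min_depth
#' @export
filter_config <- function(min_depth = 50L,
                          min_alt = 5L,
                          min_corrected_vaf = 0.05,
                          clonal_vaf_threshold = 0.10,
                          genotype_alpha = 0.01,
                          loh_alpha = 0.05,
                          min_error_rate = 1e-4,
                          bonferroni = FALSE,
                          bh_correct_loh = FALSE) {
  cfg <- list(
    min_depth = as.integer(min_depth),
    min_alt = as.integer(min_alt),
    min_corrected_vaf = min_corrected_vaf,
    clonal_vaf_threshold = clonal_vaf_threshold,
    genotype_alpha = genotype_alpha,
    loh_alpha = loh_alpha,
    min_error_rate = min_error_rate,
    bonferroni = isTRUE(bonferroni),
    bh_correct_loh = isTRUE(bh_correct_loh)
  )
  if (is.na(cfg$min_depth) || cfg$min_depth < 0L) {
    stop("config error: min_depth must be a non-negative integer", call. = FALSE)
  }
  if (is.na(cfg$min_alt) || cfg$min_alt < 0L) {
    stop("config error: min_alt must be a non-negative integer", call. = FALSE)
  }
  v <- cfg$min_corrected_vaf # 0 is allowed: it disables the VAF gate
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
    stop("config error: min_corrected_vaf must be a fraction in [0, 1]",
         call. = FALSE)
  }
  v <- cfg$clonal_vaf_threshold
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1) {
    stop("config error: clonal_vaf_threshold must be a fraction in (0, 1]",
         call. = FALSE)
  }
  for (nm in c("genotype_alpha", "loh_alpha")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v >= 1) {
      stop("config error: ", nm, " must lie in (0, 1)", call. = FALSE)
    }
  }
  if (!is.numeric(cfg$min_error_rate) || is.na(cfg$min_error_rate) ||
      cfg$min_error_rate < 0 || cfg$min_error_rate >= 0.5) {
    stop("config error: min_error_rate must lie in [0, 0.5)", call. = FALSE)
  }
  structure(cfg, class = c("filter_config", "list"))
}

#' @export
print.filter_config <- function(x, ...) {
  cat("filter_config:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Synthetic multi-region tumor simulation settings
#'
#' Describes one simulated patient: the number of tumor regions sequenced
#' alongside one matched normal, the clonal architecture (trunk mutations
#' shared by all regions, branch mutations shared by a proper subset,
#' private mutations confined to one region), true cancer-cell VAF ranges,
#' exome coverage, per-region tumor purity, the per-base sequencing error
#' rate, and the germline heterozygous sites and copy-number segments used
#' by the LOH stage.
#'
#' Defaults mirror the sequencing design the package studies: three tumor
#' regions plus one normal at ~100x exome coverage, a trunk burden of ~90
#' mutations, purity 0.7, and a per-base error rate of 1e-3. A quarter of
#' the non-trunk mutations are drawn from the sub-clonal VAF range so that
#' low-frequency variants with region-restricted patterns are present, as
#' they are in real multi-region data.
#'
#' @param n_regions Number of tumor regions (>= 2). Default 3.
#' @param n_trunk,n_branch,n_private Mutation counts per topology class.
#' @param clonal_vaf_range True cancer-cell VAF interval for clonal
#'   mutations. Default `c(0.2, 0.5)`.
#' @param subclonal_vaf_range True VAF interval for sub-clonal mutations.
#'   Default `c(0.02, 0.08)`.
#' @param subclonal_fraction Fraction of branch and private mutations drawn
#'   from `subclonal_vaf_range`; trunk mutations are always clonal.
#'   Default 0.25.
#' @param private_vaf_range Optional VAF interval overriding the clonal /
#'   sub-clonal ranges for private mutations (used by the hypermutator
#'   preset). `NULL` (default) means private mutations follow the same
#'   clonal/sub-clonal draw as branch mutations.
#' @param coverage_mean Mean sequencing depth per site (reads); depth is
#'   Poisson-distributed around it. Default 100.
#' @param purity Tumor purity per region, recycled to `n_regions`; observed
#'   VAF is diluted by this factor. Default 0.7.
#' @param error_rate Per-base probability of a non-reference read from
#'   sequencing error. Default 1e-3.
#' @param n_germline_het Number of germline heterozygous sites simulated for
#'   the LOH stage. Default 1000.
#' @param n_loh_segments Number of B-allele-loss segments. Default 10.
#' @param hypermutator If `TRUE`, applies the hypermutator preset: 500
#'   private mutations at true VAF 0.10-0.15, all confined to region 1, on
#'   top of the trunk backbone. Observed VAFs then sit near the detection
#'   threshold once diluted by purity and pooling.
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce byte-identical outputs.
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 7)
#' hyp <- sim_config(hypermutator = TRUE, seed = 7)
#' hyp$n_private
#' @export
sim_config <- function(n_regions = 3L,
                       n_trunk = 90L,
                       n_branch = 30L,
                       n_private = 30L,
                       clonal_vaf_range = c(0.2, 0.5),
                       subclonal_vaf_range = c(0.02, 0.08),
                       subclonal_fraction = 0.25,
                       private_vaf_range = NULL,
                       coverage_mean = 100,
                       purity = 0.7,
                       error_rate = 1e-3,
                       n_germline_het = 1000L,
                       n_loh_segments = 10L,
                       hypermutator = FALSE,
                       seed = 1L) {
  if (isTRUE(hypermutator)) {
    # hypermutator preset: a large private sub-clonal burden in one region
    n_private <- 500L
    private_vaf_range <- c(0.10, 0.15)
  }
  cfg <- list(
    n_regions = as.integer(n_regions),
    n_trunk = as.integer(n_trunk),
    n_branch = as.integer(n_branch),
    n_private = as.integer(n_private),
    clonal_vaf_range = clonal_vaf_range,
    subclonal_vaf_range = subclonal_vaf_range,
    subclonal_fraction = subclonal_fraction,
    private_vaf_range = private_vaf_range,
    coverage_mean = coverage_mean,
    purity = rep_len(purity, as.integer(n_regions)),
    error_rate = error_rate,
    n_germline_het = as.integer(n_germline_het),
    n_loh_segments = as.integer(n_loh_segments),
    hypermutator = isTRUE(hypermutator),
    seed = as.integer(seed)
  )
  if (is.na(cfg$n_regions) || cfg$n_regions < 2L) {
    stop("config error: n_regions must be >= 2", call. = FALSE)
  }
  for (nm in c("n_trunk", "n_branch", "n_private", "n_germline_het",
               "n_loh_segments")) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0L) {
      stop("config error: ", nm, " must be >= 0", call. = FALSE)
    }
  }
  if (cfg$n_branch > 0L && cfg$n_regions < 3L) {
    stop("config error: branch mutations (shared by a proper subset of >= 2 ",
         "regions) require n_regions >= 3", call. = FALSE)
  }
  if (!is.numeric(cfg$coverage_mean) || cfg$coverage_mean <= 0) {
    stop("config error: coverage_mean must be > 0", call. = FALSE)
  }
  check_range <- function(r, nm) {
    if (!is.numeric(r) || length(r) != 2L || any(is.na(r)) ||
        r[1] > r[2] || r[1] <= 0 || r[2] > 1) {
      stop("config error: ", nm, " must be an interval within (0, 1]",
           call. = FALSE)
    }
  }
  check_range(cfg$clonal_vaf_range, "clonal_vaf_range")
  check_range(cfg$subclonal_vaf_range, "subclonal_vaf_range")
  if (!is.null(cfg$private_vaf_range)) {
    check_range(cfg$private_vaf_range, "private_vaf_range")
  }
  if (any(cfg$purity <= 0) || any(cfg$purity > 1)) {
    stop("config error: purity must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$subclonal_fraction < 0 || cfg$subclonal_fraction > 1) {
    stop("config error: subclonal_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.5) {
    stop("config error: error_rate must lie in [0, 0.5)", call. = FALSE)
  }
  if (cfg$n_loh_segments > cfg$n_germline_het) {
    stop("config error: n_loh_segments must not exceed n_germline_het",
         call. = FALSE)
  }
  structure(cfg, class = c("sim_config", "list"))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

# Run `code` under a fixed RNG state when seed is given, without disturbing
# the caller's RNG stream; seeds derived elsewhere stay below 2^31.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Deterministic stage-seed derivation from one top-level seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% (.Machine$integer.max - 1))
}
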