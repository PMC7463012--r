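#' @importFrom stats rbinom rhyper rpois runif p.adjust fisher.test ppois
#' @importFrom utils read.delim write.table
NULL

# ---- count-table helpers ----------------------------------------------------

count_cols <- c("chrom", "pos", "ref", "alt", "sample", "depth", "alt_count")

# Validates the long count-table contract shared by all stages:
# one row per site x sample, 1-based positions, alt_count <= depth.
assert_counts <- function(counts, arg = "counts") {
  if (!is.data.frame(counts)) {
    stop(arg, " must be a data.frame", call. = FALSE)
  }
  missing <- setdiff(count_cols, names(counts))
  if (length(missing)) {
    stop(arg, " is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(counts)) {
    if (any(counts$pos < 1L)) {
      stop(arg, ": positions must be 1-based (pos >= 1)", call. = FALSE)
    }
    if (any(counts$depth < 0L) || any(counts$alt_count < 0L)) {
      stop(arg, ": depth and alt_count must be non-negative", call. = FALSE)
    }
    if (any(counts$alt_count > counts$depth)) {
      stop(arg, ": alt_count exceeds depth at some site", call. = FALSE)
    }
    key <- paste(counts$chrom, counts$pos, counts$ref, counts$alt,
                 counts$sample)
    if (anyDuplicated(key)) {
      stop(arg, ": duplicated site x sample rows", call. = FALSE)
    }
  }
  invisible(counts)
}

site_key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")

assert_meta <- function(meta) {
  if (!is.data.frame(meta) ||
      !all(c("sample", "role", "purity") %in% names(meta))) {
    stop("meta must be a data.frame with columns sample, role, purity",
         call. = FALSE)
  }
  if (anyDuplicated(meta$sample)) {
    stop("meta: duplicated sample ids", call. = FALSE)
  }
  ok_roles <- c("normal", "biopsy", "local", "global", "region")
  if (!all(meta$role %in% ok_roles)) {
    stop("meta: role must be one of ", paste(ok_roles, collapse = ", "),
         call. = FALSE)
  }
  if (sum(meta$role == "normal") != 1L) {
    stop("meta: exactly one normal sample is required per patient",
         call. = FALSE)
  }
  tum <- meta$role != "normal"
  if (any(is.na(meta$purity[tum])) ||
      any(meta$purity[tum] <= 0) || any(meta$purity[tum] > 1)) {
    stop("config error: missing or invalid purity for a tumor sample",
         call. = FALSE)
  }
  invisible(meta)
}

# ---- purity-corrected VAF ---------------------------------------------------

#' Purity-corrected variant allele frequency
#'
#' Divides the raw VAF (`alt_count / depth`) by the estimated tumor purity
#' (cellularity) and clamps at 1. A mutation carried by every tumor cell in
#' a specimen of purity `p` is observed at VAF ~ `p/2` (diploid
#' heterozygous), so dividing by purity puts specimens of different
#' cellularity on a common scale before VAF thresholds are applied.
#'
#' @param alt_count Mutant reads (vectorized).
#' @param depth Total reads at the site; must be positive.
#' @param purity Tumor purity in (0, 1].
#' @return Corrected VAF in `[0, 1]`.
#' @examples
#' purity_corrected_vaf(10, 100, 0.5) # 0.2
#' purity_corrected_vaf(90, 100, 0.6) # clamped to 1
#' @export
purity_corrected_vaf <- function(alt_count, depth, purity) {
  n <- max(length(alt_count), length(depth), length(purity))
  alt_count <- rep_len(alt_count, n)
  depth <- rep_len(depth, n)
  purity <- rep_len(purity, n)
  if (any(is.na(depth)) || any(depth <= 0)) {
    stop("undefined-input error: depth must be > 0 for VAF correction",
         call. = FALSE)
  }
  if (any(is.na(purity)) || any(purity <= 0) || any(purity > 1)) {
    stop("config error: purity must lie in (0, 1]", call. = FALSE)
  }
  if (any(alt_count < 0) || any(alt_count > depth)) {
    stop("undefined-input error: alt_count must lie in [0, depth]",
         call. = FALSE)
  }
  pmin(1, (alt_count / depth) / purity)
}

# ---- hard filters -----------------------------------------------------------

#' Apply the somatic hard filters to a count table
#'
#' Evaluates, per tumor sample, the sample-level pass (depth at least
#' `min_depth` and purity-corrected VAF at least `min_corrected_vaf`) and,
#' per site, the site-level pass (additionally, at least `min_alt` mutant
#' reads in at least one tumor sample). Normal-sample rows never pass and
#' are excluded from the site-level mutant-read check.
#'
#' @param counts Long count table (`chrom pos ref alt sample depth
#'   alt_count`).
#' @param meta Sample metadata (`sample role purity`), one normal per
#'   patient.
#' @param cfg A [filter_config()].
#' @return `counts` with added columns `corrected_vaf`, `sample_pass`, and
#'   `site_pass` (the latter repeated across all rows of a site).
#' @examples
#' counts <- data.frame(
#'   chrom = "chr1", pos = 100, ref = "A", alt = "T",
#'   sample = c("R1", "R2", "N"), depth = c(100L, 100L, 90L),
#'   alt_count = c(6L, 0L, 0L)
#' )
#' meta <- data.frame(sample = c("R1", "R2", "N"),
#'                    role = c("region", "region", "normal"),
#'                    purity = c(1, 1, 1))
#' passes_site_filters(counts, meta, filter_config())
#' @export
passes_site_filters <- function(counts, meta, cfg = filter_config()) {
  assert_counts(counts)
  assert_meta(meta)
  stopifnot(inherits(cfg, "filter_config"))
  extra <- setdiff(unique(counts$sample), meta$sample)
  if (length(extra)) {
    stop("config error: samples without metadata (purity): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  idx <- match(counts$sample, meta$sample)
  purity <- meta$purity[idx]
  is_tumor <- meta$role[idx] != "normal"

  cvaf <- rep(NA_real_, nrow(counts))
  pos_depth <- counts$depth > 0
  cvaf[pos_depth] <- purity_corrected_vaf(counts$alt_count[pos_depth],
                                          counts$depth[pos_depth],
                                          purity[pos_depth])
  sample_pass <- is_tumor &
    counts$depth >= cfg$min_depth &
    !is.na(cvaf) & cvaf >= cfg$min_corrected_vaf

  key <- site_key(counts)
  has_support <- is_tumor & counts$alt_count >= cfg$min_alt
  support_by_site <- tapply(has_support, key, any)
  pass_by_site <- tapply(sample_pass, key, any)
  site_pass <- as.logical(support_by_site[key]) & as.logical(pass_by_site[key])

  counts$corrected_vaf <- cvaf
  counts$sample_pass <- sample_pass
  counts$site_pass <- site_pass
  counts
}

# ---- topology / clonality ---------------------------------------------------

#' Classify a mutation's topology from its presence pattern
#'
#' A mutation present in every tumor sample of the patient is a trunk
#' mutation, one present in exactly one sample is private, and anything in
#' between is a branch mutation. Given a logical matrix (sites x samples),
#' classifies each row.
#'
#' @param presence Logical vector over tumor samples for one site, or a
#'   logical matrix (sites x samples).
#' @return A character scalar (or vector for a matrix input) with values
#'   `"trunk"`, `"branch"`, or `"private"`.
#' @examples
#' classify_topology(c(TRUE, TRUE, TRUE))   # trunk
#' classify_topology(c(TRUE, FALSE, TRUE))  # branch
#' classify_topology(c(FALSE, TRUE, FALSE)) # private
#' @export
classify_topology <- function(presence) {
  if (is.matrix(presence)) {
    if (ncol(presence) < 2L) {
      stop("classify_topology requires at least 2 tumor samples",
           call. = FALSE)
    }
    k <- rowSums(presence)
    if (any(k == 0L)) {
      stop("not-present error: a site absent from every sample cannot be ",
           "classified", call. = FALSE)
    }
    out <- rep("branch", nrow(presence))
    out[k == ncol(presence)] <- "trunk"
    out[k == 1L] <- "private"
    return(out)
  }
  if (!is.logical(presence) || length(presence) < 2L) {
    stop("classify_topology requires a logical vector over >= 2 tumor samples",
         call. = FALSE)
  }
  k <- sum(presence)
  if (k == 0L) {
    stop("not-present error: a site absent from every sample cannot be ",
         "classified", call. = FALSE)
  }
  if (k == length(presence)) "trunk" else if (k == 1L) "private" else "branch"
}

#' Classify a mutation as clonal or sub-clonal by VAF
#'
#' Mutations at or above the clonal VAF threshold (default 10%) are labeled
#' clonal; below it, sub-clonal. The boundary value itself is assigned to
#' the clonal class so the two labels are exhaustive.
#'
#' @param vaf VAF in `[0, 1]` (vectorized).
#' @param cfg A [filter_config()]; uses `clonal_vaf_threshold`.
#' @return `"clonal"` or `"subclonal"` per element.
#' @examples
#' classify_clonality(c(0.4, 0.02, 0.10))
#' @export
classify_clonality <- function(vaf, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (any(is.na(vaf)) || any(vaf < 0) || any(vaf > 1)) {
    stop("vaf must lie in [0, 1]", call. = FALSE)
  }
  ifelse(vaf >= cfg$clonal_vaf_threshold, "clonal", "subclonal")
}

#' Per-sample trunk proportion
#'
#' For each sample, the fraction of mutations present in that sample that
#' are trunk mutations (present in every sample). This is the summary that
#' quantifies how pooling dilutes region-private mutations: a pooled sample
#' losing sub-clonal privates shows a higher trunk share.
#'
#' @param presence Logical matrix, sites x samples; rows with no presence
#'   anywhere are not allowed.
#' @return Named numeric vector, one value in `[0, 1]` per sample; `NA` for
#'   a sample with no present mutations.
#' @examples
#' m <- rbind(c(TRUE, TRUE, TRUE), c(TRUE, FALSE, FALSE),
#'            c(TRUE, FALSE, FALSE))
#' trunk_proportion(m) # 1/3, 1, 1
#' @export
trunk_proportion <- function(presence) {
  if (!is.matrix(presence) || !is.logical(presence) || nrow(presence) == 0L) {
    stop("presence must be a nonempty logical matrix (sites x samples)",
         call. = FALSE)
  }
  labels <- classify_topology(presence)
  is_trunk <- labels == "trunk"
  denom <- colSums(presence)
  num <- colSums(presence & is_trunk)
  out <- ifelse(denom > 0, num / denom, NA_real_)
  names(out) <- colnames(presence)
  out
}

# ---- presence / classification pipeline ------------------------------------

#' Classify candidate somatic sites across the samples of one patient
#'
#' Combines the hard filters with the Poisson joint genotyper to decide,
#' per site and tumor sample, whether the mutation is present; then labels
#' each site's topology (trunk/branch/private) and each present site x
#' sample's clonality (clonal/sub-clonal, on raw VAF). A mutation is
#' "present" in a sample if it passes the sample-level hard filters or is
#' rescued by the genotyper at adequate depth (depth >= `min_depth`).
#' Sites absent from every tumor sample are dropped (with their count
#' reported in the result).
#'
#' @param counts Long count table covering all samples of the patient.
#' @param meta Sample metadata (`sample role purity`).
#' @param cfg A [filter_config()].
#' @param background Per-sample background models as returned by
#'   [estimate_background_rate()] (a data.frame `sample, error_rate,
#'   n_observed_bases`), or a single error rate applied to all samples.
#' @return An object of class `site_classification`: a list with
#'   `sites` (per-site table with `topology`), `presence`, `vaf` (raw VAF),
#'   and `clonality` matrices (sites x tumor samples), `trunk_proportion`
#'   per sample, and `n_dropped` (sites absent everywhere).
#' @examples
#' cfg <- sim_config(seed = 3)
#' pat <- simulate_patient(cfg)
#' cls <- classify_sites(pat$counts, pat$meta, filter_config(),
#'                       background = cfg$error_rate)
#' table(cls$sites$topology)
#' @export
classify_sites <- function(counts, meta, cfg = filter_config(),
                           background = 1e-3) {
  filtered <- passes_site_filters(counts, meta, cfg)
  calls <- joint_genotype(counts, background, cfg)

  idx <- match(meta$sample, meta$sample) # keep order
  tumor_samples <- meta$sample[meta$role != "normal"]
  tum <- filtered$sample %in% tumor_samples

  ck <- paste(site_key(filtered), filtered$sample)
  calls_ck <- paste(site_key(calls), calls$sample)
  accepted <- calls$accepted[match(ck, calls_ck)]
  accepted[is.na(accepted)] <- FALSE

  present <- tum & (filtered$sample_pass |
                      (filtered$depth >= cfg$min_depth & accepted))

  keys <- site_key(filtered)
  ukeys <- unique(keys)
  pres_mat <- matrix(FALSE, nrow = length(ukeys), ncol = length(tumor_samples),
                     dimnames = list(ukeys, tumor_samples))
  vaf_mat <- matrix(0, nrow = length(ukeys), ncol = length(tumor_samples),
                    dimnames = list(ukeys, tumor_samples))
  tum_rows <- which(tum)
  i <- cbind(match(keys[tum_rows], ukeys),
             match(filtered$sample[tum_rows], tumor_samples))
  pres_mat[i] <- present[tum_rows]
  vaf_mat[i] <- ifelse(filtered$depth[tum_rows] > 0,
                       filtered$alt_count[tum_rows] / filtered$depth[tum_rows],
                       0)

  keep <- rowSums(pres_mat) > 0L
  n_dropped <- sum(!keep)
  pres_mat <- pres_mat[keep, , drop = FALSE]
  vaf_mat <- vaf_mat[keep, , drop = FALSE]

  if (nrow(pres_mat) == 0L) {
    stop("no site is present in any tumor sample after filtering",
         call. = FALSE)
  }
  topo <- classify_topology(pres_mat)
  clon <- matrix(classify_clonality(as.vector(vaf_mat), cfg),
                 nrow = nrow(vaf_mat), dimnames = dimnames(vaf_mat))

  first <- match(rownames(pres_mat), keys)
  sites <- data.frame(
    chrom = filtered$chrom[first],
    pos = filtered$pos[first],
    ref = filtered$ref[first],
    alt = filtered$alt[first],
    topology = topo,
    stringsAsFactors = FALSE
  )
  rownames(sites) <- rownames(pres_mat)

  structure(list(
    sites = sites,
    presence = pres_mat,
    vaf = vaf_mat,
    clonality = clon,
    trunk_proportion = trunk_proportion(pres_mat),
    n_dropped = n_dropped
  ), class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat("site_classification:", nrow(x$sites), "sites x",
      ncol(x$presence), "tumor samples\n")
  print(table(x$sites$topology))
  cat("trunk proportion per sample:\n")
  print(round(x$trunk_proportion, 3))
  invisible(x)
}
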