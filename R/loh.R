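# Loss-of-heterozygosity detection: germline heterozygous sites falling in
# B-allele-loss copy-number segments are tested for an allele-frequency
# shift between the matched normal and the tumor with Fisher's exact test.

segment_cols <- c("chrom", "start", "end", "total_copies", "minor_copies")

#' Validate a copy-number segment table
#'
#' Segments use BED conventions: 0-based inclusive `start`, exclusive
#' `end`. `b_allele_loss` (minor copy number zero with at least one copy
#' retained) is derived if not supplied. Segments must not overlap within a
#' chromosome.
#'
#' @param segments data.frame with columns
#'   `chrom start end total_copies minor_copies`.
#' @return The table with a `b_allele_loss` logical column.
#' @export
validate_segments <- function(segments) {
  if (!is.data.frame(segments) || !all(segment_cols %in% names(segments))) {
    stop("segments must have columns ", paste(segment_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(segments)) {
    if (any(segments$start >= segments$end)) {
      stop("input error: segment start must be < end", call. = FALSE)
    }
    if (any(segments$minor_copies > segments$total_copies) ||
        any(segments$minor_copies < 0) || any(segments$total_copies < 0)) {
      stop("input error: need 0 <= minor_copies <= total_copies",
           call. = FALSE)
    }
    for (chr in unique(segments$chrom)) {
      s <- segments[segments$chrom == chr, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1L && any(s$start[-1] < s$end[-nrow(s)])) {
        stop("input error: overlapping segments on ", chr, call. = FALSE)
      }
    }
  }
  segments$b_allele_loss <- segments$minor_copies == 0 & segments$total_copies >= 1
  segments
}

het_cols <- c("chrom", "pos", "normal_ref", "normal_alt",
              "tumor_ref", "tumor_alt")

assert_het_sites <- function(sites) {
  if (!is.data.frame(sites) || !all(het_cols %in% names(sites))) {
    stop("sites must have columns ", paste(het_cols, collapse = ", "),
         call. = FALSE)
  }
  cnt <- sites[, c("normal_ref", "normal_alt", "tumor_ref", "tumor_alt")]
  if (nrow(sites) && any(as.matrix(cnt) < 0)) {
    stop("input error: negative read counts", call. = FALSE)
  }
  invisible(sites)
}

#' Select germline heterozygous sites informative for LOH
#'
#' Keeps the sites whose (1-based) position falls inside a segment with
#' B-allele loss (minor copy number zero). Only such segments can convert a
#' balanced germline heterozygous site into a shifted one, so sites outside
#' them are uninformative for LOH. Containment is resolved with
#' `GenomicRanges::findOverlaps`, honoring the 0-based half-open segment
#' convention.
#'
#' @param sites Germline het table
#'   (`chrom pos normal_ref normal_alt tumor_ref tumor_alt`).
#' @param segments Copy-number segment table (see [validate_segments()]).
#' @return The subset of `sites` lying in B-allele-loss segments, with the
#'   matched segment's `total_copies` attached.
#' @export
select_informative_sites <- function(sites, segments) {
  assert_het_sites(sites)
  segments <- validate_segments(segments)
  loss <- segments[segments$b_allele_loss, , drop = FALSE]
  if (nrow(sites) == 0L || nrow(loss) == 0L) {
    out <- sites[integer(0), , drop = FALSE]
    out$total_copies <- integer(0)
    return(out)
  }
  q <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(sites$pos, sites$pos))
  s <- GenomicRanges::GRanges(loss$chrom,
                              IRanges::IRanges(loss$start + 1L, loss$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  out <- sites[S4Vectors::queryHits(hits), , drop = FALSE]
  out$total_copies <- loss$total_copies[S4Vectors::subjectHits(hits)]
  out
}

#' Fisher's exact test for a normal-vs-tumor allele-frequency shift
#'
#' Two-sided exact test on the 2x2 table
#' `[[normal_ref, normal_alt], [tumor_ref, tumor_alt]]` using the
#' minimum-likelihood convention (the p-value sums the probabilities of all
#' tables, with the observed margins, no more probable than the observed
#' one). Vectorized over sites.
#'
#' @param normal_ref,normal_alt Reference and alternate read counts in the
#'   matched normal.
#' @param tumor_ref,tumor_alt The same in the tumor sample.
#' @return Two-sided p-value(s) in `(0, 1]`.
#' @examples
#' fisher_shift_test(50, 50, 50, 50) # 1
#' fisher_shift_test(50, 50, 95, 5)  # ~1e-12
#' @export
fisher_shift_test <- function(normal_ref, normal_alt, tumor_ref, tumor_alt) {
  n <- max(length(normal_ref), length(normal_alt),
           length(tumor_ref), length(tumor_alt))
  normal_ref <- rep_len(normal_ref, n)
  normal_alt <- rep_len(normal_alt, n)
  tumor_ref <- rep_len(tumor_ref, n)
  tumor_alt <- rep_len(tumor_alt, n)
  cnt <- cbind(normal_ref, normal_alt, tumor_ref, tumor_alt)
  if (any(is.na(cnt)) || any(cnt < 0)) {
    stop("input error: counts must be non-negative", call. = FALSE)
  }
  if (any(normal_ref + normal_alt == 0) || any(tumor_ref + tumor_alt == 0)) {
    stop("undefined-test error: a sample with zero reads cannot be tested",
         call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    stats::fisher.test(matrix(cnt[i, ], nrow = 2, byrow = TRUE))$p.value
  }, numeric(1))
}

#' Call loss of heterozygosity at germline heterozygous sites
#'
#' Restricts to sites inside B-allele-loss segments, tests each for an
#' allele-frequency shift between normal and tumor, and calls LOH where the
#' (optionally BH-adjusted) p-value is at most `loh_alpha`. The direction
#' records which allele was lost: `alt-loss` when the tumor's alternate
#' allele fraction fell below the normal's, `ref-loss` when it rose.
#'
#' @param sites Germline het table
#'   (`chrom pos normal_ref normal_alt tumor_ref tumor_alt`).
#' @param segments Copy-number segment table.
#' @param cfg A [filter_config()]; uses `loh_alpha` and `bh_correct_loh`.
#' @return data.frame of the informative sites with added columns
#'   `p_value`, `loh`, `direction` (`NA` when the allele fractions are
#'   identical).
#' @examples
#' sites <- data.frame(chrom = "chr1", pos = 150,
#'                     normal_ref = 50, normal_alt = 50,
#'                     tumor_ref = 95, tumor_alt = 5)
#' segs <- data.frame(chrom = "chr1", start = 100, end = 200,
#'                    total_copies = 1, minor_copies = 0)
#' call_loh(sites, segs, filter_config())
#' @export
call_loh <- function(sites, segments, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  informative <- select_informative_sites(sites, segments)
  if (nrow(informative) == 0L) {
    informative$p_value <- numeric(0)
    informative$loh <- logical(0)
    informative$direction <- character(0)
    return(informative)
  }
  p <- fisher_shift_test(informative$normal_ref, informative$normal_alt,
                         informative$tumor_ref, informative$tumor_alt)
  p_use <- if (cfg$bh_correct_loh) stats::p.adjust(p, method = "BH") else p
  normal_af <- informative$normal_alt /
    (informative$normal_ref + informative$normal_alt)
  tumor_af <- informative$tumor_alt /
    (informative$tumor_ref + informative$tumor_alt)
  shifted <- tumor_af != normal_af
  informative$p_value <- p
  informative$loh <- p_use <= cfg$loh_alpha & shifted
  informative$direction <- ifelse(!shifted, NA_character_,
                                  ifelse(tumor_af < normal_af,
                                         "alt-loss", "ref-loss"))
  informative
}
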