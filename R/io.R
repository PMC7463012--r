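# Readers and writers for the pipeline's plain-text exchange formats:
# the long count TSV (1-based positions), sample metadata TSV, BED-like
# segment TSV (0-based half-open), truth TSV, and VCF 4.2 with per-sample
# allele depths.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) {
    stop("named-file error: no such file: ", path, call. = FALSE)
  }
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read / write the long count table
#'
#' Tab-separated with header `chrom pos ref alt sample depth alt_count`,
#' one row per site x sample, positions 1-based.
#'
#' @param path File path.
#' @param counts Count table to write.
#' @return `read_counts` returns the validated count table;
#'   `write_counts` returns `path` invisibly.
#' @export
read_counts <- function(path) {
  assert_counts(read_tsv(path), arg = path)
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  assert_counts(counts)
  write_tsv(counts[, count_cols], path)
}

#' Read / write sample metadata
#'
#' Tab-separated with header `sample role purity`.
#'
#' @param path File path.
#' @param meta Metadata table to write.
#' @return `read_sample_meta` returns the validated table.
#' @export
read_sample_meta <- function(path) {
  assert_meta(read_tsv(path))
}

#' @rdname read_sample_meta
#' @export
write_sample_meta <- function(meta, path) {
  assert_meta(meta)
  write_tsv(meta[, c("sample", "role", "purity")], path)
}

#' Read / write copy-number segments
#'
#' BED-like TSV with header `chrom start end total_copies minor_copies`,
#' 0-based half-open intervals.
#'
#' @param path File path.
#' @param segments Segment table to write.
#' @return `read_segments` returns the validated table with a derived
#'   `b_allele_loss` column.
#' @export
read_segments <- function(path) {
  validate_segments(read_tsv(path))
}

#' @rdname read_segments
#' @export
write_segments <- function(segments, path) {
  segments <- validate_segments(segments)
  write_tsv(segments[, segment_cols], path)
}

#' Read / write a mutation truth table
#'
#' Tab-separated with header `chrom pos ref alt origin clonality`.
#'
#' @param path File path.
#' @param truth Truth table to write.
#' @return `read_truth` returns the validated table.
#' @export
read_truth <- function(path) {
  assert_truth(read_tsv(path))
}

#' @rdname read_truth
#' @export
write_truth <- function(truth, path) {
  assert_truth(truth)
  write_tsv(truth[, c("chrom", "pos", "ref", "alt", "origin", "clonality")],
            path)
}

# ---- VCF --------------------------------------------------------------------

#' Read per-sample allele depths from a VCF into a count table
#'
#' Consumes variant-caller output (VCF 4.2) carrying a per-sample `AD`
#' (allelic depths) FORMAT field. Depth is the sum of a sample's allelic
#' depths (all alleles); `alt_count` is the depth of the named alternate.
#' Multi-allelic records are split into one row per alternate allele.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param sample_ids Optional subset of sample columns to keep.
#' @return Long count table `chrom pos ref alt sample depth alt_count`.
#' @export
read_vcf_counts <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) {
    stop("named-file error: no such file: ", path, call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (is.null(v@gt) || ncol(v@gt) < 2L || nrow(v@gt) == 0L) {
    stop("format error: VCF has no per-sample genotype columns: ", path,
         call. = FALSE)
  }
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("(^|:)AD(:|$)", fmt))) {
    bad <- which(!grepl("(^|:)AD(:|$)", fmt))[1]
    stop("format error: record ", fix[bad, "CHROM"], ":", fix[bad, "POS"],
         " has no per-sample AD (allelic depths) field", call. = FALSE)
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(ad)
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, samples)
    if (length(missing)) {
      stop("format error: samples not in VCF: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    samples <- sample_ids
  }
  rows <- list()
  for (i in seq_len(nrow(ad))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (s in samples) {
      field <- ad[i, s]
      if (is.na(field) || field == ".") {
        stop("format error: missing AD for sample ", s, " at record ",
             fix[i, "CHROM"], ":", fix[i, "POS"], call. = FALSE)
      }
      depths <- suppressWarnings(
        as.integer(strsplit(field, ",", fixed = TRUE)[[1]]))
      if (any(is.na(depths)) || length(depths) != length(alts) + 1L) {
        stop("format error: malformed AD '", field, "' at record ",
             fix[i, "CHROM"], ":", fix[i, "POS"], call. = FALSE)
      }
      for (j in seq_along(alts)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
          ref = fix[i, "REF"], alt = alts[j], sample = s,
          depth = sum(depths), alt_count = depths[j + 1L],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  assert_counts(out, arg = path)
}

#' Write a count table as a VCF 4.2 file
#'
#' Emits one record per site with one genotype column per sample carrying
#' `AD` (reference depth = depth - alt_count, alternate depth = alt_count)
#' and `DP`. Reading the file back with [read_vcf_counts()] reproduces the
#' depths exactly.
#'
#' @param counts Long count table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_counts <- function(counts, path) {
  assert_counts(counts)
  samples <- unique(counts$sample)
  keys <- site_key(counts)
  ukeys <- unique(keys)
  first <- match(ukeys, keys)
  idx <- matrix(match(paste(rep(ukeys, length(samples)),
                            rep(samples, each = length(ukeys))),
                      paste(keys, counts$sample)),
                nrow = length(ukeys))
  gt <- matrix(".:.", nrow = length(ukeys), ncol = length(samples))
  found <- !is.na(idx)
  gt[found] <- sprintf("%d,%d:%d",
                       counts$depth[idx[found]] - counts$alt_count[idx[found]],
                       counts$alt_count[idx[found]],
                       counts$depth[idx[found]])
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tumorpool",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(counts$chrom[first], counts$pos[first], ".",
                counts$ref[first], counts$alt[first], ".", ".", ".",
                "AD:DP",
                apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Long-format table behind a mutation presence heatmap
#'
#' One row per site x tumor sample with presence, raw VAF, the site's
#' topology label and the sample-level clonality label — the data behind a
#' presence/VAF heatmap of the patient's mutations.
#'
#' @param classification A `site_classification` from [classify_sites()].
#' @param path Optional path; when given the table is also written as TSV.
#' @return data.frame `site sample present vaf topology clonality`.
#' @export
write_presence_heatmap_table <- function(classification, path = NULL) {
  stopifnot(inherits(classification, "site_classification"))
  pres <- classification$presence
  out <- data.frame(
    site = rep(rownames(pres), ncol(pres)),
    sample = rep(colnames(pres), each = nrow(pres)),
    present = as.vector(pres),
    vaf = ifelse(as.vector(pres), as.vector(classification$vaf), 0),
    topology = rep(classification$sites$topology, ncol(pres)),
    clonality = as.vector(classification$clonality),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) write_tsv(out, path)
  out
}
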