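# Synthetic multi-region tumor generator. Emulates the sequencing design
# the package analyzes: several tumor regions plus one matched normal per
# patient at ~100x exome coverage, a clonal architecture of trunk / branch /
# private mutations, observed VAFs diluted by tumor purity, per-base
# sequencing error as Poisson background, and germline heterozygous sites
# inside and outside B-allele-loss segments for the LOH stage.

region_names <- function(n) paste0("R", seq_len(n))

draw_vaf <- function(n, range) runif(n, range[1], range[2])

#' Simulate the clonal ground truth of one patient
#'
#' Assigns each mutation a topology (trunk: all regions; branch: a random
#' proper subset of at least two regions; private: exactly one region), a
#' clonality class (trunk mutations are clonal; branch/private mutations
#' are sub-clonal with probability `subclonal_fraction`), and a true
#' cancer-cell VAF per region drawn from the matching range. In the
#' hypermutator preset all private mutations are confined to region 1.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `clonal_truth`: list with `mutations`
#'   (per-mutation table: `id chrom pos ref alt topology origin
#'   clonality`) and `vaf` (mutations x regions matrix of true VAFs; zero
#'   where the mutation is absent).
#' @examples
#' truth <- simulate_truth(sim_config(seed = 1))
#' table(truth$mutations$topology)
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  R <- cfg$n_regions
  n <- cfg$n_trunk + cfg$n_branch + cfg$n_private
  if (n == 0L) stop("config error: no mutations to simulate", call. = FALSE)

  with_seed_if(derive_seed(cfg$seed, 1L), {
    pos <- sort(sample.int(3e7, n))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                  character(1))
    topology <- rep(c("trunk", "branch", "private"),
                    c(cfg$n_trunk, cfg$n_branch, cfg$n_private))

    present <- matrix(FALSE, n, R, dimnames = list(NULL, region_names(R)))
    present[topology == "trunk", ] <- TRUE
    for (i in which(topology == "branch")) {
      k <- if (R > 3L) sample(2:(R - 1L), 1L) else 2L
      present[i, sample.int(R, k)] <- TRUE
    }
    for (i in which(topology == "private")) {
      reg <- if (cfg$hypermutator) 1L else sample.int(R, 1L)
      present[i, reg] <- TRUE
    }

    clonality <- rep("clonal", n)
    non_trunk <- topology != "trunk"
    clonality[non_trunk] <-
      ifelse(runif(sum(non_trunk)) < cfg$subclonal_fraction,
             "subclonal", "clonal")

    vaf_of <- function(i) {
      if (topology[i] == "private" && !is.null(cfg$private_vaf_range)) {
        return(draw_vaf(sum(present[i, ]), cfg$private_vaf_range))
      }
      rng <- if (clonality[i] == "clonal") cfg$clonal_vaf_range else
        cfg$subclonal_vaf_range
      draw_vaf(sum(present[i, ]), rng)
    }
    vaf <- matrix(0, n, R, dimnames = list(NULL, region_names(R)))
    for (i in seq_len(n)) vaf[i, present[i, ]] <- vaf_of(i)

    origin <- vapply(seq_len(n), function(i) {
      if (topology[i] == "trunk") "all" else
        paste(region_names(R)[present[i, ]], collapse = ",")
    }, character(1))

    mutations <- data.frame(
      id = sprintf("mut%04d", seq_len(n)),
      chrom = "chr1", pos = pos, ref = ref, alt = alt,
      topology = topology, origin = origin, clonality = clonality,
      stringsAsFactors = FALSE
    )
    rownames(vaf) <- mutations$id
    structure(list(mutations = mutations, vaf = vaf),
              class = "clonal_truth")
  })
}

#' @export
print.clonal_truth <- function(x, ...) {
  cat("clonal_truth:", nrow(x$mutations), "mutations x",
      ncol(x$vaf), "regions\n")
  print(table(x$mutations$topology, x$mutations$clonality))
  invisible(x)
}

#' Simulate observed read counts from a clonal truth
#'
#' Per region and mutation: depth is Poisson around `coverage_mean` and
#' mutant reads are binomial with success probability
#' `purity * true_vaf + error_rate` (tumor cells diluted by stromal
#' contamination, plus the sequencing-error floor). The matched normal
#' ("N") carries error reads only at somatic sites.
#'
#' @param truth A `clonal_truth` from [simulate_truth()].
#' @param cfg The same [sim_config()].
#' @return list with `counts` (long count table over all regions and the
#'   normal) and `meta` (`sample role purity`).
#' @export
simulate_counts <- function(truth, cfg) {
  stopifnot(inherits(truth, "clonal_truth"), inherits(cfg, "sim_config"))
  R <- cfg$n_regions
  mut <- truth$mutations
  n <- nrow(mut)
  with_seed_if(derive_seed(cfg$seed, 2L), {
    tabs <- lapply(seq_len(R), function(r) {
      depth <- rpois(n, cfg$coverage_mean)
      p <- pmin(1, cfg$purity[r] * truth$vaf[, r] + cfg$error_rate)
      alt_count <- rbinom(n, depth, p)
      data.frame(chrom = mut$chrom, pos = mut$pos, ref = mut$ref,
                 alt = mut$alt, sample = region_names(R)[r],
                 depth = depth, alt_count = alt_count,
                 stringsAsFactors = FALSE)
    })
    depth_n <- rpois(n, cfg$coverage_mean)
    normal <- data.frame(chrom = mut$chrom, pos = mut$pos, ref = mut$ref,
                         alt = mut$alt, sample = "N", depth = depth_n,
                         alt_count = rbinom(n, depth_n, cfg$error_rate),
                         stringsAsFactors = FALSE)
    counts <- do.call(rbind, c(tabs, list(normal)))
    rownames(counts) <- NULL
    meta <- data.frame(
      sample = c(region_names(R), "N"),
      role = c(rep("region", R), "normal"),
      purity = c(cfg$purity, 1),
      stringsAsFactors = FALSE
    )
    list(counts = counts, meta = meta)
  })
}

#' Simulate a full patient (truth plus observed counts)
#'
#' @param cfg A [sim_config()].
#' @return list with `truth`, `counts`, `meta`.
#' @examples
#' pat <- simulate_patient(sim_config(seed = 42))
#' head(pat$counts)
#' @export
simulate_patient <- function(cfg) {
  truth <- simulate_truth(cfg)
  obs <- simulate_counts(truth, cfg)
  list(truth = truth, counts = obs$counts, meta = obs$meta)
}

#' Pool several regions into one global sample
#'
#' Emulates a global specimen whose DNA is combined from several distinct
#' regions and sequenced once: each region's read pool is thinned to its
#' weight and the thinned counts are summed per site, so the pooled
#' coverage stays at one sample's coverage while region-private mutations
#' are diluted by their weight.
#'
#' @param regions List of read pools (or a count table plus `samples`).
#' @param weights Mixing weights, one per region, summing to 1. Equal by
#'   default.
#' @param seed Optional integer seed.
#' @param counts Alternatively, a long count table from which pools are
#'   extracted for `samples`.
#' @param samples Sample ids to extract from `counts`.
#' @return A read pool for the pooled sample.
#' @export
make_global_pool <- function(regions = NULL, weights = NULL, seed = NULL,
                             counts = NULL, samples = NULL) {
  if (is.null(regions)) {
    if (is.null(counts) || is.null(samples)) {
      stop("provide either a list of pools or counts + samples",
           call. = FALSE)
    }
    regions <- lapply(samples, function(s) read_pool(counts, s))
  }
  k <- length(regions)
  if (k == 0L) stop("config error: no regions to pool", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || abs(sum(weights) - 1) > 1e-8 ||
      any(weights < 0)) {
    stop("config error: weights must be non-negative, one per region, ",
         "and sum to 1", call. = FALSE)
  }
  if (k == 1L) return(regions[[1L]])
  with_seed_if(seed, {
    pooled <- NULL
    for (i in seq_len(k)) {
      thinned <- if (weights[i] == 0) NULL else
        thin_counts(regions[[i]], weights[i])
      if (is.null(thinned)) next
      pooled <- if (is.null(pooled)) thinned else
        combine_pools(pooled, thinned)
    }
    pooled
  })
}

#' Simulate germline heterozygous sites and copy-number segments for LOH
#'
#' Places `n_germline_het` heterozygous sites along one chromosome and
#' `n_loh_segments` B-allele-loss segments (total copy number 1, minor 0)
#' over a random subset of them; an equal number of copy-neutral segments
#' (2/1) covers other sites. Normal counts are balanced binomial draws;
#' tumor counts at LOH sites are shifted to the expected B-allele fraction
#' `(1 - purity) / ((1 - purity) * 2 + purity * total_cn)` (the lost allele
#' is chosen at random per segment), while sites outside loss segments stay
#' balanced.
#'
#' @param cfg A [sim_config()]; uses `n_germline_het`, `n_loh_segments`,
#'   `coverage_mean`, and the first region's purity.
#' @return list with `sites` (germline het table), `segments`, and `truth`
#'   (per-site logical `in_loh`).
#' @examples
#' loh <- simulate_loh_data(sim_config(seed = 5))
#' table(loh$truth$in_loh)
#' @export
simulate_loh_data <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_germline_het
  n_seg <- cfg$n_loh_segments
  purity <- cfg$purity[1]
  with_seed_if(derive_seed(cfg$seed, 3L), {
    # evenly spaced site blocks so segments can be laid down without overlap
    pos <- sort(sample.int(5e7, n))
    # carve the chromosome into 2 * n_seg equal windows: odd ones get the
    # B-allele-loss state, even ones stay copy-neutral
    n_win <- max(1L, 2L * n_seg)
    brk <- seq(0L, 5e7, length.out = n_win + 1L)
    segments <- data.frame(
      chrom = "chr1",
      start = as.integer(floor(brk[-length(brk)])),
      end = as.integer(floor(brk[-1])),
      total_copies = 2L, minor_copies = 1L,
      stringsAsFactors = FALSE
    )
    if (n_seg > 0L) {
      loss_idx <- seq(1L, n_win, by = 2L)[seq_len(n_seg)]
      segments$total_copies[loss_idx] <- 1L
      segments$minor_copies[loss_idx] <- 0L
    }
    seg_of <- findInterval(pos - 1L, segments$start)
    in_loh <- segments$minor_copies[seg_of] == 0L

    total_cn <- segments$total_copies[seg_of]
    baf_loh <- (1 - purity) / ((1 - purity) * 2 + purity * total_cn)
    alt_lost <- runif(nrow(segments)) < 0.5 # per segment, which allele goes
    site_alt_lost <- alt_lost[seg_of]
    p_tumor <- ifelse(in_loh,
                      ifelse(site_alt_lost, baf_loh, 1 - baf_loh),
                      0.5)

    depth_n <- rpois(n, cfg$coverage_mean)
    alt_n <- rbinom(n, depth_n, 0.5)
    depth_t <- rpois(n, cfg$coverage_mean)
    alt_t <- rbinom(n, depth_t, p_tumor)

    sites <- data.frame(
      chrom = "chr1", pos = pos,
      normal_ref = depth_n - alt_n, normal_alt = alt_n,
      tumor_ref = depth_t - alt_t, tumor_alt = alt_t,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(chrom = "chr1", pos = pos, in_loh = in_loh,
                        alt_lost = site_alt_lost & in_loh,
                        stringsAsFactors = FALSE)
    list(sites = sites, segments = segments, truth = truth)
  })
}
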