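test_that("simulation configs validate their invariants", {
  expect_error(sim_config(n_regions = 1), "n_regions")
  expect_error(sim_config(n_regions = 2, n_branch = 5), "branch")
  expect_error(sim_config(purity = 1.5), "purity")
  expect_error(sim_config(clonal_vaf_range = c(0.5, 0.2)), "clonal_vaf_range")
  expect_error(sim_config(n_germline_het = 5, n_loh_segments = 6),
               "n_loh_segments")
  hyp <- sim_config(hypermutator = TRUE)
  expect_equal(hyp$n_private, 500L)
  expect_equal(hyp$private_vaf_range, c(0.10, 0.15))
})

test_that("truth respects the clonal topology constraints", {
  cfg <- sim_config(n_trunk = 80, n_branch = 0, n_private = 0, seed = 2)
  truth <- simulate_truth(cfg)
  expect_true(all(truth$mutations$topology == "trunk"))
  expect_true(all(truth$vaf > 0)) # trunk present in every region

  cfg <- sim_config(n_trunk = 0, n_branch = 0, n_private = 30, seed = 2)
  truth <- simulate_truth(cfg)
  expect_true(all(rowSums(truth$vaf > 0) == 1)) # private: exactly one region

  cfg <- sim_config(n_trunk = 0, n_branch = 40, n_private = 0,
                    n_regions = 4, seed = 2)
  truth <- simulate_truth(cfg)
  k <- rowSums(truth$vaf > 0)
  expect_true(all(k >= 2 & k < 4)) # branch: proper subset of >= 2

  # noiseless presence recovers the labels
  labels <- classify_topology(truth$vaf > 0)
  expect_true(all(labels == "branch"))
})

test_that("identical config and seed reproduce the simulation byte for byte", {
  cfg <- sim_config(seed = 77)
  p1 <- simulate_patient(cfg)
  p2 <- simulate_patient(cfg)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$counts, p2$counts)
  p3 <- simulate_patient(sim_config(seed = 78))
  expect_false(identical(p1$counts, p3$counts))
})

test_that("generated tables satisfy the count invariants", {
  for (s in c(1, 2)) {
    pat <- simulate_patient(sim_config(seed = s))
    cnt <- pat$counts
    expect_true(all(cnt$alt_count <= cnt$depth))
    expect_true(all(cnt$pos >= 1))
    expect_false(anyDuplicated(
      paste(cnt$chrom, cnt$pos, cnt$ref, cnt$alt, cnt$sample)) > 0)
    expect_setequal(unique(cnt$sample), c("R1", "R2", "R3", "N"))
  }
})

test_that("observed VAF expectation is purity times true VAF", {
  # high coverage pins the observed VAF to its expectation
  cfg <- sim_config(n_regions = 2, n_trunk = 200, n_branch = 0, n_private = 0,
                    subclonal_fraction = 0, clonal_vaf_range = c(0.5, 0.5),
                    coverage_mean = 10000, purity = 1, error_rate = 0,
                    seed = 31)
  pat <- simulate_patient(cfg)
  r1 <- pat$counts[pat$counts$sample == "R1", ]
  vaf <- r1$alt_count / r1$depth
  expect_gte(mean(vaf >= 0.48 & vaf <= 0.52), 0.99)

  cfg2 <- sim_config(n_regions = 2, n_trunk = 300, n_branch = 0,
                     n_private = 0, subclonal_fraction = 0,
                     clonal_vaf_range = c(0.4, 0.4), coverage_mean = 400,
                     purity = 0.5, error_rate = 0, seed = 32)
  pat2 <- simulate_patient(cfg2)
  r1 <- pat2$counts[pat2$counts$sample == "R1", ]
  expect_lt(abs(mean(r1$alt_count / r1$depth) - 0.2), 0.01)

  # error_rate 0 and true VAF 0: the normal never shows alt reads
  expect_true(all(pat2$counts$alt_count[pat2$counts$sample == "N"] == 0))
})

test_that("global pooling preserves shared VAF and dilutes private ones", {
  cfg <- sim_config(n_trunk = 150, n_branch = 0, n_private = 150,
                    subclonal_fraction = 0, clonal_vaf_range = c(0.4, 0.4),
                    private_vaf_range = c(0.3, 0.3), coverage_mean = 300,
                    purity = 1, error_rate = 0, seed = 41)
  pat <- simulate_patient(cfg)
  pools <- lapply(c("R1", "R2", "R3"), function(s) read_pool(pat$counts, s))
  expect_identical(make_global_pool(pools[1], weights = 1), pools[[1]])

  glob <- make_global_pool(pools, seed = 7)
  tr <- pat$truth$mutations
  key_g <- paste(glob$chrom, glob$pos)
  vaf_g <- ifelse(glob$depth > 0, glob$alt_count / glob$depth, NA)
  trunk_vaf <- vaf_g[match(paste(tr$chrom, tr$pos)[tr$topology == "trunk"],
                           key_g)]
  priv_vaf <- vaf_g[match(paste(tr$chrom, tr$pos)[tr$topology == "private"],
                          key_g)]
  expect_lt(abs(mean(trunk_vaf, na.rm = TRUE) - 0.4), 0.02)
  expect_lt(abs(mean(priv_vaf, na.rm = TRUE) - 0.1), 0.02)

  expect_error(make_global_pool(pools, weights = c(0.5, 0.5)), "weights")
})

test_that("LOH simulation shifts only sites inside loss segments", {
  cfg <- sim_config(seed = 51, n_germline_het = 400, n_loh_segments = 5,
                    purity = 1)
  sim <- simulate_loh_data(cfg)
  expect_equal(nrow(sim$sites), 400)
  segs <- validate_segments(sim$segments)
  expect_equal(sum(segs$b_allele_loss), 5)

  baf <- sim$sites$tumor_alt / (sim$sites$tumor_ref + sim$sites$tumor_alt)
  # purity 1 with full B-allele loss: one allele vanishes entirely
  shifted <- sim$truth$in_loh
  expect_true(all(baf[shifted] %in% c(0, 1)))
  expect_true(all(abs(baf[!shifted] - 0.5) < 0.35))

  # determinism
  sim2 <- simulate_loh_data(cfg)
  expect_identical(sim, sim2)
})
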