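test_that("purity-corrected VAF divides by purity and clamps at 1", {
  expect_equal(purity_corrected_vaf(10, 100, 0.5), 0.20)
  expect_equal(purity_corrected_vaf(0, 80, 0.7), 0)
  expect_equal(purity_corrected_vaf(90, 100, 0.6), 1) # clamped from 1.5
  # equals raw VAF at purity 1
  expect_equal(purity_corrected_vaf(13, 100, 1), 0.13)
  expect_error(purity_corrected_vaf(5, 0, 0.5), "depth")
  expect_error(purity_corrected_vaf(5, 100, 0), "purity")
  expect_error(purity_corrected_vaf(5, 100, 1.2), "purity")
  expect_error(purity_corrected_vaf(101, 100, 1), "alt_count")
})

test_that("purity-corrected VAF is monotone in alt_count and purity", {
  alts <- 0:50
  v <- purity_corrected_vaf(alts, 100, 0.8)
  expect_true(all(diff(v) >= 0))
  purities <- seq(0.1, 1, by = 0.05)
  v2 <- purity_corrected_vaf(20, 100, purities)
  expect_true(all(diff(v2) <= 0))
})

test_that("hard filters gate on depth, corrected VAF and mutant reads", {
  cfg <- filter_config()
  meta <- meta_for(c("R1", "R2", "R3"))

  cnt <- one_site_counts(c(100, 100, 100), c(6, 0, 0))
  out <- passes_site_filters(cnt, meta, cfg)
  expect_equal(out$sample_pass, c(TRUE, FALSE, FALSE))
  expect_true(all(out$site_pass))

  # all depths below 50: site fails
  out <- passes_site_filters(one_site_counts(c(40, 40, 40), c(10, 10, 10)),
                             meta, cfg)
  expect_false(any(out$site_pass))

  # no region reaches 5 mutant reads: site fails even if samples pass VAF
  out <- passes_site_filters(one_site_counts(c(100, 100, 100), c(4, 4, 4)),
                             meta, cfg)
  expect_equal(out$sample_pass, c(FALSE, FALSE, FALSE)) # cvaf 0.04 < 0.05
  expect_false(any(out$site_pass))

  # purity correction can rescue the VAF gate: 4/100 at purity 0.5 -> 0.08
  out <- passes_site_filters(one_site_counts(c(100, 100, 100), c(4, 4, 4)),
                             meta_for(c("R1", "R2", "R3"), purity = 0.5), cfg)
  expect_equal(out$sample_pass, c(TRUE, TRUE, TRUE))
  expect_false(any(out$site_pass)) # still no sample with >= 5 mutant reads

  expect_error(
    passes_site_filters(one_site_counts(100, 5, samples = "X"), meta, cfg),
    "metadata")
})

test_that("normal-sample rows never pass and do not lend mutant-read support", {
  cfg <- filter_config()
  cnt <- one_site_counts(c(100, 100), c(0, 50), samples = c("R1", "NORM"))
  out <- passes_site_filters(cnt, meta_for("R1"), cfg)
  expect_equal(out$sample_pass, c(FALSE, FALSE))
  expect_false(any(out$site_pass)) # the 50 alt reads sit in the normal
})

test_that("degenerate thresholds pass every site with coverage", {
  cfg <- filter_config(min_depth = 0, min_alt = 0, min_corrected_vaf = 0)
  cnt <- one_site_counts(c(80, 1, 200), c(0, 0, 3))
  out <- passes_site_filters(cnt, meta_for(c("R1", "R2", "R3")), cfg)
  expect_true(all(out$sample_pass))
  expect_true(all(out$site_pass))
})

test_that("topology classification follows the presence pattern", {
  expect_equal(classify_topology(c(TRUE, TRUE, TRUE)), "trunk")
  expect_equal(classify_topology(c(TRUE, FALSE, TRUE)), "branch")
  expect_equal(classify_topology(c(FALSE, TRUE, FALSE)), "private")
  expect_error(classify_topology(c(FALSE, FALSE, FALSE)), "not-present")
  expect_error(classify_topology(TRUE), "2 tumor samples")

  m <- rbind(c(TRUE, TRUE, TRUE), c(TRUE, FALSE, TRUE), c(FALSE, TRUE, FALSE))
  expect_equal(classify_topology(m), c("trunk", "branch", "private"))
})

test_that("every present site gets exactly one topology label", {
  set.seed(42)
  for (i in 1:20) {
    n_samp <- sample(2:6, 1)
    m <- matrix(runif(40 * n_samp) < 0.5, ncol = n_samp)
    m <- m[rowSums(m) > 0, , drop = FALSE]
    labels <- classify_topology(m)
    expect_true(all(labels %in% c("trunk", "branch", "private")))
    expect_equal(labels == "trunk", rowSums(m) == n_samp)
    expect_equal(labels == "private", rowSums(m) == 1)
  }
})

test_that("clonality threshold is 10% with the boundary assigned clonal", {
  cfg <- filter_config()
  expect_equal(classify_clonality(0.40, cfg), "clonal")
  expect_equal(classify_clonality(0.02, cfg), "subclonal")
  expect_equal(classify_clonality(0.10, cfg), "clonal")
  expect_error(classify_clonality(1.2, cfg), "vaf")
})

test_that("trunk proportion counts trunk share among present sites", {
  m <- matrix(TRUE, nrow = 3, ncol = 3)
  expect_equal(unname(trunk_proportion(m)), c(1, 1, 1))

  m <- rbind(c(TRUE, TRUE, TRUE), c(TRUE, FALSE, FALSE),
             c(TRUE, FALSE, FALSE))
  expect_equal(unname(trunk_proportion(m)), c(1 / 3, 1, 1))

  # 10 trunk + 30 private-to-sample1: sample1 sees 40 sites, 10 trunk
  m <- rbind(matrix(TRUE, 10, 3),
             matrix(rep(c(TRUE, FALSE, FALSE), each = 30), ncol = 3))
  expect_equal(unname(trunk_proportion(m))[1], 0.25)
  expect_equal(unname(trunk_proportion(m))[2:3], c(1, 1))
})

test_that("trunk proportion is invariant under site-order permutation", {
  set.seed(7)
  m <- matrix(runif(60) < 0.6, ncol = 3)
  m <- m[rowSums(m) > 0, ]
  perm <- sample(nrow(m))
  expect_equal(trunk_proportion(m), trunk_proportion(m[perm, ]))
})

test_that("classify_sites recovers topology and reports trunk proportions", {
  cfg <- sim_config(seed = 3)
  pat <- simulate_patient(cfg)
  cls <- classify_sites(pat$counts, pat$meta, filter_config(),
                        background = cfg$error_rate)
  expect_s3_class(cls, "site_classification")
  expect_equal(ncol(cls$presence), 3)
  expect_true(all(rowSums(cls$presence) > 0))
  expect_true(all(cls$sites$topology %in% c("trunk", "branch", "private")))
  expect_true(all(cls$trunk_proportion > 0 & cls$trunk_proportion <= 1))
  # most sites should classify correctly at these settings
  truth <- pat$truth$mutations
  key <- paste(truth$chrom, truth$pos, truth$ref, truth$alt, sep = ":")
  found <- match(rownames(cls$sites), key)
  acc <- mean(cls$sites$topology == truth$topology[found])
  expect_gt(acc, 0.9)
})
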