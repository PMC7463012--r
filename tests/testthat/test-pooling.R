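test_that("thinning keeps counts consistent and preserves expected VAF", {
  pool <- simple_pool(depths = c(1000, 10, 0), alts = c(400, 0, 0))

  expect_identical(thin_counts(pool, 1), pool)

  out <- thin_counts(pool, 0.5, seed = 1)
  expect_true(all(out$alt_count <= out$depth))
  expect_true(all(out$depth <= pool$depth))
  expect_equal(out$alt_count[2], 0) # no alt reads to sample
  expect_equal(out$depth[3], 0)

  # Monte-Carlo: mean alt' over replicate seeds within 3 SE of 200
  alts <- vapply(1:1000, function(s) {
    thin_counts(pool, 0.5, seed = s)$alt_count[1]
  }, numeric(1))
  se <- sd(alts) / sqrt(length(alts))
  expect_lt(abs(mean(alts) - 200), 3 * se)

  expect_error(thin_counts(pool, 0), "domain")
  expect_error(thin_counts(pool, 1.5), "domain")
})

test_that("thinning is reproducible for a fixed seed", {
  pool <- simple_pool(rpois(50, 100), rbinom(50, 40, 0.5))
  expect_identical(thin_counts(pool, 0.3, seed = 99),
                   thin_counts(pool, 0.3, seed = 99))
})

test_that("iterative 10% tranches reach the target and exhaust at 1.0", {
  pool <- simple_pool(depths = rep(1000, 20), alts = rep(300, 20))
  out <- iterative_subsample(pool, 0.3, step = 0.1, seed = 5)
  total <- sum(out$depth)
  expect_lt(abs(total - 0.3 * sum(pool$depth)) / sum(pool$depth), 0.05)
  expect_true(all(out$alt_count <= out$depth))

  full <- iterative_subsample(pool, 1.0, step = 0.1, seed = 5)
  expect_equal(full$depth, pool$depth)
  expect_equal(full$alt_count, pool$alt_count)

  expect_error(iterative_subsample(pool, 0.3, step = 0), "domain")
  expect_error(iterative_subsample(pool, 0, step = 0.1), "domain")
})

test_that("iterative subsampling matches one-shot thinning in distribution", {
  pool <- simple_pool(depths = 1000, alts = 400)
  one_shot <- vapply(1:500, function(s)
    thin_counts(pool, 0.3, seed = s)$alt_count, numeric(1))
  iterative <- vapply(1:500, function(s)
    iterative_subsample(pool, 0.3, step = 0.1, seed = 100000 + s)$alt_count,
    numeric(1))
  ks <- suppressWarnings(ks.test(one_shot, iterative))
  expect_gt(ks$p.value, 0.01)
})

test_that("mixing pools dilutes private mutations by their share", {
  a <- simple_pool(depths = c(100, 100), alts = c(40, 0), pos = 1:2)
  b <- simple_pool(depths = c(100, 100), alts = c(0, 40), pos = 1:2)

  expect_identical(mix_pools(a, b, proportion_b = 0), a)
  expect_identical(mix_pools(a, b, proportion_b = 1), b)

  # site private to b at VAF 0.4, 50:50 mix of equal depths -> VAF ~ 0.2
  vafs <- vapply(1:400, function(s) {
    m <- mix_pools(a, b, 0.5, seed = s)
    m$alt_count[2] / m$depth[2]
  }, numeric(1))
  expect_lt(abs(mean(vafs) - 0.2), 3 * sd(vafs) / sqrt(length(vafs)))

  # expected mixture depth = mean of the input depths at total_scale 1
  depths <- vapply(1:400, function(s)
    mean(mix_pools(a, b, 0.5, seed = s)$depth), numeric(1))
  expect_lt(abs(mean(depths) - 100), 3 * sd(depths) / sqrt(length(depths)))

  expect_error(mix_pools(a, b, -0.1), "domain")
  expect_error(mix_pools(a, b, 0.1, total_scale = 3), "domain")
})

test_that("mixing handles disjoint site universes via the union", {
  a <- simple_pool(100, 30, pos = 1)
  b <- simple_pool(100, 20, pos = 2)
  m <- mix_pools(a, b, 0.5, seed = 1)
  expect_equal(nrow(m), 2)
  expect_true(all(m$alt_count <= m$depth))
})

test_that("combining pools sums counts site by site", {
  a <- simple_pool(c(100, 100), c(30, 0), pos = 1:2)
  b <- simple_pool(c(50, 50), c(10, 25), pos = c(1, 3))
  cmb <- combine_pools(a, b)
  expect_equal(nrow(cmb), 3)
  expect_equal(cmb$depth[cmb$pos == 1], 150)
  expect_equal(cmb$alt_count[cmb$pos == 1], 40)
  expect_equal(cmb$depth[cmb$pos == 3], 50)
})

test_that("bootstrap upscaling preserves VAF and cannot invent alt reads", {
  pool <- simple_pool(depths = c(100, 100), alts = c(40, 0))
  out <- upscale_pool(pool, 2, seed = 1)
  expect_equal(out$alt_count[2], 0)

  depths <- vapply(1:500, function(s)
    upscale_pool(pool, 2, seed = s)$depth[1], numeric(1))
  expect_lt(abs(mean(depths) - 200), 3 * sd(depths) / sqrt(length(depths)))

  # VAF concentrates around the original as fold grows
  vafs <- vapply(1:200, function(s) {
    u <- upscale_pool(pool, 10, seed = s)
    u$alt_count[1] / u$depth[1]
  }, numeric(1))
  expect_lt(mean(abs(vafs - 0.4)), 0.05)

  expect_error(upscale_pool(pool, 1), "guard")
  expect_error(upscale_pool(pool, 0.5), "guard")
})

test_that("scale_pool dispatches across the fold axis", {
  pool <- simple_pool(1000, 100)
  expect_identical(scale_pool(pool, 1), pool)
  expect_lt(scale_pool(pool, 0.1, seed = 1)$depth, 1000)
  expect_gt(scale_pool(pool, 5, seed = 1)$depth, 1000)
  expect_error(scale_pool(pool, 0), "domain")
})

test_that("thinning conserves alt' <= depth' <= depth for any seed", {
  set.seed(4)
  pool <- simple_pool(rpois(100, 120), rbinom(100, 60, 0.4))
  for (s in 1:10) {
    for (f in c(0.1, 0.5, 0.9)) {
      out <- thin_counts(pool, f, seed = s)
      expect_true(all(out$alt_count <= out$depth))
      expect_true(all(out$depth <= pool$depth))
    }
  }
})

test_that("sweep detection requires coverage plus reads or genotyper rescue", {
  cfg <- filter_config()
  pool <- simple_pool(depths = c(100, 100, 100, 30, 100),
                      alts = c(10, 3, 0, 20, 1))
  det <- detect_in_pool(pool, cfg, error_rate = 1e-3)
  expect_true(det[1])   # hard filter: 10 >= 5
  expect_true(det[2])   # rescue: P(X>=3 | 0.1) << 0.01
  expect_false(det[3])  # no alt reads
  expect_false(det[4])  # depth below 50 even with many alt reads
  expect_false(det[5])  # single read at lambda 0.1: p ~ 0.095
})

test_that("composition sweep scores detection per class and origin", {
  scfg <- sim_config(n_regions = 2, n_trunk = 30, n_branch = 0,
                     n_private = 40, subclonal_fraction = 0,
                     coverage_mean = 70, purity = 1, seed = 9)
  pat <- simulate_patient(scfg)
  tr <- pat$truth$mutations
  truth <- tr[, c("chrom", "pos", "ref", "alt", "origin", "clonality")]
  a <- read_pool(pat$counts, "R1")
  b <- read_pool(pat$counts, "R2")
  cs <- composition_sweep(a, b, truth, deciles = c(0.1, 0.5),
                          replicates = 4, base_seed = 3)
  expect_s3_class(cs, "data.frame")
  expect_setequal(unique(cs$axis_value), c(0.1, 0.5))
  expect_setequal(unique(cs$origin), c("all", "R1", "R2"))
  expect_true(all(cs$detected_fraction >= 0 & cs$detected_fraction <= 1))
  # sites private to b are invisible when b is absent from the mix
  m0 <- mix_pools(a, b, 0)
  det0 <- detect_in_pool(m0, filter_config(), 1e-3)
  b_private <- truth$origin == "R2"
  idx <- match(paste(truth$chrom, truth$pos)[b_private],
               paste(m0$chrom, m0$pos))
  expect_false(any(det0[idx], na.rm = TRUE))
  expect_error(composition_sweep(a, b, truth[0, ]), "truth")
})

test_that("detection is monotone non-decreasing in coverage fold", {
  scfg <- sim_config(n_regions = 2, n_trunk = 40, n_branch = 0,
                     n_private = 40, subclonal_fraction = 0.5,
                     coverage_mean = 50, purity = 1, seed = 13)
  pat <- simulate_patient(scfg)
  tr <- pat$truth$mutations
  truth <- tr[, c("chrom", "pos", "ref", "alt", "origin", "clonality")]
  pooled <- combine_pools(read_pool(pat$counts, "R1"),
                          read_pool(pat$counts, "R2"))
  cov <- coverage_sweep(pooled, truth, folds = c(0.25, 0.5, 1, 5, 20),
                        replicates = 6, base_seed = 17)
  md <- mean_detection(cov)
  for (cl in c("clonal", "subclonal")) {
    d <- md[md$class == cl & md$origin == "all", ]
    d <- d[order(d$axis_value), ]
    tol <- pmax(d$se[-nrow(d)], d$se[-1]) # 1 SE slack on each step
    expect_true(all(diff(d$mean_detected) >= -tol))
  }
})
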