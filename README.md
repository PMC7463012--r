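# tumorpool

Sampling-strategy analysis for multi-region tumor sequencing.

Tumors carry a clonal architecture: **trunk** mutations shared by every
region, **branch** mutations shared by a subset, and region-**private**
mutations. Because clinical sequencing usually profiles one specimen, the
sampling strategy — a single biopsy, combined local biopsies, or DNA
pooled from several distinct regions — decides which of those mutations
are detectable at all. `tumorpool` is for bioinformaticians and
method developers who want to quantify that trade-off on per-sample read
counts: it implements the filtering/genotyping stack of a multi-region
somatic pipeline and an in silico pooling experiment, together with a
synthetic data generator so every stage is testable without patient data.

## What it computes

- **Somatic hard filters and purity-corrected VAF selection** — a
  sample-level pass needs depth ≥ 50 and corrected VAF
  (raw VAF / purity, clamped at 1) ≥ 5%; a site-level call needs ≥ 5
  mutant reads in at least one tumor sample.
- **Poisson joint genotyper** — once a mutation is called anywhere in a
  patient, every other sample is tested against its own background error
  rate *e* (estimated from non-variant flanking positions): with depth
  *n* and *k* mutant reads, accept when
  `P(X ≥ k | X ~ Poisson(e·n)) ≤ α` and `k ≥ 1` (default α = 0.01).
- **Topology and clonality classification** — trunk/branch/private from
  presence patterns; clonal when VAF ≥ 10%, sub-clonal below; per-sample
  trunk proportions.
- **LOH detection** — germline heterozygous sites inside B-allele-loss
  copy-number segments, tested for a normal-vs-tumor allele-frequency
  shift with a two-sided Fisher exact test (α = 0.05).
- **In silico pooling** — composition sweeps (mix two samples' reads at
  every decile, ten replicates) and coverage sweeps (0.1- to 100-fold of
  the combined input, via binomial/hypergeometric thinning and bootstrap
  upscaling), reporting detected fractions of clonal and sub-clonal
  mutations per origin.
- **Synthetic cohorts** — multi-region patients with known clonal truth
  (including a hypermutator preset with 500 private near-threshold
  mutations in one region), plus germline/LOH data.

## Worked example

```r
library(tumorpool)

cfg <- sim_config(seed = 11)            # 3 regions + normal, 100x, purity 0.7
pat <- simulate_patient(cfg)
cls <- classify_sites(pat$counts, pat$meta, filter_config(),
                      background = cfg$error_rate)
cls
#> site_classification: 149 sites x 3 tumor samples
#>
#>  branch private   trunk
#>      27      32      90
#> trunk proportion per sample:
#>    R1    R2    R3
#> 0.756 0.769 0.750
```

Of the 150 simulated mutations (90 trunk / 30 branch / 30 private), 149
survive filtering and the trunk count is recovered exactly; each region's
detected mutations are ~75% trunk. Titrating the coverage of a two-region
pool shows why depth buys sub-clonal, not clonal, sensitivity:

```r
truth <- pat$truth$mutations[, c("chrom","pos","ref","alt","origin","clonality")]
pooled <- combine_pools(read_pool(pat$counts, "R1"),
                        read_pool(pat$counts, "R2"))
md <- mean_detection(coverage_sweep(pooled, truth, folds = c(0.5, 1, 10),
                                    replicates = 5, base_seed = 1))
md[md$origin == "all", ]
#>           axis axis_value     class origin mean_detected         se
#>  coverage_fold        0.5    clonal    all     0.9548872 0.00000000
#>  coverage_fold        1.0    clonal    all     0.9548872 0.00000000
#>  coverage_fold       10.0    clonal    all     0.9548872 0.00000000
#>  coverage_fold        0.5 subclonal    all     0.4235294 0.03373461
#>  coverage_fold        1.0 subclonal    all     0.6470588 0.00000000
#>  coverage_fold       10.0 subclonal    all     0.7647059 0.00000000
```

Clonal detection is already saturated at half the combined coverage,
while sub-clonal detection keeps climbing with depth (bootstrap
upscaling caps it below 1: a site that never showed a mutant read cannot
gain one). `run_pipeline()` chains simulate → genotype → classify → LOH →
sweeps and writes every stage as TSV with a seed-stamped log; see the
vignette in `vignettes/tumor-sampling-strategies.Rmd` for the full model
description.

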