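---
title: "How tumor sampling strategy shapes somatic mutation detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How tumor sampling strategy shapes somatic mutation detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorpool)
```

## The question

Tumors are spatially heterogeneous: a founding clone's mutations (the
*trunk*) are carried by every region, while later *branch* and
region-*private* mutations are confined to parts of the tumor. Clinical
sequencing usually profiles a single specimen, so the sampling strategy —
one biopsy, several neighboring (local) biopsies, or DNA pooled from
multiple distinct regions — determines which mutations the assay can see
at all. `tumorpool` provides the statistical machinery to study this
trade-off quantitatively: filters and genotyping on per-sample read
counts, mutation classification against a known clonal architecture, LOH
detection, and an in silico pooling experiment that mixes and titrates
samples at the read-count level.

## The data model

Every stage operates on one long table of per-sample allele counts — one
row per candidate site and sample, with `depth` (total reads) and
`alt_count` (mutant reads). This is exactly the information a somatic
caller's VCF provides through per-sample allelic depths (`AD`), and
`read_vcf_counts()` maps VCF 4.2 records onto it. Positions are 1-based;
copy-number segment files use 0-based half-open (BED) intervals.

## Filters, purity correction and classification

Candidate somatic mutations pass a *sample-level* filter when coverage is
at least `min_depth` (default 50 reads) and the purity-corrected VAF is
at least `min_corrected_vaf` (default 5%); a *site-level* call
additionally requires `min_alt` (default 5) mutant reads in at least one
tumor sample. Purity correction divides the raw VAF by the specimen's
tumor cell fraction and clamps at 1 — the standard cellularity
correction, which puts specimens of different stromal contamination on a
common scale.

Mutations present in every region are labeled trunk, in exactly one
region private, otherwise branch. Clonality is a VAF dichotomy: at or
above `clonal_vaf_threshold` (default 10%) clonal, below it sub-clonal.
The threshold itself is assigned to the clonal class so the two labels
are exhaustive (the source dichotomy of "above" vs "less than" leaves the
boundary open; including it on the clonal side is the convention here).
Clonality in the pooling experiment is evaluated on raw VAF — the purity
of an in silico read mixture is undefined — while the purity-corrected
VAF participates only in the per-sample selection filter.

## The Poisson joint genotyper

Hard filters alone are too blunt for the *joint* question: once a
mutation is called anywhere in a patient, is it also present in the other
samples, perhaps at low VAF? The genotyper answers by comparing the
observed mutant reads in each remaining sample against that sample's
sequencing-error background. With per-base error rate $e$ (estimated from
non-variant positions flanking the candidates as
$\hat e = \sum \text{nonref} / \sum \text{depth}$, with a pooled fallback
when flanking coverage is absent), the number of error-derived mutant
reads at a site of depth $n$ is approximately Poisson with mean
$\lambda = e\,n$. A genotype with $k$ mutant reads is accepted when

$$P(X \ge k \mid X \sim \mathrm{Poisson}(\lambda)) \le \alpha,\qquad k \ge 1,$$

with $\alpha$ = `genotype_alpha` (default 0.01). Two numerical choices
matter:

* **Error-rate floor.** An estimated $e = 0$ would make any single read
  significant. Rates are floored at `min_error_rate` (default $10^{-4}$)
  before forming $\lambda$.
* **No multiple-testing correction by default.** The genotyper's role is
  permissive rescue of already-called candidate sites within one patient,
  not genome-wide discovery; a per-site Bonferroni option exists for
  stricter use.

Because the Poisson test is discrete, its realized type-I error is below
the nominal $\alpha$ (at $\lambda = 1$ and $\alpha = 0.01$ the acceptance
region starts at $k = 5$, giving a true rate of about 0.0037); the test
suite checks the one-sided bound, which is the operationally relevant
property.

A mutation counts as **present** in a sample when it passes the
sample-level hard filters *or* is rescued by the genotyper at adequate
coverage (depth at least `min_depth`). The depth gate applies to both
routes: a genotype cannot be meaningfully evaluated at negligible
coverage, and without it a handful of error reads at 10x would pass the
rescue path.

## LOH detection

Loss of heterozygosity is detected at germline heterozygous sites, but
only where the copy-number profile says one parental allele was actually
lost: sites inside segments with minor copy number zero (*B-allele
loss*). For each such site the 2x2 table of (ref, alt) reads in normal
vs tumor is tested with Fisher's exact test, two-sided under the
minimum-likelihood convention (the p-value aggregates all tables with the
observed margins that are no more probable than the observed one — the
dominant convention, and the one `stats::fisher.test` implements). A site
is called LOH when the p-value is at or below `loh_alpha` (default 0.05)
and the tumor allele fraction actually moved; the direction records which
allele was lost. Raw counts are compared — no purity adjustment enters
the test — and p-values are reported uncorrected by default, with an
optional Benjamini–Hochberg flag. The expected tumor B-allele fraction
under LOH with purity $p$ and tumor total copy number $c$ is
$(1-p) / \big(2(1-p) + pc\big)$: at $p = 0.7,\ c = 1$ that is ~0.23
against 0.5 in the normal, comfortably separable at 100x.

## The pooling experiment

The original experiment manipulated aligned reads (BAM files). This
package resamples per-site *counts* instead: keeping each read
independently with probability $f$ makes the retained depth
$\mathrm{Binomial}(n, f)$ and, given the retained depth, the retained
mutant reads hypergeometric — exactly the law of drawing reads without
replacement. For site-level detection statistics the two are
distributionally equivalent, and the count-level version needs no
alignment machinery.

* `thin_counts()` — one without-replacement draw of a fraction of reads.
* `iterative_subsample()` — repeated 10% tranches until a target
  fraction is reached. Each tranche keeps remaining reads with the
  appropriate conditional probability, so the union is distributed
  exactly as a one-shot draw (the suite verifies this with a two-sample
  KS test over 500 seeds).
* `mix_pools()` — composition mixing: fraction $1 - q$ of pool A plus
  fraction $q$ of pool B over the union of their sites.
* `upscale_pool()` — coverage beyond the original reads by bootstrap:
  new depth ~ Poisson(fold x depth), mutant reads binomial at the
  observed VAF. This deliberately differs from physically re-sequencing:
  a site with zero observed mutant reads can never gain one, so
  sub-clonal detection saturates below 100% at high folds. That floor is
  visible in the coverage curves and is a documented limitation, not a
  bug.
* "Onefold" coverage means the combined depth of both input pools
  (`combine_pools()`), matching how the coverage titration is defined.

Detection inside sweeps uses the presence rule above (hard filters or
genotyper rescue, gated on depth); the corrected-VAF filter is off
because a mixture has no defined purity. Replicate $r$ of every grid
point derives its seed as `base_seed + r` (via a fixed affine map), so
each replicate is independently reproducible.

## The synthetic cohort

The generator emulates the sequencing design under study: three tumor
regions plus one matched normal per patient at 100x exome coverage
(depth ~ Poisson around `coverage_mean`), tumor purity 0.7 per region,
and per-base error rate $10^{-3}$. The clonal architecture defaults to 90
trunk mutations (the observed trunk burden in multi-region ovarian exomes
spans roughly 80–110), 30 branch and 30 private; true clonal VAFs are
uniform on 0.2–0.5 and sub-clonal ones on 0.02–0.08, with a quarter of
non-trunk mutations sub-clonal — low-frequency, region-restricted
variation alongside a clonal backbone, as real multi-region data show.
Observed mutant reads are binomial at `purity x true VAF + error_rate`;
normals carry error reads only. The `hypermutator = TRUE` preset places
500 private mutations at true VAF 0.10–0.15 in region 1 over the trunk
backbone: after purity dilution they sit just around the detection
threshold, which is what makes pooling dissolve them.

What the generator does **not** emulate: mutational signature context,
GC- or capture-driven coverage bias (depth overdispersion beyond
Poisson), strand artifacts, mapping error, and multi-allelic or indel
sites. Passing tests therefore demonstrate the statistical behavior of
the pipeline under a clean read-count model, not robustness to every
artifact of real exomes.

## What the experiments show

Problem sizes here are chosen to keep the full suite fast while leaving
comfortable statistical margins; all are regenerated at run time.

* **Topology recovery.** At default settings, filtering plus genotyper
  rescue recovers trunk/branch/private labels with ~98% accuracy across
  10 simulated patients.
* **Hypermutator dilution.** Pooling the three regions of a hypermutator
  detects fewer total mutations than its biopsy region alone, while the
  trunk share among detected calls rises (~15% to ~17% under the
  permissive rescue rule) — the direction seen in real hypermutating
  tumors, where a biopsy dominated by private sub-clonal mutations
  contrasts with a pooled sample near the cohort-typical trunk share.
* **Composition plateau.** Mixing two ~70x pools whose clonal VAFs are
  at least 0.2, mean clonal detection exceeds 95% at every composition
  between 30% and 60%, and detection of the minor pool's clonal
  mutations rises monotonically with its share.
* **Coverage titration.** Clonal detection is already saturated at
  onefold coverage; sub-clonal detection (VAF ~ 3%) increases sharply
  from onefold to tenfold. Extra depth buys sub-clonal, not clonal,
  sensitivity.
* **LOH operating characteristics.** At 100x and purity 0.7, Fisher
  calling reaches ~97% sensitivity over ~1,100 informative sites with a
  false-positive rate at the nominal 5% on balanced sites.

```{r pipeline, eval = FALSE}
res <- run_pipeline(sim_config(seed = 11), filter_config(),
                    out_dir = "tumorpool_run")
res$classification$trunk_proportion
head(mean_detection(res$composition))
```

## Degenerate inputs and tie-breaks

* `poisson_tail(0, lam)` is exactly 1; `lam = 0` gives a point mass at
  zero. Zero mutant reads are never accepted by the genotyper.
* Fisher testing refuses a sample with zero total reads
  (undefined-test error); identical allele fractions give p = 1 and an
  `NA` direction.
* `purity_corrected_vaf` refuses depth 0 rather than returning NaN;
  rows with depth 0 simply fail the depth gate in the filters.
* Thinning at fraction 1, mixing at proportion 0 or 1, and scaling at
  fold 1 are exact identities; `upscale_pool` refuses folds at or below
  1 so the thinning and bootstrap regimes cannot be confused.
* Sites absent from every tumor sample after filtering are dropped from
  classification and counted in `n_dropped`, keeping denominators
  auditable.

## Known limitations

Count-level resampling cannot model read-level artifacts (duplicates,
strand bias, mapping ambiguity). Bootstrap upscaling understates what
true deeper sequencing would recover at very low VAF, as described above.
The clonal/sub-clonal dichotomy is a VAF proxy, not a clone-fraction
inference; no subclonal deconvolution is attempted. Copy-number segments
and purity are taken as given inputs — estimating them is out of scope.
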