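---
title: "Assessing SNP ascertainment bias with ascbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing SNP ascertainment bias with ascbias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascbias)
```

## The problem

SNP genotyping arrays are designed from a small discovery panel: a handful of
sequenced individuals from a few populations, with additional selection rules
such as discarding low minor-allele-frequency (MAF) variants. Loci that are
rare — or monomorphic — in the discovery panel never make it onto the array.
When such an array is later used to genotype a broader set of populations, the
site-frequency distribution of the assayed loci is no longer a random draw
from the genome: rare variants are underrepresented, diversity statistics are
distorted, and the distortion differs between populations depending on their
relationship to the panel. This is ascertainment bias.

`ascbias` implements a comparison workflow for quantifying that bias and for
evaluating mitigation filters. It takes two views of the same populations:

* an **array side** — individuals genotyped at the ascertained loci
  (dosages of the alternative allele, 0/1/2/missing), and
* a **reference side** — pooled whole-genome sequencing, one pool per
  population, summarised as per-locus alternative-read counts and depths.

The reference statistics are treated as the standard; the array statistics,
under various filters, are judged by how closely they reproduce them.

## Statistics compared

All allele frequencies refer to the alternative allele. With `p` a
per-population, per-locus frequency:

* **Expected heterozygosity** `He = 2p(1-p)`, averaged over loci within a
  population. Pooled sequencing gives no observed heterozygosity, so the
  expected form is the only one available on both sides.
* **Pairwise fixation index** `F_ST = s^2 / (pbar (1 - pbar))` per locus,
  averaged over loci. For populations of equal size, `s^2` is the frequency
  variance around the unweighted mean `pbar`; with unequal sizes both `s^2`
  and `pbar` are weighted by the sample sizes `n_i`
  (`pbar = sum n_i p_i / (r nbar)`, `s^2 = sum n_i (p_i - pbar)^2 / (r nbar)`
  with `r` populations and mean size `nbar`). Loci where `pbar (1 - pbar) = 0`
  carry no information and are excluded.
* **Nei's standard genetic distance** in its biallelic form,
  `D = -ln( Jxy / sqrt(Jx Jy) )` with `Jx = sum_l (p_l^2 + q_l^2)` and
  `Jxy = sum_l (p_xl p_yl + q_xl q_yl)`.
* **Neighbor-joining trees** built from the Nei matrices, compared by the
  partition (Robinson–Foulds) distance and by the branch-score distance
  (square root of summed squared branch-length differences over
  bipartition-matched branches).
* **Frobenius distance** `sqrt(trace((A-B)(A-B)'))` between two pairwise
  distance matrices.
* **PCA** of the column-centered populations-by-loci frequency matrix, with
  the variance explained by the leading components.
* **Allele frequency spectra** binned at width 0.025 (40 left-closed bins;
  the last bin `[0.975, 1]` is closed so fixed loci are counted).

Because a distance matrix built from fewer SNPs is noisier, the reference is
never compared as a single number: for each filtered array version the
package draws replicate SNP subsets of *matching size* from the reference
(100 by default), computes the statistic on each, and reports the mean and
standard error of the array-versus-replicate distances together with the
replicate-versus-replicate baseline distribution.

## Filters

Eight dataset versions are built by composing three mitigation filters on the
harmonized array data (`build_versions()`):

| version | filters |
|---|---|
| `Array_all` | none |
| `Array_MAF5` | MAF >= 0.05 |
| `GG` | polymorphic in the wild reference populations |
| `GG_MAF5` | GG, then MAF |
| `Pruned` | LD pruning |
| `Pruned_MAF5` | pruning, then MAF |
| `Pruned_GG` | pruning, then GG |
| `Pruned_GG_MAF5` | pruning, then GG, then MAF |

Conventions worth stating precisely:

* **Call-rate QC** retains SNPs with call rate strictly above 0.99 and then
  samples strictly above 0.95.
* **MAF filtering** removes loci with `min(p, 1-p)` *below* 0.05 — a locus at
  exactly 0.05 is kept. The frequency is computed over all samples pooled,
  matching the semantics of a global `--maf` command-line filter.
* The **wild-polymorphism filter** ("GG") keeps loci segregating in the
  pooled sample of designated reference populations (populations not used for
  array design); `mode = "each"` / `"any"` variants are available since the
  choice of rule is genuinely open.
* **LD pruning** uses a 50-SNP window advancing 5 SNPs with a variance
  inflation factor bound of 2, i.e. a pairwise `r^2` threshold of
  `1 - 1/VIF = 0.5`; of a correlated pair the lower-MAF SNP is removed (ties:
  the later one). `r^2` is the squared Pearson correlation of dosage columns
  over pairwise-complete samples — composite LD, appropriate for unphased
  array data. A multiple-regression `vif` mode is also provided.

### Why pruning iterates to a fixpoint

A single sliding pass (the classic `indep`-style schedule) does not guarantee
that the *final* retained set is free of correlated pairs inside a window:
removals later in the pass shrink the distances between retained SNPs, so two
SNPs that never shared a window during processing can end up fewer than 50
positions apart. With structured populations this matters, because pooling
populations induces long-range correlation between physically unlinked loci
(mixture LD), not just within-block correlation. `ld_prune()` therefore
repeats the window pass until nothing is removed and then resolves any
remaining violating pair at retained distance < 50 (worst pair first). The
result is slightly stricter than a single pass, idempotent, and satisfies the
documented contract: after pruning, no retained pair within any 50 consecutive
retained SNPs exceeds the threshold (`ld_prune_check()` verifies this by
scanning every offset).

## Harmonization

`harmonize()` reconciles the two sources in four ordered steps: drop SNPs
with missing positions; drop *all* SNPs sharing a (chromosome, position) pair
within a dataset; keep loci present in both datasets on the allowed
chromosomes; drop loci whose ref/alt alleles disagree between datasets. No
strand flipping or repair is attempted — mismatches are discarded. Chromosome
names are compared after stripping an optional `chr` prefix, coordinates are
1-based as in VCF. Duplicate-position removal is applied to both datasets
(logged separately), since applying it to one side only would leave ambiguous
matches.

One asymmetry is deliberate: `harmonize()` returns both datasets restricted
to the matched loci (useful for locus-by-locus frequency concordance), but
the comparison harness `run_comparison()` keeps the *full* reference locus
set and only requires the array loci to be a subset of it. The bias being
measured is precisely that the array loci are a non-random subset of the
genome; restricting the reference to the array loci would erase it. Replicate
subsets and the reference-side He/F_ST are therefore computed on all
reference loci.

## The synthetic-data generator

`simulate_scenario()` generates data with the statistical structure the
analysis assumes, so the whole pipeline is testable without any external
data.

* **Population structure.** Ancestral frequencies `p0` are drawn per locus
  (default Beta(0.5, 2), giving the rare-allele-heavy spectrum expected of
  genome-wide variation); each population's frequency is drawn from the
  Balding–Nichols distribution `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)` with a
  per-population drift parameter `F`. The closed-form moment
  `E[2p(1-p)] = 2 p0 (1-p0) (1-F)` makes the generator checkable. A Newick
  `population_tree` may replace the star topology, applying drift
  recursively along edges so clade structure is recoverable.
* **Genotypes.** Diploid dosages are Binomial(2, p) under HWE. LD is induced
  by template copying: per block and population a small number of template
  haplotypes is drawn, and each individual haplotype copies its chosen
  template at each locus with probability `ld_decay`, drawing fresh from `p`
  otherwise. This preserves marginal frequencies, produces tunable
  within-block `r^2`, and is sufficient to exercise window-based pruning —
  no recombination map is simulated, and that is a known limitation: the
  decay of LD with physical distance is block-shaped, not exponential.
* **Pooled reads.** Depth is Poisson with mean 20 (typical pooled-WGS target
  coverage) per population per locus; alternative reads are Binomial(depth,
  sample frequency). No sequencing-error model beyond binomial sampling.
* **Ascertainment.** A discovery panel (individuals drawn once, seeded, from
  designated populations) retains a locus iff it segregates in the panel and
  its panel MAF reaches the cutoff — the mechanism by which real arrays
  underrepresent rare variants.

### The packaged scenarios

Three YAML scenarios ship under `inst/extdata/scenarios/` and define the
conditions used throughout the tests:

* `default_bias`: 8 populations x 10 diploids, 50,000 loci over 5
  chromosomes, 20X pools, a 2-population discovery panel of 4 + 4
  individuals with MAF cutoff 0.05, moderate LD (`ld_decay` 0.5, blocks of
  20), seed 1.
* `null`: no panel, no MAF cutoff, no LD, no missingness — the bias-free
  control.
* `strong_ld`: 5,000 loci with `ld_decay` 0.95 and 2 templates per block,
  for exercising the pruning contract.

The drift parameters span F = 0.05–0.50 with the discovery-panel populations
heavily drifted (F = 0.35, 0.40) and the wild reference populations the most
diverse (F = 0.05, 0.08). This mirrors the design of array-based livestock
diversity panels, where discovery individuals come from closed commercial
lines and wild relatives retain the most variation; a narrow drift span would
compress the between-population diversity differences that the rank and
regression comparisons rest on. Per-genotype missingness is 0.002, a typical
post-calling array rate — consistent with a strict >99% SNP call-rate QC
(with 80 individuals that QC admits no missing call, so an unrealistically
high missing rate would gut the SNP set at QC rather than at ascertainment).

Under `default_bias` the simulated array reproduces the qualitative bias
phenomena: the rare bin of the spectrum is depleted among ascertained loci,
every population's He is overestimated, the He regression of array on
reference has slope > 1, and LD pruning yields the smallest Frobenius
distance to the reference among the filters. What passing these checks does
*not* show: real arrays also select on assay chemistry, spacing and genic
context, real LD decays with distance, and real pools suffer unequal
individual contributions — none of which the generator emulates.

## Numerical and design choices

* "Averaged across loci" for F_ST is the mean of per-locus ratios; a
  `ratio_of_sums` mode is provided for sensitivity analysis. Loci
  monomorphic across both populations are excluded from F_ST but contribute
  `He = 0` within a population.
* Regression orientation: the array-derived statistic is the response and
  the reference-derived the predictor (an `orientation` flag flips it).
* The branch-score tree distance matches branches by the tip bipartition
  they induce, terminal branches included; branches present in one tree only
  contribute their full length squared, and the result flags whether the
  topologies agreed (`shared_topology` attribute). When topologies agree it
  reduces exactly to the square root of the summed squared branch-length
  differences.
* Neighbor joining breaks Q-criterion ties by the smallest label-index pair
  and clamps negative branch-length estimates to zero (count recorded in the
  `clamped_branches` attribute), so trees are reproducible run to run.
* All randomness flows from one root seed through named substreams per stage
  (frequencies, genotypes, pool reads, ascertainment, replicate draws), so
  each stage is individually reproducible and full pipeline outputs are
  byte-identical at a fixed seed. Replicate `r` of a comparison uses stream
  `seed + r`; replicate-pair baselines are subsampled to 1,000 pairs when
  there are more.
* PCA operates on population-level frequency matrices because that is the
  only representation available for pooled reference data; an
  individual-dosage mode (`pca_genotypes()`) exists for array-only
  exploration.
* Problem sizes in the test suite follow the packaged scenarios (50,000 loci
  for the bias checks, 100,000 loci for closed-form moment checks, 5,000
  loci for the pruning contract) — large enough that Monte-Carlo error is
  far below the asserted effects.

## Worked example

```{r example, eval = FALSE}
library(ascbias)

sim <- simulate_scenario("default_bias")
res <- run_pipeline(sim, n_replicates = 100)
glance(res$report)

plot_he_comparison(res$report)
plot_fst_regression(res$report)
plot_distance_baseline(res$report, "branch_score")
```

`glance()` returns one row per dataset version with the headline statistics;
`tidy()` returns the long form. In the run above (seed 1), `Array_all`
retains 21,510 of 50,000 simulated loci, its He regression slope is 1.25
(overestimation growing with diversity), and the Pruned version attains the
smallest mean Frobenius distance to the reference replicates (0.59 versus
0.60–0.71 for the other versions) — the direction in which LD pruning is
expected to help.

## Limitations

* The generator works at the frequency level; no coalescent, mutation or
  selection dynamics, no sequence-level realism.
* Pool read sampling is binomial at equal individual contribution.
* The wild-polymorphism filter's defaults (pooled-sample polymorphism,
  judged on array genotypes) are one of several defensible readings; both
  are switchable.
* Tree comparisons use unrooted NJ topologies only; no bootstrap support and
  no geodesic tree-space distances.
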