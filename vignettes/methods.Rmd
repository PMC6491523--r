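---
title: "Methods: diversity analysis of inbred SNP panels with pigdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity analysis of inbred SNP panels with pigdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigdiv)
```

`pigdiv` implements the statistical toolchain for characterising genetic
diversity in genebank collections of predominantly selfing crops genotyped
on biallelic SNP arrays: quality control, duplicate detection and core
selection, diversity and differentiation statistics, ordination and
tree building, minimal fingerprinting panels, and seed-phenotype analysis.
This vignette documents the models and the numerical choices.

## Data model

A `genotype_matrix` holds an accessions x markers integer dosage matrix
(0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
`NA` = missing), a marker map sorted by chromosome and position, and a
passport table (region, subspecies, colour class, country). All analysis
functions consume this one class.

## Synthetic panels with known truth

Real array data for a given collection is rarely redistributable, so every
statistical claim in the package is validated against simulated panels
whose generating parameters are known.

- **Structured allele frequencies (Balding-Nichols).** An ancestral
  frequency $p_0$ is drawn per locus; each group's frequency comes from
  $\mathrm{Beta}\!\left(p_0\frac{1-F}{F},\,(1-p_0)\frac{1-F}{F}\right)$.
  The divergence parameter $F$ *is* the expected pairwise $F_{ST}$, which
  turns differentiation estimation into a quantitative recovery test.
- **Selfing.** Genotypes are drawn at Hardy-Weinberg proportions and then
  passed through $t$ generations of selfing; each heterozygote resolves to
  a homozygote with probability $1/2$ per generation, so the expected
  inbreeding coefficient is $F_{IS} = 1 - (1/2)^t$. Four to five
  generations reproduce the near-complete homozygosity typical of
  traditional inbred rice.
- **Duplicates.** A configurable number of accessions are exact copies of
  earlier entries (drawn with replacement, so clusters larger than two
  occur), made distinct only by independent missing-call masks. The planted
  partition is the ground truth for the duplicate pipeline.
- **Phenotypes.** Per-class trait means with a shared factor-structured
  covariance (grain geometry, colour coordinates, and a deliberately
  near-collinear intensity/lightness pair) are sampled from a multivariate
  normal; an indel screen at a pigmentation locus is simulated with a
  configurable genotype-phenotype concordance.

The generators are bit-reproducible from their seeds and validate their
inputs (divergence in $[0, 1)$, positive semi-definite covariance).

## Quality control

`filter_markers()` applies call-rate then minor-allele-frequency thresholds
with strict inequalities, and reports exactly what was removed at each
step. `ld_prune()` removes the downstream member of any marker pair whose
composite linkage-disequilibrium $r^2$ (squared Pearson correlation of
dosage vectors on pairwise-complete samples - the appropriate measure for
unphased, highly inbred genotypes) exceeds the threshold inside a sliding
physical window, repeating until stable. The windowed result equals a
brute-force all-pairs scan whenever the window covers the panel, and
pruning is idempotent.

## Duplicate detection and core selection

`relatedness()` computes the identity-by-state distance (mean of
$|d_i - d_j|/2$ over co-called loci) and a method-of-moments estimate of
the kinship statistic $\hat\pi$ from the observed IBS-state counts and
their expectations under IBD states; both are evaluated with dense matrix
products so collection-scale panels (hundreds of accessions) run in
seconds. Pairs with no co-called loci are reported as undefined rather
than zero. No small-sample bias corrections are applied to the expected
counts; at array marker densities the uncorrected estimator already
returns exactly 1 for duplicates and ~0.5 for full sibs, which is what
duplicate screening needs.

`find_duplicates()` single-links all pairs with $\hat\pi$ at or above the
threshold (0.99 by default - duplicates differ only by missing calls) and
keeps one representative per cluster: highest call rate, ties broken by
lexicographic identifier so the selection is permutation-invariant.

## Diversity statistics

Per locus and group: observed heterozygosity, gene diversity
$H_e = 2p(1-p)$, and its small-sample unbiased version
$H_e \cdot 2n/(2n-1)$. Allelic richness uses hypergeometric rarefaction to
a common number of allele copies (evaluated with `lchoose` for numerical
safety). $F_{IS}$ is the ratio-of-averages estimator
$1 - \bar H_o / \bar H_e$ - more stable than averaging per-locus ratios
when many loci are nearly fixed, which is the norm in selfers - with a
percentile bootstrap over loci for its confidence interval.

## Differentiation

`wc_fst()` implements the Weir-Cockerham (1984) variance-component
estimator: per-locus components $a$ (among populations), $b$ (among
individuals within populations) and $c$ (within individuals), combined as
the multilocus ratio of sums. Estimates are deliberately not clamped at
zero; small negative values are the honest behaviour of a moment estimator
on undifferentiated groups. The unit tests verify the implementation
against an independent oracle - a nested ANOVA on allele copies fitted
with `stats::aov` and converted through the expected mean squares - to
near machine precision.

`amova()` partitions allele-copy variance across three strata (between
groups / among accessions within groups / within accessions). Each
accession contributes two allele copies per locus, so a heterozygote
contributes $1/2$ to the within-accession sum of squares. Degrees of
freedom follow the full design ($G-1$, $N-G$, $N$, total $2N-1$), the
among-accession expected-mean-square coefficient is 2, and the
between-group coefficient uses the standard unequal-size correction.
Negative components are retained and flagged. A label-permutation test for
the between-group stratum is available but off by default.

## Ordination and trees

`relationship_matrix()` builds the additive (VanRaden) relationship matrix
$A = ZZ'/2\sum p(1-p)$ with missing calls imputed to the locus mean;
`grm_pca()` eigendecomposes it (scores $= U\sqrt{\Lambda}$, negative
eigenvalues floored for variance shares and flagged) and retains
marker-space loadings so `pca_project()` can place new samples on a fixed
reference basis - projecting the reference onto itself reproduces its own
scores. `nj_tree()` wraps `ape::nj` on the IBS distance with a locus
bootstrap for bipartition supports; neighbour joining is consistent on
additive distances, and the tests exercise exact recovery of random
tree-generated metrics.

## Fingerprinting

The fingerprinting fitness of a marker subset is the number of accessions
distinguishable from *every* other accession by at least one
opposite-homozygote call (heterozygous and missing calls are wildcards -
a conservative rule for inbred material where residual heterozygosity is
unreliable). Three solvers share this objective:

- `brute_force_select()` - exhaustive, for small instances and as the
  oracle in tests;
- `greedy_select()` - forward selection on pair coverage, fast and
  near-optimal at collection scale;
- `ga_select()` - a genetic algorithm over $k$-subsets with elitist
  truncation selection and a partially-matched crossover adapted to
  distinct-index chromosomes (offspring are repaired through the PMX
  mapping, with random replacement as the fallback), stopping at full
  fitness, a generation cap, or a fitness plateau.

Pairs left unresolved by the final panel are reported together with their
IBS distance, separating true duplicates from panel limitations.

## Phenotypes

`rc_crosstab()` cross-tabulates pigmentation-locus indel scores against
pericarp colour classes, excludes ambiguous PCR profiles from the
percentage columns while counting them separately, and lists discordant
accessions (pigmented deletion carriers, white non-carriers).
`describe_traits()`, `trait_correlations()` (pairwise-complete Pearson
with t-distribution p-values) and `trait_pca()` (correlation-matrix PCA)
cover the descriptive layer. `colour_anova()` gates a one-way ANOVA on its
assumptions: residual normality (Shapiro-Wilk) and variance homogeneity
(Bartlett) are tested first; on heterogeneity the trait is log-transformed
and retested, and if heterogeneity persists the trait is marked
*precluded* and no Tukey HSD post-hoc comparisons are produced. Singleton
colour classes are dropped with a warning.

## A worked example

```{r example, eval = FALSE}
cfg <- panel_config(
  n_markers = 1536,
  groups = data.frame(group = c("indica", "japonica", "admixed"),
                      n = c(132, 155, 20), F = c(0.5, 0.5, 0.2)),
  selfing_generations = 4, n_duplicates = 282, missing_rate = 0.03,
  rng_seed = 1)
sim <- simulate_panel(cfg)

qc   <- filter_markers(sim$panel)
core <- find_duplicates(relatedness(qc$panel))
gm   <- gm_subset(qc$panel, accessions = core$core_ids)
gl   <- group_labels(gm, "subspecies")

diversity_summary(gm, gl, n_boot = 200)
wc_fst(gm, gl, c("indica", "japonica"))$theta
amova(gm, gl)
grm_pca(gm, n_pcs = 4)$pct_variance[1:2]
greedy_select(gm, k = 20)$fitness
```

On this study-scale configuration the pipeline removes exactly the 282
planted duplicates, recovers within-group $F_{IS}$ near the selfing
expectation $1 - (1/2)^4 = 0.9375$, estimates indica-japonica
$\theta \approx 0.5$, and a 20-marker greedy panel distinguishes all 307
core accessions.
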