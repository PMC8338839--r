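---
title: "Pleiotropy degree, effect sizes and background selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pleiotropy degree, effect sizes and background selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioselect)
```

## The scientific question

A locus detected by genome-wide association studies is *pleiotropic of
degree d* when it is associated with *d* distinct traits; degree 1 is
non-pleiotropic. Two families of observations are in tension: variants
found at higher degrees of pleiotropy tend to have larger effect sizes and
higher minor allele frequencies — yet if pleiotropic variants are
deleterious, purifying selection should remove them or keep them rare. One
way to probe the selection side is through *background selection*: the B
statistic gives, for every genomic position, the expected fraction of
neutral diversity remaining after linked purifying selection (B = 1, no
loss; B = 0, maximal loss). If highly pleiotropic loci sit under stronger
purifying selection, their genomic neighbourhoods should show lower B —
after accounting for the local recombination rate (RR), which also shapes
B.

`pleioselect` implements that analysis as a reusable, fully tested
pipeline: catalog filtering, liability-scale effect conversion, degree
assignment, genomic-track annotation, and simple/partial regression
inference, together with a synthetic-data generator that plants every
relationship with known parameters so the pipeline can be validated by
recovery.

## The pipeline and its filters

Starting from a GWAS-Catalog-style association table (SNP, chromosome,
position, mapped gene, trait, study accession, p-value, effect reported as
an odds ratio or beta-coefficient, risk allele frequency), the stages are:

1. **Parsing** (`parse_catalog()`): rows with missing or unparseable
   required fields are dropped and counted; chromosome labels are
   normalized; the analysis is restricted to autosomes 1–22.
2. **Significance** (`filter_significant()`): only genome-wide significant
   associations are kept, p ≤ 5×10⁻⁸. The boundary is *kept*: associations
   with significance *worse* than the standard threshold are discarded, so
   equality survives.
3. **One SNP per gene and trait** (`select_representative()`): within each
   (mapped gene, trait) group the lowest-p record is retained and its gene
   (or intergenic label, verbatim) becomes the candidate causal locus.
   p-value ties are broken by larger absolute effect, then SNP id, so the
   result never depends on file row order.
4. **Trait robustness** (`filter_traits()`): only traits with ≥ 30 distinct
   loci and ≥ 3 distinct studies are analyzed. Study support is counted on
   the significant records *before* locus deduplication, since every
   contributing study attests the trait.
5. **Trait clustering** (`cluster_traits()`): traits whose locus sets have
   Jaccard similarity ≥ 0.5 are merged transitively (single linkage) and
   relabelled by the lexicographically smallest member. The threshold is
   exposed because the clustering rule is a robustness device, not a sharp
   scientific constant.
6. **Degrees** (`assign_degrees()`): the degree of a locus is the number of
   distinct (post-clustering) traits it is associated with.

## Liability-scale conversion

Quantitative traits report effects in trait SD units and pass through
unchanged. For dichotomous traits the reported per-allele odds ratio OR is
converted to a liability-scale effect via the threshold model
(`liability_effect()`):

* the prevalence K fixes the threshold $t = \Phi^{-1}(1-K)$;
* genotype penetrances satisfy $\mathrm{odds}(p_i) =
  \mathrm{odds}(p_0)\,\mathrm{OR}^i$ for allele count $i \in \{0,1,2\}$ and
  the prevalence constraint $\sum_i f_i p_i = K$ under Hardy–Weinberg
  frequencies $f = ((1-q)^2,\, 2q(1-q),\, q^2)$; $p_0$ is found by monotone
  root finding, polished until the residual is ≤ 1e-13;
* genotype liability means are recovered as $\mu_i = t - \Phi^{-1}(1-p_i)$
  (unit within-genotype variance), and
* $\beta$ is the $f$-weighted least-squares slope of $\mu_i$ on $i$ — the
  allele substitution effect. OR = 1 gives $\beta = 0$ exactly.

Per-trait prevalence is *required configuration* for every odds-ratio
trait; there is no defensible default, and the synthetic generator emits a
prevalence map for exactly this reason. Membership in the prevalence map is
also what marks a trait as dichotomous, because the catalog's single
"OR or BETA" column cannot distinguish the two kinds by itself.

Each locus contributes heritability $h^2 = 2\beta^2 q(1-q)$
(`heritability_contribution()`), and effect sizes are summarized as the
absolute homozygous effect $|2\beta|$: risk-allele coding makes signs
arbitrary across traits, and the homozygote span is the natural per-locus
magnitude.

## Per-degree summaries and the two dispersion statistics

`summarize_by_degree()` reports, per degree: the mean absolute homozygous
effect pooled over trait–locus observations, the mean MAF per locus, the
mean $h^2$ per observation, and the mean *within-locus* standard deviation
of effects. The effect/MAF/$h^2$ regressions on degree run over
per-observation (or per-locus) data, not per-degree means — a handful of
degree classes cannot produce the very small R² with highly significant p
that thousands of observations do; only the dispersion trend is fitted on
the per-degree means, as there is a single SD summary per degree.

Two dispersion statistics are deliberately distinguished:

* `within_locus_sd()` — the sample SD of the effects one locus has across
  its traits, averaged over loci of the same degree. Undefined (NA, not 0)
  at degree 1.
* `variance_of_locus_means()` — the variance *across* loci of each locus's
  *mean* effect. Because higher-degree loci average more effects, this
  statistic declines with degree by the law of large numbers even for
  i.i.d. effects, so the two statistics can legitimately trend in opposite
  directions on the same data.

## Genomic tracks, annotation and masking

B and RR are represented as stepped tracks (`stepped_track()`):
piecewise-constant values over sorted, non-overlapping, 0-based half-open
segments. All internal coordinates are 0-based half-open, converted once at
the reading boundary (catalog positions and GFF3 are 1-based; BED is
0-based; genetic-map positions are taken directly as segment starts).
Annotation uses the point value at the SNP position, or the
length-weighted mean over all positions of a gene or region
(`interval_mean()`); uncovered bases are excluded from the mean rather than
imputed, and the coverage fraction is reported so users can filter.
Numerical choices:

* B maps distributed as integers 0–1000 are auto-detected (any value > 1)
  and rescaled, unless an explicit scale is given.
* log₁₀RR applies a floor of 10⁻³ cM/Mb before the logarithm, since the
  plotted and fitted scale is log₁₀[cM/Mb], which is undefined at 0.
* The MHC region — 25–34 Mb of chromosome 6, whose diversity and LD are
  unrepresentative — is excluded (`mhc_mask()`): points inside the window
  are removed, and intervals are removed on *any* overlap, the operational
  reading of "located in, or strongly linked to" the region.

## Regression inference

`ols_simple()` and `ols_two()` fit ordinary least squares through R's
`lm()`/`summary.lm()` — the same machinery the original analysis states it
used — and return the slope(s), standard errors, t and p per coefficient,
R², the overall F with its degrees of freedom, and the overall p. The
partial regression of B on degree and RR (`degree_regressions()`) is the
headline inference: the coefficient on degree (b′) measures the
association between pleiotropy and background selection *net of*
recombination. Degree enters as a numeric covariate (a single slope per
unit degree), never as a factor. RR enters the partial fit as log₁₀ cM/Mb
by default, matching the plotted scale, with a switch for raw cM/Mb since
either reading of the original fit is defensible.

## The synthetic-data generator

`generate_bundle()` draws a complete input set — catalog, BED/GFF3 genes,
B bedGraph, HapMap-style genetic map, region table, prevalence and domain
maps — plus a truth file holding every planted parameter and latent value.
What it emulates, and the defaults (all in `generator_config()`):

* **Degree law**: truncated geometric with ratio 0.23 up to degree 12, so
  about 23% of loci are pleiotropic and class counts decline with degree.
* **Effect model**: $|2\beta| = 0.2 + 0.035\,d + N(0, 0.05)$ — the planted
  effect–degree slope echoes the magnitude seen in real catalog data. The
  intercept is set high enough that truncation at zero is a negligible-mass
  event and cannot bias slope recovery.
* **MAF model**: $0.25 + 0.006\,d + N(0, 0.03)$, clipped to [0.01, 0.5]
  with, again, negligible clipping mass by construction.
* **B model** (per gene): $0.8 - 0.02\,d + 0.15\log_{10}\mathrm{RR} +
  N(0, 0.04)$, clipped to [0, 1]; inter-gene baseline segments are drawn
  around 0.77 so the genome-wide length-weighted mean B lands in the
  0.74–0.81 band typical of autosomes.
* **RR model**: log-normal (meanlog 0, sdlog 0.5), i.e. median 1 cM/Mb and
  no dependence on degree — recombination is planted as *independent* of
  pleiotropy, which is what the partial regression must hold fixed.
* **Filter fodder**: ~5% sub-threshold rows, ~10% duplicate SNPs per
  gene–trait pair, plus "weak" traits (too few genes, or too few studies)
  on dedicated extra genes, so every filter has something to remove.
* Half the traits are dichotomous; their odds ratios are planted by
  inverting the threshold model (`or_from_liability()`), so the liability
  conversion is exercised on every run and recovers the planted β within
  5% in the small-effect regime.

Each gene hosts exactly one SNP per associated trait, B and RR are constant
over each gene ± 2 kb flank, and every main trait is guaranteed to survive
the trait filters by degree-preserving label swaps — so planted degrees,
B, RR and effects are *exact* truth for the retained loci. What the
generator does **not** emulate: linkage disequilibrium (so "spurious
pleiotropy" from LD cannot arise), winner's-curse ascertainment,
population structure, or realistic gene-length/recombination landscapes.
Passing recovery tests therefore demonstrates that the pipeline's
*computations* are correct under its stated model, not that the model
captures every property of real catalog data.

## Problem sizes used in validation

The recovery experiment runs 100 seeded replicates at 2,000 genes and 40
traits — the scale at which the planted slopes are estimated with standard
errors a few percent of their values — and requires each replicate-mean
estimate to land within two Monte-Carlo standard errors of the truth. The
null calibration (no planted B–degree slope) checks that the partial-slope
p-value is uniform over 500 replicates of 400 genes and 15 traits; p-value
uniformity under the null is size-free, so the smaller per-replicate size
simply trades precision per replicate for more replicates.

## Known limitations

* The liability conversion assumes per-allele (multiplicative-odds)
  reporting of catalog odds ratios and unit within-genotype liability
  variance; strong-effect loci (|β| well above 0.3) leave the small-effect
  regime in which the inverse mapping is accurate.
* Trait clustering uses a single Jaccard threshold with single linkage;
  pathological chaining is possible in principle and the threshold is
  user-visible for that reason.
* Interval means exclude uncovered bases; sparsely covered genes should be
  filtered on the reported coverage fraction rather than trusted.
* The degree distribution is capped (default 12); real catalogs with many
  more traits reach higher degrees and heavier tails.
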