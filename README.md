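# pleioselect

Are highly pleiotropic variants under stronger purifying selection?
`pleioselect` relates the **degree of pleiotropy** of trait-associated
variants — the number of distinct traits a locus is associated with — to
their effect sizes, minor allele frequencies, heritability contributions,
local recombination rate (RR) and the strength of **background selection**
(the B statistic: the expected fraction of neutral diversity remaining at a
site; 1 = no loss, 0 = maximal loss). It is written for population
geneticists who want the whole analysis — catalog filtering, liability-scale
conversion, genomic-track annotation and regression inference — as tested,
reusable R functions rather than a one-off script.

## What it computes

Starting from a GWAS-Catalog-style association table, the pipeline

1. keeps genome-wide significant associations (p ≤ 5×10⁻⁸, boundary kept),
   one SNP per mapped gene and trait (lowest p), and only traits with ≥ 30
   distinct loci from ≥ 3 studies, clustering traits with highly
   overlapping locus sets (Jaccard ≥ 0.5, single linkage);
2. converts odds-ratio effects to the liability scale via the threshold
   model — penetrances with odds(pᵢ) = odds(p₀)·ORⁱ constrained to the
   trait prevalence K, genotype means μᵢ = t − Φ⁻¹(1−pᵢ) with
   t = Φ⁻¹(1−K), and β the Hardy–Weinberg-weighted slope of μᵢ on allele
   count — and computes each locus's heritability contribution
   h² = 2β²q(1−q);
3. assigns each locus its degree d (distinct traits, post-clustering) and
   summarizes |2β|, within-locus effect SD, MAF and h² per degree;
4. annotates loci with B and RR from stepped genomic tracks (point values
   for SNPs, length-weighted interval means for genes/regions), excluding
   the MHC window (chr6:25–34 Mb);
5. fits the simple regression of B on d (slope *b*) and the partial
   regression of B on d and log₁₀RR (slopes *b′*), with R², F and
   p-values — the partial slope on degree is the headline quantity:
   the pleiotropy–selection association net of recombination.

A seeded synthetic-data generator (`generate_bundle()`) emulates all four
input families with planted, recoverable parameters and a machine-readable
truth file, so every stage has a recovery test.

## Worked example

```r
library(pleioselect)

bundle <- generate_bundle(generator_config(seed = 1))
report <- run_analysis(bundle$catalog, genes = bundle$genes,
                       b_track = bundle$b_track, rr_track = bundle$rr_track,
                       prevalence = bundle$prevalence,
                       domain_map = bundle$domain_map)

unlist(report$counts)
#>             parsed        significant         trait_loci after_trait_filter
#>               3126               2971               2731               2631
#>        kept_traits   after_clustering           clusters               loci
#>                 40               2631                 40               2000
#>   pleiotropic_loci annotated_complete        mhc_removed
#>                491               2000                 18

report$regressions$b_partial
#> least-squares fit, n = 1982
#>             estimate       se      t          p
#> (Intercept)  0.80418 0.002102 382.60  0.000e+00
#> x1          -0.02231 0.001444 -15.45  6.408e-51
#> x2           0.14944 0.004172  35.82 4.994e-217
#> R^2 = 0.4315, F(2, 1979) = 751.2, p = 1.89e-243
```

Of the 3,126 catalog rows, 2,971 survive the significance filter, collapse
to 2,631 trait–locus pairs across 40 traits, and resolve to 2,000 loci of
which 491 (24.6%) are pleiotropic. The partial regression recovers the
planted B–degree slope (−0.0223, planted −0.02) and B–log₁₀RR slope
(0.1494, planted 0.15): loci of higher pleiotropy degree sit in regions of
measurably stronger background selection, net of recombination.

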