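# subtypeGWAS

Subphenotype-stratified genetic association for heterogeneous case cohorts.

## The problem

In case-control GWAS of phenotypically heterogeneous disorders — autism
spectrum disorders being the motivating case — pooling all cases dilutes
variants whose effect is confined to a subset of cases with a particular
symptom profile. This package implements a three-stage design that
recovers such subtype-dependent signals:

1. **Quantitative-trait screen.** Item-level symptom severities (123
   interview items scored 0–3) are summed into five behavioural traits
   (language, non-verbal communication, play, insistence on sameness,
   social development). Each trait is regressed on each SNP's additive
   genotype over the cases; SNPs with unadjusted *p* ≤ 10⁻⁵ form that
   trait's QTL set.
2. **Subtype association.** Cases are partitioned into K = 4 phenotypic
   subtypes by missing-aware K-means on the item matrix. Each QTL set is
   tested subtype-by-subtype against all controls with the 1-df allelic
   chi-square
   χ² = N(ad − bc)² / [(a+b)(c+d)(a+c)(b+d)]
   and the minor-allele odds ratio OR = ad/bc, adjusting within each run
   (Bonferroni and Benjamini–Hochberg, m = QTL-set size). SNPs with
   Bonferroni-adjusted *p* ≤ 0.05 in ≥ 1 subtype are combined.
3. **Final association and replication.** The combined list is re-tested
   in every subtype and in the pooled cases (m = list size); SNPs
   significant or suggestive in more than one of the disjoint subtypes
   count as internally replicated, with per-subtype ORs exposing effect
   heterogeneity.

Because the motivating study's genotypes are access-restricted, the
package ships a synthetic cohort generator (Hardy–Weinberg genotypes,
archetype-based item severities, planted case-control and
quantitative-trait effects with known odds ratios and slopes) plus the
published summary tables as plain-text worked examples. PLINK PED/MAP
text genotypes, item-score/trait tables, QC filters (missingness > 10%,
MAF < 1%, control-HWE *p* < 0.001) and the PLINK-style association table
layout are all supported.

## Worked example

Simulate a study-scale cohort (1867 cases in four subtypes of
639/478/363/387, 2438 controls) with one SNP whose risk-allele frequency
is odds-shifted by OR = 2.0 in the most severe subtype only, recover the
subtypes from the item scores, and test a 20-SNP QTL set:

```r
library(subtypeGWAS)

cfg <- sim_config(n_snps = 40, maf_range = c(0.1, 0.5),
                  planted_cc_effects = list(list(snp_index = 7L,
                                                 subtypes = 1L, or = 2.0)),
                  seed = 42)
sim    <- simulate_genotypes(cfg)
items  <- simulate_item_scores(cfg, sim$truth$subtype)
scores <- recode_items(items)
asg    <- name_clusters(kmeans_cluster(scores, 4, seed = 1), scores)
print(asg)
#> subtype_assignment: K = 4 , n = 1867 , objective = 41695.7
#>          Moderate              Mild      Intermediate Language-impaired
#>               363               387               478               639

st <- subtype_assoc(sim$dataset,
                    list(language = sim$dataset$variants$snp_id[1:20]), asg)
subset(st, snp_id == "snp00007",
       c(subtype, f_a, f_u, or_a1, p_unadj, p_bonf))
#>              subtype   f_a   f_u or_a1  p_unadj   p_bonf
#> 7           Moderate 0.415 0.393  1.09 2.70e-01 1.00e+00
#> 27              Mild 0.379 0.393  0.94 4.39e-01 1.00e+00
#> 47      Intermediate 0.407 0.393  1.06 4.26e-01 1.00e+00
#> 67 Language-impaired 0.563 0.393  1.99 6.91e-28 1.38e-26
#> 87          Combined 0.456 0.393  1.29 4.57e-09 9.13e-08
```

Reading the output: clustering recovers the four planted subtype sizes
exactly; the planted SNP is overwhelmingly significant in the targeted
Language-impaired cohort with its odds ratio estimated at 1.99 (truth
2.0), null in the three unaffected subtypes, and — the design's point —
much weaker when all cases are pooled (case frequency 0.456 vs 0.563 in
the targeted subtype).

The numbered scripts under `analysis/` run the same machinery as a full
narrative workflow (simulate → subtype → screen → subtype association →
final/replication → published-table worked example), writing their
tables under `results/analysis/`; large raw files go to `scratch/`.
`example_assoc_table()` loads the bundled published tables; applying
`select_and_combine()` and `replication_report()` to the final table
reproduces its headline bookkeeping — 18 unique subtype-significant SNPs,
10 of them qualifying in more than one subtype.

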