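---
title: "Subphenotype-stratified genetic association: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subphenotype-stratified genetic association: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtypeGWAS)
```

## The problem this package addresses

Case-control association studies of phenotypically heterogeneous disorders
pool cases that may be genetically distinct. If a variant raises risk only
in a subset of cases with a particular symptom profile, its allele-frequency
signal is diluted in the pooled comparison and can disappear entirely, even
at sample sizes in the thousands. Autism spectrum disorders are the
motivating example: cases assessed with a structured diagnostic interview
carry 123 item-level symptom-severity scores, and clustering those profiles
yields reproducible subgroups ranging from a severely language-impaired
profile to a mild one.

`subtypeGWAS` implements a three-stage design that exploits this structure:

1. **Quantitative-trait screen.** Item severities are summed into five
   behavioural trait scores (spoken language, non-verbal communication,
   play skills, insistence on sameness, social development). Each trait is
   regressed on each SNP's additive genotype over the cases, and SNPs with
   unadjusted $p \le 10^{-5}$ for some trait are retained as that trait's
   QTL set. The threshold is deliberately nominal: the screen's job is to
   enrich for potentially trait-relevant loci, not to provide inference.
2. **Subtype-dependent case-control association.** Cases are partitioned
   into K phenotypic subtypes by K-means on the item-severity matrix
   (K = 4 by default). Each trait's QTL set is tested for allelic
   association subtype-by-subtype against the full control group, with
   Bonferroni and Benjamini-Hochberg adjustment within each
   (trait x subtype) run using the QTL-set size as the number of tests.
   SNPs Bonferroni-significant ($p \le 0.05$) in at least one subtype are
   combined into a single deduplicated list.
3. **Final association and replication.** The combined list is re-tested
   in every subtype and in the pooled cases, adjusting over the combined
   list. A SNP significant or suggestive in more than one subtype has
   replicated across independent case cohorts; because the subtypes are
   disjoint, the per-subtype odds ratios expose effect heterogeneity.

Pooled-case rows are computed at every stage for context but never drive
selection: the design's point is that the per-subtype comparisons carry the
power.

## Statistical components

**Allelic test.** For each SNP the 2x2 table of minor/major allele counts
in cases and controls (two alleles per genotyped individual; per-SNP
complete-case deletion) is tested with the 1-df Pearson chi-square without
continuity correction,
$$\chi^2 = \frac{N(ad - bc)^2}{(a+b)(c+d)(a+c)(b+d)},$$
and summarised by the minor-allele odds ratio $\mathrm{OR} = ad/bc$. The
minor allele is defined on the pooled sample; an exact 0.5/0.5 tie is
broken lexicographically on the allele label so results are reproducible.
A zero cell leaves the OR undefined (`NA`) unless the Haldane-Anscombe
+0.5 correction is requested. Note on orientation: association tables in
this field sometimes label the OR column as being "with respect to the
major allele", but the printed values in the tables this package
reproduces are numerically the minor-allele odds ratios computed from the
printed case/control minor-allele frequencies (e.g. frequencies
0.391/0.447 give 0.79); the package follows the numerically consistent
convention.

**Quantitative-trait regression.** Ordinary least squares of the trait on
the 0/1/2 genotype code, with the two-sided p-value from the t
distribution on $n - 2$ degrees of freedom rather than the normal
approximation — exact at small n and indistinguishable at cohort scale.
Monomorphic SNPs are flagged untestable and never enter a QTL set.

**Multiple testing.** `bonferroni(p, m)` is $\min(1, pm)$ and
`bh_adjust(p, m)` is the Benjamini-Hochberg step-up with an explicit test
count `m`, which may exceed the number of supplied p-values. Supplying `m`
explicitly is mandatory in the pipeline because adjusted columns are only
reproducible when the denominator is the size of the tested set, not the
number of reported rows: in the reproduced tables the Bonferroni column is
exactly `m x UNADJ` for the run's full set size.

**Quality control.** Variants are excluded before analysis if call
missingness exceeds 10%, pooled minor-allele frequency is below 1%, or the
1-df Hardy-Weinberg chi-square in controls has $p < 0.001$. The chi-square
(rather than exact) HWE test matches the era of the cleaning rules being
reproduced; both the statistic and the thresholds are arguments.

## Subtyping

K-means uses a missing-aware squared Euclidean distance: for a case row
$x$ with observed item set $O$ and a centroid $c$,
$$d(x, c) = \frac{p}{|O|} \sum_{i \in O} (x_i - c_i)^2,$$
so cases with sparse missingness are clustered rather than dropped.
Centroids are per-cluster means over observed entries. Because the
$p/|O|$ factor is constant within a row it never changes which centroid is
nearest, so the reported objective is the unscaled within-cluster observed
sum of squares — the quantity that both Lloyd steps monotonically
decrease, which the test suite checks per run. Restarts seed centroids
from random data rows (10 by default); a cluster that empties is re-seeded
from the farthest point. Clusters are named by descending mean severity;
for K = 4 the conventional labels are Language-impaired, Intermediate,
Moderate, Mild. The severity ranking deliberately does not attempt to
distinguish "Moderate" by savant-item semantics — that distinction is not
numerically specified, so naming is strictly rank-based.

**Choosing K.** `fom_curve()` computes a leave-one-item-out figure of
merit: cluster on all items but one, and score how well cluster membership
predicts the held-out item, summed over items and divided by the
$\sqrt{(n-K)/n}$ adjustment. Two reads of the curve are provided, because
they answer different questions. The maximum-curvature knee
(`fom_elbow()`) finds the sharpest bend; on equidistant, well-separated
archetypes it recovers the planted cluster number. On *graded* severity
structure — which real severity data resemble — the dominant bend is the
severe/mild split at K = 2, while the curve visibly continues to improve
until K = 4 and flattens after (further improvement under 5%). The
analysis drivers therefore print the whole curve with per-step
improvements rather than a single number. The raw (unadjusted) FOM is
monotone decreasing in K and is not useful for model choice on its own.

PCA (`pca_project()`) is used only as an unsupervised separation check;
missing entries are column-mean imputed before the decomposition, a choice
that shrinks variance slightly but is immaterial at the few-percent
missingness the generator and typical data exhibit.

## The synthetic cohort generator

The study's genotype data are access-restricted, so the package ships a
generator whose defaults emulate the analysed cohort's structure:

| parameter | default | rationale |
|---|---|---|
| cases per subtype | 639 / 478 / 363 / 387 | the four subtype cohort sizes the design targets (1867 cases) |
| controls | 2438 | control cohort size |
| SNPs | 2000 | scaled down from a ~513k chip panel; statistics are per-SNP, so panel size matters only through multiplicity |
| control MAF | Uniform(0.05, 0.5) | common-variant panel post MAF-QC |
| severity noise SD | 0.3 | within-subtype item variability that still leaves archetype profiles recognisable; real cohorts are noisier (see below) |
| item missing rate | 0.02 | a few percent of interview items not applicable/not asked |

Genotypes are drawn genotype-wise from Hardy-Weinberg proportions at the
SNP's frequency; there is no linkage disequilibrium, no population
stratification, and no family structure. Case-control effects are planted
on allele *frequency* — cases in the targeted subtypes draw the tracked
allele at the odds-shifted frequency
$m' = \mathrm{OR}\,\frac{m}{1-m} \big/ \big(1 + \mathrm{OR}\,\frac{m}{1-m}\big)$
— rather than through a penetrance model, because the pipeline's statistic
is allelic: the planted OR is then exactly the estimand of the allelic
test. Quantitative-trait effects add $\beta$ trait-units per allele copy
directly to a trait sum.

The four archetypes place the subtypes on a severity gradient with one
qualitative reversal (the Moderate profile is elevated on
insistence-on-sameness items), giving mean-severity block profiles of
2.6/2.0/1.8/1.6/2.0 (severe), 1.6/1.5/1.4/1.3/1.5 (intermediate),
1.0/1.0/1.0/1.8/1.0 (moderate) and 0.6/0.5/0.5/0.5/0.5 (mild) over the
language / nonverbal / play / sameness / social item blocks. The closest
archetype pair is ~5.7 apart in item-space L2 distance, which at noise
SD 0.3 puts per-case misassignment probability effectively at zero — so
clustering tests recover planted subtype sizes exactly. Item scores are
`clamp(round(archetype + noise), 0, 3)`: the simplest mechanism that
yields ordinal 0-3 scores with controllable separation.

**What passing these tests does not show.** The generator's subtypes are
genuinely well-separated Gaussian-ish blobs; real severity data have
heavier overlap, instrument-specific item semantics, and missingness that
is informative rather than random. Recovery results on synthetic data
demonstrate that the machinery is correct and calibrated, not that four
subtypes (or any particular K) exist in a given real cohort. Likewise the
bundled trait map (`default_trait_definitions()`) is a synthetic partition
of 123 items into five blocks; with real interview data the
instrument-specific item-to-category mapping must be supplied by the
analyst (`read_trait_map()`), as must the severity recode map if the
instrument's special codes differ from the 7 -> 0, 8/9 -> missing default.

## Numerical and design choices

- **Genotype orientation.** Parsed calls count copies of the second
  allele observed in file order; minor-allele orientation is decided at
  association time. This keeps file I/O deterministic and orientation-free.
  Writing then re-reading a freshly parsed dataset is the identity;
  datasets constructed in other orientations are preserved up to the
  per-variant relabelling that parsing canonicalises.
- **Missing trait items** contribute zero to a trait sum (sum over
  observed), and a case missing more than 20% of a trait's items gets a
  missing trait value — summing raw scores without imputation matches how
  such trait sums are built in practice, and the cap prevents near-empty
  sums from masquerading as low severity.
- **Inclusive thresholds.** The screen keeps $p \le 10^{-5}$ and selection
  keeps $p_{\mathrm{Bonf}} \le 0.05$; the distinction from strict
  inequality is measure-zero.
- **Per-component seeds.** One master seed per simulation config;
  genotype and phenotype streams derive from it deterministically, so a
  cohort is bit-reproducible from its config alone.
- **Problem sizes in tests.** The test and acceptance simulations use
  5000 null SNPs for type-I calibration, 50 seeds at full cohort scale for
  the subtype-OR recovery rate, 100 seeds of 1500-case cohorts for the
  screen-power rate, and one full-scale clustering recovery — sizes chosen
  so each claim is tested at the scale it is made while the whole suite
  runs in well under a minute per property.
- **Screen-power simulations use a homogeneous cohort** (all cases drawn
  from one archetype). With the default four-archetype mixture the
  between-subtype trait variance (trait-sum SD around 15-20) dominates the
  per-allele effect, and a $\beta = 3$ effect is analytically
  undetectable at $10^{-5}$ with 1500 cases; isolating the
  genotype-to-trait signal is the point of that recovery check, while the
  mixture's dilution effects are exercised by the pipeline tests instead.

## Known limitations

- No covariate adjustment, genotypic/trend models, or family-based tests;
  the allelic test assumes unrelated individuals and no stratification.
- No linkage disequilibrium in the generator, hence no multi-SNP or
  haplotype structure to stress the screen's multiplicity behaviour.
- Mendelian-error QC is out of scope (no pedigrees), as are binary PLINK
  formats and multi-allelic variants.
- The K-means objective is non-convex; determinism comes from seeding,
  and the restart count trades runtime against local optima. The FOM
  curve inherits this noise, which is why the drivers report it with
  per-step improvements instead of a single statistic.
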