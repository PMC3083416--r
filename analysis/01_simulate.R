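#!/usr/bin/env Rscript
# Stage 0: simulate a study-scale synthetic cohort.
#
# Builds the cohort the downstream drivers analyse: 1867 cases in four
# phenotypic subtypes (639/478/363/387), 2438 controls, and a 1200-SNP panel
# in Hardy-Weinberg equilibrium. Four SNPs carry planted quantitative-trait
# effects (5 trait-score units per allele copy) and three of those also
# carry subtype-specific case-control effects with heterogeneous odds
# ratios, emulating loci whose effect differs between subtypes; one further
# SNP carries a case-control effect with no trait association and should be
# removed by the trait screen. Raw genotype/phenotype files go to scratch/
# (they are large); the ground truth and a summary go to results/analysis/.

suppressMessages(library(subtypeGWAS))

dir.create("scratch/cohort", recursive = TRUE, showWarnings = FALSE)
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

cc_effects <- list(
  list(snp_index = 101L, subtypes = 1L,        or = 1.8),
  list(snp_index = 202L, subtypes = 3L,        or = 2.0),
  list(snp_index = 303L, subtypes = c(1L, 4L), or = 1.6),
  list(snp_index = 505L, subtypes = 2L,        or = 1.8)  # no trait effect
)
qt_effects <- list(
  list(snp_index = 101L, trait = "language", beta = 5),
  list(snp_index = 202L, trait = "sameness", beta = 5),
  list(snp_index = 303L, trait = "social",   beta = 5),
  list(snp_index = 404L, trait = "play",     beta = 5)
)

cfg <- sim_config(n_snps = 1200L, maf_range = c(0.1, 0.5),
                  planted_cc_effects = cc_effects,
                  planted_qt_effects = qt_effects, seed = 20260101L)

sim <- simulate_genotypes(cfg)
print(sim$dataset)

items <- simulate_item_scores(cfg, sim$truth$subtype)
traits <- trait_sums(recode_items(items), default_trait_definitions())
traits <- plant_qt_effect(sim$dataset, traits, qt_effects)

write_ped_map(sim$dataset, "scratch/cohort/cohort.ped", "scratch/cohort/cohort.map")
write_item_scores(items, "scratch/cohort/items.tsv")
utils::write.table(traits, "scratch/cohort/traits.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(individual_id = names(sim$truth$subtype),
             subtype = sim$truth$subtype),
  "results/analysis/ground_truth_subtypes.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)

planted <- rbind(
  data.frame(snp_id = sprintf("snp%05d", vapply(cc_effects, `[[`, 1L, "snp_index")),
             kind = "case_control",
             detail = vapply(cc_effects, function(e)
               sprintf("subtypes=%s;or=%.2f",
                       paste(e$subtypes, collapse = "+"), e$or), character(1))),
  data.frame(snp_id = sprintf("snp%05d", vapply(qt_effects, `[[`, 1L, "snp_index")),
             kind = "quantitative_trait",
             detail = vapply(qt_effects, function(e)
               sprintf("trait=%s;beta=%.1f", e$trait, e$beta), character(1)))
)
utils::write.table(planted, "results/analysis/planted_effects.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("cohort written to scratch/cohort/ (PED/MAP, items, traits)\n")
cat("planted-effect record in results/analysis/planted_effects.tsv\n")
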