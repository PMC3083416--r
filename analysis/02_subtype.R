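#!/usr/bin/env Rscript
# Stage 1a: phenotypic subtyping of the cases.
#
# Recode the raw item codes to 0-3 severities, cluster the cases with
# missing-aware K-means (K = 4, 10 restarts), verify the choice of K with a
# figure-of-merit curve on a case/item subsample (the curve needs one
# clustering run per left-out item and per K, so a 300-case x 40-item
# subsample keeps it to a few seconds), name the clusters by severity rank,
# and check cluster separation with a PCA projection.

suppressMessages(library(subtypeGWAS))
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

items <- read_item_scores("scratch/cohort/items.tsv")
scores <- recode_items(items)

asg <- name_clusters(kmeans_cluster(scores, K = 4, seed = 11L), scores)
print(asg)

truth <- utils::read.table("results/analysis/ground_truth_subtypes.tsv",
                           header = TRUE, sep = "\t", stringsAsFactors = FALSE)
cat(sprintf("Rand index vs planted subtypes: %.4f\n",
            rand_index(asg$cluster[truth$individual_id], truth$subtype)))

set.seed(12)
sub_cases <- sample(nrow(scores), 300)
fc <- fom_curve(scores[sub_cases, ], k_range = 1:6, seed = 13L,
                n_restarts = 2)
fc$improvement_to_next <- c(round(-diff(fc$fom) / fc$fom[-nrow(fc)], 3), NA)
print(fc, digits = 4)
# two complementary reads of the curve: the maximum-curvature knee picks the
# dominant severity split; the flattening point (first K whose further
# improvement drops under 5%) marks where added clusters stop paying
flat <- fc$K[which(fc$improvement_to_next < 0.05)[1]]
cat(sprintf("max-curvature knee at K = %d; curve flattens beyond K = %d\n",
            fom_elbow(fc), flat))
utils::write.table(fc, "results/analysis/fom_curve.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

pc <- pca_project(scores, 2)
cat(sprintf("PC1/PC2 explained variance: %.2f / %.2f\n",
            pc$explained[1], pc$explained[2]))

utils::write.table(
  data.frame(individual_id = names(asg$cluster),
             cluster = unname(asg$cluster),
             subtype = unname(asg$case_names),
             pc1 = round(pc$scores[names(asg$cluster), 1], 4),
             pc2 = round(pc$scores[names(asg$cluster), 2], 4)),
  "results/analysis/subtype_assignment.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)
cat("assignment written to results/analysis/subtype_assignment.tsv\n")
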