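#!/usr/bin/env Rscript
# Stage 1b: quality control and quantitative-trait screening.
#
# Apply the standard cleaning rules (missingness > 10%, MAF < 1%, control
# HWE p < 0.001), then regress each of the five trait sums on every SNP's
# additive genotype over the cases and keep, per trait, the SNPs with
# unadjusted p <= 1e-5. This discovery filter is what turns the full panel
# into small per-trait QTL sets for the subtype association stage.

suppressMessages(library(subtypeGWAS))
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

ds <- read_ped_map("scratch/cohort/cohort.ped", "scratch/cohort/cohort.map")
qc <- qc_filter(ds)
cat(sprintf("QC: %d of %d SNPs retained (%d excluded)\n",
            nrow(qc$dataset$variants), nrow(ds$variants),
            nrow(qc$exclusions)))
utils::write.table(qc$exclusions, "results/analysis/qc_exclusions.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

traits <- utils::read.table("scratch/cohort/traits.tsv", header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
scr <- qt_screen(qc$dataset, traits, p_threshold = 1e-5)

qtl <- do.call(rbind, lapply(names(scr$qtl_sets), function(trait) {
  snps <- scr$qtl_sets[[trait]]
  if (length(snps) == 0L) return(NULL)
  r <- scr$results[scr$results$trait == trait & scr$results$snp_id %in% snps, ]
  r[, c("trait", "snp_id", "beta", "se", "p_unadj", "n_used")]
}))
if (is.null(qtl)) qtl <- scr$results[0, c("trait", "snp_id", "beta", "se",
                                          "p_unadj", "n_used")]
cat(sprintf("screen: %d trait-QTL pairs over %d unique SNPs\n",
            nrow(qtl), length(unique(qtl$snp_id))))
print(qtl, digits = 3)
utils::write.table(qtl, "results/analysis/qtl_sets.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
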