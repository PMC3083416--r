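#' Pipeline configuration
#'
#' Thresholds and settings for the three-stage subtype-association design:
#' quantitative-trait screening of the SNP panel, per-subtype case-control
#' association of the retained loci, and the final combined association and
#' replication report.
#'
#' @param qt_p_threshold unadjusted p-value cutoff of the quantitative-trait
#'   screen (default 1e-5, inclusive).
#' @param bonf_select_threshold Bonferroni-adjusted p-value cutoff used to
#'   select subtype-associated SNPs (default 0.05, inclusive).
#' @param suggestive_threshold BH-adjusted p-value bound under which a
#'   replication in another subtype counts as suggestive (default 0.09,
#'   exclusive).
#' @param K number of phenotypic subtypes (default 4).
#' @param n_restarts,kmeans_max_iter K-means settings.
#' @param max_missing,min_maf,hwe_alpha QC thresholds, see [qc_filter()].
#' @param max_missing_fraction per-trait missingness tolerance, see
#'   [trait_sums()].
#' @param seed integer seed for the clustering restarts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(qt_p_threshold = 1e-5,
                            bonf_select_threshold = 0.05,
                            suggestive_threshold = 0.09,
                            K = 4L, n_restarts = 10L, kmeans_max_iter = 100L,
                            max_missing = 0.10, min_maf = 0.01,
                            hwe_alpha = 0.001, max_missing_fraction = 0.2,
                            seed = 1L) {
  stopifnot(qt_p_threshold > 0, qt_p_threshold < 1,
            bonf_select_threshold > 0, bonf_select_threshold < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Quantitative-trait screen of the SNP panel
#'
#' Regresses each trait on each SNP's additive genotype code over the cases
#' with a non-missing trait value ([qt_linear_assoc()]) and keeps, per
#' trait, the SNPs with unadjusted p-value at or below the screening
#' threshold. This is the discovery filter that turns the full panel into
#' small per-trait QTL sets; the threshold is deliberately nominal (no
#' multiplicity adjustment) because the screen's job is enrichment, not
#' inference.
#'
#' @param dataset a (QC-filtered) [genotype_dataset()].
#' @param trait_table data.frame from [trait_sums()] /
#'   [plant_qt_effect()], covering (a subset of) the dataset's cases.
#' @param p_threshold screening cutoff on the unadjusted p-value (inclusive;
#'   default 1e-5).
#' @param traits trait columns to screen (default: all non-id columns).
#' @return List with `qtl_sets` (trait name -> character vector of snp_ids)
#'   and `results` (per trait x SNP regression table).
#' @export
qt_screen <- function(dataset, trait_table, p_threshold = 1e-5,
                      traits = setdiff(names(trait_table), "individual_id")) {
  idx <- match(trait_table$individual_id, dataset$samples$individual_id)
  if (anyNA(idx)) stop("trait table contains ids absent from the dataset")
  snp_ids <- dataset$variants$snp_id
  res <- vector("list", length(traits))
  names(res) <- traits
  for (trait in traits) {
    y <- trait_table[[trait]]
    rows <- lapply(seq_along(snp_ids), function(j) {
      fit <- qt_linear_assoc(dataset$calls[idx, j], y)
      data.frame(trait = trait, snp_id = snp_ids[j], beta = fit$beta,
                 se = fit$se, stat = fit$stat, p_unadj = fit$p_unadj,
                 n_used = fit$n_used, testable = fit$testable,
                 stringsAsFactors = FALSE)
    })
    res[[trait]] <- do.call(rbind, rows)
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  qtl_sets <- lapply(traits, function(trait) {
    r <- results[results$trait == trait & results$testable, ]
    r$snp_id[r$p_unadj <= p_threshold]
  })
  names(qtl_sets) <- traits
  list(qtl_sets = qtl_sets, results = results)
}

# group label -> case sample indices, in severity-rank order
subtype_groups <- function(dataset, assignment) {
  case_ids <- dataset$samples$individual_id[case_indices(dataset)]
  labels <- if (!is.null(assignment$case_names)) assignment$case_names
            else stats::setNames(paste0("cluster", assignment$cluster),
                                 names(assignment$cluster))
  labels <- labels[names(labels) %in% case_ids]
  order_names <- if (!is.null(assignment$names)) assignment$names
                 else paste0("cluster", seq_len(assignment$K))
  groups <- lapply(order_names, function(nm) {
    match(names(labels)[labels == nm], dataset$samples$individual_id)
  })
  names(groups) <- order_names
  groups[lengths(groups) > 0L]
}

#' Per-subtype case-control association of the QTL sets
#'
#' For each trait's QTL set, runs the allelic test of every retained SNP for
#' each case subtype against all controls, and for the combined cases
#' against the same controls. Within each (trait, group) run, BH and
#' Bonferroni adjustments use `m = |trait QTL set|`; runs are never pooled
#' across subtypes. Combined-case rows are reported for context but are
#' excluded from downstream selection.
#'
#' @param dataset a [genotype_dataset()].
#' @param qtl_sets named list, trait -> snp_id vector (from [qt_screen()]).
#' @param assignment a named `subtype_assignment` covering the genotyped
#'   cases (see [kmeans_cluster()], [name_clusters()]).
#' @param include_combined also test the pooled cases (default TRUE).
#' @return data.frame of adjusted association rows with leading columns
#'   `trait` and `subtype` (`"Combined"` for the pooled run).
#' @export
subtype_assoc <- function(dataset, qtl_sets, assignment,
                          include_combined = TRUE) {
  ctl <- control_indices(dataset)
  groups <- subtype_groups(dataset, assignment)
  if (include_combined)
    groups <- c(groups, list(Combined = case_indices(dataset)))
  out <- list()
  for (trait in names(qtl_sets)) {
    snps <- qtl_sets[[trait]]
    if (length(snps) == 0L) next
    m <- length(snps)
    for (grp in names(groups)) {
      rows <- cc_assoc_table(dataset, groups[[grp]], ctl, snps)
      rows <- adjust_assoc(rows, m_tests = m)
      rows <- cbind(data.frame(trait = trait, subtype = grp,
                               stringsAsFactors = FALSE), rows)
      out[[length(out) + 1L]] <- rows
    }
  }
  if (length(out) == 0L) return(empty_subtype_assoc())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_subtype_assoc <- function() {
  data.frame(trait = character(0), subtype = character(0),
             chrom = character(0), snp_id = character(0), bp = integer(0),
             a1 = character(0), a2 = character(0), f_a = numeric(0),
             f_u = numeric(0), chisq = numeric(0), or_a1 = numeric(0),
             p_unadj = numeric(0), n_case_used = integer(0),
             n_control_used = integer(0), p_fdr_bh = numeric(0),
             p_bonf = numeric(0), m_tests = integer(0),
             stringsAsFactors = FALSE)
}

#' Select subtype-significant SNPs and combine them
#'
#' Union of the SNPs whose Bonferroni-adjusted p-value meets the selection
#' threshold in at least one subtype (combined-case rows never drive
#' selection), deduplicated.
#'
#' @param tables association rows from [subtype_assoc()], or any data.frame
#'   with columns `snp_id`/`SNP`, `subtype`/`Subtype`, `p_bonf`/`BONF`.
#' @param bonf_threshold selection cutoff (inclusive; default 0.05).
#' @return Character vector of unique snp_ids, in first-appearance order.
#' @export
select_and_combine <- function(tables, bonf_threshold = 0.05) {
  tab <- normalize_assoc_cols(tables)
  tab <- tab[tab$subtype != "Combined", , drop = FALSE]
  unique(tab$snp_id[!is.na(tab$p_bonf) & tab$p_bonf <= bonf_threshold])
}

# accept both internal (lowercase) and PLINK-style (uppercase) column names
normalize_assoc_cols <- function(tab) {
  map <- c(SNP = "snp_id", Subtype = "subtype", OR = "or_a1",
           UNADJ = "p_unadj", FDR_BH = "p_fdr_bh", BONF = "p_bonf",
           F_A = "f_a", F_U = "f_u")
  for (from in names(map)) {
    if (from %in% names(tab) && !(map[[from]] %in% names(tab)))
      names(tab)[names(tab) == from] <- map[[from]]
  }
  need <- c("snp_id", "subtype")
  if (!all(need %in% names(tab)))
    stop("association table must have snp_id/SNP and subtype/Subtype columns")
  tab
}

#' Final association of the combined SNP list
#'
#' Re-tests the combined selection in every subtype and in the pooled
#' cases, adjusting with `m = length(snp_ids)` for both BH and Bonferroni.
#'
#' @param dataset a [genotype_dataset()].
#' @param snp_ids combined SNP list from [select_and_combine()]; must be
#'   nonempty.
#' @param assignment named `subtype_assignment`.
#' @param include_combined also test the pooled cases (default TRUE).
#' @return data.frame of adjusted rows with a leading `subtype` column.
#' @export
final_assoc <- function(dataset, snp_ids, assignment,
                        include_combined = TRUE) {
  if (length(snp_ids) == 0L) stop("combined SNP list is empty")
  ctl <- control_indices(dataset)
  groups <- subtype_groups(dataset, assignment)
  if (include_combined)
    groups <- c(groups, list(Combined = case_indices(dataset)))
  m <- length(snp_ids)
  out <- lapply(names(groups), function(grp) {
    rows <- adjust_assoc(cc_assoc_table(dataset, groups[[grp]], ctl, snp_ids),
                         m_tests = m)
    cbind(data.frame(subtype = grp, stringsAsFactors = FALSE), rows)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-subtype replication report
#'
#' Groups the final association rows by SNP and reports, for each SNP, the
#' set of subtypes in which it is significant (Bonferroni-adjusted p at or
#' below `sig_threshold`) or suggestive (BH-adjusted p below
#' `suggestive_threshold`), with the per-subtype odds ratios. A SNP
#' qualifying in more than one subtype is replicated across independent
#' case cohorts. Combined-case rows are ignored.
#'
#' @param final_table rows from [final_assoc()], or any table with
#'   `snp_id`/`SNP`, `subtype`/`Subtype`, `or_a1`/`OR`, `p_fdr_bh`/`FDR_BH`,
#'   `p_bonf`/`BONF` columns.
#' @param sig_threshold Bonferroni significance cutoff (inclusive; default
#'   0.05).
#' @param suggestive_threshold BH suggestive cutoff (exclusive; default
#'   0.09).
#' @return List with `per_snp` (data.frame: `snp_id`, `n_subtypes`,
#'   `subtypes`, `ors`, `p_bonf`, `p_fdr_bh`, comma-separated in subtype
#'   order), `n_snps`, and `n_shared` (SNPs qualifying in > 1 subtype).
#' @export
replication_report <- function(final_table, sig_threshold = 0.05,
                               suggestive_threshold = 0.09) {
  tab <- normalize_assoc_cols(final_table)
  tab <- tab[tab$subtype != "Combined", , drop = FALSE]
  qual <- (!is.na(tab$p_bonf) & tab$p_bonf <= sig_threshold) |
          (!is.na(tab$p_fdr_bh) & tab$p_fdr_bh < suggestive_threshold)
  tab <- tab[qual, , drop = FALSE]
  snps <- unique(tab$snp_id)
  per_snp <- do.call(rbind, lapply(snps, function(s) {
    rows <- tab[tab$snp_id == s, , drop = FALSE]
    data.frame(snp_id = s, n_subtypes = nrow(rows),
               subtypes = paste(rows$subtype, collapse = ","),
               ors = paste(sprintf("%.2f", rows$or_a1), collapse = ","),
               p_bonf = paste(sprintf("%.4f", rows$p_bonf), collapse = ","),
               p_fdr_bh = paste(sprintf("%.4f", rows$p_fdr_bh), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_snp))
    per_snp <- data.frame(snp_id = character(0), n_subtypes = integer(0),
                          subtypes = character(0), ors = character(0),
                          p_bonf = character(0), p_fdr_bh = character(0),
                          stringsAsFactors = FALSE)
  list(per_snp = per_snp, n_snps = nrow(per_snp),
       n_shared = sum(per_snp$n_subtypes > 1L))
}

#' Run the full subtype-association pipeline
#'
#' End to end: severity recoding and trait construction, genotype QC,
#' K-means subtyping of the genotyped cases, quantitative-trait screening,
#' per-subtype association of the QTL sets, selection and combination of
#' subtype-significant SNPs, final association, and the replication report.
#' Deterministic given `config$seed`.
#'
#' @param dataset a [genotype_dataset()].
#' @param raw_items raw item-code matrix covering (at least) the genotyped
#'   cases.
#' @param trait_definitions trait -> item-name list (see [trait_sums()]).
#' @param config a [pipeline_config()].
#' @param recode_map see [recode_items()].
#' @return List with elements `qc`, `scores`, `traits`, `assignment`,
#'   `screen`, `subtype_tables`, `combined_snps`, `final_table`,
#'   `replication`, `config`.
#' @export
run_pipeline <- function(dataset, raw_items, trait_definitions,
                         config = pipeline_config(),
                         recode_map = default_recode_map()) {
  qc <- qc_filter(dataset, max_missing = config$max_missing,
                  min_maf = config$min_maf, hwe_alpha = config$hwe_alpha)
  ds <- qc$dataset
  case_ids <- ds$samples$individual_id[case_indices(ds)]
  genotyped <- intersect(rownames(raw_items), case_ids)
  if (length(genotyped) < config$K)
    stop("fewer genotyped cases with item scores than clusters")
  scores <- recode_items(raw_items[genotyped, , drop = FALSE], recode_map)
  traits <- trait_sums(scores, trait_definitions,
                       max_missing_fraction = config$max_missing_fraction)
  assignment <- kmeans_cluster(scores, config$K,
                               n_restarts = config$n_restarts,
                               max_iter = config$kmeans_max_iter,
                               seed = config$seed)
  assignment <- name_clusters(assignment, scores)
  screen <- qt_screen(ds, traits, p_threshold = config$qt_p_threshold)
  subtype_tables <- subtype_assoc(ds, screen$qtl_sets, assignment)
  combined <- select_and_combine(subtype_tables,
                                 bonf_threshold = config$bonf_select_threshold)
  final_table <- if (length(combined) > 0L)
    final_assoc(ds, combined, assignment) else NULL
  replication <- if (!is.null(final_table))
    replication_report(final_table,
                       sig_threshold = config$bonf_select_threshold,
                       suggestive_threshold = config$suggestive_threshold)
    else NULL
  list(qc = qc, scores = scores, traits = traits, assignment = assignment,
       screen = screen, subtype_tables = subtype_tables,
       combined_snps = combined, final_table = final_table,
       replication = replication, config = config)
}
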