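#' Default subtype archetypes for the synthetic phenotype generator
#'
#' A 4 x 123 matrix of mean item severities (0-3 scale) defining the four
#' phenotypic subtype archetypes the generator emulates: a severe,
#' language-dominated profile; an intermediate profile; a moderate profile
#' with elevated insistence-on-sameness items; and a mild profile. Items are
#' grouped into five behavioural blocks (spoken language, items 1-26;
#' non-verbal communication, 27-46; play skills, 47-61; insistence on
#' sameness, 62-83; social development, 84-123) matching
#' [default_trait_definitions()].
#'
#' @return Numeric matrix with archetype rownames and item colnames.
#' @export
default_archetypes <- function() {
  blocks <- trait_item_blocks()
  arch <- rbind(
    language_impaired = c(2.6, 2.0, 1.8, 1.6, 2.0),
    intermediate      = c(1.6, 1.5, 1.4, 1.3, 1.5),
    moderate          = c(1.0, 1.0, 1.0, 1.8, 1.0),
    mild              = c(0.6, 0.5, 0.5, 0.5, 0.5)
  )
  out <- matrix(0, 4L, 123L,
                dimnames = list(rownames(arch), sprintf("item%03d", 1:123)))
  for (b in seq_along(blocks)) out[, blocks[[b]]] <- arch[, b]
  out
}

# item index blocks underlying the synthetic trait map
trait_item_blocks <- function() {
  list(language = 1:26, nonverbal = 27:46, play = 47:61,
       sameness = 62:83, social = 84:123)
}

#' Synthetic trait-definition mapping
#'
#' Partition of the 123 synthetic items into the five behavioural trait
#' categories (language, nonverbal, play, sameness, social). This is a
#' synthetic stand-in: the item-to-category mapping used with real
#' diagnostic-instrument data is instrument-specific and must be supplied by
#' the analyst (see [read_trait_map()]).
#'
#' @return Named list: trait name -> item-name vector, as [trait_sums()]
#'   expects.
#' @export
default_trait_definitions <- function() {
  items <- sprintf("item%03d", 1:123)
  lapply(trait_item_blocks(), function(ix) items[ix])
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic genotype/phenotype
#' generator. The defaults emulate the cohort the analysis design targets:
#' four case subtypes of 639/478/363/387 individuals (1867 cases), 2438
#' controls, and a SNP panel scaled down to 2000 markers (population-scale
#' panels are two to three orders of magnitude larger; the statistics are
#' per-SNP, so panel size only affects multiplicity).
#'
#' @param n_cases_per_subtype four case counts, one per subtype.
#' @param n_controls number of controls.
#' @param n_snps number of simulated SNPs.
#' @param maf_range interval in (0, 0.5] from which control minor-allele
#'   frequencies are drawn uniformly.
#' @param archetypes 4 x n_items matrix of mean severities in \[0, 3\].
#' @param severity_noise_sd Gaussian noise SD added to the archetype mean
#'   before rounding/clamping to the 0-3 scale (default 0.3).
#' @param item_missing_rate probability that an item is recorded as a
#'   special non-severity code (8 or 9) instead of its score (default 0.02).
#' @param planted_cc_effects list of case-control effects, each a list with
#'   `snp_index`, `subtypes` (integer set in 1..4), and `or` (case odds
#'   ratio on the tracked allele, > 0).
#' @param planted_qt_effects list of quantitative-trait effects, each a list
#'   with `snp_index`, `trait` (trait name), and `beta` (trait-score units
#'   per allele copy).
#' @param seed integer master seed; all generator streams derive from it.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases_per_subtype = c(639L, 478L, 363L, 387L),
                       n_controls = 2438L,
                       n_snps = 2000L,
                       maf_range = c(0.05, 0.5),
                       archetypes = default_archetypes(),
                       severity_noise_sd = 0.3,
                       item_missing_rate = 0.02,
                       planted_cc_effects = list(),
                       planted_qt_effects = list(),
                       seed = 1L) {
  stopifnot(length(n_cases_per_subtype) == 4L, all(n_cases_per_subtype >= 1L),
            n_controls >= 1L, n_snps >= 1L,
            length(maf_range) == 2L, maf_range[1L] > 0, maf_range[2L] <= 0.5,
            maf_range[1L] <= maf_range[2L],
            nrow(archetypes) == 4L, all(archetypes >= 0 & archetypes <= 3),
            severity_noise_sd >= 0,
            item_missing_rate >= 0, item_missing_rate < 1)
  for (eff in planted_cc_effects) {
    stopifnot(eff$snp_index >= 1L, eff$snp_index <= n_snps,
              all(eff$subtypes %in% 1:4), eff$or > 0)
  }
  trait_names <- names(trait_item_blocks())
  for (eff in planted_qt_effects) {
    stopifnot(eff$snp_index >= 1L, eff$snp_index <= n_snps,
              eff$trait %in% trait_names)
  }
  structure(list(n_cases_per_subtype = as.integer(n_cases_per_subtype),
                 n_controls = as.integer(n_controls),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 archetypes = archetypes,
                 severity_noise_sd = severity_noise_sd,
                 item_missing_rate = item_missing_rate,
                 planted_cc_effects = planted_cc_effects,
                 planted_qt_effects = planted_qt_effects,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Shift an allele frequency by an odds ratio
#'
#' `m' = (OR * m / (1 - m)) / (1 + OR * m / (1 - m))`: the allele frequency
#' whose odds are `OR` times the odds of `m`. Planting effects on allele
#' frequency (rather than penetrance) makes the allelic-test odds ratio of
#' the simulated data directly interpretable.
#'
#' @param m baseline allele frequency in (0, 1).
#' @param or odds ratio (> 0).
#' @return Shifted frequency.
#' @export
shift_maf <- function(m, or) {
  odds <- or * m / (1 - m)
  odds / (1 + odds)
}

#' Simulate case-control genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP gets a control minor-allele frequency `m ~ Uniform(maf_range)`;
#' control genotypes are drawn genotype-wise from Hardy-Weinberg proportions
#' at `m` (binomial with two draws). Cases draw from the same frequencies
#' except at planted case-control SNPs, where cases in the targeted subtypes
#' draw the tracked allele at the odds-ratio-shifted frequency
#' [shift_maf()]`(m, or)` and remain in HWE at that frequency. Deterministic
#' given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List with `dataset` (a [genotype_dataset()]; cases first, then
#'   controls; calls count copies of the tracked allele `allele_b`) and
#'   `truth`: ground-truth record with `subtype` (named integer vector per
#'   case), `control_maf` (named per SNP), and the planted effect lists.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_case <- sum(config$n_cases_per_subtype)
  n_ctl <- config$n_controls
  n_snp <- config$n_snps
  subtype <- rep(1:4, times = config$n_cases_per_subtype)

  sim <- with_seed(config$seed, {
    m <- stats::runif(n_snp, config$maf_range[1L], config$maf_range[2L])
    alleles <- t(replicate(n_snp, sample(c("A", "C", "G", "T"), 2L)))
    # per-case frequency matrix: baseline m, shifted where planted
    case_freq <- matrix(m, n_case, n_snp, byrow = TRUE)
    for (eff in config$planted_cc_effects) {
      j <- eff$snp_index
      rows <- subtype %in% eff$subtypes
      case_freq[rows, j] <- shift_maf(m[j], eff$or)
    }
    case_calls <- matrix(stats::rbinom(n_case * n_snp, 2L, case_freq),
                         n_case, n_snp)
    ctl_calls <- matrix(stats::rbinom(n_ctl * n_snp, 2L,
                                      rep(m, each = n_ctl)),
                        n_ctl, n_snp)
    list(m = m, alleles = alleles, calls = rbind(case_calls, ctl_calls))
  })

  ids <- c(sprintf("case%04d", seq_len(n_case)),
           sprintf("ctrl%04d", seq_len(n_ctl)))
  samples <- data.frame(
    family_id = ids, individual_id = ids,
    status = rep(c("case", "control"), c(n_case, n_ctl)),
    stringsAsFactors = FALSE
  )
  snp_ids <- sprintf("snp%05d", seq_len(n_snp))
  variants <- data.frame(
    chrom = as.character(1L + (seq_len(n_snp) - 1L) %% 22L),
    snp_id = snp_ids,
    bp = 1000L * seq_len(n_snp),
    allele_a = sim$alleles[, 1L], allele_b = sim$alleles[, 2L],
    stringsAsFactors = FALSE
  )
  dataset <- genotype_dataset(samples, variants, sim$calls)
  truth <- list(
    subtype = stats::setNames(subtype, ids[seq_len(n_case)]),
    control_maf = stats::setNames(sim$m, snp_ids),
    cc_effects = config$planted_cc_effects,
    qt_effects = config$planted_qt_effects
  )
  list(dataset = dataset, truth = truth)
}

#' Simulate raw item scores around subtype archetypes
#'
#' Each case's score for each item is
#' `clamp(round(archetype[subtype, item] + Normal(0, severity_noise_sd)),
#' 0, 3)`; with probability `item_missing_rate` the recorded raw code is
#' instead a special non-severity code (8 or 9, equiprobable), emulating
#' not-applicable / not-asked entries. Deterministic given `config$seed`
#' (a stream distinct from the genotype stream is derived from it).
#'
#' @param config a [sim_config()].
#' @param subtype_labels named integer vector (case id -> subtype in 1..4),
#'   as in the `truth` element of [simulate_genotypes()].
#' @return Integer matrix of raw codes (cases x items): severities 0-3 with
#'   8/9 special codes; recode with [recode_items()] before analysis.
#' @export
simulate_item_scores <- function(config, subtype_labels) {
  stopifnot(inherits(config, "sim_config"), all(subtype_labels %in% 1:4))
  arch <- config$archetypes
  n <- length(subtype_labels); p <- ncol(arch)
  with_seed(config$seed + 1L, {
    mu <- arch[subtype_labels, , drop = FALSE]
    noise <- matrix(stats::rnorm(n * p, 0, config$severity_noise_sd), n, p)
    score <- pmin(pmax(round(mu + noise), 0), 3)
    if (config$item_missing_rate > 0) {
      miss <- matrix(stats::runif(n * p) < config$item_missing_rate, n, p)
      special <- matrix(sample(c(8, 9), n * p, replace = TRUE), n, p)
      score[miss] <- special[miss]
    }
    storage.mode(score) <- "integer"
    dimnames(score) <- list(names(subtype_labels), colnames(arch))
    score
  })
}

#' Plant additive quantitative-trait effects into a trait table
#'
#' Adds `beta * (copies of the tracked allele)` to the named trait for each
#' planted effect, leaving other traits untouched; cases with a missing
#' genotype at the planted SNP are left unchanged. Makes the
#' quantitative-trait screen testable with known effect sizes.
#'
#' @param dataset a [genotype_dataset()].
#' @param trait_table data.frame from [trait_sums()] (column
#'   `individual_id` + one column per trait).
#' @param effects list of effects as in [sim_config()]'s
#'   `planted_qt_effects` (elements `snp_index` or `snp_id`, `trait`,
#'   `beta`).
#' @return The modified trait table (trait columns become numeric).
#' @export
plant_qt_effect <- function(dataset, trait_table, effects) {
  idx <- match(trait_table$individual_id, dataset$samples$individual_id)
  if (anyNA(idx)) stop("trait table contains ids absent from the dataset")
  for (eff in effects) {
    j <- if (!is.null(eff$snp_id)) match(eff$snp_id, dataset$variants$snp_id)
         else eff$snp_index
    if (is.na(j) || is.null(j)) stop("planted effect names an unknown SNP")
    if (!eff$trait %in% names(trait_table))
      stop("planted effect names unknown trait '", eff$trait, "'")
    g <- dataset$calls[idx, j]
    shift <- eff$beta * ifelse(is.na(g), 0, g)
    trait_table[[eff$trait]] <- trait_table[[eff$trait]] + shift
  }
  trait_table
}
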