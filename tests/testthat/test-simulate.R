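test_that("the generator is deterministic in the seed and sensitive to it", {
  cfg <- function(s) sim_config(n_cases_per_subtype = c(5L, 5L, 5L, 5L),
                                n_controls = 10L, n_snps = 20L, seed = s)
  a <- simulate_genotypes(cfg(7L))
  b <- simulate_genotypes(cfg(7L))
  c <- simulate_genotypes(cfg(8L))
  expect_identical(a, b)
  expect_false(identical(a$dataset$calls, c$dataset$calls))
  ia <- simulate_item_scores(cfg(7L), a$truth$subtype)
  ib <- simulate_item_scores(cfg(7L), a$truth$subtype)
  expect_identical(ia, ib)
})

test_that("planted odds ratios shift the case allele frequency as derived", {
  # odds-ratio shift of m = 0.20 by OR = 2 gives m' = 1/3 in closed form
  expect_equal(shift_maf(0.20, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(shift_maf(0.30, 1), 0.30)

  cfg <- sim_config(n_cases_per_subtype = c(500L, 500L, 500L, 500L),
                    n_controls = 100L, n_snps = 2L, maf_range = c(0.2, 0.2),
                    planted_cc_effects = list(list(snp_index = 1L,
                                                   subtypes = 1:4, or = 2.0)),
                    seed = 31L)
  sim <- simulate_genotypes(cfg)
  ca <- case_indices(sim$dataset)
  m_hat <- mean(sim$dataset$calls[ca, 1]) / 2
  se <- sqrt((1 / 3) * (2 / 3) / (2 * 2000))
  expect_lt(abs(m_hat - 1 / 3), 3 * se)
  # unplanted SNP stays at the control frequency
  m0 <- mean(sim$dataset$calls[ca, 2]) / 2
  expect_lt(abs(m0 - 0.2), 3 * sqrt(0.2 * 0.8 / (2 * 2000)))
})

test_that("control genotypes follow Hardy-Weinberg proportions", {
  m <- 0.3
  cfg <- sim_config(n_cases_per_subtype = c(1L, 1L, 1L, 1L),
                    n_controls = 10000L, n_snps = 1L,
                    maf_range = c(m, m), seed = 13L)
  sim <- simulate_genotypes(cfg)
  g <- sim$dataset$calls[control_indices(sim$dataset), 1]
  n <- length(g)
  expd <- c((1 - m)^2, 2 * m * (1 - m), m^2)
  for (k in 0:2) {
    p <- expd[k + 1]
    expect_lt(abs(mean(g == k) - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("item scores reproduce the archetypes when noise-free", {
  cfg <- sim_config(n_cases_per_subtype = c(2L, 2L, 2L, 2L), n_controls = 1L,
                    n_snps = 1L, severity_noise_sd = 0,
                    item_missing_rate = 0, seed = 5L)
  labels <- stats::setNames(rep(1:4, each = 2L), sprintf("c%d", 1:8))
  items <- simulate_item_scores(cfg, labels)
  expected <- round(cfg$archetypes[labels, ])
  dimnames(expected) <- dimnames(items)
  expect_equal(items, expected, ignore_attr = FALSE)
})

test_that("special-code rate matches the configured missingness", {
  rate <- 0.1
  cfg <- sim_config(n_cases_per_subtype = c(25L, 25L, 25L, 25L),
                    n_controls = 1L, n_snps = 1L,
                    item_missing_rate = rate, seed = 21L)
  labels <- stats::setNames(rep(1:4, each = 25L), sprintf("c%03d", 1:100))
  items <- simulate_item_scores(cfg, labels)
  frac <- mean(items %in% c(8L, 9L))
  n <- length(items)
  expect_lt(abs(frac - rate), 3 * sqrt(rate * (1 - rate) / n))
  # recoding turns exactly those codes into missing severities
  sc <- recode_items(items)
  expect_equal(sum(is.na(sc)), sum(items %in% c(8L, 9L)))
})

test_that("planted quantitative-trait effects are recoverable by regression", {
  cfg <- sim_config(n_cases_per_subtype = c(250L, 250L, 250L, 250L),
                    n_controls = 10L, n_snps = 3L, maf_range = c(0.3, 0.3),
                    archetypes = default_archetypes()[rep(2, 4), , drop = FALSE],
                    item_missing_rate = 0, seed = 17L)
  sim <- simulate_genotypes(cfg)
  items <- simulate_item_scores(cfg, sim$truth$subtype)
  tt0 <- trait_sums(recode_items(items), default_trait_definitions())

  # beta = 0 leaves the table untouched
  same <- plant_qt_effect(sim$dataset, tt0,
                          list(list(snp_index = 1L, trait = "language", beta = 0)))
  expect_equal(same$language, as.numeric(tt0$language))

  eff <- list(list(snp_index = 1L, trait = "language", beta = 2))
  tt <- plant_qt_effect(sim$dataset, tt0, eff)
  # untargeted traits unchanged
  expect_identical(tt$social, tt0$social)
  idx <- match(tt$individual_id, sim$dataset$samples$individual_id)
  fit <- qt_linear_assoc(sim$dataset$calls[idx, 1], tt$language)
  expect_lt(abs(fit$beta - 2), 3 * fit$se)
})

test_that("null SNPs keep the allelic test calibrated at the 5% level", {
  cfg <- sim_config(n_cases_per_subtype = c(125L, 125L, 125L, 125L),
                    n_controls = 500L, n_snps = 5000L,
                    maf_range = c(0.3, 0.3), seed = 11L)
  sim <- simulate_genotypes(cfg)
  tab <- cc_assoc_table(sim$dataset, case_indices(sim$dataset),
                        control_indices(sim$dataset))
  rate <- mean(tab$p_unadj < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})
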