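test_that("minor allele determination handles ties, missingness and errors", {
  # calls = copies of allele_b (G); 4/8 G alleles -> exact tie, lexicographic
  ds <- make_dataset(matrix(c(0L, 1L, 1L, 2L), 4, 1),
                     status = c("case", "case", "control", "control"))
  res <- minor_allele_and_counts(ds, 1:2, 3:4, "rs1")
  expect_equal(res$a1, "A")  # tie at 0.5 broken lexicographically
  expect_equal(res$counts[["case_minor"]], 3L)   # A copies among cases
  expect_equal(res$counts[["case_minor"]] + res$counts[["case_major"]], 4L)

  ds2 <- make_dataset(matrix(NA_integer_, 4, 1))
  expect_error(minor_allele_and_counts(ds2, 1:2, 3:4, "rs1"), "missing")
  expect_error(minor_allele_and_counts(ds, 1:3, 4:5, "nope"), "not found")
})

test_that("allele counts agree with a brute-force tally", {
  set.seed(12)
  calls <- matrix(sample(c(0:2, NA), 20, replace = TRUE,
                         prob = c(0.3, 0.3, 0.3, 0.1)), 20, 1)
  status <- rep(c("case", "control"), each = 10)
  ds <- make_dataset(calls, status = status)
  res <- minor_allele_and_counts(ds, 1:10, 11:20, 1L)
  # tally alleles individual by individual
  tally <- function(rows) {
    g <- calls[rows, 1]; g <- g[!is.na(g)]
    c(G = sum(g), A = 2 * length(g) - sum(g))
  }
  ta <- tally(1:10); tu <- tally(11:20)
  minor <- if ((ta[["G"]] + tu[["G"]]) <= (ta[["A"]] + tu[["A"]])) "G" else "A"
  expect_equal(res$counts[["case_minor"]], unname(ta[minor]))
  expect_equal(res$counts[["control_minor"]], unname(tu[minor]))
  expect_equal(sum(res$counts), 2L * (sum(!is.na(calls))))
})

test_that("parsed call categories always partition the samples", {
  cfg <- sim_config(n_cases_per_subtype = c(5L, 5L, 5L, 5L), n_controls = 20L,
                    n_snps = 30L, seed = 3L)
  ds <- simulate_genotypes(cfg)$dataset
  ds$calls[sample(length(ds$calls), 50)] <- NA
  for (j in seq_len(ncol(ds$calls))) {
    g <- ds$calls[, j]
    expect_equal(sum(g == 0, na.rm = TRUE) + sum(g == 1, na.rm = TRUE) +
                   sum(g == 2, na.rm = TRUE) + sum(is.na(g)),
                 nrow(ds$samples))
  }
})

test_that("the allelic chi-square matches its textbook form and edge cases", {
  # proportional counts: no association
  null <- allelic_chisq(c(case_minor = 30, case_major = 70,
                          control_minor = 60, control_major = 140))
  expect_equal(null$chisq, 0)
  expect_equal(null$or_a1, 1)
  expect_equal(null$p_unadj, 1)

  # brute-force sum over the four cells of (O - E)^2 / E
  brute <- function(a, b, c_, d) {
    obs <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    sum((obs - expd)^2 / expd)
  }
  expect_equal(allelic_chisq(c(case_minor = 10, case_major = 10,
                               control_minor = 10, control_major = 10))$chisq,
               brute(10, 10, 10, 10), tolerance = 1e-10)
  set.seed(4)
  for (rep in 1:20) {
    cnt <- sample(5:200, 4)
    names(cnt) <- c("case_minor", "case_major", "control_minor", "control_major")
    got <- allelic_chisq(cnt)
    expect_equal(got$chisq, brute(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-10)
    # independent route: base chisq.test without continuity correction
    ct <- suppressWarnings(stats::chisq.test(matrix(cnt, 2, byrow = TRUE),
                                             correct = FALSE))
    expect_equal(got$chisq, unname(ct$statistic), tolerance = 1e-10)
    expect_equal(got$p_unadj, ct$p.value, tolerance = 1e-10)
  }

  # zero cell: OR undefined unless the Haldane-Anscombe correction is on
  z <- c(case_minor = 0, case_major = 20, control_minor = 5, control_major = 15)
  expect_true(is.na(allelic_chisq(z)$or_a1))
  expect_equal(allelic_chisq(z, haldane = TRUE)$or_a1,
               (0.5 * 15.5) / (20.5 * 5.5))
  expect_error(allelic_chisq(c(case_minor = 0, case_major = 0,
                               control_minor = 5, control_major = 5)),
               "margin")
})

test_that("swapping the allele orientation inverts the OR and fixes the test", {
  set.seed(9)
  for (rep in 1:20) {
    cnt <- sample(5:100, 4)
    names(cnt) <- c("case_minor", "case_major", "control_minor", "control_major")
    swapped <- cnt[c(2, 1, 4, 3)]
    names(swapped) <- names(cnt)
    a <- allelic_chisq(cnt); b <- allelic_chisq(swapped)
    expect_equal(a$chisq, b$chisq, tolerance = 1e-12)
    expect_equal(a$p_unadj, b$p_unadj, tolerance = 1e-12)
    expect_equal(a$or_a1, 1 / b$or_a1, tolerance = 1e-12)
  }
})

test_that("chi-square p-values reproduce published table entries", {
  expect_equal(chisq_p(0, 1), 1)
  expect_equal(round(chisq_p(13.71, 1), 4), 0.0002)
  expect_equal(round(chisq_p(7.61, 1), 4), 0.0058)
  x <- seq(0, 30, by = 0.5)
  expect_true(all(diff(chisq_p(x, 1)) < 0))
})

test_that("worked-example counts reproduce the published OR and chi-square", {
  # Moderate-subtype promoter SNP: 363 cases (F_A 0.256), 2438 controls
  # (F_U 0.326) -> allele counts on 726 / 4876 alleles
  cnt <- c(case_minor = 186, case_major = 540,
           control_minor = 1590, control_major = 3286)
  res <- allelic_chisq(cnt)
  expect_lt(abs(res$or_a1 - 0.71), 0.01)
  expect_lt(abs(res$chisq - 14.2) / 14.2, 0.05)
  expect_equal(round(res$f_a, 3), 0.256)
  expect_equal(round(res$f_u, 3), 0.326)
})

test_that("printed ORs are consistent with the printed 3-dp frequencies", {
  # every published row: the 2-dp OR must be attainable from frequencies
  # within half a rounding unit of the printed 3-dp MAFs
  odds <- function(f) f / (1 - f)
  for (tab in list(example_assoc_table("final"),
                   example_assoc_table("chr5p14"))) {
    lo <- odds(pmax(tab$F_A - 5e-4, 1e-6)) / odds(tab$F_U + 5e-4)
    hi <- odds(tab$F_A + 5e-4) / odds(pmax(tab$F_U - 5e-4, 1e-6))
    expect_true(all(tab$OR + 5e-3 >= lo - 1e-9 & tab$OR - 5e-3 <= hi + 1e-9))
    # and the point estimate is close throughout
    point <- odds(tab$F_A) / odds(tab$F_U)
    expect_lt(max(abs(point - tab$OR)), 0.015)
  }
})

test_that("quantitative-trait regression matches lm and handles edge cases", {
  cons <- qt_linear_assoc(c(0, 1, 2, 1, 0), rep(4, 5))
  expect_equal(cons$beta, 0)
  expect_equal(cons$p_unadj, 1)

  exact <- qt_linear_assoc(c(0, 1, 2), c(1, 3, 5))
  expect_equal(exact$beta, 2)
  expect_equal(exact$se, 0)  # zero residual: exact fit

  mono <- qt_linear_assoc(rep(1, 10), rnorm(10))
  expect_false(mono$testable)

  set.seed(5)
  g <- sample(0:2, 80, replace = TRUE)
  y <- 1.5 * g + rnorm(80)
  y[c(3, 9)] <- NA; g[15] <- NA
  fit <- qt_linear_assoc(g, y)
  ref <- summary(stats::lm(y ~ g))$coefficients["g", ]
  expect_equal(fit$beta, unname(ref["Estimate"]), tolerance = 1e-12)
  expect_equal(fit$se, unname(ref["Std. Error"]), tolerance = 1e-12)
  expect_equal(fit$p_unadj, unname(ref["Pr(>|t|)"]), tolerance = 1e-12)
})

test_that("the t-based p agrees with a permutation null at moderate n", {
  set.seed(19)
  n <- 50
  g <- rbinom(n, 2, 0.3)
  y <- 0.3 * g + rnorm(n)
  fit <- qt_linear_assoc(g, y)
  perm <- replicate(10000, abs(qt_linear_assoc(g, sample(y))$stat))
  p_perm <- mean(perm >= abs(fit$stat))
  expect_lt(abs(fit$p_unadj - p_perm) / fit$p_unadj, 0.10)
})

test_that("planted regression slopes are recovered across repeated draws", {
  set.seed(23)
  betas <- ses <- numeric(200)
  for (i in 1:200) {
    g <- rbinom(300, 2, 0.3)
    y <- 2 * g + rnorm(300, sd = 2)
    fit <- qt_linear_assoc(g, y)
    betas[i] <- fit$beta; ses[i] <- fit$se
  }
  se_mean <- sqrt(mean(ses^2) / 200)
  expect_lt(abs(mean(betas) - 2), 3 * se_mean)
})

test_that("the HWE test matches its expected-count formula", {
  expect_equal(hwe_test(25, 50, 25), 1)
  expect_lt(hwe_test(50, 0, 50), 1e-20)
  n <- 100; q <- (2 * 48 + 40) / 200
  expd <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chisq <- sum((c(12, 40, 48) - expd)^2 / expd)
  expect_equal(hwe_test(12, 40, 48), chisq_p(chisq, 1), tolerance = 1e-10)
  expect_equal(hwe_test(10, 0, 0), 1)  # monomorphic
})

test_that("QC removes variants by missingness, frequency and HWE", {
  set.seed(6)
  n <- 100
  good <- rbinom(n, 2, 0.3)
  sparse <- good; sparse[1:11] <- NA            # 11% missing
  rare <- c(rep(1L, 1), rep(0L, n - 1))         # MAF 0.005
  dis <- rep(c(0L, 2L), n / 2)                  # no hets at q = 0.5
  ds <- make_dataset(cbind(good, sparse, rare, dis),
                     status = rep(c("case", "control"), each = n / 2))
  res <- qc_filter(ds)
  expect_equal(res$dataset$variants$snp_id, "rs1")
  ex <- res$exclusions
  expect_equal(ex$reasons[ex$snp_id == "rs2"], "missingness")
  expect_equal(ex$reasons[ex$snp_id == "rs3"], "maf")
  expect_match(ex$reasons[ex$snp_id == "rs4"], "hwe")
})

test_that("the HWE filter excludes about its nominal share of null SNPs", {
  cfg <- sim_config(n_cases_per_subtype = c(5L, 5L, 5L, 5L), n_controls = 800L,
                    n_snps = 1000L, maf_range = c(0.2, 0.5), seed = 27L)
  ds <- simulate_genotypes(cfg)$dataset
  res <- qc_filter(ds, max_missing = 0.5, min_maf = 1e-6, hwe_alpha = 0.001)
  n_hwe <- sum(grepl("hwe", res$exclusions$reasons))
  # binomial(1000, 0.001): within 3 SE of 1
  expect_lte(n_hwe, 1 + 3 * sqrt(1000 * 0.001 * 0.999))
})
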