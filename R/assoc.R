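#' Minor allele and 2x2 allele counts at one variant
#'
#' Determines the minor allele over the pooled (cases + controls) non-missing
#' calls and tallies allele counts by group. Individuals with a missing call
#' at this variant are excluded (per-SNP complete case). The minor allele is
#' the allele with the lower pooled frequency; an exact tie is broken
#' lexicographically on the allele label.
#'
#' @param dataset a [genotype_dataset()].
#' @param case_idx,control_idx sample row indices of the two groups.
#' @param variant snp_id or column index of the variant.
#' @return List with `a1` (minor allele), `a2` (major allele), and `counts`:
#'   named integer vector `case_minor`, `case_major`, `control_minor`,
#'   `control_major` (allele counts, two per genotyped individual).
#' @export
minor_allele_and_counts <- function(dataset, case_idx, control_idx, variant) {
  j <- if (is.character(variant)) match(variant, dataset$variants$snp_id) else variant
  if (is.na(j) || j < 1L || j > nrow(dataset$variants))
    stop("variant not found: ", variant)
  v <- dataset$variants[j, ]
  ca <- dataset$calls[case_idx, j]
  co <- dataset$calls[control_idx, j]
  ca <- ca[!is.na(ca)]
  co <- co[!is.na(co)]
  n_tot <- length(ca) + length(co)
  if (n_tot == 0L) stop("all calls missing at ", v$snp_id)
  # calls count copies of allele_b
  b_count <- sum(ca) + sum(co)
  b_freq <- b_count / (2 * n_tot)
  minor_is_b <- if (b_freq != 0.5) b_freq < 0.5 else v$allele_b < v$allele_a
  if (minor_is_b) {
    a1 <- v$allele_b; a2 <- v$allele_a
    case_minor <- sum(ca); control_minor <- sum(co)
  } else {
    a1 <- v$allele_a; a2 <- v$allele_b
    case_minor <- 2L * length(ca) - sum(ca)
    control_minor <- 2L * length(co) - sum(co)
  }
  list(
    a1 = a1, a2 = a2,
    counts = c(case_minor = as.integer(case_minor),
               case_major = as.integer(2L * length(ca) - case_minor),
               control_minor = as.integer(control_minor),
               control_major = as.integer(2L * length(co) - control_minor)),
    n_case_used = length(ca), n_control_used = length(co)
  )
}

#' Allelic chi-square test on a 2x2 allele-count table
#'
#' One-degree-of-freedom Pearson chi-square on the minor/major x case/control
#' allele-count table, without continuity correction, plus the minor-allele
#' odds ratio `OR = (case_minor * control_major) / (case_major *
#' control_minor)`: the odds of carrying the minor allele in cases over the
#' same odds in controls.
#'
#' @param counts named numeric vector with elements `case_minor`,
#'   `case_major`, `control_minor`, `control_major`.
#' @param haldane if `TRUE`, add 0.5 to every cell for the odds ratio when
#'   any cell is zero (Haldane-Anscombe); otherwise a zero cell gives
#'   `or_a1 = NA`.
#' @return List with `chisq`, `p_unadj`, `or_a1`, `f_a` (case minor-allele
#'   frequency), `f_u` (control minor-allele frequency).
#' @export
allelic_chisq <- function(counts, haldane = FALSE) {
  a <- as.numeric(counts[["case_minor"]])
  b <- as.numeric(counts[["case_major"]])
  c_ <- as.numeric(counts[["control_minor"]])
  d <- as.numeric(counts[["control_major"]])
  if (any(c(a, b, c_, d) < 0)) stop("allele counts must be nonnegative")
  n <- a + b + c_ + d
  if (a + b == 0 || c_ + d == 0) stop("empty case or control margin")
  if (a + c_ == 0 || b + d == 0) stop("degenerate allele margin: statistic undefined")
  chisq <- n * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  or <- if (b > 0 && c_ > 0 && a > 0 && d > 0) {
    (a * d) / (b * c_)
  } else if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    NA_real_
  }
  list(chisq = chisq, p_unadj = chisq_p(chisq, 1L), or_a1 = or,
       f_a = a / (a + b), f_u = c_ / (c_ + d))
}

#' Upper-tail chi-square p-value
#'
#' @param chisq nonnegative chi-square statistic(s).
#' @param df degrees of freedom.
#' @return Upper-tail probability, monotone decreasing in `chisq`.
#' @export
chisq_p <- function(chisq, df = 1L) {
  if (any(chisq < 0)) stop("chisq must be nonnegative")
  stats::pchisq(chisq, df = df, lower.tail = FALSE)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom Pearson chi-square comparing observed genotype
#' counts to the Hardy-Weinberg expectations `n*(1-q)^2, 2*n*q*(1-q), n*q^2`
#' at the sample allele frequency `q`. Used as a genotype quality filter;
#' monomorphic samples return p = 1.
#'
#' @param hom_a,het,hom_b observed genotype counts.
#' @return p-value.
#' @export
hwe_test <- function(hom_a, het, hom_b) {
  n <- hom_a + het + hom_b
  if (n <= 0) stop("no genotyped individuals")
  q <- (2 * hom_b + het) / (2 * n)
  if (q == 0 || q == 1) return(1)
  expd <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  obs <- c(hom_a, het, hom_b)
  chisq <- sum((obs - expd)^2 / expd)
  chisq_p(chisq, 1L)
}

#' Per-SNP quantitative-trait linear regression
#'
#' Ordinary least squares of a quantitative trait on the additive genotype
#' code (0/1/2 copies of the a1 allele). Pairs with a missing genotype or
#' trait are dropped. The two-sided p-value uses the t distribution with
#' `n - 2` degrees of freedom.
#'
#' @param genotypes numeric vector of 0/1/2 codes (NA = missing).
#' @param trait numeric trait values aligned to `genotypes`.
#' @return List with `beta`, `se`, `stat`, `p_unadj`, `n_used`, and
#'   `testable` (`FALSE` for monomorphic genotypes or n < 3, in which case
#'   the statistics are `NA`).
#' @export
qt_linear_assoc <- function(genotypes, trait) {
  ok <- !is.na(genotypes) & !is.na(trait)
  g <- genotypes[ok]; y <- trait[ok]
  n <- length(g)
  out <- list(beta = NA_real_, se = NA_real_, stat = NA_real_,
              p_unadj = NA_real_, n_used = n, testable = FALSE)
  if (n < 3L) return(out)
  sxx <- sum((g - mean(g))^2)
  if (sxx == 0) return(out)
  sxy <- sum((g - mean(g)) * (y - mean(y)))
  beta <- sxy / sxx
  resid <- y - mean(y) - beta * (g - mean(g))
  rss <- sum(resid^2)
  sigma2 <- rss / (n - 2L)
  if (sigma2 == 0) {
    # exact fit (or constant trait with beta 0): p from the limit
    se <- 0
    stat <- if (beta == 0) 0 else Inf
    p <- if (beta == 0) 1 else 0
  } else {
    se <- sqrt(sigma2 / sxx)
    stat <- beta / se
    p <- 2 * stats::pt(abs(stat), df = n - 2L, lower.tail = FALSE)
  }
  list(beta = beta, se = se, stat = stat, p_unadj = p, n_used = n,
       testable = TRUE)
}

#' Quality-control filter for variants
#'
#' Removes variants failing any of the standard pre-association cleaning
#' rules: call missingness above `max_missing` (over all samples),
#' minor-allele frequency below `min_maf` (pooled non-missing calls), or
#' Hardy-Weinberg equilibrium p-value below `hwe_alpha` evaluated in
#' controls only.
#'
#' @param dataset a [genotype_dataset()].
#' @param max_missing maximum tolerated fraction of missing calls (default
#'   0.10).
#' @param min_maf minimum minor-allele frequency (default 0.01).
#' @param hwe_alpha HWE p-value threshold (default 0.001).
#' @return List with `dataset` (filtered) and `exclusions`: data.frame of
#'   `snp_id` and comma-separated `reasons` for each removed variant.
#' @export
qc_filter <- function(dataset, max_missing = 0.10, min_maf = 0.01,
                      hwe_alpha = 0.001) {
  stopifnot(max_missing > 0, max_missing < 1, min_maf > 0, min_maf < 1,
            hwe_alpha > 0, hwe_alpha < 1)
  calls <- dataset$calls
  n_var <- ncol(calls)
  ctl <- control_indices(dataset)
  miss_frac <- colMeans(is.na(calls))
  maf <- vapply(seq_len(n_var), function(j) {
    cj <- calls[, j]; cj <- cj[!is.na(cj)]
    if (length(cj) == 0L) return(0)
    f <- sum(cj) / (2 * length(cj))
    min(f, 1 - f)
  }, numeric(1L))
  hwe_p <- vapply(seq_len(n_var), function(j) {
    cj <- calls[ctl, j]; cj <- cj[!is.na(cj)]
    if (length(cj) == 0L) return(1)
    hwe_test(sum(cj == 0L), sum(cj == 1L), sum(cj == 2L))
  }, numeric(1L))

  fail_miss <- miss_frac > max_missing
  fail_maf <- maf < min_maf
  fail_hwe <- hwe_p < hwe_alpha
  failed <- fail_miss | fail_maf | fail_hwe
  reasons <- vapply(seq_len(n_var), function(j) {
    paste(c("missingness", "maf", "hwe")[c(fail_miss[j], fail_maf[j], fail_hwe[j])],
          collapse = ",")
  }, character(1L))

  keep <- which(!failed)
  out <- genotype_dataset(dataset$samples,
                          dataset$variants[keep, , drop = FALSE],
                          calls[, keep, drop = FALSE])
  list(dataset = out,
       exclusions = data.frame(snp_id = dataset$variants$snp_id[failed],
                               reasons = reasons[failed],
                               stringsAsFactors = FALSE))
}

#' Case-control allelic association over a set of variants
#'
#' Runs [minor_allele_and_counts()] + [allelic_chisq()] for each requested
#' variant and returns one row per variant in the conventional association
#' table layout (unadjusted; see [adjust_assoc()] for the multiple-testing
#' columns).
#'
#' @param dataset a [genotype_dataset()].
#' @param case_idx,control_idx sample row indices of the two groups.
#' @param snp_ids variants to test (default: all).
#' @param haldane passed to [allelic_chisq()].
#' @return data.frame with columns `chrom`, `snp_id`, `bp`, `a1`, `a2`,
#'   `f_a`, `f_u`, `chisq`, `or_a1`, `p_unadj`, `n_case_used`,
#'   `n_control_used`.
#' @export
cc_assoc_table <- function(dataset, case_idx, control_idx,
                           snp_ids = dataset$variants$snp_id, haldane = FALSE) {
  jj <- match(snp_ids, dataset$variants$snp_id)
  if (anyNA(jj)) stop("unknown snp_id: ", paste(snp_ids[is.na(jj)], collapse = ", "))
  rows <- lapply(jj, function(j) {
    mac <- minor_allele_and_counts(dataset, case_idx, control_idx, j)
    st <- allelic_chisq(mac$counts, haldane = haldane)
    v <- dataset$variants[j, ]
    data.frame(chrom = v$chrom, snp_id = v$snp_id, bp = v$bp,
               a1 = mac$a1, a2 = mac$a2, f_a = st$f_a, f_u = st$f_u,
               chisq = st$chisq, or_a1 = st$or_a1, p_unadj = st$p_unadj,
               n_case_used = mac$n_case_used,
               n_control_used = mac$n_control_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
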