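#' Bonferroni adjustment with an explicit test count
#'
#' `min(1, p * m_tests)` per p-value. `m_tests` is the size of the full set
#' of tests in the run, which may exceed the number of p-values supplied
#' (unsupplied tests are assumed nonsignificant); supplying it explicitly is
#' deliberate, because the adjusted columns of an association table are only
#' reproducible when the denominator is the tested-set size rather than the
#' reported-row count.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param m_tests total number of tests; must be >= `length(p)`.
#' @return Adjusted p-values in the input order.
#' @export
bonferroni <- function(p, m_tests = length(p)) {
  check_pvals(p, m_tests)
  pmin(1, p * m_tests)
}

#' Benjamini-Hochberg step-up adjustment with an explicit test count
#'
#' Step-up adjusted p-values: with p-values sorted ascending,
#' `adj(i) = min_{j >= i} (p_(j) * m_tests / j)`, capped at 1 and mapped back
#' to the input order. Computed via [stats::p.adjust()] with `n = m_tests`.
#' As with [bonferroni()], `m_tests` may exceed the number of supplied
#' p-values.
#'
#' @inheritParams bonferroni
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p, m_tests = length(p)) {
  check_pvals(p, m_tests)
  stats::p.adjust(p, method = "BH", n = m_tests)
}

check_pvals <- function(p, m_tests) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  if (m_tests < length(p))
    stop("m_tests (", m_tests, ") must be >= number of p-values (", length(p), ")")
  invisible(TRUE)
}

#' Append multiple-testing columns to an association table
#'
#' Adds `p_fdr_bh`, `p_bonf` and `m_tests` columns to a table of unadjusted
#' association rows, adjusting over the `m_tests` tests of the run the rows
#' came from.
#'
#' @param rows data.frame with a `p_unadj` column (as from
#'   [cc_assoc_table()]).
#' @param m_tests total number of tests in the run; defaults to `nrow(rows)`.
#' @return `rows` with the three columns appended.
#' @export
adjust_assoc <- function(rows, m_tests = nrow(rows)) {
  rows$p_fdr_bh <- if (nrow(rows)) bh_adjust(rows$p_unadj, m_tests) else numeric(0)
  rows$p_bonf <- if (nrow(rows)) bonferroni(rows$p_unadj, m_tests) else numeric(0)
  rows$m_tests <- if (nrow(rows)) as.integer(m_tests) else integer(0)
  rows
}
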