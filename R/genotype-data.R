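#' Construct a genotype dataset
#'
#' Container for biallelic SNP genotypes of a case-control cohort. Calls are
#' stored as counts of `allele_b` copies (0, 1, 2, or `NA` for missing), one
#' row per sample and one column per variant. Which of the two alleles is
#' `allele_b` is a property of how the data were read or simulated; minor
#' allele orientation is decided at association time, not here.
#'
#' @param samples data.frame with columns `family_id`, `individual_id`,
#'   `status` (`"case"` or `"control"`); `(family_id, individual_id)` pairs
#'   must be unique.
#' @param variants data.frame with columns `chrom`, `snp_id`, `bp` (1-based
#'   position, >= 1), `allele_a`, `allele_b`; `snp_id` must be unique and
#'   `allele_a != allele_b` per variant.
#' @param calls integer matrix, `nrow(samples)` x `nrow(variants)`, values in
#'   \{0, 1, 2, NA\}, counting copies of `allele_b`.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `samples`, `variants`, `calls`.
#' @export
genotype_dataset <- function(samples, variants, calls) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req_s <- c("family_id", "individual_id", "status")
  req_v <- c("chrom", "snp_id", "bp", "allele_a", "allele_b")
  if (!all(req_s %in% names(samples)))
    stop("samples must have columns: ", paste(req_s, collapse = ", "))
  if (!all(req_v %in% names(variants)))
    stop("variants must have columns: ", paste(req_v, collapse = ", "))
  if (!all(samples$status %in% c("case", "control")))
    stop("sample status must be 'case' or 'control'")
  key <- paste(samples$family_id, samples$individual_id)
  if (anyDuplicated(key))
    stop("duplicated (family_id, individual_id) pairs")
  if (anyDuplicated(variants$snp_id))
    stop("duplicated snp_id: ",
         paste(unique(variants$snp_id[duplicated(variants$snp_id)]), collapse = ", "))
  if (any(variants$bp < 1)) stop("bp positions must be >= 1")
  if (any(variants$allele_a == variants$allele_b))
    stop("allele_a must differ from allele_b")
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(variants))
    stop("calls must be ", nrow(samples), " x ", nrow(variants),
         ", got ", nrow(calls), " x ", ncol(calls))
  if (!all(calls %in% c(0L, 1L, 2L, NA)))
    stop("non-missing calls must be 0, 1 or 2")
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(samples$individual_id, variants$snp_id)
  structure(list(samples = samples, variants = variants, calls = calls),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$samples), "samples (",
      sum(x$samples$status == "case"), "cases /",
      sum(x$samples$status == "control"), "controls ) x",
      nrow(x$variants), "variants\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing call rate: %.4f\n", miss))
  invisible(x)
}

#' Row indices of cases / controls in a genotype dataset
#'
#' @param dataset a `genotype_dataset`.
#' @return Integer vector of sample row indices.
#' @export
case_indices <- function(dataset) which(dataset$samples$status == "case")

#' @rdname case_indices
#' @export
control_indices <- function(dataset) which(dataset$samples$status == "control")
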