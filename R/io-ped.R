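#' Read PLINK PED/MAP text genotypes
#'
#' Parses whitespace-delimited PED (6 leading columns, then two allele tokens
#' per variant; `"0"` = missing allele) and MAP (chromosome, SNP id, genetic
#' distance, base-pair position) files into a [genotype_dataset()].
#'
#' Orientation convention: for each variant, `allele_a` is the first distinct
#' non-missing allele symbol observed in file order (scanning samples top to
#' bottom, left token before right) and `allele_b` is the second; calls count
#' copies of `allele_b`. A variant at which only one allele symbol is ever
#' observed gets `allele_a = "0"` as a placeholder. Minor-allele orientation
#' is resolved later, during association.
#'
#' PED column 6 encodes phenotype: `2` = case, `1` = control; samples with any
#' other code are dropped with a warning (PLINK convention for missing
#' phenotype).
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return A [genotype_dataset()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  if (length(map_lines) < 1L) stop("MAP file is empty: ", map_path)
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_fields)
  if (any(nf != 4L))
    stop("MAP parse error at line ", which(nf != 4L)[1L],
         ": expected 4 fields, found ", nf[nf != 4L][1L])
  mm <- do.call(rbind, map_fields)
  bp <- suppressWarnings(as.integer(mm[, 4L]))
  if (anyNA(bp))
    stop("MAP parse error at line ", which(is.na(bp))[1L],
         ": non-integer bp position")
  n_var <- length(map_lines)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_fields <- strsplit(trimws(ped_lines), "[ \t]+")
  expected <- 6L + 2L * n_var
  nf <- lengths(ped_fields)
  if (any(nf != expected))
    stop("PED parse error at line ", which(nf != expected)[1L],
         ": expected ", expected, " fields, found ", nf[nf != expected][1L])

  pm <- do.call(rbind, ped_fields)
  pheno <- pm[, 6L]
  keep <- pheno %in% c("1", "2")
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) dropped: phenotype code not 1/2 at PED line(s) ",
            paste(utils::head(which(!keep), 5L), collapse = ", "))
    pm <- pm[keep, , drop = FALSE]
  }
  if (nrow(pm) == 0L) stop("no samples with phenotype code 1 or 2 in ", ped_path)

  samples <- data.frame(
    family_id = pm[, 1L],
    individual_id = pm[, 2L],
    status = ifelse(pm[, 6L] == "2", "case", "control"),
    stringsAsFactors = FALSE
  )

  left  <- pm[, 6L + 2L * seq_len(n_var) - 1L, drop = FALSE]
  right <- pm[, 6L + 2L * seq_len(n_var), drop = FALSE]

  allele_a <- character(n_var)
  allele_b <- character(n_var)
  calls <- matrix(NA_integer_, nrow(pm), n_var)
  for (j in seq_len(n_var)) {
    # file-order scan: sample by sample, left token then right token
    seen <- as.vector(rbind(left[, j], right[, j]))
    syms <- unique(seen[seen != "0"])
    if (length(syms) > 2L)
      stop("variant ", mm[j, 2L], " has more than two alleles: ",
           paste(syms, collapse = "/"))
    a <- if (length(syms) >= 1L) syms[1L] else "0"
    b <- if (length(syms) == 2L) syms[2L] else a
    if (length(syms) < 2L) { b <- a; a <- "0" }  # monomorphic placeholder
    allele_a[j] <- a
    allele_b[j] <- b
    miss <- left[, j] == "0" | right[, j] == "0"
    cj <- (left[, j] == b) + (right[, j] == b)
    cj[miss] <- NA_integer_
    calls[, j] <- cj
  }

  variants <- data.frame(
    chrom = mm[, 1L], snp_id = mm[, 2L], bp = bp,
    allele_a = allele_a, allele_b = allele_b,
    stringsAsFactors = FALSE
  )
  genotype_dataset(samples, variants, calls)
}

#' Write PLINK PED/MAP text genotypes
#'
#' Inverse of [read_ped_map()]: heterozygotes are written as
#' `allele_a allele_b`, missing calls as `0 0`, and case/control status as
#' phenotype code 2/1. Re-reading a file pair written from a freshly parsed
#' dataset reproduces it exactly; for datasets constructed in other
#' orientations the genotypes are preserved up to the per-variant allele
#' relabelling that parsing canonicalises.
#'
#' @param dataset a [genotype_dataset()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, `NULL`.
#' @export
write_ped_map <- function(dataset, ped_path, map_path) {
  v <- dataset$variants
  s <- dataset$samples
  map_lines <- if (nrow(v) == 0L) character(0)
               else paste(v$chrom, v$snp_id, 0L, v$bp)
  writeLines(map_lines, map_path)

  n <- nrow(s)
  if (nrow(v) == 0L) {
    gt <- rep("", n)
  } else {
    gt_mat <- matrix("", n, nrow(v))
    for (j in seq_len(nrow(v))) {
      a <- v$allele_a[j]; b <- v$allele_b[j]
      cj <- dataset$calls[, j]
      tok <- c(paste(a, a), paste(a, b), paste(b, b))[cj + 1L]
      tok[is.na(cj)] <- "0 0"
      gt_mat[, j] <- tok
    }
    gt <- apply(gt_mat, 1L, paste, collapse = " ")
  }
  pheno <- ifelse(s$status == "case", 2L, 1L)
  lead <- paste(s$family_id, s$individual_id, 0L, 0L, 0L, pheno)
  writeLines(trimws(paste(lead, gt)), ped_path)
  invisible(NULL)
}
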