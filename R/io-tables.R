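#' Read an item-severity score table
#'
#' Reads a delimited text table of raw diagnostic-instrument item codes, one
#' row per individual (first column = individual id) and one column per item,
#' with a header line of item names. Codes are kept as read (no severity
#' recoding; see [recode_items()]); blank cells become `NA`.
#'
#' @param path path to a tab- or comma-delimited text file.
#' @param sep field separator (default tab).
#' @return Integer matrix with individual ids as rownames and item names as
#'   colnames.
#' @export
read_item_scores <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("item-score table needs an id column plus >= 1 item")
  ids <- df[[1L]]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  raw[!nzchar(trimws(raw))] <- NA_character_
  num <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(!is.na(raw) & (is.na(num) | num != round(num)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-integer item code '", raw[bad[1L, , drop = FALSE]],
         "' for individual ", ids[bad[1L, 1L]],
         ", item ", colnames(raw)[bad[1L, 2L]])
  out <- matrix(as.integer(num), nrow(raw), ncol(raw),
                dimnames = list(ids, colnames(raw)))
  out
}

#' Write an item-severity score table
#'
#' @param scores integer matrix as returned by [read_item_scores()] or
#'   [simulate_item_scores()]; `NA` entries are written as blank cells.
#' @param path output path.
#' @param sep field separator (default tab).
#' @param id_name header name for the id column.
#' @return Invisibly, `NULL`.
#' @export
write_item_scores <- function(scores, path, sep = "\t", id_name = "individual_id") {
  df <- data.frame(rownames(scores), scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(NULL)
}

#' Write an association result table
#'
#' Writes per-SNP association rows in the conventional PLINK-style column
#' layout `CHR SNP BP A1 F_A F_U A2 CHISQ OR [Band Location Gene] UNADJ
#' FDR_BH BONF [SUBTYPE]`, tab-delimited with one header line. Frequencies
#' are printed to 3 decimals, CHISQ and OR to 2, p-values to 4. Annotation
#' columns appear only when present in `rows`.
#'
#' @param rows data.frame of adjusted association rows as produced by
#'   [adjust_assoc()] / [subtype_assoc()] (columns `chrom`, `snp_id`, `bp`,
#'   `a1`, `f_a`, `f_u`, `a2`, `chisq`, `or_a1`, `p_unadj`, `p_fdr_bh`,
#'   `p_bonf`, optionally `band`, `location`, `gene`, `subtype`).
#' @param path output path.
#' @return Invisibly, `NULL`.
#' @export
write_assoc_table <- function(rows, path) {
  fmt <- function(x, digits) ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
  out <- data.frame(
    CHR = rows$chrom, SNP = rows$snp_id, BP = rows$bp, A1 = rows$a1,
    F_A = fmt(rows$f_a, 3L), F_U = fmt(rows$f_u, 3L), A2 = rows$a2,
    CHISQ = fmt(rows$chisq, 2L), OR = fmt(rows$or_a1, 2L),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (ann in c("band", "location", "gene")) {
    if (ann %in% names(rows)) out[[toupper(ann)]] <- rows[[ann]]
  }
  out$UNADJ <- fmt(rows$p_unadj, 4L)
  out$FDR_BH <- fmt(rows$p_fdr_bh, 4L)
  out$BONF <- fmt(rows$p_bonf, 4L)
  if ("subtype" %in% names(rows)) out$SUBTYPE <- rows$subtype
  if (nrow(rows) == 0L) out <- out[0L, , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Bundled worked-example association tables
#'
#' Returns one of the two published subtype-stratified allelic-association
#' tables shipped with the package as plain-text worked examples: `"final"`,
#' the 30-row table of 18 SNPs significant in at least one of four case
#' subtypes, and `"chr5p14"`, the 31-row table re-testing six previously
#' reported chr5p14.1 SNPs in each subtype and in the combined cases.
#' Columns follow PLINK association output conventions (`A1` minor allele,
#' `F_A`/`F_U` case/control minor-allele frequencies, `CHISQ`, `OR`,
#' `UNADJ`/`FDR_BH`/`BONF` p-values) plus `Subtype` and `N_cases`.
#'
#' @param which `"final"` or `"chr5p14"`.
#' @return data.frame of the table rows.
#' @export
example_assoc_table <- function(which = c("final", "chr5p14")) {
  which <- match.arg(which)
  fn <- c(final = "subtype_assoc_example.tsv",
          chr5p14 = "chr5p14_subtype_assoc.tsv")[[which]]
  path <- system.file("extdata", fn, package = "subtypeGWAS", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "")
}
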