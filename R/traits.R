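#' Default recode map for raw diagnostic-interview item codes
#'
#' Raw ADI-R-style item codes mix true severities (0-3) with special codes:
#' 7 conventionally marks an abnormality that is not scored for severity,
#' and 8/9 mark not-applicable / not-asked items. The default map passes
#' severities through, sends 7 to severity 0 and 8/9 to missing. Scoring
#' conventions differ between instruments and studies, so the map is an
#' argument of [recode_items()] rather than a constant.
#'
#' @return List with integer vectors `pass` (codes kept as-is), `zero`
#'   (codes recoded to 0) and `missing` (codes recoded to `NA`).
#' @export
default_recode_map <- function() {
  list(pass = 0:3, zero = 7L, missing = c(8L, 9L))
}

#' Recode raw item codes to 0-3 severities
#'
#' @param raw integer matrix of raw codes (individuals x items), as from
#'   [read_item_scores()]; `NA` entries stay missing.
#' @param recode_map list with `pass`, `zero`, `missing` code sets; see
#'   [default_recode_map()]. Every code present in `raw` must be covered.
#' @return Integer matrix of severities in \{0, 1, 2, 3\} with `NA` for
#'   missing, same dimnames as `raw`.
#' @export
recode_items <- function(raw, recode_map = default_recode_map()) {
  known <- c(recode_map$pass, recode_map$zero, recode_map$missing)
  bad <- which(!is.na(raw) & !(raw %in% known), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("unmapped item code ", raw[bad[1L, , drop = FALSE]],
         " at item ", colnames(raw)[bad[1L, 2L]],
         " (individual ", rownames(raw)[bad[1L, 1L]], ")")
  }
  out <- raw
  out[raw %in% recode_map$zero] <- 0L
  out[raw %in% recode_map$missing] <- NA_integer_
  storage.mode(out) <- "integer"
  out
}

#' Build quantitative-trait sums from item severities
#'
#' For each trait category, sums the severities of its member items over the
#' observed (non-missing) entries. An individual whose fraction of missing
#' items within a trait exceeds `max_missing_fraction` gets a missing trait
#' value and is excluded from quantitative-trait association for that trait.
#' Item lists may overlap between traits.
#'
#' @param scores severity matrix from [recode_items()] (values 0-3 or `NA`).
#' @param definitions named list: trait name -> character vector of item
#'   (column) names.
#' @param max_missing_fraction per-trait missingness tolerance (default 0.2).
#' @return data.frame with column `individual_id` followed by one integer
#'   column per trait (`NA` where the trait is unscorable).
#' @export
trait_sums <- function(scores, definitions, max_missing_fraction = 0.2) {
  if (length(definitions) == 0L) stop("no trait definitions supplied")
  if (is.null(names(definitions)) || any(!nzchar(names(definitions))))
    stop("trait definitions must be named")
  out <- data.frame(individual_id = rownames(scores), stringsAsFactors = FALSE)
  for (trait in names(definitions)) {
    items <- definitions[[trait]]
    if (length(items) == 0L) stop("empty item list for trait '", trait, "'")
    missing_items <- setdiff(items, colnames(scores))
    if (length(missing_items) > 0L)
      stop("trait '", trait, "' refers to unknown item(s): ",
           paste(missing_items, collapse = ", "))
    sub <- scores[, items, drop = FALSE]
    miss_frac <- rowMeans(is.na(sub))
    sums <- as.integer(rowSums(sub, na.rm = TRUE))
    sums[miss_frac > max_missing_fraction] <- NA_integer_
    out[[trait]] <- sums
  }
  out
}

#' Read a trait-definition mapping from a plain config file
#'
#' One trait per line, `name = item1,item2,...`; blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path path to the config file.
#' @return Named list of item-name vectors, as [trait_sums()] expects.
#' @export
read_trait_map <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  defs <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed trait-map line: '", ln, "'")
    items <- trimws(strsplit(parts[2L], ",", fixed = TRUE)[[1L]])
    defs[[trimws(parts[1L])]] <- items[nzchar(items)]
  }
  defs
}
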