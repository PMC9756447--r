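#' Read per-SNP GWAS summary statistics
#'
#' Reads a delimited text table of single-SNP association results into the
#' internal summary-statistic layout: one row per SNP with columns `snp_id`,
#' `chrom`, `pos` (1-based), `effect` (additive allele-substitution effect on
#' the trait scale) and, when present in the input, `se` and `pvalue`. There
#' is no fixed source dialect: `column_map` names the input columns holding
#' each field.
#'
#' Rows failing validation (non-finite effect, non-positive position,
#' p-value outside (0, 1]) are an error by default; with `lenient = TRUE`
#' they are dropped with a warning and the accepted/rejected counts are
#' reported.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector or list mapping internal field
#'   names (`snp_id`, `chrom`, `pos`, `effect`, and optionally `se`,
#'   `pvalue`) to column names in the file.
#' @param sep Field separator (default tab).
#' @param lenient Drop invalid rows with a warning instead of failing.
#' @return A `data.frame` with columns `snp_id`, `chrom`, `pos`, `effect`,
#'   `se`, `pvalue` (the last two `NA` when unmapped), rows in file order.
#' @export
read_summary_stats <- function(path,
                               column_map = default_column_map(),
                               sep = "\t",
                               lenient = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  column_map <- as.list(column_map)
  required <- c("snp_id", "chrom", "pos", "effect")
  missing_keys <- setdiff(required, names(column_map))
  if (length(missing_keys))
    stop("column_map must map the required fields: ",
         paste(missing_keys, collapse = ", "))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  for (field in c(required, intersect(c("se", "pvalue"), names(column_map)))) {
    col <- column_map[[field]]
    if (!col %in% names(raw))
      stop("mapped column '", col, "' (field '", field,
           "') not found in ", path)
  }
  n <- nrow(raw)
  num <- function(field) {
    if (is.null(column_map[[field]])) return(rep(NA_real_, n))
    suppressWarnings(as.numeric(raw[[column_map[[field]]]]))
  }
  out <- data.frame(
    snp_id = raw[[column_map$snp_id]],
    chrom  = raw[[column_map$chrom]],
    pos    = num("pos"),
    effect = num("effect"),
    se     = num("se"),
    pvalue = num("pvalue"),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(out$effect) |
    !is.finite(out$pos) | out$pos < 1 | out$pos != floor(out$pos) |
    !nzchar(out$snp_id) |
    (!is.na(out$pvalue) & (out$pvalue <= 0 | out$pvalue > 1)) |
    (!is.na(out$se) & out$se <= 0)
  if (any(bad)) {
    lines <- which(bad) + 1L  # header is line 1
    if (!lenient)
      stop("invalid summary-statistic row(s) at line(s) ",
           paste(utils::head(lines, 5L), collapse = ", "),
           if (sum(bad) > 5L) " ..." else "",
           " (non-finite effect, bad position or p-value);",
           " use lenient = TRUE to skip")
    warning(sum(bad), " row(s) rejected at line(s) ",
            paste(utils::head(lines, 5L), collapse = ", "),
            if (sum(bad) > 5L) " ..." else "")
    out <- out[!bad, , drop = FALSE]
  }
  out$pos <- as.integer(out$pos)
  rownames(out) <- NULL
  message("read_summary_stats: ", nrow(out), " SNP record(s) accepted, ",
          sum(bad), " rejected")
  out
}

#' Default summary-statistic column mapping
#'
#' @return Named list mapping internal fields to same-named input columns.
#' @export
default_column_map <- function() {
  list(snp_id = "snp_id", chrom = "chrom", pos = "pos",
       effect = "effect", se = "se", pvalue = "pvalue")
}
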