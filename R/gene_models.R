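#' Read gene models from GFF3 or BED
#'
#' Parses gene coordinates into the internal convention: 1-based, inclusive
#' start/end on a named chromosome. GFF3 is already 1-based inclusive; BED's
#' 0-based half-open intervals are converted on import (a BED interval of
#' width 1 becomes a valid 1-bp gene). Gene identifiers come from the GFF3
#' `ID` attribute or the BED name column and must be unique within a file.
#' Strand is recorded but ignored by SNP assignment.
#'
#' @param path Path to a GFF3 or BED file.
#' @param format `"gff3"` or `"bed"`.
#' @param feature_type For GFF3, which feature type rows to keep
#'   (default `"gene"`).
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_models <- function(path, format = c("gff3", "bed"),
                             feature_type = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    if ("type" %in% names(S4Vectors::mcols(gr)))
      gr <- gr[as.character(gr$type) %in% feature_type]
    if (length(gr) == 0L)
      stop("no '", paste(feature_type, collapse = "/"),
           "' features in ", path)
    ids <- if ("ID" %in% names(S4Vectors::mcols(gr)))
      as.character(gr$ID) else rep(NA_character_, length(gr))
    if (anyNA(ids) || any(!nzchar(ids)))
      stop("GFF3 gene feature without an ID attribute in ", path)
  } else {
    ids <- if ("name" %in% names(S4Vectors::mcols(gr)))
      as.character(gr$name) else rep(NA_character_, length(gr))
    if (anyNA(ids) || any(!nzchar(ids)))
      stop("BED record without a name column in ", path)
  }
  if (anyDuplicated(ids))
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr),
             strand = strand,
             stringsAsFactors = FALSE)
}

#' Write gene models as BED
#'
#' Converts the internal 1-based inclusive intervals back to BED's 0-based
#' half-open convention; [read_gene_models()] on the output is the identity.
#'
#' @param genes Gene-model `data.frame` as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(genes, path) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  lines <- sprintf("%s\t%d\t%d\t%s", genes$chrom,
                   as.integer(genes$start) - 1L, as.integer(genes$end),
                   genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read a precomputed SNP-to-gene assignment table
#'
#' Alternative to positional assignment: a tab-delimited file with header
#' columns `snp_id` and `gene_id`, one assignment per row (a SNP may appear
#' with several genes).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `snp_id`, `gene_id`.
#' @export
read_snp_gene_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (!all(c("snp_id", "gene_id") %in% names(tab)))
    stop("SNP-gene map must have columns snp_id and gene_id")
  tab <- unique(tab[, c("snp_id", "gene_id")])
  rownames(tab) <- NULL
  tab
}
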