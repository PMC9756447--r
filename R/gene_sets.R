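#' Pathway collections
#'
#' A pathway collection is an ordered set of named gene sets (e.g. KEGG
#' maps), the unit that defines the columns of the gene-by-pathway incidence
#' matrix and the entries of the Jaccard covariance. Order is the file order
#' and is preserved throughout so that results are deterministic.
#'
#' @param pathway_id Character vector of unique pathway identifiers.
#' @param description Character vector of free-text descriptions.
#' @param genes List of character vectors, one non-empty set of gene IDs per
#'   pathway (duplicates are removed, first occurrence kept).
#' @return An object of class `"pathway_collection"`: a list with elements
#'   `pathway_id`, `description` and `genes`.
#' @examples
#' pc <- pathway_collection(c("p1", "p2"), c("one", "two"),
#'                          list(c("A", "B", "C"), c("B", "C", "D")))
#' length(pc)
#' @export
pathway_collection <- function(pathway_id, description, genes) {
  pathway_id <- as.character(pathway_id)
  description <- as.character(description)
  if (length(pathway_id) != length(description) ||
      length(pathway_id) != length(genes))
    stop("pathway_id, description and genes must have equal length")
  if (anyDuplicated(pathway_id))
    stop("duplicate pathway_id: ",
         paste(unique(pathway_id[duplicated(pathway_id)]), collapse = ", "))
  genes <- lapply(genes, function(g) unique(as.character(g)))
  if (any(vapply(genes, length, 1L) == 0L))
    stop("every pathway must contain at least one gene")
  structure(list(pathway_id = pathway_id,
                 description = description,
                 genes = genes),
            class = "pathway_collection")
}

#' @export
length.pathway_collection <- function(x) length(x$pathway_id)

#' @export
print.pathway_collection <- function(x, ...) {
  sizes <- vapply(x$genes, length, 1L)
  cat("Pathway collection:", length(x), "gene sets,",
      length(unique(unlist(x$genes))), "distinct genes\n")
  cat("Set sizes: min", min(sizes), "/ median", stats::median(sizes),
      "/ max", max(sizes), "\n")
  invisible(x)
}

#' Subset a pathway collection
#'
#' @param x A `pathway_collection`.
#' @param i Index vector (integer, logical or pathway IDs).
#' @param ... Ignored.
#' @export
`[.pathway_collection` <- function(x, i, ...) {
  if (is.character(i)) {
    i <- match(i, x$pathway_id)
    if (anyNA(i)) stop("unknown pathway_id in subset")
  }
  pathway_collection(x$pathway_id[i], x$description[i], x$genes[i])
}

#' Read gene sets from a GMT file
#'
#' GMT is the tab-delimited gene-set exchange format: each line is
#' `pathway_id <TAB> description <TAB> gene1 <TAB> gene2 ...`. Duplicate gene
#' IDs within one set are silently de-duplicated; lines with fewer than three
#' fields, empty gene lists and duplicated pathway IDs are format errors.
#'
#' @param path Path to a GMT file.
#' @return A [pathway_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1L],
         ": fewer than 3 tab-separated fields")
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate pathway_id in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- vapply(fields, `[[`, "", 2L)
  genes <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    g[nzchar(g)]
  })
  empty <- vapply(genes, length, 1L) == 0L
  if (any(empty))
    stop("GMT line ", which(empty)[1L], ": empty gene list")
  pathway_collection(ids, desc, genes)
}

#' Write gene sets to a GMT file
#'
#' Inverse of [read_gmt()]: re-reading the written file yields an identical
#' collection (same order, IDs and sets).
#'
#' @param pathways A [pathway_collection()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  stopifnot(inherits(pathways, "pathway_collection"))
  lines <- mapply(function(id, d, g) paste(c(id, d, g), collapse = "\t"),
                  pathways$pathway_id, pathways$description, pathways$genes)
  writeLines(lines, path)
  invisible(path)
}
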