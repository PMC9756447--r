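#' Assign SNPs to genes by position
#'
#' A SNP is assigned to every gene whose (optionally flank-extended)
#' interval contains it: chromosome match and
#' `start - flank_bp <= pos <= end + flank_bp`. Overlapping or nested genes
#' each receive the SNP; SNPs inside no gene yield no assignment. Strand is
#' ignored.
#'
#' @param stats Summary-statistic `data.frame` (see [read_summary_stats()]).
#' @param genes Gene-model `data.frame` (see [read_gene_models()]).
#' @param flank_bp Non-negative integer flanking window in base pairs
#'   (default 0).
#' @return A `data.frame` with columns `snp_id`, `gene_id`, one row per
#'   unique assignment, ordered by `gene_id` then `snp_id`.
#' @export
assign_snps_to_genes <- function(stats, genes, flank_bp = 0L) {
  stopifnot(is.numeric(flank_bp), length(flank_bp) == 1L, flank_bp >= 0)
  flank_bp <- as.integer(flank_bp)
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, as.integer(genes$start) - flank_bp),
                     as.integer(genes$end) + flank_bp))
  snp_gr <- GenomicRanges::GRanges(
    stats$chrom, IRanges::IRanges(stats$pos, stats$pos))
  # disjoint chromosome sets between SNPs and genes are a valid (empty) case
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(snp_gr, gene_gr, ignore.strand = TRUE))
  out <- unique(data.frame(
    snp_id = stats$snp_id[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE))
  out <- out[order(out$gene_id, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse SNPs to one representative per gene
#'
#' When several SNPs fall in one gene, only the single strongest association
#' represents the gene, so that each gene contributes one element to the
#' model's response vector. Under `"max_abs_effect"` (default) the SNP with
#' the largest absolute effect wins; ties are broken by smaller p-value when
#' available, then lexicographic `snp_id`, making the selection
#' order-invariant and reproducible. Under `"min_pvalue"` the smallest
#' p-value wins (ties by larger absolute effect, then `snp_id`); this
#' requires p-values for every assigned SNP.
#'
#' The gene-level response is `y = |effect|` of the winning SNP.
#'
#' @param stats Summary-statistic `data.frame`.
#' @param assignments SNP-to-gene `data.frame` from
#'   [assign_snps_to_genes()] or [read_snp_gene_map()].
#' @param criterion `"max_abs_effect"` or `"min_pvalue"`.
#' @return A `data.frame` with one row per gene having at least one assigned
#'   SNP: `gene_id`, `snp_id`, `chrom`, `pos`, `effect`, `y`, ordered by
#'   `gene_id`.
#' @export
select_top_snp_per_gene <- function(stats, assignments,
                                    criterion = c("max_abs_effect",
                                                  "min_pvalue")) {
  criterion <- match.arg(criterion)
  idx <- match(assignments$snp_id, stats$snp_id)
  if (anyNA(idx))
    stop("assignment references unknown snp_id: ",
         paste(utils::head(unique(assignments$snp_id[is.na(idx)]), 5L),
               collapse = ", "))
  tab <- data.frame(gene_id = assignments$gene_id,
                    stats[idx, c("snp_id", "chrom", "pos", "effect",
                                 "pvalue")],
                    stringsAsFactors = FALSE)
  if (criterion == "min_pvalue" && anyNA(tab$pvalue))
    stop("criterion 'min_pvalue' requires a p-value for every assigned SNP")
  # NA p-values sort last so the tie-break chain is total
  p_key <- ifelse(is.na(tab$pvalue), Inf, tab$pvalue)
  ord <- if (criterion == "max_abs_effect")
    order(tab$gene_id, -abs(tab$effect), p_key, tab$snp_id)
  else
    order(tab$gene_id, p_key, -abs(tab$effect), tab$snp_id)
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(tab$gene_id), , drop = FALSE]
  out <- data.frame(gene_id = tab$gene_id, snp_id = tab$snp_id,
                    chrom = tab$chrom, pos = tab$pos, effect = tab$effect,
                    y = abs(tab$effect), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build the gene-by-pathway incidence matrix
#'
#' Constructs the binary design matrix Z linking gene-level observations to
#' the pathways containing each gene: row i, column j is 1 iff gene i
#' belongs to pathway j. By default genes belonging to no pathway are
#' dropped (they cannot inform pathway effects and would only enter the
#' general mean); `keep_unmapped = TRUE` retains them with all-zero rows.
#' Pathways with no observed gene are dropped from the matrix and reported.
#'
#' @param gene_effects Collapsed gene table from [select_top_snp_per_gene()].
#' @param pathways A [pathway_collection()].
#' @param keep_unmapped Retain genes outside every pathway (all-zero rows).
#' @return A list with components:
#'   \describe{
#'     \item{gene_effects}{the (possibly filtered) gene table, with an added
#'       list column `pathways` of member pathway IDs per gene;}
#'     \item{Z}{the binary incidence matrix with gene/pathway dimnames;}
#'     \item{retained}{the subsetted `pathway_collection` matching Z's
#'       columns;}
#'     \item{dropped_pathways}{IDs of pathways with zero observed genes.}
#'   }
#' @export
build_incidence <- function(gene_effects, pathways, keep_unmapped = FALSE) {
  stopifnot(inherits(pathways, "pathway_collection"))
  gid <- gene_effects$gene_id
  Z <- vapply(pathways$genes, function(g) as.numeric(gid %in% g),
              numeric(length(gid)))
  Z <- matrix(Z, nrow = length(gid),
              dimnames = list(gid, pathways$pathway_id))
  if (sum(Z) == 0)
    stop("no overlap between summary statistics and gene sets")
  mapped <- rowSums(Z) > 0
  if (!keep_unmapped && any(!mapped)) {
    message("build_incidence: dropping ", sum(!mapped),
            " gene(s) outside every pathway")
    Z <- Z[mapped, , drop = FALSE]
    gene_effects <- gene_effects[mapped, , drop = FALSE]
  }
  empty <- colSums(Z) == 0
  dropped <- colnames(Z)[empty]
  if (any(empty)) {
    message("build_incidence: dropping ", sum(empty),
            " pathway(s) with no observed genes: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) " ..." else "")
    Z <- Z[, !empty, drop = FALSE]
  }
  retained <- pathways[colnames(Z)]
  gene_effects$pathways <- lapply(seq_len(nrow(Z)), function(i)
    colnames(Z)[Z[i, ] == 1])
  rownames(gene_effects) <- NULL
  list(gene_effects = gene_effects, Z = Z, retained = retained,
       dropped_pathways = dropped)
}
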