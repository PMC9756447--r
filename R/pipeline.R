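#' Write pathway and gene result tables
#'
#' Emits the two standard reports of a fit: `<prefix>_pathways.tsv`
#' (pathway ID, number of observed genes, predicted effect, p-value,
#' adjusted p-value, significance flag at the fit's alpha; sorted by
#' p-value ascending with ties broken by pathway ID) and
#' `<prefix>_genes.tsv` (gene ID, selected SNP, coordinates, response value
#' and comma-separated member pathways). Numbers are printed with 6
#' significant digits; both files are tab-delimited with a header.
#'
#' @param fit A `"pathmix"` fit.
#' @param out_prefix Output path prefix.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_results <- function(fit, out_prefix) {
  stopifnot(inherits(fit, "pathmix"))
  dir <- dirname(out_prefix)
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  num <- function(x) sprintf("%.6g", x)

  ptab <- summary(fit)
  ptab$t_hat <- num(ptab$t_hat)
  ptab$pvalue <- num(ptab$pvalue)
  ptab$padj <- num(ptab$padj)
  ptab$significant <- ifelse(ptab$significant, "yes", "no")
  p_path <- paste0(out_prefix, "_pathways.tsv")
  utils::write.table(as.data.frame(ptab), p_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ge <- fit$gene_effects
  gtab <- data.frame(gene_id = ge$gene_id, snp_id = ge$snp_id,
                     chrom = ge$chrom, pos = ge$pos, y = num(ge$y),
                     pathways = vapply(ge$pathways, paste, "",
                                       collapse = ","),
                     stringsAsFactors = FALSE)
  g_path <- paste0(out_prefix, "_genes.tsv")
  utils::write.table(gtab, g_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pathways = p_path, genes = g_path))
}

#' Run the pathway-analysis pipeline end to end
#'
#' Orchestrates read -> assign -> collapse -> incidence -> covariance ->
#' variance partition -> mixed model equations -> p-values -> write, with
#' per-stage record counts logged and echoed into a run-metadata file
#' (`<prefix>_run_metadata.yaml`) so input attrition is always visible.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `summary_stats` (path), `gene_sets` (GMT path), exactly one of
#'   `gene_models` (GFF3/BED path) / `snp_gene_map` (TSV path), and the
#'   optional fitting parameters `column_map`, `flank_bp`, `criterion`,
#'   `keep_unmapped`, `ratio_t`, `jitter`, `alpha`, `adjust`, `lenient`,
#'   plus the output `out_prefix`.
#' @return The `"pathmix"` fit, invisibly; result tables and metadata are
#'   written next to `out_prefix`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("summary_stats", "gene_sets", "out_prefix")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys))
    stop("pipeline config is missing: ",
         paste(missing_keys, collapse = ", "))
  if (is.null(config$gene_models) == is.null(config$snp_gene_map))
    stop("pipeline config must name exactly one of gene_models / snp_gene_map")
  getd <- function(key, default) {
    if (is.null(config[[key]])) default else config[[key]]
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }

  cmap <- getd("column_map", default_column_map())
  stats <- stage("read_summary_stats",
                 read_summary_stats(config$summary_stats, column_map = cmap,
                                    lenient = isTRUE(config$lenient)))
  pathways <- stage("read_gmt", read_gmt(config$gene_sets))
  message("run_pipeline: ", nrow(stats), " SNPs, ", length(pathways),
          " pathways read")
  fit <- stage("fit", pathmix(
    stats, pathways,
    gene_models = config$gene_models,
    snp_gene_map = config$snp_gene_map,
    flank_bp = getd("flank_bp", 0L),
    criterion = getd("criterion", "max_abs_effect"),
    keep_unmapped = isTRUE(config$keep_unmapped),
    ratio_t = getd("ratio_t", 0.3),
    jitter = getd("jitter", 1e-8),
    alpha = getd("alpha", 0.05),
    adjust = getd("adjust", "none")))
  message("run_pipeline: ", fit$counts["n_genes_model"], " genes in ",
          fit$counts["n_pathways_retained"], " retained pathways; ",
          sum(fit$significant), " significant at alpha = ", fit$alpha)
  stage("write_results", write_results(fit, config$out_prefix))

  meta <- list(
    package = "pathmix",
    version = as.character(utils::packageVersion("pathmix")),
    config = config[order(names(config))],
    counts = as.list(fit$counts),
    dropped_pathways = as.list(fit$dropped_pathways),
    n_significant = sum(fit$significant),
    jitter_applied = fit$diagnostics$jitter_applied)
  yaml::write_yaml(meta, paste0(config$out_prefix, "_run_metadata.yaml"))
  invisible(fit)
}
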