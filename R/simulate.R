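#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic-data generator. The
#' generator emulates the model the estimator assumes: gene-level responses
#' `y = mu + (Z t)_g + e_g` with pathway effects drawn from the Jaccard-
#' covariance prior, re-expressed as SNP-level summary statistics (one
#' designated top SNP per gene carrying the gene's response as its effect
#' magnitude with random sign, plus strictly weaker decoy SNPs).
#'
#' Defaults describe a typical well-powered study: 40 pathways of 25 genes,
#' 20% of each set shared with the next so the covariance has non-trivial
#' off-diagonals, 3 SNPs per gene, a mean effect magnitude of 1 with total
#' response variance 0.04 (so responses are essentially always positive and
#' taking absolute values does not fold the distribution), and a 0.3/0.7
#' pathway/residual variance split.
#'
#' @param n_pathways Number of pathways (>= 1).
#' @param genes_per_pathway Genes per pathway: a single count or a
#'   `c(min, max)` range sampled per pathway.
#' @param overlap_fraction Fraction of each set shared with the following
#'   pathway, in \[0, 1).
#' @param snps_per_gene SNPs per gene: a single count or a `c(min, max)`
#'   range.
#' @param mu True general mean of the gene-level response.
#' @param sigma_y2_target Total response variance; the pathway and residual
#'   components are `ratio_t` and `1 - ratio_t` of it.
#' @param ratio_t Pathway fraction of the variance, in (0, 1).
#' @param null_fraction Fraction of pathways whose true effect is forced to
#'   exactly zero, in \[0, 1\].
#' @param seed Integer seed; identical configs give identical output.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_pathways = 40L, genes_per_pathway = 25L,
                       overlap_fraction = 0.2, snps_per_gene = 3L,
                       mu = 1, sigma_y2_target = 0.04, ratio_t = 0.3,
                       null_fraction = 0, seed = 1L) {
  stopifnot(n_pathways >= 1, all(genes_per_pathway >= 1),
            length(genes_per_pathway) %in% 1:2,
            all(snps_per_gene >= 1), length(snps_per_gene) %in% 1:2,
            overlap_fraction >= 0, overlap_fraction < 1,
            sigma_y2_target > 0, ratio_t > 0, ratio_t < 1,
            null_fraction >= 0, null_fraction <= 1)
  min_size <- min(genes_per_pathway)
  if (round(overlap_fraction * min_size) >= min_size)
    stop("overlap_fraction too large: consecutive sets would coincide")
  structure(list(n_pathways = as.integer(n_pathways),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 overlap_fraction = overlap_fraction,
                 snps_per_gene = as.integer(snps_per_gene),
                 mu = mu, sigma_y2_target = sigma_y2_target,
                 ratio_t = ratio_t, null_fraction = null_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

draw_counts <- function(counts, n) {
  if (length(counts) == 1L) rep(counts, n)
  else sample(seq(counts[1L], counts[2L]), n, replace = TRUE)
}

#' Generate synthetic gene sets
#'
#' Builds `n_pathways` gene sets of the configured sizes in which
#' consecutive pathways share `round(overlap_fraction * size)` genes, so the
#' Jaccard covariance has a banded non-trivial structure. Deterministic
#' under the config seed.
#'
#' @param config A [sim_config()].
#' @return A [pathway_collection()] over synthetic gene IDs `g000001`, ...
#' @export
simulate_gene_sets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sizes <- draw_counts(config$genes_per_pathway, config$n_pathways)
  genes <- vector("list", config$n_pathways)
  next_gene <- 1L
  gid <- function(i) sprintf("g%06d", i)
  for (k in seq_len(config$n_pathways)) {
    n_shared <- if (k == 1L) 0L
      else min(round(config$overlap_fraction * sizes[k]),
               length(genes[[k - 1L]]), sizes[k] - 1L)
    shared <- if (n_shared > 0L)
      utils::tail(genes[[k - 1L]], n_shared) else character()
    n_new <- sizes[k] - n_shared
    fresh <- gid(seq(next_gene, length.out = n_new))
    next_gene <- next_gene + n_new
    genes[[k]] <- c(shared, fresh)
  }
  pathway_collection(sprintf("sim%03d", seq_len(config$n_pathways)),
                     sprintf("synthetic pathway %d",
                             seq_len(config$n_pathways)),
                     genes)
}

#' Generate synthetic SNP-level summary statistics
#'
#' Draws pathway effects `t ~ N(0, V*sigma_t2)` (entries of the configured
#' null pathways set to exactly zero) and residuals `e ~ N(0, sigma_e2)` per
#' gene, forms the true gene response `mu + (Z t)_g + e_g`, and emits it as
#' SNP records: each gene's designated top SNP carries the response as its
#' effect magnitude with a random sign, and any additional decoy SNPs carry
#' strictly smaller magnitudes, so per-gene collapsing provably recovers the
#' designated SNP. Genes are laid out as non-overlapping 1-kb intervals on
#' one synthetic chromosome. A constant standard error of 0.1 and the
#' corresponding two-sided normal p-value accompany each effect.
#'
#' Randomness is seeded at `config$seed + 1` so gene-set construction and
#' effect generation are independently reproducible.
#'
#' @param config A [sim_config()].
#' @param pathways The collection from [simulate_gene_sets()] (same config).
#' @return A list of class `"pathway_sim"` with components `stats`
#'   (summary-statistic `data.frame`), `genes` (gene-model `data.frame`),
#'   `pathways`, and `truth` (true `mu`, `t`, per-gene `y_true`, `null_mask`
#'   over pathways, the generated `V` and incidence `Z`).
#' @export
simulate_summary_stats <- function(config, pathways) {
  stopifnot(inherits(config, "sim_config"),
            inherits(pathways, "pathway_collection"))
  set.seed(config$seed + 1L)
  gene_ids <- unique(unlist(pathways$genes))
  n_genes <- length(gene_ids)
  p <- length(pathways)

  Z <- vapply(pathways$genes, function(g) as.numeric(gene_ids %in% g),
              numeric(n_genes))
  Z <- matrix(Z, nrow = n_genes,
              dimnames = list(gene_ids, pathways$pathway_id))
  V <- suppressWarnings(build_covariance(pathways))
  sigma_t2 <- config$ratio_t * config$sigma_y2_target
  sigma_e2 <- (1 - config$ratio_t) * config$sigma_y2_target

  Lv <- chol(V + diag(1e-10, p))
  t_true <- drop(crossprod(Lv, stats::rnorm(p))) * sqrt(sigma_t2)
  null_mask <- rep(FALSE, p)
  n_null <- round(config$null_fraction * p)
  if (n_null > 0L) {
    null_mask[sample.int(p, n_null)] <- TRUE
    t_true[null_mask] <- 0
  }
  names(t_true) <- pathways$pathway_id
  e <- stats::rnorm(n_genes, sd = sqrt(sigma_e2))
  y_true <- config$mu + drop(Z %*% t_true) + e
  names(y_true) <- gene_ids

  gene_len <- 1000L
  gap <- 500L
  starts <- (seq_len(n_genes) - 1L) * (gene_len + gap) + 1L
  genes <- data.frame(gene_id = gene_ids, chrom = "1",
                      start = starts, end = starts + gene_len - 1L,
                      strand = ".", stringsAsFactors = FALSE)

  n_snps <- draw_counts(config$snps_per_gene, n_genes)
  gene_idx <- rep.int(seq_len(n_genes), n_snps)
  rank <- sequence(n_snps)
  # the designated top SNP (rank 1) carries the full magnitude; decoys get a
  # strictly smaller multiplier so collapsing provably recovers rank 1
  mult <- stats::runif(length(gene_idx), 0.05, 0.95)
  mult[rank == 1L] <- 1
  mag <- abs(y_true)[gene_idx] * mult
  eff <- sample(c(-1, 1), length(mag), replace = TRUE) * mag
  spacing <- gene_len %/% n_snps[gene_idx]
  pos <- starts[gene_idx] + (rank - 1L) * spacing + spacing %/% 2L
  stats <- data.frame(
    snp_id = sprintf("%s_snp%02d", gene_ids[gene_idx], rank),
    chrom = "1", pos = as.integer(pos), effect = eff,
    se = 0.1,
    pvalue = pmin(1, pmax(2 * stats::pnorm(-abs(eff) / 0.1),
                          .Machine$double.xmin)),
    stringsAsFactors = FALSE)

  structure(list(stats = stats, genes = genes, pathways = pathways,
                 truth = list(mu = config$mu, t = t_true, y_true = y_true,
                              null_mask = null_mask, V = V, Z = Z,
                              sigma_t2 = sigma_t2, sigma_e2 = sigma_e2)),
            class = "pathway_sim")
}

#' Run the full generator
#'
#' Convenience wrapper: [simulate_gene_sets()] then
#' [simulate_summary_stats()].
#'
#' @param config A [sim_config()].
#' @return A `"pathway_sim"` object.
#' @export
simulate_study <- function(config) {
  simulate_summary_stats(config, simulate_gene_sets(config))
}

#' Write a simulated study to disk
#'
#' Emits the exact formats the readers consume: `summary_stats.tsv`,
#' `pathways.gmt` and `genes.bed` in `dir`, making the simulator an
#' end-to-end fixture factory for the pipeline.
#'
#' @param sim A `"pathway_sim"` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "pathway_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stats_path <- file.path(dir, "summary_stats.tsv")
  tab <- sim$stats
  tab$effect <- sprintf("%.10g", tab$effect)
  tab$se <- sprintf("%.10g", tab$se)
  tab$pvalue <- sprintf("%.10g", tab$pvalue)
  utils::write.table(tab, stats_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gmt_path <- file.path(dir, "pathways.gmt")
  write_gmt(sim$pathways, gmt_path)
  bed_path <- file.path(dir, "genes.bed")
  write_bed(sim$genes, bed_path)
  invisible(c(stats = stats_path, gmt = gmt_path, bed = bed_path))
}

#' Recovery metrics of a fit against simulation truth
#'
#' Compares predicted pathway effects with the generator's true effects over
#' the pathways retained in the fit: Pearson and Spearman correlation, root
#' mean squared error, the empirical type-I error rate at `alpha` among
#' true-null pathways, and power among true-non-null pathways (either is
#' `NA` when its class is empty).
#'
#' @param fit A `"pathmix"` fit on data generated from `truth`'s run.
#' @param truth The `truth` component of a `"pathway_sim"` (or the whole
#'   `"pathway_sim"` object).
#' @param alpha Significance level for the error/power rates (default 0.05).
#' @return A `data.frame` with columns `metric` and `value`.
#' @export
recovery_report <- function(fit, truth, alpha = 0.05) {
  stopifnot(inherits(fit, "pathmix"))
  if (inherits(truth, "pathway_sim")) truth <- truth$truth
  ids <- names(fit$t_hat)
  idx <- match(ids, names(truth$t))
  if (anyNA(idx))
    stop("fit contains pathways absent from the simulation truth: ",
         paste(utils::head(ids[is.na(idx)], 5L), collapse = ", "))
  t_true <- truth$t[idx]
  nulls <- truth$null_mask[idx]
  # correlation is undefined against a constant truth (e.g. all-null)
  cor_safe <- function(a, b, method = "pearson") {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
    else stats::cor(a, b, method = method)
  }
  data.frame(
    metric = c("pearson", "spearman", "rmse", "type1", "power"),
    value = c(
      cor_safe(fit$t_hat, t_true),
      cor_safe(fit$t_hat, t_true, method = "spearman"),
      sqrt(mean((fit$t_hat - t_true)^2)),
      if (any(nulls)) mean(fit$pvalue[nulls] <= alpha) else NA_real_,
      if (any(!nulls)) mean(fit$pvalue[!nulls] <= alpha) else NA_real_),
    stringsAsFactors = FALSE)
}
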