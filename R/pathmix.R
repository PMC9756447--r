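#' Fit the pathway-effect mixed linear model
#'
#' `pathmix()` is the package's central fitting function. Starting from
#' per-SNP GWAS summary statistics and a collection of gene sets, it
#'
#' 1. assigns SNPs to genes (positional overlap against gene models, or a
#'    precomputed SNP-gene map),
#' 2. collapses to one strongest SNP per gene, giving the response
#'    `y = |effect|` of each gene's representative SNP,
#' 3. builds the gene-by-pathway incidence matrix Z and the Jaccard
#'    similarity covariance V between the retained pathways,
#' 4. partitions the sample variance of y into pathway and residual
#'    components with the fixed ratio `ratio_t`,
#' 5. solves Henderson's mixed model equations
#'    `y = 1*mu + Z*t + e`, `t ~ N(0, V*sigma_t2)`, `e ~ N(0, I*sigma_e2)`
#'    for the general mean and the BLUP of pathway effects, and
#' 6. computes one-sided p-values for `H1: t_i > 0` from the `N(0, sigma_t2)`
#'    prior null.
#'
#' @param stats Summary statistics `data.frame` (see
#'   [read_summary_stats()]), or a path to a file readable by it.
#' @param pathways A [pathway_collection()], or a path to a GMT file.
#' @param gene_models Gene models `data.frame` (see [read_gene_models()]),
#'   or a path to a GFF3/BED file (format guessed from the extension).
#'   Exactly one of `gene_models` / `snp_gene_map` must be given.
#' @param snp_gene_map Precomputed assignment `data.frame` with columns
#'   `snp_id`, `gene_id`, or a path readable by [read_snp_gene_map()].
#' @param flank_bp Flanking window for positional assignment (default 0).
#' @param criterion SNP collapsing rule, `"max_abs_effect"` (default) or
#'   `"min_pvalue"`; see [select_top_snp_per_gene()].
#' @param keep_unmapped Keep genes outside every pathway (default `FALSE`).
#' @param ratio_t Pathway fraction of the response variance, in (0, 1);
#'   default 0.3.
#' @param jitter Ridge added to a singular covariance (default `1e-8`); 0
#'   makes singularity an error.
#' @param alpha Significance level for the reported flag (default 0.05;
#'   comparison is `<=`).
#' @param adjust Multiple-testing adjustment, `"none"` (default) or `"bh"`.
#' @return An object of class `"pathmix"`; see Details. Supports `print`,
#'   `summary`, `coef`, `fitted`, `residuals`, `predict`, `simulate` and
#'   `plot`.
#'
#' @details The returned object is a list with components `mu_hat`, `t_hat`
#'   (named vector over retained pathways), `pvalue`, `padj`, `significant`,
#'   `variance` (the `"variance_partition"`), `V`, `Z`, `gene_effects` (the
#'   collapsed per-gene table with `y` and member pathways),
#'   `dropped_pathways`, `diagnostics`, `counts` (per-stage record counts),
#'   `alpha`, `adjust`, `call`.
#'
#' @examples
#' pc <- pathway_collection(c("p1", "p2"), c("", ""),
#'                          list(c("g1", "g2"), c("g2", "g3")))
#' stats <- data.frame(snp_id = paste0("s", 1:3), chrom = "1",
#'                     pos = c(150L, 1150L, 2150L),
#'                     effect = c(0.4, -0.1, 0.3), se = NA, pvalue = NA)
#' genes <- data.frame(gene_id = paste0("g", 1:3), chrom = "1",
#'                     start = c(100L, 1100L, 2100L),
#'                     end = c(900L, 1900L, 2900L), strand = ".")
#' fit <- pathmix(stats, pc, gene_models = genes)
#' summary(fit)
#' @export
pathmix <- function(stats, pathways,
                    gene_models = NULL, snp_gene_map = NULL,
                    flank_bp = 0L,
                    criterion = c("max_abs_effect", "min_pvalue"),
                    keep_unmapped = FALSE,
                    ratio_t = 0.3, jitter = 1e-8,
                    alpha = 0.05, adjust = c("none", "bh")) {
  cl <- match.call()
  criterion <- match.arg(criterion)
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (is.character(stats)) stats <- read_summary_stats(stats)
  if (is.character(pathways)) pathways <- read_gmt(pathways)
  if (is.null(gene_models) == is.null(snp_gene_map))
    stop("provide exactly one of gene_models or snp_gene_map")

  if (!is.null(gene_models)) {
    if (is.character(gene_models)) {
      fmt <- if (grepl("\\.bed$", gene_models, ignore.case = TRUE))
        "bed" else "gff3"
      gene_models <- read_gene_models(gene_models, format = fmt)
    }
    assignments <- assign_snps_to_genes(stats, gene_models,
                                        flank_bp = flank_bp)
  } else {
    if (is.character(snp_gene_map))
      snp_gene_map <- read_snp_gene_map(snp_gene_map)
    assignments <- snp_gene_map
  }
  gene_effects <- select_top_snp_per_gene(stats, assignments,
                                          criterion = criterion)
  inc <- build_incidence(gene_effects, pathways,
                         keep_unmapped = keep_unmapped)
  V <- build_covariance(inc$retained)
  y <- inc$gene_effects$y
  vp <- partition_variance(y, ratio_t = ratio_t)
  sol <- solve_mme(y, inc$Z, V, vp, jitter = jitter)
  pvalue <- pathway_pvalues(sol$t_hat, vp)
  padj <- adjust_pvalues(pvalue, method = adjust)

  structure(list(
    mu_hat = sol$mu_hat,
    t_hat = sol$t_hat,
    pvalue = pvalue,
    padj = padj,
    significant = padj <= alpha,
    variance = vp,
    V = V,
    Z = inc$Z,
    gene_effects = inc$gene_effects,
    dropped_pathways = inc$dropped_pathways,
    diagnostics = sol$diagnostics,
    counts = c(n_snps = nrow(stats),
               n_assignments = nrow(assignments),
               n_genes_collapsed = nrow(gene_effects),
               n_genes_model = nrow(inc$Z),
               n_pathways_input = length(pathways),
               n_pathways_retained = ncol(inc$Z)),
    alpha = alpha,
    adjust = adjust,
    call = cl), class = "pathmix")
}

#' @export
print.pathmix <- function(x, ...) {
  cat("Pathway mixed linear model (y = 1*mu + Z*t + e)\n")
  cat(sprintf("  %d genes, %d pathways retained (%d input, %d empty)\n",
              nrow(x$Z), ncol(x$Z), x$counts["n_pathways_input"],
              length(x$dropped_pathways)))
  cat(sprintf("  mu_hat = %.6g; sigma_t2 = %.6g, sigma_e2 = %.6g\n",
              x$mu_hat, x$variance$sigma_t2, x$variance$sigma_e2))
  cat(sprintf("  %d pathway(s) significant at alpha = %g (%s p-values)\n",
              sum(x$significant), x$alpha,
              if (x$adjust == "none") "raw" else "BH-adjusted"))
  invisible(x)
}

#' Pathway-level results table
#'
#' @param object A `"pathmix"` fit.
#' @param ... Ignored.
#' @return A `data.frame` (class `"summary.pathmix"`) with one row per
#'   retained pathway -- `pathway_id`, `n_genes_observed`, `t_hat`,
#'   `pvalue`, `padj`, `significant` -- sorted by p-value, ties broken by
#'   pathway ID.
#' @export
summary.pathmix <- function(object, ...) {
  tab <- data.frame(pathway_id = colnames(object$Z),
                    n_genes_observed = as.integer(colSums(object$Z)),
                    t_hat = unname(object$t_hat),
                    pvalue = unname(object$pvalue),
                    padj = unname(object$padj),
                    significant = unname(object$significant),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$pvalue, tab$pathway_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "alpha") <- object$alpha
  class(tab) <- c("summary.pathmix", "data.frame")
  tab
}

#' @export
print.summary.pathmix <- function(x, n = 10L, ...) {
  cat("Top pathways (alpha =", attr(x, "alpha"), "):\n")
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more pathway(s)\n")
  invisible(x)
}

#' @export
coef.pathmix <- function(object, ...) {
  c("(Intercept)" = object$mu_hat, object$t_hat)
}

#' @export
fitted.pathmix <- function(object, ...) {
  f <- object$mu_hat + drop(object$Z %*% object$t_hat)
  names(f) <- rownames(object$Z)
  f
}

#' @export
residuals.pathmix <- function(object, ...) {
  r <- object$gene_effects$y - fitted(object)
  names(r) <- rownames(object$Z)
  r
}

#' Predicted gene-level responses
#'
#' Returns fitted values `mu_hat + Z t_hat` for the model's genes, or for a
#' new incidence matrix over the same pathways.
#'
#' @param object A `"pathmix"` fit.
#' @param newZ Optional incidence matrix whose columns match the retained
#'   pathways of the fit.
#' @param ... Ignored.
#' @return Numeric vector of predictions.
#' @export
predict.pathmix <- function(object, newZ = NULL, ...) {
  if (is.null(newZ)) return(fitted(object))
  newZ <- as.matrix(newZ)
  if (ncol(newZ) != length(object$t_hat))
    stop("newZ must have one column per retained pathway (",
         length(object$t_hat), ")")
  object$mu_hat + drop(newZ %*% object$t_hat)
}

#' Simulate gene-level responses from a fitted model
#'
#' Draws new response vectors from the fitted generative model
#' `y* = 1*mu_hat + Z t* + e*` with `t* ~ N(0, V*sigma_t2)` and
#' `e* ~ N(0, I*sigma_e2)`, using the fit's incidence and covariance.
#'
#' @param object A `"pathmix"` fit.
#' @param nsim Number of replicate response vectors.
#' @param seed Optional integer seed.
#' @param ... Ignored.
#' @return A `data.frame` with `nrow(Z)` rows and `nsim` columns
#'   (`sim_1`, ...), as for `stats::simulate`.
#' @export
simulate.pathmix <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(object$Z)
  p <- ncol(object$Z)
  Lv <- chol(object$V + diag(1e-10, p))
  st <- sqrt(object$variance$sigma_t2)
  se <- sqrt(object$variance$sigma_e2)
  out <- vapply(seq_len(nsim), function(k) {
    tstar <- drop(crossprod(Lv, stats::rnorm(p))) * st
    object$mu_hat + drop(object$Z %*% tstar) + stats::rnorm(n, sd = se)
  }, numeric(n))
  out <- as.data.frame(matrix(out, nrow = n))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- rownames(object$Z)
  out
}

#' Plot predicted pathway effects
#'
#' Plots the predicted effect of each retained pathway in model order, with
#' pathways significant at the fit's alpha highlighted and the one-sided
#' significance threshold `sigma_t * qnorm(1 - alpha)` drawn as a reference
#' line.
#'
#' @param x A `"pathmix"` fit.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pathmix <- function(x, ...) {
  p <- length(x$t_hat)
  thr <- sqrt(x$variance$sigma_t2) * stats::qnorm(1 - x$alpha)
  graphics::plot(seq_len(p), x$t_hat,
                 col = ifelse(x$significant, "blue", "grey40"),
                 pch = 19, xlab = "pathway (model order)",
                 ylab = expression(hat(t)), ...)
  graphics::abline(h = c(0, thr), lty = c(1, 2), col = c("black", "blue"))
  invisible(x)
}
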