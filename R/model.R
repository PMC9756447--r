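#' Jaccard similarity between two gene sets
#'
#' `J(i, j) = M / N` where M is the number of genes shared by the two sets
#' and N the total number of distinct genes involved in either (the union).
#'
#' @param set_i,set_j Non-empty character vectors of gene IDs.
#' @return A number in \[0, 1\].
#' @examples
#' jaccard(c("A", "B", "C"), c("B", "C", "D"))  # 2 shared / 4 total = 0.5
#' @export
jaccard <- function(set_i, set_j) {
  set_i <- unique(as.character(set_i))
  set_j <- unique(as.character(set_j))
  if (length(set_i) == 0L || length(set_j) == 0L)
    stop("jaccard is undefined for empty gene sets")
  m <- length(intersect(set_i, set_j))
  m / (length(set_i) + length(set_j) - m)
}

#' Jaccard covariance matrix between pathways
#'
#' Builds the symmetric pathway-similarity matrix V with `V[i, j]` the
#' Jaccard coefficient of gene sets i and j, so V has unit diagonal and
#' entries in \[0, 1\]. The Jaccard coefficient is a positive semidefinite
#' kernel, so V is a valid random-effect covariance; off-diagonal entries
#' equal to 1 (duplicate gene sets) make it singular and trigger a warning
#' here and regularisation downstream in the solver.
#'
#' Computed vectorised over the gene-by-pathway membership matrix, so it
#' scales to hundreds of pathways over thousands of genes.
#'
#' @param pathways A [pathway_collection()] (the retained pathways, in
#'   model order).
#' @return A symmetric numeric matrix with pathway IDs as dimnames.
#' @export
build_covariance <- function(pathways) {
  stopifnot(inherits(pathways, "pathway_collection"))
  p <- length(pathways)
  all_genes <- unique(unlist(pathways$genes))
  M <- vapply(pathways$genes, function(g) as.numeric(all_genes %in% g),
              numeric(length(all_genes)))
  M <- matrix(M, ncol = p)
  inter <- crossprod(M)
  sizes <- colSums(M)
  uni <- outer(sizes, sizes, "+") - inter
  V <- inter / uni
  V <- (V + t(V)) / 2  # kill rounding asymmetry
  diag(V) <- 1
  dimnames(V) <- list(pathways$pathway_id, pathways$pathway_id)
  dup <- which(V == 1 & upper.tri(V), arr.ind = TRUE)
  if (nrow(dup))
    warning("identical gene sets (Jaccard = 1): ",
            paste(utils::head(
              paste(rownames(V)[dup[, 1]], colnames(V)[dup[, 2]],
                    sep = " = "), 5L), collapse = ", "),
            "; covariance is singular and will be regularised")
  V
}

#' Partition the response variance into pathway and residual components
#'
#' Variance components are assumed known rather than estimated: the total
#' variance is the unbiased (n-1 denominator) sample variance of the
#' gene-level response y, of which a fixed fraction `ratio_t` (default 0.3)
#' is attributed to pathway effects and the remainder to residuals.
#'
#' @param y Numeric gene-level response vector (length >= 2, non-constant).
#' @param ratio_t Pathway fraction of the total variance, in (0, 1).
#' @return An object of class `"variance_partition"`: a list with
#'   `sigma_y2`, `ratio_t`, `sigma_t2`, `sigma_e2`.
#' @export
partition_variance <- function(y, ratio_t = 0.3) {
  if (length(y) < 2L) stop("need at least 2 observations to partition variance")
  if (!is.numeric(ratio_t) || length(ratio_t) != 1L ||
      ratio_t <= 0 || ratio_t >= 1)
    stop("ratio_t must be a single number in (0, 1)")
  s2 <- stats::var(y)
  if (!is.finite(s2) || s2 <= 0)
    stop("response vector is constant; variance cannot be partitioned")
  structure(list(sigma_y2 = s2, ratio_t = ratio_t,
                 sigma_t2 = ratio_t * s2,
                 sigma_e2 = (1 - ratio_t) * s2),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf(
    "Variance partition: sigma_y2 = %.6g; sigma_t2 = %.6g (%.0f%%), sigma_e2 = %.6g (%.0f%%)\n",
    x$sigma_y2, x$sigma_t2, 100 * x$ratio_t, x$sigma_e2,
    100 * (1 - x$ratio_t)))
  invisible(x)
}

#' Solve Henderson's mixed model equations
#'
#' Jointly computes the generalized-least-squares estimate of the general
#' mean and the best linear unbiased prediction (BLUP) of the pathway
#' effects for the model `y = 1*mu + Z*t + e`, with `t ~ N(0, V*sigma_t2)`
#' and `e ~ N(0, I*sigma_e2)`. The (p+1)-dimensional coefficient system
#'
#' \deqn{\left[\begin{array}{cc} 1'R^{-1}1 & 1'R^{-1}Z \\
#'   Z'R^{-1}1 & Z'R^{-1}Z + G^{-1} \end{array}\right]
#'   \left[\begin{array}{c} \hat\mu \\ \hat t \end{array}\right] =
#'   \left[\begin{array}{c} 1'R^{-1}y \\ Z'R^{-1}y \end{array}\right]}
#'
#' with `R = I*sigma_e2` and `G = V*sigma_t2` is factorised directly by a
#' symmetric positive-definite (Cholesky) decomposition; no iterative solver
#' is needed at typical pathway counts (a few hundred). If V (or the
#' coefficient matrix) is numerically singular -- e.g. duplicate gene
#' sets -- `jitter * I` is added to V once and reported; if the system is
#' still singular the offending pathway pairs are named in the error.
#'
#' @param y Numeric gene-level response vector.
#' @param Z Binary gene-by-pathway incidence matrix (rows match `y`).
#' @param V Pathway covariance matrix from [build_covariance()].
#' @param vp A `"variance_partition"` from [partition_variance()].
#' @param jitter Non-negative ridge added to V's diagonal when singular
#'   (default `1e-8`); strict mode `jitter = 0` errors instead.
#' @return A list with `mu_hat`, named vector `t_hat`, and `diagnostics`
#'   (`rcond`: reciprocal condition estimate of the coefficient matrix;
#'   `jitter_applied`: the ridge actually used, 0 if none).
#' @export
solve_mme <- function(y, Z, V, vp, jitter = 1e-8) {
  stopifnot(inherits(vp, "variance_partition"))
  Z <- as.matrix(Z)
  V <- as.matrix(V)
  n <- length(y)
  p <- ncol(Z)
  if (nrow(Z) != n)
    stop("non-conforming dimensions: length(y) = ", n,
         " but nrow(Z) = ", nrow(Z))
  if (nrow(V) != p || ncol(V) != p)
    stop("non-conforming dimensions: ncol(Z) = ", p,
         " but V is ", nrow(V), "x", ncol(V))
  if (!is.numeric(jitter) || jitter < 0)
    stop("jitter must be a non-negative number")

  inv_e <- 1 / vp$sigma_e2
  build <- function(Vj) {
    Vinv <- tryCatch(chol2inv(chol(Vj)), error = function(e) NULL)
    if (is.null(Vinv)) return(NULL)
    C <- matrix(0, p + 1L, p + 1L)
    C[1L, 1L] <- n * inv_e
    zc <- colSums(Z) * inv_e
    C[1L, -1L] <- zc
    C[-1L, 1L] <- zc
    C[-1L, -1L] <- crossprod(Z) * inv_e + Vinv / vp$sigma_t2
    C
  }
  jitter_applied <- 0
  C <- build(V)
  L <- if (is.null(C)) NULL else tryCatch(chol(C), error = function(e) NULL)
  if (is.null(L) && jitter > 0) {
    jitter_applied <- jitter
    message("solve_mme: coefficient matrix singular; adding jitter ",
            format(jitter), " * I to V")
    C <- build(V + diag(jitter, p))
    L <- if (is.null(C)) NULL else tryCatch(chol(C), error = function(e) NULL)
  }
  if (is.null(L)) {
    dup <- which(V == 1 & upper.tri(V), arr.ind = TRUE)
    hint <- if (nrow(dup))
      paste0("; duplicate gene sets: ",
             paste(paste(rownames(V)[dup[, 1]], colnames(V)[dup[, 2]],
                         sep = " = "), collapse = ", "))
    else ""
    stop("mixed model equations are singular even after jitter", hint)
  }
  rhs <- c(sum(y), crossprod(Z, y)) * inv_e
  sol <- backsolve(L, backsolve(L, rhs, transpose = TRUE))
  t_hat <- sol[-1L]
  names(t_hat) <- colnames(Z)
  list(mu_hat = sol[1L], t_hat = t_hat,
       diagnostics = list(rcond = 1 / kappa(C, exact = FALSE),
                          jitter_applied = jitter_applied))
}

#' One-sided pathway significance
#'
#' Each predicted pathway effect is tested against `H0: t_i <= 0` versus
#' `H1: t_i > 0` by the probability of a more extreme (larger) value under
#' the prior null density `N(0, sigma_t2)`:
#' `p_i = 1 - Phi(t_hat_i / sigma_t)`. Only positive predicted effects can
#' reach small p-values; the test uses the prior standard deviation of the
#' pathway effects, not the prediction-error variance of the BLUP, and is
#' therefore conservative for shrunken predictors (see the package
#' vignette).
#'
#' @param t_hat Numeric vector of predicted pathway effects.
#' @param vp A `"variance_partition"` (supplies `sigma_t2 > 0`).
#' @return Vector of upper-tail p-values in (0, 1), same names as `t_hat`.
#' @export
pathway_pvalues <- function(t_hat, vp) {
  stopifnot(inherits(vp, "variance_partition"), vp$sigma_t2 > 0)
  stats::pnorm(t_hat, mean = 0, sd = sqrt(vp$sigma_t2), lower.tail = FALSE)
}

#' Multiple-testing adjustment for pathway p-values
#'
#' The default is no adjustment (raw per-pathway p-values are reported);
#' Benjamini-Hochberg step-up FDR control is available as `"bh"`.
#'
#' @param pvalues Numeric vector of p-values.
#' @param method `"none"` or `"bh"`.
#' @return Adjusted p-values, same length and names.
#' @export
adjust_pvalues <- function(pvalues, method = c("none", "bh")) {
  method <- match.arg(method)
  if (method == "none") return(pvalues)
  stats::p.adjust(pvalues, method = "BH")
}
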