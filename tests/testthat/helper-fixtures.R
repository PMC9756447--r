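# Shared fixtures and independent oracles.

# Dense GLS/BLUP closed form: the textbook equivalent of the mixed model
# equations, computed through the full n x n marginal covariance so it is
# independent of the solver's (p+1)-dimensional factorization.
gls_oracle <- function(y, Z, V, sigma_t2, sigma_e2) {
  n <- length(y)
  G <- V * sigma_t2
  Sigma <- Z %*% G %*% t(Z) + diag(sigma_e2, n)
  Si <- solve(Sigma)
  one <- rep(1, n)
  mu <- drop((t(one) %*% Si %*% y) / (t(one) %*% Si %*% one))
  t_hat <- unname(drop(G %*% t(Z) %*% Si %*% (y - mu)))
  list(mu_hat = mu, t_hat = t_hat)
}

# Random family of gene sets drawn from a shared pool, so the resulting
# Jaccard matrix has genuinely mixed overlaps.
random_geneset_family <- function(p, pool_size = 40L, min_size = 3L,
                                  max_size = 12L) {
  pool <- sprintf("G%03d", seq_len(pool_size))
  genes <- lapply(seq_len(p), function(i)
    sample(pool, sample(min_size:max_size, 1L)))
  pathway_collection(sprintf("p%02d", seq_len(p)),
                     rep("", p), genes)
}

# Random small model instance with every gene in at least one pathway.
random_instance <- function(n_max = 30L, p_max = 8L) {
  n <- sample(4:n_max, 1L)
  p <- sample(2:p_max, 1L)
  Z <- matrix(rbinom(n * p, 1L, 0.35), n, p)
  empty_rows <- rowSums(Z) == 0
  Z[cbind(which(empty_rows), sample.int(p, sum(empty_rows),
                                        replace = TRUE))] <- 1L
  dimnames(Z) <- list(sprintf("g%02d", seq_len(n)),
                      sprintf("p%02d", seq_len(p)))
  fam <- random_geneset_family(p)
  V <- suppressWarnings(build_covariance(fam))
  y <- abs(rnorm(n, mean = 1, sd = 0.3))
  list(y = y, Z = Z, V = V)
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# A 3-gene / 2-pathway toy study whose every intermediate is known by hand.
toy_study <- function() {
  list(
    stats = data.frame(
      snp_id = c("s1", "s2", "s3", "s4"),
      chrom = c("1", "1", "1", "2"),
      pos = c(150L, 180L, 1150L, 2150L),
      effect = c(0.1, -0.5, 0.2, 0.3),
      se = c(0.1, 0.1, 0.1, 0.1),
      pvalue = c(0.4, 0.01, 0.2, 0.1),
      stringsAsFactors = FALSE),
    genes = data.frame(
      gene_id = c("g1", "g2", "g3"),
      chrom = c("1", "1", "2"),
      start = c(100L, 1100L, 2100L),
      end = c(900L, 1900L, 2900L),
      strand = ".",
      stringsAsFactors = FALSE),
    pathways = pathway_collection(
      c("p1", "p2"), c("first", "second"),
      list(c("g1", "g2"), c("g2", "g3"))))
}
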