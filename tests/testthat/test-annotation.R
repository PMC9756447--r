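test_that("positional assignment respects boundaries and the flank window", {
  genes <- data.frame(gene_id = "g1", chrom = "1", start = 100L, end = 200L,
                      strand = ".", stringsAsFactors = FALSE)
  mk <- function(pos) data.frame(snp_id = "s1", chrom = "1", pos = pos,
                                 effect = 0.1, se = NA_real_,
                                 pvalue = NA_real_)
  expect_equal(nrow(assign_snps_to_genes(mk(150L), genes)), 1L)
  expect_equal(nrow(assign_snps_to_genes(mk(100L), genes)), 1L)
  expect_equal(nrow(assign_snps_to_genes(mk(200L), genes)), 1L)
  expect_equal(nrow(assign_snps_to_genes(mk(99L), genes)), 0L)
  expect_equal(nrow(assign_snps_to_genes(mk(99L), genes, flank_bp = 1L)), 1L)
  expect_equal(nrow(assign_snps_to_genes(mk(201L), genes, flank_bp = 1L)), 1L)
  # chromosome must match even if the position falls inside the interval
  other <- mk(150L)
  other$chrom <- "2"
  expect_equal(nrow(assign_snps_to_genes(other, genes)), 0L)
})

test_that("a SNP inside nested or overlapping genes represents each of them", {
  genes <- data.frame(gene_id = c("outer", "inner"), chrom = "1",
                      start = c(100L, 140L), end = c(300L, 160L),
                      strand = ".", stringsAsFactors = FALSE)
  stats <- data.frame(snp_id = "s1", chrom = "1", pos = 150L, effect = 0.2,
                      se = NA_real_, pvalue = NA_real_)
  asn <- assign_snps_to_genes(stats, genes)
  expect_equal(asn$gene_id, c("inner", "outer"))
  expect_equal(asn$snp_id, c("s1", "s1"))
})

test_that("per-gene collapsing keeps the strongest SNP with full tie-breaks", {
  stats <- data.frame(
    snp_id = c("a", "b", "c", "d", "e"),
    chrom = "1", pos = 1:5,
    effect = c(0.1, -0.5, 0.2, 0.3, -0.3),
    se = NA_real_,
    pvalue = c(NA, NA, NA, 0.04, 0.01),
    stringsAsFactors = FALSE)
  asn <- data.frame(snp_id = c("a", "b", "c"), gene_id = "g1")
  ge <- select_top_snp_per_gene(stats, asn)
  expect_equal(ge$snp_id, "b")      # largest |effect| wins
  expect_equal(ge$y, 0.5)           # response is the absolute effect

  one <- select_top_snp_per_gene(stats,
                                 data.frame(snp_id = "e", gene_id = "g2"))
  expect_equal(one$y, 0.3)

  # |effect| tie: smaller p-value wins
  tie <- data.frame(snp_id = c("d", "e"), gene_id = "g3")
  expect_equal(select_top_snp_per_gene(stats, tie)$snp_id, "e")

  # |effect| and p both tied: lexicographic snp_id
  stats2 <- stats
  stats2$pvalue <- 0.5
  expect_equal(select_top_snp_per_gene(stats2, tie)$snp_id, "d")
})

test_that("min_pvalue criterion selects by p and demands p-values", {
  stats <- data.frame(snp_id = c("a", "b"), chrom = "1", pos = 1:2,
                      effect = c(0.9, 0.1), se = NA_real_,
                      pvalue = c(0.2, 0.01), stringsAsFactors = FALSE)
  asn <- data.frame(snp_id = c("a", "b"), gene_id = "g1")
  ge <- select_top_snp_per_gene(stats, asn, criterion = "min_pvalue")
  expect_equal(ge$snp_id, "b")
  stats$pvalue[2] <- NA
  expect_error(select_top_snp_per_gene(stats, asn, criterion = "min_pvalue"),
               "p-value")
})

test_that("collapsing is idempotent and invariant to input row order", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    stats <- data.frame(
      snp_id = sprintf("s%02d", sample(n)),
      chrom = "1", pos = seq_len(n),
      effect = round(rnorm(n), 2),  # rounding forces occasional ties
      se = NA_real_,
      pvalue = round(runif(n), 2),
      stringsAsFactors = FALSE)
    asn <- data.frame(snp_id = stats$snp_id,
                      gene_id = sprintf("g%d", sample(1:4, n, replace = TRUE)))
    ref <- select_top_snp_per_gene(stats, asn)
    perm <- sample(n)
    shuffled <- select_top_snp_per_gene(stats[perm, ], asn[sample(n), ])
    expect_identical(shuffled, ref)
    # feeding the winners back in changes nothing
    again <- select_top_snp_per_gene(
      stats[stats$snp_id %in% ref$snp_id, ],
      asn[asn$snp_id %in% ref$snp_id, ])
    expect_identical(again, ref)
  }
})

test_that("incidence matrix encodes membership with correct margins", {
  ge <- data.frame(gene_id = c("g1", "g2"), snp_id = c("s1", "s2"),
                   chrom = "1", pos = 1:2, effect = c(0.1, 0.2),
                   y = c(0.1, 0.2), stringsAsFactors = FALSE)
  pc <- pathway_collection(c("p1", "p2"), c("", ""),
                           list(c("g1", "g2"), c("g2", "gX")))
  inc <- build_incidence(ge, pc)
  expect_equal(unname(inc$Z), matrix(c(1, 1, 0, 1), 2, 2))
  expect_equal(rownames(inc$Z), c("g1", "g2"))
  expect_equal(inc$gene_effects$pathways, list("p1", c("p1", "p2")))
})

test_that("incidence drops unmapped genes and empty pathways as contracted", {
  ge <- data.frame(gene_id = c("g1", "g2", "g9"), snp_id = paste0("s", 1:3),
                   chrom = "1", pos = 1:3, effect = 0.1, y = 0.1,
                   stringsAsFactors = FALSE)
  pc <- pathway_collection(c("p1", "p3"), c("", ""),
                           list(c("g1", "g2"), c("gA", "gB")))
  expect_message(inc <- build_incidence(ge, pc), "dropping")
  expect_equal(dim(inc$Z), c(2L, 1L))
  expect_equal(inc$dropped_pathways, "p3")
  expect_equal(length(inc$retained), 1L)

  kept <- suppressMessages(build_incidence(ge, pc, keep_unmapped = TRUE))
  expect_equal(nrow(kept$Z), 3L)
  expect_equal(unname(rowSums(kept$Z)["g9" == rownames(kept$Z)]), 0)

  none <- pathway_collection("p1", "", list(c("zz")))
  expect_error(build_incidence(ge, none), "no overlap")
})

test_that("incidence margins match the pathway collection on random studies", {
  set.seed(11)
  for (rep in 1:10) {
    cfg <- sim_config(n_pathways = sample(3:8, 1),
                      genes_per_pathway = c(4L, 10L),
                      overlap_fraction = runif(1, 0, 0.4),
                      snps_per_gene = 1L, seed = rep)
    sim <- simulate_study(cfg)
    asn <- assign_snps_to_genes(sim$stats, sim$genes)
    ge <- select_top_snp_per_gene(sim$stats, asn)
    inc <- suppressMessages(build_incidence(ge, sim$pathways))
    # row sums = number of pathways containing the gene
    for (i in seq_len(nrow(inc$Z))) {
      gid <- rownames(inc$Z)[i]
      expect_equal(sum(inc$Z[i, ]),
                   sum(vapply(sim$pathways$genes, function(g) gid %in% g,
                              logical(1))))
    }
    # column sums = observed genes per pathway
    for (j in seq_len(ncol(inc$Z))) {
      pid <- colnames(inc$Z)[j]
      members <- sim$pathways$genes[[match(pid, sim$pathways$pathway_id)]]
      expect_equal(sum(inc$Z[, j]), sum(inc$gene_effects$gene_id %in% members))
    }
  }
})

test_that("a precomputed SNP-gene map replaces positional assignment", {
  toy <- toy_study()
  map_path <- write_tsv_fixture(c("snp_id\tgene_id",
                                  "s1\tg1", "s2\tg1", "s3\tg2", "s4\tg3"))
  fit_map <- suppressMessages(pathmix(toy$stats, toy$pathways,
                                      snp_gene_map = map_path))
  fit_pos <- suppressMessages(pathmix(toy$stats, toy$pathways,
                                      gene_models = toy$genes))
  expect_equal(fit_map$t_hat, fit_pos$t_hat)
  expect_error(pathmix(toy$stats, toy$pathways), "exactly one")
  expect_error(pathmix(toy$stats, toy$pathways, gene_models = toy$genes,
                       snp_gene_map = map_path), "exactly one")
})
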