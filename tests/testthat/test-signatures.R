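test_that("per-cell signature scores are row-subset means", {
  mat <- toy_matrix(rbind(G1 = c(2, 4), G2 = c(4, 0), G3 = c(9, 9)),
                    genes = c("G1", "G2", "G3"))
  s <- cell_set_score(mat, c("G1", "G2"))
  expect_equal(unname(as.numeric(s)), c(3, 2))
  expect_equal(attr(s, "n_genes_used"), 2L)
  # a one-gene set is the gene's own row
  expect_equal(unname(as.numeric(cell_set_score(mat, "G3"))), c(9, 9))
  # brute force on a random matrix, genes outside the matrix ignored
  set.seed(28)
  mat2 <- random_matrix(30, 12)
  set <- c(sample(rownames(mat2), 7), "NOT_THERE")
  s2 <- cell_set_score(mat2, set)
  expect_equal(unname(as.numeric(s2)),
               unname(colMeans(em_values(mat2)[intersect(set, rownames(mat2)), ])))
  expect_error(cell_set_score(mat, c("Z1", "Z2")), "intersect")
})

test_that("signature scores are linear in the expression matrix", {
  set.seed(29)
  a <- random_matrix(20, 10)
  b <- random_matrix(20, 10)
  ab <- toy_matrix(em_values(a) + em_values(b))
  set <- rownames(a)[1:6]
  expect_equal(as.numeric(cell_set_score(ab, set)),
               as.numeric(cell_set_score(a, set)) +
                 as.numeric(cell_set_score(b, set)))
})

test_that("score correlations behave on exact, null and coupled data", {
  set.seed(30)
  a <- stats::setNames(rnorm(1000), paste0("c", 1:1000))
  # exact linear dependence
  expect_equal(score_correlation(a, 2 * a)$estimate, 1)
  # independent scores stay near zero
  b <- stats::setNames(rnorm(1000), names(a))
  expect_lt(abs(score_correlation(a, b)$estimate), 0.1)
  # zero-variance flagged, not an error
  flat <- stats::setNames(rep(1, 1000), names(a))
  expect_false(score_correlation(a, flat)$defined)
  # pearson on standardized scores equals their covariance
  za <- (a - mean(a)) / stats::sd(a)
  zb <- (b - mean(b)) / stats::sd(b)
  expect_equal(score_correlation(za, zb)$estimate,
               unname(stats::cov(za, zb)), tolerance = 1e-12)
  # unmatched cells dropped and counted
  short <- a[1:500]
  cc <- score_correlation(short, b)
  expect_equal(cc$n, 500L)
  expect_equal(cc$n_dropped, 500L)
})

test_that("a shared latent factor induces the designed score coupling", {
  sim <- generate(simulation_spec(
    n_genes = 300, set_sizes = rep(30L, 5),
    cell_types = c(mal = 400L), malignant_types = "mal", n_tumors = 1L,
    tumor_effect_sd = 0, dropout = NULL, library_size_sd = 0,
    base_mean = 6, base_sd = 1, tpm_normalize = FALSE,
    latent_loadings = c(PATHWAY_01 = 0.7, PATHWAY_02 = 0.5),
    seed = 41))
  s1 <- cell_set_score(sim$matrix, sim$gene_sets$PATHWAY_01)
  s2 <- cell_set_score(sim$matrix, sim$gene_sets$PATHWAY_02)
  got <- score_correlation(s1, s2)$estimate
  # generative correlation of the two set means: both driven by the
  # same N(0,1) latent against independent gene noise averaged over
  # 30 genes per set
  l1 <- 0.7; l2 <- 0.5; nse <- 1 / 30
  expected <- (l1 * l2) / sqrt((l1^2 + nse) * (l2^2 + nse))
  expect_equal(got, expected, tolerance = 0.1)
  expect_gt(got, 0.5)
})

test_that("pairwise gene correlations summarize shared structure", {
  set.seed(31)
  # the same gene on both sides correlates exactly 1
  mat <- random_matrix(10, 30)
  single <- pairwise_gene_correlations(mat, "g1", "g1")
  expect_equal(unname(single$correlations[1, 1]), 1)

  # independent genes: about half the pairs positive
  big <- toy_matrix(matrix(rnorm(40 * 300, 8, 1), 40, 300))
  pg <- pairwise_gene_correlations(big, rownames(big)[1:20],
                                   rownames(big)[21:40])
  expect_gt(pg$fraction_positive, 0.35)
  expect_lt(pg$fraction_positive, 0.65)

  # a shared factor drives most pairs positive
  latent <- rnorm(300)
  coupled <- toy_matrix(matrix(rnorm(40 * 300, 8, 1), 40, 300) +
                          matrix(rep(latent, each = 40), 40))
  pc <- pairwise_gene_correlations(coupled, rownames(coupled)[1:20],
                                   rownames(coupled)[21:40])
  expect_gt(pc$fraction_positive, 0.8)

  # constant genes are excluded with a warning
  cm <- em_values(big); cm[1, ] <- 2
  expect_warning(
    pairwise_gene_correlations(toy_matrix(cm), rownames(big)[1:5],
                               rownames(big)[6:10]),
    "constant")
})

test_that("relative mutual information is 1 for matched partitions", {
  a <- rep(c("x", "y", "z"), each = 10)
  expect_equal(as.numeric(relative_mutual_information(a, a)), 1)
  renamed <- c(x = "k1", y = "k2", z = "k3")[a]
  expect_equal(as.numeric(relative_mutual_information(a, renamed)), 1)
  # a refinement of the coarser partition still scores 1 under min-entropy
  fine <- paste0(a, rep(1:2, 15))
  expect_equal(as.numeric(relative_mutual_information(a, fine)), 1,
               tolerance = 1e-12)
  # symmetry
  set.seed(32)
  b <- sample(c("p", "q"), 30, replace = TRUE)
  expect_equal(relative_mutual_information(a, b),
               relative_mutual_information(b, a))
  # degenerate single-cluster agreement
  one <- relative_mutual_information(rep("u", 5), rep("v", 5))
  expect_equal(as.numeric(one), 1)
  expect_true(attr(one, "degenerate"))
})

test_that("independent labelings have near-zero relative MI", {
  set.seed(33)
  vals <- replicate(20, {
    a <- sample(paste0("a", 1:5), 1000, replace = TRUE)
    b <- sample(paste0("b", 1:5), 1000, replace = TRUE)
    as.numeric(relative_mutual_information(a, b))
  })
  expect_true(all(vals < 0.05))
  expect_true(all(vals >= 0))
})
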