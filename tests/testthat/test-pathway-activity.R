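test_that("cell-type means equal brute-force group means", {
  mat <- toy_matrix(matrix(c(1, 3, 2, 4), 1, 4))
  ann <- toy_annotation(colnames(mat), c("A", "A", "B", "B"))
  E <- celltype_means(mat, ann)
  expect_equal(unname(E[1, ]), c(2, 3))

  set.seed(9)
  mat2 <- random_matrix(30, 40)
  types <- sample(c("A", "B", "C"), 40, replace = TRUE)
  E2 <- celltype_means(mat2, types)
  for (ty in c("A", "B", "C")) {
    brute <- rowMeans(em_values(mat2)[, types == ty, drop = FALSE])
    expect_equal(unname(E2[, ty]), unname(brute))
  }

  # one cell per type: means are the cells themselves
  E3 <- celltype_means(mat2[, 1:3], c("x", "y", "z"))
  expect_equal(unname(E3), unname(em_values(mat2[, 1:3])))
})

test_that("relative expression divides by the across-type mean", {
  E <- rbind(a = c(2, 2, 2), b = c(1, 3, 2), z = c(0, 0, 0))
  re <- relative_expression(E)
  expect_equal(unname(re$r["a", ]), c(1, 1, 1))
  expect_equal(unname(re$r["b", ]), c(0.5, 1.5, 1))
  expect_false(re$valid["z"])
  expect_true(all(is.na(re$r["z", ])))
})

test_that("relative expression rows average to exactly 1", {
  set.seed(10)
  for (i in 1:100) {
    E <- matrix(stats::rlnorm(20 * 4), 20, 4,
                dimnames = list(paste0("g", 1:20), paste0("t", 1:4)))
    re <- relative_expression(E)
    expect_lt(max(abs(rowMeans(re$r[re$valid, ]) - 1)), 1e-12)
  }
})

test_that("gene weights are reciprocal set-membership counts", {
  gs <- gene_set_collection(list(P = c("a", "b"), Q = c("b", "c")))
  w <- gene_weights(gs)
  expect_equal(unname(w[c("a", "b", "c")]), c(1, 0.5, 1))
})

test_that("the weighted two-gene pathway score matches hand arithmetic", {
  # gene a only in P (w = 1), gene b shared with Q (w = 1/2);
  # r(a) = (2, 0), r(b) = (0, 2)  ->  P scores (4/3, 2/3)
  gs <- gene_set_collection(list(P = c("a", "b"), Q = c("b", "c")))
  r <- rbind(a = c(2, 0), b = c(0, 2))
  colnames(r) <- c("t1", "t2")
  relexpr <- list(r = r, valid = c(a = TRUE, b = TRUE))
  ps <- pathway_scores(relexpr, gs)
  p_scores <- ps$score[ps$pathway == "P"]
  expect_equal(p_scores[ps$group[ps$pathway == "P"] == "t1"], 4 / 3,
               tolerance = 0)
  expect_equal(p_scores[ps$group[ps$pathway == "P"] == "t2"], 2 / 3,
               tolerance = 0)
})

test_that("all-average relative expression gives unit pathway scores", {
  gs <- gene_set_collection(list(P = paste0("g", 1:5),
                                 Q = paste0("g", 4:8)))
  r <- matrix(1, 8, 3, dimnames = list(paste0("g", 1:8), paste0("t", 1:3)))
  ps <- pathway_scores(list(r = r, valid = rep(TRUE, 8)), gs)
  expect_equal(ps$score, rep(1, 6))
  expect_equal(unique(ps$n_outliers), 0L)
})

test_that("outlier genes are excluded pathway-wide and scores recomputed", {
  set.seed(12)
  genes <- paste0("g", 1:6)
  r <- matrix(stats::runif(12, 0.8, 1.2), 6, 2,
              dimnames = list(genes, c("t1", "t2")))
  r <- r / rowMeans(r)
  r["g6", ] <- c(100, 100) * r["g6", ]   # wild gene
  gs <- gene_set_collection(list(P = genes))
  ps <- pathway_scores(list(r = r, valid = rep(TRUE, 6)), gs)
  expect_equal(attr(ps, "outliers")$P, "g6")
  expect_equal(ps$n_genes_used, c(5L, 5L))
  # brute force after removal (all weights are 1)
  expect_equal(ps$score, as.vector(colMeans(r[1:5, ])))
  # weighted-average bounds over surviving genes
  expect_true(all(ps$score >= apply(r[1:5, ], 2, min) - 1e-12))
  expect_true(all(ps$score <= apply(r[1:5, ], 2, max) + 1e-12))
})

test_that("a pathway with no surviving genes is flagged, not zero", {
  gs <- gene_set_collection(list(P = "absent_gene"))
  r <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("t1", "t2")))
  ps <- pathway_scores(list(r = r, valid = c(TRUE, TRUE)), gs)
  expect_true(all(is.na(ps$score)))
})

test_that("pathway scores are invariant to duplicating every cell", {
  set.seed(13)
  mat <- random_matrix(40, 30)
  types <- rep(c("A", "B", "C"), each = 10)
  gs <- gene_set_collection(list(P = paste0("g", 1:10),
                                 Q = paste0("g", 8:20)))
  score_of <- function(m, ty) {
    re <- relative_expression(celltype_means(m, ty))
    pathway_scores(re, gs)$score
  }
  dup <- toy_matrix(em_values(mat)[, rep(1:30, 2)],
                    cells = sprintf("d%02d", 1:60))
  expect_equal(score_of(dup, rep(types, 2)), score_of(mat, types))
})

test_that("permutation test is reproducible and finds a planted effect", {
  sim <- generate(simulation_spec(
    n_genes = 300, set_sizes = rep(20L, 10),
    cell_types = c(A = 60L, B = 60L, C = 60L),
    malignant_types = character(0), n_tumors = 1L, tumor_effect_sd = 0,
    planted_effects = data.frame(pathway = "PATHWAY_03", cell_type = "B",
                                 log2fc = 1),
    seed = 31))
  pt1 <- permutation_test(sim$matrix, sim$annotation, sim$gene_sets,
                          n_perm = 200, seed = 7)
  pt2 <- permutation_test(sim$matrix, sim$annotation, sim$gene_sets,
                          n_perm = 200, seed = 7)
  expect_identical(pt1$p_value, pt2$p_value)
  expect_identical(pt1$score, pt2$score)

  hit <- pt1[pt1$pathway == "PATHWAY_03" & pt1$group == "B", ]
  expect_gt(hit$score, 1)
  expect_lt(hit$p_value, 0.01)

  # directional p is at most the two-sided p
  ptd <- permutation_test(sim$matrix, sim$annotation, sim$gene_sets,
                          n_perm = 200, seed = 7, p_type = "directional")
  expect_true(all(ptd$p_value <= pt1$p_value + 1e-12))

  expect_error(permutation_test(sim$matrix, rep("A", ncol(sim$matrix)),
                                sim$gene_sets, n_perm = 200), "2 groups")
  expect_error(permutation_test(sim$matrix, sim$annotation,
                                sim$gene_sets, n_perm = 10), "at least 100")
})

test_that("bulk two-group activity reduces to the same machinery", {
  # identical groups: every score is exactly 1 and p = 1
  m <- matrix(rep(c(3, 7, 1, 5), 8), 4, 8,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:8)))
  gs <- gene_set_collection(list(P = paste0("g", 1:2),
                                 Q = paste0("g", 3:4)))
  ba <- bulk_group_activity(expression_matrix(m, "log2tpm1"),
                            rep(c("tumor", "normal"), each = 4), gs,
                            n_perm = 100, seed = 2)
  expect_equal(ba$score, rep(1, 4))
  expect_equal(ba$p_value, rep(1, 4))

  # doubling one pathway's genes in the tumor group moves its score as
  # hand-computed from the weighted-average definition
  m2 <- m
  m2[1:2, 1:4] <- m2[1:2, 1:4] * 2
  ba2 <- bulk_group_activity(expression_matrix(m2, "log2tpm1"),
                             rep(c("tumor", "normal"), each = 4), gs,
                             n_perm = 100, seed = 2)
  E <- cbind(normal = rowMeans(m2[, 5:8]), tumor = rowMeans(m2[, 1:4]))
  r <- E / rowMeans(E)
  expect_equal(ba2$score[ba2$pathway == "P" & ba2$group == "tumor"],
               mean(r[1:2, "tumor"]))
})
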