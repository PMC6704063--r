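lengths4 <- function(mat, len = 1000) {
  gene_length_table(stats::setNames(rep(len, nrow(mat)), rownames(mat)))
}

test_that("TPM/pseudo-count conversion multiplies by length and inverts", {
  mat <- toy_matrix(matrix(5, 1, 2), unit = "tpm")
  lens <- gene_length_table(c(g1 = 2000))
  cnt <- tpm_counts_convert(mat, lens, "to_counts")
  expect_equal(unname(em_values(cnt)[1, 1]), 10000)
  expect_equal(em_unit(cnt), "counts")
  back <- tpm_counts_convert(cnt, lens, "to_tpm")
  expect_equal(em_values(back), em_values(mat), tolerance = 1e-12)

  expect_error(gene_length_table(c(g1 = 0)), "positive")
  mat2 <- toy_matrix(matrix(1, 2, 2), unit = "tpm")
  expect_error(tpm_counts_convert(mat2, lens, "to_counts"), "g2")
})

test_that("identical cells get unit size factors under every method", {
  m <- matrix(rep(c(5, 80, 200, 12, 40), 60), 5, 60)
  mat <- toy_matrix(m, unit = "counts")
  ann <- toy_annotation(colnames(mat),
                        rep(c("A", "B"), each = 30))
  for (method in c("rle", "tmm", "upper_quartile", "deconvolution")) {
    sf <- size_factors(mat, method, annotation = ann)
    expect_equal(unname(as.numeric(sf)), rep(1, 60), tolerance = 1e-6,
                 label = method)
  }
})

test_that("tripling a cell's counts triples its size factor", {
  set.seed(21)
  m <- matrix(rpois(200 * 50, 20) + 1, 200, 50)
  m[, 2] <- m[, 1] * 3
  mat <- toy_matrix(m, unit = "counts")
  ann <- toy_annotation(colnames(mat), "A")
  for (method in c("rle", "tmm", "upper_quartile", "deconvolution")) {
    sf <- size_factors(mat, method, annotation = ann)
    expect_equal(unname(sf[2] / sf[1]), 3, tolerance = 0.05,
                 label = method)
  }
})

test_that("RLE equals the classic median-of-ratios on dense counts", {
  set.seed(3)
  m <- matrix(rpois(101 * 20, 30) + 1, 101, 20)   # odd gene count: the
  mat <- toy_matrix(m, unit = "counts")           # ratio median is exact
  sf <- size_factors(mat, "rle")
  geo <- exp(rowMeans(log(m)))
  oracle <- apply(m / geo, 2, stats::median)
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(unname(as.numeric(sf)), unname(oracle), tolerance = 1e-10)
})

test_that("size factors are invariant to cell order and count scaling", {
  set.seed(4)
  m <- matrix(rpois(80 * 30, 15) + 1, 80, 30)
  mat <- toy_matrix(m, unit = "counts")
  perm <- sample(ncol(m))
  for (method in c("rle", "tmm", "upper_quartile")) {
    sf <- size_factors(mat, method)
    sfp <- size_factors(mat[, perm], method)
    expect_equal(as.numeric(sfp[colnames(mat)]), unname(as.numeric(sf)),
                 tolerance = 1e-10, label = method)
    sfs <- size_factors(toy_matrix(m * 7, unit = "counts"), method)
    expect_equal(unname(as.numeric(sfs)), unname(as.numeric(sf)),
                 tolerance = 1e-10, label = paste(method, "scaled"))
  }
})

test_that("apply_size_factors divides counts and returns log2(TPM+1)", {
  set.seed(5)
  tpm <- matrix(rpois(30 * 10, 50) + 1, 30, 10)
  mat_tpm <- toy_matrix(tpm + 0, unit = "tpm")
  lens <- lengths4(mat_tpm)
  cnt <- tpm_counts_convert(mat_tpm, lens, "to_counts")

  ones <- structure(stats::setNames(rep(1, 10), colnames(cnt)),
                    method = "rle", class = c("size_factors", "numeric"))
  out <- apply_size_factors(cnt, ones, lens)
  expect_equal(em_values(out), log2(em_values(mat_tpm) + 1),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(em_unit(out), "log2tpm1")

  # a factor of 2 halves that cell's normalized expression
  twos <- ones; twos[3] <- 2
  out2 <- apply_size_factors(cnt, twos, lens)
  expect_equal(2^em_values(out2)[, 3] - 1,
               (2^em_values(out)[, 3] - 1) / 2, tolerance = 1e-9,
               ignore_attr = TRUE)

  # composition with RLE factors on identical cells is the identity
  ident <- toy_matrix(matrix(rep(c(4, 9, 25), 6), 3, 6), unit = "tpm")
  icnt <- tpm_counts_convert(ident, lengths4(ident), "to_counts")
  isf <- size_factors(icnt, "rle")
  iout <- apply_size_factors(icnt, isf, lengths4(ident))
  expect_equal(em_values(iout), log2(em_values(ident) + 1),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("normalization ranking is a tie at zero for identical cells", {
  m <- matrix(rep(c(10, 40, 90, 7), 40), 4, 40)
  mat <- toy_matrix(m, unit = "counts")
  ann <- toy_annotation(colnames(mat), rep(c("A", "B"), each = 20))
  ev <- evaluate_normalizations(mat, ann, lengths4(mat),
                                methods = c("rle", "tmm"))
  expect_equal(ev$score, c(0, 0))

  ev1 <- evaluate_normalizations(mat, ann, lengths4(mat),
                                 methods = "rle")
  expect_equal(nrow(ev1), 1L)
  expect_equal(attr(ev1, "selected"), "rle")
})

test_that("deconvolution ranks first under cell-type composition bias", {
  set.seed(7)
  n_g <- 400; per <- 60; types <- c("A", "B", "C")
  mu <- rlnorm(n_g, 2, 1)
  genes <- sprintf("g%03d", 1:n_g)
  de <- split(1:240, rep(1:3, each = 80))
  cells <- sprintf("c%03d", 1:(per * 3))
  ty <- rep(types, each = per)
  lam <- matrix(mu, n_g, per * 3)
  for (i in 1:3)
    lam[de[[i]], ty == types[i]] <- lam[de[[i]], ty == types[i]] * 6
  truth <- rlnorm(per * 3, 0, 0.3)
  counts <- matrix(rpois(n_g * per * 3, sweep(lam, 2, truth, "*")), n_g,
                   dimnames = list(genes, cells))
  ann <- toy_annotation(cells, ty)
  mat <- expression_matrix(counts + 0, "counts")
  ev <- evaluate_normalizations(mat, ann, lengths4(mat))
  expect_equal(attr(ev, "selected"), "deconvolution")
  expect_equal(ev$method[1], "deconvolution")
})

test_that("cells with no reference-gene counts are a named error", {
  m <- matrix(rpois(40, 5) + 1, 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:4)))
  m[, 2] <- 0
  expect_error(size_factors(expression_matrix(m, "counts"), "rle"), "c2")
})
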