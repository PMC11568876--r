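# Kernel construction and the expected hidden kernel closed forms

test_that("product kernel matches forced arithmetic and the naive loop", {
  x <- diag(2)
  ids <- data.frame(fid = c("F1", "F2"), iid = c("I1", "I2"))
  g <- genotype_matrix(x, ids, data.frame(chrom = 1, id = c("a", "b"), cm = 0,
                                          bp = c(1, 2), allele1 = "A",
                                          allele2 = "C"))
  expect_equal(product_kernel(g)$values, diag(2) / 2, ignore_attr = TRUE)
  g0 <- genotype_matrix(matrix(0, 3, 2), data.frame(fid = paste0("F", 1:3),
                                                    iid = paste0("I", 1:3)),
                        .dummy_variants(2))
  expect_equal(product_kernel(g0)$values, matrix(0, 3, 3), ignore_attr = TRUE)

  g1 <- sim_genotypes(20, 50, seed = 9)
  expect_lt(max(abs(product_kernel(g1)$values -
                      oracle_product_kernel(g1$dosages))), 1e-12)
})

test_that("gaussian kernel: unit diagonal, all-ones limit, naive-loop agreement", {
  g <- sim_genotypes(10, 5, seed = 3)
  k <- gaussian_kernel(g, bandwidth = 2)
  expect_equal(diag(k$values), rep(1, 10))
  expect_lt(max(abs(k$values - oracle_gaussian_kernel(g$dosages, 2))), 1e-12)
  khuge <- gaussian_kernel(g, bandwidth = 1e8)
  expect_true(all(khuge$values >= 1 - 1e-4))
  expect_error(gaussian_kernel(g, bandwidth = 0), "positive")
})

test_that("polynomial kernel reduces to the product kernel and matches the naive loop", {
  g <- sim_genotypes(8, 4, seed = 4)
  expect_equal(polynomial_kernel(g, degree = 1, offset = 0)$values,
               product_kernel(g)$values)
  g0 <- genotype_matrix(matrix(0, 3, 4), data.frame(fid = paste0("F", 1:3),
                                                    iid = paste0("I", 1:3)),
                        .dummy_variants(4))
  expect_equal(polynomial_kernel(g0, degree = 2, offset = 1)$values,
               matrix(1, 3, 3), ignore_attr = TRUE)
  expect_lt(max(abs(polynomial_kernel(g, degree = 3, offset = 0.5)$values -
                      oracle_polynomial_kernel(g$dosages, 3, 0.5))), 1e-12)
  expect_error(polynomial_kernel(g, degree = 0), "integer")
})

test_that("built-in square kernels are symmetric and PSD on simulated genotypes", {
  for (seed in 1:5) {
    g <- sim_genotypes(15, 25, seed = seed)
    for (k in list(product_kernel(g), product_kernel(g, standardize = TRUE),
                   gaussian_kernel(g, 1.5), polynomial_kernel(g, 2, 0.5))) {
      expect_lt(max(abs(k$values - t(k$values))), 1e-10)
      expect_true(is_psd(k))
    }
  }
})

test_that("standardization drops zero-variance variants with a warning", {
  d <- cbind(c(0, 1, 2, 1), rep(2, 4))
  g <- genotype_matrix(d, data.frame(fid = paste0("F", 1:4),
                                     iid = paste0("I", 1:4)),
                       .dummy_variants(2))
  expect_warning(k <- product_kernel(g, standardize = TRUE), "zero-variance")
  expect_equal(k$params$p, 1)
})

test_that("cross kernel equals the off-diagonal block of the stacked square kernel", {
  g_all <- sim_genotypes(14, 12, seed = 6)
  tr <- subset_samples(g_all, 1:9)
  te <- subset_samples(g_all, 10:14)
  for (kind in c("product", "gaussian", "polynomial")) {
    sq <- switch(kind, product = product_kernel(g_all),
                 gaussian = gaussian_kernel(g_all, 1.3),
                 polynomial = polynomial_kernel(g_all, 2, 0.7))
    cr <- cross_kernel(te, tr, kind = kind, bandwidth = 1.3, degree = 2,
                       offset = 0.7)
    expect_equal(cr$values, sq$values[10:14, 1:9], ignore_attr = TRUE)
    expect_equal(cr$row_diag, unname(diag(sq$values)[10:14]))
    expect_equal(cr$col_diag, unname(diag(sq$values)[1:9]))
  }
  # test set identical to train set reproduces the square kernel
  cr2 <- cross_kernel(tr, tr, kind = "product")
  expect_equal(cr2$values, product_kernel(tr)$values, ignore_attr = TRUE)
  expect_error(cross_kernel(subset_variants(te, 1:5), tr, "product"),
               "different variants")
})

test_that("cross-kernel standardization statistics come from the training set only", {
  g_all <- sim_genotypes(20, 10, seed = 7)
  tr <- subset_samples(g_all, 1:15)
  te <- subset_samples(g_all, 16:20)
  cr <- cross_kernel(te, tr, "product", standardize = TRUE)
  st <- list(center = colMeans(tr$dosages), scale = apply(tr$dosages, 2, sd))
  xt <- sweep(sweep(te$dosages, 2, st$center), 2, st$scale, "/")
  xr <- sweep(sweep(tr$dosages, 2, st$center), 2, st$scale, "/")
  expect_equal(cr$values, tcrossprod(xt, xr) / 10, ignore_attr = TRUE)
})

test_that("expected hidden kernel: degree-1 linearity and the degree-2 Gaussian moments", {
  k_u <- product_kernel(sim_genotypes(6, 30, seed = 8))
  expect_equal(expected_hidden_kernel(k_u, degree = 1, offset = 0)$values,
               k_u$values)
  expect_equal(expected_hidden_kernel(k_u, degree = 1, offset = 2)$values,
               k_u$values + 2)
  # k_u = I, m = 1: E[z^4] = 3 on the diagonal, E[z^2 w^2] = 1 off it
  eh <- expected_hidden_kernel(diag(4), degree = 2, offset = 0, m = 1)
  expect_equal(eh$values, diag(4) * 2 + 1, ignore_attr = TRUE)
  expect_error(expected_hidden_kernel(k_u, degree = 3), "degree")
})

test_that("degree-2 closed form matches Monte Carlo within 4 standard errors", {
  set.seed(100)
  for (rep in 1:6) {
    n <- 4
    a <- matrix(rnorm(n * n), n)
    k_u <- crossprod(a) / n
    m <- sample(1:4, 1)
    off <- runif(1, 0, 1)
    eh <- expected_hidden_kernel(k_u, degree = 2, offset = off, m = m)
    mc <- mc_hidden_kernel(k_u, degree = 2, offset = off, m = m,
                           draws = 2e4, seed = rep)
    expect_true(all(abs(eh$values - mc$mean) <= 4 * mc$se + 1e-12))
  }
})
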