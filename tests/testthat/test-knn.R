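# MINQUE estimation, component expansion, fitting and BLUP prediction

test_that("component expansion covers the documented model structures", {
  g <- sim_genotypes(10, 20, seed = 1)
  K <- product_kernel(g)
  # degree-1 hidden kernel collapses to the standard LMM basis [K, I]
  sp <- knn_spec(list(K), list(hidden_kernel(1)))
  comps <- expand_components(sp)
  expect_length(comps, 2)
  expect_equal(comps[[1]], K$values)
  expect_equal(comps$I, diag(10))
  # two input kernels, degree-1 hidden: [K1, K2, I]
  K2 <- gaussian_kernel(g, 1)
  expect_length(expand_components(knn_spec(list(K, K2), list(hidden_kernel(1)))), 3)
  # degree-2, offset 0: the Isserlis component; large m leaves K*K
  spec2 <- knn_spec(list(K), list(hidden_kernel(2, 0, m = 1e9)))
  c2 <- expand_components(spec2)
  expect_length(c2, 2)
  expect_lt(max(abs(c2[[1]] - K$values^2)), 1e-7)
  # finite m adds the diagonal-product term
  c2m <- expand_components(knn_spec(list(K), list(hidden_kernel(2, 0, m = 4))))
  d <- diag(K$values)
  expect_equal(c2m[[1]], (1 + 1 / 4) * K$values^2 + outer(d, d) / 4)
  # nonzero offset brings in the input kernel and the all-ones matrix
  c2o <- expand_components(knn_spec(list(K), list(hidden_kernel(2, 1, m = 4))))
  expect_length(c2o, 4)
  expect_true(any(vapply(c2o, function(v) max(abs(v - 1)) < 1e-12, TRUE)))
})

test_that("expansion reproduces the expected hidden kernel as a linear combination", {
  # sanity for the free-coefficient parameterization: with tau = xi = 1 the
  # component combination must equal tau * E[H(U)] for both degrees
  g <- sim_genotypes(8, 15, seed = 2)
  K <- product_kernel(g)
  for (h in list(hidden_kernel(1, 0.5), hidden_kernel(2, 0.3, m = 3))) {
    comps <- expand_components(knn_spec(list(K), list(h)))
    eh <- expected_hidden_kernel(K, h$degree, h$offset, h$m)$values
    cg <- comps[-length(comps)]
    coef <- if (h$degree == 1) c(1, h$offset) else c(1, 2 * h$offset, h$offset^2)
    built <- Reduce(`+`, Map(`*`, coef, cg))
    expect_equal(built, eh, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("MINQUE(0) with only the identity recovers the sample variance", {
  set.seed(11)
  y <- rnorm(25, 3, 2)
  f <- minque(y, matrix(1, 25, 1), list(diag(25)))
  expect_equal(f$theta, var(y))
  expect_equal(f$beta, mean(y), ignore_attr = TRUE)
})

test_that("the MINQUE linear system matches the naive trace/quadratic-form oracle", {
  set.seed(12)
  n <- 6
  g <- sim_genotypes(n, 12, seed = 12)
  K <- product_kernel(g)$values
  comps <- list(K, diag(n))
  Z <- cbind(1, rnorm(n))
  y <- rnorm(n)
  f0 <- minque(y, Z, comps)
  or0 <- oracle_minque_system(y, Z, comps)
  expect_lt(max(abs(f0$S - or0$S)), 1e-10)
  expect_lt(max(abs(f0$q - or0$q)), 1e-10)
  expect_lt(f0$resid_rel, 1e-8)
  # weighted (iterative-step) system too
  fw <- minque(y, Z, comps, weights = c(0.7, 1.3))
  orw <- oracle_minque_system(y, Z, comps, weights = c(0.7, 1.3))
  expect_lt(max(abs(fw$S - orw$S)), 1e-10)
  expect_lt(max(abs(fw$q - orw$q)), 1e-10)
})

test_that("iterative MINQUE is a fixpoint and handles degenerate input", {
  g <- sim_genotypes(60, 40, seed = 13)
  sim <- sim_knn_phenotype(g, hidden_kernel(1), tau = 1, xi = 1, phi = 1,
                           seed = 14)
  spec <- knn_spec(list(product_kernel(g)), list(hidden_kernel(1)), sim$Z)
  m <- fit_knn(spec, sim$y, tol = 1e-10, max_iter = 50)
  # self-consistency: one more weighted MINQUE step reproduces theta
  w <- pmax(m$theta, 0); w[2] <- max(w[2], 1e-6 * var(sim$y))
  again <- minque(sim$y, sim$Z, m$components, weights = w)
  expect_equal(again$theta, m$theta, tolerance = 1e-6)
  expect_lt(max(m$fit_meta$resid_rel), 1e-8)
  # constant phenotype: flagged degenerate, all components zero
  md <- fit_knn(spec, rep(2, 60))
  expect_true(md$fit_meta$degenerate)
  expect_equal(md$theta, rep(0, 2))
})

test_that("MINQUE agrees with REML on a single-kernel Gaussian model", {
  # independent oracle: direct optimization of the restricted likelihood
  g <- sim_genotypes(150, 80, seed = 15)
  K <- product_kernel(g)
  diffs <- t(sapply(1:12, function(r) {
    sim <- sim_knn_phenotype(g, hidden_kernel(1), tau = 2, xi = 1, phi = 1,
                             beta = c(1, 0.5), seed = 100 + r)
    spec <- knn_spec(list(K), list(hidden_kernel(1)), sim$Z)
    m <- fit_knn(spec, sim$y)
    reml <- oracle_reml(sim$y, sim$Z, K$values)
    m$theta - reml
  }))
  se <- apply(diffs, 2, sd) / sqrt(nrow(diffs))
  expect_true(all(abs(colMeans(diffs)) <= 3 * pmax(se, 0.02)))
})

test_that("fitting is invariant to a simultaneous permutation of samples", {
  g <- sim_genotypes(40, 30, seed = 16)
  sim <- sim_knn_phenotype(g, hidden_kernel(2, 0, 5), tau = 1, xi = 1,
                           phi = 1, seed = 17)
  K <- product_kernel(g)
  spec <- knn_spec(list(K), list(hidden_kernel(2, 0, 5)), sim$Z)
  m1 <- fit_knn(spec, sim$y)
  perm <- sample(40)
  Kp <- kernel_matrix(K$values[perm, perm], K$row_ids[perm, ], kind = "product")
  specp <- knn_spec(list(Kp), list(hidden_kernel(2, 0, 5)),
                    sim$Z[perm, , drop = FALSE])
  m2 <- fit_knn(specp, sim$y[perm])
  expect_equal(m2$theta, m1$theta, tolerance = 1e-6)
  expect_equal(m2$beta, m1$beta, tolerance = 1e-6)
})

test_that("single-kernel BLUP prediction is exactly kernel ridge regression", {
  g <- sim_genotypes(80, 40, seed = 18)
  tr <- subset_samples(g, 1:60)
  te <- subset_samples(g, 61:80)
  sim <- sim_knn_phenotype(tr, hidden_kernel(1), tau = 1.5, xi = 1, phi = 0.8,
                           seed = 19)
  Ktr <- product_kernel(tr)
  spec <- knn_spec(list(Ktr), list(hidden_kernel(1)), sim$Z)
  m <- fit_knn(spec, sim$y)
  kc <- cross_kernel(te, tr, "product")
  cc <- expand_cross_components(list(kc), list(hidden_kernel(1)))
  Zt <- cbind(1, rnorm(20))
  pred <- predict_knn(m, cc, Zt)
  tau <- m$theta_trunc[1]; phi <- m$theta_trunc[2]
  resid <- sim$y - drop(sim$Z %*% m$beta)
  krr <- oracle_krr(resid, Ktr$values, kc$values, ridge = phi / tau)
  expect_equal(pred, drop(Zt %*% m$beta) + krr, tolerance = 1e-10)
})

test_that("prediction limits: interpolation as phi -> 0, fixed effects when genetic variance is zero", {
  g <- sim_genotypes(30, 60, seed = 20)
  K <- product_kernel(g)
  sim <- sim_knn_phenotype(g, hidden_kernel(1), tau = 1, xi = 1, phi = 1,
                           seed = 21)
  spec <- knn_spec(list(K), list(hidden_kernel(1)), sim$Z)
  m <- fit_knn(spec, sim$y)
  # force the phi -> 0 limit on the fitted model: predictions at the
  # training points interpolate y
  m0 <- m
  m0$theta_trunc <- c(m$theta_trunc[1], 1e-12)
  cc <- list(K$values)
  expect_equal(predict_knn(m0, cc, sim$Z), sim$y, tolerance = 1e-4)
  # all genetic components zero: fixed effects only
  mz <- m
  mz$theta_trunc <- c(0, 1)
  expect_equal(predict_knn(mz, cc, sim$Z), drop(sim$Z %*% m$beta))
})

test_that("classify thresholds with ties toward the positive class", {
  expect_equal(classify(c(0.2, 0.7), 0.5), c(0L, 1L))
  expect_equal(classify(c(0.5, 0.49999), 0.5), c(1L, 0L))
  set.seed(22)
  sc <- runif(50)
  lab <- classify(sc, threshold = mean(sc))
  expect_equal(sum(lab), sum(sc >= mean(sc)))
})
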