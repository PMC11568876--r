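# B-spline bases, genotype smoothing, the functional network and training

test_that("B-spline basis: partition of unity and local support on a dense grid", {
  for (kn in c(0, 3, 8)) {
    b <- bspline_basis(kn, order = 4)
    grid <- seq(0, 1, length.out = 211)
    B <- basis_eval(b, grid)
    expect_equal(dim(B), c(211, kn + 4))
    expect_lt(max(abs(rowSums(B) - 1)), 1e-12)
  }
  # local support: each basis function vanishes outside `order` knot spans
  b <- bspline_basis(6, order = 4)
  B <- basis_eval(b, seq(0, 1, length.out = 400))
  supp <- apply(B > 1e-12, 2, function(v) diff(range(which(v))) / 400)
  expect_true(all(supp <= 4 / 7 + 0.01))
})

test_that("penalty Gram matrices match numerical quadrature and vanish on affine functions", {
  b <- bspline_basis(5, order = 4)
  P <- basis_gram(b, c(2, 2))
  # independent oracle: adaptive quadrature of second-derivative products
  for (pair in list(c(1, 1), c(2, 4), c(3, 6))) {
    f <- function(t) basis_eval(b, t, 2)[, pair[1]] * basis_eval(b, t, 2)[, pair[2]]
    num <- integrate(function(t) sapply(t, f), 0, 1, subdivisions = 1000,
                     rel.tol = 1e-10)$value
    expect_lt(abs(P[pair[1], pair[2]] - num), 1e-8)
  }
  # affine functions live in the penalty null space; coefficients along the
  # Greville abscissae reproduce a + b t exactly
  kv <- b$knot_vector
  grev <- sapply(seq_len(b$dim), function(a) mean(kv[(a + 1):(a + b$order - 1)]))
  co <- 2 - 3 * grev
  expect_lt(abs(drop(t(co) %*% P %*% co)), 1e-10)
})

test_that("genotype smoothing reproduces constants, flattens under heavy penalty, and improves with basis size", {
  g <- sim_genotypes(5, 30, seed = 50)
  g$dosages[] <- 2                      # constant profile
  b <- bspline_basis(6)
  fc <- smooth_genotypes(g, b, 1e-6)
  expect_lt(max(abs(eval_curves(fc) - 2)), 1e-6)
  # heavy penalty drives the fit to a straight line (zero curvature)
  g2 <- sim_genotypes(4, 40, seed = 51)
  fc2 <- smooth_genotypes(g2, b, 1e8)
  curv <- fc2$coefs %*% t(basis_eval(b, seq(0.05, 0.95, length.out = 50), 2))
  expect_lt(max(abs(curv)), 1e-3)
  # nested-model check: a 12-dim basis fits a smooth dosage signal better
  # than a 2-dim basis
  p <- 30
  tpos <- seq(0, 1, length.out = p)
  prob <- 0.2 + 0.6 * sin(pi * tpos)^2
  set.seed(52)
  dos <- matrix(rbinom(8 * p, 2, rep(prob, each = 8)), 8, p)
  gg <- genotype_matrix(dos, data.frame(fid = paste0("F", 1:8),
                                        iid = paste0("I", 1:8)),
                        .dummy_variants(p))
  err <- sapply(c(0, 8), function(kn) {
    bb <- bspline_basis(kn, order = if (kn == 0) 2 else 4)
    fcx <- smooth_genotypes(gg, bb, 1e-8)
    mean((eval_curves(fcx, tpos) - rep(2 * prob, each = 8))^2)
  })
  expect_lt(err[2], err[1])
  # underdetermined without penalty
  expect_error(smooth_genotypes(sim_genotypes(3, 5, seed = 1),
                                bspline_basis(10), 0), "underdetermined")
  # missing dosages are omitted, not imputed: constant profile survives holes
  g3 <- g; g3$dosages[1, c(3, 7, 20)] <- NA
  fc3 <- smooth_genotypes(g3, b, 1e-6)
  expect_lt(max(abs(eval_curves(fc3) - 2)), 1e-6)
})

test_that("zero-weight networks produce constant output", {
  b <- bspline_basis(5)
  mod <- fnn(b, hidden_knots = c(4), seed = 1)
  v <- fnn_pack(mod); v[] <- 0
  mod0 <- fnn_unpack(mod, v)
  C <- matrix(rnorm(6 * b$dim), 6, b$dim)
  expect_equal(fnn_forward(mod0, C), rep(0, 6))
  # constant intercept function, zero weights, identity activation:
  # output independent of the input curve
  modc <- fnn(b, hidden_knots = c(4), activation = "identity", seed = 1)
  v <- fnn_pack(modc); v[] <- 0
  modc <- fnn_unpack(modc, v)
  modc$layers[[1]]$b0[] <- 1          # alpha0 == 1 (partition of unity)
  modc$head$a0 <- 0.5
  out <- fnn_forward(modc, C)
  expect_lt(diff(range(out)), 1e-10)
})

test_that("a single linear layer reduces to the functional linear model", {
  # with identity activation, the network computes an affine functional of
  # the input curve: pred = const + <alpha, x> with alpha having basis
  # coefficients W' J_out w. The oracle evaluates <alpha, x> by dense
  # trapezoid quadrature on the raw curves, fully independent of the
  # package's Gram-matrix route.
  b <- bspline_basis(6)
  set.seed(60)
  C <- matrix(rnorm(40 * b$dim), 40, b$dim)
  mod <- fnn(b, hidden_knots = c(6), activation = "identity", seed = 2)
  pred <- fnn_forward(mod, C)
  L <- mod$layers[[1]]
  b2 <- mod$bases[[1]]
  grid <- seq(0, 1, length.out = 4001)
  wtrap <- rep(1 / (length(grid) - 1), length(grid))
  wtrap[c(1, length(grid))] <- wtrap[1] / 2
  Bg_in <- basis_eval(b, grid)           # curves and alpha on the grid
  Bg_out <- basis_eval(b2, grid)
  alpha_coef <- t(L$W) %*% basis_gram(b2, c(0, 0)) %*% mod$head$w
  const <- mod$head$a0 +
    sum((Bg_out %*% mod$head$w) * (Bg_out %*% L$b0) * wtrap)
  f_or <- const +
    drop((C %*% t(Bg_in)) %*% (wtrap * (Bg_in %*% alpha_coef)))
  expect_equal(pred, f_or, tolerance = 1e-6)
})

test_that("penalized-loss gradient matches central finite differences", {
  b <- bspline_basis(5)
  g <- sim_genotypes(15, 25, seed = 61)
  fc <- smooth_genotypes(g, b, 1e-6)
  set.seed(62)
  y <- rnorm(15)
  Zc <- matrix(rnorm(15), 15, 1)
  for (fam in c("gaussian", "binomial")) {
    yy <- if (fam == "binomial") rbinom(15, 1, 0.5) else y
    mod <- fnn(b, hidden_knots = c(4, 3), n_covar = 1, family = fam, seed = 63)
    v0 <- fnn_pack(mod)
    gr <- fnn_grad(mod, fc$coefs, yy, Zc, lambda = 0.05)
    gv <- gennet:::.fnn_pack_grad(gr)
    idx <- sample(length(v0), 25)
    eps <- 1e-4
    num <- sapply(idx, function(i) {
      vp <- v0; vp[i] <- vp[i] + eps
      vm <- v0; vm[i] <- vm[i] - eps
      (fnn_loss(fnn_unpack(mod, vp), fc$coefs, yy, Zc, 0.05) -
         fnn_loss(fnn_unpack(mod, vm), fc$coefs, yy, Zc, 0.05)) / (2 * eps)
    })
    expect_lt(max(abs(num - gv[idx]) / pmax(abs(num), 1e-6)), 1e-4)
  }
})

test_that("loss structure: lambda = 0 is the pure data loss, perfect predictions give zero", {
  b <- bspline_basis(4)
  mod <- fnn(b, hidden_knots = c(3), seed = 5)
  C <- matrix(rnorm(8 * b$dim), 8)
  y <- fnn_forward(mod, C)
  expect_equal(fnn_loss(mod, C, y, lambda = 0), 0)
  y2 <- y + 1
  expect_equal(fnn_loss(mod, C, y2, lambda = 0), 1)
  pen <- fnn_loss(mod, C, y, lambda = 2)
  expect_gte(pen, 0)
  expect_equal(fnn_loss(mod, C, y, lambda = 1), pen / 2)
  expect_error(fnn_loss(fnn(b, c(3), family = "binomial", seed = 1), C,
                        y2, lambda = 0), "0/1")
})

test_that("training is deterministic given seed and reduces the training loss", {
  b <- bspline_basis(5)
  g <- sim_genotypes(40, 30, seed = 70)
  sim <- sim_fnn_phenotype(g, "linear", snr = 3, seed = 71)
  fc <- smooth_genotypes(g, b, 1e-6)
  mod <- fnn(b, hidden_knots = c(4), seed = 72)
  run <- function() fnn_train(mod, fc$coefs[1:30, ], sim$y[1:30], NULL,
                              fc$coefs[31:40, ], sim$y[31:40],
                              lambdas = c(1e-3, 1e-1), epochs = 120,
                              lr = 5e-3, seed = 73)
  r1 <- run(); r2 <- run()
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$lambda, r2$lambda)
  expect_lt(r1$trace[length(r1$trace)], r1$trace[1])
})

test_that("growing the roughness penalty flattens the learned functions", {
  b <- bspline_basis(5)
  g <- sim_genotypes(35, 25, seed = 74)
  sim <- sim_fnn_phenotype(g, "linear", snr = 3, seed = 75)
  fc <- smooth_genotypes(g, b, 1e-6)
  mod <- fnn(b, hidden_knots = c(4), seed = 76)
  grid <- seq(0.02, 0.98, length.out = 60)
  curv <- sapply(c(1e-3, 1e-1, 10, 1e3), function(lam) {
    r <- fnn_train(mod, fc$coefs[1:28, ], sim$y[1:28], NULL,
                   fc$coefs[29:35, ], sim$y[29:35], lambdas = lam,
                   epochs = 1500, lr = 2e-2, seed = 77)
    hb <- r$model$bases[[1]]
    L <- r$model$layers[[1]]
    B2 <- basis_eval(hb, grid, 2)
    # curvature across all learned functions: alpha0, the weight surface
    # (in its output coordinate), and the head function
    max(abs(B2 %*% L$b0)) + max(abs(B2 %*% L$W)) +
      max(abs(B2 %*% r$model$head$w))
  })
  expect_true(all(diff(curv) <= 1e-6 + 0.05 * curv[-length(curv)]))
  expect_lt(curv[4], 0.5 * curv[1])
})
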