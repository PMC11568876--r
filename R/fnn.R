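# Functional neural network.
#
# Layer d maps a function x(t) on the incoming basis to a function on the
# outgoing basis: pre-activation g(s) = alpha0(s) + int alpha(s, t) x(t) dt
# (+ covariate term at the first layer), with alpha0 and alpha represented
# on the outgoing basis / the tensor of outgoing x incoming bases. In
# coefficients: u = b0 + W J c (+ Gamma z), where J is the incoming-basis
# L2 Gram matrix. The activation sigma is applied on a quadrature grid and
# re-projected onto the outgoing basis (an exact L2 projection, since the
# per-interval Gauss-Legendre rule integrates basis products exactly).
# The scalar head is a0 + int alpha_D(t) x_D(t) dt = a0 + w' J_D c_D;
# binary phenotypes pass through a logistic link.

.fnn_act <- function(name) {
  switch(name,
    tanh = list(f = tanh, df = function(g, h) 1 - h^2),
    relu = list(f = function(g) pmax(g, 0), df = function(g, h) (g > 0) * 1),
    identity = list(f = identity, df = function(g, h) 1),
    .stopf("unknown activation '%s'", name))
}

#' Construct a functional neural network
#'
#' @param input_basis bspline_basis carrying the genotype curves (from
#'   [smooth_genotypes()]).
#' @param hidden_knots interior-knot counts of the hidden layers; the
#'   candidate-gene protocol default is `c(100, 50)`.
#' @param order spline order of the hidden bases (default 4).
#' @param n_covar number of scalar covariates entering at the first layer.
#' @param activation "tanh" (default), "relu" or "identity".
#' @param family "gaussian" (squared-error loss) or "binomial"
#'   (cross-entropy with logistic link).
#' @param seed seed for the N(0, 1/fan_in) coefficient initialization.
#' @return object of class `fnn_model`.
#' @export
fnn <- function(input_basis, hidden_knots = c(100, 50), order = 4,
                n_covar = 0, activation = "tanh",
                family = c("gaussian", "binomial"), seed = 1) {
  stopifnot(inherits(input_basis, "bspline_basis"), length(hidden_knots) >= 1)
  family <- match.arg(family)
  bases <- lapply(hidden_knots, bspline_basis, order = order,
                  domain = input_basis$domain)
  D <- length(bases)
  layers <- vector("list", D)
  pre <- vector("list", D)
  for (d in seq_len(D)) {
    bin <- if (d == 1) input_basis else bases[[d - 1]]
    bout <- bases[[d]]
    q <- basis_quad(bout)
    Bq <- basis_eval(bout, q$nodes)
    M <- crossprod(Bq * q$weights, Bq)
    pre[[d]] <- list(
      J_in = basis_gram(bin, c(0, 0)),
      P_in = basis_gram(bin, c(2, 2)),
      J_out = basis_gram(bout, c(0, 0)),
      P_out = basis_gram(bout, c(2, 2)),
      Bq = Bq, wq = q$weights,
      # projection of quadrature values back onto the outgoing basis
      proj = t(solve(M, t(Bq * q$weights))))
    layers[[d]] <- list(W = matrix(0, bout$dim, bin$dim), b0 = numeric(bout$dim),
                        Gamma = if (d == 1 && n_covar > 0)
                          matrix(0, bout$dim, n_covar) else NULL)
  }
  head_pre <- list(J = basis_gram(bases[[D]], c(0, 0)),
                   P = basis_gram(bases[[D]], c(2, 2)))
  model <- structure(list(input_basis = input_basis, bases = bases,
                          layers = layers, head = list(w = numeric(bases[[D]]$dim),
                                                       a0 = 0),
                          pre = pre, head_pre = head_pre,
                          activation = activation, act = .fnn_act(activation),
                          family = family, n_covar = n_covar),
                     class = "fnn_model")
  fnn_init(model, seed)
}

#' Re-initialize FNN parameters from a seed
#'
#' All coefficients are drawn i.i.d. N(0, 1/fan_in), with fan_in the
#' incoming basis dimension (plus covariates at the first layer).
#'
#' @param model fnn_model.
#' @param seed RNG seed.
#' @return model with fresh parameters.
#' @export
fnn_init <- function(model, seed = 1) {
  .with_seed(seed, {
    for (d in seq_along(model$layers)) {
      L <- model$layers[[d]]
      fan <- ncol(L$W) + if (is.null(L$Gamma)) 0 else ncol(L$Gamma)
      sd_ <- 1 / sqrt(fan)
      L$W[] <- stats::rnorm(length(L$W), 0, sd_)
      L$b0[] <- stats::rnorm(length(L$b0), 0, sd_)
      if (!is.null(L$Gamma)) L$Gamma[] <- stats::rnorm(length(L$Gamma), 0, sd_)
      model$layers[[d]] <- L
    }
    fan <- length(model$head$w)
    model$head$w[] <- stats::rnorm(fan, 0, 1 / sqrt(fan))
    model$head$a0 <- 0
  })
  model
}

#' @export
print.fnn_model <- function(x, ...) {
  dims <- c(x$input_basis$dim, vapply(x$bases, `[[`, 0L, "dim"))
  cat(sprintf("functional neural network: %s basis dims %s, activation %s, family %s\n",
              paste(length(x$bases), "hidden layer(s),"),
              paste(dims, collapse = " -> "), x$activation, x$family))
  invisible(x)
}

# inputs: C n x dim_in coefficient matrix (or functional_curves), Z n x q
.fnn_inputs <- function(model, C, Z) {
  if (inherits(C, "functional_curves")) C <- C$coefs
  C <- as.matrix(C)
  if (ncol(C) != model$input_basis$dim)
    .stopf("curve coefficients have dim %d, model input basis has %d",
           ncol(C), model$input_basis$dim)
  if (model$n_covar > 0) {
    if (is.null(Z)) .stopf("model expects %d covariates", model$n_covar)
    Z <- as.matrix(Z)
    stopifnot(nrow(Z) == nrow(C), ncol(Z) == model$n_covar)
  }
  list(C = C, Z = Z)
}

#' Forward pass of the functional neural network
#'
#' @param model fnn_model.
#' @param C n x dim coefficient matrix of input curves (or a
#'   `functional_curves` object).
#' @param Z covariate matrix (first layer only), if the model has
#'   covariates.
#' @param keep return intermediate layer states (for backpropagation).
#' @return numeric predictions (probabilities for family "binomial"), or a
#'   list with caches when `keep = TRUE`.
#' @export
fnn_forward <- function(model, C, Z = NULL, keep = FALSE) {
  io <- .fnn_inputs(model, C, Z)
  C_cur <- io$C
  cache <- list()
  for (d in seq_along(model$layers)) {
    L <- model$layers[[d]]; P <- model$pre[[d]]
    CJ <- C_cur %*% P$J_in
    U <- CJ %*% t(L$W) + matrix(L$b0, nrow(C_cur), length(L$b0), byrow = TRUE)
    if (!is.null(L$Gamma)) U <- U + io$Z %*% t(L$Gamma)
    G <- U %*% t(P$Bq)
    H <- model$act$f(G)
    C_next <- H %*% P$proj
    if (keep) cache[[d]] <- list(C_in = C_cur, CJ = CJ, G = G, H = H)
    C_cur <- C_next
  }
  f <- drop(C_cur %*% (model$head_pre$J %*% model$head$w)) + model$head$a0
  out <- if (model$family == "binomial") stats::plogis(f) else f
  if (!keep) return(out)
  list(pred = out, link = f, C_out = C_cur, cache = cache, Z = io$Z)
}

#' Predict from a fitted FNN
#' @param object fnn_model.
#' @param curves input curves (coefficient matrix or functional_curves).
#' @param Z covariates.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.fnn_model <- function(object, curves, Z = NULL, ...) {
  fnn_forward(object, curves, Z)
}

.fnn_penalty <- function(model) {
  pen <- 0
  for (d in seq_along(model$layers)) {
    L <- model$layers[[d]]; P <- model$pre[[d]]
    pen <- pen + drop(crossprod(L$b0, P$P_out %*% L$b0)) +
      sum((t(L$W) %*% P$P_out %*% L$W) * P$J_in) +   # int (d2_s alpha)^2
      sum((t(L$W) %*% P$J_out %*% L$W) * P$P_in)     # int (d2_t alpha)^2
  }
  pen + drop(crossprod(model$head$w, model$head_pre$P %*% model$head$w))
}

.fnn_data_loss <- function(model, pred, link, y) {
  n <- length(y)
  if (model$family == "gaussian") {
    mean((y - pred)^2)
  } else {
    if (!all(y %in% c(0, 1))) .stopf("cross-entropy labels must be 0/1")
    p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
}

#' Penalized FNN loss
#'
#' Mean squared error (gaussian) or mean cross-entropy (binomial) plus
#' `lambda` times the total roughness penalty: for every layer the
#' integrated squared second derivative of the intercept function and of
#' the weight surface in each coordinate, plus the head function's
#' penalty, all computed exactly from spline Gram matrices.
#'
#' @param model fnn_model.
#' @param C input curve coefficients.
#' @param y response.
#' @param Z covariates.
#' @param lambda roughness penalty weight (>= 0).
#' @return scalar loss.
#' @export
fnn_loss <- function(model, C, y, Z = NULL, lambda = 0) {
  stopifnot(lambda >= 0)
  fw <- fnn_forward(model, C, Z, keep = TRUE)
  .fnn_data_loss(model, fw$pred, fw$link, y) +
    if (lambda > 0) lambda * .fnn_penalty(model) else 0
}

#' Gradient of the penalized FNN loss
#'
#' Exact reverse-mode gradient with respect to every parameter (layer
#' weight surfaces, intercept functions, covariate weights, head).
#'
#' @inheritParams fnn_loss
#' @return list mirroring the parameter structure: `layers` (each with
#'   `W`, `b0`, optional `Gamma`) and `head` (`w`, `a0`), plus the `loss`.
#' @export
fnn_grad <- function(model, C, y, Z = NULL, lambda = 0) {
  fw <- fnn_forward(model, C, Z, keep = TRUE)
  n <- length(y)
  loss <- .fnn_data_loss(model, fw$pred, fw$link, y) +
    if (lambda > 0) lambda * .fnn_penalty(model) else 0
  # dL/dlink
  e <- if (model$family == "gaussian") 2 * (fw$pred - y) / n
       else (fw$pred - y) / n
  Jw <- model$head_pre$J %*% model$head$w
  g_head <- list(w = drop(model$head_pre$J %*% crossprod(fw$C_out, e)),
                 a0 = sum(e))
  if (lambda > 0)
    g_head$w <- g_head$w + 2 * lambda * drop(model$head_pre$P %*% model$head$w)
  dC <- tcrossprod(e, drop(Jw))          # n x dim_D
  g_layers <- vector("list", length(model$layers))
  for (d in rev(seq_along(model$layers))) {
    L <- model$layers[[d]]; P <- model$pre[[d]]; ch <- fw$cache[[d]]
    dH <- dC %*% t(P$proj)
    dG <- dH * model$act$df(ch$G, ch$H)
    dU <- dG %*% P$Bq
    gW <- crossprod(dU, ch$CJ)
    gb <- colSums(dU)
    if (lambda > 0) {
      gW <- gW + 2 * lambda * (P$P_out %*% L$W %*% P$J_in +
                                 P$J_out %*% L$W %*% P$P_in)
      gb <- gb + 2 * lambda * drop(P$P_out %*% L$b0)
    }
    g_layers[[d]] <- list(W = gW, b0 = gb,
                          Gamma = if (is.null(L$Gamma)) NULL else
                            crossprod(dU, fw$Z))
    dC <- (dU %*% L$W) %*% P$J_in
  }
  list(layers = g_layers, head = g_head, loss = loss)
}

# ---- parameter vector packing (for Adam and finite-difference checks) ----

#' Flatten FNN parameters into a numeric vector
#' @param model fnn_model.
#' @return numeric vector.
#' @export
fnn_pack <- function(model) {
  unlist(c(lapply(model$layers, function(L)
    c(as.numeric(L$W), L$b0, if (!is.null(L$Gamma)) as.numeric(L$Gamma))),
    list(model$head$w, model$head$a0)), use.names = FALSE)
}

#' Restore FNN parameters from a flat vector
#' @param model fnn_model (provides the shapes).
#' @param v numeric vector from [fnn_pack()].
#' @return fnn_model with parameters set.
#' @export
fnn_unpack <- function(model, v) {
  pos <- 0L
  take <- function(k) { out <- v[pos + seq_len(k)]; pos <<- pos + k; out }
  for (d in seq_along(model$layers)) {
    L <- model$layers[[d]]
    L$W[] <- take(length(L$W))
    L$b0[] <- take(length(L$b0))
    if (!is.null(L$Gamma)) L$Gamma[] <- take(length(L$Gamma))
    model$layers[[d]] <- L
  }
  model$head$w[] <- take(length(model$head$w))
  model$head$a0 <- take(1L)
  stopifnot(pos == length(v))
  model
}

.fnn_pack_grad <- function(g) {
  unlist(c(lapply(g$layers, function(L)
    c(as.numeric(L$W), L$b0, if (!is.null(L$Gamma)) as.numeric(L$Gamma))),
    list(g$head$w, g$head$a0)), use.names = FALSE)
}

# Layer-sequential variance calibration of a freshly initialized network:
# random 1/fan_in initialization leaves integral-operator layers badly
# scaled (the basis Gram matrices shrink between-sample signal by an order
# of magnitude per layer), so each layer's parameters are rescaled until
# its pre-activations have unit between-sample standard deviation on the
# training curves, and the head is rescaled toward unit output spread.
# Deterministic given (seed, data).
.fnn_calibrate <- function(model, C, Z, target = 1) {
  C_cur <- C
  for (d in seq_along(model$layers)) {
    L <- model$layers[[d]]; P <- model$pre[[d]]
    U <- C_cur %*% P$J_in %*% t(L$W) +
      matrix(L$b0, nrow(C_cur), length(L$b0), byrow = TRUE)
    if (!is.null(L$Gamma)) U <- U + Z %*% t(L$Gamma)
    G <- U %*% t(P$Bq)
    s <- stats::sd(sweep(G, 2, colMeans(G)))
    if (is.finite(s) && s > 1e-12) {
      f <- target / s
      L$W <- L$W * f; L$b0 <- L$b0 * f
      if (!is.null(L$Gamma)) L$Gamma <- L$Gamma * f
      model$layers[[d]] <- L
      G <- G * f
    }
    C_cur <- model$act$f(G) %*% P$proj
  }
  fs <- drop(C_cur %*% (model$head_pre$J %*% model$head$w))
  s <- stats::sd(fs)
  if (is.finite(s) && s > 1e-12)
    model$head$w <- model$head$w * (target / s)
  model
}

# one full-batch Adam run at fixed lambda; returns model + loss trace
.fnn_adam <- function(model, C, y, Z, lambda, epochs, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  v <- fnn_pack(model)
  m1 <- m2 <- numeric(length(v))
  trace <- numeric(0)
  for (ep in seq_len(epochs)) {
    g <- fnn_grad(model, C, y, Z, lambda)
    gv <- .fnn_pack_grad(g)
    if (!is.finite(g$loss) || any(!is.finite(gv)))
      return(list(model = model, trace = c(trace, NaN), failed = TRUE))
    trace[ep] <- g$loss
    m1 <- beta1 * m1 + (1 - beta1) * gv
    m2 <- beta2 * m2 + (1 - beta2) * gv^2
    mh <- m1 / (1 - beta1^ep)
    vh <- m2 / (1 - beta2^ep)
    v <- v - lr * mh / (sqrt(vh) + eps)
    model <- fnn_unpack(model, v)
  }
  list(model = model, trace = trace, failed = FALSE)
}

#' Train the FNN with Adam and validation-based penalty selection
#'
#' For each penalty value in `lambdas` the parameters are re-initialized
#' from `seed` and trained by full-batch Adam on the penalized loss for
#' `epochs` epochs; the model with the smallest validation *data* loss
#' (no penalty term) is returned. A non-finite loss triggers one restart
#' at half the learning rate, then an abort with a diagnostic. Training is
#' fully deterministic given (seed, lambdas, epochs).
#'
#' @param model fnn_model (architecture; parameters are re-initialized).
#' @param C_train,y_train,Z_train training curves, response, covariates.
#' @param C_valid,y_valid,Z_valid validation data (disjoint from training).
#' @param lambdas penalty grid; default 6 log-spaced points in
#'   [1e-4, 10].
#' @param epochs Adam epochs per penalty value (protocol default 10000;
#'   reduce for small studies).
#' @param lr Adam learning rate.
#' @param seed initialization seed.
#' @param calibrate rescale each layer at initialization so pre-activations
#'   have unit between-sample spread on the training curves (recommended;
#'   see the methods vignette).
#' @return list with `model` (best fit), `lambda` (selected), `valid_loss`
#'   (per-lambda validation data loss), `trace` (training-loss history of
#'   the selected fit).
#' @export
fnn_train <- function(model, C_train, y_train, Z_train = NULL,
                      C_valid, y_valid, Z_valid = NULL,
                      lambdas = 10^seq(-4, 1, length.out = 6),
                      epochs = 10000, lr = 1e-3, seed = 1, calibrate = TRUE) {
  stopifnot(epochs >= 1, length(lambdas) >= 1)
  if (inherits(C_train, "functional_curves")) C_train <- C_train$coefs
  if (inherits(C_valid, "functional_curves")) C_valid <- C_valid$coefs
  best <- NULL; vloss <- rep(NA_real_, length(lambdas)); best_trace <- NULL
  m_init <- fnn_init(model, seed)
  if (calibrate) m_init <- .fnn_calibrate(m_init, C_train, Z_train)
  # the raw roughness integrals scale like (knot spacing)^-4 and would make
  # any fixed lambda grid architecture-dependent; one shared normalization
  # by the penalty at initialization makes lambda dimensionless
  pen0 <- .fnn_penalty(m_init)
  pen_scale <- if (is.finite(pen0) && pen0 > 0) 1 / pen0 else 1
  for (i in seq_along(lambdas)) {
    lam <- lambdas[i] * pen_scale
    run <- .fnn_adam(m_init, C_train, y_train, Z_train, lam, epochs, lr)
    if (run$failed) {
      run <- .fnn_adam(m_init, C_train, y_train, Z_train, lam, epochs, lr / 2)
      if (run$failed)
        .stopf("FNN training diverged (non-finite loss) at lambda = %g even after halving the learning rate", lambdas[i])
    }
    fw <- fnn_forward(run$model, C_valid, Z_valid, keep = TRUE)
    vloss[i] <- .fnn_data_loss(run$model, fw$pred, fw$link, y_valid)
    if (is.null(best) || vloss[i] < min(vloss[seq_len(i - 1)], Inf, na.rm = TRUE)) {
      best <- run$model; best_lam <- lambdas[i]; best_trace <- run$trace
    }
  }
  list(model = best, lambda = best_lam, valid_loss = vloss,
       lambdas = lambdas, penalty_scale = pen_scale, trace = best_trace)
}

#' Candidate-gene FNN pipeline
#'
#' Smooths the genotypes of a candidate region onto a B-spline basis,
#' splits the training samples into sub-training and validation sets,
#' trains over the penalty grid and reports accuracy.
#'
#' @param x genotype_matrix of the candidate region (training samples).
#' @param y response vector aligned with `x`.
#' @param covar optional covariate matrix.
#' @param input_knots interior knots of the genotype-smoothing basis;
#'   default `min(20, p - order)`.
#' @param hidden_knots interior knots of the hidden layers (default
#'   c(100, 50)).
#' @param order spline order (default 4).
#' @param family "gaussian" or "binomial"; default chosen from y.
#' @param valid_frac fraction of training samples held out for penalty
#'   selection.
#' @param lambdas,epochs,lr,seed passed to [fnn_train()].
#' @param activation hidden activation (default "tanh").
#' @param smooth_lambda genotype-smoothing penalty.
#' @return list with `model`, `lambda`, `curves` (training curves),
#'   `basis`, `valid_loss`, the train split indices, and the input/response
#'   transforms (`center`, `scale`, `y_mean`, `y_sd`) that
#'   [predict_fnn_fit()] applies to new data.
#'
#' @details Before training, curves are functionally centered (the mean
#' training curve is subtracted) and divided by one global factor, the
#' root mean squared L2 norm of the centered training curves; a continuous
#' response is standardized and predictions are mapped back. Both
#' transforms condition the optimization without changing the model class.
#' @export
fit_fnn <- function(x, y, covar = NULL, input_knots = NULL,
                    hidden_knots = c(100, 50), order = 4, family = NULL,
                    valid_frac = 0.2, lambdas = 10^seq(-4, 1, length.out = 6),
                    epochs = 10000, lr = 1e-3, seed = 1, activation = "tanh",
                    smooth_lambda = 1e-6) {
  stopifnot(inherits(x, "genotype_matrix"))
  y <- as.numeric(y)
  n <- nrow(x$dosages); p <- ncol(x$dosages)
  stopifnot(length(y) == n)
  if (is.null(family))
    family <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"
  if (is.null(input_knots)) input_knots <- max(min(20L, p - order), 0L)
  basis <- bspline_basis(knots = input_knots, order = order)
  curves <- smooth_genotypes(x, basis, smooth_lambda)
  idx_valid <- .with_seed(seed, sample.int(n, max(round(valid_frac * n), 1)))
  idx_train <- setdiff(seq_len(n), idx_valid)
  nc <- if (is.null(covar)) 0L else ncol(as.matrix(covar))
  model <- fnn(basis, hidden_knots = hidden_knots, order = order,
               n_covar = nc, activation = activation, family = family,
               seed = seed)
  Zm <- if (nc > 0) as.matrix(covar) else NULL
  # functional centering + one global scale (training statistics only)
  center <- colMeans(curves$coefs[idx_train, , drop = FALSE])
  Cc <- sweep(curves$coefs, 2, center)
  J0 <- basis_gram(basis, c(0, 0))
  scale_ <- sqrt(mean(rowSums((Cc[idx_train, , drop = FALSE] %*% J0) *
                                Cc[idx_train, , drop = FALSE])))
  if (!is.finite(scale_) || scale_ <= 0) scale_ <- 1
  Cc <- Cc / scale_
  y_mean <- 0; y_sd <- 1
  if (family == "gaussian") {
    y_mean <- mean(y[idx_train])
    y_sd <- stats::sd(y[idx_train])
    if (!is.finite(y_sd) || y_sd <= 0) y_sd <- 1
  }
  ys <- (y - y_mean) / y_sd
  fit <- fnn_train(model,
                   Cc[idx_train, , drop = FALSE], ys[idx_train],
                   if (nc > 0) Zm[idx_train, , drop = FALSE] else NULL,
                   Cc[idx_valid, , drop = FALSE], ys[idx_valid],
                   if (nc > 0) Zm[idx_valid, , drop = FALSE] else NULL,
                   lambdas = lambdas, epochs = epochs, lr = lr, seed = seed)
  c(fit, list(curves = curves, basis = basis, idx_train = idx_train,
              idx_valid = idx_valid, family = family, center = center,
              scale = scale_, y_mean = y_mean, y_sd = y_sd,
              smooth_lambda = smooth_lambda))
}

#' Predict from a [fit_fnn()] result on new genotypes or curves
#'
#' Applies the stored curve centering/scaling and, for a continuous
#' response, maps standardized network output back to the phenotype scale.
#'
#' @param fit result of [fit_fnn()].
#' @param x genotype_matrix of new samples (same region), or a coefficient
#'   matrix / `functional_curves` on the fit's basis via `curves`.
#' @param covar covariates for the new samples, if the model uses any.
#' @param curves optional pre-smoothed curves, overriding `x`.
#' @return numeric predictions on the phenotype scale (probabilities for a
#'   binary response).
#' @export
predict_fnn_fit <- function(fit, x = NULL, covar = NULL, curves = NULL) {
  if (is.null(curves)) {
    stopifnot(inherits(x, "genotype_matrix"))
    curves <- smooth_genotypes(x, fit$basis, fit$smooth_lambda)
  }
  C <- if (inherits(curves, "functional_curves")) curves$coefs else
    as.matrix(curves)
  Cc <- sweep(C, 2, fit$center) / fit$scale
  out <- fnn_forward(fit$model, Cc, if (is.null(covar)) NULL else
    as.matrix(covar))
  if (fit$family == "gaussian") out * fit$y_sd + fit$y_mean else out
}
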