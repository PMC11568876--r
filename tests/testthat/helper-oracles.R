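# Independent oracles used across the suite. Each one recomputes a
# quantity by a route the implementation does not share: naive loops,
# brute-force enumeration, direct likelihood optimization, or closed-form
# regression algebra.

.dummy_variants <- function(p) {
  data.frame(chrom = 1, id = paste0("snp", seq_len(p)), cm = 0,
             bp = seq_len(p) * 100, allele1 = "A", allele2 = "C",
             stringsAsFactors = FALSE)
}

# entrywise double-loop kernels
oracle_product_kernel <- function(x) {
  n <- nrow(x); p <- ncol(x)
  k <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    k[i, j] <- sum(x[i, ] * x[j, ]) / p
  k
}

oracle_gaussian_kernel <- function(x, bandwidth) {
  n <- nrow(x); p <- ncol(x)
  k <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    k[i, j] <- exp(-sum((x[i, ] - x[j, ])^2) / (bandwidth * p))
  k
}

oracle_polynomial_kernel <- function(x, degree, offset) {
  n <- nrow(x); p <- ncol(x)
  k <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    k[i, j] <- (sum(x[i, ] * x[j, ]) / p + offset)^degree
  k
}

# naive MINQUE system: explicit matrix formulas, no shared code path
oracle_minque_system <- function(y, Z, comps, weights = NULL) {
  n <- length(y)
  vw <- diag(n)
  if (!is.null(weights)) {
    vw <- matrix(0, n, n)
    for (r in seq_along(comps)) vw <- vw + weights[r] * comps[[r]]
  }
  wi <- solve(vw)
  R <- wi - wi %*% Z %*% solve(t(Z) %*% wi %*% Z) %*% t(Z) %*% wi
  c_ <- length(comps)
  S <- matrix(0, c_, c_); q <- numeric(c_)
  for (r in seq_len(c_)) {
    q[r] <- drop(t(y) %*% R %*% comps[[r]] %*% R %*% y)
    for (s in seq_len(c_))
      S[r, s] <- sum(diag(R %*% comps[[r]] %*% R %*% comps[[s]]))
  }
  list(S = S, q = q)
}

# REML via direct optimization of the Gaussian restricted log-likelihood
oracle_reml <- function(y, Z, K) {
  n <- length(y)
  nll <- function(par) {
    tau <- exp(par[1]); phi <- exp(par[2])
    V <- tau * K + phi * diag(n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_Z <- backsolve(ch, forwardsolve(t(ch), Z))
    XtViX <- t(Z) %*% Vi_Z
    beta <- solve(XtViX, t(Vi_Z) %*% y)
    r <- y - Z %*% beta
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    as.numeric(sum(log(diag(ch))) + 0.5 * determinant(XtViX)$modulus +
                 0.5 * t(r) %*% Vi_r)
  }
  fit <- optim(c(0, 0), nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  exp(fit$par)
}

# kernel ridge regression oracle: f = K_cross (K + ridge I)^-1 y
oracle_krr <- function(y, K_train, K_cross, ridge) {
  drop(K_cross %*% solve(K_train + ridge * diag(nrow(K_train)), y))
}

# functional linear model oracle: y ~ a0 + <alpha, x> with alpha on the
# input basis; design columns are J c_i (inner products of basis pairs),
# ridge-stabilized least squares assembled directly
oracle_flm <- function(C_train, y_train, C_test, basis, ridge = 1e-8) {
  J <- basis_gram(basis, c(0, 0))
  X <- cbind(1, C_train %*% J)
  cf <- solve(crossprod(X) + ridge * diag(ncol(X)), crossprod(X, y_train))
  list(coef = cf,
       train = drop(cbind(1, C_train %*% J) %*% cf),
       test = drop(cbind(1, C_test %*% J) %*% cf))
}

# brute-force AUC over all positive-negative pairs, ties counted 1/2
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# hand-decode a PLINK bed byte stream from the published 2-bit table
oracle_decode_bed <- function(bytes, n, p) {
  dos <- matrix(NA_real_, n, p)
  bpv <- ceiling(n / 4)
  map <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  for (v in seq_len(p)) for (i in seq_len(n)) {
    byte <- as.integer(bytes[(v - 1) * bpv + ceiling(i / 4)])
    shift <- 2 * ((i - 1) %% 4)
    code <- bitwAnd(bitwShiftR(byte, shift), 3L)
    dos[i, v] <- map[[as.character(code)]]
  }
  dos
}

# genotype fixture whose empirical allele-1 frequency stays below 1/2 for
# every variant, so text-format polarity inference is exact
sim_genotypes_polarized <- function(n, p, seed = 1, missing_rate = 0) {
  g <- sim_genotypes(n, p, maf_range = c(0.05, 0.35), seed = seed,
                     missing_rate = missing_rate)
  freq <- colMeans(g$dosages, na.rm = TRUE) / 2
  subset_variants(g, freq < 0.5 & freq > 0)
}
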