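#' Kernel matrix container
#'
#' An n_row x n_col similarity matrix with sample identity attached. Square
#' kernels (train x train) must be symmetric; cross kernels (test x train)
#' additionally carry the self-similarities (`row_diag`, `col_diag`) of the
#' two sample sets, which the degree-2 hidden-kernel expansion needs.
#'
#' @param values numeric matrix.
#' @param row_ids,col_ids data.frames with columns `fid`, `iid`.
#' @param kind tag: "product", "gaussian", "polynomial", "hidden_expected"
#'   or "custom".
#' @param params list of kernel hyperparameters.
#' @param row_diag,col_diag self-similarity vectors for cross kernels; for a
#'   square kernel both default to `diag(values)`.
#' @return Object of class `kernel_matrix`.
#' @export
kernel_matrix <- function(values, row_ids, col_ids = row_ids, kind = "custom",
                          params = list(), row_diag = NULL, col_diag = NULL) {
  values <- as.matrix(values)
  row_ids <- as.data.frame(row_ids, stringsAsFactors = FALSE)
  col_ids <- as.data.frame(col_ids, stringsAsFactors = FALSE)
  if (nrow(values) != nrow(row_ids) || ncol(values) != nrow(col_ids))
    .stopf("kernel dimensions (%d x %d) do not match id lists (%d, %d)",
           nrow(values), ncol(values), nrow(row_ids), nrow(col_ids))
  square <- identical(.key_str(row_ids), .key_str(col_ids)) &&
    nrow(values) == ncol(values)
  if (square) {
    if (.asym(values) > 1e-10)
      .stopf("square kernel is not symmetric (relative asymmetry %.3g)", .asym(values))
    values <- (values + t(values)) / 2
    if (is.null(row_diag)) row_diag <- diag(values)
    if (is.null(col_diag)) col_diag <- row_diag
  } else if (is.null(row_diag) || is.null(col_diag)) {
    .stopf("cross kernels must supply row_diag and col_diag")
  }
  structure(list(values = values, row_ids = row_ids[c("fid", "iid")],
                 col_ids = col_ids[c("fid", "iid")], kind = kind,
                 params = params, row_diag = as.numeric(row_diag),
                 col_diag = as.numeric(col_diag), square = square),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix [%s]: %d x %d%s\n", x$kind, nrow(x$values),
              ncol(x$values), if (x$square) " (square)" else " (cross)"))
  invisible(x)
}

#' @export
dim.kernel_matrix <- function(x) dim(x$values)

#' @export
sample_keys.kernel_matrix <- function(x) x$row_ids

#' Positive semi-definiteness check for a square kernel
#'
#' @param k kernel_matrix or symmetric matrix.
#' @param tol eigenvalues above `-tol * trace / n` are treated as
#'   non-negative.
#' @return TRUE/FALSE.
#' @export
is_psd <- function(k, tol = 1e-8) {
  v <- if (inherits(k, "kernel_matrix")) k$values else as.matrix(k)
  ev <- eigen((v + t(v)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(sum(diag(v)), .Machine$double.eps) / nrow(v)
}

# center/scale statistics for GCTA-style standardization, from training data
.std_stats <- function(xmat) {
  mu <- colMeans(xmat)
  sd <- apply(xmat, 2, stats::sd)
  list(center = mu, scale = sd)
}

.apply_std <- function(xmat, stats, drop_zero = TRUE) {
  keep <- stats$scale > 0
  if (!all(keep)) {
    if (!drop_zero) .stopf("zero-variance variant under standardization")
    .warnf("dropping %d zero-variance variant(s) before standardization", sum(!keep))
  }
  xs <- sweep(xmat[, keep, drop = FALSE], 2, stats$center[keep], "-")
  sweep(xs, 2, stats$scale[keep], "/")
}

#' Product (linear) kernel / genetic relationship matrix
#'
#' Computes K = X X' / p over the p variants, the product kernel. With
#' `standardize = TRUE` the dosage columns are first centered and scaled to
#' unit variance (GCTA-style GRM); zero-variance variants are then dropped
#' with a warning. Missing dosages are mean-imputed per variant first.
#'
#' @param x genotype_matrix (or numeric dosage matrix).
#' @param standardize center and scale columns before the product.
#' @return square `kernel_matrix` of kind "product".
#' @export
product_kernel <- function(x, standardize = FALSE) {
  ids <- if (inherits(x, "genotype_matrix")) x$samples else
    data.frame(fid = paste0("F", seq_len(nrow(as.matrix(x)))),
               iid = paste0("I", seq_len(nrow(as.matrix(x)))))
  xm <- .geno_values(x)
  if (standardize) xm <- .apply_std(xm, .std_stats(xm))
  p <- ncol(xm)
  k <- tcrossprod(xm) / p
  kernel_matrix(k, ids, kind = "product",
                params = list(standardize = standardize, p = p))
}

#' Gaussian (RBF) kernel on genotypes
#'
#' K_ij = exp(-||x_i - x_j||^2 / (bandwidth * p)), so the bandwidth is
#' dimensionless in the number of variants p and the diagonal is exactly 1.
#'
#' @param x genotype_matrix (or numeric dosage matrix).
#' @param bandwidth positive scale of the squared distance.
#' @param standardize center/scale columns first.
#' @return square `kernel_matrix` of kind "gaussian".
#' @export
gaussian_kernel <- function(x, bandwidth = 1, standardize = FALSE) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    .stopf("bandwidth must be a positive scalar")
  ids <- if (inherits(x, "genotype_matrix")) x$samples else
    data.frame(fid = paste0("F", seq_len(nrow(as.matrix(x)))),
               iid = paste0("I", seq_len(nrow(as.matrix(x)))))
  xm <- .geno_values(x)
  if (standardize) xm <- .apply_std(xm, .std_stats(xm))
  p <- ncol(xm)
  sq <- rowSums(xm^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(xm)
  d2[d2 < 0] <- 0
  k <- exp(-d2 / (bandwidth * p))
  diag(k) <- 1
  kernel_matrix(k, ids, kind = "gaussian",
                params = list(bandwidth = bandwidth, standardize = standardize, p = p))
}

#' Polynomial kernel on genotypes
#'
#' K = (X X' / p + offset)^degree, entrywise power of the (offset) product
#' kernel. `degree = 1`, `offset = 0` reduces exactly to the product kernel.
#'
#' @param x genotype_matrix (or numeric dosage matrix).
#' @param degree integer >= 1.
#' @param offset additive constant inside the power.
#' @param standardize center/scale columns first.
#' @return square `kernel_matrix` of kind "polynomial".
#' @export
polynomial_kernel <- function(x, degree = 2, offset = 0, standardize = FALSE) {
  if (!is.numeric(degree) || length(degree) != 1L || degree < 1 ||
      degree != round(degree))
    .stopf("degree must be an integer >= 1")
  pk <- product_kernel(x, standardize = standardize)
  k <- (pk$values + offset)^degree
  kernel_matrix(k, pk$row_ids, kind = "polynomial",
                params = list(degree = as.integer(degree), offset = offset,
                              standardize = standardize, p = pk$params$p))
}

#' Cross kernel between test and training genotypes
#'
#' Builds the n_test x n_train block of the chosen kernel, consistent with
#' the square kernel on the stacked data. Standardization statistics are
#' taken from the training set only. Both sets must carry the same variants
#' in the same order.
#'
#' @param x_test,x_train genotype_matrix objects with identical variants.
#' @param kind "product", "gaussian" or "polynomial".
#' @param standardize center/scale using training-set statistics.
#' @param bandwidth,degree,offset kernel hyperparameters (as in the square
#'   constructors).
#' @return cross `kernel_matrix` with row/col self-similarities attached.
#' @export
cross_kernel <- function(x_test, x_train,
                         kind = c("product", "gaussian", "polynomial"),
                         standardize = FALSE, bandwidth = 1, degree = 2,
                         offset = 0) {
  kind <- match.arg(kind)
  stopifnot(inherits(x_test, "genotype_matrix"), inherits(x_train, "genotype_matrix"))
  if (!identical(x_test$variants$id, x_train$variants$id) ||
      !identical(x_test$variants$allele1, x_train$variants$allele1))
    .stopf("test and training sets carry different variants")
  xt <- .geno_values(x_test)
  xr <- .geno_values(x_train)
  if (standardize) {
    st <- .std_stats(xr)
    keep <- st$scale > 0
    xr <- .apply_std(xr, st)
    xt <- sweep(sweep(xt[, keep, drop = FALSE], 2, st$center[keep], "-"),
                2, st$scale[keep], "/")
  }
  p <- ncol(xr)
  lin <- tcrossprod(xt, xr) / p
  dr <- rowSums(xt^2) / p
  dc <- rowSums(xr^2) / p
  if (kind == "product") {
    k <- lin
  } else if (kind == "polynomial") {
    k <- (lin + offset)^degree
    dr <- (dr + offset)^degree
    dc <- (dc + offset)^degree
  } else {
    sqt <- rowSums(xt^2); sqr <- rowSums(xr^2)
    d2 <- outer(sqt, sqr, "+") - 2 * tcrossprod(xt, xr)
    d2[d2 < 0] <- 0
    k <- exp(-d2 / (bandwidth * p))
    dr <- rep(1, nrow(xt)); dc <- rep(1, nrow(xr))
  }
  kernel_matrix(k, x_test$samples, x_train$samples, kind = kind,
                params = list(standardize = standardize, bandwidth = bandwidth,
                              degree = degree, offset = offset, p = p),
                row_diag = dr, col_diag = dc)
}

#' Expected hidden kernel under the Gaussian latent law
#'
#' In the kernel neural network the hidden units u_1, ..., u_m are i.i.d.
#' N(0, K_u) vectors and the hidden kernel is the polynomial kernel of the
#' n x m hidden-unit matrix, H_ij = (u_i . u_j / m + offset)^degree with
#' u_i the i-th row. This returns E[H] in closed form:
#' \itemize{
#'   \item degree 1: E[H]_ij = (K_u)_ij + offset (linearity);
#'   \item degree 2: E[H]_ij = ((K_u)_ij + offset)^2 +
#'     ((K_u)_ii (K_u)_jj + (K_u)_ij^2) / m, from the Gaussian fourth-moment
#'     identity (Isserlis' theorem).
#' }
#' Degrees above 2 have no closed form here; request Monte Carlo explicitly
#' via [mc_hidden_kernel()].
#'
#' @param k_u covariance of each hidden-unit vector (kernel_matrix or
#'   symmetric matrix).
#' @param degree 1 or 2.
#' @param offset polynomial offset.
#' @param m number of hidden units.
#' @return square `kernel_matrix` of kind "hidden_expected".
#' @export
expected_hidden_kernel <- function(k_u, degree = 2, offset = 0, m = 1) {
  if (!degree %in% c(1, 2))
    .stopf("closed form implemented for degree 1 and 2 only; use mc_hidden_kernel() for degree %s", degree)
  if (m < 1) .stopf("m must be >= 1")
  ids <- if (inherits(k_u, "kernel_matrix")) k_u$row_ids else
    data.frame(fid = paste0("F", seq_len(nrow(as.matrix(k_u)))),
               iid = paste0("I", seq_len(nrow(as.matrix(k_u)))))
  kv <- if (inherits(k_u, "kernel_matrix")) k_u$values else as.matrix(k_u)
  if (degree == 1) {
    h <- kv + offset
  } else {
    d <- diag(kv)
    h <- (kv + offset)^2 + (outer(d, d) + kv^2) / m
  }
  kernel_matrix(h, ids, kind = "hidden_expected",
                params = list(degree = degree, offset = offset, m = m))
}

#' Monte-Carlo estimate of the expected hidden kernel
#'
#' Averages H(U) = (U U' / m + offset)^degree over `draws` samples of the
#' n x m hidden-unit matrix U with i.i.d. N(0, k_u) columns. Serves as the
#' simulation cross-check of [expected_hidden_kernel()] and as the only
#' route for degree > 2.
#'
#' @param k_u hidden-unit covariance (kernel_matrix or symmetric matrix).
#' @param degree polynomial degree.
#' @param offset polynomial offset.
#' @param m number of hidden units.
#' @param draws Monte-Carlo sample size.
#' @param seed RNG seed.
#' @return list with `mean` (n x n matrix) and `se` (entrywise Monte-Carlo
#'   standard errors).
#' @export
mc_hidden_kernel <- function(k_u, degree = 2, offset = 0, m = 1,
                             draws = 1e4, seed = 1) {
  kv <- if (inherits(k_u, "kernel_matrix")) k_u$values else as.matrix(k_u)
  n <- nrow(kv)
  rt <- .mat_sqrt(kv)
  .with_seed(seed, {
    # all draws at once: column block b of A holds the m hidden units of
    # draw b, so G_ij over draws is a blockwise inner product
    A <- rt %*% matrix(stats::rnorm(n * m * draws), n, m * draws)
    mu <- matrix(0, n, n); se <- matrix(0, n, n)
    rows <- lapply(seq_len(n), function(i) matrix(A[i, ], m, draws))
    for (i in seq_len(n)) for (j in i:n) {
      h <- (colSums(rows[[i]] * rows[[j]]) / m + offset)^degree
      mu[i, j] <- mu[j, i] <- mean(h)
      se[i, j] <- se[j, i] <- stats::sd(h) / sqrt(draws)
    }
    list(mean = mu, se = se)
  })
}

# symmetric matrix square root with clamping of tiny negative eigenvalues
.mat_sqrt <- function(a, tol = 1e-8) {
  a <- (a + t(a)) / 2
  e <- eigen(a, symmetric = TRUE)
  lam <- e$values
  floor_ <- -tol * max(sum(pmax(lam, 0)), 1) / length(lam)
  if (min(lam) < floor_)
    .stopf("matrix is not PSD (min eigenvalue %.3g)", min(lam))
  e$vectors %*% (sqrt(pmax(lam, 0)) * t(e$vectors))
}
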