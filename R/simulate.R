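# Synthetic-data generators. Every generator is a pure function of its
# seed: the caller's RNG stream is saved and restored around each call.

#' Simulate diploid SNP genotypes with optional LD
#'
#' Each individual carries two latent Gaussian haplotype vectors with AR(1)
#' correlation `ld_rho` along the chromosome; an allele is present when the
#' latent value falls below the MAF quantile, so marginal allele
#' frequencies match the per-variant MAF drawn from `maf_range` and both
#' linkage disequilibrium and Hardy-Weinberg structure are plausible.
#' Base-pair positions are equally spaced with uniform jitter.
#'
#' @param n samples.
#' @param p variants.
#' @param maf_range range of minor-allele frequencies, within (0, 0.5].
#' @param ld_rho AR(1) latent correlation between adjacent variants, in
#'   \[0, 1).
#' @param seed RNG seed.
#' @param missing_rate fraction of calls set missing (default 0).
#' @return genotype_matrix; allele1 ("A") is the counted minor allele.
#' @export
sim_genotypes <- function(n, p, maf_range = c(0.05, 0.5), ld_rho = 0,
                          seed = 1, missing_rate = 0) {
  stopifnot(length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            ld_rho >= 0, ld_rho < 1, missing_rate >= 0, missing_rate < 1)
  .with_seed(seed, {
    maf <- stats::runif(p, maf_range[1], maf_range[2])
    thr <- stats::qnorm(maf)
    dos <- matrix(0, n, p)
    for (h in 1:2) {
      z <- matrix(stats::rnorm(n * p), n, p)
      if (ld_rho > 0 && p > 1) {
        lat <- z
        for (j in 2:p)
          lat[, j] <- ld_rho * lat[, j - 1] + sqrt(1 - ld_rho^2) * z[, j]
        z <- lat
      }
      dos <- dos + (z < rep(thr, each = n))
    }
    if (missing_rate > 0)
      dos[stats::runif(n * p) < missing_rate] <- NA
    spacing <- 1000L
    bp <- cumsum(spacing + sample.int(200L, p, replace = TRUE))
    samples <- data.frame(fid = paste0("F", seq_len(n)),
                          iid = paste0("I", seq_len(n)),
                          stringsAsFactors = FALSE)
    variants <- data.frame(chrom = 1L, id = paste0("snp", seq_len(p)), cm = 0,
                           bp = bp, allele1 = "A", allele2 = "C",
                           stringsAsFactors = FALSE)
    genotype_matrix(dos, samples, variants)
  })
}

#' Simulate a phenotype from the kernel neural network hierarchy
#'
#' Draws exactly from the three-level generative model: hidden units
#' u_1, ..., u_m i.i.d. N(0, sum_l xi_l K_l); genetic effect
#' a ~ N(0, sum_j tau_j H_j(U)) with H_j the polynomial hidden kernel of
#' the hidden-unit matrix; phenotype y ~ N(Z beta + a, phi I). The fixed
#' design Z is an intercept plus one standard-normal covariate.
#'
#' @param x genotype_matrix; its product kernel is the single input kernel
#'   unless `kernels` is given.
#' @param hidden list of hidden-kernel configurations from
#'   [hidden_kernel()] (one per H_j).
#' @param tau variance weights of the hidden kernels (length = number of
#'   hidden kernels).
#' @param xi variance weights of the input kernels (length = number of
#'   input kernels).
#' @param phi residual variance.
#' @param beta fixed-effect coefficients, length 2 (intercept, covariate).
#' @param seed RNG seed.
#' @param kernels optional list of square kernel_matrix inputs overriding
#'   the product kernel of `x`.
#' @return list with `y`, `Z`, `a` (genetic effect), `U` (hidden units)
#'   and `kernels`.
#' @export
sim_knn_phenotype <- function(x = NULL, hidden = list(hidden_kernel()),
                              tau = 1, xi = 1, phi = 1, beta = c(0, 0),
                              seed = 1, kernels = NULL) {
  if (is.null(kernels)) {
    stopifnot(inherits(x, "genotype_matrix"))
    kernels <- list(product_kernel(x))
  }
  if (inherits(hidden, "hidden_kernel")) hidden <- list(hidden)
  stopifnot(length(xi) == length(kernels), length(tau) == length(hidden),
            all(tau >= 0), all(xi >= 0), phi >= 0)
  n <- nrow(kernels[[1]]$values)
  ku <- Reduce(`+`, Map(function(w, k) w * k$values, xi, kernels))
  .with_seed(seed, {
    z <- cbind(1, stats::rnorm(n))
    a <- numeric(n); U <- NULL
    if (any(tau > 0) && any(xi > 0)) {
      rt <- .mat_sqrt(ku)
      acov <- matrix(0, n, n)
      U <- vector("list", length(hidden))
      for (j in seq_along(hidden)) {
        hj <- hidden[[j]]
        U[[j]] <- rt %*% matrix(stats::rnorm(n * hj$m), n, hj$m)
        hmat <- (tcrossprod(U[[j]]) / hj$m + hj$offset)^hj$degree
        acov <- acov + tau[j] * hmat
      }
      a <- drop(.mat_sqrt(acov) %*% stats::rnorm(n))
    }
    y <- drop(z %*% beta) + a + sqrt(phi) * stats::rnorm(n)
    list(y = y, Z = z, a = a, U = U, kernels = kernels)
  })
}

#' Simulate a phenotype with a functional genetic signal
#'
#' Test-bed generator for the functional neural network:
#' \describe{
#'   \item{linear}{y = <alpha*, G> + e, the inner product of a fixed smooth
#'     coefficient function alpha*(t) = sin(2 pi t) with the smoothed
#'     genotype curve of each sample;}
#'   \item{interaction}{y = b1 * b2 + e, the product of the centered mean
#'     dosages (burdens) of the first and second halves of the region — a
#'     purely non-additive signal invisible to a linear model;}
#'   \item{nonlinear}{y = sin(b) + e with b the standardized burden of the
#'     whole region.}
#' }
#' The noise standard deviation is set so that var(signal) / var(noise)
#' equals `snr`.
#'
#' @param x genotype_matrix for the candidate region.
#' @param signal "linear", "interaction" or "nonlinear".
#' @param snr signal-to-noise variance ratio, > 0.
#' @param seed RNG seed.
#' @param basis basis for the linear signal's genotype smoothing; default
#'   order-4 B-splines with interior knots = min(8, p - 4).
#' @return list with `y`, `signal` (noise-free), and `noise_sd`.
#' @export
sim_fnn_phenotype <- function(x, signal = c("linear", "interaction", "nonlinear"),
                              snr = 1, seed = 1, basis = NULL) {
  signal <- match.arg(signal)
  stopifnot(inherits(x, "genotype_matrix"), snr > 0)
  d <- .geno_values(x)
  n <- nrow(d); p <- ncol(d)
  if (signal == "linear") {
    if (is.null(basis))
      basis <- bspline_basis(knots = max(min(8L, p - 4L), 1L))
    fc <- smooth_genotypes(x, basis, smooth_lambda = 1e-6)
    grid <- seq(0, 1, length.out = 201)
    bg <- basis_eval(basis, grid)
    curves <- fc$coefs %*% t(bg)
    astar <- sin(2 * pi * grid)
    s <- drop(curves %*% astar) / length(grid)
  } else if (signal == "interaction") {
    half <- floor(p / 2)
    b1 <- rowMeans(d[, seq_len(half), drop = FALSE])
    b2 <- rowMeans(d[, (half + 1):p, drop = FALSE])
    s <- (b1 - mean(b1)) * (b2 - mean(b2))
  } else {
    b <- rowMeans(d)
    b <- (b - mean(b)) / max(stats::sd(b), 1e-12)
    s <- sin(b)
  }
  vs <- stats::var(s)
  noise_sd <- sqrt(vs / snr)
  .with_seed(seed, {
    y <- s + noise_sd * stats::rnorm(n)
    list(y = y, signal = s, noise_sd = noise_sd)
  })
}
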