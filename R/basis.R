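# Cardinal B-spline basis systems on [0, 1] with exact (per-interval
# Gauss-Legendre) inner products. Order 4 splines are cubic; basis
# dimension = interior knots + order.

#' B-spline basis system
#'
#' Clamped B-splines of the given order on equally spaced interior knots
#' over `domain`. Basis dimension is `knots + order`. The basis satisfies
#' partition of unity and has local support of `order` knot spans.
#'
#' @param knots number of interior knots (>= 0).
#' @param order spline order (degree + 1); default 4 (cubic).
#' @param domain length-2 numeric interval.
#' @return object of class `bspline_basis` with fields `order`, `knots`,
#'   `domain`, `dim` and the full (clamped) knot vector.
#' @export
bspline_basis <- function(knots = 10, order = 4, domain = c(0, 1)) {
  knots <- as.integer(knots); order <- as.integer(order)
  stopifnot(knots >= 0, order >= 1, length(domain) == 2, domain[1] < domain[2])
  interior <- if (knots > 0)
    seq(domain[1], domain[2], length.out = knots + 2L)[-c(1L, knots + 2L)]
  else numeric(0)
  kv <- c(rep(domain[1], order), interior, rep(domain[2], order))
  structure(list(order = order, knots = knots, domain = domain,
                 dim = knots + order, knot_vector = kv,
                 breaks = c(domain[1], interior, domain[2])),
            class = "bspline_basis")
}

#' @export
print.bspline_basis <- function(x, ...) {
  cat(sprintf("bspline_basis: order %d, %d interior knots, dim %d on [%g, %g]\n",
              x$order, x$knots, x$dim, x$domain[1], x$domain[2]))
  invisible(x)
}

#' Evaluate B-spline basis functions (or derivatives) at points
#'
#' @param basis bspline_basis.
#' @param t evaluation points within the domain.
#' @param deriv derivative order (0 <= deriv < order).
#' @return length(t) x dim matrix of basis values.
#' @export
basis_eval <- function(basis, t, deriv = 0) {
  stopifnot(inherits(basis, "bspline_basis"), deriv >= 0)
  t <- as.numeric(t)
  # derivatives at or beyond the polynomial order vanish identically
  if (deriv >= basis$order)
    return(matrix(0, length(t), basis$dim))
  eps <- 1e-12 * diff(basis$domain)
  t <- pmin(pmax(t, basis$domain[1]), basis$domain[2])
  # splineDesign treats the right endpoint as outside; nudge inward
  t[t >= basis$domain[2]] <- basis$domain[2] - eps
  splines::splineDesign(basis$knot_vector, x = t, ord = basis$order,
                        derivs = rep(deriv, length(t)))
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch
.gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b; J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = 2 * e$vectors[1, ord]^2)
}

#' Quadrature rule over a basis domain
#'
#' Per-knot-interval Gauss-Legendre nodes and weights; with `nper >= order`
#' points per interval all products of basis functions (and of their
#' derivatives) are integrated exactly.
#'
#' @param basis bspline_basis.
#' @param nper nodes per knot interval; default `order`.
#' @return list with `nodes` and `weights`.
#' @export
basis_quad <- function(basis, nper = basis$order) {
  gl <- .gauss_legendre(nper)
  br <- basis$breaks
  nodes <- weights <- numeric(0)
  for (i in seq_len(length(br) - 1L)) {
    a <- br[i]; b <- br[i + 1]
    nodes <- c(nodes, (gl$x + 1) / 2 * (b - a) + a)
    weights <- c(weights, gl$w * (b - a) / 2)
  }
  list(nodes = nodes, weights = weights)
}

#' Gram matrix of basis derivatives
#'
#' G_ab = integral of B_a^(d1)(t) B_b^(d2)(t) dt over the domain, computed
#' exactly by per-interval Gauss-Legendre quadrature. `derivs = c(0, 0)`
#' gives the L2 Gram matrix, `c(2, 2)` the roughness-penalty matrix.
#'
#' @param basis bspline_basis.
#' @param derivs length-2 derivative orders.
#' @return dim x dim symmetric matrix.
#' @export
basis_gram <- function(basis, derivs = c(0, 0)) {
  stopifnot(length(derivs) == 2)
  q <- basis_quad(basis)
  b1 <- basis_eval(basis, q$nodes, derivs[1])
  b2 <- if (derivs[2] == derivs[1]) b1 else basis_eval(basis, q$nodes, derivs[2])
  g <- crossprod(b1 * q$weights, b2)
  (g + t(g)) / 2
}

#' Smooth genotype profiles into functional curves
#'
#' Represents each sample's dosage profile as a smooth function of genomic
#' position: positions are min-max scaled to [0, 1] and per-sample basis
#' coefficients solve the roughness-penalized least squares
#' argmin sum_k (x_ik - c . B(t_k))^2 + lambda int (c . B'')^2. Missing
#' dosages are simply omitted from the sum, so neighbouring markers carry
#' the information.
#'
#' @param x genotype_matrix (variant bp positions must be strictly
#'   increasing after sorting).
#' @param basis bspline_basis.
#' @param smooth_lambda roughness penalty; with `smooth_lambda = 0` the
#'   number of variants must be at least the basis dimension.
#' @return object of class `functional_curves`: `coefs` (n x dim), `basis`,
#'   `t` (scaled positions) and `ids`.
#' @export
smooth_genotypes <- function(x, basis, smooth_lambda = 1e-6) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(basis, "bspline_basis"),
            smooth_lambda >= 0)
  ord <- order(x$variants$bp)
  bp <- x$variants$bp[ord]
  if (any(diff(bp) <= 0))
    .stopf("variant bp positions must be strictly increasing after sorting")
  d <- x$dosages[, ord, drop = FALSE]
  p <- ncol(d)
  if (smooth_lambda == 0 && p < basis$dim)
    .stopf("underdetermined: %d variants for basis dimension %d with no penalty",
           p, basis$dim)
  t_ <- if (p > 1) (bp - bp[1]) / (bp[p] - bp[1]) else 0.5
  t_ <- basis$domain[1] + t_ * diff(basis$domain)
  B <- basis_eval(basis, t_)
  P <- basis_gram(basis, c(2, 2))
  n <- nrow(d)
  coefs <- matrix(0, n, basis$dim)
  if (!anyNA(d)) {
    A <- crossprod(B) + smooth_lambda * P
    coefs <- t(solve(A, crossprod(B, t(d))))
  } else {
    A_full <- crossprod(B) + smooth_lambda * P
    for (i in seq_len(n)) {
      obs <- !is.na(d[i, ])
      if (all(obs)) {
        coefs[i, ] <- solve(A_full, crossprod(B, d[i, ]))
      } else {
        Bi <- B[obs, , drop = FALSE]
        coefs[i, ] <- solve(crossprod(Bi) + smooth_lambda * P,
                            crossprod(Bi, d[i, obs]))
      }
    }
  }
  structure(list(coefs = coefs, basis = basis, t = t_, ids = x$samples),
            class = "functional_curves")
}

#' @export
print.functional_curves <- function(x, ...) {
  cat(sprintf("functional_curves: %d samples on a dim-%d basis\n",
              nrow(x$coefs), x$basis$dim))
  invisible(x)
}

#' Evaluate functional curves on a grid
#' @param curves functional_curves.
#' @param grid evaluation points; default 101 equally spaced.
#' @return n x length(grid) matrix of curve values.
#' @export
eval_curves <- function(curves, grid = seq(curves$basis$domain[1],
                                           curves$basis$domain[2],
                                           length.out = 101)) {
  curves$coefs %*% t(basis_eval(curves$basis, grid))
}
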