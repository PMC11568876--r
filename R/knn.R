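# Kernel neural network: variance-component estimation by MINQUE.
#
# Marginal phenotype covariance: Var(y) = tau_j E[H_j(U)] summed over
# hidden kernels + phi I, with E[H_j] expanded in closed form (degree 1-2
# polynomial hidden kernels, Isserlis' theorem) into a linear basis of
# known matrices V_r with free coefficients theta_r. MINQUE solves the
# linear system S theta = q with S_rs = tr(R V_r R V_s),
# q_r = y' R V_r R y, R = Vw^-1 - Vw^-1 Z (Z' Vw^-1 Z)^-1 Z' Vw^-1.

#' Hidden-kernel configuration
#'
#' Describes one polynomial hidden kernel H_j of the KNN: H built from m
#' latent unit vectors as (U U' / m + offset)^degree. Degree 1 is the
#' linear hidden kernel ("lin"), degree 2 the quadratic ("poly2").
#'
#' @param degree polynomial degree, 1 or 2.
#' @param offset polynomial offset.
#' @param m number of hidden units.
#' @return object of class `hidden_kernel`.
#' @export
hidden_kernel <- function(degree = 1, offset = 0, m = 10) {
  if (!degree %in% c(1, 2)) .stopf("hidden kernel degree must be 1 or 2")
  if (m < 1) .stopf("m must be >= 1")
  structure(list(degree = as.integer(degree), offset = offset,
                 m = as.integer(m)), class = "hidden_kernel")
}

#' Kernel neural network model specification
#'
#' Bundles the input kernels K_l, the hidden-kernel configurations H_j and
#' the fixed-effect design Z (including the intercept). All kernels must
#' share the sample order of Z.
#'
#' @param kernels list of square kernel_matrix inputs.
#' @param hidden list of [hidden_kernel()] configurations.
#' @param Z n x q fixed-effect design matrix; default intercept only.
#' @return object of class `knn_spec`.
#' @export
knn_spec <- function(kernels, hidden = list(hidden_kernel()), Z = NULL) {
  if (inherits(kernels, "kernel_matrix")) kernels <- list(kernels)
  if (inherits(hidden, "hidden_kernel")) hidden <- list(hidden)
  stopifnot(length(kernels) >= 1, all(vapply(kernels, inherits, TRUE, "kernel_matrix")),
            all(vapply(hidden, inherits, TRUE, "hidden_kernel")))
  n <- nrow(kernels[[1]]$values)
  key0 <- .key_str(kernels[[1]]$row_ids)
  for (k in kernels[-1])
    if (!identical(.key_str(k$row_ids), key0))
      .stopf("input kernels disagree on sample identity/order")
  if (is.null(Z)) Z <- matrix(1, n, 1)
  Z <- as.matrix(Z)
  if (nrow(Z) != n) .stopf("Z has %d rows, kernels have %d samples", nrow(Z), n)
  if (ncol(Z) >= n) .stopf("q = %d fixed effects with only n = %d samples", ncol(Z), n)
  structure(list(kernels = kernels, hidden = hidden, Z = Z, n = n,
                 ids = kernels[[1]]$row_ids), class = "knn_spec")
}

# shared expansion logic; square path uses matrices K_l with diag d_l,
# cross path uses cross blocks with row/col self-similarity vectors
.expand_basis <- function(kmats, diags_row, diags_col, hidden, cross, n_row, n_col) {
  comps <- list(); labels <- character(0)
  add <- function(v, lab) {
    for (i in seq_along(comps))
      if (max(abs(comps[[i]] - v)) <= 1e-12 * max(1, max(abs(v)))) return()
    comps[[length(comps) + 1L]] <<- v
    labels[length(labels) + 1L] <<- lab
  }
  L <- length(kmats)
  for (j in seq_along(hidden)) {
    h <- hidden[[j]]
    if (h$degree == 1L) {
      for (l in seq_len(L)) add(kmats[[l]], sprintf("K%d", l))
      if (h$offset != 0) add(matrix(1, n_row, n_col), "ones")
    } else {
      for (l in seq_len(L)) for (lp in l:L) {
        v <- (1 + 1 / h$m) * kmats[[l]] * kmats[[lp]] +
          (outer(diags_row[[l]], diags_col[[lp]]) +
             outer(diags_row[[lp]], diags_col[[l]])) / (2 * h$m)
        add(v, sprintf("K%d*K%d[deg2,m=%d]", l, lp, h$m))
      }
      if (h$offset != 0) {
        for (l in seq_len(L)) add(kmats[[l]], sprintf("K%d", l))
        add(matrix(1, n_row, n_col), "ones")
      }
    }
  }
  names(comps) <- labels
  comps
}

#' Expand the KNN covariance into a linear component basis
#'
#' Returns matrices V_1, ..., V_c such that the marginal covariance of y is
#' a free linear combination sum_r theta_r V_r: for a degree-1 hidden
#' kernel these are the input kernels themselves (plus the all-ones matrix
#' when the offset is nonzero); for degree 2, the Isserlis expansion of the
#' expected hidden kernel generates an entrywise product K_l * K_l' plus a
#' 1/m diagonal-product term per kernel pair, the input kernels for the
#' offset cross term, and the all-ones matrix for the squared offset.
#' Duplicate matrices arising from several hidden kernels are merged. The
#' identity is appended last as the residual-variance (phi) component.
#'
#' @param spec knn_spec.
#' @return named list of n x n matrices; the last element is `I`.
#' @export
expand_components <- function(spec) {
  stopifnot(inherits(spec, "knn_spec"))
  kmats <- lapply(spec$kernels, `[[`, "values")
  diags <- lapply(spec$kernels, function(k) diag(k$values))
  comps <- .expand_basis(kmats, diags, diags, spec$hidden, FALSE, spec$n, spec$n)
  comps$I <- diag(spec$n)
  comps
}

#' Expand cross-covariance components for prediction
#'
#' Builds the test x train blocks of the same component basis as
#' [expand_components()] (residual identity excluded, since independent
#' noise does not transfer), from cross kernels carrying row/col
#' self-similarities.
#'
#' @param cross_kernels list of cross kernel_matrix objects, one per input
#'   kernel, in the order used in the training spec.
#' @param hidden list of [hidden_kernel()] configurations (as in training).
#' @return named list of n_test x n_train matrices.
#' @export
expand_cross_components <- function(cross_kernels, hidden) {
  if (inherits(cross_kernels, "kernel_matrix")) cross_kernels <- list(cross_kernels)
  if (inherits(hidden, "hidden_kernel")) hidden <- list(hidden)
  kmats <- lapply(cross_kernels, `[[`, "values")
  dr <- lapply(cross_kernels, `[[`, "row_diag")
  dc <- lapply(cross_kernels, `[[`, "col_diag")
  .expand_basis(kmats, dr, dc, hidden, TRUE, nrow(kmats[[1]]), ncol(kmats[[1]]))
}

# Precompute the MINQUE projection and trace system for fixed weights.
# weights = NULL means MINQUE(0): Vw = I.
.minque_system <- function(Z, components, weights = NULL,
                           ridge_tol = 1e-8) {
  n <- nrow(Z)
  notes <- character(0)
  if (is.null(weights)) {
    wi_z <- Z
    R <- diag(n) - Z %*% solve(crossprod(Z), t(Z))
  } else {
    vw <- Reduce(`+`, Map(`*`, weights, components))
    wi <- tryCatch(chol2inv(chol(vw)), error = function(e) NULL)
    if (is.null(wi)) {
      bump <- ridge_tol * sum(diag(vw)) / n
      if (bump <= 0) bump <- ridge_tol
      wi <- chol2inv(chol(vw + bump * diag(n)))
      notes <- c(notes, sprintf("singular V_w: ridge bump %.3g applied", bump))
    }
    wi_z <- wi %*% Z
    R <- wi - wi_z %*% solve(crossprod(Z, wi_z), t(wi_z))
  }
  RV <- lapply(components, function(v) R %*% v)
  c <- length(components)
  S <- matrix(0, c, c)
  for (r in seq_len(c)) for (s in r:c) {
    S[r, s] <- S[s, r] <- sum(RV[[r]] * t(RV[[s]]))
  }
  list(R = R, RV = RV, S = S, notes = notes)
}

.minque_solve <- function(sys, y, components) {
  Ry <- drop(sys$R %*% y)
  q <- vapply(components, function(v) drop(crossprod(Ry, v %*% Ry)), 0)
  notes <- sys$notes
  sv <- svd(sys$S)
  rc <- if (sv$d[1] > 0) min(sv$d) / max(sv$d) else 0
  if (rc < 1e-12) {
    pos <- sv$d > 1e-12 * max(sv$d)
    theta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% q) / sv$d[pos])
    theta <- drop(theta)
    notes <- c(notes, "singular MINQUE system: pseudo-inverse solve")
  } else {
    theta <- drop(solve(sys$S, q))
  }
  resid <- sqrt(sum((sys$S %*% theta - q)^2)) / max(sqrt(sum(q^2)), .Machine$double.eps)
  list(theta = theta, q = q, resid_rel = resid, notes = notes)
}

# GLS fixed effects under Sigma = sum(theta+ V) with phi floored
.gls_beta <- function(y, Z, components, theta, phi_floor) {
  w <- pmax(theta, 0)
  w[length(w)] <- max(w[length(w)], phi_floor)
  sig <- Reduce(`+`, Map(`*`, w, components))
  si_z <- solve(sig, Z)
  drop(solve(crossprod(Z, si_z), crossprod(si_z, y)))
}

#' MINQUE estimation of variance components
#'
#' Minimum norm quadratic unbiased estimation: solves S theta = q with
#' S_rs = tr(R V_r R V_s) and q_r = y' R V_r R y, where R is the projected
#' inverse of the working covariance V_w = sum_r weights_r V_r (identity
#' when `weights` is NULL, i.e. MINQUE(0)). Fixed effects are estimated by
#' GLS under the fitted covariance. A singular S falls back to a
#' pseudo-inverse solve and a singular V_w receives a logged ridge bump;
#' both are recorded in `notes`.
#'
#' @param y response vector (complete cases).
#' @param Z n x q fixed-effect design.
#' @param components list of n x n component matrices (last one the
#'   identity for the residual variance).
#' @param weights prior variance-component weights for V_w, or NULL for
#'   MINQUE(0).
#' @return list with `theta`, `beta`, `S`, `q`, `resid_rel` (relative
#'   residual of the linear system) and `notes`.
#' @export
minque <- function(y, Z, components, weights = NULL) {
  y <- as.numeric(y)
  Z <- as.matrix(Z)
  stopifnot(length(y) == nrow(Z), all(vapply(components, nrow, 0L) == length(y)))
  sys <- .minque_system(Z, components, weights)
  sol <- .minque_solve(sys, y, components)
  phi_floor <- max(1e-6 * stats::var(y), .Machine$double.eps)
  beta <- .gls_beta(y, Z, components, sol$theta, phi_floor)
  list(theta = sol$theta, beta = beta, S = sys$S, q = sol$q,
       resid_rel = sol$resid_rel, notes = sol$notes)
}

#' Fit the kernel neural network by iterative MINQUE
#'
#' Expands the model covariance into its linear component basis, takes
#' MINQUE(0) estimates as initial values, then iterates MINQUE with the
#' working covariance rebuilt from the current (non-negativity-truncated)
#' estimates until the maximum relative change falls below `tol` or
#' `max_iter` is reached. Non-convergence sets a flag rather than raising.
#'
#' @param spec knn_spec.
#' @param y response vector aligned with the spec's samples.
#' @param max_iter maximum MINQUE iterations (default 20).
#' @param tol relative-change convergence tolerance (default 1e-4).
#' @return object of class `knn_model`: `components`, `theta` (raw MINQUE
#'   estimates; last entry is phi), `theta_trunc` (negatives set to zero
#'   for prediction), `beta`, `y`, `Z`, `spec`, and `fit_meta` (iterations,
#'   convergence flag, per-iteration estimates, notes, system residuals).
#' @export
fit_knn <- function(spec, y, max_iter = 20, tol = 1e-4) {
  stopifnot(inherits(spec, "knn_spec"))
  y <- as.numeric(y)
  if (length(y) != spec$n) .stopf("y has length %d, spec has n = %d", length(y), spec$n)
  if (anyNA(y)) .stopf("y must be complete-case; filter missing phenotypes first")
  components <- expand_components(spec)
  c <- length(components)
  if (spec$n < c + ncol(spec$Z))
    .stopf("n = %d too small for %d components + %d fixed effects", spec$n, c, ncol(spec$Z))
  vy <- stats::var(y)
  meta <- list(iterations = 0L, converged = FALSE, degenerate = FALSE,
               notes = character(0), resid_rel = numeric(0), path = list())
  if (vy <= .Machine$double.eps) {
    theta <- rep(0, c)
    meta$degenerate <- TRUE; meta$converged <- TRUE
    beta <- drop(solve(crossprod(spec$Z), crossprod(spec$Z, y)))
    return(.knn_model(spec, components, theta, beta, y, meta))
  }
  phi_floor <- max(1e-6 * vy, .Machine$double.eps)
  fit <- minque(y, spec$Z, components)          # MINQUE(0) initialization
  meta$resid_rel <- fit$resid_rel
  meta$notes <- fit$notes
  meta$path <- list(fit$theta)
  theta <- fit$theta
  for (it in seq_len(max_iter)) {
    w <- pmax(theta, 0)
    w[c] <- max(w[c], phi_floor)
    fit <- minque(y, spec$Z, components, weights = w)
    meta$resid_rel <- c(meta$resid_rel, fit$resid_rel)
    meta$notes <- unique(c(meta$notes, fit$notes))
    meta$path <- c(meta$path, list(fit$theta))
    delta <- max(abs(fit$theta - theta)) / max(max(abs(theta)), 1e-12)
    theta <- fit$theta
    meta$iterations <- it
    if (delta < tol) { meta$converged <- TRUE; break }
  }
  .knn_model(spec, components, theta, fit$beta, y, meta)
}

.knn_model <- function(spec, components, theta, beta, y, meta) {
  tt <- pmax(theta, 0)
  structure(list(spec = spec, components = components, theta = theta,
                 theta_trunc = tt, beta = beta, y = y, Z = spec$Z,
                 fit_meta = meta), class = "knn_model")
}

#' @export
print.knn_model <- function(x, ...) {
  cat("kernel neural network fit (MINQUE)\n")
  cat(sprintf("  n = %d, components = %d, iterations = %d, converged: %s\n",
              length(x$y), length(x$theta), x$fit_meta$iterations,
              x$fit_meta$converged))
  tab <- data.frame(component = names(x$components), theta = x$theta,
                    used = x$theta_trunc)
  print(tab, row.names = FALSE)
  cat("  beta:", format(x$beta, digits = 4), "\n")
  invisible(x)
}

#' Render the variance-component table as plain text
#' @param model knn_model.
#' @return character vector of table lines.
#' @export
vc_table <- function(model) {
  stopifnot(inherits(model, "knn_model"))
  c(sprintf("%-20s %14s %14s", "component", "theta_hat", "theta_used"),
    sprintf("%-20s %14.6g %14.6g", names(model$components), model$theta,
            model$theta_trunc))
}

#' BLUP prediction from a fitted KNN model
#'
#' yhat = Z_test beta + (sum_r theta_r V_r^cross)
#' (sum_r theta_r V_r + phi I)^-1 (y - Z beta), with the truncated
#' non-negative estimates, i.e. the best linear unbiased predictor of the
#' genetic effect plus fixed effects.
#'
#' @param model knn_model.
#' @param cross_components list of n_test x n_train matrices matching the
#'   training components (identity excluded), e.g. from
#'   [expand_cross_components()].
#' @param Z_test n_test x q fixed-effect design for the new samples.
#' @return numeric vector of predictions.
#' @export
predict_knn <- function(model, cross_components, Z_test = NULL) {
  stopifnot(inherits(model, "knn_model"))
  n <- length(model$y)
  cg <- length(model$components) - 1L      # genetic components (excl. I)
  if (length(cross_components) != cg)
    .stopf("expected %d cross components (training has %d incl. identity), got %d",
           cg, cg + 1L, length(cross_components))
  nt <- nrow(cross_components[[1]])
  if (any(vapply(cross_components, ncol, 0L) != n))
    .stopf("cross components must have %d training columns", n)
  if (is.null(Z_test)) Z_test <- matrix(1, nt, ncol(model$Z))
  Z_test <- as.matrix(Z_test)
  tt <- model$theta_trunc
  fixed <- drop(Z_test %*% model$beta)
  if (all(tt[seq_len(cg)] == 0)) return(fixed)
  sig <- Reduce(`+`, Map(`*`, tt, model$components))
  resid <- model$y - drop(model$Z %*% model$beta)
  alpha <- tryCatch(solve(sig, resid), error = function(e) {
    solve(sig + 1e-10 * mean(diag(sig)) * diag(n), resid)
  })
  kc <- Reduce(`+`, Map(`*`, tt[seq_len(cg)], cross_components))
  fixed + drop(kc %*% alpha)
}

#' Threshold scores into binary class labels
#'
#' @param scores numeric vector (linear-probability scale).
#' @param threshold decision threshold; ties classify positive.
#' @return integer 0/1 labels.
#' @export
classify <- function(scores, threshold = 0.5) {
  as.integer(scores >= threshold)
}
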