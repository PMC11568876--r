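# Batch training: partition samples, fit the KNN per batch, average the
# variance-component and fixed-effect estimates.

#' Split samples into balanced random batches
#'
#' Deterministic in `seed`; batch sizes differ by at most one and the
#' batches partition the input. Indices inside each batch are kept in the
#' original (ascending) order, so B = 1 reproduces the input order exactly.
#'
#' @param ids sample keys (data.frame with fid/iid), a vector, or a single
#'   integer n.
#' @param B number of batches, 1 <= B <= n.
#' @param seed RNG seed for the random assignment.
#' @return list of B integer index vectors (positions into `ids`).
#' @export
split_batches <- function(ids, B, seed = 1) {
  n <- if (is.data.frame(ids)) nrow(ids) else if (length(ids) == 1L &&
    is.numeric(ids) && ids == round(ids) && ids > 1) as.integer(ids) else length(ids)
  B <- as.integer(B)
  if (B < 1L) .stopf("B must be >= 1")
  if (B > n) .stopf("B = %d exceeds n = %d", B, n)
  perm <- .with_seed(seed, sample.int(n))
  grp <- rep(seq_len(B), length.out = n)    # balanced: sizes differ by <= 1
  out <- lapply(seq_len(B), function(b) sort(perm[grp == b]))
  out
}

# slice a square kernel_matrix to a sample subset
.slice_kernel <- function(k, idx) {
  kernel_matrix(k$values[idx, idx, drop = FALSE],
                k$row_ids[idx, , drop = FALSE], kind = k$kind,
                params = k$params)
}

#' Fit the KNN with batch training
#'
#' Partitions the samples into B batches, fits the kernel neural network
#' independently on each (sub-kernels are sliced from the full input
#' kernels), and averages the per-batch variance-component and
#' fixed-effect estimates (unweighted; batch sizes differ by at most one).
#' With B = 1 this is exactly [fit_knn()]. Batches whose fit fails are
#' dropped with a warning; if every batch fails, an error is raised.
#'
#' @param spec knn_spec on the full sample.
#' @param y full response vector.
#' @param B number of batches.
#' @param seed seed for the batch assignment.
#' @param max_iter,tol passed to [fit_knn()].
#' @return knn_model with full-sample components (for prediction against
#'   all training samples) and averaged estimates; per-batch models are
#'   kept in `fit_meta$batches` and the partition in `fit_meta$batch_idx`.
#' @export
fit_knn_batched <- function(spec, y, B = 1, seed = 1, max_iter = 20,
                            tol = 1e-4) {
  stopifnot(inherits(spec, "knn_spec"))
  y <- as.numeric(y)
  if (B == 1) return(fit_knn(spec, y, max_iter = max_iter, tol = tol))
  idx <- split_batches(spec$ids, B, seed)
  fits <- vector("list", B)
  for (b in seq_len(B)) {
    sub <- idx[[b]]
    bspec <- knn_spec(lapply(spec$kernels, .slice_kernel, idx = sub),
                      spec$hidden, spec$Z[sub, , drop = FALSE])
    fits[[b]] <- tryCatch(fit_knn(bspec, y[sub], max_iter = max_iter, tol = tol),
                          error = function(e) e)
  }
  ok <- !vapply(fits, inherits, TRUE, "error")
  if (!any(ok)) .stopf("all %d batches failed to fit", B)
  if (!all(ok))
    .warnf("%d of %d batches failed and were dropped from averaging",
           sum(!ok), B)
  kept <- fits[ok]
  theta <- rowMeans(vapply(kept, `[[`, numeric(length(kept[[1]]$theta)), "theta"))
  beta <- rowMeans(vapply(kept, `[[`, numeric(length(kept[[1]]$beta)), "beta"))
  components <- expand_components(spec)
  meta <- list(iterations = max(vapply(kept, function(f) f$fit_meta$iterations, 0L)),
               converged = all(vapply(kept, function(f) f$fit_meta$converged, TRUE)),
               degenerate = FALSE,
               notes = unique(unlist(lapply(kept, function(f) f$fit_meta$notes))),
               batches = fits, batch_idx = idx, B = B, dropped = sum(!ok))
  .knn_model(spec, components, theta, beta, y, meta)
}

#' Prediction from a batch-trained KNN model
#'
#' Default mode "parameters" predicts with the averaged estimates and
#' cross-components against all training samples (identical to
#' [predict_knn()]); mode "predictions" instead predicts from each
#' per-batch model using that batch's training columns and averages the
#' predictions.
#'
#' @param model knn_model from [fit_knn_batched()].
#' @param cross_components list of n_test x n_train matrices over the full
#'   training sample.
#' @param Z_test fixed-effect design of the new samples.
#' @param mode "parameters" or "predictions".
#' @return numeric vector of predictions.
#' @export
predict_knn_batched <- function(model, cross_components, Z_test = NULL,
                                mode = c("parameters", "predictions")) {
  mode <- match.arg(mode)
  if (mode == "parameters" || is.null(model$fit_meta$batches))
    return(predict_knn(model, cross_components, Z_test))
  idx <- model$fit_meta$batch_idx
  fits <- model$fit_meta$batches
  preds <- NULL; used <- 0
  for (b in seq_along(fits)) {
    if (inherits(fits[[b]], "error")) next
    cc <- lapply(cross_components, function(v) v[, idx[[b]], drop = FALSE])
    p <- predict_knn(fits[[b]], cc, Z_test)
    preds <- if (is.null(preds)) p else preds + p
    used <- used + 1
  }
  preds / used
}
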