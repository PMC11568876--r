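# Train/test accuracy reporting: MSE and Pearson correlation for
# continuous phenotypes, misclassification rate and AUC for binary ones.

#' Mean squared error and Pearson correlation
#'
#' MSE uses the population denominator (divide by n, "mean" literally).
#' When either vector has zero variance the correlation is undefined and
#' reported as 0 with `cor_defined = FALSE`.
#'
#' @param y observed values.
#' @param yhat predictions.
#' @return list with `mse`, `cor`, `cor_defined`, `n`.
#' @export
mse_cor <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  stopifnot(length(y) == length(yhat), length(y) >= 2,
            all(is.finite(y)), all(is.finite(yhat)))
  mse <- mean((y - yhat)^2)
  defined <- stats::sd(y) > 0 && stats::sd(yhat) > 0
  r <- if (defined) stats::cor(y, yhat) else 0
  list(mse = mse, cor = r, cor_defined = defined, n = length(y))
}

#' Misclassification rate and AUC
#'
#' Misclassification at the given threshold (ties classify positive, as in
#' [classify()]); AUC as the Mann-Whitney probability that a random
#' positive outscores a random negative, ties counted one half (mid-rank
#' formula). With a single observed class the AUC is undefined and
#' reported as `NA` with `auc_defined = FALSE`.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @param threshold classification threshold (default 0.5).
#' @return list with `mce`, `auc`, `auc_defined`, `n`.
#' @export
mce_auc <- function(labels, scores, threshold = 0.5) {
  labels <- as.numeric(labels); scores <- as.numeric(scores)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)),
            all(is.finite(scores)))
  pred <- classify(scores, threshold)
  mce <- mean(pred != labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    return(list(mce = mce, auc = NA_real_, auc_defined = FALSE,
                n = length(labels)))
  }
  r <- rank(scores)                     # mid-ranks: ties counted 1/2
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(mce = mce, auc = auc, auc_defined = TRUE, n = length(labels))
}

#' Assemble a train/test fit report
#'
#' Computes the appropriate accuracy metrics for each split: MSE and
#' correlation for a continuous phenotype, misclassification rate and AUC
#' for a binary one.
#'
#' @param y_train,pred_train,y_test,pred_test observed and predicted
#'   values per split (test may be NULL).
#' @param type "continuous" or "binary".
#' @param threshold classification threshold for the binary case.
#' @return object of class `fit_report`: a list of per-split metric lists.
#' @export
fit_report <- function(y_train, pred_train, y_test = NULL, pred_test = NULL,
                       type = c("continuous", "binary"), threshold = 0.5) {
  type <- match.arg(type)
  one <- function(y, p) {
    if (type == "continuous") mse_cor(y, p) else mce_auc(y, p, threshold)
  }
  out <- list(type = type, train = one(y_train, pred_train))
  if (!is.null(y_test)) out$test <- one(y_test, pred_test)
  structure(out, class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(render_fit_report(x), sep = "\n")
  invisible(x)
}

#' Render a fit report as an aligned text table
#' @param report fit_report.
#' @return character vector of lines.
#' @export
render_fit_report <- function(report) {
  stopifnot(inherits(report, "fit_report"))
  if (report$type == "continuous") {
    hdr <- sprintf("%-8s %12s %12s %8s", "split", "MSE", "Cor", "n")
    row <- function(nm, m) sprintf("%-8s %12.6f %12.6f %8d", nm, m$mse, m$cor, m$n)
  } else {
    hdr <- sprintf("%-8s %12s %12s %8s", "split", "MCE", "AUC", "n")
    row <- function(nm, m) sprintf("%-8s %12.6f %12.6f %8d", nm, m$mce,
                                   if (is.na(m$auc)) NaN else m$auc, m$n)
  }
  lines <- hdr
  for (nm in intersect(c("train", "test"), names(report)))
    lines <- c(lines, row(nm, report[[nm]]))
  lines
}

#' Serialize a fit report to JSON
#' @param report fit_report.
#' @param path optional output file; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
fit_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "fit_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
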