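#' Genotype matrix container
#'
#' Holds an n x p allele-count (dosage) matrix together with sample and
#' variant metadata, mirroring the information content of a PLINK fileset.
#' Dosages count copies of `allele1` (the A1 allele), so values are 0, 1, 2
#' or `NA` for missing.
#'
#' @param dosages n x p numeric matrix with entries in \{0, 1, 2, NA\}.
#' @param samples data.frame with columns `fid`, `iid` (one row per sample).
#' @param variants data.frame with columns `chrom`, `id`, `cm`, `bp`,
#'   `allele1`, `allele2` (one row per variant).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, samples, variants) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages); p <- ncol(dosages)
  if (n < 1L || p < 1L) .stopf("genotype matrix must have >= 1 sample and >= 1 variant")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (!all(c("fid", "iid") %in% names(samples)))
    .stopf("samples needs columns fid, iid")
  need <- c("chrom", "id", "cm", "bp", "allele1", "allele2")
  if (!all(need %in% names(variants)))
    .stopf("variants needs columns %s", paste(need, collapse = ", "))
  if (nrow(samples) != n) .stopf("samples rows (%d) != dosage rows (%d)", nrow(samples), n)
  if (nrow(variants) != p) .stopf("variants rows (%d) != dosage cols (%d)", nrow(variants), p)
  bad <- !(dosages %in% c(0, 1, 2)) & !is.na(dosages)
  if (any(bad)) .stopf("dosages must be 0, 1, 2 or NA; %d offending entries", sum(bad))
  structure(list(dosages = dosages, samples = samples[c("fid", "iid")],
                 variants = variants[need]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d missing calls)\n",
              nrow(x$dosages), ncol(x$dosages), sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Sample keys of a genetic object
#'
#' Returns the `(fid, iid)` key data.frame of a genotype matrix, kernel
#' matrix or phenotype table; used for alignment across sources.
#'
#' @param x object with sample identity.
#' @return data.frame with columns `fid`, `iid`.
#' @export
sample_keys <- function(x) UseMethod("sample_keys")

#' @export
sample_keys.genotype_matrix <- function(x) x$samples

#' @export
sample_keys.data.frame <- function(x) x[c("fid", "iid")]

.key_str <- function(keys) paste(keys$fid, keys$iid, sep = "\r")

#' Subset samples of a genotype matrix
#'
#' @param x genotype_matrix.
#' @param idx integer or logical index over samples.
#' @return genotype_matrix restricted to the selected samples.
#' @export
subset_samples <- function(x, idx) {
  stopifnot(inherits(x, "genotype_matrix"))
  genotype_matrix(x$dosages[idx, , drop = FALSE], x$samples[idx, , drop = FALSE],
                  x$variants)
}

#' Subset variants of a genotype matrix
#' @param x genotype_matrix.
#' @param idx integer or logical index over variants.
#' @return genotype_matrix restricted to the selected variants.
#' @export
subset_variants <- function(x, idx) {
  stopifnot(inherits(x, "genotype_matrix"))
  genotype_matrix(x$dosages[, idx, drop = FALSE], x$samples,
                  x$variants[idx, , drop = FALSE])
}

#' Mean-impute missing dosages per variant
#'
#' Missing calls are replaced by the per-variant mean dosage among observed
#' calls (the GCTA-style default applied immediately before kernel
#' construction). Variants that are entirely missing become all-zero.
#'
#' @param x genotype_matrix.
#' @return genotype_matrix with no missing dosages; imputed entries are
#'   fractional, which downstream kernel code accepts.
#' @export
impute_missing <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- x$dosages
  if (!anyNA(d)) return(x)
  mu <- colMeans(d, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2L]]
  out <- x
  out$dosages <- d
  out
}

# numeric dosage matrix, imputed; internal entry point for kernels / FNN
.geno_values <- function(x, impute = TRUE) {
  d <- if (inherits(x, "genotype_matrix")) x$dosages else as.matrix(x)
  if (impute && anyNA(d)) d <- impute_missing(
    if (inherits(x, "genotype_matrix")) x else
      genotype_matrix(d, data.frame(fid = paste0("F", seq_len(nrow(d))),
                                    iid = paste0("I", seq_len(nrow(d)))),
                      .default_variants(ncol(d))))$dosages
  d
}

.default_variants <- function(p, chrom = 1L, bp = NULL) {
  data.frame(chrom = chrom, id = paste0("snp", seq_len(p)), cm = 0,
             bp = if (is.null(bp)) seq_len(p) * 1000L else bp,
             allele1 = "A", allele2 = "C", stringsAsFactors = FALSE)
}
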