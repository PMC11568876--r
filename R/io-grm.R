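# GCTA binary GRM I/O: *.grm.bin holds the lower triangle (i >= j,
# row-major) in single precision, *.grm.id the sample keys, *.grm.N.bin the
# per-pair marker counts in the same packed order.

#' Read a GCTA binary GRM
#'
#' @param prefix path prefix; `prefix.grm.bin` and `prefix.grm.id` must
#'   exist, `prefix.grm.N.bin` is attached when present.
#' @return square `kernel_matrix` of kind "custom" with ids in file order;
#'   pair counts, if present, in `params$n_markers`.
#' @export
read_grm_bin <- function(prefix) {
  bin <- paste0(prefix, ".grm.bin"); idf <- paste0(prefix, ".grm.id")
  for (f in c(bin, idf)) if (!file.exists(f)) .stopf("missing file %s", f)
  ids <- utils::read.table(idf, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  ids <- data.frame(fid = ids[[1]], iid = ids[[2]], stringsAsFactors = FALSE)
  n <- nrow(ids)
  npair <- n * (n + 1) / 2
  if (file.size(bin) != 4 * npair)
    .stopf("%s: expected %d bytes for n = %d (lower triangle, float32), found %d",
           bin, 4 * npair, n, file.size(bin))
  tri <- readBin(bin, "numeric", n = npair, size = 4)
  k <- matrix(0, n, n)
  k[upper.tri(k, diag = TRUE)] <- tri   # column-wise upper == row-wise lower
  k <- k + t(k) - diag(diag(k))
  params <- list()
  nf <- paste0(prefix, ".grm.N.bin")
  if (file.exists(nf) && file.size(nf) == 4 * npair) {
    nm <- readBin(nf, "numeric", n = npair, size = 4)
    nmat <- matrix(0, n, n)
    nmat[upper.tri(nmat, diag = TRUE)] <- nm
    params$n_markers <- nmat + t(nmat) - diag(diag(nmat))
  }
  kernel_matrix(k, ids, kind = "custom", params = params)
}

#' Write a kernel matrix as a GCTA binary GRM
#'
#' @param k square kernel_matrix (or symmetric matrix).
#' @param prefix output path prefix; writes `prefix.grm.bin`,
#'   `prefix.grm.id` and `prefix.grm.N.bin`.
#' @param n_markers marker count written for every pair (scalar or packed
#'   vector); defaults to the kernel's `params$p` when known, else 1.
#' @return `prefix`, invisibly.
#' @export
write_grm_bin <- function(k, prefix, n_markers = NULL) {
  if (inherits(k, "kernel_matrix")) {
    if (!k$square) .stopf("only square kernels can be written as a GRM")
    v <- k$values; ids <- k$row_ids
    if (is.null(n_markers)) n_markers <- k$params$p
  } else {
    v <- as.matrix(k)
    if (!.is_square_sym(v)) .stopf("GRM input must be symmetric")
    ids <- data.frame(fid = paste0("F", seq_len(nrow(v))),
                      iid = paste0("I", seq_len(nrow(v))))
  }
  if (is.null(n_markers)) n_markers <- 1
  n <- nrow(v)
  tri <- v[upper.tri(v, diag = TRUE)]     # == row-major lower triangle
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(tri), con, size = 4)
  close(con)
  utils::write.table(ids, paste0(prefix, ".grm.id"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(rep_len(n_markers, n * (n + 1) / 2)), con, size = 4)
  close(con)
  invisible(prefix)
}
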