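# PLINK genotype I/O.
#
# bed encoding (SNP-major, 2 bits per call, 4 calls per byte, low bits
# first): 00 = homozygous A1 (dosage 2), 10 = heterozygous (1),
# 11 = homozygous A2 (0), 01 = missing. Dosages count copies of the bim A1
# allele throughout the package.

.BED_MAGIC <- as.raw(c(0x6c, 0x1b))
.BED_SNP_MAJOR <- as.raw(0x01)
# 2-bit code -> dosage (code 0,1,2,3)
.BED_DECODE <- c(2, NA, 1, 0)

.read_fam <- function(path) {
  f <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(f) < 2L) .stopf("fam file %s has fewer than 2 columns", path)
  data.frame(fid = f[[1]], iid = f[[2]], stringsAsFactors = FALSE)
}

.read_bim <- function(path) {
  b <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "numeric",
                                        "numeric", "character", "character"))
  names(b) <- c("chrom", "id", "cm", "bp", "allele1", "allele2")
  b
}

#' Read PLINK binary genotypes (bed/bim/fam)
#'
#' Decodes the 2-bit SNP-major bed format; dosages count copies of the bim
#' A1 allele (00 -> 2, 10 -> 1, 11 -> 0, 01 -> missing). Sample order
#' follows the fam file, variant order the bim file.
#'
#' @param prefix path prefix; `prefix.bed`, `prefix.bim`, `prefix.fam` must
#'   exist.
#' @return genotype_matrix.
#' @export
read_plink_bed <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  for (f in paste0(prefix, c(".bed", ".bim", ".fam")))
    if (!file.exists(f)) .stopf("missing file %s", f)
  samples <- .read_fam(paste0(prefix, ".fam"))
  variants <- .read_bim(paste0(prefix, ".bim"))
  n <- nrow(samples); p <- nrow(variants)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || !identical(raw[1:2], .BED_MAGIC))
    .stopf("%s: bad magic bytes; not a PLINK bed file", bed)
  if (!identical(raw[3], .BED_SNP_MAJOR))
    .stopf("%s: only SNP-major bed files are supported", bed)
  bpv <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bpv * p)
    .stopf("%s: truncated; expected %d data bytes, found %d", bed, bpv * p,
           length(body))
  bytes <- matrix(as.integer(body), nrow = bpv, ncol = p)
  dos <- matrix(NA_real_, n, p)
  for (pos in 0:3) {
    rows <- seq.int(pos + 1L, by = 4L, length.out = bpv)
    rows <- rows[rows <= n]
    if (!length(rows)) next
    code <- bitwAnd(bitwShiftR(bytes[seq_along(rows), , drop = FALSE],
                               2L * pos), 3L)
    dos[rows, ] <- .BED_DECODE[code + 1L]
  }
  genotype_matrix(dos, samples, variants)
}

#' Read PLINK text genotypes (ped/map)
#'
#' Parses allele pairs from the ped file. The counted (A1) allele of each
#' variant is the minor allele by observed frequency, ties broken toward
#' the lexicographically smaller allele; a monomorphic variant gets A1 "0"
#' (absent) so its dosages are all zero, matching PLINK's convention.
#' Allele pairs "0 0" are missing.
#'
#' @param prefix path prefix; `prefix.ped` and `prefix.map` must exist.
#' @return genotype_matrix equivalent to the binary reader on the same data.
#' @export
read_plink_text <- function(prefix) {
  ped <- paste0(prefix, ".ped"); map <- paste0(prefix, ".map")
  for (f in c(ped, map)) if (!file.exists(f)) .stopf("missing file %s", f)
  m <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "numeric",
                                        "numeric"))
  names(m) <- c("chrom", "id", "cm", "bp")
  p <- nrow(m)
  lines <- readLines(ped)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  n <- length(toks)
  nfield <- lengths(toks)
  if (any(nfield != 6L + 2L * p))
    .stopf("ped rows must have 6 + 2p fields (p = %d); row %d has %d", p,
           which(nfield != 6L + 2L * p)[1], nfield[nfield != 6L + 2L * p][1])
  tm <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  samples <- data.frame(fid = tm[, 1], iid = tm[, 2], stringsAsFactors = FALSE)
  a_odd <- tm[, 6L + 2L * seq_len(p) - 1L, drop = FALSE]
  a_even <- tm[, 6L + 2L * seq_len(p), drop = FALSE]
  dos <- matrix(NA_real_, n, p)
  a1 <- a2 <- character(p)
  for (j in seq_len(p)) {
    al <- c(a_odd[, j], a_even[, j])
    obs <- al[al != "0"]
    miss <- a_odd[, j] == "0" | a_even[, j] == "0"
    if (!length(obs)) { a1[j] <- "0"; a2[j] <- "0"; next }
    tab <- sort(table(obs))
    alleles <- names(tab)
    if (length(alleles) > 2L)
      .stopf("variant %s has more than two alleles", m$id[j])
    if (length(alleles) == 1L) {
      a1[j] <- "0"; a2[j] <- alleles[1]
    } else {
      if (tab[1] == tab[2]) alleles <- sort(alleles)
      a1[j] <- alleles[1]; a2[j] <- alleles[2]
    }
    cnt <- (a_odd[, j] == a1[j]) + (a_even[, j] == a1[j])
    cnt[miss] <- NA
    dos[, j] <- cnt
  }
  variants <- cbind(m, data.frame(allele1 = a1, allele2 = a2,
                                  stringsAsFactors = FALSE))
  genotype_matrix(dos, samples, variants)
}

#' Write genotypes in PLINK format
#'
#' @param x genotype_matrix.
#' @param prefix output path prefix.
#' @param format "bed" writes bed/bim/fam (2-bit binary, SNP-major); "ped"
#'   writes ped/map text.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(x, prefix, format = c("bed", "ped")) {
  stopifnot(inherits(x, "genotype_matrix"))
  format <- match.arg(format)
  n <- nrow(x$dosages); p <- ncol(x$dosages)
  if (format == "bed") {
    utils::write.table(cbind(x$samples$fid, x$samples$iid, 0, 0, 0, -9),
                       paste0(prefix, ".fam"), quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(x$variants[c("chrom", "id", "cm", "bp", "allele1",
                                    "allele2")],
                       paste0(prefix, ".bim"), quote = FALSE,
                       row.names = FALSE, col.names = FALSE, sep = "\t")
    # dosage -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
    enc <- matrix(1L, n, p)
    d <- x$dosages
    enc[!is.na(d) & d == 2] <- 0L
    enc[!is.na(d) & d == 1] <- 2L
    enc[!is.na(d) & d == 0] <- 3L
    bpv <- ceiling(n / 4)
    pad <- bpv * 4L - n
    if (pad > 0) enc <- rbind(enc, matrix(0L, pad, p))
    i4 <- matrix(seq_len(bpv * 4L), nrow = 4L)
    bytes <- enc[i4[1L, ], , drop = FALSE] +
      enc[i4[2L, ], , drop = FALSE] * 4L +
      enc[i4[3L, ], , drop = FALSE] * 16L +
      enc[i4[4L, ], , drop = FALSE] * 64L
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(c(.BED_MAGIC, .BED_SNP_MAJOR), con)
    writeBin(as.raw(as.vector(bytes)), con)
  } else {
    utils::write.table(x$variants[c("chrom", "id", "cm", "bp")],
                       paste0(prefix, ".map"), quote = FALSE,
                       row.names = FALSE, col.names = FALSE, sep = "\t")
    d <- x$dosages
    a1 <- x$variants$allele1; a2 <- x$variants$allele2
    rows <- vapply(seq_len(n), function(i) {
      g <- d[i, ]
      first <- ifelse(is.na(g), "0", ifelse(g >= 1, a1, a2))
      second <- ifelse(is.na(g), "0", ifelse(g == 2, a1, a2))
      paste(c(x$samples$fid[i], x$samples$iid[i], "0", "0", "0", "-9",
              as.vector(rbind(first, second))), collapse = " ")
    }, character(1))
    writeLines(rows, paste0(prefix, ".ped"))
  }
  invisible(prefix)
}

#' Read a phenotype / covariate table
#'
#' Whitespace-delimited text with family ID and individual ID in the first
#' two columns and phenotypes or covariates after. Values matching a
#' missing code (default "-9" and "NA") are set to `NA` and flagged; rows
#' are retained so alignment stays by key.
#'
#' @param path file path.
#' @param column 1-based index of the phenotype column (among the non-key
#'   columns) marked as the default response.
#' @param missing_codes character vector of missing-value codes.
#' @param header set TRUE if the file carries a header line.
#' @return data.frame of class `pheno_table` with columns `fid`, `iid`, the
#'   value columns, and attribute `column` naming the selected phenotype.
#' @export
read_pheno <- function(path, column = 1, missing_codes = c("-9", "NA"),
                       header = FALSE) {
  tb <- utils::read.table(path, header = header, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(tb) < 3L) .stopf("%s: need >= 3 columns (fid iid value...)", path)
  names(tb)[1:2] <- c("fid", "iid")
  if (!header)
    names(tb)[-(1:2)] <- paste0("V", seq_len(ncol(tb) - 2L))
  key <- paste(tb$fid, tb$iid)
  if (anyDuplicated(key))
    .stopf("%s: duplicate (fid, iid) key: %s", path, key[duplicated(key)][1])
  for (j in seq(3L, ncol(tb))) {
    v <- tb[[j]]
    v[v %in% missing_codes] <- NA
    tb[[j]] <- suppressWarnings(as.numeric(v))
  }
  if (column < 1 || column > ncol(tb) - 2L)
    .stopf("phenotype column %s out of range", column)
  structure(tb, class = c("pheno_table", "data.frame"),
            column = names(tb)[2L + column])
}

#' Write a phenotype table
#'
#' @param keys data.frame with `fid`, `iid`.
#' @param values numeric vector or matrix of phenotype/covariate columns.
#' @param path output file.
#' @param missing_code code written for `NA` (default "-9").
#' @return `path`, invisibly.
#' @export
write_pheno <- function(keys, values, path, missing_code = "-9") {
  values <- as.matrix(values)
  out <- cbind(keys$fid, keys$iid,
               apply(values, 2, function(v) ifelse(is.na(v), missing_code,
                                                   format(v, digits = 10))))
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Phenotype values of the selected column
#' @param tbl pheno_table.
#' @param column column index or name; default the table's selected column.
#' @return numeric vector.
#' @export
pheno_values <- function(tbl, column = NULL) {
  if (is.null(column)) column <- attr(tbl, "column")
  if (is.numeric(column)) column <- names(tbl)[2L + column]
  tbl[[column]]
}

#' Align samples across genetic data sources by (fid, iid)
#'
#' Joins a genotype matrix or kernel matrix with a phenotype table on the
#' (family ID, individual ID) key — never by row position. Returns the
#' intersection in the genotype/kernel sample order and fails loudly when
#' the sources share no samples.
#'
#' @param x genotype_matrix or square kernel_matrix.
#' @param pheno pheno_table (or data.frame with fid/iid plus values).
#' @return list with `x` (subset, same class as input), `pheno` (rows
#'   reordered to match) and `idx` (positions kept in `x`).
#' @export
intersect_samples <- function(x, pheno) {
  xk <- .key_str(sample_keys(x))
  pk <- .key_str(sample_keys(pheno))
  keep <- which(xk %in% pk)
  if (!length(keep))
    .stopf("no samples shared between genotype/kernel and phenotype sources")
  ord <- match(xk[keep], pk)
  xs <- if (inherits(x, "genotype_matrix")) subset_samples(x, keep)
  else kernel_matrix(x$values[keep, keep, drop = FALSE],
                     x$row_ids[keep, , drop = FALSE], kind = x$kind,
                     params = x$params)
  list(x = xs, pheno = pheno[ord, , drop = FALSE], idx = keep)
}
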