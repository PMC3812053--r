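#' Read PLINK 1 binary genotypes
#'
#' Decodes a SNP-major PLINK 1 \code{.bed}/\code{.bim}/\code{.fam} fileset.
#' Two-bit codes per the format definition: 00 = homozygous A1 (dosage 2 of
#' the counted A1 allele), 01 = missing, 10 = heterozygous, 11 = homozygous
#' A2 (dosage 0). Row (sample) and column (SNP) order follow the
#' \code{.fam} and \code{.bim} files.
#'
#' @param prefix path prefix (without extension).
#' @return a \code{\link{genotype_matrix}}.
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = "character")
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed, "raw", n = file.info(bed)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop_snpher("snpher_format_error", "%s: bad PLINK .bed magic bytes", bed)
  if (raw[3] == as.raw(0x00))
    stop_snpher("snpher_format_error", "%s: individual-major .bed not supported", bed)
  if (raw[3] != as.raw(0x01))
    stop_snpher("snpher_format_error", "%s: unknown .bed mode byte", bed)
  bps <- ceiling(n / 4)  # bytes per SNP
  if (length(raw) - 3 != bps * m)
    stop_snpher("snpher_format_error",
                "%s: payload is %d bytes, expected %d for %d samples x %d SNPs",
                bed, length(raw) - 3, bps * m, n, m)
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bps)
  # expand each byte into 4 two-bit codes (low bits first)
  codes <- matrix(0L, nrow = bps * 4, ncol = m)
  b <- body
  for (k in 1:4) {
    codes[seq(k, by = 4, length.out = bps), ] <- b %% 4L
    b <- b %/% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # 0 -> 2 copies of A1, 1 -> NA, 2 -> 1, 3 -> 0
  calls <- matrix(c(2L, NA_integer_, 1L, 0L)[codes + 1L], nrow = n)
  snps <- data.frame(id = bim$V2, chr = bim$V1, pos = bim$V4,
                     a1 = bim$V5, a2 = bim$V6, stringsAsFactors = FALSE)
  genotype_matrix(calls, data.frame(fid = fam$V1, iid = fam$V2,
                                    stringsAsFactors = FALSE), snps)
}

#' Write PLINK 1 binary genotypes
#'
#' Writes a bit-exact SNP-major \code{.bed} with matching \code{.bim} and
#' \code{.fam}; round-trips through \code{\link{read_plink}}.
#'
#' @param g a \code{\link{genotype_matrix}} (chromosomes 1-22, alleles set).
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_plink <- function(g, prefix) {
  if (any(is.na(g$snps$a1)) || any(is.na(g$snps$a2)) ||
      any(g$snps$a1 == "") || any(g$snps$a2 == ""))
    stop_snpher("snpher_format_error", "missing alleles in SNP table")
  if (any(g$snps$chr < 1 | g$snps$chr > 22))
    stop_snpher("snpher_format_error", "chromosomes must be in 1..22")
  n <- n_samples(g); m <- n_snps(g)
  # dosage -> two-bit code
  code <- matrix(1L, nrow = n, ncol = m)  # missing
  code[which(g$calls == 2L)] <- 0L
  code[which(g$calls == 1L)] <- 2L
  code[which(g$calls == 0L)] <- 3L
  bps <- ceiling(n / 4)
  padded <- matrix(0L, nrow = bps * 4, ncol = m)
  padded[seq_len(n), ] <- code
  bytes <- padded[seq(1, by = 4, length.out = bps), , drop = FALSE] +
    4L * padded[seq(2, by = 4, length.out = bps), , drop = FALSE] +
    16L * padded[seq(3, by = 4, length.out = bps), , drop = FALSE] +
    64L * padded[seq(4, by = 4, length.out = bps), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  utils::write.table(data.frame(g$snps$chr, g$snps$id, 0, g$snps$pos,
                                g$snps$a1, g$snps$a2),
                     paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(g$samples$fid, g$samples$iid, 0, 0, 0, -9),
                     paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read / write GCTA binary GRM filesets
#'
#' \code{.grm.bin} holds the lower triangle (including the diagonal) of the
#' relatedness matrix row-major as little-endian 4-byte floats;
#' \code{.grm.N.bin} holds the per-pair non-missing SNP counts in the same
#' layout; \code{.grm.id} is a two-column FID/IID text file.
#'
#' @param prefix path prefix (without extension).
#' @return \code{read_grm_bin} returns a \code{grm} object (see
#'   \code{\link{compute_grm}}); \code{write_grm_bin} returns \code{prefix}
#'   invisibly. Round-trips are exact to float32 precision.
#' @export
read_grm_bin <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           colClasses = "character")
  n <- nrow(ids)
  ntri <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = ntri + 1,
                  size = 4, endian = "little")
  if (length(vals) != ntri)
    stop_snpher("snpher_format_error",
                "%s.grm.bin holds %d values, expected %d for %d ids",
                prefix, length(vals), ntri, n)
  nfile <- paste0(prefix, ".grm.N.bin")
  cnts <- if (file.exists(nfile)) {
    x <- readBin(nfile, "numeric", n = ntri + 1, size = 4, endian = "little")
    if (length(x) != ntri)
      stop_snpher("snpher_format_error", "%s: triangle length mismatch", nfile)
    x
  } else rep(NA_real_, ntri)
  A <- matrix(0, n, n); N <- matrix(0, n, n)
  lt <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
  lt <- lt[order(lt[, 1], lt[, 2]), , drop = FALSE]
  A[lt] <- vals; N[lt] <- cnts
  A <- A + t(A) - diag(diag(A))
  N <- N + t(N) - diag(diag(N))
  new_grm(A, data.frame(fid = ids$V1, iid = ids$V2, stringsAsFactors = FALSE),
          pair_counts = N, snp_set = basename(prefix))
}

#' @rdname read_grm_bin
#' @param grm a \code{grm} object.
#' @export
write_grm_bin <- function(grm, prefix) {
  n <- nrow(grm$A)
  lt <- which(lower.tri(grm$A, diag = TRUE), arr.ind = TRUE)
  lt <- lt[order(lt[, 1], lt[, 2]), , drop = FALSE]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(grm$A[lt]), con, size = 4, endian = "little")
  close(con)
  cnts <- grm$pair_counts
  if (is.null(cnts)) cnts <- matrix(0, n, n)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(cnts[lt]), con, size = 4, endian = "little")
  close(con)
  utils::write.table(grm$ids, paste0(prefix, ".grm.id"), quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Write a phenotype file (FID IID status)
#'
#' Whitespace-delimited, one row per individual, using the 1 = control /
#' 2 = case dialect; missing = -9.
#'
#' @param samples data.frame with \code{fid}, \code{iid}.
#' @param status 0/1 vector (1 = case) or NA.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_phenotype <- function(samples, status, path) {
  code <- ifelse(is.na(status), -9L, as.integer(status) + 1L)
  utils::write.table(data.frame(samples$fid, samples$iid, code), path,
                     quote = FALSE, sep = " ", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate file
#'
#' Whitespace-delimited FID IID value(s); \code{-9} and \code{NA} are
#' treated as missing. A two-valued 1/2 phenotype column is recoded to 0/1.
#'
#' @param path input file.
#' @return data.frame with \code{fid}, \code{iid} and value columns.
#' @export
read_phenotype <- function(path) {
  x <- utils::read.table(path, header = FALSE, colClasses = "character")
  out <- data.frame(fid = x$V1, iid = x$V2, stringsAsFactors = FALSE)
  for (j in seq(3, ncol(x))) {
    v <- suppressWarnings(as.numeric(x[[j]]))
    v[v == -9] <- NA
    out[[paste0("v", j - 2)]] <- v
  }
  if (ncol(out) == 3 && all(out$v1 %in% c(1, 2, NA)))
    out$v1 <- out$v1 - 1
  out
}
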