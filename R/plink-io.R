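#' Read a PLINK binary genotype fileset
#'
#' Reads a `.bed`/`.bim`/`.fam` triple (SNP-major `.bed`, magic bytes
#' `0x6c 0x1b 0x01`) into a [geno_matrix()]. The dosage counts copies of
#' allele 1 of the `.bim` record, i.e. allele 1 is the effect allele.
#'
#' Two-bit codes are decoded per the standard encoding: `00` = homozygous
#' allele 1 (dosage 2), `01` = missing, `10` = heterozygous (dosage 1),
#' `11` = homozygous allele 2 (dosage 0). Samples are packed 4 per byte,
#' least-significant bits first.
#'
#' @param prefix Path prefix; `<prefix>.bed`, `<prefix>.bim` and
#'   `<prefix>.fam` must all exist.
#' @return A [geno_matrix()].
#' @seealso [write_plink()]
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    rlang::abort(paste0("missing PLINK file(s): ", paste(missing, collapse = ", ")))
  }

  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  bim <- if (file.size(paths[2]) > 0) {
    utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                      colClasses = c("character", "character", "numeric",
                                     "integer", "character", "character"))
  } else {
    data.frame(V1 = character(), V2 = character(), V3 = numeric(),
               V4 = integer(), V5 = character(), V6 = character())
  }
  n <- nrow(fam)
  m <- nrow(bim)

  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    rlang::abort("not a PLINK .bed file: bad magic bytes", class = "plink_format_error")
  }
  if (raw[3] != as.raw(0x01)) {
    rlang::abort("only SNP-major .bed files are supported", class = "plink_format_error")
  }
  bytes_per_snp <- ceiling(n / 4)
  expected <- 3 + bytes_per_snp * m
  if (length(raw) != expected) {
    rlang::abort(
      sprintf(".bed payload truncated or oversized: expected %d bytes, found %d",
              expected, length(raw)),
      class = "plink_format_error"
    )
  }

  # vectorized decode: expand every byte into its 4 two-bit codes
  payload <- as.integer(raw[-(1:3)])
  codes <- rbind(
    payload %% 4L,
    (payload %/% 4L) %% 4L,
    (payload %/% 16L) %% 4L,
    (payload %/% 64L) %% 4L
  )
  # per-SNP blocks of 4 * bytes_per_snp slots; keep first n
  dim(codes) <- c(4L * bytes_per_snp, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  lookup <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  dos <- matrix(lookup[codes + 1L], nrow = n, ncol = m)

  geno_matrix(
    dos,
    snp_meta = tibble::tibble(
      snp_id = bim$V2, chrom = bim$V1, pos = bim$V4,
      allele1 = bim$V5, allele2 = bim$V6
    ),
    sample_ids = as.character(fam$V2)
  )
}

#' Write a PLINK binary genotype fileset
#'
#' Inverse of [read_plink()]: `read_plink(write_plink(g, p))` reproduces
#' `g` exactly, including the missingness mask.
#'
#' @param g A [geno_matrix()].
#' @param prefix Output path prefix for the `.bed`/`.bim`/`.fam` triple.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "geno_matrix"))
  dir <- dirname(prefix)
  if (!dir.exists(dir)) rlang::abort(paste0("directory does not exist: ", dir))

  n <- n_samples(g)
  m <- n_snps(g)
  meta <- g$snp_meta

  fam <- data.frame(g$sample_ids, g$sample_ids, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  bim <- data.frame(meta$chrom, meta$snp_id, rep(0, nrow(meta)), meta$pos,
                    meta$allele1, meta$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")

  # dosage -> 2-bit code
  code_of <- function(d) {
    out <- integer(length(d))
    out[is.na(d)] <- 1L
    out[!is.na(d) & d == 2L] <- 0L
    out[!is.na(d) & d == 1L] <- 2L
    out[!is.na(d) & d == 0L] <- 3L
    out
  }
  bytes_per_snp <- ceiling(n / 4)
  slots <- 4L * bytes_per_snp
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (m > 0) {
    codes <- matrix(0L, nrow = slots, ncol = m)
    codes[seq_len(n), ] <- apply(g$dosages, 2, code_of)
    dim(codes) <- c(4L, bytes_per_snp * m)
    bytes <- codes[1, ] + 4L * codes[2, ] + 16L * codes[3, ] + 64L * codes[4, ]
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read / write the text dosage dialect
#'
#' A TSV with a header row of SNP ids, one row per sample, first column
#' `sample_id`, remaining cells in `{0, 1, 2, NA}`. The dialect carries no
#' positional metadata; `snp_meta` may be supplied, otherwise placeholder
#' metadata (chromosome `"0"`, positions 1..m, alleles `A`/`B`) is attached.
#'
#' @param path TSV file path.
#' @param snp_meta Optional data frame as in [geno_matrix()].
#' @return A [geno_matrix()].
#' @export
read_dosage_tsv <- function(path, snp_meta = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  dos <- as.matrix(tab[, -1, drop = FALSE])
  if (is.null(snp_meta)) {
    snp_meta <- tibble::tibble(
      snp_id = colnames(dos), chrom = "0", pos = seq_len(ncol(dos)),
      allele1 = "A", allele2 = "B"
    )
  }
  geno_matrix(dos, snp_meta, ids)
}

#' @rdname read_dosage_tsv
#' @param g A [geno_matrix()].
#' @export
write_dosage_tsv <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  tab <- data.frame(sample_id = g$sample_ids, g$dosages, check.names = FALSE)
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
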