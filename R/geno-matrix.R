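#' Genotype dosage matrix
#'
#' Container for a samples x SNPs matrix of effect-allele dosages together
#' with per-SNP metadata. Dosages count copies of allele 1 (the declared
#' effect allele) and are restricted to 0, 1, 2 or `NA` (missing).
#'
#' @param dosages Numeric matrix, samples in rows, SNPs in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param snp_meta Data frame with one row per SNP: columns `snp_id`,
#'   `chrom`, `pos` (1-based base-pair position), `allele1` (effect /
#'   counted allele), `allele2`.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   row of `dosages`.
#'
#' @return An object of class `geno_matrix`: a list with elements `dosages`
#'   (integer matrix with dimnames), `snp_meta` (tibble) and `sample_ids`.
#' @examples
#' g <- geno_matrix(
#'   matrix(c(0, 1, 2, NA, 0, 1), nrow = 3),
#'   snp_meta = data.frame(
#'     snp_id = c("rs1", "rs2"), chrom = c(1L, 1L), pos = c(100L, 200L),
#'     allele1 = c("A", "C"), allele2 = c("G", "T")
#'   ),
#'   sample_ids = c("s1", "s2", "s3")
#' )
#' n_snps(g)
#' @export
geno_matrix <- function(dosages, snp_meta, sample_ids) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  snp_meta <- tibble::as_tibble(snp_meta)
  sample_ids <- as.character(sample_ids)

  need <- c("snp_id", "chrom", "pos", "allele1", "allele2")
  if (!all(need %in% names(snp_meta))) {
    rlang::abort(paste0(
      "snp_meta must have columns: ", paste(need, collapse = ", ")
    ))
  }
  if (nrow(snp_meta) != ncol(dosages)) {
    rlang::abort("snp_meta must have one row per dosage column")
  }
  snp_meta$snp_id <- as.character(snp_meta$snp_id)
  snp_meta$chrom <- as.character(snp_meta$chrom)
  snp_meta$pos <- as.integer(snp_meta$pos)
  snp_meta$allele1 <- as.character(snp_meta$allele1)
  snp_meta$allele2 <- as.character(snp_meta$allele2)
  if (length(sample_ids) != nrow(dosages)) {
    rlang::abort("sample_ids must have one entry per dosage row")
  }
  if (anyDuplicated(sample_ids)) rlang::abort("sample_ids must be unique")
  if (anyDuplicated(snp_meta$snp_id)) rlang::abort("snp ids must be unique")
  bad <- !(dosages %in% c(0L, 1L, 2L, NA))
  if (any(bad)) rlang::abort("dosages must be 0, 1, 2 or NA")
  if (any(snp_meta$pos < 0)) rlang::abort("positions must be non-negative")

  rownames(dosages) <- sample_ids
  colnames(dosages) <- snp_meta$snp_id
  structure(
    list(dosages = dosages, snp_meta = snp_meta, sample_ids = sample_ids),
    class = "geno_matrix"
  )
}

#' @rdname geno_matrix
#' @param x A `geno_matrix`.
#' @export
n_samples <- function(x) UseMethod("n_samples")

#' @export
n_samples.geno_matrix <- function(x) nrow(x$dosages)

#' @rdname geno_matrix
#' @export
n_snps <- function(x) UseMethod("n_snps")

#' @export
n_snps.geno_matrix <- function(x) ncol(x$dosages)

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d samples x %d SNPs (%.2f%% missing)\n",
    n_samples(x), n_snps(x),
    if (length(x$dosages)) 100 * mean(is.na(x$dosages)) else 0
  ))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x A `geno_matrix`.
#' @param samples Row index (logical, integer or sample-id character vector).
#' @param snps Column index (logical, integer or snp-id character vector).
#' @return A `geno_matrix` restricted to the requested rows/columns.
#' @export
subset_geno <- function(x, samples = NULL, snps = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  d <- x$dosages
  meta <- x$snp_meta
  ids <- x$sample_ids
  if (!is.null(snps)) {
    j <- if (is.character(snps)) match(snps, meta$snp_id) else seq_len(ncol(d))[snps]
    if (anyNA(j)) rlang::abort("unknown snp ids in subset")
    d <- d[, j, drop = FALSE]
    meta <- meta[j, , drop = FALSE]
  }
  if (!is.null(samples)) {
    i <- if (is.character(samples)) match(samples, ids) else seq_len(nrow(d))[samples]
    if (anyNA(i)) rlang::abort("unknown sample ids in subset")
    d <- d[i, , drop = FALSE]
    ids <- ids[i]
  }
  geno_matrix(d, meta, ids)
}

#' Convert a genotype matrix to a tibble of dosages
#'
#' @param x A `geno_matrix`.
#' @param ... Unused.
#' @return A tibble with a `sample_id` column and one column per SNP.
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$dosages))
  dplyr::bind_cols(tibble::tibble(sample_id = x$sample_ids), out)
}
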