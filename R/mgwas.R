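#' Single-SNP association test for a metabolite
#'
#' Ordinary least squares of a metabolite concentration on one SNP dosage
#' plus covariates (age and sex by default), with a two-sided t-test on the
#' dosage slope. Rows with missing dosage, metabolite or covariate values
#' are dropped for that SNP.
#'
#' @param y Numeric metabolite vector.
#' @param dosage Dosage vector in `{0, 1, 2, NA}`.
#' @param covariates Optional data frame / matrix of covariates (no
#'   missing values among used rows).
#' @return A list with `beta`, `se`, `p`, `n` (complete cases used) and
#'   `degenerate` (TRUE when the dosage is constant; then beta = 0, p = 1).
#' @export
single_snp_assoc <- function(y, dosage, covariates = NULL) {
  X_cov <- if (is.null(covariates)) {
    matrix(numeric(0), nrow = length(y), ncol = 0)
  } else {
    as.matrix(covariates)
  }
  ok <- !is.na(y) & !is.na(dosage)
  if (ncol(X_cov)) ok <- ok & stats::complete.cases(X_cov)
  n <- sum(ok)
  p_par <- 2L + ncol(X_cov) # intercept + dosage + covariates
  if (n < p_par + 1L) {
    rlang::abort(sprintf("too few complete cases (%d) for %d parameters", n, p_par))
  }
  g <- dosage[ok]
  if (stats::var(g) == 0) {
    return(list(beta = 0, se = NA_real_, p = 1, n = n, degenerate = TRUE))
  }
  X <- cbind(1, g, X_cov[ok, , drop = FALSE])
  fit <- stats::lm.fit(X, y[ok])
  rss <- sum(fit$residuals^2)
  df <- n - ncol(X)
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- unname(sqrt(sigma2 * XtXinv[2, 2]))
  beta <- unname(fit$coefficients[2])
  tval <- beta / se
  list(beta = beta, se = se,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       n = n, degenerate = FALSE)
}

#' Metabolite genome-wide association scan
#'
#' Runs [single_snp_assoc()] for every (metabolite, SNP) pair, adjusting
#' for the supplied covariates.
#'
#' @param g A [geno_matrix()].
#' @param metabolites Data frame or matrix of metabolite concentrations,
#'   samples in rows; either rownames or a `sample_id` column must align
#'   with `g$sample_ids`.
#' @param covariates Optional covariate data frame aligned the same way
#'   (e.g. columns `age`, `sex`).
#' @return A tibble with columns `metabolite_id`, `snp_id`, `chrom`,
#'   `pos`, `effect_allele`, `beta`, `se`, `p`, `n`.
#' @export
run_mgwas <- function(g, metabolites, covariates = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  M <- align_to_samples(metabolites, g$sample_ids, "metabolites")
  C <- if (is.null(covariates)) NULL else
    align_to_samples(covariates, g$sample_ids, "covariates")
  meta <- g$snp_meta
  dos <- g$dosages

  rows <- purrr::map(colnames(M), function(m_id) {
    y <- M[, m_id]
    res <- purrr::map(seq_len(ncol(dos)), function(j) {
      single_snp_assoc(y, dos[, j], C)
    })
    tibble::tibble(
      metabolite_id = m_id,
      snp_id = meta$snp_id,
      chrom = meta$chrom,
      pos = meta$pos,
      effect_allele = meta$allele1,
      beta = purrr::map_dbl(res, "beta"),
      se = purrr::map_dbl(res, "se"),
      p = purrr::map_dbl(res, "p"),
      n = purrr::map_int(res, ~ as.integer(.x$n))
    )
  })
  dplyr::bind_rows(rows)
}

# align a per-sample table (rownames or sample_id column) to sample_ids;
# returns a numeric matrix with samples in rows
align_to_samples <- function(tab, sample_ids, what = "table") {
  if (is.matrix(tab)) {
    if (!is.null(rownames(tab))) {
      idx <- match(sample_ids, rownames(tab))
      if (anyNA(idx)) {
        rlang::abort(paste0(
          what, " missing samples: ",
          paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", ")
        ))
      }
      return(tab[idx, , drop = FALSE])
    }
    if (nrow(tab) != length(sample_ids)) {
      rlang::abort(paste0(what, " has no sample ids and wrong row count"))
    }
    rownames(tab) <- sample_ids
    return(tab)
  }
  tab <- as.data.frame(tab)
  if ("sample_id" %in% names(tab)) {
    idx <- match(sample_ids, tab$sample_id)
    if (anyNA(idx)) {
      rlang::abort(paste0(
        what, " missing samples: ",
        paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", ")
      ))
    }
    tab <- tab[idx, setdiff(names(tab), "sample_id"), drop = FALSE]
  } else if (!is.null(rownames(tab)) &&
             all(sample_ids %in% rownames(tab))) {
    tab <- tab[sample_ids, , drop = FALSE]
  } else if (nrow(tab) != length(sample_ids)) {
    rlang::abort(paste0(what, " has no sample ids and wrong row count"))
  }
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  rownames(m) <- sample_ids
  m
}

#' Squared LD correlation between two dosage vectors
#'
#' Squared Pearson correlation over pairwise-complete samples. Constant
#' vectors give r-squared 0 with a warning (no LD information).
#'
#' @param g1,g2 Dosage vectors.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  a <- g1[ok]; b <- g2[ok]
  if (length(a) < 2 || stats::var(a) == 0 || stats::var(b) == 0) {
    rlang::warn("constant dosage vector: r^2 defined as 0")
    return(0)
  }
  stats::cor(a, b)^2
}

#' Clumping specification
#'
#' @param window_kb Physical window around an index SNP, kilobases.
#' @param r2_cutoff SNPs with squared correlation above this to the index
#'   SNP (same chromosome, within the window) are removed.
#' @param p_threshold p-value threshold applied before clumping (see
#'   [threshold_by_p()]).
#' @export
clump_spec <- function(window_kb = 250, r2_cutoff = 0.2, p_threshold = 1e-4) {
  if (window_kb <= 0) rlang::abort("window_kb must be positive")
  if (r2_cutoff <= 0 || r2_cutoff > 1) rlang::abort("r2_cutoff must be in (0, 1]")
  if (p_threshold <= 0 || p_threshold > 1) rlang::abort("p_threshold must be in (0, 1]")
  structure(list(window_kb = window_kb, r2_cutoff = r2_cutoff,
                 p_threshold = p_threshold),
            class = "clump_spec")
}

#' Greedy LD clumping of association results
#'
#' Iteratively takes the smallest-p unassigned SNP as an index SNP and
#' removes all unassigned SNPs on the same chromosome within `window_kb`
#' (inclusive) whose squared dosage correlation with it exceeds
#' `r2_cutoff`. Index SNPs form the result. Ties on p are broken by
#' (chromosome, position, snp id) for determinism.
#'
#' @param assoc Association tibble rows for one metabolite (columns
#'   `snp_id`, `chrom`, `pos`, `p`).
#' @param g A [geno_matrix()] holding the dosages of those SNPs.
#' @param spec A [clump_spec()].
#' @return Character vector of retained (index) SNP ids, in selection order.
#' @export
clump <- function(assoc, g, spec = clump_spec()) {
  stopifnot(inherits(g, "geno_matrix"), inherits(spec, "clump_spec"))
  if (!nrow(assoc)) return(character())
  if (!all(assoc$snp_id %in% g$snp_meta$snp_id)) {
    rlang::abort("assoc contains SNPs absent from the genotype matrix")
  }
  ord <- order(assoc$p, assoc$chrom, assoc$pos, assoc$snp_id)
  a <- assoc[ord, , drop = FALSE]
  unassigned <- rep(TRUE, nrow(a))
  keep <- character()
  dcols <- g$dosages[, a$snp_id, drop = FALSE]
  while (any(unassigned)) {
    i <- which(unassigned)[1]
    keep <- c(keep, a$snp_id[i])
    unassigned[i] <- FALSE
    cand <- which(unassigned &
                    a$chrom == a$chrom[i] &
                    abs(a$pos - a$pos[i]) <= spec$window_kb * 1000)
    for (j in cand) {
      r2 <- suppressWarnings(ld_r2(dcols[, i], dcols[, j]))
      if (r2 > spec$r2_cutoff) unassigned[j] <- FALSE
    }
  }
  keep
}

#' Threshold association results by p-value
#'
#' @param assoc Association tibble with a `p` column.
#' @param p_threshold Rows with `p <= p_threshold` are retained.
#' @return The filtered tibble.
#' @export
threshold_by_p <- function(assoc, p_threshold) {
  if (p_threshold <= 0 || p_threshold > 1) {
    rlang::abort("p_threshold must be in (0, 1]")
  }
  out <- dplyr::filter(assoc, .data$p <= p_threshold)
  if (!nrow(out)) {
    rlang::warn("no associations pass the p-value threshold")
  }
  out
}
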