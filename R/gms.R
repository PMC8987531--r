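#' Build a SNP effect set from thresholded + clumped associations
#'
#' Convenience constructor for the "single-SNP" genetic metabolomic score
#' route: for each metabolite, applies [threshold_by_p()] then [clump()]
#' and keeps the regression slopes of the surviving index SNPs as scoring
#' weights.
#'
#' @param assoc Full association tibble from [run_mgwas()].
#' @param g A [geno_matrix()].
#' @param spec A [clump_spec()]; its `p_threshold` is the thresholding
#'   cutoff.
#' @return A tibble (`metabolite_id`, `snp_id`, `effect_allele`, `effect`)
#'   with attribute `method = "single"`. Metabolites with no surviving SNP
#'   have no rows (their scores are zero).
#' @export
single_snp_effects <- function(assoc, g, spec = clump_spec()) {
  out <- assoc |>
    dplyr::group_by(.data$metabolite_id) |>
    dplyr::group_modify(function(rows, key) {
      kept <- suppressWarnings(threshold_by_p(rows, spec$p_threshold))
      if (!nrow(kept)) return(kept[, c("snp_id", "effect_allele", "beta")])
      idx <- clump(kept, g, spec)
      dplyr::filter(kept, .data$snp_id %in% idx)[, c("snp_id", "effect_allele", "beta")]
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(effect = "beta")
  attr(out, "method") <- "single"
  out
}

#' Genetic metabolomic scores from SNP effects
#'
#' Per-sample weighted sums of effect-allele dosages,
#' `score[j, m] = sum_s effect[s, m] * dosage[j, s]`. Effects whose stated
#' effect allele is allele 2 of the genotype record are applied to the
#' reflected dosage `2 - d`. Missing dosages are mean-imputed as twice the
#' effect-allele frequency (computed from the non-missing genotypes).
#'
#' @param g A [geno_matrix()].
#' @param effects Effect-set tibble (`metabolite_id`, `snp_id`,
#'   `effect_allele`, `effect`).
#' @param metabolite_ids Optional full metabolite id set; metabolites with
#'   no effects get all-zero score columns.
#' @return A numeric matrix (samples x metabolites) with dimnames, class
#'   `gms_matrix`, attribute `method` carried over from `effects`.
#' @export
compute_gms <- function(g, effects, metabolite_ids = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  unknown <- setdiff(effects$snp_id, g$snp_meta$snp_id)
  if (length(unknown)) {
    rlang::abort(paste0("unknown SNP ids in effect set: ",
                        paste(utils::head(unknown, 5), collapse = ", ")))
  }
  mets <- metabolite_ids %||% unique(effects$metabolite_id)
  scores <- matrix(0, nrow = n_samples(g), ncol = length(mets),
                   dimnames = list(g$sample_ids, mets))
  if (nrow(effects)) {
    meta <- g$snp_meta
    for (m in intersect(mets, unique(effects$metabolite_id))) {
      e <- effects[effects$metabolite_id == m, , drop = FALSE]
      j <- match(e$snp_id, meta$snp_id)
      d <- g$dosages[, j, drop = FALSE]
      # orient dosages to the stated effect allele
      flip <- e$effect_allele != meta$allele1[j]
      mismatch <- flip & e$effect_allele != meta$allele2[j]
      if (any(mismatch)) {
        rlang::abort(paste0("effect allele matches neither genotype allele for: ",
                            paste(e$snp_id[mismatch], collapse = ", ")))
      }
      if (any(flip)) d[, flip] <- 2L - d[, flip, drop = FALSE]
      storage.mode(d) <- "double"
      # mean imputation at 2 * effect-allele frequency
      for (col in which(colSums(is.na(d)) > 0)) {
        f <- effect_allele_freq(d[, col])
        d[is.na(d[, col]), col] <- 2 * f
      }
      scores[, m] <- d %*% e$effect
    }
  }
  structure(scores, class = c("gms_matrix", "matrix", "array"),
            method = attr(effects, "method"))
}

#' Genomic relationship matrix
#'
#' VanRaden-style GRM of standardized genotypes: column j of `W` is
#' `(dosage - 2 p_j) / sqrt(2 p_j (1 - p_j))` with `p_j` the effect-allele
#' frequency; `GRM = W W' / m`. Missing dosages contribute 0 after
#' centering. Monomorphic SNPs are dropped with a warning.
#'
#' @param g A [geno_matrix()].
#' @return A list of class `grm`: `K` (n x n symmetric matrix), `m`
#'   (number of SNPs used), `freq` (effect-allele frequencies used).
#' @export
compute_grm <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  W <- standardize_genotypes(g)
  if (!ncol(W)) rlang::abort("no polymorphic SNPs available for the GRM")
  K <- tcrossprod(W) / ncol(W)
  dimnames(K) <- list(g$sample_ids, g$sample_ids)
  structure(list(K = K, m = ncol(W), freq = attr(W, "freq"),
                 snp_id = colnames(W)),
            class = "grm")
}

# standardized genotype matrix W (missing -> 0 after centering);
# drops monomorphic columns, keeps frequencies as an attribute
standardize_genotypes <- function(g) {
  d <- g$dosages
  storage.mode(d) <- "double"
  p <- apply(d, 2, effect_allele_freq)
  poly <- !is.na(p) & p > 0 & p < 1
  if (any(!poly)) {
    rlang::warn(sprintf("dropping %d monomorphic SNP(s) from standardization",
                        sum(!poly)))
  }
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(d, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  W[is.na(W)] <- 0
  attr(W, "freq") <- p
  W
}

#' REML variance components under a GRM random effect
#'
#' Restricted maximum likelihood for `y = X b + u + e` with
#' `u ~ N(0, sigma_g^2 K)` and `e ~ N(0, sigma_e^2 I)`, profiled over the
#' heritability ratio `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)` on a grid
#' that is refined once around the maximum, using a single
#' eigendecomposition of `K`.
#'
#' @param y Numeric response vector.
#' @param grm A [compute_grm()] result (or bare symmetric matrix).
#' @param X Fixed-effect design matrix (default: intercept only).
#' @param grid_size Points in each grid pass.
#' @return A list: `sigma_g2`, `sigma_e2`, `h2`, `loglik` (restricted),
#'   `boundary` (TRUE when h2 hit the grid edge), `degenerate` (TRUE when
#'   the GRM spectrum is flat and the components are not separately
#'   identifiable; then the estimates are NA).
#' @export
estimate_variance_components <- function(y, grm, X = NULL, grid_size = 50) {
  K <- if (inherits(grm, "grm")) grm$K else as.matrix(grm)
  n <- length(y)
  stopifnot(nrow(K) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (!all(abs(K - t(K)) < 1e-8)) rlang::abort("GRM must be symmetric")
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values))) {
    rlang::abort("GRM is not positive semi-definite")
  }
  vals <- pmax(eig$values, 0)
  if (stats::sd(vals) < 1e-8 * max(mean(vals), 1)) {
    rlang::warn("flat GRM spectrum: variance components not identifiable")
    return(list(sigma_g2 = NA_real_, sigma_e2 = NA_real_, h2 = NA_real_,
                loglik = NA_real_, boundary = FALSE, degenerate = TRUE))
  }
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  p <- qr(X)$rank

  restricted_ll <- function(h2) {
    v <- h2 * vals + (1 - h2) # V up to overall scale
    vi <- 1 / v
    XtVX <- crossprod(Xs, Xs * vi)
    b <- solve(XtVX, crossprod(Xs, ys * vi))
    r <- ys - drop(Xs %*% b)
    s2 <- sum(r^2 * vi) / (n - p)
    -0.5 * (sum(log(v)) + determinant(XtVX, logarithm = TRUE)$modulus +
              (n - p) * log(s2) + (n - p))
  }

  grid <- seq(0.001, 0.999, length.out = grid_size)
  ll <- vapply(grid, restricted_ll, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  fine <- seq(lo, hi, length.out = grid_size)
  llf <- vapply(fine, restricted_ll, numeric(1))
  j <- which.max(llf)
  h2 <- fine[j]

  v <- h2 * vals + (1 - h2)
  vi <- 1 / v
  XtVX <- crossprod(Xs, Xs * vi)
  b <- solve(XtVX, crossprod(Xs, ys * vi))
  r <- ys - drop(Xs %*% b)
  s2 <- sum(r^2 * vi) / (n - p)
  list(sigma_g2 = h2 * s2, sigma_e2 = (1 - h2) * s2, h2 = h2,
       loglik = llf[j], boundary = (h2 <= grid[1] + 1e-9 || h2 >= grid[length(grid)] - 1e-9),
       degenerate = FALSE)
}

#' GBLUP SNP effects for one metabolite
#'
#' BLUP of per-SNP random effects under the GBLUP model, via the ridge
#' identity `a = W' (W W' + lambda I)^{-1} y_adj` with
#' `lambda = m * sigma_e^2 / sigma_g^2` and `W` the standardized genotype
#' matrix. The phenotype is first residualized on the covariates
#' (intercept always included). Effects are reported on the dosage scale
#' (standardized-scale effect divided by the SNP's dosage SD) so they can
#' be applied directly by [compute_gms()].
#'
#' @param g A [geno_matrix()].
#' @param y Metabolite vector aligned with `g$sample_ids`.
#' @param covariates Optional covariate table (see [run_mgwas()]).
#' @param components Optional variance components (list with `sigma_g2`,
#'   `sigma_e2`) from [estimate_variance_components()]; estimated if NULL.
#' @param metabolite_id Label used in the returned effect-set rows.
#' @return Effect-set tibble (`metabolite_id`, `snp_id`, `effect_allele`,
#'   `effect`) with attribute `method = "gblup"`; includes every
#'   polymorphic SNP.
#' @export
gblup_snp_effects <- function(g, y, covariates = NULL, components = NULL,
                              metabolite_id = "metabolite") {
  stopifnot(inherits(g, "geno_matrix"))
  n <- n_samples(g)
  X <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    X <- cbind(X, align_to_samples(covariates, g$sample_ids, "covariates"))
  }
  y_adj <- drop(stats::lm.fit(X, y)$residuals)
  W <- standardize_genotypes(g)
  m <- ncol(W)
  if (is.null(components)) {
    K <- tcrossprod(W) / m
    components <- estimate_variance_components(y, K, X)
  }
  meta <- g$snp_meta[match(colnames(W), g$snp_meta$snp_id), ]
  if (is.na(components$sigma_g2) || components$sigma_g2 <= 0) {
    rlang::warn("sigma_g2 is zero or unidentifiable: all GBLUP effects set to 0")
    a_dos <- rep(0, m)
  } else {
    lambda <- m * components$sigma_e2 / components$sigma_g2
    a_std <- drop(crossprod(W, solve(tcrossprod(W) + lambda * diag(n), y_adj)))
    sd_dos <- sqrt(2 * attr(W, "freq") * (1 - attr(W, "freq")))
    a_dos <- a_std / sd_dos
  }
  out <- tibble::tibble(
    metabolite_id = metabolite_id,
    snp_id = colnames(W),
    effect_allele = meta$allele1,
    effect = a_dos,
    chrom = meta$chrom,
    pos = meta$pos
  )
  attr(out, "method") <- "gblup"
  out
}

#' Keep the largest-magnitude fraction of SNP effects
#'
#' Retains `ceiling(fraction * m)` SNPs per metabolite with the largest
#' absolute effects, keeping their originally estimated effect sizes.
#' Ties are broken by (larger absolute effect, chromosome, position,
#' snp id) so the selection is deterministic.
#'
#' @param effects Effect-set tibble; `chrom`/`pos` columns are used for
#'   tie-breaking when present.
#' @param fraction Fraction in `(0, 1]` to retain (default 0.2).
#' @return The filtered effect-set tibble (method attribute preserved).
#' @export
select_top_fraction <- function(effects, fraction = 0.2) {
  if (!nrow(effects)) rlang::abort("empty effect set")
  if (fraction <= 0 || fraction > 1) rlang::abort("fraction must be in (0, 1]")
  method <- attr(effects, "method")
  has_pos <- all(c("chrom", "pos") %in% names(effects))
  out <- effects |>
    dplyr::group_by(.data$metabolite_id) |>
    dplyr::group_modify(function(rows, key) {
      k <- ceiling(fraction * nrow(rows))
      ord <- if (has_pos) {
        order(-abs(rows$effect), rows$chrom, rows$pos, rows$snp_id)
      } else {
        order(-abs(rows$effect), rows$snp_id)
      }
      rows[ord[seq_len(k)], , drop = FALSE]
    }) |>
    dplyr::ungroup()
  attr(out, "method") <- method
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
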