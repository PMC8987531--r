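#' Select ridge penalties by stratified k-fold cross-validation
#'
#' For every `(lambda_m, lambda_p)` pair in the grid, fits the model on
#' each training fold and records the mean held-out Bernoulli deviance.
#' Folds are stratified by class so every fold contains both classes.
#' The pair with the smallest mean deviance wins; ties go to the larger
#' `lambda_m + lambda_p`, then the larger `lambda_p` (prefer the stronger
#' shrinkage when the data cannot tell).
#'
#' @param design A [build_design()] result.
#' @param y Binary phenotype vector.
#' @param grid Data frame with columns `lambda_m`, `lambda_p` (a default
#'   log-spaced grid is used when NULL).
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param penalize_intercept Passed to [penalty_config()].
#' @return A list: `best` (a [penalty_config()]), `cv_table` (tibble with
#'   the grid and mean held-out deviance, one row per pair).
#' @export
cv_select_lambda <- function(design, y, grid = NULL, n_folds = 5, seed = 1,
                             penalize_intercept = TRUE) {
  if (is.null(grid)) {
    grid <- expand.grid(lambda_m = 10^seq(-1, 2, by = 1),
                        lambda_p = 10^seq(-1, 2, by = 1))
  }
  grid <- tibble::as_tibble(grid)
  if (!nrow(grid)) rlang::abort("penalty grid is empty")
  y <- as.numeric(y)
  n <- length(y)

  folds <- integer(n)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  for (cls in unique(y)) {
    i <- which(y == cls)
    if (length(i) < n_folds) {
      rlang::abort("too few samples in a class to stratify the folds")
    }
    folds[i] <- sample(rep_len(seq_len(n_folds), length(i)))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  dev <- vapply(seq_len(nrow(grid)), function(r) {
    pen <- penalty_config(grid$lambda_m[r], grid$lambda_p[r],
                          penalize_intercept)
    fold_dev <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      d_tr <- subset_design(design, tr)
      fit <- fit_hiscom(d_tr, y[tr], pen)
      d_te <- subset_design(design, !tr)
      pi_te <- predict(fit, d_te)
      pi_te <- pmin(pmax(pi_te, 1e-12), 1 - 1e-12)
      -2 * mean(y[!tr] * log(pi_te) + (1 - y[!tr]) * log(1 - pi_te))
    }, numeric(1))
    mean(fold_dev)
  }, numeric(1))

  cv_table <- dplyr::mutate(grid, deviance = dev)
  ord <- order(dev, -(grid$lambda_m + grid$lambda_p), -grid$lambda_p)
  best_row <- cv_table[ord[1], ]
  list(
    best = penalty_config(best_row$lambda_m, best_row$lambda_p,
                          penalize_intercept),
    cv_table = cv_table
  )
}

# row-subset of a design, keeping the block layout and standardization
subset_design <- function(design, rows) {
  out <- design
  out$X <- design$X[rows, , drop = FALSE]
  out$sample_ids <- design$sample_ids[rows]
  out
}

#' Permutation p-values for pathway coefficients
#'
#' Refits the model on `B` phenotype permutations with the same penalties
#' (cold starts, no re-run of cross-validation) and compares the observed
#' identified pathway coefficients `|beta_eff_k|` with their permutation
#' null. The empirical p-value uses the add-one correction,
#' `p_k = (1 + #\{b : |beta*_bk| >= |beta_hat_k|\}) / (B + 1)`, so p is
#' never zero. Benjamini-Hochberg q-values are attached.
#'
#' @param design A [build_design()] result.
#' @param y Binary phenotype vector.
#' @param pen A [penalty_config()] (typically the CV-chosen one).
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed for the permutation stream.
#' @param observed_fit Optional pre-computed fit on the original `y`.
#' @return An object of class `hiscom_perm`: a tibble with one row per
#'   pathway (`pathway_id`, `beta_obs`, `exceedances`, `p_empirical`,
#'   `q_bh`) plus attributes `B`, `pen`, `null_abs_beta` (B x K matrix)
#'   and `redraws`.
#' @export
permutation_pvalues <- function(design, y, pen, B, seed = 1,
                                observed_fit = NULL) {
  if (B < 1) rlang::abort("B must be at least 1")
  fit <- observed_fit %||% fit_hiscom(design, y, pen)
  obs <- abs(fit$beta_eff)
  K <- length(obs)

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  null_abs <- matrix(NA_real_, B, K, dimnames = list(NULL, names(obs)))
  redraws <- 0
  max_redraws <- max(10, B)
  b <- 1
  while (b <= B) {
    y_perm <- sample(y)
    res <- tryCatch(fit_hiscom(design, y_perm, pen), error = function(e) NULL)
    if (is.null(res)) {
      redraws <- redraws + 1
      if (redraws > max_redraws) {
        rlang::abort("too many diverging permutation refits")
      }
      next
    }
    null_abs[b, ] <- abs(res$beta_eff)
    b <- b + 1
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  exceed <- colSums(sweep(null_abs, 2, obs, ">=") * 1)
  p <- (1 + exceed) / (B + 1)
  out <- tibble::tibble(
    pathway_id = names(obs),
    beta_obs = unname(fit$beta_eff),
    exceedances = unname(exceed),
    p_empirical = unname(p),
    q_bh = bh_fdr(unname(p))
  )
  structure(out, class = c("hiscom_perm", class(out)),
            B = B, pen = pen, null_abs_beta = null_abs, redraws = redraws)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1).
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    rlang::abort("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Combined pathway results table
#'
#' Joins a fitted model with its permutation result into the reporting
#' table: identified coefficient, its magnitude rank, empirical p and BH
#' q, sorted by q then by absolute coefficient (descending) — the usual
#' way pathways are short-listed (large effect, small q).
#'
#' @param fit A `hiscom_fit`.
#' @param perm A `hiscom_perm` for the same design.
#' @return A tibble: `pathway_id`, `pathway_name`, `T_k`, `beta`,
#'   `abs_beta_rank`, `p_empirical`, `q_bh`, `n_perm`, `lambda_m`,
#'   `lambda_p`.
#' @export
pathway_report <- function(fit, perm) {
  if (!setequal(names(fit$beta_eff), perm$pathway_id)) {
    rlang::abort("fit and permutation result cover different pathways")
  }
  names_tab <- dplyr::distinct(fit$blocks, .data$pathway_id, .data$pathway_name)
  tibble::tibble(
    pathway_id = names(fit$beta_eff),
    beta = unname(fit$beta_eff),
    T_k = unname(fit$Tk[names(fit$beta_eff)])
  ) |>
    dplyr::left_join(names_tab, by = "pathway_id") |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(perm), "pathway_id", "p_empirical", "q_bh"),
      by = "pathway_id"
    ) |>
    dplyr::mutate(
      abs_beta_rank = rank(-abs(.data$beta), ties.method = "min"),
      n_perm = attr(perm, "B"),
      lambda_m = attr(perm, "pen")$lambda_m,
      lambda_p = attr(perm, "pen")$lambda_p
    ) |>
    dplyr::arrange(.data$q_bh, dplyr::desc(abs(.data$beta))) |>
    dplyr::select("pathway_id", "pathway_name", "T_k", "beta",
                  "abs_beta_rank", "p_empirical", "q_bh", "n_perm",
                  "lambda_m", "lambda_p")
}
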