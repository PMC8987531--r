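#' Ridge penalty configuration for the hierarchical model
#'
#' Two ridge penalties control the two layers: `lambda_m` shrinks the
#' within-pathway score weights `w_kt`, `lambda_p` shrinks the pathway
#' coefficients `beta_k`. The penalized log-likelihood sums the pathway
#' penalty from the intercept onward, so the intercept is penalized by
#' default; set `penalize_intercept = FALSE` for the conventional
#' unpenalized intercept.
#'
#' @param lambda_m Non-negative ridge penalty on score weights.
#' @param lambda_p Non-negative ridge penalty on pathway coefficients.
#' @param penalize_intercept Include `beta_0` in the pathway ridge term.
#' @export
penalty_config <- function(lambda_m = 1, lambda_p = 1,
                           penalize_intercept = TRUE) {
  if (lambda_m < 0 || lambda_p < 0) rlang::abort("penalties must be non-negative")
  structure(list(lambda_m = lambda_m, lambda_p = lambda_p,
                 penalize_intercept = isTRUE(penalize_intercept)),
            class = "penalty_config")
}

# numerically stable log(1 + exp(eta))
log1pexp <- function(eta) {
  out <- eta
  pos <- eta > 0
  out[pos] <- eta[pos] + log1p(exp(-eta[pos]))
  out[!pos] <- log1p(exp(eta[!pos]))
  out
}

# penalized Bernoulli log-likelihood (the fitting objective)
hiscom_objective <- function(y, eta, w, beta, beta0, pen) {
  ll <- sum(y * eta - log1pexp(eta))
  pen_w <- 0.5 * pen$lambda_m * sum(w^2)
  pen_b <- 0.5 * pen$lambda_p *
    (sum(beta^2) + if (pen$penalize_intercept) beta0^2 else 0)
  ll - pen_w - pen_b
}

# analytic gradient of the objective in all parameters (beta0, beta, w)
hiscom_gradient <- function(design, y, w, beta, beta0, pen) {
  X <- design$X
  Fmat <- latent_scores(design, w)
  eta <- drop(beta0 + Fmat %*% beta)
  r <- y - stats::plogis(eta)
  col_beta <- beta[block_index(design)]
  g_w <- drop(crossprod(X, r)) * col_beta - pen$lambda_m * w
  g_beta <- drop(crossprod(Fmat, r)) - pen$lambda_p * beta
  g_beta0 <- sum(r) - if (pen$penalize_intercept) pen$lambda_p * beta0 else 0
  c(beta0 = g_beta0, stats::setNames(g_beta, names(design$Tk)), g_w)
}

# pathway block index (length P, values 1..K) for the design columns
block_index <- function(design) {
  rep(seq_len(design$K), times = design$Tk)
}

# latent pathway scores F (N x K) for given weights: one matmul through a
# sparse block-map matrix
latent_scores <- function(design, w) {
  idx <- block_index(design)
  Wm <- matrix(0, length(w), design$K)
  Wm[cbind(seq_along(w), idx)] <- w
  out <- design$X %*% Wm
  colnames(out) <- names(design$Tk)
  out
}

# one penalized-logistic block update by Newton/IRLS with step halving.
# A: design for this block; offset added to the linear predictor;
# penalty: diagonal ridge vector (same length as theta).
ridge_irls <- function(A, y, offset, theta, penalty,
                       tol = 1e-10, max_iter = 50) {
  obj <- function(th) {
    eta <- offset + drop(A %*% th)
    sum(y * eta - log1pexp(eta)) - 0.5 * sum(penalty * th^2)
  }
  f <- obj(theta)
  for (it in seq_len(max_iter)) {
    eta <- offset + drop(A %*% theta)
    pi <- stats::plogis(eta)
    grad <- drop(crossprod(A, y - pi)) - penalty * theta
    if (max(abs(grad)) < tol) break
    s <- pmax(pi * (1 - pi), 1e-10)
    H <- crossprod(A, A * s)
    diag(H) <- diag(H) + penalty
    step <- tryCatch(solve(H, grad), error = function(e) {
      solve(H + diag(1e-10, nrow(H)), grad)
    })
    # step halving keeps the update monotone
    t_step <- 1
    repeat {
      cand <- theta + t_step * step
      f_new <- obj(cand)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      t_step <- t_step / 2
      if (t_step < 1e-8) break
    }
    theta <- cand
    f <- f_new
  }
  theta
}

#' Fit the hierarchical structural component logistic model
#'
#' Maximizes the ridge-penalized Bernoulli log-likelihood of the two-layer
#' model `logit(pi_j) = beta_0 + sum_k (sum_t w_kt x_jkt) beta_k` by
#' alternating least squares: with `w` fixed, `(beta_0, beta)` is updated
#' by ridge-penalized IRLS on the latent pathway scores; with `beta`
#' fixed, all `w_kt` are updated jointly by ridge-penalized IRLS on the
#' beta-scaled design. Iteration stops when both the largest parameter
#' change and the largest analytic gradient entry fall below tolerance,
#' so converged fits are stationary points of the penalized objective.
#'
#' For reporting, the scale split between each pathway's weight vector and
#' its coefficient is resolved as `w_k / ||w_k||` and
#' `beta_eff_k = beta_k * ||w_k||` (sign fixed so the largest-magnitude
#' weight is positive), which leaves the linear predictor unchanged.
#'
#' @param design A [build_design()] result.
#' @param y Binary 0/1 phenotype vector (both classes present).
#' @param pen A [penalty_config()].
#' @param tol Convergence tolerance on parameter change (default 1e-6).
#' @param grad_tol Convergence tolerance on the gradient (default 1e-6).
#' @param max_iter Maximum outer alternations.
#' @param init Optional list with starting `w`, `beta`, `beta0`.
#' @return An object of class `hiscom_fit`: raw parameters `w`, `beta`,
#'   `beta0`; identified versions `w_unit`, `beta_eff`; fitted
#'   probabilities `pi`; objective `phi`; `iterations`, `converged`,
#'   `grad_max`; the penalty configuration and the block layout.
#' @export
fit_hiscom <- function(design, y, pen = penalty_config(),
                       tol = 1e-6, grad_tol = 1e-6, max_iter = 500,
                       init = NULL) {
  stopifnot(inherits(design, "hier_design"))
  y <- as.numeric(y)
  if (length(y) != nrow(design$X)) rlang::abort("design and phenotype are not aligned")
  if (!all(y %in% c(0, 1))) rlang::abort("phenotype must be 0/1")
  if (length(unique(y)) < 2) rlang::abort("both phenotype classes must be present")

  X <- design$X
  K <- design$K
  idx <- block_index(design)
  P <- ncol(X)

  w <- init$w %||% rep(1 / sqrt(design$Tk), times = design$Tk)
  beta <- init$beta %||% rep(0, K)
  beta0 <- init$beta0 %||% stats::qlogis(mean(y))

  pen_beta <- c(if (pen$penalize_intercept) pen$lambda_p else 0,
                rep(pen$lambda_p, K))
  converged <- FALSE
  it <- 0
  repeat {
    it <- it + 1
    old <- c(beta0, beta, w)

    # beta-step: latent scores fixed
    Fmat <- latent_scores(design, w)
    theta <- ridge_irls(cbind(1, Fmat), y, 0, c(beta0, beta), pen_beta)
    beta0 <- theta[1]
    beta <- theta[-1]

    # w-step: coefficients fixed; columns scaled by their pathway beta
    col_beta <- beta[idx]
    active <- (abs(col_beta) > 1e-12) | (pen$lambda_m > 0)
    if (any(active)) {
      Xb <- sweep(X[, active, drop = FALSE], 2, col_beta[active], "*")
      w[active] <- ridge_irls(Xb, y, beta0, w[active],
                              rep(pen$lambda_m, sum(active)))
    }

    grad <- hiscom_gradient(design, y, w, beta, beta0, pen)
    delta <- max(abs(c(beta0, beta, w) - old))
    if (max(abs(grad)) < grad_tol && delta < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
  }

  eta <- drop(beta0 + latent_scores(design, w) %*% beta)
  phi <- hiscom_objective(y, eta, w, beta, beta0, pen)
  if (!is.finite(phi)) {
    rlang::abort(sprintf("objective diverged (non-finite) at iteration %d", it))
  }

  # unit-norm / sign identification for reporting (logit-invariant)
  norms <- vapply(seq_len(K), function(k) sqrt(sum(w[idx == k]^2)), numeric(1))
  signs <- vapply(seq_len(K), function(k) {
    wk <- w[idx == k]
    s <- sign(wk[which.max(abs(wk))])
    if (s == 0) 1 else s
  }, numeric(1))
  safe_norm <- ifelse(norms > 0, norms, 1)
  w_unit <- w / (safe_norm[idx] * signs[idx])
  beta_eff <- beta * norms * signs

  structure(
    list(w = w, beta = stats::setNames(beta, names(design$Tk)), beta0 = beta0,
         w_unit = w_unit,
         beta_eff = stats::setNames(beta_eff, names(design$Tk)),
         pi = stats::plogis(eta), phi = phi, iterations = it,
         converged = converged, grad_max = max(abs(grad)),
         pen = pen, blocks = design$blocks, Tk = design$Tk,
         n = length(y)),
    class = "hiscom_fit"
  )
}

#' @export
print.hiscom_fit <- function(x, ...) {
  cat(sprintf(
    "<hiscom_fit> %d samples, %d pathways; phi = %.4f, %d iterations (%s)\n",
    x$n, length(x$beta), x$phi, x$iterations,
    if (x$converged) "converged" else "NOT converged"
  ))
  cat("pathway coefficients (identified scale):\n")
  print(round(x$beta_eff, 4))
  invisible(x)
}

#' Predict case probabilities from a fitted hierarchical model
#'
#' @param object A `hiscom_fit`.
#' @param design A `hier_design` laid out identically to the training
#'   design (same blocks and standardization).
#' @param ... Unused.
#' @return Vector of fitted probabilities.
#' @export
predict.hiscom_fit <- function(object, design, ...) {
  Fmat <- latent_scores(design, object$w)
  stats::plogis(drop(object$beta0 + Fmat %*% object$beta))
}
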