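test_that("total shrinkage drives all effects to zero and pi to prevalence", {
  d <- random_design(n = 80, K = 3, Tk = 2, seed = 1)
  set.seed(2)
  y <- rbinom(80, 1, 0.4)
  fit <- fit_hiscom(d, y, penalty_config(1e10, 1e10, penalize_intercept = FALSE))
  prod_scale <- abs(fit$w * fit$beta[rep(seq_len(d$K), times = d$Tk)])
  expect_lt(max(prod_scale), 1e-4)
  expect_lt(max(abs(fit$pi - mean(y))), 1e-3)
})

test_that("the one-pathway, one-score model reduces to plain logistic regression", {
  for (seed in 1:3) {
    d <- random_design(n = 120, K = 1, Tk = 1, seed = seed)
    set.seed(seed + 10)
    y <- rbinom(120, 1, plogis(0.2 + 0.9 * d$X[, 1]))
    if (length(unique(y)) < 2) next
    fit <- fit_hiscom(d, y, penalty_config(0, 0, penalize_intercept = FALSE))
    ref <- glm(y ~ d$X[, 1], family = binomial)
    expect_lt(abs(fit$w * fit$beta - coef(ref)[2]), 1e-4)
    expect_lt(abs(fit$beta0 - coef(ref)[1]), 1e-4)
  }
})

test_that("converged fits are stationary points of the penalized objective", {
  for (seed in 1:5) {
    d <- random_design(n = 60, K = 3, Tk = 2, seed = 20 + seed)
    set.seed(seed)
    y <- rbinom(60, 1, 0.5)
    fit <- fit_hiscom(d, y, penalty_config(1, 1))
    expect_true(fit$converged)
    expect_lt(max(abs(fd_gradient(d, y, fit))), 1e-4)
  }
})

test_that("unit-norm identification preserves the linear predictor", {
  d <- random_design(n = 100, K = 4, Tk = 3, seed = 31)
  set.seed(5)
  y <- rbinom(100, 1, 0.5)
  fit <- fit_hiscom(d, y, penalty_config(0.5, 2))
  idx <- rep(seq_len(d$K), times = d$Tk)
  for (k in seq_len(d$K)) {
    expect_equal(sum(fit$w_unit[idx == k]^2), 1, tolerance = 1e-10)
    wk <- fit$w_unit[idx == k]
    expect_gt(wk[which.max(abs(wk))], 0)
  }
  eta_raw <- drop(d$X %*% (fit$w * fit$beta[idx])) + fit$beta0
  eta_id <- drop(d$X %*% (fit$w_unit * fit$beta_eff[idx])) + fit$beta0
  expect_equal(eta_raw, eta_id, tolerance = 1e-10)
})

test_that("pathway shrinkage is monotone in the pathway penalty", {
  for (seed in 1:3) {
    d <- random_design(n = 90, K = 3, Tk = 2, seed = 40 + seed)
    set.seed(seed)
    f_true <- rowSums(d$X[, 1:2])
    y <- rbinom(90, 1, plogis(0.8 * scale(f_true)))
    ladder <- c(0.1, 1, 10, 100)
    ss <- vapply(ladder, function(lp) {
      sum(fit_hiscom(d, y, penalty_config(1, lp))$beta_eff^2)
    }, numeric(1))
    expect_true(all(diff(ss) <= 1e-8))
  }
})

test_that("degenerate phenotypes and misaligned inputs error", {
  d <- random_design(n = 30, K = 2, Tk = 2, seed = 3)
  expect_error(fit_hiscom(d, rep(1, 30), penalty_config()), "both")
  expect_error(fit_hiscom(d, rep(0:1, 10), penalty_config()), "aligned")
  expect_error(fit_hiscom(d, c(rep(0.5, 30)), penalty_config()), "0/1")
})

test_that("cross-validation returns grids, honours ties and is reproducible", {
  d <- random_design(n = 60, K = 2, Tk = 2, seed = 8)
  set.seed(9)
  y <- rbinom(60, 1, 0.5)
  one <- cv_select_lambda(d, y, grid = data.frame(lambda_m = 2, lambda_p = 3),
                          seed = 4)
  expect_equal(one$best$lambda_m, 2)
  expect_equal(one$best$lambda_p, 3)
  expect_equal(nrow(one$cv_table), 1)
  grid <- expand.grid(lambda_m = c(0.5, 5), lambda_p = c(0.5, 5))
  a <- cv_select_lambda(d, y, grid, seed = 11)
  b <- cv_select_lambda(d, y, grid, seed = 11)
  expect_identical(a$cv_table, b$cv_table)
  expect_true(all(is.finite(a$cv_table$deviance)))
})

test_that("cross-validation prefers heavy penalties on pure noise", {
  grid <- data.frame(lambda_m = c(0.01, 100), lambda_p = c(0.01, 100))
  picks <- vapply(1:20, function(seed) {
    d <- random_design(n = 80, K = 3, Tk = 2, seed = 50 + seed)
    set.seed(seed)
    y <- rbinom(80, 1, 0.5)
    cv_select_lambda(d, y, grid, seed = seed)$best$lambda_p
  }, numeric(1))
  expect_gt(mean(picks == 100), 0.5)
})

test_that("empirical p-values obey the add-one correction and boundaries", {
  d <- random_design(n = 80, K = 2, Tk = 2, seed = 71)
  set.seed(6)
  f <- scale(rowSums(d$X[, 1:2]))
  y <- rbinom(80, 1, plogis(2 * f))
  pen <- penalty_config(1, 1)
  fit <- fit_hiscom(d, y, pen)
  perm <- permutation_pvalues(d, y, pen, B = 19, seed = 2, observed_fit = fit)
  expect_true(all(perm$p_empirical >= 1 / 20))
  expect_true(all(perm$p_empirical <= 1))
  expect_equal(perm$p_empirical, (1 + perm$exceedances) / 20)
  # a zero observed coefficient is never beaten: p = 1
  fit0 <- fit
  fit0$beta_eff[] <- 0
  perm0 <- permutation_pvalues(d, y, pen, B = 19, seed = 2, observed_fit = fit0)
  expect_true(all(perm0$p_empirical == 1))
  # reproducible stream
  perm2 <- permutation_pvalues(d, y, pen, B = 19, seed = 2, observed_fit = fit)
  expect_identical(perm$p_empirical, perm2$p_empirical)
  expect_error(permutation_pvalues(d, y, pen, B = 0), "at least 1")
})

test_that("BH adjustment matches p.adjust semantics on known cases", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(numeric()), numeric())
  expect_error(bh_fdr(c(0.1, 0)), "in \\(0, 1\\]")
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_manual(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("the report joins fit and permutations, sorted by q then effect", {
  sc <- make_scenario("one_active_pathway", seed = 5, n_samples = 200)
  pen <- penalty_config(1, 1)
  fit <- fit_hiscom(sc$design, sc$y, pen)
  perm <- permutation_pvalues(sc$design, sc$y, pen, B = 19, seed = 3,
                              observed_fit = fit)
  rep1 <- pathway_report(fit, perm)
  expect_setequal(rep1$pathway_id, names(fit$beta_eff))
  expect_equal(rep1$beta[match(perm$pathway_id, rep1$pathway_id)],
               perm$beta_obs)
  expect_true(!is.unsorted(rep1$q_bh))
  expect_identical(pathway_report(fit, perm), rep1)
  sig <- rep1[rep1$q_bh < 0.05, ]
  expect_equal(nrow(sig), sum(rep1$q_bh < 0.05))
})

test_that("tidy and glance expose coefficients and fit metadata", {
  sc <- make_scenario("null", seed = 6, n_samples = 120)
  fit <- fit_hiscom(sc$design, sc$y, penalty_config(1, 1))
  td <- tidy(fit)
  expect_equal(nrow(td), sc$design$K)
  expect_named(td, c("pathway_id", "T_k", "estimate"))
  tw <- tidy(fit, level = "weight")
  expect_equal(nrow(tw), ncol(sc$design$X))
  gl <- glance(fit)
  expect_equal(gl$n, 120)
  expect_true(gl$converged)
})
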