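toy_effects <- function(...) {
  e <- tibble::tibble(...)
  attr(e, "method") <- "single"
  e
}

test_that("score computation is linear and orientation-aware", {
  g <- geno_matrix(
    matrix(c(0L, 1L, 2L), ncol = 1),
    tibble::tibble(snp_id = "s1", chrom = "1", pos = 100L,
                   allele1 = "A", allele2 = "B"),
    c("i1", "i2", "i3")
  )
  e <- toy_effects(metabolite_id = "m", snp_id = "s1",
                   effect_allele = "A", effect = 0.5)
  expect_equal(unname(compute_gms(g, e)[, "m"]), c(0, 0.5, 1))
  # zero effects give zero scores
  e0 <- toy_effects(metabolite_id = "m", snp_id = "s1",
                    effect_allele = "A", effect = 0)
  expect_true(all(compute_gms(g, e0) == 0))
  # scoring on the other allele reflects the dosage
  eb <- toy_effects(metabolite_id = "m", snp_id = "s1",
                    effect_allele = "B", effect = 0.5)
  expect_equal(unname(compute_gms(g, eb)[, "m"]), c(1, 0.5, 0))
  expect_error(compute_gms(g, toy_effects(metabolite_id = "m", snp_id = "zz",
                                          effect_allele = "A", effect = 1)),
               "unknown SNP")
})

test_that("scores are additive over disjoint effect sets", {
  g <- random_geno(30, 6, seed = 4, miss_rate = 0)
  eA <- toy_effects(metabolite_id = "m", snp_id = paste0("s", 1:3),
                    effect_allele = g$snp_meta$allele1[1:3],
                    effect = c(0.2, -0.4, 0.1))
  eB <- toy_effects(metabolite_id = "m", snp_id = paste0("s", 4:6),
                    effect_allele = g$snp_meta$allele1[4:6],
                    effect = c(0.5, 0.3, -0.2))
  eAB <- toy_effects(metabolite_id = "m", snp_id = paste0("s", 1:6),
                     effect_allele = g$snp_meta$allele1,
                     effect = c(0.2, -0.4, 0.1, 0.5, 0.3, -0.2))
  expect_equal(compute_gms(g, eA) + compute_gms(g, eB),
               compute_gms(g, eAB), ignore_attr = TRUE)
})

test_that("allele relabelling shifts scores by a constant only", {
  g <- random_geno(25, 1, seed = 6, miss_rate = 0)
  e1 <- toy_effects(metabolite_id = "m", snp_id = "s1",
                    effect_allele = g$snp_meta$allele1, effect = 0.7)
  e2 <- toy_effects(metabolite_id = "m", snp_id = "s1",
                    effect_allele = g$snp_meta$allele2, effect = -0.7)
  diff <- compute_gms(g, e1)[, 1] - compute_gms(g, e2)[, 1]
  expect_equal(max(diff) - min(diff), 0, tolerance = 1e-12)
})

test_that("missing dosages are mean-imputed at twice the allele frequency", {
  d <- matrix(c(0L, 2L, NA, 2L), ncol = 1)
  g <- geno_matrix(d, tibble::tibble(snp_id = "s1", chrom = "1", pos = 1L,
                                     allele1 = "A", allele2 = "B"),
                   paste0("i", 1:4))
  e <- toy_effects(metabolite_id = "m", snp_id = "s1",
                   effect_allele = "A", effect = 1)
  # effect-allele frequency among observed = 4/6
  expect_equal(unname(compute_gms(g, e)[3, "m"]), 2 * 4 / 6)
})

test_that("GRM matches the explicit summation formula", {
  set.seed(12)
  d <- matrix(rbinom(12, 2, 0.5), 4, 3)
  d[2, 1] <- 1L # ensure polymorphism jitter
  g <- geno_matrix(d, tibble::tibble(snp_id = paste0("s", 1:3), chrom = "1",
                                     pos = 1:3 * 10L, allele1 = "A",
                                     allele2 = "B"), paste0("i", 1:4))
  grm <- suppressWarnings(compute_grm(g))
  # direct double-sum oracle over the used (polymorphic) SNPs
  used <- grm$snp_id
  p <- vapply(used, function(s) mean(d[, match(s, g$snp_meta$snp_id)]) / 2,
              numeric(1))
  K_direct <- matrix(0, 4, 4)
  for (i in 1:4) for (k in 1:4) {
    K_direct[i, k] <- mean((d[i, match(used, g$snp_meta$snp_id)] - 2 * p) *
                             (d[k, match(used, g$snp_meta$snp_id)] - 2 * p) /
                             (2 * p * (1 - p)))
  }
  expect_equal(unname(grm$K), K_direct, tolerance = 1e-12)
  # duplicate sample rows give identical relatedness entries
  d2 <- d; d2[2, ] <- d2[1, ]
  g2 <- geno_matrix(d2, g$snp_meta, g$sample_ids)
  grm2 <- suppressWarnings(compute_grm(g2))
  expect_equal(grm2$K[1, 2], grm2$K[1, 1], tolerance = 1e-12)
})

test_that("REML recovers heritability and flags degeneracy", {
  # parameter recovery at h2 = 0.5
  h2_hat <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 500; m <- 400
    W <- matrix(rnorm(n * m), n, m)
    K <- tcrossprod(W) / m
    u <- drop(W %*% rnorm(m, sd = sqrt(1 / m)))
    y <- u + rnorm(n, sd = sd(u) * sqrt(1 / 1)) # var_e = var_u -> h2 = 0.5
    estimate_variance_components(y, K)$h2
  }, numeric(1))
  expect_lt(abs(mean(h2_hat) - 0.5), 0.15)

  # pure noise: h2 near zero most of the time
  low <- vapply(1:20, function(seed) {
    set.seed(100 + seed)
    n <- 300; m <- 100 # m < n keeps the GRM spectrum informative
    W <- matrix(rnorm(n * m), n, m)
    K <- tcrossprod(W) / m
    estimate_variance_components(rnorm(n), K)$h2 < 0.1
  }, logical(1))
  expect_gte(sum(low), 18)

  # identity GRM: components not separately identifiable
  expect_warning(
    res <- estimate_variance_components(rnorm(50), diag(50)),
    "not identifiable"
  )
  expect_true(res$degenerate)
  expect_true(is.na(res$sigma_g2))
})

test_that("GBLUP effects satisfy the ridge identity", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- 8; m <- 5
    d <- matrix(rbinom(n * m, 2, runif(1, 0.25, 0.5)), n, m)
    # keep every SNP polymorphic for a clean oracle
    for (j in 1:m) if (var(d[, j]) == 0) d[1:2, j] <- c(0L, 2L)
    g <- geno_matrix(d, tibble::tibble(snp_id = paste0("s", 1:m), chrom = "1",
                                       pos = 1:m * 10L, allele1 = "A",
                                       allele2 = "B"), paste0("i", 1:n))
    y <- rnorm(n)
    comp <- list(sigma_g2 = 0.6, sigma_e2 = 0.4)
    eff <- gblup_snp_effects(g, y, components = comp)
    # independent route: primal ridge solution on the standardized scale
    p <- colMeans(d) / 2
    W <- sweep(sweep(d, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
    lambda <- m * comp$sigma_e2 / comp$sigma_g2
    y_adj <- drop(lm.fit(matrix(1, n, 1), y)$residuals)
    a_primal <- solve(crossprod(W) + lambda * diag(m), crossprod(W, y_adj))
    expect_equal(eff$effect * sqrt(2 * p * (1 - p)), drop(a_primal),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("huge ridge shrinks GBLUP effects to zero", {
  g <- random_geno(20, 6, seed = 13, miss_rate = 0)
  eff <- gblup_snp_effects(g, rnorm(20),
                           components = list(sigma_g2 = 1e-12 * 6, sigma_e2 = 1))
  expect_lt(max(abs(eff$effect)), 1e-6)
})

test_that("a dominant causal SNP attains the largest GBLUP effect", {
  wins <- vapply(1:20, function(seed) {
    g <- simulate_genotypes(300, 20, maf = c(0.2, 0.4), ld_rho = 0,
                            seed = 400 + seed)
    set.seed(seed)
    y <- 1.5 * g$dosages[, 7] + rnorm(300)
    eff <- gblup_snp_effects(g, y,
                             components = list(sigma_g2 = 0.5, sigma_e2 = 0.5))
    eff$snp_id[which.max(abs(eff$effect))] == g$snp_meta$snp_id[7]
  }, logical(1))
  expect_gte(sum(wins), 18)
})

test_that("top-fraction selection keeps the largest effects deterministically", {
  e <- toy_effects(metabolite_id = "m", snp_id = sprintf("s%02d", 1:10),
                   effect_allele = "A",
                   effect = c(0.1, -0.9, 0.3, 0.8, -0.2, 0.05, 0.4, -0.6, 0.15, 0.25))
  top <- select_top_fraction(e, 0.2)
  expect_setequal(top$snp_id, c("s02", "s04"))
  expect_equal(select_top_fraction(e, 1)$snp_id[order(select_top_fraction(e, 1)$snp_id)],
               sort(e$snp_id))
  # ties resolved by position/id, stable across calls
  et <- toy_effects(metabolite_id = "m", snp_id = sprintf("s%02d", 1:10),
                    effect_allele = "A", effect = rep(0.5, 10),
                    chrom = "1", pos = 1:10 * 100L)
  t1 <- select_top_fraction(et, 0.2)
  expect_identical(t1$snp_id, c("s01", "s02"))
  expect_identical(select_top_fraction(et, 0.2)$snp_id, t1$snp_id)
  expect_error(select_top_fraction(e[0, ], 0.2), "empty")
})
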