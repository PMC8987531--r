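test_that("single-SNP regression matches the lm oracle", {
  set.seed(10)
  n <- 6
  g <- c(0, 1, 2, 0, 1, 2)
  cov <- data.frame(age = c(41, 52, 63, 45, 58, 66), sex = c(0, 1, 0, 1, 0, 1))
  y <- 0.5 * g + 0.02 * cov$age + rnorm(n, sd = 0.3)
  res <- single_snp_assoc(y, g, cov)
  fit <- lm(y ~ g + age + sex, data = cov)
  s <- summary(fit)$coefficients["g", ]
  expect_equal(res$beta, unname(s["Estimate"]), tolerance = 1e-10)
  expect_equal(res$se, unname(s["Std. Error"]), tolerance = 1e-10)
  expect_equal(res$p, unname(s["Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("a perfect fit returns slope one with vanishing residual variance", {
  g <- rep(c(0, 1, 2), length.out = 10)
  res <- single_snp_assoc(g, g)
  expect_equal(res$beta, 1, tolerance = 1e-12)
  expect_lt(res$se, 1e-8)
})

test_that("constant dosage is flagged degenerate; tiny n errors", {
  res <- single_snp_assoc(rnorm(10), rep(1, 10))
  expect_true(res$degenerate)
  expect_equal(res$beta, 0)
  expect_equal(res$p, 1)
  expect_error(single_snp_assoc(rnorm(2), c(0, 1)), "too few")
})

test_that("null regression p-values are uniform", {
  set.seed(77)
  g <- rbinom(60, 2, 0.3)
  p <- replicate(2000, single_snp_assoc(rnorm(60), g)$p)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("run_mgwas composes per-SNP tests and aligns metadata", {
  g <- random_geno(40, 3, seed = 5, miss_rate = 0)
  M <- matrix(rnorm(40), dimnames = list(g$sample_ids, "metA"))
  tab <- run_mgwas(g, M)
  expect_equal(nrow(tab), 3)
  for (j in 1:3) {
    ref <- single_snp_assoc(M[, 1], g$dosages[, j])
    expect_equal(tab$beta[j], ref$beta)
    expect_equal(tab$p[j], ref$p)
  }
  expect_identical(tab$effect_allele, g$snp_meta$allele1)
})

test_that("the scan finds a causal SNP and keeps the null calibrated", {
  hits <- 0
  for (seed in 1:20) {
    g <- simulate_genotypes(500, 30, maf = c(0.2, 0.4), ld_block_size = 5,
                            ld_rho = 0.3, seed = seed)
    spec <- list(list(metabolite_id = "m1",
                      causal = data.frame(snp_id = "snp0013", effect = 1),
                      h2 = 0.3))
    M <- simulate_metabolites(g, spec, seed = seed + 50)
    tab <- run_mgwas(g, M)
    top <- tab$snp_id[which.min(tab$p)]
    if (top == "snp0013") hits <- hits + 1
  }
  expect_gte(hits, 19) # 95% of 20 seeds
  # null scan calibration
  set.seed(99)
  g0 <- simulate_genotypes(100, 500, maf = c(0.2, 0.4), ld_rho = 0, seed = 1)
  M0 <- matrix(rnorm(100 * 20), nrow = 100,
               dimnames = list(g0$sample_ids, paste0("n", 1:20)))
  tab0 <- run_mgwas(g0, M0)
  frac <- mean(tab0$p < 0.05)
  ci <- binom.test(round(0.05 * nrow(tab0)), nrow(tab0))$conf.int
  expect_gt(frac, 0.05 - 3 * sqrt(0.05 * 0.95 / nrow(tab0)))
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(tab0)))
})

test_that("ld_r2 is symmetric, flip-invariant and matches Pearson", {
  set.seed(8)
  g1 <- rbinom(50, 2, 0.4)
  g2 <- rbinom(50, 2, 0.3)
  expect_equal(ld_r2(g1, g1), 1)
  expect_equal(ld_r2(g1, 2 - g1), 1)
  expect_equal(ld_r2(g1, g2), cor(g1, g2)^2, tolerance = 1e-12)
  expect_warning(r0 <- ld_r2(g1, rep(1, 50)), "constant")
  expect_equal(r0, 0)
})

test_that("clumping keeps index SNPs and respects window and chromosome", {
  # two correlated SNPs 10 kb apart: only the stronger survives
  set.seed(21)
  base <- rbinom(200, 2, 0.3)
  twin <- base; flip <- runif(200) < 0.05
  twin[flip] <- rbinom(sum(flip), 2, 0.3)
  g <- geno_matrix(cbind(a = base, b = twin),
                   tibble::tibble(snp_id = c("a", "b"), chrom = "1",
                                  pos = c(100000L, 110000L),
                                  allele1 = "A", allele2 = "B"),
                   paste0("i", 1:200))
  assoc <- tibble::tibble(snp_id = c("a", "b"), chrom = "1",
                          pos = c(100000L, 110000L), p = c(1e-9, 1e-4))
  expect_identical(clump(assoc, g, clump_spec()), "a")
  # different chromosomes: both retained regardless of correlation
  g2 <- g; g2$snp_meta$chrom <- c("1", "2")
  assoc2 <- assoc; assoc2$chrom <- c("1", "2")
  expect_setequal(clump(assoc2, g2, clump_spec()), c("a", "b"))
})

test_that("greedy clumping equals the step-by-step trace oracle", {
  spec <- clump_spec(window_kb = 50, r2_cutoff = 0.2)
  for (seed in 1:100) {
    set.seed(seed)
    m <- sample(2:6, 1)
    g <- random_geno(80, m, seed = seed + 300, miss_rate = 0,
                     chrom = sample(c("1", "2"), m, replace = TRUE))
    g$snp_meta$pos <- sort(sample.int(100000L, m))
    assoc <- tibble::tibble(snp_id = g$snp_meta$snp_id,
                            chrom = g$snp_meta$chrom,
                            pos = g$snp_meta$pos,
                            p = runif(m))
    expect_identical(clump(assoc, g, spec),
                     suppressWarnings(clump_trace(assoc, g, spec)))
  }
})

test_that("clump default spec matches the 250 kb / r2 0.2 convention", {
  s <- clump_spec()
  expect_equal(s$window_kb, 250)
  expect_equal(s$r2_cutoff, 0.2)
})

test_that("p-value thresholding filters exactly", {
  assoc <- tibble::tibble(snp_id = c("a", "b", "c"),
                          p = c(1e-9, 1e-4, 0.2))
  expect_equal(threshold_by_p(assoc, 1)$snp_id, c("a", "b", "c"))
  expect_equal(threshold_by_p(assoc, 1e-3)$snp_id, c("a", "b"))
  expect_warning(out <- threshold_by_p(assoc, 1e-12), "no associations")
  expect_equal(nrow(out), 0)
})
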