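#' Simulate blocked-LD genotypes
#'
#' Dosages are drawn per SNP as Binomial(2, MAF) with linkage
#' disequilibrium induced inside consecutive blocks by a Gaussian-copula
#' construction: each haplotype thresholds a latent normal that shares a
#' block-level factor with correlation `ld_rho`. Between-block LD is zero
#' by construction. SNPs are placed on one chromosome per block-group of
#' `blocks_per_chrom`, `spacing_bp` apart.
#'
#' @param n_samples,n_snps Dimensions.
#' @param maf MAF per SNP: a single value, a length-2 range to draw from
#'   uniformly, or a length-`n_snps` vector.
#' @param ld_block_size SNPs per LD block.
#' @param ld_rho Latent within-block correlation in `[0, 1)`.
#' @param spacing_bp Base pairs between adjacent SNPs.
#' @param blocks_per_chrom LD blocks per chromosome.
#' @param seed Integer seed (reproducible).
#' @return A [geno_matrix()] (no missing genotypes).
#' @export
simulate_genotypes <- function(n_samples, n_snps, maf = c(0.1, 0.4),
                               ld_block_size = 5, ld_rho = 0.8,
                               spacing_bp = 10000, blocks_per_chrom = 100,
                               seed = 1) {
  if (ld_rho < 0 || ld_rho >= 1) rlang::abort("ld_rho must be in [0, 1)")
  if (any(maf <= 0) || any(maf > 0.5)) rlang::abort("maf must be in (0, 0.5]")
  set.seed(seed)
  p <- if (length(maf) == 1) rep(maf, n_snps)
  else if (length(maf) == 2) stats::runif(n_snps, maf[1], maf[2])
  else if (length(maf) == n_snps) maf
  else rlang::abort("maf must have length 1, 2 or n_snps")

  block <- (seq_len(n_snps) - 1) %/% ld_block_size + 1
  n_blocks <- max(block)
  dos <- matrix(0L, n_samples, n_snps)
  for (h in 1:2) {
    common <- matrix(stats::rnorm(n_samples * n_blocks), n_samples, n_blocks)
    z <- sqrt(ld_rho) * common[, block, drop = FALSE] +
      sqrt(1 - ld_rho) * matrix(stats::rnorm(n_samples * n_snps), n_samples, n_snps)
    alleles <- sweep(z, 2, stats::qnorm(p), "<")
    dos <- dos + alleles
  }
  chrom <- (block - 1) %/% blocks_per_chrom + 1
  pos <- integer(n_snps)
  for (cc in unique(chrom)) {
    i <- which(chrom == cc)
    pos[i] <- seq_along(i) * spacing_bp
  }
  geno_matrix(
    dos,
    snp_meta = tibble::tibble(
      snp_id = sprintf("snp%04d", seq_len(n_snps)),
      chrom = as.character(chrom), pos = pos,
      allele1 = "A", allele2 = "B"
    ),
    sample_ids = sprintf("ind%04d", seq_len(n_samples))
  )
}

#' Simulate SNP-driven metabolite concentrations
#'
#' Each metabolite is a linear combination of its causal SNP dosages plus
#' covariate terms plus Gaussian noise, with the noise variance scaled so
#' the genetic fraction of the (genetic + noise) variance hits the target
#' heritability.
#'
#' @param g A [geno_matrix()].
#' @param spec A list with one element per metabolite, each a list with
#'   `metabolite_id`, `causal` (data frame `snp_id`, `effect`), `h2`
#'   (target heritability in `[0, 1)`), and optionally `age_effect`,
#'   `sex_effect`, `noise_sd` (base noise SD, used when `h2 = 0`).
#' @param covariates Optional data frame with `age`, `sex` columns aligned
#'   to the samples.
#' @param seed Integer seed.
#' @return Numeric matrix samples x metabolites with dimnames.
#' @export
simulate_metabolites <- function(g, spec, covariates = NULL, seed = 1) {
  stopifnot(inherits(g, "geno_matrix"))
  set.seed(seed)
  n <- n_samples(g)
  out <- matrix(0, n, length(spec),
                dimnames = list(g$sample_ids,
                                purrr::map_chr(spec, "metabolite_id")))
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    h2 <- s$h2 %||% 0
    if (h2 < 0 || h2 >= 1) rlang::abort("heritability must be in [0, 1)")
    genetic <- rep(0, n)
    if (!is.null(s$causal) && nrow(s$causal)) {
      j <- match(s$causal$snp_id, g$snp_meta$snp_id)
      if (anyNA(j)) rlang::abort("causal SNPs absent from genotype matrix")
      d <- g$dosages[, j, drop = FALSE]
      storage.mode(d) <- "double"
      genetic <- drop(d %*% s$causal$effect)
    }
    var_g <- stats::var(genetic)
    if (h2 > 0) {
      if (var_g == 0) rlang::abort("target heritability unattainable: no causal variance")
      noise_sd <- sqrt(var_g * (1 - h2) / h2)
    } else {
      noise_sd <- s$noise_sd %||% 1
    }
    cov_term <- rep(0, n)
    if (!is.null(covariates)) {
      if (!is.null(s$age_effect)) cov_term <- cov_term + s$age_effect * covariates$age
      if (!is.null(s$sex_effect)) cov_term <- cov_term + s$sex_effect * covariates$sex
    }
    out[, i] <- genetic + cov_term +
      if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else 0
  }
  out
}

#' Simulate a binary phenotype from the hierarchical model
#'
#' Draws `y_j ~ Bernoulli(pi_j)` with
#' `logit(pi_j) = beta0 + sum_k (sum_t w_kt x_jkt) beta_k`.
#'
#' @param design A [build_design()] result.
#' @param w Weight vector (length = total design columns).
#' @param beta Pathway coefficient vector (length K).
#' @param beta0 Intercept.
#' @param seed Integer seed.
#' @return Integer 0/1 vector.
#' @export
simulate_phenotype <- function(design, w, beta, beta0 = 0, seed = 1) {
  stopifnot(inherits(design, "hier_design"))
  if (length(w) != ncol(design$X)) rlang::abort("w has wrong length")
  if (length(beta) != design$K) rlang::abort("beta has wrong length")
  set.seed(seed)
  eta <- drop(beta0 + latent_scores(design, w) %*% beta)
  stats::rbinom(length(eta), 1, stats::plogis(eta))
}

#' Fully aligned simulation scenarios
#'
#' Builds a complete input bundle — genotypes, metabolites, covariates,
#' pathway map, blocked design, phenotype — with the generating truth
#' recorded, for three stress cases:
#' \describe{
#'   \item{null}{all pathway coefficients zero; the intercept matches a
#'     near-balanced case fraction (0.507).}
#'   \item{one_active_pathway}{exactly one pathway with coefficient
#'     `beta_active` (default 1.2), the rest zero.}
#'   \item{overlapping_pathways}{as null, but one metabolite belongs to
#'     two pathways, so the design carries a duplicated column.}
#' }
#' Default architecture: 5 pathways of 2 metabolites; each metabolite is
#' driven by 3 causal SNPs in its own LD block (heritability 0.3);
#' age ~ Uniform(40, 70) and sex ~ Bernoulli(0.5) enter the metabolites
#' weakly.
#'
#' @param name Scenario name.
#' @param seed Integer seed controlling every draw.
#' @param n_samples Sample count.
#' @param beta_active Active-pathway coefficient.
#' @param h2 Per-metabolite heritability.
#' @return A list: `genotypes`, `metabolites`, `covariates`, `map`,
#'   `gms` (scores from the true effects), `design`, `y`, `truth`
#'   (list `w`, `beta`, `beta0`, `effects`).
#' @export
make_scenario <- function(name = c("null", "one_active_pathway",
                                   "overlapping_pathways"),
                          seed = 1, n_samples = 400, beta_active = 1.2,
                          h2 = 0.3) {
  name <- match.arg(name)
  K <- 5
  mets_per_pathway <- 2
  n_met <- K * mets_per_pathway
  snps_per_met <- 5
  causal_per_met <- 3

  g <- simulate_genotypes(n_samples, n_met * snps_per_met,
                          maf = c(0.15, 0.4), ld_block_size = snps_per_met,
                          ld_rho = 0.5, seed = seed)
  met_ids <- sprintf("met%02d", seq_len(n_met))
  spec <- purrr::map(seq_len(n_met), function(i) {
    snps <- g$snp_meta$snp_id[(i - 1) * snps_per_met + seq_len(causal_per_met)]
    list(metabolite_id = met_ids[i],
         causal = data.frame(snp_id = snps, effect = c(0.6, -0.4, 0.5)),
         h2 = h2, age_effect = 0.01, sex_effect = 0.1)
  })
  set.seed(seed + 1000003L)
  covariates <- tibble::tibble(
    sample_id = g$sample_ids,
    age = stats::runif(n_samples, 40, 70),
    sex = stats::rbinom(n_samples, 1, 0.5)
  )
  metabolites <- simulate_metabolites(g, spec, covariates, seed = seed + 2000003L)

  map <- tibble::tibble(
    pathway_id = rep(sprintf("path%02d", seq_len(K)), each = mets_per_pathway),
    pathway_name = rep(sprintf("pathway %d", seq_len(K)), each = mets_per_pathway),
    metabolite_id = met_ids
  )
  if (name == "overlapping_pathways") {
    map <- dplyr::bind_rows(map, tibble::tibble(
      pathway_id = "path02", pathway_name = "pathway 2",
      metabolite_id = met_ids[1]
    ))
  }

  effects <- dplyr::bind_rows(purrr::map(spec, function(s) {
    tibble::tibble(metabolite_id = s$metabolite_id,
                   snp_id = s$causal$snp_id,
                   effect_allele = "A", effect = s$causal$effect)
  }))
  attr(effects, "method") <- "truth"
  gms <- compute_gms(g, effects, metabolite_ids = met_ids)
  design <- suppressWarnings(build_design(gms, map, standardize = TRUE))

  w <- rep(1 / sqrt(design$Tk), times = design$Tk)
  beta <- rep(0, design$K)
  if (name == "one_active_pathway") beta[1] <- beta_active
  beta0 <- stats::qlogis(318 / 627) # near-balanced case fraction
  y <- simulate_phenotype(design, w, beta, beta0, seed = seed + 3000017L)
  if (length(unique(y)) < 2) {
    y[1:2] <- c(0L, 1L) # degenerate draw guard for tiny n
  }

  list(genotypes = g, metabolites = metabolites, covariates = covariates,
       map = map, gms = gms, design = design, y = y,
       truth = list(w = w, beta = beta, beta0 = beta0, effects = effects,
                    active_pathway = if (name == "one_active_pathway")
                      names(design$Tk)[1] else NA_character_))
}
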