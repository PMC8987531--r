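#' Minor allele frequency of a dosage vector
#'
#' Frequency of the less common allele among non-missing genotypes.
#' Always in `[0, 0.5]`: if the counted (effect) allele is the major one
#' the frequency of the other allele is returned.
#'
#' @param dosages Vector of values in `{0, 1, 2, NA}`.
#' @return Minor allele frequency.
#' @export
minor_allele_frequency <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) rlang::abort("all genotypes missing; MAF undefined")
  p <- sum(d) / (2 * length(d))
  min(p, 1 - p)
}

# frequency of the counted allele (allele 1), not folded to <= 0.5
effect_allele_freq <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) return(NA_real_)
  sum(d) / (2 * length(d))
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, sums the
#' probabilities of all heterozygote configurations that are no more
#' probable than the observed one under Hardy-Weinberg equilibrium.
#' Uses the standard mid-out recurrence on the heterozygote count.
#'
#' @param n_het Observed heterozygote count.
#' @param n_hom_minor Observed minor-homozygote count.
#' @param n_hom_major Observed major-homozygote count.
#' @return Exact p-value in `(0, 1]`.
#' @export
hwe_exact_pvalue <- function(n_het, n_hom_minor, n_hom_major) {
  if (any(c(n_het, n_hom_minor, n_hom_major) < 0)) {
    rlang::abort("genotype counts must be non-negative")
  }
  n <- n_het + n_hom_minor + n_hom_major
  if (n < 1) rlang::abort("need at least one genotype")
  # rare allele count (label-symmetric: use the smaller of the two)
  na1 <- 2 * n_hom_minor + n_het
  na2 <- 2 * n_hom_major + n_het
  nr <- min(na1, na2)
  if (nr == 0) return(1) # monomorphic: single configuration

  # feasible het counts share parity with nr
  hets <- seq(nr %% 2, nr, by = 2)
  probs <- numeric(length(hets))
  # start at an interior feasible het count near the HWE mode and recurse
  mid <- floor(nr * (2 * n - nr) / (2 * n))
  if (mid %% 2 != nr %% 2) mid <- mid + 1
  if (mid > nr) mid <- mid - 2
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  # P(h-2)/P(h) = h(h-1) / ((nr-h+2)/2 * ((2n-nr-h+2)/2)) ... derive via
  # counts: hom_rare = (nr-h)/2, hom_common = (2n-nr-h)/2
  if (i_mid > 1) {
    for (i in seq(i_mid - 1, 1)) {
      h <- hets[i + 1]
      hr <- (nr - h) / 2
      hc <- (2 * n - nr - h) / 2
      probs[i] <- probs[i + 1] * h * (h - 1) / (4 * (hr + 1) * (hc + 1))
    }
  }
  if (i_mid < length(hets)) {
    for (i in seq(i_mid + 1, length(hets))) {
      h <- hets[i - 1]
      hr <- (nr - h) / 2
      hc <- (2 * n - nr - h) / 2
      probs[i] <- probs[i - 1] * 4 * hr * hc / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  if (is.na(p_obs)) rlang::abort("inconsistent genotype counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# per-column HWE p for a dosage matrix (dosage counts allele1)
hwe_pvalues <- function(dosages) {
  apply(dosages, 2, function(d) {
    d <- d[!is.na(d)]
    if (!length(d)) return(NA_real_)
    n2 <- sum(d == 2L)
    n1 <- sum(d == 1L)
    n0 <- sum(d == 0L)
    # which homozygote class is "minor" is irrelevant (test is symmetric)
    hwe_exact_pvalue(n1, min(n0, n2), max(n0, n2))
  })
}

#' Quality-control thresholds
#'
#' Defaults follow common practice for common-variant association work:
#' drop SNPs with missing rate over 0.1, exact HWE p below 1e-6, or MAF
#' at or below 0.05; then drop samples with call rate at or below 0.9.
#'
#' @param max_snp_missing_rate Maximum tolerated per-SNP missing fraction.
#' @param hwe_p_cutoff SNPs with exact HWE p strictly below this are dropped.
#' @param min_maf SNPs with MAF less than or equal to this are dropped.
#' @param min_sample_call_rate Samples with call rate not exceeding this are
#'   dropped.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_snp_missing_rate = 0.1,
                          hwe_p_cutoff = 1e-6,
                          min_maf = 0.05,
                          min_sample_call_rate = 0.9) {
  if (max_snp_missing_rate < 0 || max_snp_missing_rate > 1)
    rlang::abort("max_snp_missing_rate must be in [0, 1]")
  if (hwe_p_cutoff < 0 || hwe_p_cutoff > 1)
    rlang::abort("hwe_p_cutoff must be in [0, 1]")
  if (min_maf < 0 || min_maf > 0.5)
    rlang::abort("min_maf must be in [0, 0.5]")
  if (min_sample_call_rate < 0 || min_sample_call_rate > 1)
    rlang::abort("min_sample_call_rate must be in [0, 1]")
  structure(
    list(max_snp_missing_rate = max_snp_missing_rate,
         hwe_p_cutoff = hwe_p_cutoff,
         min_maf = min_maf,
         min_sample_call_rate = min_sample_call_rate),
    class = "qc_thresholds"
  )
}

#' Apply variant- and sample-level quality control
#'
#' Filters are applied in a fixed, logged order: SNP missing rate, then
#' exact HWE, then MAF, then sample call rate (computed on the surviving
#' SNPs). A SNP is removed by the first filter it fails.
#'
#' @param g A [geno_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return A list with elements `genotypes` (filtered [geno_matrix()]) and
#'   `report` (tibble: one row per filter with counts removed/retained, in
#'   application order).
#' @export
apply_qc <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "geno_matrix"))
  if (!inherits(thresholds, "qc_thresholds")) {
    thresholds <- do.call(qc_thresholds, as.list(thresholds))
  }
  t <- thresholds
  d <- g$dosages
  n0_snp <- ncol(d)
  n0_sample <- nrow(d)

  miss <- colMeans(is.na(d))
  keep1 <- miss <= t$max_snp_missing_rate
  removed_miss <- sum(!keep1)
  d <- d[, keep1, drop = FALSE]

  hwe <- if (ncol(d)) hwe_pvalues(d) else numeric()
  keep2 <- is.na(hwe) | hwe >= t$hwe_p_cutoff
  removed_hwe <- sum(!keep2)
  d <- d[, keep2, drop = FALSE]

  maf <- if (ncol(d)) apply(d, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(0) else minor_allele_frequency(x)
  }) else numeric()
  keep3 <- maf > t$min_maf
  removed_maf <- sum(!keep3)
  d <- d[, keep3, drop = FALSE]

  call_rate <- if (ncol(d)) rowMeans(!is.na(d)) else rep(1, nrow(d))
  keep_s <- call_rate > t$min_sample_call_rate
  removed_samples <- sum(!keep_s)

  kept <- subset_geno(g, snps = colnames(d))
  kept <- subset_geno(kept, samples = which(keep_s))

  report <- tibble::tibble(
    filter = c("snp_missing_rate", "snp_hwe", "snp_maf", "sample_call_rate"),
    unit = c("snp", "snp", "snp", "sample"),
    threshold = c(t$max_snp_missing_rate, t$hwe_p_cutoff, t$min_maf,
                  t$min_sample_call_rate),
    removed = c(removed_miss, removed_hwe, removed_maf, removed_samples),
    retained = c(n0_snp - removed_miss,
                 n0_snp - removed_miss - removed_hwe,
                 n0_snp - removed_miss - removed_hwe - removed_maf,
                 n0_sample - removed_samples)
  )
  list(genotypes = kept, report = report)
}
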