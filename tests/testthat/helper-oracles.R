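# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately different route to the same quantity as the
# implementation it checks.

# --- naive PLINK .bed decoder: per-byte bit shifting via rawToBits ----------
naive_bed_decode <- function(bed_path, n_samples, n_snps) {
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  stopifnot(raw[1] == as.raw(0x6c), raw[2] == as.raw(0x1b), raw[3] == as.raw(0x01))
  payload <- raw[-(1:3)]
  bits <- as.integer(rawToBits(payload)) # little-endian within each byte
  bpsnp <- ceiling(n_samples / 4)
  out <- matrix(NA_integer_, n_samples, n_snps)
  for (s in seq_len(n_snps)) {
    base <- (s - 1) * bpsnp * 8
    for (i in seq_len(n_samples)) {
      b0 <- bits[base + 2 * (i - 1) + 1]
      b1 <- bits[base + 2 * (i - 1) + 2]
      code <- b0 + 2L * b1
      out[i, s] <- switch(code + 1L, 2L, NA_integer_, 1L, 0L)
    }
  }
  out
}

# --- exact HWE by direct enumeration with log-factorials --------------------
hwe_enum <- function(n_het, n_hom_minor, n_hom_major) {
  n <- n_het + n_hom_minor + n_hom_major
  nr <- min(2 * n_hom_minor + n_het, 2 * n_hom_major + n_het)
  if (nr == 0) return(1)
  hets <- seq(nr %% 2, nr, by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (nr - h) / 2
    hc <- n - h - hr
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2) + lfactorial(nr) + lfactorial(2 * n - nr) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# --- textbook Benjamini-Hochberg step-up ------------------------------------
bh_manual <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  for (i in seq(m - 1, 1, length.out = max(0, m - 1))) {
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# --- literal step-by-step greedy clumping trace -----------------------------
clump_trace <- function(assoc, g, spec) {
  a <- assoc[order(assoc$p, assoc$chrom, assoc$pos, assoc$snp_id), , drop = FALSE]
  pool <- a$snp_id
  kept <- character()
  while (length(pool)) {
    idx_id <- pool[1]
    kept <- c(kept, idx_id)
    row_i <- a[a$snp_id == idx_id, ]
    drop_ids <- idx_id
    for (cand in setdiff(pool, idx_id)) {
      row_c <- a[a$snp_id == cand, ]
      if (row_c$chrom != row_i$chrom) next
      if (abs(row_c$pos - row_i$pos) > spec$window_kb * 1000) next
      x1 <- g$dosages[, idx_id]
      x2 <- g$dosages[, cand]
      ok <- !is.na(x1) & !is.na(x2)
      r2 <- if (stats::var(x1[ok]) == 0 || stats::var(x2[ok]) == 0) 0
        else stats::cor(x1[ok], x2[ok])^2
      if (r2 > spec$r2_cutoff) drop_ids <- c(drop_ids, cand)
    }
    pool <- setdiff(pool, drop_ids)
  }
  kept
}

# --- small random genotype fixture ------------------------------------------
random_geno <- function(n, m, seed, miss_rate = 0.05, chrom = NULL) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2, runif(1, 0.2, 0.5)), n, m)
  if (miss_rate > 0) d[runif(n * m) < miss_rate] <- NA
  geno_matrix(
    d,
    snp_meta = tibble::tibble(
      snp_id = paste0("s", seq_len(m)),
      chrom = chrom %||% rep("1", m),
      pos = seq_len(m) * 1000L,
      allele1 = sample(c("A", "C"), m, replace = TRUE),
      allele2 = "G"
    ),
    sample_ids = paste0("id", seq_len(n))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small blocked design for model-level tests:
# K pathways of Tk columns each, standardized columns
random_design <- function(n, K, Tk, seed) {
  set.seed(seed)
  gms <- matrix(rnorm(n * K * Tk), n,
                dimnames = list(paste0("i", seq_len(n)),
                                sprintf("m%02d", seq_len(K * Tk))))
  map <- tibble::tibble(
    pathway_id = rep(sprintf("pw%02d", seq_len(K)), each = Tk),
    pathway_name = rep(sprintf("pw%02d", seq_len(K)), each = Tk),
    metabolite_id = colnames(gms)
  )
  build_design(gms, map, standardize = TRUE)
}

# penalized objective recomputed from scratch (independent of fit internals)
objective_direct <- function(design, y, w, beta, beta0, lambda_m, lambda_p,
                             penalize_intercept = TRUE) {
  idx <- rep(seq_len(design$K), times = design$Tk)
  eta <- rep(beta0, nrow(design$X))
  for (k in seq_len(design$K)) {
    cols <- which(idx == k)
    eta <- eta + (design$X[, cols, drop = FALSE] %*% w[cols]) * beta[k]
  }
  eta <- drop(eta)
  ll <- sum(ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
                   stats::plogis(-eta, log.p = TRUE)))
  ll - 0.5 * lambda_m * sum(w^2) -
    0.5 * lambda_p * (sum(beta^2) + if (penalize_intercept) beta0^2 else 0)
}

# central finite-difference gradient of objective_direct in all parameters
fd_gradient <- function(design, y, fit, h = 1e-5) {
  pen <- fit$pen
  pack <- c(fit$beta0, fit$beta, fit$w)
  K <- length(fit$beta)
  f_at <- function(v) {
    objective_direct(design, y,
                     w = v[-(1:(K + 1))], beta = v[2:(K + 1)], beta0 = v[1],
                     lambda_m = pen$lambda_m, lambda_p = pen$lambda_p,
                     penalize_intercept = pen$penalize_intercept)
  }
  vapply(seq_along(pack), function(i) {
    e <- numeric(length(pack)); e[i] <- h
    (f_at(pack + e) - f_at(pack - e)) / (2 * h)
  }, numeric(1))
}
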