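#' Run the full pathway-analysis pipeline
#'
#' Orchestrates QC, the metabolite association scan, genetic metabolomic
#' score construction (clumping+thresholding or GBLUP), design building,
#' penalty selection by cross-validation, the final fit, permutation
#' p-values and FDR, writing every result table plus a provenance log to
#' `out_dir`.
#'
#' @param config A named list or a YAML file path. Recognised fields:
#'   `genotype_prefix` (PLINK triple) or `dosage_tsv`; `metabolite_tsv`;
#'   `covariate_tsv` (optional; columns `sample_id`, `age`, `sex`);
#'   `pathway_map`; `phenotype_tsv` (columns `sample_id`, `y`) or
#'   `glycemic_tsv` (columns `sample_id`, `fbs`, `pp2`, `hba1c`,
#'   `on_drug`); `method` ("single" or "gblup"); `qc` (list of
#'   [qc_thresholds()] fields); `clump` (list of [clump_spec()] fields);
#'   `top_fraction`; `lambda_grid` (list with `lambda_m`, `lambda_p`
#'   vectors, crossed); `n_folds`; `n_perm`; `seed`; `standardize`;
#'   `penalize_intercept`; `out_dir`.
#' @return Invisibly, a list with the in-memory results (`qc_report`,
#'   `assoc`, `effects`, `gms`, `design`, `cv`, `fit`, `perm`, `report`)
#'   and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  method <- match.arg(cfg$method %||% "single", c("single", "gblup"))
  seed <- as.integer(cfg$seed %||% 1)
  out_dir <- cfg$out_dir %||% rlang::abort("config needs out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
  }

  g <- stage("read_genotypes", {
    if (!is.null(cfg$genotype_prefix)) read_plink(cfg$genotype_prefix)
    else if (!is.null(cfg$dosage_tsv)) read_dosage_tsv(cfg$dosage_tsv)
    else rlang::abort("need genotype_prefix or dosage_tsv")
  })
  qc <- stage("qc", {
    apply_qc(g, do.call(qc_thresholds, as.list(cfg$qc %||% list())))
  })
  g <- qc$genotypes

  met_tab <- stage("read_metabolites", {
    utils::read.table(cfg$metabolite_tsv, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
  })
  cov_tab <- if (!is.null(cfg$covariate_tsv)) {
    utils::read.table(cfg$covariate_tsv, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else NULL

  pheno <- stage("read_phenotype", {
    if (!is.null(cfg$phenotype_tsv)) {
      utils::read.table(cfg$phenotype_tsv, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    } else if (!is.null(cfg$glycemic_tsv)) {
      gl <- utils::read.table(cfg$glycemic_tsv, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      cl <- classify_glycemic_status(gl)
      lab <- label_case_control(cl$status)
      data.frame(sample_id = gl$sample_id[lab$index], y = lab$y)
    } else rlang::abort("need phenotype_tsv or glycemic_tsv")
  })

  # restrict to samples with genotype + metabolite + phenotype
  met_ids_col <- if ("sample_id" %in% names(met_tab)) met_tab$sample_id else rownames(met_tab)
  keep <- intersect(intersect(g$sample_ids, met_ids_col), pheno$sample_id)
  if (length(keep) < 10) rlang::abort("fewer than 10 samples shared across inputs")
  g <- subset_geno(g, samples = keep)
  y <- pheno$y[match(keep, pheno$sample_id)]

  M <- align_to_samples(met_tab, keep, "metabolites")
  assoc <- stage("mgwas", run_mgwas(g, M, cov_tab))

  cspec <- do.call(clump_spec, as.list(cfg$clump %||% list()))
  effects <- stage("gms_effects", {
    if (method == "single") {
      single_snp_effects(assoc, g, cspec)
    } else {
      grm <- compute_grm(g)
      X <- matrix(1, length(keep), 1)
      if (!is.null(cov_tab)) {
        X <- cbind(X, align_to_samples(cov_tab, keep, "covariates"))
      }
      eff <- dplyr::bind_rows(purrr::map(colnames(M), function(m) {
        comp <- estimate_variance_components(M[, m], grm, X)
        gblup_snp_effects(g, M[, m], cov_tab, comp, metabolite_id = m)
      }))
      attr(eff, "method") <- "gblup"
      select_top_fraction(eff, cfg$top_fraction %||% 0.2)
    }
  })

  gms <- stage("gms_scores", {
    compute_gms(g, effects, metabolite_ids = colnames(M))
  })
  map <- stage("read_map", {
    if (is.character(cfg$pathway_map)) read_pathway_map(cfg$pathway_map)
    else tibble::as_tibble(cfg$pathway_map)
  })
  design <- stage("design", {
    build_design(gms, map, standardize = isTRUE(cfg$standardize %||% TRUE))
  })

  grid <- if (!is.null(cfg$lambda_grid)) {
    expand.grid(lambda_m = cfg$lambda_grid$lambda_m,
                lambda_p = cfg$lambda_grid$lambda_p)
  } else NULL
  cv <- stage("cv", {
    cv_select_lambda(design, y, grid, n_folds = cfg$n_folds %||% 5,
                     seed = seed,
                     penalize_intercept = isTRUE(cfg$penalize_intercept %||% TRUE))
  })
  fit <- stage("fit", fit_hiscom(design, y, cv$best))
  perm <- stage("permute", {
    permutation_pvalues(design, y, cv$best, B = cfg$n_perm %||% 99,
                        seed = seed + 1L, observed_fit = fit)
  })
  report <- stage("report", pathway_report(fit, perm))

  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE
  )
  wt(qc$report, "qc_report.tsv")
  wt(assoc, "assoc.tsv")
  wt(effects, "effects.tsv")
  wt(data.frame(sample_id = rownames(gms), gms, check.names = FALSE), "gms.tsv")
  wt(cv$cv_table, "cv_table.tsv")
  wt(report, "pathway_results.tsv")
  yaml::write_yaml(list(
    method = method, seed = seed,
    n_samples = length(keep), n_snps = n_snps(g),
    n_metabolites = ncol(M), n_pathways = design$K,
    lambda_m = cv$best$lambda_m, lambda_p = cv$best$lambda_p,
    n_perm = attr(perm, "B"),
    clump = unclass(cspec),
    package_version = as.character(utils::packageVersion("hiscomsm"))
  ), file.path(out_dir, "provenance.yaml"))

  invisible(list(qc_report = qc$report, assoc = assoc, effects = effects,
                 gms = gms, design = design, cv = cv, fit = fit,
                 perm = perm, report = report, out_dir = out_dir))
}
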