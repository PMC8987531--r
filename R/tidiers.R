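#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted hierarchical model
#'
#' @param x A `hiscom_fit`.
#' @param level `"pathway"` (default) returns one row per pathway with the
#'   identified coefficient; `"weight"` returns one row per (pathway,
#'   metabolite) score weight on the unit-norm scale.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hiscom_fit <- function(x, level = c("pathway", "weight"), ...) {
  level <- match.arg(level)
  if (level == "pathway") {
    tibble::tibble(
      pathway_id = names(x$beta_eff),
      T_k = unname(x$Tk[names(x$beta_eff)]),
      estimate = unname(x$beta_eff)
    )
  } else {
    dplyr::mutate(x$blocks, weight = x$w_unit[.data$column])[
      , c("pathway_id", "metabolite_id", "weight")]
  }
}

#' @rdname tidy.hiscom_fit
#' @export
glance.hiscom_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_pathways = length(x$beta),
    phi = x$phi, beta0 = x$beta0,
    lambda_m = x$pen$lambda_m, lambda_p = x$pen$lambda_p,
    iterations = x$iterations, converged = x$converged,
    grad_max = x$grad_max
  )
}

#' @rdname tidy.hiscom_fit
#' @export
tidy.hiscom_perm <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.hiscom_fit
#' @export
glance.hiscom_perm <- function(x, ...) {
  tibble::tibble(
    n_pathways = nrow(x), B = attr(x, "B"),
    lambda_m = attr(x, "pen")$lambda_m,
    lambda_p = attr(x, "pen")$lambda_p,
    redraws = attr(x, "redraws"),
    n_significant_q05 = sum(x$q_bh < 0.05)
  )
}

#' Plot pathway permutation evidence
#'
#' Bars of `-log10` empirical p per pathway, shaded by the sign of the
#' identified coefficient, with the q < 0.05 pathways labelled.
#'
#' @param object A `hiscom_perm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hiscom_perm <- function(object, ...) {
  d <- tibble::as_tibble(unclass(object))
  d$direction <- factor(ifelse(d$beta_obs >= 0, "positive", "negative"),
                        levels = c("positive", "negative"))
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$pathway_id, -log10(.data$p_empirical)),
    y = -log10(.data$p_empirical), fill = .data$direction
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ "empirical p"),
                  fill = "effect sign") +
    ggplot2::theme_minimal()
}

#' Plot the score-weight profile of a fitted model
#'
#' @param object A `hiscom_fit`.
#' @param ... Unused.
#' @return A ggplot object: unit-norm weights per pathway block.
#' @export
autoplot.hiscom_fit <- function(object, ...) {
  d <- tidy(object, level = "weight")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metabolite_id, y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~pathway_id, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "score weight (unit-norm scale)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Manhattan data and plot for one metabolite scan
#'
#' `export_manhattan()` returns (and optionally writes) the per-SNP
#' `-log10 p` table sorted by genomic position; `plot_manhattan()` draws
#' it.
#'
#' @param assoc Association tibble from [run_mgwas()].
#' @param metabolite_id Metabolite to export.
#' @param path Optional TSV output path.
#' @return A tibble: `snp_id`, `chrom`, `pos`, `neglog10_p`.
#' @export
export_manhattan <- function(assoc, metabolite_id, path = NULL) {
  if (!metabolite_id %in% assoc$metabolite_id) {
    rlang::abort(paste0("unknown metabolite: ", metabolite_id))
  }
  out <- assoc |>
    dplyr::filter(.data$metabolite_id == !!metabolite_id) |>
    dplyr::mutate(neglog10_p = -log10(.data$p)) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::select("snp_id", "chrom", "pos", "neglog10_p")
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' @rdname export_manhattan
#' @param significance Horizontal reference line (p scale).
#' @export
plot_manhattan <- function(assoc, metabolite_id, significance = 1e-8) {
  d <- export_manhattan(assoc, metabolite_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$neglog10_p)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::geom_hline(yintercept = -log10(significance), linetype = 2) +
    ggplot2::labs(x = "position", y = expression(-log[10] ~ p),
                  title = metabolite_id) +
    ggplot2::theme_minimal()
}
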