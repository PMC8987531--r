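#' Read a GMT-like metabolite pathway map
#'
#' Tab-separated, one pathway per line: pathway id, pathway name, then the
#' member metabolite ids.
#'
#' @param path File path.
#' @return A pathway map: tibble with columns `pathway_id`, `pathway_name`,
#'   `metabolite_id` (one row per membership).
#' @export
read_pathway_map <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::map(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) rlang::abort("pathway map lines need id, name and >= 1 member")
    tibble::tibble(pathway_id = f[1], pathway_name = f[2],
                   metabolite_id = f[-(1:2)])
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(unique(out[, c("pathway_id", "pathway_name")])$pathway_id)) {
    rlang::abort("duplicate pathway ids in map")
  }
  out
}

#' @rdname read_pathway_map
#' @param map Pathway-map tibble.
#' @export
write_pathway_map <- function(map, path) {
  lines <- map |>
    dplyr::group_by(.data$pathway_id, .data$pathway_name) |>
    dplyr::summarise(members = paste(.data$metabolite_id, collapse = "\t"),
                     .groups = "drop") |>
    dplyr::arrange(.data$pathway_id)
  writeLines(paste(lines$pathway_id, lines$pathway_name, lines$members,
                   sep = "\t"), path)
  invisible(path)
}

#' Build the pathway-blocked hierarchical design
#'
#' Lays out the genetic metabolomic scores as column blocks, one block per
#' pathway; a metabolite shared by several pathways contributes one column
#' per containing pathway (each with its own weight downstream). Mapped
#' metabolites absent from the score matrix are dropped with a warning, as
#' are pathways left empty. Blocks are ordered by pathway id, columns
#' within a block by metabolite id.
#'
#' @param gms Score matrix from [compute_gms()] (samples x metabolites,
#'   dimnames required), or any numeric matrix shaped that way.
#' @param map Pathway-map tibble (see [read_pathway_map()]).
#' @param standardize Z-score every column (default TRUE); means and SDs
#'   are recorded. Zero-variance columns are left at 0 with a warning.
#' @return An object of class `hier_design`: list with `X` (N x P matrix),
#'   `blocks` (tibble: `pathway_id`, `pathway_name`, `metabolite_id`,
#'   `column`), `K`, `Tk` (named per-pathway column counts), `sample_ids`,
#'   `center`, `scale`.
#' @export
build_design <- function(gms, map, standardize = TRUE) {
  gms <- as.matrix(gms)
  if (is.null(colnames(gms))) rlang::abort("gms must have metabolite column names")
  measured <- colnames(gms)
  map <- tibble::as_tibble(map)

  all_pathways <- unique(map$pathway_id)
  dropped <- setdiff(unique(map$metabolite_id), measured)
  if (length(dropped)) {
    rlang::warn(sprintf("dropping %d mapped metabolite(s) without scores", length(dropped)))
    map <- dplyr::filter(map, .data$metabolite_id %in% measured)
  }
  if (!nrow(map)) rlang::abort("no pathway retains any measured metabolite")
  empty <- setdiff(all_pathways, unique(map$pathway_id))
  if (length(empty)) {
    rlang::warn(sprintf("dropping %d pathway(s) left without measured metabolites",
                        length(empty)))
  }

  blocks <- map |>
    dplyr::distinct(.data$pathway_id, .data$pathway_name, .data$metabolite_id) |>
    dplyr::arrange(.data$pathway_id, .data$metabolite_id) |>
    dplyr::mutate(column = dplyr::row_number())

  X <- gms[, blocks$metabolite_id, drop = FALSE]
  colnames(X) <- paste(blocks$pathway_id, blocks$metabolite_id, sep = ":")
  center <- rep(0, ncol(X))
  scale <- rep(1, ncol(X))
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    zero <- scale < 1e-12 | is.na(scale)
    if (any(zero)) {
      rlang::warn(sprintf("%d design column(s) have zero variance; left at 0", sum(zero)))
      scale[zero] <- 1
    }
    X <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  }
  Tk <- table(factor(blocks$pathway_id, levels = unique(blocks$pathway_id)))
  structure(
    list(X = X, blocks = blocks, K = length(Tk),
         Tk = stats::setNames(as.integer(Tk), names(Tk)),
         sample_ids = rownames(gms), center = center, scale = scale,
         standardized = standardize),
    class = "hier_design"
  )
}

#' @export
print.hier_design <- function(x, ...) {
  cat(sprintf("<hier_design> %d samples, %d pathways, %d score columns\n",
              nrow(x$X), x$K, ncol(x$X)))
  invisible(x)
}
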