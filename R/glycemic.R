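#' Classify glycemic status from clinical measurements
#'
#' Applies the standard diagnostic cutoffs for type 2 diabetes to fasting
#' blood sugar (FBS, mg/dl), 2-h postprandial glucose (2PP, mg/dl), HbA1c
#' (%) and anti-diabetic drug treatment. A record is
#' \describe{
#'   \item{T2D}{if ANY of: FBS >= 126, 2PP >= 200, HbA1c >= 6.5, on drug;}
#'   \item{preT2D}{else if ANY of: 100 <= FBS < 126, 140 <= 2PP < 200,
#'     5.6 < HbA1c < 6.5 (and not on drug);}
#'   \item{normal}{else if ALL of: FBS < 100, 2PP < 140, HbA1c <= 5.6,
#'     not on drug.}
#' }
#' T2D takes precedence over preT2D (the trigger sets are ORs, the normal
#' set an AND). A missing measurement makes the record unclassifiable
#' unless an observed T2D trigger already fires.
#'
#' @param records Data frame with columns `fbs`, `pp2`, `hba1c`,
#'   `on_drug` (logical or 0/1).
#' @return The input tibble with a `status` factor column
#'   (`normal`, `preT2D`, `T2D`, `unclassifiable`).
#' @export
classify_glycemic_status <- function(records) {
  r <- tibble::as_tibble(records)
  need <- c("fbs", "pp2", "hba1c", "on_drug")
  if (!all(need %in% names(r))) {
    rlang::abort(paste0("records need columns: ", paste(need, collapse = ", ")))
  }
  num <- c("fbs", "pp2", "hba1c")
  if (any(unlist(r[num]) < 0, na.rm = TRUE)) {
    rlang::abort("measurements must be non-negative")
  }
  drug <- as.logical(r$on_drug)

  t2d <- (!is.na(r$fbs) & r$fbs >= 126) |
    (!is.na(r$pp2) & r$pp2 >= 200) |
    (!is.na(r$hba1c) & r$hba1c >= 6.5) |
    (!is.na(drug) & drug)
  complete <- !is.na(r$fbs) & !is.na(r$pp2) & !is.na(r$hba1c) & !is.na(drug)
  pre <- complete & !t2d & !drug &
    ((r$fbs >= 100 & r$fbs < 126) |
       (r$pp2 >= 140 & r$pp2 < 200) |
       (r$hba1c > 5.6 & r$hba1c < 6.5))
  normal <- complete & !t2d & !pre & !drug &
    r$fbs < 100 & r$pp2 < 140 & r$hba1c <= 5.6

  status <- rep("unclassifiable", nrow(r))
  status[normal] <- "normal"
  status[pre] <- "preT2D"
  status[t2d] <- "T2D"
  r$status <- factor(status,
                     levels = c("normal", "preT2D", "T2D", "unclassifiable"))
  r
}

#' Binary case/control labels from glycemic status
#'
#' Cases are preT2D or T2D; controls are normal; unclassifiable records
#' are dropped (with a message reporting how many).
#'
#' @param status Factor/character vector of statuses as produced by
#'   [classify_glycemic_status()].
#' @return A tibble with `index` (position in the input), `status` and
#'   `y` (1 = case, 0 = control); attribute `n_dropped`.
#' @export
label_case_control <- function(status) {
  status <- as.character(status)
  keep <- status %in% c("normal", "preT2D", "T2D")
  n_dropped <- sum(!keep)
  if (n_dropped) {
    rlang::inform(sprintf("dropping %d unclassifiable record(s)", n_dropped))
  }
  y <- ifelse(status[keep] == "normal", 0L, 1L)
  if (length(unique(y)) < 2) {
    rlang::abort("need both cases and controls after labelling")
  }
  structure(
    tibble::tibble(index = which(keep), status = status[keep], y = y),
    n_dropped = n_dropped
  )
}
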