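# Confrontation of predicted and measured human intestinal absorption.

FA_CUTOFF <- 0.30

#' Curate measured fraction-absorbed (Fa) values
#'
#' Consolidates per-study literature Fa entries into one retained value and
#' a high/low label per compound, following the curation rules used for
#' human pharmacokinetics data: a range reported for one ingested dose is
#' collapsed to its median; several values (different studies or doses) are
#' averaged; the label is `"high"` when the retained Fa is >= 0.30 (the
#' boundary counts as high), `"low"` otherwise.
#'
#' Literature values stated only as bounds (e.g. "Fa > 0.48") are accepted
#' through the `operator` column; a bound decides the label directly when it
#' already implies one side of the cutoff (every such bound in practice
#' does), and the bound value itself is retained as `fa_final`.
#'
#' @param entries data frame with columns `compound_id`, `fa` (value, or
#'   range midpoint source: use `fa_lo`/`fa_hi` for ranges) and optionally
#'   `operator` (one of `"="`, `">"`, `">="`, `"<"`, `"<="`; default `"="`).
#'   One row per study entry; several rows per compound are averaged.
#' @return a tibble: `compound_id`, `n_entries`, `fa_final`,
#'   `measured_label`.
#' @export
curate_measured_fa <- function(entries) {
  stopifnot(is.data.frame(entries), "compound_id" %in% names(entries))
  entries <- tibble::as_tibble(entries)
  if (!nrow(entries)) stop("no measured-Fa entries supplied", call. = FALSE)
  has_range <- all(c("fa_lo", "fa_hi") %in% names(entries))
  if (!"fa" %in% names(entries) && !has_range) {
    stop("entries need an 'fa' column or 'fa_lo'/'fa_hi' range columns",
         call. = FALSE)
  }
  if (!"operator" %in% names(entries)) entries$operator <- "="
  entries$operator[is.na(entries$operator)] <- "="

  val <- rep(NA_real_, nrow(entries))
  if ("fa" %in% names(entries)) val <- as.numeric(entries$fa)
  if (has_range) {
    r <- !is.na(entries$fa_lo) & !is.na(entries$fa_hi)
    if (any(r)) {
      lo <- entries$fa_lo[r]; hi <- entries$fa_hi[r]
      if (any(lo > hi | lo < 0 | hi > 1)) {
        stop("invalid Fa range (need 0 <= lo <= hi <= 1)", call. = FALSE)
      }
      # a range for one ingested dose collapses to its median
      val[r] <- (lo + hi) / 2
    }
  }
  if (any(is.na(val))) stop("missing Fa value in entries", call. = FALSE)
  if (any(val < 0 | val > 1)) {
    stop("Fa values must lie in [0, 1]", call. = FALSE)
  }

  entries$.val <- val
  out <- entries |>
    dplyr::group_by(compound_id = as.character(.data$compound_id)) |>
    dplyr::summarise(
      n_entries = dplyr::n(),
      fa_final = mean(.data$.val),
      # a pure lower bound >= cutoff forces "high"; an upper bound < cutoff
      # forces "low"; otherwise the retained value decides
      measured_label = {
        ops <- .data$operator
        v <- mean(.data$.val)
        if (any(ops %in% c(">", ">=") & .data$.val >= FA_CUTOFF)) "high"
        else if (any(ops %in% c("<", "<=") & .data$.val < FA_CUTOFF)) "low"
        else if (v >= FA_CUTOFF) "high" else "low"
      },
      .groups = "drop"
    )
  out
}

#' Confront predicted and measured intestinal absorption
#'
#' Counts, per compound, whether the predicted gastrointestinal label
#' (`gi_label`: high/low) agrees with the measured label derived from human
#' Fa data, and computes the prediction accuracy as
#' 100 x (compounds with identical predicted and measured absorption) /
#' (total compounds).
#'
#' @param measured output of [curate_measured_fa()] (needs `compound_id`,
#'   `measured_label`).
#' @param predicted output of [classify_permeation()] (needs `id`,
#'   `gi_label`).
#' @return a `permeation_confrontation` object: list with `table` (per
#'   compound: measured and predicted labels, concordant flag), `n_total`,
#'   `n_concordant`, `accuracy` (percent), `discordant` (ids).
#' @export
confront <- function(measured, predicted) {
  stopifnot(is.data.frame(measured), is.data.frame(predicted),
            "compound_id" %in% names(measured),
            all(c("id", "gi_label") %in% names(predicted)))
  miss <- setdiff(measured$compound_id, predicted$id)
  if (length(miss)) {
    stop("no prediction for measured compound(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tab <- tibble::tibble(
    compound_id = as.character(measured$compound_id),
    measured_label = measured$measured_label,
    predicted_label = predicted$gi_label[match(measured$compound_id,
                                               predicted$id)]
  )
  tab$concordant <- tab$measured_label == tab$predicted_label
  res <- list(
    table = tab,
    n_total = nrow(tab),
    n_concordant = sum(tab$concordant),
    accuracy = 100 * sum(tab$concordant) / nrow(tab),
    discordant = tab$compound_id[!tab$concordant]
  )
  class(res) <- "permeation_confrontation"
  res
}

#' @export
print.permeation_confrontation <- function(x, ...) {
  cat(sprintf(
    "Predicted vs measured intestinal absorption: %d/%d concordant (accuracy %.1f%%)\n",
    x$n_concordant, x$n_total, x$accuracy))
  if (length(x$discordant)) {
    cat("  discordant:", paste(x$discordant, collapse = ", "), "\n")
  }
  invisible(x)
}
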