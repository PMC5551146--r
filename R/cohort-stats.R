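# Cohort-level aggregation and descriptor-association statistics.

#' Summarize permeation predictions by chemical class
#'
#' One row per chemical class plus an `"all"` row, giving compound counts
#' and the percentage predicted intestine-permeant (`pct_gi_high`) and
#' brain-permeant (`pct_bbb_yes`). Class-level percentages are reported
#' rounded to the nearest integer and the overall row to one decimal,
#' matching the reporting convention for this kind of cohort; the raw
#' (unrounded) percentages are kept in `pct_gi_high_raw` / `pct_bbb_yes_raw`.
#'
#' @param predictions output of [classify_permeation()] with a class column.
#' @param class_col name of the class column (default `"chem_class"`).
#' @return a tibble of class summaries; classes with no members are dropped
#'   with a warning.
#' @export
summarize_by_class <- function(predictions, class_col = "chem_class") {
  stopifnot(is.data.frame(predictions),
            all(c("gi_label", "bbb_label") %in% names(predictions)))
  if (!class_col %in% names(predictions)) {
    stop("class column '", class_col, "' not found", call. = FALSE)
  }
  df <- tibble::as_tibble(predictions)
  df$.class <- as.character(df[[class_col]])
  if (any(is.na(df$.class) | !nzchar(df$.class))) {
    warning("compounds with empty class label excluded from class rows",
            call. = FALSE)
  }
  one <- function(d, label, digits) {
    n <- nrow(d)
    n_gi <- sum(d$gi_label == "high", na.rm = TRUE)
    n_bbb <- sum(d$bbb_label == "yes", na.rm = TRUE)
    tibble::tibble(
      chem_class = label, n_total = n, n_gi_high = n_gi,
      pct_gi_high = round(100 * n_gi / n, digits),
      n_bbb_yes = n_bbb,
      pct_bbb_yes = round(100 * n_bbb / n, digits),
      pct_gi_high_raw = 100 * n_gi / n,
      pct_bbb_yes_raw = 100 * n_bbb / n
    )
  }
  keep <- !is.na(df$.class) & nzchar(df$.class)
  per_class <- df[keep, ] |>
    dplyr::group_by(.class) |>
    dplyr::group_map(~ one(.x, .y$.class, digits = 0)) |>
    dplyr::bind_rows()
  dplyr::bind_rows(per_class, one(df, "all", digits = 1))
}

#' Compare descriptor distributions between two predicted groups
#'
#' For each descriptor, compares its distribution between the two groups
#' with the two-sided Student's t test (pooled variance by default; Welch
#' available behind `welch = TRUE` for sensitivity analysis). No
#' multiple-testing correction is applied: each descriptor is tested at the
#' raw p < 0.05 criterion, mirroring the univariate reporting convention of
#' permeation-descriptor tables.
#'
#' @param data data frame holding descriptor columns and a grouping column.
#' @param group_col name of the two-level grouping column (e.g. `gi_label`).
#' @param params descriptor columns to test; defaults to all numeric
#'   descriptor panel columns present.
#' @param welch use the Welch (unequal-variance) t statistic.
#' @param alpha significance criterion (default 0.05).
#' @return a `group_comparison` tibble: one row per parameter with group
#'   means, SDs, sizes, `t`, `p`, and `significant`. Group A is the first
#'   level in sorted order; the `groups` attribute records the order.
#'   Degenerate parameters (zero variance in both groups with equal means)
#'   are reported with `t = 0`, `p = 1` and flagged in `note`.
#' @export
compare_groups <- function(data, group_col, params = NULL, welch = FALSE,
                           alpha = 0.05) {
  stopifnot(is.data.frame(data), group_col %in% names(data))
  g <- as.character(data[[group_col]])
  lv <- sort(unique(g[!is.na(g)]))
  if (length(lv) != 2L) {
    stop("group column must have exactly 2 levels, found ", length(lv),
         call. = FALSE)
  }
  if (is.null(params)) {
    panel <- c("mw", "mv_mean_vdw", "mp_mean_polarizability", "n_heavy",
               "n_aromatic_heavy", "frac_csp3", "n_rotatable", "n_hba",
               "n_hbd", "logs_silicos", "xlogp3", "molar_refractivity",
               "tpsa", "n_NO")
    params <- intersect(panel, names(data))
    params <- params[vapply(data[params], is.numeric, logical(1))]
  }
  rows <- purrr::map_dfr(params, function(p) {
    xa <- data[[p]][g == lv[1] & !is.na(g)]
    xb <- data[[p]][g == lv[2] & !is.na(g)]
    xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
    if (length(xa) < 2L || length(xb) < 2L) {
      stop("parameter '", p, "' needs >= 2 finite values per group",
           call. = FALSE)
    }
    degenerate <- stats::sd(xa) == 0 && stats::sd(xb) == 0 &&
      mean(xa) == mean(xb)
    if (degenerate) {
      tt <- list(statistic = c(t = 0), p.value = 1)
      note <- "zero variance in both groups"
    } else {
      tt <- stats::t.test(xa, xb, var.equal = !welch)
      note <- NA_character_
    }
    tibble::tibble(
      parameter = p,
      mean_A = mean(xa), sd_A = stats::sd(xa), n_A = length(xa),
      mean_B = mean(xb), sd_B = stats::sd(xb), n_B = length(xb),
      t = unname(tt$statistic), p = tt$p.value,
      significant = tt$p.value < alpha,
      note = note
    )
  })
  attr(rows, "groups") <- stats::setNames(lv, c("A", "B"))
  attr(rows, "test") <- if (welch) "Welch t" else "Student t (pooled)"
  attr(rows, "alpha") <- alpha
  class(rows) <- c("group_comparison", class(rows))
  rows
}

#' Compare brain-permeation predictions of parent compounds and their oxons
#'
#' Organophosphorus parents carry a thiophosphoryl (P=S) group that hepatic
#' oxidation converts to phosphoryl (P=O); the resulting "oxon" metabolites
#' are the bioactive anticholinesterase forms, so their brain access matters
#' independently of the parents'. This pairs each parent with its oxon and
#' tabulates both blood-brain-barrier calls.
#'
#' @param parents,oxons outputs of [classify_permeation()]; `id` required.
#' @param pairing data frame with columns `parent_id`, `oxon_id`; every oxon
#'   must be paired (unpaired oxons are an error listing the offenders).
#' @return an `oxon_comparison` object: tibble with one row per pair
#'   (`parent_id`, `parent_bbb`, `oxon_id`, `oxon_bbb`, `flipped`) plus
#'   attributes `pct_oxon_bbb_yes`, `n_parent_bbb_yes`, `n_oxon_bbb_yes`.
#' @export
oxon_comparison <- function(parents, oxons, pairing) {
  stopifnot(is.data.frame(parents), is.data.frame(oxons),
            all(c("parent_id", "oxon_id") %in% names(pairing)))
  unpaired <- setdiff(oxons$id, pairing$oxon_id)
  if (length(unpaired)) {
    stop("unpaired oxon metabolite(s): ", paste(unpaired, collapse = ", "),
         call. = FALSE)
  }
  missing_parent <- setdiff(pairing$parent_id, parents$id)
  if (length(missing_parent)) {
    stop("pairing references unknown parent(s): ",
         paste(missing_parent, collapse = ", "), call. = FALSE)
  }
  tab <- tibble::tibble(
    parent_id = pairing$parent_id,
    parent_bbb = parents$bbb_label[match(pairing$parent_id, parents$id)],
    oxon_id = pairing$oxon_id,
    oxon_bbb = oxons$bbb_label[match(pairing$oxon_id, oxons$id)]
  )
  tab$flipped <- tab$parent_bbb != tab$oxon_bbb
  attr(tab, "n_parent_bbb_yes") <- sum(tab$parent_bbb == "yes")
  attr(tab, "n_oxon_bbb_yes") <- sum(tab$oxon_bbb == "yes")
  attr(tab, "pct_oxon_bbb_yes") <- 100 * mean(tab$oxon_bbb == "yes")
  class(tab) <- c("oxon_comparison", class(tab))
  tab
}
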