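#' Read a compound table from CSV or TSV
#'
#' Expects at least an identifier column, a SMILES column and optionally a
#' chemical-class column, a compound name, a measured fraction absorbed
#' (`measured_fa`) and a `role` column (`parent` / `oxon_metabolite` /
#' `other`). Column names can be remapped with `col_map` for files using a
#' different header layout.
#'
#' Every row is validated: the SMILES must parse to a molecular graph with at
#' least one heavy atom, ids must be unique, and `measured_fa` (when present)
#' must lie in \[0, 1\]. Rows failing validation are never silently dropped:
#' they are removed from the returned table, reported with a warning, and
#' recorded row-by-row in the `rejections` attribute; the `parse_log`
#' attribute carries the accepted/rejected accounting.
#'
#' @param path file path.
#' @param format `"auto"` (default; decided by file extension), `"csv"` or
#'   `"tsv"`.
#' @param col_map optional named character vector mapping standard names to
#'   file column names, e.g. `c(id = "Compound", smiles = "SMILES")`.
#' @return a tibble of validated compounds with attributes `rejections`
#'   (tibble: row, id, reason) and `parse_log` (list: source, rows_in,
#'   rows_accepted, rows_rejected).
#' @export
read_compound_table <- function(path, format = c("auto", "csv", "tsv"),
                                col_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE))
      "tsv" else "csv"
  }
  raw <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (col_map[[std]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[std]]] <- std
      }
    }
  }
  required <- c("id", "smiles")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_compound_table(raw, source = path)
}

# Shared validation: SMILES parse, id uniqueness, measured_fa range.
validate_compound_table <- function(raw, source = "<data.frame>") {
  raw <- tibble::as_tibble(raw)
  n_in <- nrow(raw)
  raw$id <- as.character(raw$id)
  reasons <- rep(NA_character_, n_in)

  dup <- duplicated(raw$id)
  reasons[dup] <- "duplicate id"

  if ("measured_fa" %in% names(raw)) {
    bad_fa <- !is.na(raw$measured_fa) &
      (raw$measured_fa < 0 | raw$measured_fa > 1)
    reasons[bad_fa & is.na(reasons)] <- "measured_fa outside [0, 1]"
  }

  todo <- which(is.na(reasons))
  if (length(todo)) {
    mols <- suppressWarnings(
      mols_from_smiles(as.character(raw$smiles[todo]), ids = raw$id[todo])
    )
    failed <- attr(mols, "failed")
    reasons[todo[raw$id[todo] %in% failed]] <- "SMILES parse failure"
    no_heavy <- names(mols)[vapply(mols, function(m) sum(!m$is_h) < 1L,
                                   logical(1))]
    reasons[todo[raw$id[todo] %in% no_heavy]] <- "no heavy atoms"
  }

  rejected <- which(!is.na(reasons))
  rejections <- tibble::tibble(
    row = rejected,
    id = raw$id[rejected],
    reason = reasons[rejected]
  )
  if (nrow(rejections)) {
    warning(sprintf("%d row(s) rejected: %s", nrow(rejections),
                    paste(sprintf("row %d (%s): %s", rejections$row,
                                  rejections$id, rejections$reason),
                          collapse = "; ")),
            call. = FALSE)
  }
  out <- raw[setdiff(seq_len(n_in), rejected), , drop = FALSE]
  attr(out, "rejections") <- rejections
  attr(out, "parse_log") <- list(
    source = source,
    rows_in = n_in,
    rows_accepted = nrow(out),
    rows_rejected = nrow(rejections)
  )
  out
}

#' Standardize SMILES strings for descriptor computation
#'
#' Applies the package's standardization policy: parse, keep the largest
#' organic fragment of multi-fragment (salt) inputs, preserve formal charges,
#' drop stereochemical annotations (no implemented descriptor is
#' stereo-dependent), and emit OpenBabel canonical SMILES. The operation is
#' idempotent: standardizing a standardized SMILES returns it unchanged.
#'
#' A single covalently bonded unit is always retained whole, charges and all
#' (e.g. a bipyridinium dication is one fragment, not a salt). "Organic"
#' means carbon-containing; when no fragment contains carbon the largest
#' fragment by heavy-atom count is kept.
#'
#' @param smiles character vector of SMILES.
#' @param keep_largest_fragment keep only the largest organic fragment of
#'   multi-fragment inputs (default `TRUE`).
#' @param drop_stereo drop stereo annotations (default `TRUE`).
#' @return character vector of canonical SMILES; `NA` (with a warning) for
#'   inputs that do not parse.
#' @examples
#' standardize_structure("OCC")                  # "CCO"
#' standardize_structure("CC(=O)[O-].[Na+]")     # acetate fragment kept
#' @export
standardize_structure <- function(smiles, keep_largest_fragment = TRUE,
                                  drop_stereo = TRUE) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  for (i in seq_along(smiles)) {
    s <- smiles[i]
    if (is.na(s)) next
    if (drop_stereo) {
      # tetrahedral (@) and cis/trans (/ \) marks are plain annotation
      # characters in SMILES; removing them at text level is exact
      s <- gsub("@", "", s, fixed = TRUE)
      s <- gsub("/", "", s, fixed = TRUE)
      s <- gsub("\\", "", s, fixed = TRUE)
    }
    can <- ob_canonical(s)
    if (is.na(can)) {
      warning("SMILES parse failure: ", smiles[i], call. = FALSE)
      next
    }
    if (keep_largest_fragment && grepl(".", can, fixed = TRUE)) {
      frags <- strsplit(can, ".", fixed = TRUE)[[1]]
      info <- lapply(frags, function(f) {
        m <- suppressWarnings(mols_from_smiles(f))
        if (!length(m)) return(c(0L, 0L))
        el <- m[[1]]$atoms$element
        c(sum(el == "C"), sum(el != "H"))
      })
      has_c <- vapply(info, function(x) x[1] > 0L, logical(1))
      pool <- if (any(has_c)) which(has_c) else seq_along(frags)
      sizes <- vapply(info, function(x) x[2], integer(1))
      keep <- pool[which.max(sizes[pool])]
      can <- ob_canonical(frags[keep])
    }
    out[i] <- can
  }
  out
}

# OpenBabel canonical SMILES of one input (NA if unparseable).
ob_canonical <- function(smiles) {
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = smiles,
                              options = data.frame(names = character(),
                                                   args = character())),
    error = function(e) ""
  )
  txt <- trimws(sub("\t.*$", "", txt))
  if (!nzchar(txt)) NA_character_ else strsplit(txt, "\n")[[1]][1]
}

#' Write per-compound classification results to CSV
#'
#' One row per compound in a fixed, documented column order: `id`, `name`,
#' `chem_class`, the descriptor panel, then `gi_label` and `bbb_label`.
#' Compounds and predictions must align one-to-one on `id`.
#'
#' @param table compound table (needs `id`; `name`/`chem_class` optional).
#' @param predictions result of [classify_permeation()] for the same
#'   compounds.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, predictions, path) {
  stopifnot(is.data.frame(table), is.data.frame(predictions))
  if (!"id" %in% names(predictions)) {
    stop("predictions must carry an 'id' column", call. = FALSE)
  }
  if (nrow(table) != nrow(predictions) ||
      !setequal(table$id, predictions$id)) {
    stop("compounds and predictions are not aligned 1:1 by id",
         call. = FALSE)
  }
  desc_cols <- c("mw", "wlogp", "tpsa", "n_heavy", "n_aromatic_heavy",
                 "n_rotatable", "n_hba", "n_hbd", "frac_csp3",
                 "molar_refractivity", "n_NO", "mv_mean_vdw",
                 "mp_mean_polarizability")
  pred <- predictions[match(table$id, predictions$id), , drop = FALSE]
  out <- tibble::tibble(
    id = table$id,
    name = if ("name" %in% names(table)) table$name else NA_character_,
    chem_class = if ("chem_class" %in% names(table)) table$chem_class
                 else NA_character_
  )
  for (col in desc_cols) {
    out[[col]] <- if (col %in% names(pred)) pred[[col]] else NA
  }
  out$gi_label <- pred$gi_label
  out$bbb_label <- pred$bbb_label
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
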