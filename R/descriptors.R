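#' Compute the physicochemical descriptor panel for a compound table
#'
#' Appends one column per descriptor to `data`, computed from the `smiles`
#' column: molecular weight (`mw`, g/mol), Wildman-Crippen lipophilicity
#' (`wlogp`) and molar refractivity (`molar_refractivity`), Ertl topological
#' polar surface area (`tpsa`, squared angstroms), heavy-atom, aromatic
#' heavy-atom, rotatable-bond, H-bond acceptor/donor and N+O counts, the
#' fraction of sp3 carbons (`frac_csp3`), and carbon-scaled mean atomic
#' van der Waals volume (`mv_mean_vdw`) and polarizability
#' (`mp_mean_polarizability`) surrogates.
#'
#' All descriptors are topological and computed on the hydrogen-completed
#' molecular graph; aromatic and Kekule SMILES of the same structure give
#' identical values. Rows whose SMILES do not parse get `NA` descriptors and
#' a warning.
#'
#' @param data data frame with at least a SMILES column.
#' @param smiles_col name of the SMILES column (default `"smiles"`).
#' @param include_sp logical; include the extended sulfur/phosphorus
#'   contributions in TPSA (default `TRUE`). The choice is recorded in the
#'   `tpsa_include_sp` attribute of the result.
#' @param external optional data frame of externally computed descriptor
#'   columns (e.g. `xlogp3`, `logs_silicos`) keyed by the same `id` column as
#'   `data`; joined onto the result untouched.
#' @return `data` as a tibble with descriptor columns appended.
#' @examples
#' compute_descriptors(data.frame(id = "ethanol", smiles = "CCO"))
#' @export
compute_descriptors <- function(data, smiles_col = "smiles", include_sp = TRUE,
                                external = NULL) {
  stopifnot(is.data.frame(data))
  if (!smiles_col %in% names(data)) {
    stop("column '", smiles_col, "' not found in `data`", call. = FALSE)
  }
  smi <- as.character(data[[smiles_col]])
  ids <- if ("id" %in% names(data)) as.character(data$id) else
    as.character(seq_along(smi))
  mols <- mols_from_smiles(smi, ids = ids)
  desc <- if (length(smi)) {
    purrr::map_dfr(seq_along(smi), function(i) {
      m <- if (ids[i] %in% names(mols)) mols[[ids[i]]] else NULL
      descriptor_row(m, include_sp = include_sp)
    })
  } else {
    descriptor_row(NULL)[0, ]
  }
  out <- dplyr::bind_cols(tibble::as_tibble(data), desc)
  if (!is.null(external)) {
    stopifnot("id" %in% names(external), "id" %in% names(out))
    out <- dplyr::left_join(out, tibble::as_tibble(external), by = "id")
  }
  attr(out, "tpsa_include_sp") <- include_sp
  out
}

descriptor_row <- function(mol, include_sp = TRUE) {
  if (is.null(mol)) {
    return(tibble::tibble(
      mw = NA_real_, wlogp = NA_real_, tpsa = NA_real_,
      n_heavy = NA_integer_, n_aromatic_heavy = NA_integer_,
      n_rotatable = NA_integer_, n_hba = NA_integer_, n_hbd = NA_integer_,
      frac_csp3 = NA_real_, molar_refractivity = NA_real_,
      n_NO = NA_integer_, mv_mean_vdw = NA_real_,
      mp_mean_polarizability = NA_real_
    ))
  }
  lm <- wc_logp_mr(mol)
  ct <- mol_counts(mol)
  tibble::tibble(
    mw = mol_mw(mol),
    wlogp = unname(lm["wlogp"]),
    tpsa = tpsa_mol(mol, include_sp = include_sp),
    n_heavy = as.integer(ct$n_heavy),
    n_aromatic_heavy = as.integer(ct$n_aromatic_heavy),
    n_rotatable = as.integer(ct$n_rotatable),
    n_hba = as.integer(ct$n_hba),
    n_hbd = as.integer(ct$n_hbd),
    frac_csp3 = ct$frac_csp3,
    molar_refractivity = unname(lm["mr"]),
    n_NO = as.integer(ct$n_NO),
    mv_mean_vdw = mol_mean_atomic(mol, VDW_SCALED),
    mp_mean_polarizability = mol_mean_atomic(mol, POLARIZABILITY_SCALED)
  )
}

#' Descriptor panel for a single SMILES string
#'
#' Convenience wrapper around [compute_descriptors()] for one molecule.
#'
#' @param smiles a single SMILES string.
#' @inheritParams compute_descriptors
#' @return a one-row tibble of descriptors.
#' @export
descriptor_vector <- function(smiles, include_sp = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  compute_descriptors(tibble::tibble(id = "x", smiles = smiles),
                      include_sp = include_sp)[, -(1:2)]
}
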