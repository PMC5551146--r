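# Count-type descriptors, molecular weight, and the carbon-scaled mean
# atomic property surrogates.

# IUPAC 2021 standard atomic weights (abridged).
ATOMIC_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845, Cu = 63.546,
  Zn = 65.38, As = 74.922, Se = 78.971, Br = 79.904, Sn = 118.71, I = 126.904,
  Hg = 200.59, Li = 6.94, Rb = 85.468, Cs = 132.905
)

# Atomic van der Waals volumes scaled to carbon = 1 (from Bondi radii,
# volume ratio r^3 / r_C^3) and static dipole polarizabilities scaled to
# carbon = 1 (CRC values in cubic angstroms / 1.76). These are documented
# surrogates for the corresponding whole-molecule averages of commercial
# descriptor software; they follow the same carbon-scaling convention but
# are not bit-compatible with it.
VDW_SCALED <- local({
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
         S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, Si = 2.10, B = 1.92,
         Se = 1.90, As = 1.85, Na = 2.27, K = 2.75, Li = 1.82)
  (r / r[["C"]])^3
})
POLARIZABILITY_SCALED <- local({
  p <- c(H = 0.667, C = 1.760, N = 1.100, O = 0.802, F = 0.557, P = 3.630,
         S = 2.900, Cl = 2.180, Br = 3.050, I = 5.350, Si = 5.380, B = 3.030,
         Se = 3.770, As = 4.310, Na = 24.11, K = 43.40, Li = 24.33)
  p / p[["C"]]
})

mol_mw <- function(mol) {
  m <- ATOMIC_MASS[mol$atoms$element]
  if (anyNA(m)) {
    warning("element(s) without tabulated atomic mass skipped: ",
            paste(unique(mol$atoms$element[is.na(m)]), collapse = ", "),
            call. = FALSE)
    m <- m[!is.na(m)]
  }
  sum(m)
}

mol_mean_atomic <- function(mol, table) {
  v <- table[mol$atoms$element]
  if (all(is.na(v))) return(NA_real_)
  if (anyNA(v)) {
    warning("element(s) without tabulated atomic constant excluded from ",
            "mean: ", paste(unique(mol$atoms$element[is.na(v)]),
                            collapse = ", "),
            call. = FALSE)
  }
  mean(v, na.rm = TRUE)
}

# sp3 carbon: non-aromatic carbon whose bonds are all single
is_sp3_carbon <- function(mol, i) {
  mol$atoms$element[i] == "C" && !mol$aromatic[i] &&
    all(mol$btype[[i]] %in% c("1", "am", "du", "un"))
}

#' Count descriptors of a parsed molecule
#'
#' Definitions (fixed, documented):
#' * `n_rotatable`: single, acyclic bonds between two heavy atoms that each
#'   carry at least one further heavy neighbour; amide C-N bonds excluded.
#' * `n_hbd`: hydrogens borne by nitrogen or oxygen.
#' * `n_hba`: nitrogen or oxygen atoms with an available lone pair, i.e.
#'   excluding pyrrole-type aromatic nitrogen (three sigma connections) and
#'   amide/sulfonamide-type nitrogen.
#' * `frac_csp3`: sp3 carbons / total carbons (0 when the molecule has no
#'   carbon).
#' @keywords internal
#' @noRd
mol_counts <- function(mol) {
  heavy <- which(!mol$is_h)
  el <- mol$atoms$element
  n_heavy <- length(heavy)
  n_aromatic_heavy <- sum(mol$aromatic[heavy])
  n_NO <- sum(el[heavy] %in% c("N", "O"))

  carbons <- heavy[el[heavy] == "C"]
  frac_csp3 <- if (length(carbons)) {
    sum(vapply(carbons, function(i) is_sp3_carbon(mol, i), logical(1))) /
      length(carbons)
  } else 0

  n_hbd <- sum(mol$n_h[heavy][el[heavy] %in% c("N", "O")])

  n_hba <- sum(vapply(heavy, function(i) {
    e <- el[i]
    if (!(e %in% c("N", "O"))) return(FALSE)
    if (e == "N") {
      if (mol$aromatic[i] && (mol$deg_heavy[i] + mol$n_h[i]) >= 3L)
        return(FALSE)                       # pyrrole-type nitrogen
      hn <- heavy_nbrs(mol, i)
      amide <- any(vapply(hn, function(y) {
        if (el[y] != "C" && el[y] != "S") return(FALSE)
        yo <- heavy_orders(mol, y)
        ye <- el[heavy_nbrs(mol, y)]
        any(abs(yo - 2) < 1e-9 & ye == "O")
      }, logical(1)))
      if (amide) return(FALSE)              # amide / sulfonamide nitrogen
    }
    TRUE
  }, logical(1)))

  # rotatable bonds
  n_rot <- 0L
  bd <- mol$bonds
  for (k in seq_len(nrow(bd))) {
    if (bd$ring[k] || !(bd$type[k] %in% c("1", "am"))) next
    i <- bd$a1[k]; j <- bd$a2[k]
    if (mol$is_h[i] || mol$is_h[j]) next
    if (mol$deg_heavy[i] < 2L || mol$deg_heavy[j] < 2L) next
    if (is_amide_cn(mol, i, j) || is_amide_cn(mol, j, i)) next
    n_rot <- n_rot + 1L
  }

  list(n_heavy = n_heavy, n_aromatic_heavy = n_aromatic_heavy,
       n_rotatable = n_rot, n_hba = n_hba, n_hbd = n_hbd, n_NO = n_NO,
       frac_csp3 = frac_csp3)
}

# is the bond c(i)-n(j) an amide C-N (carbon doubly bonded to O)?
is_amide_cn <- function(mol, ci, nj) {
  el <- mol$atoms$element
  if (el[ci] != "C" || el[nj] != "N") return(FALSE)
  ho <- heavy_orders(mol, ci)
  he <- el[heavy_nbrs(mol, ci)]
  any(abs(ho - 2) < 1e-9 & he == "O")
}
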