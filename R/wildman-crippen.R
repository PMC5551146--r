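# Wildman-Crippen atom-contribution lipophilicity (WLogP) and molar
# refractivity (MR).
#
# Every atom (hydrogens included) is assigned one of the published atom
# classes; WLogP and MR are the sums of the class contributions. The class
# definitions below are a procedural translation of the published typing
# table (Wildman & Crippen 1999): carbon classes C1-C27 + fallback CS,
# hydrogen H1-H4 + HS, nitrogen N1-N14 + NS, oxygen O1-O12 + OS, halogens,
# P, S1-S3 and two metal classes. An atom that matches no specific class
# falls to its element's wildcard class, as the method prescribes.

WC_LOGP <- c(
  C1 = 0.1441,  C2 = 0.0000,  C3 = -0.2035, C4 = -0.2051, C5 = -0.2783,
  C6 = 0.1551,  C7 = 0.0017,  C8 = 0.08452, C9 = -0.1444, C10 = -0.0516,
  C11 = 0.1193, C12 = -0.0967, C13 = -0.5443, C14 = 0.0000, C15 = 0.2450,
  C16 = 0.1980, C17 = 0.0000, C18 = 0.1581, C19 = 0.2955, C20 = 0.2713,
  C21 = 0.1360, C22 = 0.4619, C23 = 0.5437, C24 = 0.1893, C25 = -0.8186,
  C26 = 0.2640, C27 = 0.2148, CS = 0.08129,
  H1 = 0.1230,  H2 = -0.2677, H3 = 0.2142,  H4 = 0.2980,  HS = 0.1125,
  N1 = -1.0190, N2 = -0.7096, N3 = -1.0270, N4 = -0.5188, N5 = 0.08387,
  N6 = 0.1836,  N7 = -0.3187, N8 = -0.4458, N9 = 0.01508, N10 = -1.950,
  N11 = -0.3239, N12 = -1.119, N13 = -0.3396, N14 = 0.2887, NS = -0.4806,
  O1 = 0.1552,  O2 = -0.2893, O3 = -0.0684, O4 = -0.4195, O5 = 0.0335,
  O6 = -0.3339, O7 = -1.189,  O8 = 0.1788,  O9 = -0.1526, O10 = 0.1129,
  O11 = 0.4833, O12 = -1.326, OS = -0.1188,
  F = 0.4202,   Cl = 0.6895,  Br = 0.8456,  I = 0.8857,   Hal = -2.996,
  P = 0.8612,   S1 = 0.6482,  S2 = -0.0024, S3 = 0.6237,
  Me1 = -0.3808, Me2 = -0.0025
)

WC_MR <- c(
  C1 = 2.503,  C2 = 2.433,  C3 = 2.753,  C4 = 2.731,  C5 = 5.007,
  C6 = 3.513,  C7 = 3.888,  C8 = 2.464,  C9 = 2.412,  C10 = 2.488,
  C11 = 2.582, C12 = 2.576, C13 = 4.041, C14 = 3.257, C15 = 3.564,
  C16 = 3.180, C17 = 3.104, C18 = 3.350, C19 = 4.346, C20 = 3.904,
  C21 = 3.509, C22 = 4.067, C23 = 3.853, C24 = 2.673, C25 = 3.135,
  C26 = 4.305, C27 = 2.693, CS = 3.243,
  H1 = 1.057,  H2 = 1.395,  H3 = 0.9627, H4 = 1.805,  HS = 1.112,
  N1 = 2.262,  N2 = 2.173,  N3 = 2.827,  N4 = 3.000,  N5 = 1.757,
  N6 = 2.428,  N7 = 1.839,  N8 = 2.819,  N9 = 1.725,  N10 = 0,
  N11 = 2.202, N12 = 0,     N13 = 0.2604, N14 = 3.359, NS = 2.134,
  O1 = 1.080,  O2 = 0.8238, O3 = 1.085,  O4 = 1.182,  O5 = 3.367,
  O6 = 0.7774, O7 = 0.000,  O8 = 3.135,  O9 = 0.000,  O10 = 0.2215,
  O11 = 0.3890, O12 = 0,    OS = 0.6865,
  F = 1.108,   Cl = 5.853,  Br = 8.927,  I = 14.02,   Hal = 0,
  P = 6.920,   S1 = 7.591,  S2 = 7.365,  S3 = 6.691,
  Me1 = 5.754, Me2 = 0
)

HALOGENS <- c("F", "Cl", "Br", "I")
WC_HET_ALI <- c("N", "O", "P", "S", HALOGENS)
ALKALI <- c("Li", "Na", "K", "Rb", "Cs")

# Assign the Wildman-Crippen class of every atom in a parsed molecule.
# Returns a character vector of class labels, length = number of atoms.
wc_atom_types <- function(mol) {
  vapply(seq_len(mol$n_atoms), function(i) wc_type_one(mol, i), character(1))
}

wc_type_one <- function(mol, i) {
  el <- mol$atoms$element[i]
  switch(el,
    "C" = wc_type_carbon(mol, i),
    "H" = wc_type_hydrogen(mol, i),
    "N" = wc_type_nitrogen(mol, i),
    "O" = wc_type_oxygen(mol, i),
    "S" = if (mol$aromatic[i]) "S3"
          else if (mol$atoms$fcharge[i] != 0L || has_order(mol, i, 2)) "S2"
          else "S1",
    "P" = "P",
    "F" = if (mol$atoms$fcharge[i] == 0L) "F" else "Hal",
    "Cl" = if (mol$atoms$fcharge[i] == 0L) "Cl" else "Hal",
    "Br" = if (mol$atoms$fcharge[i] == 0L) "Br" else "Hal",
    "I" = if (mol$atoms$fcharge[i] == 0L) "I" else "Hal",
    if (el %in% ALKALI && mol$atoms$fcharge[i] > 0L) "Hal" else "Me1"
  )
}

wc_type_carbon <- function(mol, i) {
  hn <- heavy_nbrs(mol, i)
  ho <- heavy_orders(mol, i)
  nh <- mol$n_h[i]
  nel <- mol$atoms$element[hn]
  naro <- mol$aromatic[hn]

  if (mol$aromatic[i]) {
    if (nh >= 1L) return("C18")
    sub <- which(ho != 1.5)          # non-aromatic bonds out of the ring atom
    if (!length(sub)) return("C19")  # ring-fusion carbon, three aromatic bonds
    dbl <- sub[abs(ho[sub] - 2) < 1e-9]
    if (length(dbl) && any(nel[dbl] %in% c("C", "N", "O")))
      return("C25")                  # exocyclic double bond
    sng <- sub[abs(ho[sub] - 1) < 1e-9]
    if (length(sng)) {
      e <- nel[sng]; a <- naro[sng]
      if (any(!a & !(e %in% c("C", "N", "O", "S", HALOGENS)))) return("C13")
      if (any(e == "F" & !a))  return("C14")
      if (any(e == "Cl" & !a)) return("C15")
      if (any(e == "Br" & !a)) return("C16")
      if (any(e == "I" & !a))  return("C17")
      if (any(a))              return("C20")
      if (any(e == "C"))       return("C21")
      if (any(e == "N"))       return("C22")
      if (any(e == "O"))       return("C23")
      if (any(e == "S"))       return("C24")
      return("C13")
    }
    return("CS")
  }

  # mol2 carboxylate bonds (order 1.5 outside rings) are chemically one
  # double + one single bond: give the carbon its carbonyl character
  co2 <- !mol$aromatic[i] & abs(ho - 1.5) < 1e-9 & nel == "O"
  if (any(co2)) ho[which(co2)[1]] <- 2
  has_dbl <- any(abs(ho - 2) < 1e-9)
  has_trp <- any(abs(ho - 3) < 1e-9)
  if (!has_dbl && !has_trp) {
    # sp3 carbon: aromatic attachment outranks aliphatic-heteroatom attachment
    if (any(naro)) {
      if (nh >= 3L) {
        return(if (any(naro & nel == "C")) "C8" else "C9")
      }
      return(c("C12", "C11", "C10")[min(nh, 2L) + 1L])
    }
    het_ali <- any(nel %in% WC_HET_ALI)
    if (het_ali) return(if (nh >= 2L) "C3" else "C4")
    other <- any(!(nel %in% c("C", WC_HET_ALI)))
    if (other) return("C27")
    return(if (nh >= 2L) "C1" else "C2")
  }
  dbl <- which(abs(ho - 2) < 1e-9)
  if (any(!naro[dbl] & !(nel[dbl] %in% c("C", "H")))) return("C5")
  if (has_trp) return("C7")
  # double bond(s) to carbon
  if (any(naro[dbl])) return("C26")            # [C]=c
  if (any(naro)) return("C26")                 # vinyl bearing aromatic subst.
  return("C6")
}

wc_type_hydrogen <- function(mol, i) {
  nb <- mol$nbr[[i]]
  if (!length(nb)) return("HS")
  x <- nb[1]
  el <- mol$atoms$element[x]
  if (el %in% c("C", "H")) return("H1")
  if (el == "N") return("H3")
  if (el == "O") {
    yy <- setdiff(mol$nbr[[x]], i)
    yy <- yy[!mol$is_h[yy]]
    if (!length(yy)) return("H2")               # water / bare hydroxide
    ye <- mol$atoms$element[yy]
    ya <- mol$aromatic[yy]
    sp3c <- vapply(yy, function(y) {
      mol$atoms$element[y] == "C" && !mol$aromatic[y] &&
        all(abs(mol$border[[y]] - 1) < 1e-9 | mol$btype[[y]] == "am")
    }, logical(1))
    if (any(sp3c) || any(ya & ye == "C")) return("H2")  # alcohol / phenol
    if (any(!(ye %in% c("C", "N", "O", "S")))) return("H2")  # e.g. H-O-P
    if (any(ye == "N")) return("H3")
    enol <- vapply(yy, function(y) {
      if (mol$atoms$element[y] != "C") return(FALSE)
      ho <- heavy_orders(mol, y)
      he <- mol$atoms$element[heavy_nbrs(mol, y)]
      any(abs(ho - 2) < 1e-9 & he %in% c("C", "N", "O", "S"))
    }, logical(1))
    if (any(enol) || any(ye %in% c("O", "S"))) return("H4")
    return("HS")
  }
  "H2"  # H on S, P, Si, ...
}

wc_type_nitrogen <- function(mol, i) {
  chg <- mol$atoms$fcharge[i]
  if (mol$aromatic[i]) return(if (chg > 0L) "N12" else "N11")
  hn <- heavy_nbrs(mol, i)
  ho <- heavy_orders(mol, i)
  nh <- mol$n_h[i]
  naro <- mol$aromatic[hn]
  has_trp <- any(abs(ho - 3) < 1e-9)
  if (chg < 0L) return("N14")
  if (chg > 0L) {
    if (has_trp) return("N14")
    if (nh >= 1L) return("N10")
    return("N13")
  }
  if (has_trp) return("N9")
  if (any(abs(ho - 2) < 1e-9)) {
    if (nh >= 1L) return("N5")
    return("N6")
  }
  if (nh >= 2L) return(if (any(naro)) "N3" else "N1")
  if (nh == 1L) return(if (any(naro)) "N4" else "N2")
  if (length(hn)) return(if (any(naro)) "N8" else "N7")
  "NS"
}

wc_type_oxygen <- function(mol, i) {
  if (mol$aromatic[i]) return("O1")
  chg <- mol$atoms$fcharge[i]
  hn <- heavy_nbrs(mol, i)
  ho <- heavy_orders(mol, i)
  nel <- mol$atoms$element[hn]
  naro <- mol$aromatic[hn]
  nh <- mol$n_h[i]
  if (chg < 0L) {
    if (any(nel == "N")) return("O5")
    if (any(nel == "S")) return("O6")
    carboxylate <- any(vapply(seq_along(hn), function(k) {
      y <- hn[k]
      if (nel[k] != "C") return(FALSE)
      yo <- heavy_orders(mol, y)
      ye <- mol$atoms$element[heavy_nbrs(mol, y)]
      any(abs(yo - 2) < 1e-9 & ye == "O") ||
        sum(ye == "O" & abs(yo - 1.5) < 1e-9) >= 2  # mol2 O.co2 form
    }, logical(1)))
    if (carboxylate) return("O12")
    return("O7")
  }
  dbl <- which(abs(ho - 2) < 1e-9)
  if (!length(dbl) && mol$atoms$sybyl[i] == "O.co2") {
    # neutral partner of a mol2 carboxylate: treat as the carbonyl oxygen
    dbl <- which(abs(ho - 1.5) < 1e-9 & nel == "C")
  }
  if (length(dbl)) {
    y <- hn[dbl[1]]
    ye <- nel[dbl[1]]
    if (ye %in% c("N", "O")) return("O5")
    if (ye == "S") return("O6")
    if (mol$aromatic[y]) return("O8")
    if (ye == "C") {
      rest <- setdiff(heavy_nbrs(mol, y), i)
      re <- mol$atoms$element[rest]
      ra <- mol$aromatic[rest]
      if (length(rest) == 2L && all(!(re %in% c("C", "H")))) return("O11")
      if (any(ra)) return("O10")
      return("O9")
    }
    return("OS")  # O=P and other exotics fall to the wildcard class
  }
  if (nh >= 1L) return("O2")
  if (length(hn) >= 2L) return(if (any(naro)) "O4" else "O3")
  "OS"
}

#' Wildman-Crippen WLogP and molar refractivity of a parsed molecule
#' @keywords internal
#' @noRd
wc_logp_mr <- function(mol) {
  ty <- wc_atom_types(mol)
  c(wlogp = sum(WC_LOGP[ty]), mr = sum(WC_MR[ty]))
}
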