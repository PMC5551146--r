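# Internal molecular-graph backend.
#
# SMILES are parsed by OpenBabel (through ChemmineOB): it performs valence and
# implicit-hydrogen perception, aromaticity assignment and formal-charge
# bookkeeping. The result is converted to MOL2 with explicit hydrogens and
# re-read here into a light adjacency structure that the descriptor engines
# consume. Nothing downstream touches SMILES text again.

MOL2_OPTS <- data.frame(names = "h", args = "")

#' Convert SMILES strings to parsed molecular graphs
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional identifiers (defaults to positional ids); used to track
#'   which inputs failed to parse.
#' @return a named list with one entry per *successfully parsed* input: each a
#'   `mol` object (see [mol_graph()]); failed inputs are reported in the
#'   `failed` attribute (character vector of ids) and raise a warning.
#' @keywords internal
#' @noRd
mols_from_smiles <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (is.null(ids)) ids <- paste0("m", seq_len(n))
  ids <- as.character(ids)
  if (n == 0L) {
    out <- list()
    attr(out, "failed") <- character()
    return(out)
  }
  # internal alignment keys: mol2 titles survive the round trip
  keys <- paste0("bek", seq_len(n))
  convert <- function(idx) {
    src <- paste(paste(smiles[idx], keys[idx]), collapse = "\n")
    tryCatch(
      ChemmineOB::convertFormat("SMI", "MOL2", source = src, options = MOL2_OPTS),
      error = function(e) ""
    )
  }
  blocks <- parse_mol2_blocks(convert(seq_len(n)))
  out <- vector("list", n)
  ok <- logical(n)
  take <- function(blocks) {
    got <- vapply(blocks, function(b) b$title, character(1))
    for (j in seq_along(blocks)) {
      i <- match(got[j], keys)
      if (!is.na(i) && blocks[[j]]$n_atoms > 0L) {
        m <- mol_graph(blocks[[j]])
        m$id <- ids[i]
        out[[i]] <<- m
        ok[i] <<- TRUE
      }
    }
  }
  take(blocks)
  # OpenBabel's SMILES stream reader stops at the first invalid line, so any
  # molecules after a bad input are retried one-by-one before being declared
  # unparseable.
  if (any(!ok)) for (i in which(!ok)) take(parse_mol2_blocks(convert(i)))
  failed <- ids[!ok]
  if (length(failed)) {
    warning(sprintf("SMILES parse failure for %d input(s): %s",
                    length(failed), paste(failed, collapse = ", ")),
            call. = FALSE)
  }
  out <- out[ok]
  names(out) <- ids[ok]
  attr(out, "failed") <- failed
  out
}

# Split concatenated MOL2 text into per-molecule records.
parse_mol2_blocks <- function(txt) {
  if (!nzchar(txt)) return(list())
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(starts)) return(list())
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    parse_mol2_one(lines[starts[k]:ends[k]])
  })
}

parse_mol2_one <- function(lines) {
  title <- trimws(lines[2])
  sec <- function(tag) {
    i <- grep(paste0("^@<TRIPOS>", tag, "$"), lines)
    if (!length(i)) return(character())
    j <- grep("^@<TRIPOS>", lines)
    nxt <- j[j > i[1]]
    end <- if (length(nxt)) nxt[1] - 1L else length(lines)
    if (i[1] + 1L > end) return(character())
    out <- lines[(i[1] + 1L):end]
    out[nzchar(trimws(out))]
  }
  at <- sec("ATOM")
  bd <- sec("BOND")
  n_atoms <- length(at)
  atoms <- NULL
  bonds <- NULL
  if (n_atoms) {
    f <- strsplit(trimws(at), "[[:space:]]+")
    atoms <- data.frame(
      idx = as.integer(vapply(f, `[`, "", 1L)),
      sybyl = vapply(f, `[`, "", 6L),
      frag = as.integer(vapply(f, `[`, "", 7L)),
      stringsAsFactors = FALSE
    )
    atoms$element <- toupper(sub("\\..*$", "", atoms$sybyl))
    atoms$fcharge <- 0L
  }
  if (length(bd)) {
    f <- strsplit(trimws(bd), "[[:space:]]+")
    bonds <- data.frame(
      a1 = as.integer(vapply(f, `[`, "", 2L)),
      a2 = as.integer(vapply(f, `[`, "", 3L)),
      type = vapply(f, `[`, "", 4L),
      stringsAsFactors = FALSE
    )
  } else {
    bonds <- data.frame(a1 = integer(), a2 = integer(), type = character(),
                        stringsAsFactors = FALSE)
  }
  # formal charges live in the UNITY_ATOM_ATTR section
  ua <- sec("UNITY_ATOM_ATTR")
  if (length(ua) && !is.null(atoms)) {
    k <- 1L
    while (k <= length(ua)) {
      hd <- strsplit(trimws(ua[k]), "[[:space:]]+")[[1]]
      aid <- as.integer(hd[1]); nattr <- as.integer(hd[2])
      for (q in seq_len(nattr)) {
        kv <- strsplit(trimws(ua[k + q]), "[[:space:]]+")[[1]]
        if (kv[1] == "charge") atoms$fcharge[atoms$idx == aid] <- as.integer(kv[2])
      }
      k <- k + 1L + nattr
    }
  }
  list(title = title, n_atoms = n_atoms, atoms = atoms, bonds = bonds)
}

# Standard element symbols recognised downstream (normalised capitalisation).
normalize_element <- function(el) {
  two <- c("CL", "BR", "NA", "SI", "SE", "LI", "MG", "CA", "ZN", "FE", "CU",
           "MN", "HG", "SN", "AS", "AL")
  ifelse(el %in% two, paste0(substr(el, 1, 1), tolower(substr(el, 2, 2))), el)
}

#' Build the annotated graph used by the descriptor engines
#'
#' Adds, per atom: element, formal charge, attached-H count, heavy degree,
#' aromatic flag, ring membership, 3-ring membership; per bond: numeric order
#' (aromatic = 1.5, amide = 1) and ring flag.
#' @keywords internal
#' @noRd
mol_graph <- function(block) {
  atoms <- block$atoms
  bonds <- block$bonds
  n <- nrow(atoms)
  atoms$element <- normalize_element(atoms$element)
  ord <- c("1" = 1, "2" = 2, "3" = 3, "ar" = 1.5, "am" = 1, "du" = 1, "un" = 1)
  bonds$order <- unname(ord[bonds$type])
  bonds$order[is.na(bonds$order)] <- 1

  nbr <- vector("list", n)
  border <- vector("list", n)
  btype <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$a1[k]; j <- bonds$a2[k]
    nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
    border[[i]] <- c(border[[i]], bonds$order[k])
    border[[j]] <- c(border[[j]], bonds$order[k])
    btype[[i]] <- c(btype[[i]], bonds$type[k])
    btype[[j]] <- c(btype[[j]], bonds$type[k])
  }

  is_h <- atoms$element == "H"
  n_h <- vapply(seq_len(n), function(i) sum(is_h[nbr[[i]]]), integer(1))
  deg_heavy <- vapply(seq_len(n), function(i) sum(!is_h[nbr[[i]]]), integer(1))

  # ring bonds: edges that are not bridges of their component
  ring_bond <- rep(FALSE, nrow(bonds))
  if (nrow(bonds)) {
    g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a1", "a2")]),
                                     directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    br <- igraph::bridges(g)
    ring_bond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  }
  bonds$ring <- ring_bond
  in_ring <- rep(FALSE, n)
  if (any(ring_bond)) {
    in_ring[unique(c(bonds$a1[ring_bond], bonds$a2[ring_bond]))] <- TRUE
  }

  # aromatic atom: >= 2 aromatic ring bonds (excludes mol2's carboxylate 'ar')
  n_ar_ring <- vapply(seq_len(n), function(i) {
    if (!length(btype[[i]])) return(0L)
    w <- which(btype[[i]] == "ar")
    if (!length(w)) return(0L)
    sum(vapply(w, function(q) {
      j <- nbr[[i]][q]
      any(bonds$ring & ((bonds$a1 == i & bonds$a2 == j) |
                          (bonds$a1 == j & bonds$a2 == i)))
    }, logical(1)))
  }, integer(1))
  aromatic <- n_ar_ring >= 2L & in_ring

  # 3-membered-ring membership (two neighbours mutually bonded)
  adj <- matrix(FALSE, n, n)
  if (nrow(bonds)) {
    adj[cbind(bonds$a1, bonds$a2)] <- TRUE
    adj[cbind(bonds$a2, bonds$a1)] <- TRUE
  }
  in_3ring <- vapply(seq_len(n), function(i) {
    nb <- nbr[[i]]
    if (length(nb) < 2) return(FALSE)
    cmb <- utils::combn(nb, 2)
    any(adj[t(cmb)])
  }, logical(1))

  structure(list(
    id = block$title,
    n_atoms = n,
    atoms = atoms,
    bonds = bonds,
    nbr = nbr,
    border = border,
    btype = btype,
    is_h = is_h,
    n_h = n_h,
    deg_heavy = deg_heavy,
    aromatic = aromatic,
    in_ring = in_ring,
    in_3ring = in_3ring
  ), class = "bemol")
}

# ---- small per-atom helpers used by the typing engines ----

# heavy neighbours of atom i
heavy_nbrs <- function(mol, i) {
  nb <- mol$nbr[[i]]
  nb[!mol$is_h[nb]]
}

# numeric orders of bonds from i to its heavy neighbours (aligned)
heavy_orders <- function(mol, i) {
  nb <- mol$nbr[[i]]
  mol$border[[i]][!mol$is_h[nb]]
}

# does atom i have a bond of given numeric order to any heavy atom?
has_order <- function(mol, i, o) {
  any(abs(heavy_orders(mol, i) - o) < 1e-9)
}
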