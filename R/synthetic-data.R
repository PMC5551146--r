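# Ground-truth-bearing synthetic inputs.
#
# Two generators make every pipeline stage testable without any external
# compound list: a descriptor-space point cloud with known ellipse-region
# membership, and a small SMILES library assembled from a valence-safe
# fragment grammar that mimics the corpus structure (chemical classes,
# parent/oxon pairs). Both are driven by one seeded RNG and are
# byte-reproducible for a fixed seed.

#' Generate a descriptor-space cloud with known region membership
#'
#' Rejection-samples (tPSA, WLogP) points whose true membership in the four
#' regions of the two-ellipse model — inside both ellipses, intestinal-only,
#' brain-only, outside both — matches the requested counts exactly. Each
#' point carries its ground-truth labels, so a classifier run on the cloud
#' must recover them perfectly; any disagreement is a classifier defect.
#'
#' Points are proposed from Gaussians centered on the relevant ellipse
#' (dispersion controlled by `jitter`) or uniformly over a bounding box for
#' the outside region, then accepted or rejected by the exact membership
#' test. The brain-only region of the default geometry is a thin sliver
#' (the brain ellipse pokes just past the intestinal one at negative tPSA),
#' so requesting many brain-only points is slow and may be declared
#' infeasible; such points are geometric test points, not chemically
#' meaningful descriptor values.
#'
#' @param n_inside_both,n_intestinal_only,n_brain_only,n_outside region
#'   counts.
#' @param model an `egg_model`.
#' @param seed integer seed; identical seed and spec give identical output.
#' @param jitter dispersion of the Gaussian proposals, as a multiple of the
#'   ellipse semi-axes (default 1).
#' @param max_proposals proposal budget per requested point before the
#'   region is declared infeasible.
#' @return tibble with `id`, `tpsa`, `wlogp`, `region`, and the ground-truth
#'   `gi_true` / `bbb_true` labels.
#' @export
generate_descriptor_cloud <- function(n_inside_both = 25L,
                                      n_intestinal_only = 25L,
                                      n_brain_only = 0L,
                                      n_outside = 25L,
                                      model = boiled_egg_model(),
                                      seed = 1L,
                                      jitter = 1,
                                      max_proposals = 20000L) {
  counts <- c(inside_both = n_inside_both, intestinal_only = n_intestinal_only,
              brain_only = n_brain_only, outside = n_outside)
  stopifnot(all(counts >= 0L), jitter > 0)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  gi_e <- model$intestinal
  bb_e <- model$brain
  inc <- attr(model, "boundary_inclusive")
  member <- function(x, y) {
    c(gi = point_in_ellipse(x, y, gi_e, inc),
      bbb = point_in_ellipse(x, y, bb_e, inc))
  }
  want <- list(
    inside_both = c(TRUE, TRUE),
    intestinal_only = c(TRUE, FALSE),
    brain_only = c(FALSE, TRUE),
    outside = c(FALSE, FALSE)
  )
  box_x <- c(gi_e$center_tpsa - 2.2 * gi_e$semi_axis_tpsa,
             gi_e$center_tpsa + 2.2 * gi_e$semi_axis_tpsa)
  box_y <- c(gi_e$center_wlogp - 2.2 * gi_e$semi_axis_wlogp,
             gi_e$center_wlogp + 2.2 * gi_e$semi_axis_wlogp)

  propose <- function(region) {
    if (region == "inside_both" || region == "brain_only") {
      c(stats::rnorm(1, bb_e$center_tpsa, jitter * bb_e$semi_axis_tpsa),
        stats::rnorm(1, bb_e$center_wlogp, jitter * bb_e$semi_axis_wlogp))
    } else if (region == "intestinal_only") {
      c(stats::rnorm(1, gi_e$center_tpsa, jitter * gi_e$semi_axis_tpsa),
        stats::rnorm(1, gi_e$center_wlogp, jitter * gi_e$semi_axis_wlogp))
    } else {
      c(stats::runif(1, box_x[1], box_x[2]),
        stats::runif(1, box_y[1], box_y[2]))
    }
  }

  out <- vector("list", sum(counts))
  k <- 0L
  for (region in names(counts)) {
    need <- counts[[region]]
    if (need == 0L) next
    target <- want[[region]]
    got <- 0L
    tries <- 0L
    budget <- max_proposals * need
    while (got < need) {
      tries <- tries + 1L
      if (tries > budget) {
        stop("region '", region, "' infeasible: ", got, "/", need,
             " points found after ", budget, " proposals", call. = FALSE)
      }
      p <- propose(region)
      m <- member(p[1], p[2])
      if (identical(unname(m), target)) {
        got <- got + 1L
        k <- k + 1L
        out[[k]] <- tibble::tibble(
          id = sprintf("%s_%03d", region, got),
          tpsa = p[1], wlogp = p[2], region = region,
          gi_true = if (target[1]) "high" else "low",
          bbb_true = if (target[2]) "yes" else "no"
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

# run code under a private RNG state; returns the restore function
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# ---- fragment grammar ----

SYN_ALKYL <- c("C", "CC", "CCC", "C(C)C", "CC(C)C", "CCCC")
SYN_RING_SUB <- c("Cl", "Cl", "F", "C", "OC", "[N+](=O)[O-]")

syn_ring <- function(subs) {
  # benzene core in Kekule form with up to 3 substituents
  pos <- c("", "", "")
  pos[seq_along(subs)] <- subs
  br <- function(s) if (nzchar(s)) paste0("(", s, ")") else ""
  paste0("C1=CC", br(pos[1]), "=CC", br(pos[2]), "=C1", br(pos[3]))
}

syn_pick <- function(x, n = 1L) x[sample.int(length(x), n, replace = TRUE)]

#' Generate a synthetic compound library from a fragment grammar
#'
#' Assembles valence-valid SMILES from curated fragments — halogenated
#' rings, phosphorothioate/phosphate heads, carbamate and triazine cores —
#' tagged with synthetic class labels, plus a few organophosphorus
#' parent/oxon pairs (P=S to P=O substitution). Structures are returned in
#' canonical form, so they pass [standardize_structure()] unchanged. The
#' `kekule_smiles` column keeps the raw Kekule-form grammar output of the
#' same structure for dialect-invariance testing.
#'
#' @param n number of compounds (>= 1), counting each oxon as one compound.
#' @param seed integer seed.
#' @param class_counts optional named integer vector fixing how many
#'   members of each class to generate (names among `organochlorine`,
#'   `organophosphorus`, `carbamate`, `triazine`, `miscellaneous`);
#'   remaining compounds are spread over all classes.
#' @param n_oxon_pairs number of organophosphorus parent/oxon pairs to
#'   include (each pair contributes 2 compounds within `n`).
#' @return tibble: `id`, `name`, `chem_class`, `smiles` (canonical),
#'   `kekule_smiles`, `role` (`parent`/`oxon_metabolite`/`other`),
#'   `parent_id` (for oxons).
#' @export
generate_smiles_library <- function(n, seed = 1L, class_counts = NULL,
                                    n_oxon_pairs = 2L) {
  stopifnot(n >= 1L, n_oxon_pairs >= 0L, 2L * n_oxon_pairs <= n)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  classes <- c("organochlorine", "organophosphorus", "carbamate",
               "triazine", "miscellaneous")
  n_free <- n - 2L * n_oxon_pairs
  plan <- integer(0)
  if (!is.null(class_counts)) {
    stopifnot(all(names(class_counts) %in% classes),
              sum(class_counts) <= n_free)
    plan <- rep(names(class_counts), class_counts)
  }
  if (length(plan) < n_free) {
    plan <- c(plan, classes[(seq_len(n_free - length(plan)) - 1L) %%
                              length(classes) + 1L])
  }

  gen_one <- function(cls, thio = TRUE) {
    switch(cls,
      organochlorine = {
        k <- sample.int(3L, 1L)
        subs <- syn_pick(c("Cl", "Cl", "Cl", "C"), k)
        if (stats::runif(1) < 0.4) {
          paste0("OC1=C", paste0("(", subs[1], ")"), "C=CC=C1")
        } else syn_ring(subs)
      },
      organophosphorus = {
        r1 <- syn_pick(SYN_ALKYL); r2 <- syn_pick(SYN_ALKYL)
        head <- if (thio) "P(=S)" else "P(=O)"
        leaving <- if (stats::runif(1) < 0.5) {
          paste0("O", syn_ring(syn_pick(SYN_RING_SUB, 2L)))
        } else paste0("S", syn_pick(SYN_ALKYL))
        paste0(r1, "O", head, "(O", r2, ")", leaving)
      },
      carbamate = {
        aryl <- syn_ring(syn_pick(c("C", "OC", "Cl"), 2L))
        paste0("CNC(=O)O", aryl)
      },
      triazine = {
        a1 <- syn_pick(c("CC", "C(C)C", "CCC"))
        a2 <- syn_pick(c("CC", "C(C)C", "C"))
        x <- syn_pick(c("Cl", "OC", "SC"))
        paste0("N(", a1, ")C1=NC(=NC(=N1)N", a2, ")", x)
      },
      miscellaneous = {
        aryl <- syn_ring(syn_pick(SYN_RING_SUB, 2L))
        paste0("OC(=O)CO", aryl)
      }
    )
  }

  rows <- list()
  # parent/oxon pairs first: identical skeleton, P=S vs P=O head
  op_skeleton <- function() {
    r1 <- syn_pick(SYN_ALKYL); r2 <- syn_pick(SYN_ALKYL)
    leaving <- if (stats::runif(1) < 0.5) {
      paste0("O", syn_ring(syn_pick(SYN_RING_SUB, 2L)))
    } else paste0("S", syn_pick(SYN_ALKYL))
    function(h) paste0(r1, "O", h, "(O", r2, ")", leaving)
  }
  for (p in seq_len(n_oxon_pairs)) {
    build <- op_skeleton()
    parent_smi <- build("P(=S)")
    oxon_smi <- build("P(=O)")
    pid <- sprintf("syn_op_parent_%02d", p)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = pid, chem_class = "organophosphorus", kekule_smiles = parent_smi,
      role = "parent", parent_id = NA_character_)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = sprintf("syn_op_oxon_%02d", p), chem_class = "organophosphorus",
      kekule_smiles = oxon_smi, role = "oxon_metabolite", parent_id = pid)
  }
  for (i in seq_along(plan)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = sprintf("syn_%s_%03d", substr(plan[i], 1, 4), i),
      chem_class = plan[i], kekule_smiles = gen_one(plan[i]),
      role = "other", parent_id = NA_character_)
  }
  out <- dplyr::bind_rows(rows)
  out$name <- out$id
  out$smiles <- vapply(out$kekule_smiles, ob_canonical, character(1),
                       USE.NAMES = FALSE)
  out[, c("id", "name", "chem_class", "smiles", "kekule_smiles", "role",
          "parent_id")]
}
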