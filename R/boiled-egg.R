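# Two-ellipse (BOILED-Egg) permeation classifier in (tPSA, WLogP) space.
#
# A molecule is predicted to show high gastrointestinal absorption when its
# (tPSA, WLogP) point lies inside the "white" (intestinal) ellipse, and to
# permeate the blood-brain barrier when it lies inside the "yolk" (brain)
# ellipse. The two regions are not mutually exclusive.

#' Load the two-ellipse permeation model
#'
#' Reads the ellipse geometry from a versioned YAML configuration. The
#' default configuration ships with the package and carries the published
#' BOILED-Egg parameters; alternative geometries can be supplied for
#' sensitivity analyses. A checksum of the configuration is stored so every
#' downstream result can be traced to the geometry that produced it.
#'
#' @param path YAML file; `NULL` (default) loads the packaged model.
#' @return an object of class `egg_model`: a named list of two ellipses
#'   (`intestinal`, `brain`), each with fields `center_tpsa`, `center_wlogp`,
#'   `semi_axis_tpsa`, `semi_axis_wlogp`, `rotation_deg`, `interpretation`;
#'   plus `boundary_inclusive`, `version` and `config_checksum` attributes.
#' @export
boiled_egg_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "boiled_egg.yaml", package = "boiledegg")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("model configuration not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg$ellipses),
            all(c("intestinal", "brain") %in% names(cfg$ellipses)))
  for (nm in names(cfg$ellipses)) {
    e <- cfg$ellipses[[nm]]
    if (e$semi_axis_tpsa <= 0 || e$semi_axis_wlogp <= 0) {
      stop("ellipse '", nm, "' has a non-positive semi-axis", call. = FALSE)
    }
    if (e$rotation_deg <= -90 || e$rotation_deg > 90) {
      stop("ellipse '", nm, "' rotation must lie in (-90, 90] degrees",
           call. = FALSE)
    }
  }
  model <- cfg$ellipses
  attr(model, "boundary_inclusive") <- isTRUE(cfg$boundary_inclusive)
  attr(model, "version") <- cfg$version
  attr(model, "config_checksum") <- config_checksum(path)
  class(model) <- "egg_model"
  model
}

# order-independent checksum of the parsed configuration
config_checksum <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  # base-R djb2-style rolling hash; provenance tag, not cryptographic
  h <- 5381
  for (v in utf8ToInt(txt)) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

#' @export
print.egg_model <- function(x, ...) {
  cat("Two-ellipse permeation model (version ", attr(x, "version"),
      ", checksum ", attr(x, "config_checksum"), ")\n", sep = "")
  for (nm in names(x)) {
    e <- x[[nm]]
    cat(sprintf(
      "  %-10s center (%.3f, %.3f)  semi-axes (%.4f, %.4f)  rot %.6f deg  [%s]\n",
      nm, e$center_tpsa, e$center_wlogp, e$semi_axis_tpsa, e$semi_axis_wlogp,
      e$rotation_deg, e$interpretation))
  }
  cat("  boundary points count as",
      if (attr(x, "boundary_inclusive")) "inside\n" else "outside\n")
  invisible(x)
}

#' Ellipse membership test
#'
#' Rotates the displacement from the ellipse center by minus the ellipse
#' rotation, scales by the semi-axes and evaluates the quadratic form
#' \eqn{(u/a)^2 + (v/b)^2}. Membership is `form <= 1` when the model counts
#' boundary points as inside (the default geometry does), `form < 1`
#' otherwise. Rotation is applied in data units.
#'
#' @param tpsa,wlogp numeric vectors (recycled to common length).
#' @param ellipse one element of an `egg_model`, e.g. `model$intestinal`.
#' @param boundary_inclusive does the boundary count as inside?
#' @return logical vector.
#' @export
point_in_ellipse <- function(tpsa, wlogp, ellipse, boundary_inclusive = TRUE) {
  if (any(!is.finite(tpsa)) || any(!is.finite(wlogp))) {
    stop("non-finite descriptor value passed to point_in_ellipse",
         call. = FALSE)
  }
  th <- ellipse$rotation_deg * pi / 180
  dx <- tpsa - ellipse$center_tpsa
  dy <- wlogp - ellipse$center_wlogp
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  form <- (u / ellipse$semi_axis_tpsa)^2 + (v / ellipse$semi_axis_wlogp)^2
  if (boundary_inclusive) form <= 1 else form < 1
}

#' Classify intestinal absorption and brain permeation
#'
#' Adds `gi_label` (`"high"`/`"low"`) and `bbb_label` (`"yes"`/`"no"`) to a
#' descriptor table via the two independent ellipse-membership tests. Rows
#' whose descriptors could not be computed (`NA` tpsa/wlogp) get `NA` labels
#' and a warning.
#'
#' @param data data frame with `tpsa` and `wlogp` columns (typically from
#'   [compute_descriptors()]; if absent but a `smiles` column is present,
#'   descriptors are computed first).
#' @param model an `egg_model` (default: the packaged geometry).
#' @param include_sp passed to [compute_descriptors()] when descriptors must
#'   be computed here.
#' @return `data` as a tibble with `gi_label` and `bbb_label` appended;
#'   attribute `model_checksum` records the geometry used.
#' @examples
#' \donttest{
#' tbl <- data.frame(id = "caffeine",
#'                   smiles = "Cn1cnc2c1c(=O)n(C)c(=O)n2C")
#' classify_permeation(tbl)
#' }
#' @export
classify_permeation <- function(data, model = boiled_egg_model(),
                                include_sp = TRUE) {
  stopifnot(is.data.frame(data), inherits(model, "egg_model"))
  if (!all(c("tpsa", "wlogp") %in% names(data))) {
    data <- compute_descriptors(data, include_sp = include_sp)
  }
  out <- tibble::as_tibble(data)
  inc <- attr(model, "boundary_inclusive")
  ok <- is.finite(out$tpsa) & is.finite(out$wlogp)
  if (any(!ok)) {
    warning(sum(!ok), " compound(s) without finite descriptors left",
            " unclassified", call. = FALSE)
  }
  gi <- bbb <- rep(NA, nrow(out))
  if (any(ok)) {
    gi[ok] <- point_in_ellipse(out$tpsa[ok], out$wlogp[ok],
                               model$intestinal, inc)
    bbb[ok] <- point_in_ellipse(out$tpsa[ok], out$wlogp[ok],
                                model$brain, inc)
  }
  out$gi_label <- ifelse(gi, "high", "low")
  out$bbb_label <- ifelse(bbb, "yes", "no")
  attr(out, "model_checksum") <- attr(model, "config_checksum")
  attr(out, "tpsa_include_sp") <- attr(data, "tpsa_include_sp")
  out
}

#' Egg-plot geometry: ellipse outlines, scatter points and axis ranges
#'
#' Serializes everything a plotting backend needs for the classical egg
#' plot: the two ellipse outlines as sampled polylines, the compound points
#' with their labels, and padded axis ranges.
#'
#' @param predictions output of [classify_permeation()].
#' @param model the `egg_model` used.
#' @param n_vertices outline sampling resolution.
#' @return list with tibbles `points` and `outlines` plus `xlim`/`ylim`.
#' @export
egg_plot_data <- function(predictions, model = boiled_egg_model(),
                          n_vertices = 360L) {
  stopifnot(is.data.frame(predictions), nrow(predictions) >= 1L,
            all(c("tpsa", "wlogp") %in% names(predictions)))
  outlines <- purrr::map_dfr(names(model), function(nm) {
    e <- model[[nm]]
    t <- seq(0, 2 * pi, length.out = n_vertices + 1L)
    th <- e$rotation_deg * pi / 180
    u <- e$semi_axis_tpsa * cos(t)
    v <- e$semi_axis_wlogp * sin(t)
    tibble::tibble(
      region = nm,
      tpsa = e$center_tpsa + u * cos(th) - v * sin(th),
      wlogp = e$center_wlogp + u * sin(th) + v * cos(th)
    )
  })
  pts <- tibble::as_tibble(predictions)
  xr <- range(c(outlines$tpsa, pts$tpsa), na.rm = TRUE)
  yr <- range(c(outlines$wlogp, pts$wlogp), na.rm = TRUE)
  pad <- c(-0.04, 0.04)
  list(points = pts, outlines = outlines,
       xlim = xr + diff(xr) * pad, ylim = yr + diff(yr) * pad)
}
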