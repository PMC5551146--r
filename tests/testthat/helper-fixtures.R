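# shared helpers: fixture paths, small in-code compound sets, and quiet
# wrappers (OpenBabel prints parse warnings to stderr; our own R-level
# warnings are asserted explicitly where they matter)

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "boiledegg")
  if (!nzchar(p)) stop("fixture not found: ", name)
  p
}

egg_model_fixture <- function() boiled_egg_model()

quiet <- function(expr) suppressWarnings(expr)

# three small, valid compounds used across I/O tests
tiny_table <- function() {
  data.frame(
    id = c("ethanol", "benzene", "aspirin"),
    name = c("ethanol", "benzene", "aspirin"),
    chem_class = c("miscellaneous", "miscellaneous", "miscellaneous"),
    smiles = c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O"),
    stringsAsFactors = FALSE
  )
}

write_tiny_csv <- function(df = tiny_table()) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# hand-computed pooled-variance two-sided Student t (the independent oracle
# for compare_groups)
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- 2 * pt(-abs(t), df = nx + ny - 2)
  list(t = t, p = p)
}

# independent ellipse-membership oracle: expanded conic coefficients
# A x^2 + B xy + C y^2 + D x + E y + F <= 0, assembled from the geometric
# parameters by a different algebraic route than the implementation
conic_member_oracle <- function(x, y, e) {
  th <- e$rotation_deg * pi / 180
  a <- e$semi_axis_tpsa; b <- e$semi_axis_wlogp
  A <- (cos(th) / a)^2 + (sin(th) / b)^2
  C <- (sin(th) / a)^2 + (cos(th) / b)^2
  B <- 2 * cos(th) * sin(th) * (1 / a^2 - 1 / b^2)
  x0 <- e$center_tpsa; y0 <- e$center_wlogp
  dx <- x - x0; dy <- y - y0
  A * dx^2 + B * dx * dy + C * dy^2 - 1 <= 0
}
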