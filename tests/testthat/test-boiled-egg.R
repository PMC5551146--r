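test_that("the packaged model loads with valid geometry and a checksum", {
  m <- egg_model_fixture()
  expect_s3_class(m, "egg_model")
  expect_setequal(names(m), c("intestinal", "brain"))
  for (e in m) {
    expect_gt(e$semi_axis_tpsa, 0)
    expect_gt(e$semi_axis_wlogp, 0)
    expect_true(e$rotation_deg > -90 && e$rotation_deg <= 90)
  }
  expect_match(attr(m, "config_checksum"), "^[0-9a-f]{8}$")
  expect_true(attr(m, "boundary_inclusive"))
})

test_that("ellipse membership: center inside, beyond-semi-axis displacements outside", {
  m <- egg_model_fixture()
  for (e in m) {
    th <- e$rotation_deg * pi / 180
    expect_true(point_in_ellipse(e$center_tpsa, e$center_wlogp, e))
    # displacements along the rotated principal axes
    major <- c(cos(th), sin(th)) * e$semi_axis_tpsa
    minor <- c(-sin(th), cos(th)) * e$semi_axis_wlogp
    for (dir in list(major, minor)) {
      just_out <- 1.0001 * dir
      just_in <- 0.9999 * dir
      expect_false(point_in_ellipse(e$center_tpsa + just_out[1],
                                    e$center_wlogp + just_out[2], e))
      expect_true(point_in_ellipse(e$center_tpsa + just_in[1],
                                   e$center_wlogp + just_in[2], e))
    }
  }
  # boundary semantics, checked where the quadratic form is exactly
  # representable: (2, 0) on an axis-aligned 2x1 ellipse evaluates to 1
  unit <- list(center_tpsa = 0, center_wlogp = 0, semi_axis_tpsa = 2,
               semi_axis_wlogp = 1, rotation_deg = 0)
  expect_true(point_in_ellipse(2, 0, unit))
  expect_false(point_in_ellipse(2, 0, unit, boundary_inclusive = FALSE))
  expect_error(point_in_ellipse(NA_real_, 1, m$brain), "non-finite")
})

test_that("membership agrees with the brute-force conic oracle on a dense grid", {
  m <- egg_model_fixture()
  gx <- seq(-20, 180, length.out = 200)
  gy <- seq(-6, 10, length.out = 200)
  grid <- expand.grid(tpsa = gx, wlogp = gy)
  for (e in m) {
    impl <- point_in_ellipse(grid$tpsa, grid$wlogp, e)
    oracle <- conic_member_oracle(grid$tpsa, grid$wlogp, e)
    expect_identical(sum(impl != oracle), 0L)
  }
})

test_that("shrinking a point radially toward the center never flips inside to outside", {
  m <- egg_model_fixture()
  set.seed(42)
  for (e in m) {
    x <- runif(200, -20, 180)
    y <- runif(200, -6, 10)
    inside <- point_in_ellipse(x, y, e)
    for (s in c(0.8, 0.5, 0.2)) {
      xs <- e$center_tpsa + s * (x - e$center_tpsa)
      ys <- e$center_wlogp + s * (y - e$center_wlogp)
      shrunk <- point_in_ellipse(xs, ys, e)
      expect_true(all(shrunk[inside]))
    }
  }
})

test_that("classification assigns both labels independently and reproduces known compounds", {
  # lindane: the textbook low-GI / brain-permeant organochlorine
  tbl <- tibble::tibble(
    id = c("lindane", "chlorpyrifos", "paraquat", "ddt"),
    smiles = c("ClC1C(Cl)C(Cl)C(Cl)C(Cl)C1Cl",
               "CCOP(=S)(OCC)Oc1nc(Cl)c(Cl)cc1Cl",
               "C[n+]1ccc(cc1)-c1cc[n+](C)cc1",
               "Clc1ccc(cc1)C(c1ccc(Cl)cc1)C(Cl)(Cl)Cl"))
  pred <- classify_permeation(compute_descriptors(tbl))
  expect_equal(pred$gi_label, c("low", "high", "low", "low"))
  expect_equal(pred$bbb_label, c("yes", "no", "no", "no"))
  expect_match(attr(pred, "model_checksum"), "^[0-9a-f]{8}$")
})

test_that("classification is invariant to compound order and SMILES dialect", {
  tbl <- tibble::tibble(
    id = c("a", "b", "c"),
    smiles = c("c1ccccc1O", "CCOP(=S)(OCC)Oc1nc(Cl)c(Cl)cc1Cl",
               "CNC(=O)Oc1ccccc1OC(C)C"))
  kek <- tibble::tibble(
    id = tbl$id,
    smiles = c("OC1=CC=CC=C1", "CCOP(=S)(OCC)OC1=NC(Cl)=C(Cl)C=C1Cl",
               "CNC(=O)OC1=CC=CC=C1OC(C)C"))
  p1 <- classify_permeation(compute_descriptors(tbl))
  p2 <- classify_permeation(compute_descriptors(tbl[3:1, ]))
  p3 <- classify_permeation(compute_descriptors(kek))
  expect_equal(p1[match(p1$id, p2$id), c("gi_label", "bbb_label")],
               p2[, c("gi_label", "bbb_label")])
  expect_equal(p1[, c("gi_label", "bbb_label")],
               p3[, c("gi_label", "bbb_label")])
})

test_that("egg plot data carries outlines, points and sane ranges", {
  tbl <- tibble::tibble(id = "x", tpsa = 71.051, wlogp = 2.292,
                        gi_label = "high", bbb_label = "no")
  pd <- egg_plot_data(tbl)
  expect_setequal(unique(pd$outlines$region), c("intestinal", "brain"))
  expect_gt(nrow(pd$outlines), 500)
  expect_equal(nrow(pd$points), 1L)
  expect_true(pd$xlim[1] < 0 && pd$xlim[2] > 142)
  # a point at the intestinal center plots inside the grey region
  expect_true(point_in_ellipse(tbl$tpsa, tbl$wlogp,
                               egg_model_fixture()$intestinal))
  p <- plot_boiled_egg(tbl)
  expect_s3_class(p, "ggplot")
})

test_that("the brain ellipse is almost entirely nested in the intestinal one", {
  # uniform area sample of the brain ellipse: nearly all of it must lie
  # inside the intestinal ellipse (whence brain-permeant compounds are, with
  # rare exceptions, also predicted intestine-permeant)
  m <- egg_model_fixture()
  e <- m$brain
  th <- e$rotation_deg * pi / 180
  set.seed(1)
  r <- sqrt(runif(10000)); a <- runif(10000, 0, 2 * pi)
  u <- e$semi_axis_tpsa * r * cos(a)
  v <- e$semi_axis_wlogp * r * sin(a)
  px <- e$center_tpsa + u * cos(th) - v * sin(th)
  py <- e$center_wlogp + u * sin(th) + v * cos(th)
  expect_true(all(point_in_ellipse(px, py, e)))
  expect_gt(mean(point_in_ellipse(px, py, m$intestinal)), 0.95)
})
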