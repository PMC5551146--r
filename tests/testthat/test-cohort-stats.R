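test_that("class summaries count exactly on a constructed two-class set", {
  pred <- tibble::tibble(
    id = paste0("c", 1:10),
    chem_class = rep(c("alpha", "beta"), c(6, 4)),
    gi_label = c(rep("high", 5), "low", rep("high", 2), rep("low", 2)),
    bbb_label = c(rep("yes", 3), rep("no", 3), rep("yes", 1), rep("no", 3))
  )
  s <- summarize_by_class(pred)
  a <- s[s$chem_class == "alpha", ]
  expect_equal(a$n_total, 6)
  expect_equal(a$n_gi_high, 5)
  expect_equal(a$pct_gi_high, 83)        # integer rounding at class level
  expect_equal(a$n_bbb_yes, 3)
  all_row <- s[s$chem_class == "all", ]
  expect_equal(all_row$n_total, 10)
  expect_equal(all_row$pct_gi_high, 70.0)
  expect_equal(all_row$pct_bbb_yes, 40.0)
  # sum consistency
  per_class <- s[s$chem_class != "all", ]
  expect_equal(sum(per_class$n_total), all_row$n_total)
  expect_equal(sum(per_class$n_gi_high), all_row$n_gi_high)
})

test_that("pooled t equals the hand-computed formula to 1e-10 on 5-vs-5 vectors", {
  set.seed(7)
  for (rep in 1:5) {
    x <- rnorm(5, mean = 2)
    y <- rnorm(5)
    df <- tibble::tibble(grp = rep(c("a", "b"), each = 5),
                         mw = c(x, y))
    cmp <- compare_groups(df, "grp", params = "mw")
    oracle <- pooled_t_oracle(x, y)
    expect_equal(cmp$t, oracle$t, tolerance = 1e-10)
    expect_equal(cmp$p, oracle$p, tolerance = 1e-10)
  }
})

test_that("group relabeling flips the sign of t and preserves p", {
  set.seed(11)
  df <- tibble::tibble(grp = rep(c("high", "low"), each = 8),
                       tpsa = c(rnorm(8, 50, 10), rnorm(8, 80, 10)))
  ab <- compare_groups(df, "grp", params = "tpsa")
  df2 <- df
  df2$grp <- ifelse(df$grp == "high", "zlow", "ahigh")  # reverse sort order
  ba <- compare_groups(df2, "grp", params = "tpsa")
  expect_equal(ab$t, -ba$t, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
})

test_that("two identical zero-variance groups give t = 0, p = 1, flagged", {
  df <- tibble::tibble(grp = rep(c("a", "b"), each = 4), mw = rep(5, 8))
  cmp <- compare_groups(df, "grp", params = "mw")
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)
  expect_false(cmp$significant)
  expect_match(cmp$note, "zero variance")
})

test_that("Welch option changes the statistic only under unequal variances", {
  set.seed(3)
  df <- tibble::tibble(grp = rep(c("a", "b"), c(10, 10)),
                       mw = c(rnorm(10, sd = 1), rnorm(10, sd = 6)))
  student <- compare_groups(df, "grp", params = "mw")
  welch <- compare_groups(df, "grp", welch = TRUE, params = "mw")
  expect_false(isTRUE(all.equal(student$p, welch$p)))
  expect_equal(attr(welch, "test"), "Welch t")
})

test_that("tidy/glance methods expose the comparison in broom shape", {
  set.seed(5)
  df <- tibble::tibble(grp = rep(c("a", "b"), each = 6),
                       mw = rnorm(12), tpsa = rnorm(12))
  cmp <- compare_groups(df, "grp")
  td <- tidy(cmp)
  expect_true(all(c("parameter", "estimate", "statistic", "p.value") %in%
                    names(td)))
  gl <- glance(cmp)
  expect_equal(gl$n_parameters, nrow(td))
  expect_equal(gl$alpha, 0.05)
})

test_that("the organophosphorus parent/oxon fixture reproduces the printed pattern", {
  tbl <- read_compound_table(fixture_path("op_oxon_pairs.csv"))
  pred <- classify_permeation(compute_descriptors(tbl))
  parents <- pred[pred$role == "parent", ]
  oxons <- pred[pred$role == "oxon_metabolite", ]
  pairing <- tibble::tibble(parent_id = oxons$parent_id, oxon_id = oxons$id)
  cmp <- oxon_comparison(parents, oxons, pairing)
  expect_equal(nrow(cmp), 15L)
  expect_equal(attr(cmp, "n_parent_bbb_yes"), 0L)
  expect_equal(attr(cmp, "n_oxon_bbb_yes"), 3L)
  expect_equal(attr(cmp, "pct_oxon_bbb_yes"), 20)
  expect_setequal(cmp$oxon_id[cmp$oxon_bbb == "yes"],
                  c("chlorpyrifos_oxon", "chlorpyrifos_methyl_oxon",
                    "fonofos_oxon"))
  gl <- glance(cmp)
  expect_equal(gl$pct_oxon_bbb_yes, 20)
})

test_that("oxon pairing is validated: identical pairs give zero flips, unpaired oxons error", {
  preds <- tibble::tibble(id = c("p1", "p2"), bbb_label = c("no", "yes"))
  oxons <- tibble::tibble(id = c("o1", "o2"), bbb_label = c("no", "yes"))
  pairing <- tibble::tibble(parent_id = c("p1", "p2"),
                            oxon_id = c("o1", "o2"))
  cmp <- oxon_comparison(preds, oxons, pairing)
  expect_equal(sum(cmp$flipped), 0L)
  # constructed flip is counted
  oxons2 <- tibble::tibble(id = c("o1", "o2"), bbb_label = c("yes", "yes"))
  cmp2 <- oxon_comparison(preds, oxons2, pairing)
  expect_equal(sum(cmp2$flipped), 1L)
  # unpaired oxon is an error naming the offender
  expect_error(oxon_comparison(preds, oxons, pairing[1, ]), "o2")
})
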