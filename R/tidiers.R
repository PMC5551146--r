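# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a group comparison
#'
#' @param x a `group_comparison` from [compare_groups()].
#' @param ... unused.
#' @return one row per tested parameter with estimates (group means/SDs),
#'   the difference in means, `statistic` (t), `p.value` and `significant`.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter,
    estimate_A = x$mean_A, sd_A = x$sd_A, n_A = x$n_A,
    estimate_B = x$mean_B, sd_B = x$sd_B, n_B = x$n_B,
    estimate = x$mean_A - x$mean_B,
    statistic = x$t, p.value = x$p,
    significant = x$significant
  )
}

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    n_parameters = nrow(x),
    n_significant = sum(x$significant),
    test = attr(x, "test"),
    alpha = attr(x, "alpha"),
    group_A = attr(x, "groups")[["A"]],
    group_B = attr(x, "groups")[["B"]]
  )
}

#' Tidy a predicted-vs-measured confrontation
#'
#' @param x a `permeation_confrontation` from [confront()].
#' @param ... unused.
#' @return `tidy()`: the per-compound concordance table. `glance()`: a
#'   one-row summary with `n_total`, `n_concordant`, `accuracy` (percent)
#'   and the number of discordant compounds.
#' @method tidy permeation_confrontation
#' @export
tidy.permeation_confrontation <- function(x, ...) {
  x$table
}

#' @rdname tidy.permeation_confrontation
#' @method glance permeation_confrontation
#' @export
glance.permeation_confrontation <- function(x, ...) {
  tibble::tibble(
    n_total = x$n_total,
    n_concordant = x$n_concordant,
    accuracy = x$accuracy,
    n_discordant = length(x$discordant)
  )
}

#' Tidy a parent/oxon comparison
#'
#' @param x an `oxon_comparison` from [oxon_comparison()].
#' @param ... unused.
#' @return `tidy()`: the pair table. `glance()`: one-row summary with the
#'   permeant counts and the oxon brain-permeant percentage.
#' @method tidy oxon_comparison
#' @export
tidy.oxon_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "oxon_comparison")
  tibble::as_tibble(out)
}

#' @rdname tidy.oxon_comparison
#' @method glance oxon_comparison
#' @export
glance.oxon_comparison <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_parent_bbb_yes = attr(x, "n_parent_bbb_yes"),
    n_oxon_bbb_yes = attr(x, "n_oxon_bbb_yes"),
    pct_oxon_bbb_yes = attr(x, "pct_oxon_bbb_yes")
  )
}
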