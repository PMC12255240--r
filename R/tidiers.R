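#' Tidy an ICC result
#'
#' @param x An `icc_result`.
#' @param ... Unused.
#' @return One-row tibble with `icc`, `icc_single`, `conf_low`, `conf_high`,
#'   `sem`.
#' @export
tidy.icc_result <- function(x, ...) {
  tibble(icc = x$icc, icc_single = x$icc_single,
         conf_low = x$ci95[1], conf_high = x$ci95[2], sem = x$sem)
}

#' @rdname tidy.icc_result
#' @return `glance()`: one-row tibble with the design size and mean squares.
#' @export
glance.icc_result <- function(x, ...) {
  tibble(n_subjects = x$n, k = x$k, sd = x$sd,
         ms_subjects = x$ms[["msr"]], ms_ratings = x$ms[["msc"]],
         ms_error = x$ms[["mse"]], conf_level = x$conf_level)
}

#' Tidy a gated two-group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return One-row tibble with the chosen test, p-value, Cohen's d and the
#'   gate diagnostics.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(test = x$test, p = x$p, cohens_d = x$cohens_d,
         significant = x$significant, alpha = x$alpha,
         shapiro_p_a = x$shapiro_p[1], shapiro_p_b = x$shapiro_p[2],
         levene_p = x$levene_p)
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  g <- x$groups
  tibble(n_a = g$n[1], mean_a = g$mean[1], sd_a = g$sd[1],
         n_b = g$n[2], mean_b = g$mean[2], sd_b = g$sd[2],
         tails = x$tails, direction = x$direction)
}
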