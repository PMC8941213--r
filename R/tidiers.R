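#' Tidy a moderated fit into per-group results
#'
#' One row per protein group with the moderated statistics and Storey
#' q-values (computed over the tested groups only; presence/absence
#' groups keep `NA`).
#'
#' @param x A `moderated_fit` from [moderated_ttest()].
#' @param ... Unused.
#' @return Tibble `group_id`, `n_healthy`, `n_uc`, `log2_fc`, `t`,
#'   `p_value`, `q_value`, `presence_absence`, ...
#' @method tidy moderated_fit
#' @export
tidy.moderated_fit <- function(x, ...) {
  tbl <- x$table
  tested <- !tbl$presence_absence
  q <- rep(NA_real_, nrow(tbl))
  if (any(tested)) q[tested] <- qvalues(tbl$p_value[tested])
  tbl |> mutate(q_value = q) |>
    select("group_id", "n_healthy", "n_uc", "mean_healthy", "mean_uc",
           "log2_fc", "t", "df_total", "p_value", "q_value",
           "presence_absence")
}

#' One-row summary of a moderated fit
#'
#' @param x A `moderated_fit`.
#' @param ... Unused.
#' @return Tibble with `n_groups`, `n_tested`, `n_presence_absence`,
#'   `prior_df` (d0) and `prior_var` (s0^2).
#' @method glance moderated_fit
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble(
    n_groups = nrow(x$table),
    n_tested = sum(!x$table$presence_absence),
    n_presence_absence = sum(x$table$presence_absence),
    prior_df = x$prior$d0,
    prior_var = x$prior$s02
  )
}

#' @export
print.moderated_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<moderated_fit> %d groups (%d tested, %d presence/absence); prior df %.2f, prior var %.4f\n",
    g$n_groups, g$n_tested, g$n_presence_absence, g$prior_df, g$prior_var))
  invisible(x)
}

#' Tidy a dark-peptidome summary
#'
#' @param x A `dark_summary`.
#' @param ... Unused.
#' @return The per-sample tibble with dark counts and fractions.
#' @method tidy dark_summary
#' @export
tidy.dark_summary <- function(x, ...) x$per_sample

#' One-row summary of a dark-peptidome estimate
#'
#' @param x A `dark_summary`.
#' @param ... Unused.
#' @return Tibble `n_samples`, `avg_dark`, `avg_total_ms2`,
#'   `dark_fraction`, `projected_increase`.
#' @method glance dark_summary
#' @export
glance.dark_summary <- function(x, ...) {
  tibble(n_samples = x$n_samples, avg_dark = x$avg_dark,
         avg_total_ms2 = x$avg_total_ms2, dark_fraction = x$dark_fraction,
         projected_increase = x$projected_increase)
}
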