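#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a rate comparison
#'
#' @param x A `pfc_rate_comparison`.
#' @param ... Unused.
#' @return One-row tibble with `estimate_pref`, `estimate_npref`, `estimate`
#'   (difference, Hz), `statistic`, `p.value`, `parameter` (Welch df).
#' @export
tidy.pfc_rate_comparison <- function(x, ...) {
  tibble::tibble(
    preferred = x$preferred, non_preferred = x$non_preferred,
    estimate_pref = x$mean_pref, estimate_npref = x$mean_npref,
    estimate = x$mean_pref - x$mean_npref,
    statistic = x$statistic, p.value = x$p_value, parameter = x$df
  )
}

#' Tidy an experiment's outcomes
#'
#' @param x A `pfc_experiment`.
#' @param ... Unused.
#' @return The per-trial outcome tibble.
#' @export
tidy.pfc_experiment <- function(x, ...) {
  x$outcomes
}

#' One-row experiment summary
#'
#' @param x A `pfc_experiment`.
#' @param ... Unused.
#' @return One-row tibble: conditions run, trials, overall percentages.
#' @export
glance.pfc_experiment <- function(x, ...) {
  tibble::tibble(
    n_conditions = nrow(x$summary),
    n_trials = nrow(x$outcomes),
    pct_correct = 100 * mean(x$outcomes$correct),
    pct_null = 100 * mean(x$outcomes$null_response)
  )
}
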