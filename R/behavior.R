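#' Saccade decision from motor-output spike counts
#'
#' Accumulator readout: the motor group with the greatest spike count in the
#' 500-ms window before response onset determines the saccade direction. If
#' no motor neuron fired at all the trial is a null (no-response) trial,
#' returned as `NA`. Ties among maximal counts are broken by a uniform
#' random choice over the tied groups, drawn from the current RNG stream so
#' trials remain reproducible from their seed.
#'
#' @param counts Named non-negative counts, one per motor excitatory group;
#'   names are the direction labels (`"0"`, `"90"`, `"180"`, `"270"`).
#' @return The decided direction (numeric) or `NA` for a null response.
#'
#' @examples
#' decide_saccade(c(`0` = 12, `90` = 3, `180` = 1, `270` = 0))
#' decide_saccade(c(`0` = 0, `90` = 0, `180` = 0, `270` = 0)) # NA (null)
#' @export
decide_saccade <- function(counts) {
  stopifnot(all(counts >= 0), !is.null(names(counts)))
  if (all(counts == 0)) {
    return(NA_real_)
  }
  top <- which(counts == max(counts))
  pick <- if (length(top) > 1) top[sample.int(length(top), 1)] else top
  as.numeric(names(counts)[pick])
}

#' Summarise behavioral outcomes per condition
#'
#' Aggregates per-trial outcomes into the percentage of correct, incorrect
#' and null (no-response) trials for each (DA, NE) condition, mirroring the
#' 3x3 behavioral grid of the model.
#'
#' @param outcomes A tibble of trial outcomes with columns `da`, `ne`,
#'   `correct`, `null_response` (as produced by [run_experiment()]).
#' @return A tibble with one row per condition: `da`, `ne`, `n_trials`,
#'   `pct_correct`, `pct_incorrect`, `pct_null`.
#' @export
summarize_behavior <- function(outcomes) {
  stopifnot(nrow(outcomes) >= 1)
  outcomes |>
    dplyr::group_by(.data$da, .data$ne) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      pct_correct = 100 * mean(.data$correct),
      pct_null = 100 * mean(.data$null_response),
      pct_incorrect = 100 - .data$pct_correct - .data$pct_null,
      .groups = "drop"
    ) |>
    dplyr::select(
      "da", "ne", "n_trials", "pct_correct", "pct_incorrect", "pct_null"
    )
}
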