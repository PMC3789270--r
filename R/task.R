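#' Oculomotor delayed-response trial schedule
#'
#' Lays out the four task phases over a 6-s trial: fixation \[0, 1000) ms,
#' cue \[1000, 1500) ms at the cued direction, delay \[1500, 4000) ms, and
#' response \[4000, 6000) ms. A 40-Hz corollary-discharge volley drives the
#' MDSC relay for the first 500 ms of the response phase, which (via layer 5
#' and the basal ganglia) clears working memory. Background Poisson drive
#' targets all four parietal groups; the cue adds extra drive to the cued
#' group only.
#'
#' @param cue_direction Cue location in degrees: 0, 90, 180 or 270.
#' @param config Run configuration (phase durations and drive rates).
#' @return A `pfc_schedule`: list with `cue_direction`, a `phases` tibble
#'   (`phase`, `start`, `end` in ms) and a `drives` tibble (`target_area`,
#'   `direction`, `rate_hz`, `start`, `end`) describing each Poisson drive.
#' @export
build_trial_schedule <- function(cue_direction = 0, config = default_config()) {
  if (!cue_direction %in% directions()) {
    stop("cue_direction must be one of 0, 90, 180, 270", call. = FALSE)
  }
  tk <- config$task
  cue_on <- tk$fixation_ms
  cue_off <- cue_on + tk$cue_ms
  resp_on <- tk$response_onset_ms
  phases <- tibble::tibble(
    phase = c("fixation", "cue", "delay", "response"),
    start = c(0, cue_on, cue_off, resp_on),
    end = c(cue_on, cue_off, resp_on, tk$trial_ms)
  )
  bg_end <- if (isTRUE(tk$background_all_phases)) tk$trial_ms else cue_on
  drives <- dplyr::bind_rows(
    tibble::tibble(
      target_area = "PC7a", direction = directions(),
      rate_hz = tk$bg_rate_hz, start = 0, end = bg_end
    ),
    tibble::tibble(
      target_area = "PC7a", direction = cue_direction,
      rate_hz = tk$cue_rate_hz, start = cue_on, end = cue_off
    ),
    tibble::tibble(
      target_area = "MDSC", direction = NA_real_,
      rate_hz = tk$cd_rate_hz, start = resp_on, end = resp_on + tk$cd_ms
    )
  )
  structure(
    list(cue_direction = cue_direction, phases = phases, drives = drives,
         trial_ms = tk$trial_ms),
    class = "pfc_schedule"
  )
}

#' Generate homogeneous Poisson drive events
#'
#' Independent homogeneous Poisson spike trains, one per target, at a common
#' rate over a time window. Sampling draws the total event count from a
#' Poisson law and places times uniformly, which is exactly equivalent to
#' independent per-target trains.
#'
#' @param rate_hz Event rate per target (Hz, >= 0).
#' @param window Numeric length-2 `c(start, end)` in ms.
#' @param n_targets Number of target neurons.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return A tibble with `target` (1-based) and `time_ms`, sorted by time.
#' @export
generate_poisson_drive <- function(rate_hz, window, n_targets, seed = NULL) {
  stopifnot(rate_hz >= 0, length(window) == 2, window[2] >= window[1])
  if (!is.null(seed)) set.seed(seed)
  dur <- (window[2] - window[1]) / 1000
  n <- stats::rpois(1, rate_hz * dur * n_targets)
  out <- tibble::tibble(
    target = sample.int(n_targets, n, replace = TRUE),
    time_ms = stats::runif(n, window[1], window[2])
  )
  dplyr::arrange(out, .data$time_ms)
}

# Assemble all drive events of one trial into engine-ready arrays:
# global target indices and integer millisecond slots.
trial_drive_events <- function(network, schedule) {
  pops <- network$populations
  w <- network$config$network$weights
  ev_t <- list()
  ev_n <- list()
  ev_w <- list()
  for (i in seq_len(nrow(schedule$drives))) {
    dr <- schedule$drives[i, ]
    name <- if (dr$target_area == "MDSC") "MDSC" else
      paste0(dr$target_area, "_", dr$direction)
    pop <- pops[pops$name == name, ]
    events <- generate_poisson_drive(
      dr$rate_hz, c(dr$start, dr$end), pop$size
    )
    if (nrow(events) == 0) next
    ev_t[[length(ev_t) + 1]] <- pmin(floor(events$time_ms), schedule$trial_ms - 1)
    ev_n[[length(ev_n) + 1]] <- events$target + pop$start - 1L
    w_ev <- if (dr$target_area == "MDSC") w$ext_mdsc else w$ext_pc
    ev_w[[length(ev_w) + 1]] <- rep(w_ev, nrow(events))
  }
  t_all <- unlist(c(ev_t, list(integer(0))))
  ord <- order(t_all)
  list(
    ms = as.integer(t_all[ord]),
    target = as.integer(unlist(c(ev_n, list(integer(0))))[ord]),
    w = as.numeric(unlist(c(ev_w, list(numeric(0))))[ord])
  )
}
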