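#' Default run configuration
#'
#' Builds the configuration list that fully describes a simulation run:
#' population sizes, connection probabilities, base synaptic weights, the
#' neuromodulatory condition, the trial protocol and analysis windows.
#' Population sizes and connection probabilities are the model's anatomical
#' constants; base synaptic weights and Poisson drive rates are free
#' parameters of the model set by the calibration procedure
#' ([calibrate_weights()]) so that the optimal-condition network holds a
#' persistent delay-period memory at roughly 20 Hz in the cued column and
#' 10 Hz elsewhere.
#'
#' @param scale Network scale factor in (0, 1]; population sizes are
#'   multiplied by `scale` and synaptic weights divided by it (input
#'   conservation), so desk-scale runs preserve the dynamical regime.
#' @param seed Master seed for connectivity and trial randomness.
#'
#' @return A nested list with sections `network`, `condition`, `task`,
#'   `modulation` and `analysis`.
#' @export
default_config <- function(scale = 0.1, seed = 1) {
  list(
    network = list(
      scale = scale,
      seed = seed,
      sizes = list(
        pc7a = 1000, l3e = 2585, l3i = 729, l5e = 606, l5i = 133,
        mote = 1000, moti = 250, mdsc = 1000, bg = 1000
      ),
      p_within = list(
        l3e_l3e = 0.3584, l3e_l3i = 0.1008, l3i_l3e = 0.1552,
        l3i_l3i = 0.1371, l5e_l5e = 0.0758, l5e_l5i = 0.0566,
        l5i_l5e = 0.3765, l5i_l5i = 0.3158
      ),
      p_between = 0.1,
      weight_compensation = "linear",
      normalize_in_degree = TRUE,
      weights = list(
        pc_l3 = 6e-3, pc_l3i = 3e-4, rec_l3 = 2.5e-4, l3_ei = 3e-4,
        l3_ie = 8e-4, l3_ii = 3e-4, lat_ee = 1.7e-4, lat_ei = 8e-4,
        l5_ee = 1e-3, l5_ei = 1e-3, l5_ie = 4e-3, l5_ii = 2e-3,
        mdsc_l5 = 6e-3, l5_bg = 6e-3, bg_l3 = 2e-3,
        l3_mot = 2.2e-3, mot_ei = 3e-3, mot_ie = 1.2e-2,
        ext_pc = 0.12, ext_mdsc = 0.3
      )
    ),
    condition = list(da = "optimal", ne = "optimal"),
    task = list(
      trial_ms = 6000, fixation_ms = 1000, cue_ms = 500, delay_ms = 2500,
      response_onset_ms = 4000, cd_rate_hz = 40, cd_ms = 500,
      bg_rate_hz = 15, cue_rate_hz = 150, cue_direction = 0,
      n_trials = 50, background_all_phases = TRUE
    ),
    modulation = list(modulate_l3_inhibitory = FALSE),
    analysis = list(
      delay_start_ms = 1700, delay_end_ms = 4000,
      decision_window_ms = 500, bin_ms = 10, smooth_bins = 5
    )
  )
}

#' Validate a run configuration
#'
#' Structural and range checks: required sections and fields present, scale in
#' (0, 1] and large enough that the smallest population keeps at least 10
#' neurons, probabilities in \[0, 1\], weights and rates non-negative,
#' condition levels valid, and protocol windows consistent
#' (cue ends where the delay begins; delay ends at response onset).
#'
#' @param config Configuration list as from [default_config()].
#' @return Invisibly `TRUE` if valid; otherwise a character vector of error
#'   messages (and nothing is signalled), so callers can report all problems
#'   at once.
#' @export
validate_config <- function(config) {
  errs <- character()
  need <- c("network", "condition", "task", "analysis")
  missing_sec <- setdiff(need, names(config))
  if (length(missing_sec) > 0) {
    return(paste("missing section:", missing_sec))
  }
  nw <- config$network
  if (is.null(nw$scale) || !is.numeric(nw$scale) ||
    nw$scale <= 0 || nw$scale > 1) {
    errs <- c(errs, "network$scale out of range (0, 1]")
  } else {
    smallest <- min(unlist(nw$sizes))
    if (round(nw$scale * smallest) < 10) {
      errs <- c(errs, paste0(
        "network$scale too small: smallest population would have < 10 neurons"
      ))
    }
  }
  p <- c(unlist(nw$p_within), nw$p_between)
  if (any(p < 0 | p > 1)) {
    errs <- c(errs, "connection probabilities must lie in [0, 1]")
  }
  if (any(unlist(nw$weights) < 0)) {
    errs <- c(errs, "base weights must be >= 0")
  }
  cond <- config$condition
  for (fld in c("da", "ne")) {
    if (is.null(cond[[fld]]) || !cond[[fld]] %in% nm_levels()) {
      errs <- c(errs, paste0("condition$", fld, " must be low/optimal/high"))
    }
  }
  tk <- config$task
  for (fld in c(
    "trial_ms", "fixation_ms", "cue_ms", "delay_ms",
    "response_onset_ms", "bg_rate_hz", "cue_rate_hz", "n_trials"
  )) {
    if (is.null(tk[[fld]]) || tk[[fld]] < 0) {
      errs <- c(errs, paste0("task$", fld, " missing or negative"))
    }
  }
  if (!is.null(tk$fixation_ms) && !is.null(tk$cue_ms) &&
    !is.null(tk$delay_ms) && !is.null(tk$response_onset_ms)) {
    if (tk$fixation_ms + tk$cue_ms + tk$delay_ms != tk$response_onset_ms) {
      errs <- c(errs, "fixation + cue + delay must equal response onset")
    }
    if (!is.null(tk$trial_ms) && tk$response_onset_ms >= tk$trial_ms) {
      errs <- c(errs, "response onset must precede trial end")
    }
  }
  if (!is.null(tk$cue_direction) && !tk$cue_direction %in% c(0, 90, 180, 270)) {
    errs <- c(errs, "task$cue_direction must be one of 0, 90, 180, 270")
  }
  if (length(errs) > 0) {
    return(errs)
  }
  invisible(TRUE)
}

#' Read / write a run configuration as YAML
#'
#' The YAML round-trip is lossless for runs: loading an echoed configuration
#' reproduces identical simulations.
#'
#' @param path File path.
#' @param config Configuration list.
#' @return `read_run_config()` returns the configuration list;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  errs <- validate_config(config)
  if (!isTRUE(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
      call. = FALSE
    )
  }
  config
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
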