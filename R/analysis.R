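#' Population peristimulus time histogram
#'
#' Bins a population's spikes, converts to rate in Hz
#' (`count / (n_neurons * bin)`), and applies a centered moving average.
#' The unsmoothed rates conserve spike count: `sum(rate * bin * n_neurons)`
#' equals the number of spikes.
#'
#' @param spikes Spike tibble with columns `population`, `time_ms`.
#' @param population Population name to select.
#' @param n_neurons Number of neurons in that population.
#' @param t_ms Duration covered (ms).
#' @param bin_ms Bin width in ms (> 0).
#' @param smooth_bins Width of the moving average in bins (odd; 1 = none).
#' @return A `pfc_psth` tibble with `time_ms` (bin centers), `rate_hz`
#'   (smoothed) and `rate_raw_hz`.
#' @export
compute_psth <- function(spikes, population, n_neurons, t_ms = 6000,
                         bin_ms = 10, smooth_bins = 5) {
  stopifnot(bin_ms > 0, n_neurons >= 1)
  times <- spikes$time_ms[spikes$population == population]
  breaks <- seq(0, t_ms, by = bin_ms)
  counts <- graphics::hist(times, breaks = breaks, plot = FALSE, right = FALSE)$counts
  rate <- counts / (n_neurons * bin_ms / 1000)
  sm <- if (smooth_bins > 1) {
    as.numeric(stats::filter(rate, rep(1 / smooth_bins, smooth_bins), sides = 2))
  } else {
    rate
  }
  out <- tibble::tibble(
    time_ms = breaks[-length(breaks)] + bin_ms / 2,
    rate_hz = sm, rate_raw_hz = rate, population = population
  )
  class(out) <- c("pfc_psth", class(out))
  out
}

# per-neuron firing rates (Hz) within a window for one population;
# includes silent neurons as zeros
per_neuron_rates <- function(spikes, network, population, window) {
  pop <- network$populations[network$populations$name == population, ]
  stopifnot(nrow(pop) == 1, pop$size >= 1)
  sel <- spikes$population == population &
    spikes$time_ms >= window[1] & spikes$time_ms < window[2]
  counts <- tabulate(spikes$neuron[sel] - pop$start + 1L, nbins = pop$size)
  counts / ((window[2] - window[1]) / 1000)
}

#' Compare delay-period rates between preferred and non-preferred columns
#'
#' Computes per-neuron firing rates over a delay window for the
#' cue-preferring and a non-preferred layer-3 excitatory population, and
#' compares them with a Welch two-sample t-test. In the optimal condition the
#' preferred column should fire persistently at a higher rate (the working
#' memory trace); at low or high neuromodulator levels the two converge.
#'
#' @param spikes Spike tibble from a single trial.
#' @param network The `pfc_network` the spikes came from.
#' @param preferred,non_preferred Population names (e.g. `"L3e_0"`,
#'   `"L3e_90"`).
#' @param window Delay window `c(start, end)` in ms; by default the
#'   configured delay window which excludes the 200-ms post-cue transient.
#' @return A `pfc_rate_comparison` list: `mean_pref`, `mean_npref` (Hz),
#'   `statistic` (Welch t), `p_value`, `df`, plus the rate vectors.
#' @export
delay_rate_comparison <- function(spikes, network,
                                  preferred = "L3e_0",
                                  non_preferred = "L3e_90",
                                  window = NULL) {
  if (is.null(window)) {
    window <- c(
      network$config$analysis$delay_start_ms,
      network$config$analysis$delay_end_ms
    )
  }
  r_pref <- per_neuron_rates(spikes, network, preferred, window)
  r_npref <- per_neuron_rates(spikes, network, non_preferred, window)
  if (length(r_pref) < 2 || length(r_npref) < 2) {
    stop("need at least 2 neurons per group", call. = FALSE)
  }
  tt <- if (stats::sd(r_pref) == 0 && stats::sd(r_npref) == 0) {
    # degenerate: identical constant vectors give t = 0, p = 1
    list(statistic = c(t = 0), p.value = 1, parameter = c(df = NA_real_))
  } else {
    stats::t.test(r_pref, r_npref, var.equal = FALSE)
  }
  structure(
    list(
      preferred = preferred, non_preferred = non_preferred,
      window = window,
      mean_pref = mean(r_pref), mean_npref = mean(r_npref),
      statistic = unname(tt$statistic), p_value = tt$p.value,
      df = unname(tt$parameter), rates_pref = r_pref, rates_npref = r_npref
    ),
    class = "pfc_rate_comparison"
  )
}

#' @export
print.pfc_rate_comparison <- function(x, ...) {
  cat(sprintf(
    "<pfc_rate_comparison> %s %.2f Hz vs %s %.2f Hz (Welch t = %.2f, p = %.3g)\n",
    x$preferred, x$mean_pref, x$non_preferred, x$mean_npref,
    x$statistic, x$p_value
  ))
  invisible(x)
}

#' Delay-activity and behavior grid over the 3x3 condition space
#'
#' Simulates every (DA, NE) level combination: one spike-recorded trial per
#' condition for delay-period rates of the preferred (cued) and a
#' non-preferred layer-3 column, plus `n_trials` trials for the behavioral
#' summary. The returned grid carries the inverted-U structure: the
#' preferred-minus-non-preferred rate difference peaks at optimal DA and NE
#' and shrinks toward the extremes.
#'
#' @param config Run configuration.
#' @param network Optional pre-built network.
#' @param n_trials Behavioral trials per condition (0 skips behavior).
#' @param rate_seed Seed for the rate trial of each condition.
#' @return A tibble with one row per condition: `da`, `ne`, `rate_pref`,
#'   `rate_npref` (Hz), `rate_diff`, `t_statistic`, `p_value`, and when
#'   behavior was run, `pct_correct`, `pct_incorrect`, `pct_null`.
#' @export
inverted_u_grid <- function(config = default_config(), network = NULL,
                            n_trials = 0, rate_seed = config$network$seed) {
  if (is.null(network)) network <- build_network(config)
  schedule <- build_trial_schedule(config$task$cue_direction, config)
  conds <- tidyr::expand_grid(da = nm_levels(), ne = nm_levels())
  pref <- paste0("L3e_", config$task$cue_direction)
  npref_dir <- setdiff(directions(), config$task$cue_direction)[1]
  npref <- paste0("L3e_", npref_dir)
  rows <- purrr::pmap(conds, function(da, ne) {
    compiled <- compile_network(network, da, ne)
    tr <- run_trial(compiled, schedule,
      seed = derive_seed(rate_seed, which(conds$da == da & conds$ne == ne)[1], 0),
      t_ms = config$analysis$delay_end_ms
    )
    cmpr <- delay_rate_comparison(tr$spikes, network, pref, npref)
    tibble::tibble(
      da = da, ne = ne,
      rate_pref = cmpr$mean_pref, rate_npref = cmpr$mean_npref,
      rate_diff = cmpr$mean_pref - cmpr$mean_npref,
      t_statistic = cmpr$statistic, p_value = cmpr$p_value
    )
  })
  grid <- dplyr::bind_rows(rows)
  if (n_trials > 0) {
    beh <- run_experiment(config,
      network = network, sweep = TRUE,
      n_trials = n_trials
    )$summary
    grid <- dplyr::left_join(grid, beh, by = c("da", "ne"))
  }
  class(grid) <- c("pfc_inverted_u", class(grid))
  grid
}

#' Accuracy of a direct layer-3 readout
#'
#' Applies the same argmax spike-count readout used for the motor decision
#' directly to the four layer-3 excitatory columns over the decision window.
#' Comparing this with the motor-output accuracy quantifies how much the
#' motor layer's lateral inhibition filters working-memory noise: under low
#' DA the motor readout should match or beat the direct cortical readout.
#'
#' @param spikes Spike tibble of one trial.
#' @param schedule The trial's `pfc_schedule`.
#' @param network The `pfc_network`.
#' @return One-row tibble with `decision`, `correct`, `null_response`.
#' @export
l3_readout <- function(spikes, schedule, network) {
  win_end <- network$config$task$response_onset_ms
  win_start <- win_end - network$config$analysis$decision_window_ms
  counts <- vapply(directions(), function(d) {
    sum(spikes$population == paste0("L3e_", d) &
      spikes$time_ms >= win_start & spikes$time_ms < win_end)
  }, numeric(1))
  names(counts) <- as.character(directions())
  dec <- decide_saccade(counts)
  tibble::tibble(
    decision = dec,
    correct = !is.na(dec) && dec == schedule$cue_direction,
    null_response = is.na(dec)
  )
}

#' Calibrate base synaptic weights
#'
#' Coordinate search over a small set of base weights, minimising a
#' lexicographic objective on short optimal-condition trials: first satisfy
#' persistence (the cued column still firing above a floor at the end of the
#' delay), then minimise squared error of the preferred/non-preferred
#' delay-period rates against the targets (~20 Hz and ~10 Hz). Each
#' evaluation builds the network with the candidate weights and simulates one
#' trial up to the end of the delay. Deterministic given `seed`.
#'
#' @param config Starting configuration (its weights seed the search).
#' @param param_names Weight names to search over.
#' @param targets Named vector `c(pref = 20, npref = 10)` in Hz.
#' @param budget Maximum number of trial evaluations.
#' @param step Initial multiplicative step per coordinate.
#' @param persist_floor Minimum preferred-column rate (Hz) over the last
#'   500 ms of the delay to count as persistent.
#' @param seed Seed controlling the evaluation trials.
#' @return A list with `weights` (full calibrated weight list), `loss`,
#'   `persistent` (logical), `rate_pref`, `rate_npref`, `evaluations`, and
#'   `config` (the input configuration with calibrated weights substituted).
#' @export
calibrate_weights <- function(config = default_config(),
                              param_names = c("rec_l3", "l3_ie", "pc_l3"),
                              targets = c(pref = 20, npref = 10),
                              budget = 30, step = 1.3,
                              persist_floor = 5, seed = 1) {
  stopifnot(budget >= 1)
  delay_end <- config$analysis$delay_end_ms
  pref <- paste0("L3e_", config$task$cue_direction)
  npref_dir <- setdiff(directions(), config$task$cue_direction)[1]
  npref <- paste0("L3e_", npref_dir)

  evaluate <- function(weights) {
    cfg <- config
    cfg$network$weights[names(weights)] <- weights
    network <- build_network(cfg, seed = cfg$network$seed)
    compiled <- compile_network(network, "optimal", "optimal")
    schedule <- build_trial_schedule(cfg$task$cue_direction, cfg)
    tr <- run_trial(compiled, schedule, seed = seed, t_ms = delay_end)
    cmpr <- delay_rate_comparison(tr$spikes, network, pref, npref)
    tail_rate <- mean(per_neuron_rates(
      tr$spikes, network, pref, c(delay_end - 500, delay_end)
    ))
    persistent <- tail_rate >= persist_floor
    loss <- (cmpr$mean_pref - targets[["pref"]])^2 +
      (cmpr$mean_npref - targets[["npref"]])^2
    list(
      persistent = persistent, loss = loss,
      rate_pref = cmpr$mean_pref, rate_npref = cmpr$mean_npref
    )
  }
  better <- function(a, b) {
    # persistence dominates; rate error only compared within the same tier
    if (a$persistent != b$persistent) {
      return(a$persistent)
    }
    a$loss < b$loss
  }

  weights <- unlist(config$network$weights[param_names])
  best <- evaluate(weights)
  n_eval <- 1
  improved <- TRUE
  while (improved && n_eval < budget) {
    improved <- FALSE
    for (pn in param_names) {
      for (fac in c(step, 1 / step)) {
        if (n_eval >= budget) break
        cand <- weights
        cand[pn] <- cand[pn] * fac
        res <- evaluate(cand)
        n_eval <- n_eval + 1
        if (better(res, best)) {
          best <- res
          weights <- cand
          improved <- TRUE
        }
      }
    }
  }
  out_cfg <- config
  out_cfg$network$weights[names(weights)] <- as.list(weights)
  if (!best$persistent) {
    warning("calibration budget exhausted without persistent activity; ",
      "returning best candidate found",
      call. = FALSE
    )
  }
  list(
    weights = out_cfg$network$weights, loss = best$loss,
    persistent = best$persistent, rate_pref = best$rate_pref,
    rate_npref = best$rate_npref, evaluations = n_eval, config = out_cfg
  )
}
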