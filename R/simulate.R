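#' Compile a network for one neuromodulatory condition
#'
#' Folds the condition's synaptic gain factors into per-synapse effective
#' weights (fast channel = AMPA or GABA-A, slow channel = NMDA or GABA-B),
#' flattens all projections into a compressed sparse row structure ordered by
#' presynaptic neuron, and attaches the per-neuron total-current gain. The
#' result is what the compiled simulation core consumes; compiling once per
#' condition amortises the work across trials.
#'
#' @param network A `pfc_network` from [build_network()].
#' @param da,ne Neuromodulator levels (`"low"`, `"optimal"`, `"high"`).
#' @return A `pfc_compiled` object.
#' @export
compile_network <- function(network, da, ne) {
  check_level(da, "DA")
  check_level(ne, "NE")
  modl3i <- isTRUE(network$config$modulation$modulate_l3_inhibitory)
  pre <- integer(0); post <- integer(0)
  wf <- numeric(0); ws <- numeric(0)
  for (pr in network$projections) {
    if (pr$excitatory) {
      f_fast <- synaptic_factor(da, ne, pr$conn_class, "ampa")
      f_slow <- synaptic_factor(da, ne, pr$conn_class, "nmda")
    } else {
      f_fast <- synaptic_factor(da, ne, pr$conn_class, "gabaa")
      f_slow <- synaptic_factor(da, ne, pr$conn_class, "gabab")
    }
    pre <- c(pre, pr$pre)
    post <- c(post, pr$post)
    wf <- c(wf, pr$w * f_fast)
    ws <- c(ws, pr$w * f_slow)
  }
  ord <- order(pre)
  pre <- pre[ord]; post <- post[ord]; wf <- wf[ord]; ws <- ws[ord]
  ptr <- c(0L, cumsum(tabulate(pre, nbins = network$n_neurons)))
  mu_i <- vapply(
    network$neurons$population,
    function(g) current_factor(da, ne, g, modl3i),
    numeric(1)
  )
  structure(
    list(
      network = network, da = da, ne = ne,
      csr_ptr = as.integer(ptr), csr_post = as.integer(post - 1L),
      w_fast = wf, w_slow = ws, mu_i = unname(mu_i)
    ),
    class = "pfc_compiled"
  )
}

#' Simulate one trial
#'
#' Generates the trial's Poisson drive events from the schedule, runs the
#' compiled network for the full trial, and returns the spikes together with
#' the saccade decision from the motor-output accumulator readout.
#'
#' @param compiled A `pfc_compiled` network-condition object.
#' @param schedule A `pfc_schedule` from [build_trial_schedule()].
#' @param seed Trial seed (drives and tie-breaking).
#' @param t_ms Optional override of the simulated duration (ms); shorter runs
#'   are useful when only delay-period activity is needed.
#' @return A list with `spikes` (tibble: `neuron`, `time_ms`, `population`)
#'   and `outcome` (one-row tibble from [decide_saccade()] applied to the
#'   decision window).
#' @export
run_trial <- function(compiled, schedule, seed, t_ms = schedule$trial_ms) {
  network <- compiled$network
  set.seed(seed)
  drv <- trial_drive_events(network, schedule)
  keep <- drv$ms < t_ms
  res <- simulate_trial_cpp(
    network$n_neurons,
    network$neurons$a, network$neurons$b, network$neurons$c,
    network$neurons$d, compiled$mu_i, network$neurons$excitatory,
    compiled$csr_ptr, compiled$csr_post, compiled$w_fast, compiled$w_slow,
    drv$ms[keep], as.integer(drv$target[keep] - 1L), drv$w[keep],
    as.integer(t_ms)
  )
  spikes <- tibble::tibble(
    neuron = res$neuron, time_ms = res$time_ms,
    population = network$neurons$population[res$neuron]
  )
  outcome <- trial_outcome(spikes, schedule, network)
  list(spikes = spikes, outcome = outcome)
}

# decision-window MOT counts and the saccade decision for one trial
trial_outcome <- function(spikes, schedule, network) {
  win_end <- network$config$task$response_onset_ms
  win_start <- win_end - network$config$analysis$decision_window_ms
  counts <- vapply(directions(), function(d) {
    sum(spikes$population == paste0("MOTe_", d) &
      spikes$time_ms >= win_start & spikes$time_ms < win_end)
  }, numeric(1))
  names(counts) <- as.character(directions())
  dec <- decide_saccade(counts)
  tibble::tibble(
    cue = schedule$cue_direction,
    decision = dec,
    correct = !is.na(dec) && dec == schedule$cue_direction,
    null_response = is.na(dec),
    mot_0 = counts[["0"]], mot_90 = counts[["90"]],
    mot_180 = counts[["180"]], mot_270 = counts[["270"]]
  )
}

# deterministic per-trial seed derived from the master seed; kept < 2^31
derive_seed <- function(master, condition_index, trial_index) {
  as.integer((as.double(master) * 7919 + condition_index * 104729 +
    trial_index * 13) %% 2147483647)
}

#' Run a full experiment
#'
#' Simulates `n_trials` oculomotor delayed-response trials per condition. In
#' sweep mode all nine (DA, NE) level combinations are run; otherwise the
#' single condition in the configuration. Per-trial seeds derive
#' deterministically from the master seed, so identical configurations give
#' identical outcome tables.
#'
#' @param config Run configuration.
#' @param network Optionally a pre-built `pfc_network` (rebuilt from `config`
#'   when `NULL`).
#' @param sweep If `TRUE`, run the full 3x3 condition grid.
#' @param n_trials Override of `config$task$n_trials`.
#' @param keep_spikes Keep per-trial spike tibbles (memory-heavy; default
#'   keeps outcomes only).
#' @param t_ms Optional trial-duration override (ms).
#' @param progress Print a line per condition.
#' @return A `pfc_experiment`: list with `outcomes` (tibble: one row per
#'   trial with condition labels, decision, correctness, MOT counts),
#'   `summary` (from [summarize_behavior()]), and optionally `spikes`.
#' @export
run_experiment <- function(config = default_config(), network = NULL,
                           sweep = FALSE, n_trials = config$task$n_trials,
                           keep_spikes = FALSE, t_ms = NULL,
                           progress = FALSE) {
  errs <- validate_config(config)
  if (!isTRUE(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
      call. = FALSE
    )
  }
  if (is.null(network)) network <- build_network(config)
  conds <- if (sweep) {
    tidyr::expand_grid(da = nm_levels(), ne = nm_levels())
  } else {
    tibble::tibble(da = config$condition$da, ne = config$condition$ne)
  }
  schedule <- build_trial_schedule(config$task$cue_direction, config)
  t_ms <- if (is.null(t_ms)) schedule$trial_ms else t_ms
  outcomes <- list()
  spikes <- if (keep_spikes) list() else NULL
  for (ci in seq_len(nrow(conds))) {
    compiled <- compile_network(network, conds$da[ci], conds$ne[ci])
    if (progress) {
      message(sprintf("condition DA=%s NE=%s", conds$da[ci], conds$ne[ci]))
    }
    for (tr in seq_len(n_trials)) {
      res <- run_trial(
        compiled, schedule,
        seed = derive_seed(config$network$seed, ci, tr), t_ms = t_ms
      )
      outcomes[[length(outcomes) + 1]] <- dplyr::mutate(
        res$outcome,
        da = conds$da[ci], ne = conds$ne[ci], trial = tr, .before = 1
      )
      if (keep_spikes) {
        spikes[[length(spikes) + 1]] <- dplyr::mutate(
          res$spikes,
          da = conds$da[ci], ne = conds$ne[ci], trial = tr
        )
      }
    }
  }
  outcomes <- dplyr::bind_rows(outcomes)
  structure(
    list(
      outcomes = outcomes,
      summary = summarize_behavior(outcomes),
      spikes = if (keep_spikes) dplyr::bind_rows(spikes) else NULL,
      config = config
    ),
    class = "pfc_experiment"
  )
}

#' @export
print.pfc_experiment <- function(x, ...) {
  cat(sprintf(
    "<pfc_experiment> %d trials over %d condition(s)\n",
    nrow(x$outcomes), nrow(x$summary)
  ))
  print(x$summary)
  invisible(x)
}
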