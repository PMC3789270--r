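#' Izhikevich cell-class parameters
#'
#' Returns the `(a, b, c, d)` parameter set of the two-variable Izhikevich
#' point neuron for one of the two cell classes used in the model: regular
#' spiking (RS) for excitatory cortical neurons and fast spiking (FS) for
#' inhibitory interneurons.
#'
#' @param cell_class `"regular_spiking_excitatory"` or
#'   `"fast_spiking_inhibitory"`.
#'
#' @return A one-row tibble with columns `cell_class`, `a` (recovery
#'   time-scale, 1/ms), `b` (recovery sensitivity), `c` (reset potential, mV),
#'   `d` (reset recovery increment) and `excitatory` (logical).
#'
#' @examples
#' neuron_params("regular_spiking_excitatory")
#' @export
neuron_params <- function(cell_class = c(
                            "regular_spiking_excitatory",
                            "fast_spiking_inhibitory"
                          )) {
  cell_class <- match.arg(cell_class)
  if (cell_class == "regular_spiking_excitatory") {
    tibble::tibble(
      cell_class = cell_class,
      a = 0.01, b = 0.2, c = -65.0, d = 8.0, excitatory = TRUE
    )
  } else {
    tibble::tibble(
      cell_class = cell_class,
      a = 0.1, b = 0.2, c = -65.0, d = 2.0, excitatory = FALSE
    )
  }
}

#' Initialise a neuron population state
#'
#' Members start at the reset potential `c` with the recovery variable at its
#' nullcline value `b * v`, i.e. the quiescent fixed point of the dynamics in
#' the absence of input.
#'
#' @param n Number of neurons.
#' @param params A parameter row from [neuron_params()].
#'
#' @return A list with numeric vectors `v` (mV), `u` and logical `spiked`.
#' @export
init_population <- function(n, params) {
  v <- rep(params$c, n)
  list(v = v, u = params$b * v, spiked = rep(FALSE, n))
}

#' Advance a neuron population by one integration step
#'
#' One forward-Euler step of the Izhikevich dynamics
#' \deqn{\dot v = 0.04 v^2 + 5 v + 140 - u - \mu_I I_{syn}}
#' \deqn{\dot u = a (b v - u)}
#' with the reset rule: any neuron whose pre-reset voltage reaches the 30 mV
#' spike cutoff is flagged as spiking, reset to `v = c`, and has its recovery
#' variable set to the entry value plus `d` (the reset replaces the recovery
#' integration for that step). The synaptic
#' current `I_syn` follows the conductance driving-force convention of
#' [synaptic_current()], in which inward (depolarising) current is negative;
#' it therefore enters the voltage equation with a minus sign. The
#' neuromodulatory gain `mu_I` scales the total synaptic current (alpha-1 /
#' high-D1 input block).
#'
#' The cutoff comparison is `v >= 30` so numerical overshoot past 30 mV still
#' triggers a spike. Within a step, `v` is advanced first and `u` is advanced
#' using the updated `v` (the conventional discretisation for this model).
#'
#' @param state Population state from [init_population()].
#' @param params Parameter row from [neuron_params()].
#' @param I_syn Synaptic current per neuron (conductance units times mV).
#' @param mu_I Scalar current gain (> 0); 1 means unmodulated.
#' @param dt Time step in ms (> 0).
#'
#' @return The updated state; `spiked` flags neurons that crossed the cutoff
#'   during this step.
#' @export
step_population <- function(state, params, I_syn, mu_I = 1, dt = 0.5) {
  stopifnot(dt > 0, mu_I > 0, all(is.finite(I_syn)))
  v0 <- state$v
  u0 <- state$u
  v <- v0 + dt * (0.04 * v0^2 + 5 * v0 + 140 - u0 - mu_I * I_syn)
  spiked <- v >= 30 | v0 >= 30
  u <- u0 + dt * (params$a * (params$b * v - u0))
  v[spiked] <- params$c
  u[spiked] <- u0[spiked] + params$d
  # conductance inhibition cannot drive v below the most negative reversal
  # potential (-90 mV, GABA-B); below the quadratic's lower root the model
  # is invalid and a clamped floor keeps strong inhibition physical
  v <- pmax(v, -90)
  if (any(!is.finite(v)) || any(!is.finite(u))) {
    stop("non-finite membrane state: numerical blow-up (is dt too large?)",
      call. = FALSE
    )
  }
  list(v = v, u = u, spiked = spiked)
}
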