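#' Synaptic decay time constants
#'
#' Decay constants (ms) of the four conductance channels, in the fixed order
#' AMPA, NMDA, GABA-A, GABA-B.
#'
#' @return Named numeric vector `c(ampa = 5, nmda = 100, gabaa = 6, gabab = 150)`.
#' @export
synapse_tau <- function() {
  c(ampa = 5, nmda = 100, gabaa = 6, gabab = 150)
}

#' Initialise per-neuron synaptic conductances
#'
#' @param n Number of neurons.
#' @return A list of four zero vectors `g_ampa`, `g_nmda`, `g_gabaa`, `g_gabab`.
#' @export
init_conductances <- function(n) {
  z <- numeric(n)
  list(g_ampa = z, g_nmda = z, g_gabaa = z, g_gabab = z)
}

#' Decay synaptic conductances over one step
#'
#' Each channel obeys the first-order law \eqn{\dot g_i = -g_i / \tau_i}; the
#' update multiplies by the exact factor \eqn{e^{-dt/\tau_i}} rather than a
#' forward-Euler approximation, so the step is unconditionally stable and
#' exact for any `dt`.
#'
#' @param g Conductance state from [init_conductances()].
#' @param dt Step in ms (> 0).
#' @param tau Named decay constants, defaults to [synapse_tau()].
#' @return Updated conductance state.
#'
#' @examples
#' g <- init_conductances(1)
#' g$g_ampa <- 1
#' decay_conductances(g, 5)$g_ampa # exp(-1)
#' @export
decay_conductances <- function(g, dt, tau = synapse_tau()) {
  stopifnot(dt > 0)
  list(
    g_ampa = g$g_ampa * exp(-dt / tau[["ampa"]]),
    g_nmda = g$g_nmda * exp(-dt / tau[["nmda"]]),
    g_gabaa = g$g_gabaa * exp(-dt / tau[["gabaa"]]),
    g_gabab = g$g_gabab * exp(-dt / tau[["gabab"]])
  )
}

#' Apply presynaptic spikes to postsynaptic conductances
#'
#' For every presynaptic neuron that fired, each of its synapses increments
#' the target's conductances by the synaptic weight times the neuromodulatory
#' channel factor: excitatory sources add `w * mu["ampa"]` to AMPA and
#' `w * mu["nmda"]` to NMDA; inhibitory sources add `w * mu["gabaa"]` to
#' GABA-A and `w * mu["gabab"]` to GABA-B. Convergent spikes accumulate.
#'
#' @param g Postsynaptic conductance state.
#' @param projection A list with integer vectors `pre`, `post` (1-based
#'   indices into the pre/post populations), numeric `w` per synapse, and
#'   logical `excitatory` (class of the source population).
#' @param spiked_pre Logical vector over the presynaptic population.
#' @param mu Named channel factors (`ampa`, `nmda`, `gabaa`, `gabab`), all > 0;
#'   unlisted channels default to 1.
#' @return Updated conductance state.
#' @export
on_presynaptic_spikes <- function(g, projection, spiked_pre,
                                  mu = c(ampa = 1, nmda = 1, gabaa = 1, gabab = 1)) {
  mu_full <- c(ampa = 1, nmda = 1, gabaa = 1, gabab = 1)
  mu_full[names(mu)] <- mu
  stopifnot(all(mu_full > 0))
  active <- spiked_pre[projection$pre]
  if (!any(active)) {
    return(g)
  }
  post <- projection$post[active]
  if (any(post < 1) || any(post > length(g$g_ampa))) {
    stop("projection adjacency index out of range", call. = FALSE)
  }
  w <- projection$w[active]
  if (isTRUE(projection$excitatory)) {
    inc_a <- vapply(
      split(w * mu_full[["ampa"]], post), sum,
      numeric(1)
    )
    idx <- as.integer(names(inc_a))
    g$g_ampa[idx] <- g$g_ampa[idx] + inc_a
    inc_n <- vapply(split(w * mu_full[["nmda"]], post), sum, numeric(1))
    g$g_nmda[idx] <- g$g_nmda[idx] + inc_n
  } else {
    inc_a <- vapply(split(w * mu_full[["gabaa"]], post), sum, numeric(1))
    idx <- as.integer(names(inc_a))
    g$g_gabaa[idx] <- g$g_gabaa[idx] + inc_a
    inc_b <- vapply(split(w * mu_full[["gabab"]], post), sum, numeric(1))
    g$g_gabab[idx] <- g$g_gabab[idx] + inc_b
  }
  g
}

#' Voltage dependence of the NMDA channel
#'
#' The magnesium-block gating term
#' \deqn{h(v) = \frac{[(v+80)/60]^2}{1 + [(v+80)/60]^2}}
#' which vanishes at -80 mV and saturates toward 1 with depolarisation.
#'
#' @param v Membrane potential (mV).
#' @return Gating value in `[0, 1)`.
#' @export
nmda_gating <- function(v) {
  x <- ((v + 80) / 60)^2
  x / (1 + x)
}

#' Total synaptic current
#'
#' Conductance-based current with reversal potentials 0 mV (AMPA, NMDA),
#' -70 mV (GABA-A) and -90 mV (GABA-B):
#' \deqn{I = g_{A}(v-0) + g_{N} h(v) (v-0) + g_{GA}(v+70) + g_{GB}(v+90)}
#' With this convention inward (depolarising) current is negative; the neuron
#' step subtracts `mu_I * I` from the voltage derivative.
#'
#' @param v Membrane potential per neuron (mV), finite.
#' @param g Conductance state.
#' @return Current per neuron.
#' @export
synaptic_current <- function(v, g) {
  stopifnot(all(is.finite(v)))
  g$g_ampa * v + g$g_nmda * nmda_gating(v) * v +
    g$g_gabaa * (v + 70) + g$g_gabab * (v + 90)
}
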