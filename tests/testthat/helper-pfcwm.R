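# Shared fixtures: one desk-scale network reused across tests (construction
# is deterministic, so sharing does not couple tests), plus an R-level
# reference simulator mirroring the compiled core step for step.

test_config <- function(...) {
  cfg <- default_config(scale = 0.1, seed = 1)
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
  cfg
}

local_network_cache <- new.env(parent = emptyenv())

shared_network <- function() {
  if (is.null(local_network_cache$nw)) {
    local_network_cache$nw <- build_network(test_config())
  }
  local_network_cache$nw
}

# Pure-R trial simulator on an arbitrary small circuit, matching the engine's
# scheme: 1-ms synaptic slots, exact conductance decay, 1-ms transmission
# delay, current evaluated once per slot, two half-step Euler updates with
# the reset rule. Used as an independent cross-check of the compiled core.
r_reference_trial <- function(params_per_neuron, excitatory, projections,
                              drive, t_ms, mu_i = NULL, substeps = 2) {
  n <- length(excitatory)
  if (is.null(mu_i)) mu_i <- rep(1, n)
  v <- vapply(params_per_neuron, function(p) p$c, numeric(1))
  u <- vapply(params_per_neuron, function(p) p$b, numeric(1)) * v
  g <- init_conductances(n)
  tau <- synapse_tau()
  prev_spiked <- rep(FALSE, n)
  spikes <- list()
  dt <- 1 / substeps
  for (t in seq_len(t_ms) - 1L) {
    g <- decay_conductances(g, 1)
    for (pr in projections) {
      g <- on_presynaptic_spikes(g, pr, prev_spiked)
    }
    hit <- drive$ms == t
    if (any(hit)) {
      for (k in which(hit)) {
        g$g_ampa[drive$target[k]] <- g$g_ampa[drive$target[k]] + drive$w[k]
        g$g_nmda[drive$target[k]] <- g$g_nmda[drive$target[k]] + drive$w[k]
      }
    }
    I <- synaptic_current(v, g)
    fired <- rep(FALSE, n)
    for (s in seq_len(substeps)) {
      v0 <- v
      u0 <- u
      v <- v0 + dt * (0.04 * v0^2 + 5 * v0 + 140 - u0 - mu_i * I)
      sp <- v >= 30
      u <- u0 + dt * vapply(params_per_neuron, function(p) p$a, numeric(1)) *
        (vapply(params_per_neuron, function(p) p$b, numeric(1)) * v - u0)
      cvec <- vapply(params_per_neuron, function(p) p$c, numeric(1))
      dvec <- vapply(params_per_neuron, function(p) p$d, numeric(1))
      v[sp] <- cvec[sp]
      u[sp] <- u0[sp] + dvec[sp]
      v <- pmax(v, -90)
      fired <- fired | sp
    }
    prev_spiked <- fired
    if (any(fired)) {
      spikes[[length(spikes) + 1]] <- data.frame(
        neuron = which(fired), time_ms = t
      )
    }
  }
  if (length(spikes) == 0) {
    return(data.frame(neuron = integer(), time_ms = integer()))
  }
  do.call(rbind, spikes)
}
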