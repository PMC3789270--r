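test_that("conductance decay follows the closed-form exponential", {
  g <- init_conductances(1)
  g$g_ampa <- 1
  g$g_nmda <- 2
  out <- decay_conductances(g, 5)
  expect_equal(out$g_ampa, exp(-1)) # tau_AMPA = 5 ms
  out100 <- decay_conductances(g, 100)
  expect_equal(out100$g_nmda, 2 * exp(-1)) # tau_NMDA = 100 ms
  z <- decay_conductances(init_conductances(3), 17)
  expect_equal(unlist(z), rep(0, 12), ignore_attr = TRUE) # zero fixed point
})

test_that("decay time constants are (5, 100, 6, 150) ms", {
  expect_equal(
    synapse_tau(),
    c(ampa = 5, nmda = 100, gabaa = 6, gabab = 150)
  )
})

test_that("spike-triggered increments apply weight times channel gain", {
  g <- init_conductances(2)
  pr <- list(pre = 1L, post = 2L, w = 0.5, excitatory = TRUE)
  out <- on_presynaptic_spikes(g, pr, c(TRUE), mu = c(ampa = 0.1, nmda = 15))
  expect_equal(out$g_ampa[2], 0.05)
  expect_equal(out$g_nmda[2], 7.5)
  expect_equal(out$g_ampa[1], 0)

  # inhibitory source targets the GABA channels
  pri <- list(pre = 1L, post = 2L, w = 0.4, excitatory = FALSE)
  outi <- on_presynaptic_spikes(g, pri, c(TRUE))
  expect_equal(outi$g_gabaa[2], 0.4)
  expect_equal(outi$g_gabab[2], 0.4)
  expect_equal(outi$g_ampa[2], 0)

  # no spikes: identity
  expect_identical(on_presynaptic_spikes(g, pr, c(FALSE)), g)

  # convergent spikes accumulate
  pr2 <- list(pre = c(1L, 2L), post = c(1L, 1L), w = c(1, 1), excitatory = TRUE)
  g3 <- on_presynaptic_spikes(init_conductances(2), pr2, c(TRUE, TRUE))
  expect_equal(g3$g_ampa[1], 2)
})

test_that("out-of-range adjacency fails loudly", {
  g <- init_conductances(2)
  pr <- list(pre = 1L, post = 5L, w = 1, excitatory = TRUE)
  expect_error(on_presynaptic_spikes(g, pr, TRUE), "out of range")
})

test_that("total synaptic current matches the driving-force form", {
  g <- init_conductances(1)
  g$g_nmda <- 5
  expect_equal(synaptic_current(-80, g), 0) # NMDA gating vanishes at -80 mV
  g$g_nmda <- 1
  expect_equal(synaptic_current(-20, g), 0.5 * (-20)) # h(-20) = 1/2
  g <- init_conductances(1)
  g$g_gabaa <- 3
  expect_equal(synaptic_current(-70, g), 0) # GABA-A reversal
  g$g_gabab <- 2
  expect_equal(synaptic_current(-90, g), 3 * (-90 + 70)) # GABA-B reversal
})

test_that("conductances stay non-negative under decay and increments", {
  set.seed(4)
  g <- init_conductances(10)
  pr <- list(
    pre = sample(1:10, 30, TRUE), post = sample(1:10, 30, TRUE),
    w = runif(30), excitatory = TRUE
  )
  for (i in 1:50) {
    g <- decay_conductances(g, 1)
    g <- on_presynaptic_spikes(g, pr, runif(10) < 0.3)
    expect_true(all(unlist(g) >= 0))
  }
})

test_that("conductance response is linear in the presynaptic spike trains", {
  pr <- list(pre = c(1L, 2L), post = c(3L, 3L), w = c(0.3, 0.7), excitatory = TRUE)
  run <- function(spike_mat) {
    g <- init_conductances(3)
    for (t in seq_len(nrow(spike_mat))) {
      g <- decay_conductances(g, 1)
      g <- on_presynaptic_spikes(g, pr, spike_mat[t, ])
    }
    g
  }
  set.seed(11)
  a <- matrix(runif(40) < 0.3, 20)
  b <- matrix(runif(40) < 0.3, 20)
  both <- run(a | b)
  overlap <- run(a & b)
  ga <- run(a)
  gb <- run(b)
  # superposition: response(a) + response(b) = response(union) + response(overlap)
  expect_equal(ga$g_ampa + gb$g_ampa, both$g_ampa + overlap$g_ampa)
  expect_equal(ga$g_nmda + gb$g_nmda, both$g_nmda + overlap$g_nmda)
})

test_that("AMPA input depolarises and GABA-A input above reversal hyperpolarises", {
  rs <- neuron_params("regular_spiking_excitatory")
  st0 <- list(v = -60, u = -12, spiked = FALSE)
  g <- init_conductances(1)
  base <- step_population(st0, rs, synaptic_current(st0$v, g), dt = 0.5)

  g$g_ampa <- 0.5
  up <- step_population(st0, rs, synaptic_current(st0$v, g), dt = 0.5)
  expect_gt(up$v, base$v)

  g <- init_conductances(1)
  g$g_gabaa <- 0.5
  down <- step_population(st0, rs, synaptic_current(st0$v, g), dt = 0.5)
  expect_lt(down$v, base$v)
})
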