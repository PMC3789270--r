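test_that("the compiled core agrees with the pure-R reference on a microcircuit", {
  # 3 neurons: 1 -> 3 excitatory, 2 -> 3 inhibitory, driven externally
  rs <- as.list(neuron_params("regular_spiking_excitatory"))
  fs <- as.list(neuron_params("fast_spiking_inhibitory"))
  params <- list(rs, fs, rs)
  excit <- c(TRUE, FALSE, TRUE)
  projections <- list(
    list(pre = 1L, post = 3L, w = 0.4, excitatory = TRUE),
    list(pre = 1L, post = 2L, w = 0.6, excitatory = TRUE),
    list(pre = 2L, post = 3L, w = 0.5, excitatory = FALSE)
  )
  set.seed(31)
  n_ev <- 120
  drive <- list(
    ms = sort(sample(0:499, n_ev, replace = TRUE)),
    target = sample(1:2, n_ev, replace = TRUE),
    w = rep(0.35, n_ev)
  )
  ref <- r_reference_trial(params, excit, projections, drive, t_ms = 500)

  # same circuit through the compiled path
  pre <- c(1L, 1L, 2L)
  post <- c(3L, 2L, 3L)
  wf <- c(0.4, 0.6, 0.5)
  ord <- order(pre)
  ptr <- c(0L, cumsum(tabulate(pre[ord], 3)))
  res <- simulate_trial_cpp(
    3, sapply(params, `[[`, "a"), sapply(params, `[[`, "b"),
    sapply(params, `[[`, "c"), sapply(params, `[[`, "d"),
    rep(1, 3), excit,
    as.integer(ptr), as.integer(post[ord] - 1L), wf[ord], wf[ord],
    as.integer(drive$ms), as.integer(drive$target - 1L), drive$w,
    500L
  )
  got <- data.frame(neuron = res$neuron, time_ms = res$time_ms)
  expect_gt(nrow(got), 10) # the circuit is genuinely active
  expect_equal(got$neuron, ref$neuron)
  expect_equal(got$time_ms, ref$time_ms)
})

test_that("condition compilation folds gain factors into effective weights", {
  nw <- shared_network()
  opt <- compile_network(nw, "optimal", "optimal")
  low_ne <- compile_network(nw, "optimal", "low")
  # recurrent NMDA gain is 15 at optimal NE and 10 at low NE, so the summed
  # slow-channel weight must shrink when NE drops
  expect_gt(sum(opt$w_slow), sum(low_ne$w_slow))
  # current gain applies to layer-3 excitatory neurons only
  high <- compile_network(nw, "high", "high")
  l3e <- nw$neurons$population %in% paste0("L3e_", c(0, 90, 180, 270))
  expect_true(all(high$mu_i[l3e] == 0.67))
  expect_true(all(high$mu_i[!l3e] == 1))
  expect_true(all(opt$mu_i == 1))
})

test_that("trials are reproducible and independent across seeds", {
  nw <- shared_network()
  cm <- compile_network(nw, "optimal", "optimal")
  sch <- build_trial_schedule(0, nw$config)
  a <- run_trial(cm, sch, seed = 5, t_ms = 1500)
  b <- run_trial(cm, sch, seed = 5, t_ms = 1500)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$outcome, b$outcome)
  c2 <- run_trial(cm, sch, seed = 6, t_ms = 1500)
  expect_false(identical(a$spikes, c2$spikes))
})

test_that("experiments produce one outcome row per trial and a condition summary", {
  cfg <- test_config()
  cfg$task$n_trials <- 2
  exp1 <- run_experiment(cfg, network = shared_network(), t_ms = 4000)
  expect_equal(nrow(exp1$outcomes), 2)
  expect_equal(nrow(exp1$summary), 1)
  expect_true(all(c("pct_correct", "pct_incorrect", "pct_null") %in%
    names(exp1$summary)))
  expect_equal(
    exp1$summary$pct_correct + exp1$summary$pct_incorrect +
      exp1$summary$pct_null, 100
  )
  # re-running the same configuration reproduces the outcome table exactly
  exp2 <- run_experiment(cfg, network = shared_network(), t_ms = 4000)
  expect_identical(exp1$outcomes, exp2$outcomes)
  # tidiers expose outcomes and the one-line summary
  expect_identical(tidy(exp1), exp1$outcomes)
  expect_equal(glance(exp1)$n_trials, 2)
})

test_that("configuration validation reports structured errors", {
  cfg <- default_config()
  expect_true(validate_config(cfg))
  bad <- cfg
  bad$network$scale <- 0
  expect_match(validate_config(bad), "scale", all = FALSE)
  bad2 <- cfg
  bad2$condition$da <- NULL
  expect_match(validate_config(bad2), "da", all = FALSE)
  bad3 <- cfg
  bad3$task$fixation_ms <- 900
  expect_match(validate_config(bad3), "response onset", all = FALSE)
})

test_that("the YAML round-trip reproduces the configuration", {
  cfg <- default_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back$network$weights, cfg$network$weights)
  expect_equal(back$task, cfg$task, ignore_attr = TRUE)
  expect_equal(back$condition$da, cfg$condition$da)
})

test_that("saccade equivariance: rotating the cue relabels the outcome", {
  nw <- shared_network()
  cm <- compile_network(nw, "optimal", "optimal")
  cfg <- nw$config
  acc <- sapply(c(0, 90), function(d) {
    sch <- build_trial_schedule(d, cfg)
    mean(sapply(1:6, function(s) {
      run_trial(cm, sch, seed = 200 + s, t_ms = 4000)$outcome$correct
    }))
  })
  # the optimal-condition network holds any cued direction, not just the
  # default one: accuracy stays high under cue rotation
  expect_gte(acc[1], 2 / 3)
  expect_gte(acc[2], 2 / 3)
})
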