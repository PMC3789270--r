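test_that("full-scale population sizes match the anatomy table", {
  pops <- population_table(default_config(), scale = 1)
  sz <- function(nm) pops$size[pops$name == nm]
  expect_equal(sz("L3e_0"), 2585L)
  expect_equal(sz("L3i_0"), 729L)
  expect_equal(sz("L5e_90"), 606L)
  expect_equal(sz("L5i_270"), 133L)
  expect_equal(sz("PC7a_180"), 1000L)
  expect_equal(sz("MOTe_0"), 1000L)
  expect_equal(sz("MDSC"), 1000L)
  expect_equal(sz("BG"), 1000L)
  # BG is inhibitory; the relay, parietal and motor accumulators excitatory
  expect_false(pops$excitatory[pops$name == "BG"])
  expect_true(all(pops$excitatory[pops$area %in% c("MDSC", "PC7a", "MOTe")]))
})

test_that("expected synapse counts follow the binomial closed form", {
  nw <- shared_network()
  tab <- expected_synapse_counts(nw)
  expect_true(all(tab$expected >= 0))
  one <- tab[tab$from == "PC7a_0" & tab$to == "L3e_0", ]
  n_pc <- nw$populations$size[nw$populations$name == "PC7a_0"]
  n_l3 <- nw$populations$size[nw$populations$name == "L3e_0"]
  expect_equal(one$expected, 0.1 * n_pc * n_l3)
  # every realized count sits within 4 binomial standard deviations
  expect_true(all(abs(tab$realized - tab$expected) <= 4 * tab$sd + 1e-9))
})

test_that("scale-1 recurrent projection expectation matches the probability table", {
  cfg <- default_config()
  pops <- population_table(cfg, scale = 1)
  n <- pops$size[pops$name == "L3e_0"]
  expect_equal(0.3584 * n * (n - 1), 0.3584 * 2585 * 2584)
})

test_that("construction is deterministic under a fixed seed", {
  cfg <- test_config()
  a <- build_network(cfg, seed = 7)
  b <- build_network(cfg, seed = 7)
  expect_identical(
    lapply(a$projections, function(p) p[c("pre", "post", "w")]),
    lapply(b$projections, function(p) p[c("pre", "post", "w")])
  )
  c2 <- build_network(cfg, seed = 8)
  expect_false(identical(
    lapply(a$projections, function(p) p$post),
    lapply(c2$projections, function(p) p$post)
  ))
})

test_that("topographic projections link equal directions only", {
  nw <- shared_network()
  pc_targets <- vapply(
    Filter(function(p) startsWith(p$from, "PC7a_"), nw$projections),
    function(p) paste(p$from, "->", p$to), character(1)
  )
  for (d in c(0, 90, 180, 270)) {
    this <- grep(paste0("PC7a_", d, " ->"), pc_targets, value = TRUE)
    expect_setequal(this, paste0("PC7a_", d, " -> ", c("L3e_", "L3i_"), d))
  }
  mot <- Filter(function(p) p$from == "L3e_0" && startsWith(p$to, "MOTe"), nw$projections)
  expect_equal(vapply(mot, function(p) p$to, character(1)), "MOTe_0")
})

test_that("channel use matches the source cell class", {
  nw <- shared_network()
  exc_pops <- nw$populations$name[nw$populations$excitatory]
  for (p in nw$projections) {
    expect_identical(p$excitatory, p$from %in% exc_pops)
  }
  # the clearing pathway is inhibitory, the relay drive excitatory
  bg <- Filter(function(p) p$from == "BG", nw$projections)
  expect_true(all(!vapply(bg, function(p) p$excitatory, logical(1))))
  expect_true(all(grepl("^L3", vapply(bg, function(p) p$to, character(1)))))
  md <- Filter(function(p) p$from == "MDSC", nw$projections)
  expect_true(all(grepl("^L5e", vapply(md, function(p) p$to, character(1)))))
})

test_that("no projection contains a self-synapse", {
  nw <- shared_network()
  for (p in nw$projections) {
    if (p$from == p$to) expect_false(any(p$pre == p$post))
  }
})

test_that("scales that starve a population are refused", {
  cfg <- default_config()
  expect_error(build_network(cfg, scale = 0.02), "scale too small")
})

test_that("weight compensation keeps expected summed input invariant across scales", {
  cfg <- default_config()
  cfg$network$normalize_in_degree <- FALSE
  sum_in <- function(scale) {
    nw <- build_network(cfg, scale = scale, seed = 3)
    pr <- Filter(function(p) p$from == "L3e_0" && p$to == "L3e_0", nw$projections)[[1]]
    n_post <- nw$populations$size[nw$populations$name == "L3e_0"]
    sum(pr$w) / n_post
  }
  s1 <- sum_in(0.1)
  s2 <- sum_in(0.2)
  expect_lt(abs(s1 - s2) / s1, 0.05)
})

test_that("in-degree normalisation equalises summed input weight per neuron", {
  nw <- shared_network() # built with normalisation on
  pr <- Filter(function(p) p$from == "L3e_0" && p$to == "L3e_0", nw$projections)[[1]]
  post_local <- pr$post - min(pr$post) + 1L
  sums <- tapply(pr$w, post_local, sum)
  expect_lt(stats::sd(sums) / mean(sums), 1e-6)
})
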