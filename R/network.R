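directions <- function() c(0, 90, 180, 270)

#' Population table of the columnar network
#'
#' Enumerates every population at a given scale: four parietal input groups
#' (PC7a), four two-layer cortical columns (L3e/L3i/L5e/L5i), four motor
#' output areas (MOTe/MOTi), the thalamic corollary-discharge relay (MDSC)
#' and the basal-ganglia clearing pool (BG). Direction-tuned populations
#' carry their preferred saccade direction; MDSC and BG are untuned.
#'
#' @param config Run configuration (for the full-scale sizes).
#' @param scale Scale factor; sizes are `round(scale * size)`.
#' @return A tibble with columns `name`, `area`, `direction`, `size`,
#'   `cell_class`, `excitatory`, and the 1-based global index range
#'   `start`/`end` of each population's neurons.
#' @export
population_table <- function(config = default_config(), scale = config$network$scale) {
  sz <- config$network$sizes
  rows <- list()
  for (d in directions()) {
    rows <- c(rows, list(
      list(name = paste0("PC7a_", d), area = "PC7a", direction = d,
           size = sz$pc7a, cell_class = "regular_spiking_excitatory"),
      list(name = paste0("L3e_", d), area = "L3e", direction = d,
           size = sz$l3e, cell_class = "regular_spiking_excitatory"),
      list(name = paste0("L3i_", d), area = "L3i", direction = d,
           size = sz$l3i, cell_class = "fast_spiking_inhibitory"),
      list(name = paste0("L5e_", d), area = "L5e", direction = d,
           size = sz$l5e, cell_class = "regular_spiking_excitatory"),
      list(name = paste0("L5i_", d), area = "L5i", direction = d,
           size = sz$l5i, cell_class = "fast_spiking_inhibitory"),
      list(name = paste0("MOTe_", d), area = "MOTe", direction = d,
           size = sz$mote, cell_class = "regular_spiking_excitatory"),
      list(name = paste0("MOTi_", d), area = "MOTi", direction = d,
           size = sz$moti, cell_class = "fast_spiking_inhibitory")
    ))
  }
  rows <- c(rows, list(
    list(name = "MDSC", area = "MDSC", direction = NA_real_,
         size = sz$mdsc, cell_class = "regular_spiking_excitatory"),
    list(name = "BG", area = "BG", direction = NA_real_,
         size = sz$bg, cell_class = "fast_spiking_inhibitory")
  ))
  pops <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  pops$size <- as.integer(round(scale * pops$size))
  pops$excitatory <- pops$cell_class == "regular_spiking_excitatory"
  pops$end <- cumsum(pops$size)
  pops$start <- pops$end - pops$size + 1L
  pops
}

#' Projection plan
#'
#' The directed projections of the model with their connection probability,
#' base-weight name and neuromodulatory connection class. Within-column
#' probabilities follow the cortical-column table (presynaptic population in
#' columns, postsynaptic in rows); every between-group probability is 0.1.
#' Topographic ("one-to-one") projections link equal preferred directions;
#' full projections link all four.
#'
#' @param config Run configuration.
#' @return A tibble with columns `from`, `to`, `p`, `weight_name`,
#'   `conn_class`.
#' @keywords internal
projection_plan <- function(config) {
  pw <- config$network$p_within
  pb <- config$network$p_between
  plan <- list()
  add <- function(from, to, p, w, cls) {
    plan[[length(plan) + 1]] <<- tibble::tibble(
      from = from, to = to, p = p, weight_name = w, conn_class = cls
    )
  }
  for (d in directions()) {
    pc <- paste0("PC7a_", d)
    l3e <- paste0("L3e_", d); l3i <- paste0("L3i_", d)
    l5e <- paste0("L5e_", d); l5i <- paste0("L5i_", d)
    mote <- paste0("MOTe_", d); moti <- paste0("MOTi_", d)
    # parietal drive, topographic
    add(pc, l3e, pb, "pc_l3", "drive")
    add(pc, l3i, pb, "pc_l3i", "drive")
    # within-column layer 3
    add(l3e, l3e, pw$l3e_l3e, "rec_l3", "recurrent_pref")
    add(l3e, l3i, pw$l3e_l3i, "l3_ei", "other")
    add(l3i, l3e, pw$l3i_l3e, "l3_ie", "inhibitory")
    add(l3i, l3i, pw$l3i_l3i, "l3_ii", "inhibitory")
    # within-column layer 5
    add(l5e, l5e, pw$l5e_l5e, "l5_ee", "other")
    add(l5e, l5i, pw$l5e_l5i, "l5_ei", "other")
    add(l5i, l5e, pw$l5i_l5e, "l5_ie", "inhibitory")
    add(l5i, l5i, pw$l5i_l5i, "l5_ii", "inhibitory")
    # lateral (between-column) excitation from layer 3
    for (d2 in setdiff(directions(), d)) {
      add(l3e, paste0("L3e_", d2), pb, "lat_ee", "lateral_npref")
      add(l3e, paste0("L3i_", d2), pb, "lat_ei", "other")
    }
    # corollary discharge to layer 5, non-topographic
    add("MDSC", l5e, pb, "mdsc_l5", "drive")
    # layer 5 to basal ganglia; BG clears layer 3 of all columns
    add(l5e, "BG", pb, "l5_bg", "other")
    add("BG", l3e, pb, "bg_l3", "inhibitory")
    add("BG", l3i, pb, "bg_l3", "inhibitory")
    # motor output: topographic drive, lateral inhibition between areas
    add(l3e, mote, pb, "l3_mot", "other")
    add(mote, moti, pb, "mot_ei", "other")
    # lateral inhibition between motor areas: each area's interneurons
    # suppress the other areas' accumulators (winner-take-all competition)
    for (d2 in setdiff(directions(), d)) {
      add(moti, paste0("MOTe_", d2), pb, "mot_ie", "inhibitory")
    }
  }
  dplyr::bind_rows(plan)
}

sample_projection <- function(n_pre, n_post, p, exclude_self = FALSE) {
  # per-presynaptic-neuron binomial draw; memory stays linear in synapse count
  n_avail <- if (exclude_self) n_post - 1L else n_post
  k <- stats::rbinom(n_pre, n_avail, p)
  pre <- rep.int(seq_len(n_pre), k)
  total <- sum(k)
  post <- integer(total)
  off <- 0L
  for (i in seq_len(n_pre)) {
    if (k[i] == 0L) next
    tgt <- sample.int(n_avail, k[i])
    if (exclude_self) tgt <- tgt + (tgt >= i)
    post[(off + 1L):(off + k[i])] <- tgt
    off <- off + k[i]
  }
  list(pre = pre, post = post)
}

#' Build the spiking network
#'
#' Realises the populations and Bernoulli random connectivity of the model at
#' a given scale. Population sizes are multiplied by `scale` and base weights
#' divided by it (linear input conservation: the expected summed synaptic
#' drive per neuron is scale-invariant) or by `sqrt(scale)` if
#' `weight_compensation = "sqrt"`. Construction is deterministic given
#' `seed`.
#'
#' @param config Run configuration.
#' @param scale Scale factor in (0, 1]; the smallest population must keep at
#'   least 10 neurons, otherwise construction refuses (the dynamical regime
#'   is not preserved below that).
#' @param seed Integer seed for connectivity sampling.
#' @return A `pfc_network` object: list with `populations` (tibble),
#'   `projections` (list of realized projections with global-index `pre`,
#'   `post` and per-synapse weight `w`), `neurons` (per-neuron parameter
#'   vectors), `scale`, `seed` and the originating `config`.
#' @export
build_network <- function(config = default_config(),
                          scale = config$network$scale,
                          seed = config$network$seed) {
  errs <- validate_config(config)
  if (!isTRUE(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
      call. = FALSE
    )
  }
  if (round(scale * min(unlist(config$network$sizes))) < 10) {
    stop("scale too small: smallest population would have < 10 neurons",
      call. = FALSE
    )
  }
  pops <- population_table(config, scale)
  comp <- switch(config$network$weight_compensation,
    linear = 1 / scale,
    sqrt = 1 / sqrt(scale),
    stop("unknown weight_compensation", call. = FALSE)
  )
  plan <- projection_plan(config)
  weights <- config$network$weights
  idx <- stats::setNames(seq_len(nrow(pops)), pops$name)

  set.seed(seed)
  projections <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    pf <- pops[idx[[plan$from[i]]], ]
    pt <- pops[idx[[plan$to[i]]], ]
    adj <- sample_projection(
      pf$size, pt$size, plan$p[i],
      exclude_self = identical(pf$name, pt$name)
    )
    w_base <- weights[[plan$weight_name[i]]]
    w_syn <- rep(w_base * comp, length(adj$pre))
    if (isTRUE(config$network$normalize_in_degree) && length(adj$pre) > 0) {
      # per-target synaptic scaling: at reduced scale the realized in-degree
      # k_i fluctuates strongly around its expectation k_bar; scaling each
      # target's weights by k_bar / k_i keeps the summed drive per neuron at
      # its design value without changing the connectivity pattern
      k_bar <- plan$p[i] * (pf$size - as.integer(identical(pf$name, pt$name)))
      k_i <- tabulate(adj$post, nbins = pt$size)
      w_syn <- w_syn * (k_bar / pmax(k_i, 1L))[adj$post]
    }
    projections[[i]] <- list(
      from = pf$name, to = pt$name, p = plan$p[i],
      conn_class = plan$conn_class[i], weight_name = plan$weight_name[i],
      excitatory = pf$excitatory,
      pre = adj$pre + pf$start - 1L,
      post = adj$post + pt$start - 1L,
      w = w_syn,
      n_possible = pf$size * pt$size -
        if (identical(pf$name, pt$name)) pf$size else 0L
    )
  }

  n <- sum(pops$size)
  rs <- neuron_params("regular_spiking_excitatory")
  fs <- neuron_params("fast_spiking_inhibitory")
  exc <- rep(pops$excitatory, pops$size)
  neurons <- list(
    a = ifelse(exc, rs$a, fs$a),
    b = ifelse(exc, rs$b, fs$b),
    c = ifelse(exc, rs$c, fs$c),
    d = ifelse(exc, rs$d, fs$d),
    excitatory = exc,
    population = rep(pops$name, pops$size)
  )
  structure(
    list(
      populations = pops, projections = projections, neurons = neurons,
      n_neurons = n, scale = scale, seed = seed, config = config
    ),
    class = "pfc_network"
  )
}

#' @export
print.pfc_network <- function(x, ...) {
  cat(sprintf(
    "<pfc_network> %d neurons in %d populations, %d projections (scale %.3g, seed %d)\n",
    x$n_neurons, nrow(x$populations), length(x$projections), x$scale, x$seed
  ))
  invisible(x)
}

#' Expected and realized synapse counts
#'
#' For each projection, the binomial expectation `p * n_pre * n_post`
#' (excluding self-pairs for recurrent projections) and the realized count,
#' plus a grand total. Useful as a construction sanity check: realized counts
#' should sit within a few binomial standard deviations of expectation.
#'
#' @param network A `pfc_network`.
#' @return A tibble with `from`, `to`, `p`, `expected`, `realized`, `sd`
#'   (binomial standard deviation).
#' @export
expected_synapse_counts <- function(network) {
  purrr::map_dfr(network$projections, function(pr) {
    tibble::tibble(
      from = pr$from, to = pr$to, p = pr$p,
      expected = pr$p * pr$n_possible,
      realized = length(pr$pre),
      sd = sqrt(pr$n_possible * pr$p * (1 - pr$p))
    )
  })
}
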