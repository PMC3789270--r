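#' @keywords internal
nm_levels <- function() c("low", "optimal", "high")

#' @keywords internal
conn_classes <- function() {
  c("recurrent_pref", "lateral_npref", "drive", "inhibitory", "other")
}

check_level <- function(x, what) {
  if (!(is.character(x) && length(x) == 1 && x %in% nm_levels())) {
    stop(sprintf("%s level must be one of %s", what,
                 paste(nm_levels(), collapse = ", ")), call. = FALSE)
  }
  x
}

#' Neuromodulatory factor table
#'
#' Enumerates the multiplicative synaptic gain factors for every combination
#' of dopamine (D1) level, norepinephrine (alpha-2A / alpha-1) level,
#' connection class and conductance channel, together with the total-current
#' gain on layer-3 excitatory neurons. The encoded rules:
#'
#' * Recurrent excitation within a column (`recurrent_pref`): AMPA gain 0.1 in
#'   every condition; NMDA gain 10 when NE is low (weak alpha-2A activation)
#'   and 15 when NE is optimal or high.
#' * Lateral excitation between columns onto excitatory targets
#'   (`lateral_npref`): AMPA and NMDA gain 1.4 when DA is low (weak D1 leaves
#'   non-preferred inputs enhanced), 1.0 at optimal or high DA.
#' * Total synaptic current onto layer-3 excitatory neurons: gain 0.8 when
#'   exactly one of DA, NE is high (D1 over-stimulation or alpha-1
#'   activation), 0.67 when both are high, 1 otherwise.
#' * Every other (class, channel) combination has gain 1.
#'
#' @return A tibble with columns `da`, `ne`, `conn_class`, `channel`,
#'   `factor` covering all 9 conditions x 5 classes x 4 channels, plus an
#'   attribute-free companion accessible through [current_factor()].
#' @seealso [synaptic_factor()], [current_factor()]
#' @export
modulation_table <- function() {
  grid <- tidyr::expand_grid(
    da = nm_levels(), ne = nm_levels(),
    conn_class = conn_classes(),
    channel = c("ampa", "nmda", "gabaa", "gabab")
  )
  grid$factor <- purrr::pmap_dbl(
    grid, function(da, ne, conn_class, channel) {
      synaptic_factor(da, ne, conn_class, channel)
    }
  )
  grid
}

#' Synaptic neuromodulatory factor
#'
#' Gain applied to the weight of one synapse class/channel under a given
#' (DA, NE) condition; see [modulation_table()] for the rules. Any
#' combination not explicitly modulated resolves to 1.
#'
#' @param da,ne Neuromodulator levels: `"low"`, `"optimal"` or `"high"`.
#' @param conn_class One of `"recurrent_pref"`, `"lateral_npref"`, `"drive"`,
#'   `"inhibitory"`, `"other"`.
#' @param channel One of `"ampa"`, `"nmda"`, `"gabaa"`, `"gabab"`.
#' @return A single numeric gain.
#'
#' @examples
#' synaptic_factor("optimal", "optimal", "recurrent_pref", "nmda") # 15
#' synaptic_factor("low", "optimal", "lateral_npref", "ampa") # 1.4
#' @export
synaptic_factor <- function(da, ne, conn_class, channel) {
  check_level(da, "DA")
  check_level(ne, "NE")
  if (!conn_class %in% conn_classes()) {
    stop("unknown connection class: ", conn_class, call. = FALSE)
  }
  stopifnot(channel %in% c("ampa", "nmda", "gabaa", "gabab"))
  if (conn_class == "recurrent_pref") {
    if (channel == "ampa") {
      return(0.1)
    }
    if (channel == "nmda") {
      return(if (ne == "low") 10 else 15)
    }
  }
  if (conn_class == "lateral_npref" && channel %in% c("ampa", "nmda")) {
    return(if (da == "low") 1.4 else 1.0)
  }
  1.0
}

#' Total-current neuromodulatory factor
#'
#' Gain on the total synaptic current of a target group under a given
#' (DA, NE) condition. Only layer-3 excitatory populations are modulated
#' (D1 over-stimulation and alpha-1 activation block inputs to supragranular
#' working-memory neurons): 0.8 when exactly one of DA, NE is high, 0.67 when
#' both are high, 1 otherwise. Set `modulate_l3_inhibitory = TRUE` to extend
#' the same gain to layer-3 inhibitory neurons.
#'
#' @param da,ne Neuromodulator levels.
#' @param group Target population name (e.g. `"L3e_0"`, `"MOTe_90"`).
#' @param modulate_l3_inhibitory Also scale current onto L3 inhibitory cells.
#' @return A single numeric gain.
#'
#' @examples
#' current_factor("high", "high", "L3e_0") # 0.67
#' current_factor("optimal", "high", "L3e_0") # 0.8
#' @export
current_factor <- function(da, ne, group, modulate_l3_inhibitory = FALSE) {
  check_level(da, "DA")
  check_level(ne, "NE")
  is_l3e <- grepl("^L3e", group)
  is_l3i <- grepl("^L3i", group)
  if (!(is_l3e || (modulate_l3_inhibitory && is_l3i))) {
    return(1.0)
  }
  n_high <- (da == "high") + (ne == "high")
  if (n_high == 2) {
    0.67
  } else if (n_high == 1) {
    0.8
  } else {
    1.0
  }
}
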