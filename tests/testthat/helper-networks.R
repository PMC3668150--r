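# Toy networks built through the internal constructor, used as analytic
# oracles for the stochastic engines.

toy_species <- function(names) {
  tibble::tibble(
    species = names,
    pcna = 0L, lesion = 0L, ub = 0L, rad6 = 0L, rad18 = 0L, rad5 = 0L,
    ubc13mms2 = 0L, conjugated_ub = 0L
  )
}

# pure death A -> B at rate c: A(t) ~ Binomial(N, exp(-c t))
pure_death_network <- function(N = 200, c = 0.05) {
  species <- toy_species(c("A", "B"))
  reactions <- tibble::tibble(
    id = 1L, reactants = list(c(A = 1L)), products = list(c(B = 1L)),
    c = c, provenance = "toy"
  )
  prrsim:::new_prr_network(species, reactions,
                           c(A = as.integer(N), B = 0L))
}

# no reactions at all: every trajectory is frozen at the initial state
inert_network <- function(N = 10) {
  species <- toy_species("A")
  reactions <- tibble::tibble(
    id = 1L, reactants = list(c(A = 1L)), products = list(c(A = 1L)),
    c = 1e-30, provenance = "toy"
  )
  prrsim:::new_prr_network(species, reactions, c(A = as.integer(N)))
}

# down-scaled canonical network: all initial pools divided by 10
downscaled_prr_network <- function(lesions = 50, factor = 10) {
  net <- build_prr_network(lesions = lesions)
  for (sp in c("Rad5", "Rad6", "Rad18", "Ubc13:Mms2", "PCNA", "U")) {
    net <- set_initial_amount(net, sp, round(net$initial_state[[sp]] / factor))
  }
  net
}

channel_sums <- function(trajectory, network, channels) {
  ch <- isoform_channels(network)
  idx <- which(ch$channel %in% channels)
  colSums(trajectory$counts[idx, , drop = FALSE])
}
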