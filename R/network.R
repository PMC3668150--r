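# Canonical PRR reaction network: 23 species, 25 mass-action reactions.
#
# Species are composed of seven elementary units (PCNA trimer, DNA lesion,
# ubiquitin, Rad6, Rad18, Rad5, pre-formed Ubc13:Mms2). The per-species unit
# composition drives both the structural conservation checks and the isoform
# classification: `conjugated_ub` counts ubiquitins covalently attached to the
# PCNA clamp (0-3), as opposed to carrier-bound ubiquitin riding on Rad6:U or
# Ubc13:U:Mms2.

elementary_units <- c("pcna", "lesion", "ub", "rad6", "rad18", "rad5", "ubc13mms2")

#' Canonical species of the PRR ubiquitylation network
#'
#' Returns the 23 molecular species of the post-replication-repair (PRR)
#' PCNA-ubiquitylation model, with their composition in elementary units and
#' the number of ubiquitins covalently conjugated to the PCNA clamp.
#'
#' Species names use colon-concatenated complex notation (`"PCNA_on:U"` is
#' mono-ubiquitylated PCNA stalled at a lesion; `"Ubc13:U:Mms2"` is the
#' ubiquitin-charged E2 heterodimer). `PCNA_off` is the absorbing
#' switched-off clamp after lesion bypass.
#'
#' @return A tibble with one row per species: `species`, one column per
#'   elementary unit (`pcna`, `lesion`, `ub`, `rad6`, `rad18`, `rad5`,
#'   `ubc13mms2`), and `conjugated_ub` (0-3).
#' @export
#' @examples
#' prr_species()
prr_species <- function() {
  out <- tibble::tribble(
    ~species,                          ~pcna, ~lesion, ~ub, ~rad6, ~rad18, ~rad5, ~ubc13mms2, ~conjugated_ub,
    "PCNA",                                1,       0,   0,     0,      0,     0,          0,              0,
    "L",                                   0,       1,   0,     0,      0,     0,          0,              0,
    "PCNA_on",                             1,       1,   0,     0,      0,     0,          0,              0,
    "Rad18",                               0,       0,   0,     0,      1,     0,          0,              0,
    "Rad18:Rad18",                         0,       0,   0,     0,      2,     0,          0,              0,
    "Rad6",                                0,       0,   0,     1,      0,     0,          0,              0,
    "U",                                   0,       0,   1,     0,      0,     0,          0,              0,
    "Rad6:U",                              0,       0,   1,     1,      0,     0,          0,              0,
    "Rad18:Rad18:PCNA_on",                 1,       1,   0,     0,      2,     0,          0,              0,
    "Rad18:Rad18:PCNA_on:Rad6:U",          1,       1,   1,     1,      2,     0,          0,              0,
    "Rad18:Rad18:PCNA_on:U",               1,       1,   1,     0,      2,     0,          0,              1,
    "PCNA_on:U",                           1,       1,   1,     0,      0,     0,          0,              1,
    "Ubc13:Mms2",                          0,       0,   0,     0,      0,     0,          1,              0,
    "Ubc13:U:Mms2",                        0,       0,   1,     0,      0,     0,          1,              0,
    "Rad5",                                0,       0,   0,     0,      0,     1,          0,              0,
    "Rad5:PCNA_on:U",                      1,       1,   1,     0,      0,     1,          0,              1,
    "Ubc13:U:Mms2:Rad5:PCNA_on:U",         1,       1,   2,     0,      0,     1,          1,              1,
    "Rad5:PCNA_on:U:U",                    1,       1,   2,     0,      0,     1,          0,              2,
    "PCNA_on:U:U",                         1,       1,   2,     0,      0,     0,          0,              2,
    "Ubc13:U:Mms2:Rad5:PCNA_on:U:U",       1,       1,   3,     0,      0,     1,          1,              2,
    "Rad5:PCNA_on:U:U:U",                  1,       1,   3,     0,      0,     1,          0,              3,
    "PCNA_on:U:U:U",                       1,       1,   3,     0,      0,     0,          0,              3,
    "PCNA_off",                            1,       1,   0,     0,      0,     0,          0,              0
  )
  out
}

#' Canonical reactions of the PRR ubiquitylation network
#'
#' The 25 mass-action reactions of the PRR model, grouped in four functional
#' modules: lesion recognition and PCNA mono-ubiquitylation by Rad6/Rad18
#' (reactions 1-10), di-ubiquitylation by Ubc13:Mms2/Rad5 (11-17),
#' tri-ubiquitylation (18-22), and the generic ubiquitylation-signal
#' switch-off with ubiquitin recycling (23-25).
#'
#' Stochastic constants are in s^-1 under the stochastic chemical-kinetics
#' convention (propensity = c * combinatorial reactant count), for both
#' unimolecular and bimolecular reactions.
#'
#' @return A tibble with columns `id`, `reactants` and `products` (list
#'   columns of named integer multiplicities), `c` (stochastic constant,
#'   per second), and `provenance` (origin of the constant).
#' @export
#' @examples
#' prr_reactions()
prr_reactions <- function() {
  rx <- function(id, reactants, products, c, provenance) {
    tibble::tibble(
      id = id, reactants = list(reactants), products = list(products),
      c = c, provenance = provenance
    )
  }
  lit <- "literature-derived"
  cal <- "calibrated on 5 J/m2 time courses"
  dplyr::bind_rows(
    rx(1L,  c(PCNA = 1L, L = 1L),                  c(PCNA_on = 1L),                               1.5e-8, cal),
    rx(2L,  c(Rad18 = 2L),                         c(`Rad18:Rad18` = 1L),                         1e-2,   lit),
    rx(3L,  c(`Rad18:Rad18` = 1L),                 c(Rad18 = 2L),                                 1e3,    lit),
    rx(4L,  c(Rad6 = 1L, U = 1L),                  c(`Rad6:U` = 1L),                              2.5e-7, lit),
    rx(5L,  c(PCNA_on = 1L, `Rad18:Rad18` = 1L),   c(`Rad18:Rad18:PCNA_on` = 1L),                 1e5,    lit),
    rx(6L,  c(`Rad18:Rad18:PCNA_on` = 1L),         c(PCNA_on = 1L, `Rad18:Rad18` = 1L),           1e3,    lit),
    rx(7L,  c(`Rad6:U` = 1L, `Rad18:Rad18:PCNA_on` = 1L),
            c(`Rad18:Rad18:PCNA_on:Rad6:U` = 1L),                                                 3.51e-2, cal),
    rx(8L,  c(`Rad18:Rad18:PCNA_on:Rad6:U` = 1L),
            c(`Rad6:U` = 1L, `Rad18:Rad18:PCNA_on` = 1L),                                         1e-2,   cal),
    rx(9L,  c(`Rad18:Rad18:PCNA_on:Rad6:U` = 1L),
            c(Rad6 = 1L, `Rad18:Rad18:PCNA_on:U` = 1L),                                           1e-2,   lit),
    rx(10L, c(`Rad18:Rad18:PCNA_on:U` = 1L),
            c(`Rad18:Rad18` = 1L, `PCNA_on:U` = 1L),                                              1,      lit),
    rx(11L, c(`Ubc13:Mms2` = 1L, U = 1L),          c(`Ubc13:U:Mms2` = 1L),                        1e5,    cal),
    rx(12L, c(`PCNA_on:U` = 1L, Rad5 = 1L),        c(`Rad5:PCNA_on:U` = 1L),                      5e-6,   lit),
    rx(13L, c(`Rad5:PCNA_on:U` = 1L),              c(`PCNA_on:U` = 1L, Rad5 = 1L),                5e-3,   lit),
    rx(14L, c(`Ubc13:U:Mms2` = 1L, `Rad5:PCNA_on:U` = 1L),
            c(`Ubc13:U:Mms2:Rad5:PCNA_on:U` = 1L),                                                7.8e-2, cal),
    rx(15L, c(`Ubc13:U:Mms2:Rad5:PCNA_on:U` = 1L),
            c(`Rad5:PCNA_on:U` = 1L, `Ubc13:U:Mms2` = 1L),                                        1e-10,  lit),
    rx(16L, c(`Ubc13:U:Mms2:Rad5:PCNA_on:U` = 1L),
            c(`Ubc13:Mms2` = 1L, `Rad5:PCNA_on:U:U` = 1L),                                        5e-2,   "in vitro Kcat 3.0/min"),
    rx(17L, c(`Rad5:PCNA_on:U:U` = 1L),            c(Rad5 = 1L, `PCNA_on:U:U` = 1L),              7.5e-6, cal),
    rx(18L, c(`PCNA_on:U:U` = 1L, Rad5 = 1L),      c(`Rad5:PCNA_on:U:U` = 1L),                    5e-6,   cal),
    rx(19L, c(`Ubc13:U:Mms2` = 1L, `Rad5:PCNA_on:U:U` = 1L),
            c(`Ubc13:U:Mms2:Rad5:PCNA_on:U:U` = 1L),                                              7.8e-2, cal),
    rx(20L, c(`Ubc13:U:Mms2:Rad5:PCNA_on:U:U` = 1L),
            c(`Rad5:PCNA_on:U:U` = 1L, `Ubc13:U:Mms2` = 1L),                                      1e-10,  lit),
    rx(21L, c(`Ubc13:U:Mms2:Rad5:PCNA_on:U:U` = 1L),
            c(`Ubc13:Mms2` = 1L, `Rad5:PCNA_on:U:U:U` = 1L),                                      5e-3,   lit),
    rx(22L, c(`Rad5:PCNA_on:U:U:U` = 1L),          c(Rad5 = 1L, `PCNA_on:U:U:U` = 1L),            5e-3,   cal),
    rx(23L, c(`PCNA_on:U` = 1L),                   c(U = 1L, PCNA_off = 1L),                      3e-8,   cal),
    rx(24L, c(`PCNA_on:U:U` = 1L),                 c(U = 2L, PCNA_off = 1L),                      8e-4,   cal),
    rx(25L, c(`PCNA_on:U:U:U` = 1L),               c(U = 3L, PCNA_off = 1L),                      5e-3,   cal)
  )
}

#' Whole-cell protein copy numbers feeding the initial state
#'
#' Curated whole-cell copy numbers for the PRR proteins, with their nuclear
#' localisation class. Proteins present in both nucleus and cytoplasm
#' (`dual_localized = TRUE`: Rad6, Ubc13, Mms2, ubiquitin) are scaled to the
#' nuclear volume fraction; nucleus-only proteins (Rad5, Rad18, PCNA) are not.
#' PCNA is counted in homotrimers (the functional clamp).
#'
#' @return A tibble with columns `protein`, `total_amount`, `dual_localized`.
#' @export
prr_protein_amounts <- function() {
  tibble::tribble(
    ~protein,    ~total_amount, ~dual_localized,
    "Rad5",              1520L,           FALSE,
    "Rad6",              2770L,            TRUE,
    "Rad18",              206L,           FALSE,
    "Ubc13",             8970L,            TRUE,
    "Mms2",              2760L,            TRUE,
    "PCNA",              7480L,           FALSE,
    "Ubiquitin",       124260L,            TRUE
  )
}

#' Nuclear copy number of a protein
#'
#' Scales a whole-cell copy number to the nuclear compartment. In exponentially
#' growing budding yeast the nucleus occupies about 7% of cell volume; assuming
#' uniform distribution, dual-localised proteins contribute that fraction of
#' their total to nuclear reactions, while nucleus-only proteins contribute
#' their whole pool.
#'
#' @param total Whole-cell copy number (non-negative).
#' @param fraction Nuclear volume fraction, in (0, 1]. Default 0.07.
#' @param dual_localized Logical; if `TRUE` the amount is scaled by `fraction`
#'   (rounded to the nearest molecule), otherwise returned unchanged.
#' @return Integer nuclear copy number.
#' @export
#' @examples
#' nuclear_amount(124260, 0.07, dual_localized = TRUE)  # ubiquitin -> 8698
#' nuclear_amount(206, dual_localized = FALSE)          # Rad18 stays 206
nuclear_amount <- function(total, fraction = 0.07, dual_localized = TRUE) {
  if (any(total < 0)) abort("`total` must be non-negative.")
  if (any(fraction <= 0 | fraction > 1)) abort("`fraction` must be in (0, 1].")
  out <- ifelse(dual_localized, round(total * fraction), total)
  as.integer(out)
}

#' Convert a first-order catalytic rate to a stochastic constant
#'
#' For a unimolecular step the deterministic first-order rate constant and the
#' stochastic constant coincide, so the conversion is a pure change of time
#' unit from per-minute to per-second.
#'
#' @param kcat_per_min First-order rate, per minute (positive).
#' @return Stochastic constant, per second.
#' @export
#' @examples
#' kcat_to_stochastic_constant(3.0)  # 0.05 s^-1 (ubiquitin-chain extension)
kcat_to_stochastic_constant <- function(kcat_per_min) {
  if (any(kcat_per_min <= 0)) abort("`kcat_per_min` must be positive.")
  kcat_per_min / 60
}

#' Build the PRR reaction network
#'
#' Assembles the canonical 23-species/25-reaction network with its initial
#' state. The lesion count `L` is taken either directly from `lesions` or
#' converted from a UV dose via the linear dose-lesion calibration
#' (see [lesions_for_dose()]). The Ubc13:Mms2 E2 complex is modelled as
#' pre-formed, with initial copy number equal to the scarcer of its two
#' subunits' nuclear pools.
#'
#' @param uv_dose UV dose in J/m^2 (used if `lesions` is `NULL`).
#' @param lesions Integer lesion count; overrides `uv_dose`.
#' @param nuclear_fraction Nuclear volume fraction used to scale
#'   dual-localised proteins. Default 0.07.
#' @param coefficient Lesions per J/m^2 for dose conversion. Default 200.248.
#' @param amount_overrides Named numeric vector of initial-count overrides,
#'   e.g. `c(U = 870)` to emulate a ubiquitin-depleted (doa4-like) nucleus.
#'   Applied after all other initialisation.
#' @return A `prr_network` object: list with `species` and `reactions`
#'   tibbles, the species-by-reaction `stoichiometry` matrix, the
#'   `initial_state` named integer vector, and the resolved `lesions`.
#' @export
#' @examples
#' net <- build_prr_network(lesions = 1001)
#' net$initial_state[net$initial_state > 0]
build_prr_network <- function(uv_dose = NULL, lesions = NULL,
                              nuclear_fraction = 0.07,
                              coefficient = 200.248,
                              amount_overrides = NULL) {
  if (is.null(lesions)) {
    if (is.null(uv_dose)) abort("Provide either `uv_dose` or `lesions`.")
    lesions <- lesions_for_dose(uv_dose, coefficient)
  }
  lesions <- as.integer(round(lesions))
  if (lesions < 0) abort("`lesions` must be non-negative.")

  amounts <- prr_protein_amounts()
  nuc <- setNames(
    nuclear_amount(amounts$total_amount, nuclear_fraction, amounts$dual_localized),
    amounts$protein
  )

  species <- prr_species()
  reactions <- prr_reactions()
  init <- setNames(integer(nrow(species)), species$species)
  init["Rad5"] <- nuc[["Rad5"]]
  init["Rad6"] <- nuc[["Rad6"]]
  init["Rad18"] <- nuc[["Rad18"]]
  init["Ubc13:Mms2"] <- min(nuc[["Ubc13"]], nuc[["Mms2"]])
  init["PCNA"] <- nuc[["PCNA"]]
  init["U"] <- nuc[["Ubiquitin"]]
  init["L"] <- lesions

  if (!is.null(amount_overrides)) {
    unknown <- setdiff(names(amount_overrides), species$species)
    if (length(unknown) > 0) {
      abort(paste0("Unknown species in `amount_overrides`: ",
                   paste(unknown, collapse = ", ")))
    }
    if (any(amount_overrides < 0)) abort("Overrides must be non-negative.")
    init[names(amount_overrides)] <- as.integer(round(amount_overrides))
  }

  new_prr_network(species, reactions, init,
                  lesions = init[["L"]],
                  nuclear_fraction = nuclear_fraction)
}

# Constructor shared by the canonical builder and toy networks used in tests.
new_prr_network <- function(species, reactions, initial_state,
                            lesions = NA_integer_, nuclear_fraction = NA_real_) {
  stopifnot(identical(names(initial_state), species$species))
  S <- nrow(species)
  R <- nrow(reactions)
  stoich <- matrix(0L, nrow = S, ncol = R,
                   dimnames = list(species$species, paste0("r", reactions$id)))
  reactant_m <- stoich
  for (j in seq_len(R)) {
    re <- reactions$reactants[[j]]
    pr <- reactions$products[[j]]
    bad <- setdiff(c(names(re), names(pr)), species$species)
    if (length(bad) > 0) {
      abort(paste0("Reaction ", reactions$id[j], " references unknown species: ",
                   paste(bad, collapse = ", ")))
    }
    if (sum(re) < 1 || sum(re) > 2) {
      abort(paste0("Reaction ", reactions$id[j],
                   " must be unimolecular or bimolecular."))
    }
    reactant_m[names(re), j] <- as.integer(re)
    stoich[names(pr), j] <- stoich[names(pr), j] + as.integer(pr)
    stoich[names(re), j] <- stoich[names(re), j] - as.integer(re)
  }
  if (any(reactions$c <= 0)) abort("Stochastic constants must be positive.")
  structure(
    list(
      species = species,
      reactions = reactions,
      stoichiometry = stoich,
      reactant_matrix = reactant_m,
      initial_state = initial_state,
      lesions = lesions,
      nuclear_fraction = nuclear_fraction
    ),
    class = "prr_network"
  )
}

#' @export
print.prr_network <- function(x, ...) {
  cat("<prr_network> ", nrow(x$species), " species, ", nrow(x$reactions),
      " reactions\n", sep = "")
  nz <- x$initial_state[x$initial_state > 0]
  cat("initial state: ",
      paste(names(nz), nz, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Replace a stochastic constant
#'
#' Returns a copy of the network with the stochastic constant of one reaction
#' set to a new value (used by parameter sweeps and sensitivity screening).
#'
#' @param network A `prr_network`.
#' @param reaction_id Integer reaction id.
#' @param value New positive constant, per second.
#' @return The modified `prr_network`.
#' @export
set_constant <- function(network, reaction_id, value) {
  j <- match(reaction_id, network$reactions$id)
  if (is.na(j)) abort(paste0("No reaction with id ", reaction_id, "."))
  if (value <= 0) abort("Stochastic constants must be positive.")
  network$reactions$c[j] <- value
  network
}

#' Replace an initial copy number
#'
#' @param network A `prr_network`.
#' @param species Species name.
#' @param value New non-negative count.
#' @return The modified `prr_network`.
#' @export
set_initial_amount <- function(network, species, value) {
  if (!species %in% names(network$initial_state)) {
    abort(paste0("Unknown species `", species, "`."))
  }
  if (value < 0) abort("Counts must be non-negative.")
  network$initial_state[[species]] <- as.integer(round(value))
  if (species == "L") network$lesions <- as.integer(round(value))
  network
}

# Weights of the seven structural conservation laws (law x species), taken
# from the elementary-unit composition. The lesion law counts free lesions
# plus every lesion-carrying species (including the absorbing PCNA_off).
conservation_weights <- function(network) {
  sp <- network$species
  w <- t(as.matrix(sp[, elementary_units]))
  rownames(w) <- elementary_units
  colnames(w) <- sp$species
  w
}

#' Check structural conservation laws
#'
#' Verifies that the seven weighted species sums implied by elementary-unit
#' composition (total PCNA trimers, total ubiquitin counting free, carrier and
#' conjugated pools, total Rad6, Rad18, Rad5, Ubc13:Mms2, and total lesions
#' free or carried) are invariant under every reaction. These laws hold for the
#' canonical network because it has no synthesis or degradation steps, matching
#' the cycloheximide-blocked experimental design.
#'
#' @param network A `prr_network`.
#' @return A tibble of violations with columns `law`, `reaction`, `delta`
#'   (net change of the conserved sum per firing); zero rows when the network
#'   is conservative.
#' @export
#' @examples
#' validate_conservation(build_prr_network(lesions = 1001))
validate_conservation <- function(network) {
  w <- conservation_weights(network)
  change <- w %*% network$stoichiometry  # law x reaction
  idx <- which(change != 0, arr.ind = TRUE)
  tibble(
    law = rownames(change)[idx[, 1]],
    reaction = network$reactions$id[idx[, 2]],
    delta = change[idx]
  )
}

#' Conserved totals of a network state
#'
#' @param network A `prr_network`.
#' @param counts Named (or network-ordered) count vector; defaults to the
#'   initial state.
#' @return Named numeric vector of the seven conserved sums.
#' @export
conserved_totals <- function(network, counts = network$initial_state) {
  w <- conservation_weights(network)
  drop(w %*% as.numeric(counts))
}

#' File-system-safe species aliases
#'
#' Complex species names contain `:` which is not portable in file names; the
#' alias replaces it with `_`.
#'
#' @param network A `prr_network`; defaults to the canonical network shape.
#' @return A tibble with columns `species`, `alias`.
#' @export
species_aliases <- function(network = NULL) {
  nm <- if (is.null(network)) prr_species()$species else network$species$species
  tibble(species = nm, alias = gsub(":", "_", nm, fixed = TRUE))
}

#' Serialize a network to JSON
#'
#' Writes species (with composition and conjugated-ubiquitin counts),
#' reactions (reactant/product multisets, constants, provenance) and the
#' initial state to a plain-text JSON document readable by
#' [read_network_json()].
#'
#' @param network A `prr_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  doc <- list(
    format = "prrsim-network",
    version = 1L,
    species = network$species,
    reactions = list(
      id = network$reactions$id,
      c = network$reactions$c,
      provenance = network$reactions$provenance,
      reactants = lapply(network$reactions$reactants, as.list),
      products = lapply(network$reactions$products, as.list)
    ),
    initial_state = as.list(network$initial_state),
    lesions = network$lesions,
    nuclear_fraction = network$nuclear_fraction
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a network from JSON
#'
#' @param path Path written by [write_network_json()].
#' @return A `prr_network`.
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "prrsim-network")) {
    abort("Not a prrsim network JSON document.")
  }
  species <- dplyr::bind_rows(lapply(doc$species, as_tibble))
  to_named_int <- function(x) {
    vapply(x, function(el) as.integer(el), integer(1))
  }
  rx <- doc$reactions
  reactions <- tibble(
    id = vapply(rx$id, as.integer, integer(1)),
    reactants = lapply(rx$reactants, to_named_int),
    products = lapply(rx$products, to_named_int),
    c = vapply(rx$c, as.numeric, numeric(1)),
    provenance = vapply(rx$provenance, as.character, character(1))
  )
  init <- to_named_int(doc$initial_state)
  new_prr_network(species, reactions, init[species$species],
                  lesions = as.integer(doc$lesions),
                  nuclear_fraction = as.numeric(doc$nuclear_fraction))
}
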