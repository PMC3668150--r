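test_that("canonical network has the published structure and initial state", {
  net <- build_prr_network(lesions = 1001)
  expect_equal(nrow(net$species), 23L)
  expect_equal(nrow(net$reactions), 25L)
  nz <- net$initial_state[net$initial_state > 0]
  expect_equal(length(nz), 7L)
  expect_equal(
    nz[c("Rad5", "Rad6", "Rad18", "Ubc13:Mms2", "PCNA", "U", "L")],
    c(Rad5 = 1520L, Rad6 = 194L, Rad18 = 206L, `Ubc13:Mms2` = 193L,
      PCNA = 7480L, U = 8698L, L = 1001L)
  )
})

test_that("nuclear scaling reproduces the curated copy numbers", {
  expect_equal(nuclear_amount(124260, 0.07, dual_localized = TRUE), 8698L)
  expect_equal(nuclear_amount(8970, 0.07, dual_localized = TRUE), 628L)
  expect_equal(nuclear_amount(2770, 0.07, dual_localized = TRUE), 194L)
  expect_equal(nuclear_amount(2760, 0.07, dual_localized = TRUE), 193L)
  expect_equal(nuclear_amount(206, 0.07, dual_localized = FALSE), 206L)
  expect_equal(nuclear_amount(1000, 1.0, dual_localized = TRUE), 1000L)
  expect_error(nuclear_amount(-1, 0.07), "non-negative")
  expect_error(nuclear_amount(10, 0), "fraction")
  expect_error(nuclear_amount(10, 1.5), "fraction")
})

test_that("first-order Kcat converts to a per-second stochastic constant", {
  expect_equal(kcat_to_stochastic_constant(3.0), 5e-2)
  expect_equal(kcat_to_stochastic_constant(60), 1)
  expect_equal(kcat_to_stochastic_constant(0.6), 0.01)
  expect_error(kcat_to_stochastic_constant(0), "positive")
  # the converted in vitro rate is the reaction-16 constant
  rx <- prr_reactions()
  expect_equal(rx$c[rx$id == 16], kcat_to_stochastic_constant(3.0))
})

test_that("network builds from dose or lesion count, with overrides", {
  expect_equal(build_prr_network(uv_dose = 5)$lesions, 1001L)
  net <- build_prr_network(lesions = 2002, amount_overrides = c(U = 870))
  expect_equal(net$initial_state[["U"]], 870L)
  expect_equal(net$lesions, 2002L)
  expect_error(build_prr_network(lesions = 10, amount_overrides = c(Foo = 1)),
               "Unknown species")
  expect_error(build_prr_network(), "uv_dose")
  # zero lesions is a valid network in which lesion recognition never fires
  net0 <- build_prr_network(lesions = 0)
  expect_equal(propensities(net0)[1], 0)
})

test_that("reaction structure matches the mechanistic model", {
  net <- build_prr_network(lesions = 10)
  orders <- vapply(net$reactions$reactants, sum, integer(1))
  expect_true(all(orders %in% c(1L, 2L)))
  homodimer <- vapply(net$reactions$reactants,
                      function(re) length(re) == 1 && re[[1]] == 2L, logical(1))
  expect_equal(net$reactions$id[homodimer], 2L)
  # lesion recognition is the unique consumer of free lesions
  expect_equal(which(net$reactant_matrix["L", ] > 0), c(r1 = 1L))
  # the switched-off clamp is absorbing
  expect_true(all(net$reactant_matrix["PCNA_off", ] == 0))
  # stoichiometry columns are products minus reactants
  j <- which(net$reactions$id == 24)
  expected <- setNames(integer(23), net$species$species)
  expected[c("PCNA_on:U:U", "U", "PCNA_off")] <- c(-1L, 2L, 1L)
  expect_equal(net$stoichiometry[, j], expected[net$species$species],
               ignore_attr = TRUE)
})

test_that("structural conservation holds and constructed defects are flagged", {
  net <- build_prr_network(lesions = 1001)
  expect_equal(nrow(validate_conservation(net)), 0L)
  expect_equal(
    conserved_totals(net),
    c(pcna = 7480, lesion = 1001, ub = 8698, rad6 = 194, rad18 = 206,
      rad5 = 1520, ubc13mms2 = 193)
  )
  # reaction 23 emitting two ubiquitins breaks the ubiquitin law only
  bad <- net
  bad$reactions$products[[23]] <- c(U = 2L, PCNA_off = 1L)
  bad <- prrsim:::new_prr_network(bad$species, bad$reactions, bad$initial_state,
                                  lesions = bad$lesions)
  rep <- validate_conservation(bad)
  expect_equal(rep$law, "ub")
  expect_equal(rep$reaction, 23L)
  expect_equal(rep$delta, 1)
  # removing a reaction keeps a conservative system conservative
  sub <- net
  sub$reactions <- sub$reactions[-1, ]
  sub <- prrsim:::new_prr_network(sub$species, sub$reactions, sub$initial_state)
  expect_equal(nrow(validate_conservation(sub)), 0L)
})

test_that("species composition is consistent with conjugated-ubiquitin counts", {
  sp <- prr_species()
  expect_true(all(sp$conjugated_ub <= sp$ub))
  expect_true(all(sp$pcna %in% 0:1))
  expect_true(all(sp$conjugated_ub %in% 0:3))
})

test_that("constant and amount setters validate their targets", {
  net <- build_prr_network(lesions = 10)
  expect_equal(set_constant(net, 16, 0.1)$reactions$c[16], 0.1)
  expect_error(set_constant(net, 99, 0.1), "No reaction")
  expect_error(set_constant(net, 16, -1), "positive")
  expect_equal(set_initial_amount(net, "U", 870)$initial_state[["U"]], 870L)
  expect_error(set_initial_amount(net, "Foo", 1), "Unknown species")
})

test_that("network JSON serialization round-trips", {
  net <- build_prr_network(lesions = 4005, amount_overrides = c(U = 870))
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_equal(back$initial_state, net$initial_state)
  expect_equal(back$reactions$c, net$reactions$c)
  expect_equal(back$reactions$reactants, net$reactions$reactants)
  expect_equal(back$stoichiometry, net$stoichiometry)
  expect_equal(back$lesions, net$lesions)
})

test_that("species aliases are file-system safe and unique", {
  al <- species_aliases()
  expect_false(any(grepl(":", al$alias, fixed = TRUE)))
  expect_equal(anyDuplicated(al$alias), 0L)
})
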