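test_that("propensities follow the stochastic mass-action convention", {
  net <- build_prr_network(lesions = 10)
  counts <- net$initial_state
  # homodimerization Rad18 + Rad18 with n = 2: c * n(n-1)/2
  counts[] <- 0L; counts["Rad18"] <- 2L
  expect_equal(propensities(net, counts)[2], 1e-2 * 2 * 1 / 2)
  # empty reactant pool
  expect_equal(propensities(net, counts)[23], 0)
  # bimolecular product form
  counts[] <- 0L; counts["PCNA_on"] <- 3L; counts["Rad18:Rad18"] <- 4L
  expect_equal(propensities(net, counts)[5], 1e5 * 3 * 4)
})

test_that("compiled engines agree with the R propensity reference at t = 0", {
  # the very first waiting time uses the full propensity sum: a network with
  # one dominant channel fires it first, deterministically
  net <- build_prr_network(lesions = 1001)
  a <- propensities(net)
  expect_gt(a[11], 1e10)  # E2 charging dominates the initial state
  tr <- simulate_ssa(net, t_end = 1, sample_times = c(0, 1), seed = 1)
  expect_equal(tr$counts[, 1], as.numeric(net$initial_state), ignore_attr = TRUE)
  # within a second all Ubc13:Mms2 is charged
  expect_equal(unname(tr$counts["Ubc13:Mms2", 2]), 0)
  expect_equal(unname(tr$counts["Ubc13:U:Mms2", 2]), 193)
})

test_that("equal seeds give identical trajectories, different seeds differ", {
  net <- build_prr_network(lesions = 1001)
  st <- c(0, 600, 1200, 1800)
  t1 <- simulate_ssa(net, t_end = 1800, sample_times = st, seed = 7)
  t2 <- simulate_ssa(net, t_end = 1800, sample_times = st, seed = 7)
  t3 <- simulate_ssa(net, t_end = 1800, sample_times = st, seed = 8)
  expect_identical(t1$counts, t2$counts)
  expect_false(identical(t1$counts, t3$counts))
  l1 <- simulate_tau_leaping(net, t_end = 1800, sample_times = st, seed = 7)
  l2 <- simulate_tau_leaping(net, t_end = 1800, sample_times = st, seed = 7)
  expect_identical(l1$counts, l2$counts)
})

test_that("SSA matches the closed-form pure-death process", {
  # A -> B with c: A(t) ~ Binomial(N, p(t)), p(t) = exp(-c t)
  N <- 200; c <- 0.05
  net <- pure_death_network(N, c)
  tt <- c(0, 10, 20, 40, 80)
  n_runs <- 300
  ens <- run_ensemble(net, n_runs = n_runs, t_end = 80, sample_times = tt,
                      method = "ssa", base_seed = 100)
  p <- exp(-c * tt)
  expected_mean <- N * p
  expected_var <- N * p * (1 - p)
  se <- sqrt(pmax(expected_var, 1) / n_runs)
  expect_true(all(abs(ens$mean["A", ] - expected_mean) < 4 * se))
  # across-run variance matches the binomial survival variance
  mid <- 2:5
  expect_true(all(
    abs(ens$std["A", mid]^2 - expected_var[mid]) < 5 * expected_var[mid] / sqrt(n_runs)
  ))
})

test_that("tau-leaping converges to the exact law as eps shrinks", {
  # explicit tau-leaping has a weak bias of order eps; against the
  # closed-form pure-death mean the bias must shrink with eps and become
  # statistically invisible at small eps
  N <- 5000; c <- 0.02
  net <- pure_death_network(N, c)
  tt <- c(0, 25, 50, 100)
  n_runs <- 120
  exact <- N * exp(-c * tt)
  err <- function(eps, seed) {
    ens <- run_ensemble(net, n_runs = n_runs, t_end = 100, sample_times = tt,
                        method = "tau-leaping", base_seed = seed, eps = eps)
    list(dev = abs(ens$mean["A", ] - exact), std = ens$std["A", ])
  }
  coarse <- err(0.10, 5000)
  fine <- err(0.005, 6000)
  expect_lt(max(fine$dev), max(coarse$dev))
  se <- fine$std / sqrt(n_runs)
  expect_true(all(fine$dev <= 4 * pmax(se, 1e-9)))
  # at this copy number the step-size control actually leaps
  tl <- simulate_tau_leaping(net, t_end = 100, sample_times = tt, seed = 2)
  expect_gt(tl$method_params$n_leaps, 0)
  # with a vanishing error bound tau-leaping degenerates to exact stepping
  tiny <- simulate_tau_leaping(net, t_end = 100, sample_times = tt,
                               seed = 3, eps = 1e-4)
  expect_equal(tiny$method_params$n_leaps, 0)
})

test_that("counts stay non-negative and conservation holds along trajectories", {
  net <- build_prr_network(lesions = 1001)
  st <- seq(0, 1800, by = 300)
  ref <- conserved_totals(net)
  for (sim in list(simulate_ssa, simulate_tau_leaping)) {
    tr <- sim(net, t_end = 1800, sample_times = st, seed = 42)
    expect_true(all(tr$counts >= 0))
    totals <- apply(tr$counts, 2, function(x) conserved_totals(net, x))
    expect_equal(totals, matrix(ref, nrow = 7, ncol = length(st),
                                dimnames = list(names(ref), NULL)),
                 ignore_attr = TRUE)
  }
})

test_that("with zero lesions no PCNA is ever modified", {
  net <- build_prr_network(lesions = 0)
  tr <- simulate_ssa(net, t_end = 3600, sample_times = c(0, 1800, 3600),
                     seed = 9)
  modified <- channel_sums(tr, net, c("mono", "di", "tri", "off", "unmodified"))
  expect_equal(unname(modified), rep(0, 3))
  expect_equal(unname(tr$counts["PCNA", ]), rep(7480, 3))
})

test_that("the switched-off clamp count is non-decreasing", {
  net <- build_prr_network(lesions = 1001)
  tr <- simulate_ssa(net, seed = 3)
  expect_true(all(diff(tr$counts["PCNA_off", ]) >= 0))
  expect_lte(max(tr$counts["PCNA_off", ]), 1001)
})

test_that("run_ensemble summarises replicate statistics correctly", {
  expect_error(run_ensemble(pure_death_network(), n_runs = 1), "at least 2")
  # a frozen system has zero dispersion everywhere
  ens <- run_ensemble(inert_network(10), n_runs = 5, t_end = 10,
                      sample_times = c(0, 5, 10), method = "ssa", base_seed = 1)
  expect_true(all(ens$std == 0))
  expect_true(all(ens$mean["A", ] == 10))
  # tidy output is long with one row per species-time
  td <- tidy(ens)
  expect_equal(nrow(td), 1 * 3)
  expect_named(td, c("time", "species", "mean", "std", "n_runs"))
})

test_that("simulation argument validation catches malformed input", {
  net <- build_prr_network(lesions = 10)
  expect_error(simulate_ssa(net, t_end = -1), "positive")
  expect_error(simulate_ssa(net, t_end = 10, sample_times = c(0, 20)),
               "0, t_end")
  expect_error(simulate_ssa(net, t_end = 10, sample_times = c(5, 0)),
               "ascending")
  expect_error(simulate_tau_leaping(net, eps = 2), "eps")
})
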