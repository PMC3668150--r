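# Simulation engines and ensembles.
#
# The exact SSA (Gillespie direct method) is the reference engine; tau-leaping
# trades exactness for speed using the Cao-Gillespie-Petzold step-size control
# with critical-reaction partitioning. Both run in compiled code and draw from
# R's RNG, so a seed fully determines a trajectory.

#' Default experimental sampling grid
#'
#' The western-blot sampling times used throughout: 0, 3 min, 30 min, then
#' hourly to 5 h, in seconds.
#'
#' @param t_end Horizon in seconds (times beyond it are dropped).
#' @return Numeric vector of sample times, seconds.
#' @export
prr_sample_times <- function(t_end = 18000) {
  tt <- c(0, 180, 1800, 3600, 7200, 10800, 14400, 18000)
  tt[tt <= t_end]
}

#' Reaction propensities of a state
#'
#' Mass-action propensities under the stochastic kinetics convention:
#' `c * n_A` for a first-order channel, `c * n_A * n_B` for a bimolecular
#' channel with distinct reactants, and `c * n_A * (n_A - 1) / 2` for a
#' homodimerization. This is the plain-R reference against which the compiled
#' engines are checked.
#'
#' @param network A `prr_network`.
#' @param counts Count vector in network species order (defaults to the
#'   initial state).
#' @return Numeric vector of propensities (per second), one per reaction.
#' @export
#' @examples
#' net <- build_prr_network(lesions = 1001)
#' propensities(net)[1]  # lesion recognition flux at t = 0
propensities <- function(network, counts = network$initial_state) {
  counts <- as.numeric(counts)
  vapply(seq_len(nrow(network$reactions)), function(j) {
    re <- network$reactions$reactants[[j]]
    idx <- match(names(re), network$species$species)
    a <- network$reactions$c[j]
    for (k in seq_along(idx)) {
      n <- counts[idx[k]]
      a <- a * (if (re[k] == 2L) n * (n - 1) / 2 else n)
    }
    a
  }, numeric(1))
}

# Pack a network into the flat arrays the C++ engines consume.
compile_network <- function(network) {
  R <- nrow(network$reactions)
  r1_idx <- integer(R); r1_mult <- integer(R); r2_idx <- integer(R)
  for (j in seq_len(R)) {
    re <- network$reactions$reactants[[j]]
    idx <- match(names(re), network$species$species)
    if (length(re) == 1L) {
      r1_idx[j] <- idx[1] - 1L
      r1_mult[j] <- as.integer(re[1])
      r2_idx[j] <- -1L
    } else {
      r1_idx[j] <- idx[1] - 1L
      r1_mult[j] <- 1L
      r2_idx[j] <- idx[2] - 1L
    }
  }
  list(
    init = as.numeric(network$initial_state),
    stoich = network$stoichiometry,
    r1_idx = r1_idx, r1_mult = r1_mult, r2_idx = r2_idx,
    c = network$reactions$c
  )
}

check_sim_args <- function(network, t_end, sample_times) {
  if (!inherits(network, "prr_network")) abort("`network` must be a prr_network.")
  if (nrow(network$species) == 0) abort("Network has no species.")
  if (t_end <= 0) abort("`t_end` must be positive.")
  if (any(sample_times < 0) || any(sample_times > t_end)) {
    abort("`sample_times` must lie in [0, t_end].")
  }
  if (is.unsorted(sample_times, strictly = TRUE)) {
    abort("`sample_times` must be strictly ascending.")
  }
}

new_trajectory <- function(network, counts, sample_times, seed, method,
                           method_params = list()) {
  dimnames(counts) <- list(network$species$species, NULL)
  structure(
    list(
      sample_times = sample_times,
      counts = counts,
      seed = seed,
      method = method,
      method_params = method_params,
      species = network$species
    ),
    class = "prr_trajectory"
  )
}

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Simulate an exact SSA trajectory
#'
#' Gillespie direct-method simulation of a mass-action network. The state is
#' sampled at `sample_times` with last-value-before-t (piecewise-constant)
#' interpolation.
#'
#' @param network A `prr_network`.
#' @param t_end Horizon in seconds. Default 18000 (5 h).
#' @param sample_times Ascending sample times in `[0, t_end]`, seconds.
#' @param seed Integer seed; if `NULL` the current RNG stream is used.
#' @param max_steps Safety cap on the number of reaction events.
#' @return A `prr_trajectory`: `sample_times`, integer `counts` matrix
#'   (species x time), `seed`, `method`, `method_params`.
#' @export
#' @examples
#' net <- build_prr_network(lesions = 0)
#' tr <- simulate_ssa(net, t_end = 60, sample_times = c(0, 30, 60), seed = 1)
#' tidy(tr)
simulate_ssa <- function(network, t_end = 18000,
                         sample_times = prr_sample_times(t_end),
                         seed = NULL, max_steps = 1e10) {
  check_sim_args(network, t_end, sample_times)
  cn <- compile_network(network)
  counts <- with_seed_maybe(seed, {
    cpp_ssa(cn$init, cn$stoich, cn$r1_idx, cn$r1_mult, cn$r2_idx, cn$c,
            as.numeric(sample_times), t_end, max_steps)
  })
  new_trajectory(network, counts, sample_times, seed, "ssa")
}

#' Simulate a tau-leaping trajectory
#'
#' Explicit tau-leaping with the Cao-Gillespie-Petzold step-size selection.
#' Reactions within `n_critical` firings of exhausting a reactant are treated
#' as critical and fired one at a time, which prevents negative counts; when
#' the selected leap would be shorter than a few SSA steps the engine takes
#' exact SSA steps instead.
#'
#' @inheritParams simulate_ssa
#' @param eps Error-control parameter bounding the relative propensity change
#'   per leap, in (0, 1). Default 0.03.
#' @param n_critical Critical-reaction threshold (firings to exhaustion).
#'   Default 10.
#' @param ssa_fallback_steps Number of exact steps per fallback batch.
#' @param fallback_mult Fall back to SSA when the leap is below
#'   `fallback_mult / a0`. Default 10.
#' @return A `prr_trajectory`; `method_params` records the control settings
#'   and the realised leap/exact-step counts.
#' @export
simulate_tau_leaping <- function(network, t_end = 18000,
                                 sample_times = prr_sample_times(t_end),
                                 eps = 0.03, n_critical = 10,
                                 seed = NULL, ssa_fallback_steps = 100,
                                 fallback_mult = 10, max_steps = 1e10) {
  check_sim_args(network, t_end, sample_times)
  if (eps <= 0 || eps >= 1) abort("`eps` must be in (0, 1).")
  cn <- compile_network(network)
  res <- with_seed_maybe(seed, {
    cpp_tau_leap(cn$init, cn$stoich, cn$r1_idx, cn$r1_mult, cn$r2_idx, cn$c,
                 as.numeric(sample_times), t_end, eps, n_critical,
                 as.integer(ssa_fallback_steps), fallback_mult, max_steps)
  })
  new_trajectory(network, res$counts, sample_times, seed, "tau-leaping",
                 method_params = list(eps = eps, n_critical = n_critical,
                                      n_leaps = res$n_leaps,
                                      n_ssa_steps = res$n_ssa_steps))
}

#' @export
print.prr_trajectory <- function(x, ...) {
  cat("<prr_trajectory> method=", x$method, ", ",
      nrow(x$counts), " species x ", length(x$sample_times), " sample times",
      if (!is.null(x$seed)) paste0(", seed=", x$seed), "\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname simulate_ssa
#' @param x A `prr_trajectory`.
#' @param ... Unused.
tidy.prr_trajectory <- function(x, ...) {
  tibble(
    time = rep(x$sample_times, each = nrow(x$counts)),
    species = rep(rownames(x$counts), times = length(x$sample_times)),
    count = as.vector(x$counts)
  )
}

#' Run an ensemble of independent trajectories
#'
#' Repeats a stochastic simulation `n_runs` times with derived seeds
#' (`base_seed + run_index - 1`) and summarises per-species and per-isoform
#' channel means and standard deviations at each sample time. Channel sums
#' (see [classify_isoform()]) are accumulated per run, so their dispersion is
#' the true across-run standard deviation of the summed counts.
#'
#' @inheritParams simulate_ssa
#' @param n_runs Number of independent runs (>= 2).
#' @param method `"tau-leaping"` (default) or `"ssa"`.
#' @param base_seed Integer; run `i` uses seed `base_seed + i - 1`. If `NULL`,
#'   runs draw from the current RNG stream.
#' @param ... Passed to the engine (`eps`, `n_critical`, ...).
#' @return A `prr_ensemble`: `sample_times`, `mean` and `std` matrices
#'   (species x time), `channel_mean`/`channel_std` (channel x time),
#'   `n_runs`, `method`, `lesions`.
#' @export
#' @examples
#' net <- build_prr_network(lesions = 0)
#' ens <- run_ensemble(net, n_runs = 3, t_end = 60,
#'                     sample_times = c(0, 30, 60), base_seed = 1)
#' ens$n_runs
run_ensemble <- function(network, n_runs = 100, t_end = 18000,
                         sample_times = prr_sample_times(t_end),
                         method = c("tau-leaping", "ssa"),
                         base_seed = NULL, ...) {
  method <- match.arg(method)
  if (n_runs < 2) abort("`n_runs` must be at least 2.")
  simulate <- switch(method, ssa = simulate_ssa, "tau-leaping" = simulate_tau_leaping)

  channels <- isoform_channels(network)
  ch_levels <- c("free", "unmodified", "mono", "di", "tri", "off")
  ch_map <- lapply(ch_levels, function(ch) which(channels$channel == ch))
  names(ch_map) <- ch_levels

  S <- nrow(network$species); K <- length(sample_times); C <- length(ch_levels)
  sum_x <- matrix(0, S, K); sum_x2 <- matrix(0, S, K)
  sum_c <- matrix(0, C, K); sum_c2 <- matrix(0, C, K)

  for (i in seq_len(n_runs)) {
    seed_i <- if (is.null(base_seed)) NULL else base_seed + i - 1
    tr <- simulate(network, t_end = t_end, sample_times = sample_times,
                   seed = seed_i, ...)
    sum_x <- sum_x + tr$counts
    sum_x2 <- sum_x2 + tr$counts^2
    chm <- do.call(rbind, lapply(ch_map, function(idx) {
      if (length(idx) == 0) numeric(K) else colSums(tr$counts[idx, , drop = FALSE])
    }))
    sum_c <- sum_c + chm
    sum_c2 <- sum_c2 + chm^2
  }

  msd <- function(s, s2) {
    m <- s / n_runs
    v <- pmax(s2 / n_runs - m^2, 0) * n_runs / (n_runs - 1)
    list(mean = m, std = sqrt(v))
  }
  sp <- msd(sum_x, sum_x2)
  ch <- msd(sum_c, sum_c2)
  dimnames(sp$mean) <- dimnames(sp$std) <- list(network$species$species, NULL)
  dimnames(ch$mean) <- dimnames(ch$std) <- list(ch_levels, NULL)

  structure(
    list(
      sample_times = sample_times,
      mean = sp$mean, std = sp$std,
      channel_mean = ch$mean, channel_std = ch$std,
      n_runs = n_runs, method = method, base_seed = base_seed,
      lesions = network$lesions
    ),
    class = "prr_ensemble"
  )
}

#' @export
print.prr_ensemble <- function(x, ...) {
  cat("<prr_ensemble> ", x$n_runs, " runs (", x$method, "), ",
      length(x$sample_times), " sample times",
      if (!is.na(x$lesions)) paste0(", lesions=", x$lesions), "\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname run_ensemble
#' @param x A `prr_ensemble`.
tidy.prr_ensemble <- function(x, ...) {
  K <- length(x$sample_times)
  tibble(
    time = rep(x$sample_times, each = nrow(x$mean)),
    species = rep(rownames(x$mean), times = K),
    mean = as.vector(x$mean),
    std = as.vector(x$std),
    n_runs = x$n_runs
  )
}
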