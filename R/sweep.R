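# One-at-a-time parameter exploration.
#
# Parameter sweep analysis (PSA) perturbs a single stochastic constant
# (log-spaced grid) or initial amount (linear grid) while everything else
# stays at reference, and re-simulates an ensemble per grid value. The Morris
# elementary-effects (EE) screen perturbs all constants one at a time along
# randomised trajectories in log10-factor space and ranks factors by the mean
# absolute effect mu*.

#' Default sweep grid for a target
#'
#' Stochastic constants sweep logarithmically over three orders of magnitude
#' either side of the reference value; initial amounts sweep linearly from 0
#' to twice the reference (deletion to 2-fold overexpression).
#'
#' @param reference Reference value (constant in s^-1, or molecule count).
#' @param type `"constant"` or `"amount"`.
#' @param n_samples Grid size; defaults to 7 (log sweep) or 9 (linear sweep).
#' @return Numeric vector of sweep values.
#' @export
#' @examples
#' sweep_grid(1e-2, "constant", n_samples = 7)
#' sweep_grid(8698, "amount", n_samples = 9)
sweep_grid <- function(reference, type = c("constant", "amount"),
                       n_samples = NULL) {
  type <- match.arg(type)
  if (reference <= 0 && type == "constant") abort("Reference constant must be positive.")
  if (type == "constant") {
    n <- if (is.null(n_samples)) 7L else n_samples
    10^seq(log10(reference) - 3, log10(reference) + 3, length.out = n)
  } else {
    n <- if (is.null(n_samples)) 9L else n_samples
    seq(0, 2 * reference, length.out = n)
  }
}

#' One-at-a-time parameter sweep
#'
#' For each value in the grid, rebuilds the network with that single parameter
#' changed (all others at reference), runs an ensemble, and collects the
#' isoform channel summaries.
#'
#' @param network Reference `prr_network`.
#' @param target Reaction id (integer, sweeps the stochastic constant) or
#'   species name (character, sweeps the initial amount).
#' @param values Sweep values; defaults to [sweep_grid()] around the
#'   reference value.
#' @param n_samples Grid size when `values` is `NULL`.
#' @param n_replicates Runs per grid value. Default 10.
#' @param t_end,sample_times,method Passed to [run_ensemble()].
#' @param base_seed Integer; grid value `g` uses seeds derived from
#'   `base_seed + (g - 1) * n_replicates`.
#' @param ... Further engine arguments.
#' @return A `prr_sweep`: tibble with columns `target`, `type`, `value` and a
#'   list column `ensemble` of `prr_ensemble` objects; `tidy()` unnests the
#'   channel summaries.
#' @export
parameter_sweep <- function(network, target, values = NULL, n_samples = NULL,
                            n_replicates = 10, t_end = 18000,
                            sample_times = prr_sample_times(t_end),
                            method = c("tau-leaping", "ssa"),
                            base_seed = NULL, ...) {
  method <- match.arg(method)
  if (is.numeric(target)) {
    j <- match(as.integer(target), network$reactions$id)
    if (is.na(j)) abort(paste0("No reaction with id ", target, "."))
    type <- "constant"
    reference <- network$reactions$c[j]
    modify <- function(v) set_constant(network, as.integer(target), v)
    label <- paste0("c", target)
  } else if (is.character(target)) {
    if (!target %in% network$species$species) {
      abort(paste0("Unknown species `", target, "`."))
    }
    type <- "amount"
    reference <- network$initial_state[[target]]
    modify <- function(v) set_initial_amount(network, target, v)
    label <- target
  } else {
    abort("`target` must be a reaction id or a species name.")
  }
  if (is.null(values)) values <- sweep_grid(reference, type, n_samples)
  if (type == "constant" && any(values <= 0)) {
    abort("Constant sweep values must be positive.")
  }

  ensembles <- purrr::imap(values, function(v, g) {
    seed_g <- if (is.null(base_seed)) NULL else base_seed + (g - 1) * n_replicates
    run_ensemble(modify(v), n_runs = n_replicates, t_end = t_end,
                 sample_times = sample_times, method = method,
                 base_seed = seed_g, ...)
  })
  out <- tibble(
    target = label, type = type, reference = as.numeric(reference),
    value = as.numeric(values), ensemble = ensembles
  )
  class(out) <- c("prr_sweep", class(out))
  out
}

#' @export
#' @rdname parameter_sweep
#' @param x A `prr_sweep`.
tidy.prr_sweep <- function(x, ...) {
  purrr::map2_dfr(x$value, x$ensemble, function(v, ens) {
    units_representation(ens) %>%
      mutate(target = x$target[1], value = v, .before = 1)
  })
}

#' Peak channel amounts along a sweep
#'
#' Summarises a sweep by the time-course maximum of the mono and poly
#' (di + tri) ensemble-mean channels at each swept value.
#'
#' @param sweep A `prr_sweep`.
#' @return A tibble with columns `value`, `peak_mono`, `peak_poly`.
#' @export
sweep_peaks <- function(sweep) {
  purrr::map2_dfr(sweep$value, sweep$ensemble, function(v, ens) {
    mp <- mono_poly_series(ens)
    tibble(
      value = v,
      peak_mono = max(mp$mean[mp$channel == "mono"]),
      peak_poly = max(mp$mean[mp$channel == "poly"])
    )
  })
}

# ---- Morris elementary effects ------------------------------------------

#' Morris one-at-a-time screening design
#'
#' Generates `r` randomised trajectories on a `p`-level grid in the unit
#' hypercube: each trajectory starts at a random grid point and moves one
#' factor at a time by `delta = p / (2 * (p - 1))` in a random order and
#' feasible direction, giving `k + 1` design points per trajectory.
#'
#' @param k Number of factors.
#' @param r Number of trajectories (>= 2).
#' @param p Number of grid levels (even, >= 2). Default 4.
#' @param seed Optional integer seed.
#' @return A list of `r` design matrices (`k + 1` rows, `k` columns) with an
#'   attribute `delta`.
#' @export
morris_design <- function(k, r, p = 4, seed = NULL) {
  if (r < 2) abort("`r` must be at least 2.")
  if (p < 2) abort("`p` must be at least 2.")
  delta <- p / (2 * (p - 1))
  levels_lo <- seq(0, 1 - delta, by = 1 / (p - 1))
  with_seed_maybe(seed, {
    lapply(seq_len(r), function(tr) {
      base <- sample(levels_lo, k, replace = TRUE)
      dir <- sample(c(-1, 1), k, replace = TRUE)
      # a negative move is feasible only from the upper half of the grid
      start <- ifelse(dir < 0, base + delta, base)
      order_k <- sample.int(k)
      pts <- matrix(NA_real_, nrow = k + 1, ncol = k)
      x <- start
      pts[1, ] <- x
      for (s in seq_len(k)) {
        i <- order_k[s]
        x[i] <- x[i] + dir[i] * delta
        pts[s + 1, ] <- x
      }
      structure(pts, moved = order_k, dir = dir)
    }) -> traj
    attr(traj, "delta") <- delta
    traj
  })
}

#' Elementary effects from a Morris design
#'
#' Evaluates `f` at every design point and forms one elementary effect per
#' factor per trajectory: `EE_i = (y_after - y_before) / (direction * step)`,
#' where `step` is the move in the evaluation scale (`delta * span`).
#'
#' @param design Output of [morris_design()].
#' @param f Function mapping a unit-cube point (length-`k` numeric) to a named
#'   numeric vector of outputs.
#' @param span Width of the factor interval in evaluation units (e.g. decades
#'   of log10-factor); the EE denominator is `delta * span`. Default 1.
#' @return A tibble with columns `factor` (index), `output`, `ee`,
#'   `trajectory`.
#' @export
morris_ee <- function(design, f, span = 1) {
  delta <- attr(design, "delta")
  purrr::imap_dfr(design, function(pts, tr) {
    ys <- lapply(seq_len(nrow(pts)), function(i) f(pts[i, ]))
    moved <- attr(pts, "moved")
    dir <- attr(pts, "dir")
    purrr::map_dfr(seq_along(moved), function(s) {
      i <- moved[s]
      dy <- unlist(ys[[s + 1]]) - unlist(ys[[s]])
      tibble(
        factor = i,
        output = names(dy) %||% paste0("y", seq_along(dy)),
        ee = dy / (dir[i] * delta * span),
        trajectory = tr
      )
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

summarise_ee <- function(ee_samples) {
  ee_samples %>%
    group_by(.data$factor, .data$output) %>%
    summarise(
      mu = mean(.data$ee),
      mu_star = mean(abs(.data$ee)),
      sigma = sd(.data$ee),
      .groups = "drop"
    ) %>%
    group_by(.data$output) %>%
    mutate(rank = rank(-.data$mu_star, ties.method = "first")) %>%
    ungroup() %>%
    arrange(.data$output, .data$rank)
}

#' Morris elementary-effects screening of the reaction constants
#'
#' Global sensitivity screen over stochastic constants: each factor varies on
#' a `p`-level grid in log10 space spanning `decades[1]` orders of magnitude
#' below to `decades[2]` above its reference value. For every Morris design
#' point an ensemble is simulated and the outputs extracted; elementary
#' effects are output change per unit change of log10(constant).
#'
#' Default outputs are the mono- and poly-ubiquitylated PCNA channel means at
#' 30 min (near the low-dose peak) and their area under the curve over the
#' simulated horizon.
#'
#' @param network Reference `prr_network`.
#' @param factors Reaction ids to screen. Default: all.
#' @param r Number of Morris trajectories. Default 10.
#' @param p Grid levels. Default 4.
#' @param decades Orders of magnitude below/above reference. Default `c(2, 2)`.
#' @param outputs Function `prr_ensemble -> named numeric`; default
#'   [ee_default_outputs()].
#' @param n_replicates Runs per evaluation. Default 5.
#' @param t_end,sample_times,method Passed to [run_ensemble()].
#' @param base_seed Integer seed controlling both the design and the
#'   simulations.
#' @return A `prr_ee`: tibble with per-factor, per-output `mu`, `mu_star`,
#'   `sigma` and `rank` (by `mu_star`), plus attributes `ee_samples` (raw
#'   effects) and `settings`.
#' @export
elementary_effects <- function(network, factors = network$reactions$id,
                               r = 10, p = 4, decades = c(2, 2),
                               outputs = ee_default_outputs(),
                               n_replicates = 5, t_end = 18000,
                               sample_times = prr_sample_times(t_end),
                               method = c("tau-leaping", "ssa"),
                               base_seed = NULL) {
  method <- match.arg(method)
  if (!all(factors %in% network$reactions$id)) abort("Unknown reaction ids in `factors`.")
  k <- length(factors)
  span <- sum(decades)
  ref <- network$reactions$c[match(factors, network$reactions$id)]
  design <- morris_design(k, r, p,
                          seed = if (is.null(base_seed)) NULL else base_seed)

  eval_count <- 0L
  f <- function(u) {
    # u in [0,1]^k -> constants ref * 10^(span*u - decades_below)
    cs <- ref * 10^(span * u - decades[1])
    net <- network
    for (i in seq_len(k)) net <- set_constant(net, factors[i], cs[i])
    eval_count <<- eval_count + 1L
    seed_e <- if (is.null(base_seed)) NULL else
      base_seed + 1000L + (eval_count - 1L) * n_replicates
    ens <- run_ensemble(net, n_runs = n_replicates, t_end = t_end,
                        sample_times = sample_times, method = method,
                        base_seed = seed_e)
    outputs(ens)
  }
  samples <- morris_ee(design, f, span = span)
  samples$factor <- paste0("c", factors[samples$factor])
  out <- summarise_ee(samples)
  class(out) <- c("prr_ee", class(out))
  attr(out, "ee_samples") <- samples
  attr(out, "settings") <- list(factors = factors, r = r, p = p,
                                decades = decades, n_replicates = n_replicates,
                                t_end = t_end, method = method,
                                base_seed = base_seed)
  out
}

#' Default EE output statistics
#'
#' Mono- and poly-ubiquitylated PCNA ensemble means at a reference time and
#' as area under the time course (trapezoidal).
#'
#' @param at Time (seconds) of the point-statistic. Default 1800 (30 min).
#' @return A function `prr_ensemble -> named numeric`.
#' @export
ee_default_outputs <- function(at = 1800) {
  function(ens) {
    mp <- mono_poly_series(ens)
    tt <- ens$sample_times
    pick <- function(chan) mp$mean[mp$channel == chan]
    auc <- function(y) sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    j <- which.min(abs(tt - at))
    c(
      mono_at = pick("mono")[j],
      poly_at = pick("poly")[j],
      mono_auc = auc(pick("mono")),
      poly_auc = auc(pick("poly"))
    )
  }
}

#' @export
#' @rdname elementary_effects
#' @param x A `prr_ee`.
tidy.prr_ee <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
print.prr_ee <- function(x, ...) {
  s <- attr(x, "settings")
  cat("<prr_ee> Morris screening: ", length(s$factors), " factors, r=", s$r,
      ", p=", s$p, "\n", sep = "")
  print(as_tibble(unclass(x)))
  invisible(x)
}
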