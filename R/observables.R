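# Western-blot observables.
#
# A species' isoform channel is the number of ubiquitins covalently
# conjugated to its PCNA clamp, regardless of non-covalent binding partners:
# denaturing SDS-PAGE dissolves the Rad18/Rad5/Ubc13:Mms2 complexes, so band
# mobility reflects conjugated ubiquitins only. Carrier-bound ubiquitin
# (riding on Rad6:U or Ubc13:U:Mms2 within a complex) does not count.

#' Isoform channel of each species
#'
#' Maps every species of a network to its blot channel: `free` (unengaged
#' PCNA), `unmodified` (clamp at a lesion, no conjugated ubiquitin), `mono`,
#' `di`, `tri` (1-3 conjugated ubiquitins), `off` (switched-off clamp after
#' bypass), or `NA` for species without a PCNA unit.
#'
#' @param network A `prr_network`; defaults to the canonical network shape.
#' @return A tibble with columns `species`, `channel`.
#' @export
#' @examples
#' isoform_channels()
isoform_channels <- function(network = NULL) {
  sp <- if (is.null(network)) prr_species() else network$species
  channel <- dplyr::case_when(
    sp$pcna == 0 ~ NA_character_,
    sp$species == "PCNA_off" ~ "off",
    sp$lesion == 0 ~ "free",
    sp$conjugated_ub == 0 ~ "unmodified",
    sp$conjugated_ub == 1 ~ "mono",
    sp$conjugated_ub == 2 ~ "di",
    sp$conjugated_ub == 3 ~ "tri"
  )
  tibble(species = sp$species, channel = channel)
}

#' Isoform channel of one species
#'
#' @param species Species name from the canonical network.
#' @param network Optional `prr_network` providing the species table.
#' @return One of `"free"`, `"unmodified"`, `"mono"`, `"di"`, `"tri"`,
#'   `"off"`, or `NA` for species without PCNA.
#' @export
#' @examples
#' classify_isoform("PCNA_on:U")            # "mono"
#' classify_isoform("Rad5:PCNA_on:U:U")     # "di"
classify_isoform <- function(species, network = NULL) {
  ch <- isoform_channels(network)
  j <- match(species, ch$species)
  if (anyNA(j)) {
    abort(paste0("Unknown species: ",
                 paste(species[is.na(j)], collapse = ", ")))
  }
  ch$channel[j]
}

#' Units representation (UR) of an ensemble
#'
#' Extracts the absolute molecule counts of the blot channels from an
#' ensemble summary: per-channel across-run mean and standard deviation of
#' the summed species counts at each sample time.
#'
#' @param ens A `prr_ensemble` from [run_ensemble()].
#' @return An isoform series: tibble with columns `time` (seconds),
#'   `channel`, `mean`, `std`, `provenance = "simulated"`.
#' @export
units_representation <- function(ens) {
  if (!inherits(ens, "prr_ensemble")) abort("`ens` must be a prr_ensemble.")
  K <- length(ens$sample_times)
  tibble(
    time = rep(ens$sample_times, each = nrow(ens$channel_mean)),
    channel = rep(rownames(ens$channel_mean), times = K),
    mean = as.vector(ens$channel_mean),
    std = as.vector(ens$channel_std),
    provenance = "simulated"
  )
}

#' Normalized representation (NR): isoform ratios
#'
#' Converts channel amounts to the ratio of mono-, di- and tri-ubiquitylated
#' PCNA over total ubiquitylated PCNA at each time. Times whose total modified
#' signal is below `detection_threshold` (or zero) are flagged
#' `below_detection` and carry all-zero ratios, mirroring the western-blot
#' detection floor.
#'
#' @param series An isoform series (long tibble with `time`, `channel`,
#'   `mean`), e.g. from [units_representation()] or [ratios_from_blot()].
#' @param detection_threshold Minimum total modified signal (molecules) for a
#'   time point to count as detected. Default 0.
#' @return A ratio series: tibble with columns `time`, `isoform`
#'   (`mono`/`di`/`tri`), `ratio`, `below_detection`.
#' @export
#' @examples
#' s <- tibble::tibble(time = 0, channel = c("mono", "di", "tri"),
#'                     mean = c(10, 10, 20))
#' normalized_representation(s)
normalized_representation <- function(series, detection_threshold = 0) {
  ub <- series %>%
    filter(.data$channel %in% c("mono", "di", "tri")) %>%
    select("time", "channel", "mean")
  if (any(ub$mean < 0)) abort("Isoform amounts must be non-negative.")
  ub %>%
    group_by(.data$time) %>%
    mutate(
      total = sum(.data$mean),
      below_detection = .data$total < detection_threshold | .data$total <= 0,
      ratio = ifelse(.data$below_detection, 0, .data$mean / .data$total)
    ) %>%
    ungroup() %>%
    transmute(
      time = .data$time,
      isoform = factor(.data$channel, levels = c("mono", "di", "tri")),
      ratio = .data$ratio,
      below_detection = .data$below_detection
    ) %>%
    arrange(.data$time, .data$isoform)
}

#' Compare simulated and experimental ratio series
#'
#' Joins two ratio series on their common sample times, drops times flagged
#' below detection in either (reporting them), and returns per-time,
#' per-isoform absolute deviations plus summary statistics.
#'
#' @param sim,exp Ratio series tibbles (`time`, `isoform`, `ratio`,
#'   `below_detection`), e.g. from [normalized_representation()].
#' @return A list with `deviations` (tibble: `time`, `isoform`, `ratio_sim`,
#'   `ratio_exp`, `abs_dev`), `mean_dev`, `max_dev`, and `excluded_times`.
#' @export
compare_series <- function(sim, exp) {
  common <- intersect(unique(sim$time), unique(exp$time))
  if (length(common) == 0) abort("The two series share no sample times.")
  flag <- function(x) {
    x %>% group_by(.data$time) %>%
      summarise(below = any(.data$below_detection), .groups = "drop")
  }
  flags <- bind_rows(flag(sim), flag(exp)) %>%
    filter(.data$time %in% common) %>%
    group_by(.data$time) %>%
    summarise(below = any(.data$below), .groups = "drop")
  excluded <- flags$time[flags$below]
  keep <- setdiff(common, excluded)
  dev <- inner_join(
    sim %>% filter(.data$time %in% keep) %>%
      select("time", "isoform", ratio_sim = "ratio"),
    exp %>% filter(.data$time %in% keep) %>%
      select("time", "isoform", ratio_exp = "ratio"),
    by = c("time", "isoform")
  ) %>%
    mutate(abs_dev = abs(.data$ratio_sim - .data$ratio_exp)) %>%
    arrange(.data$time, .data$isoform)
  list(
    deviations = dev,
    mean_dev = if (nrow(dev)) mean(dev$abs_dev) else NA_real_,
    max_dev = if (nrow(dev)) max(dev$abs_dev) else NA_real_,
    excluded_times = excluded
  )
}

#' Mono- and poly-ubiquitylated PCNA time courses
#'
#' Convenience view of an ensemble: the mono channel and the poly channel
#' (di + tri summed), as used in the headline pathway-choice figures.
#'
#' @param ens A `prr_ensemble`.
#' @return A tibble with columns `time`, `channel` (`mono`/`poly`), `mean`.
#' @export
mono_poly_series <- function(ens) {
  ur <- units_representation(ens)
  bind_rows(
    ur %>% filter(.data$channel == "mono") %>% select("time", "channel", "mean"),
    ur %>% filter(.data$channel %in% c("di", "tri")) %>%
      group_by(.data$time) %>%
      summarise(channel = "poly", mean = sum(.data$mean), .groups = "drop")
  ) %>% arrange(.data$time, .data$channel)
}
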