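# Synthetic western-blot densitometry.
#
# Stands in for the wet readout: a ground-truth isoform series (molecule
# counts) becomes per-replicate band intensities with multiplicative lognormal
# noise, an additive background, a gain (arbitrary units per molecule) and a
# detection floor, then is quantified back to isoform ratios the same way the
# experimental protocol is: background-subtract, optionally normalise to the
# unmodified-PCNA band, express mono/di/tri as ratios summing to one, and
# average across replicates.

#' Synthetic blot noise and detection parameters
#'
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   band noise. Default 0.2 (typical replicate scatter of densitometry).
#' @param background Additive densitometry offset, arbitrary units. Default 0.
#' @param detection_threshold Molecules below which a band is not transferred
#'   to film (background-only). Default 0.
#' @param gain Arbitrary units per molecule. Default 1.
#' @param n_replicates Number of independent blots. Default 3.
#' @param clip Optional saturation ceiling of the film response (arbitrary
#'   units); `Inf` disables clipping.
#' @return A list of class `blot_params`.
#' @export
blot_params <- function(noise_cv = 0.2, background = 0,
                        detection_threshold = 0, gain = 1,
                        n_replicates = 3, clip = Inf) {
  if (noise_cv < 0) abort("`noise_cv` must be non-negative.")
  if (gain <= 0) abort("`gain` must be positive.")
  if (n_replicates < 1) abort("`n_replicates` must be at least 1.")
  structure(list(noise_cv = noise_cv, background = background,
                 detection_threshold = detection_threshold, gain = gain,
                 n_replicates = n_replicates, clip = clip),
            class = "blot_params")
}

# lognormal with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate synthetic blot quantifications
#'
#' Converts a ground-truth isoform series into noisy replicate band
#' intensities: `intensity = gain * amount * lognormal(1, cv) + background`,
#' with amounts below the detection threshold yielding background-only bands.
#' The unmodified-PCNA reference band is the sum of the `free`, `unmodified`
#' and `off` channels (clamp without conjugated ubiquitin).
#'
#' @param truth Isoform series tibble (`time`, `channel`, `mean`), e.g. from
#'   [units_representation()].
#' @param params A [blot_params()] object.
#' @param seed Optional integer seed.
#' @return A blot quantification: tibble with columns `replicate`, `time`,
#'   `band` (`mono`/`di`/`tri`/`unmodified`), `intensity`.
#' @export
generate_blot <- function(truth, params = blot_params(), seed = NULL) {
  stopifnot(inherits(params, "blot_params"))
  bands <- bind_rows(
    truth %>% filter(.data$channel %in% c("mono", "di", "tri")) %>%
      select("time", band = "channel", amount = "mean"),
    truth %>% filter(.data$channel %in% c("free", "unmodified", "off")) %>%
      group_by(.data$time) %>%
      summarise(band = "unmodified", amount = sum(.data$mean), .groups = "drop")
  )
  with_seed_maybe(seed, {
    out <- purrr::map_dfr(seq_len(params$n_replicates), function(rep_i) {
      bands %>%
        mutate(
          replicate = rep_i,
          detected = .data$amount >= params$detection_threshold & .data$amount > 0,
          intensity = ifelse(
            .data$detected,
            pmin(params$gain * .data$amount * rlnorm_cv(n(), params$noise_cv),
                 params$clip),
            0
          ) + params$background
        )
    })
    out %>%
      select("replicate", "time", "band", "intensity") %>%
      arrange(.data$replicate, .data$time, .data$band)
  })
}

#' Quantify isoform ratios from a synthetic blot
#'
#' Per replicate: subtract the background, optionally divide each band by the
#' unmodified-PCNA band of the same lane (loading normalisation; it cancels in
#' the final ratios when the gain is uniform across bands), and normalise
#' mono/di/tri to sum to one. Replicates are then averaged; times where every
#' replicate's total modified signal is at background are flagged below
#' detection.
#'
#' @param blot A blot quantification from [generate_blot()].
#' @param normalize_to_unmodified Divide by the unmodified-PCNA band first.
#'   Default `TRUE`.
#' @param background Background level to subtract (same units as intensities).
#'   Default 0.
#' @return A ratio series with dispersion: tibble with columns `time`,
#'   `isoform`, `ratio` (across-replicate mean), `std`, `below_detection`.
#' @export
ratios_from_blot <- function(blot, normalize_to_unmodified = TRUE,
                             background = 0) {
  if (nrow(blot) == 0) abort("Empty blot quantification.")
  per_rep <- blot %>%
    mutate(signal = pmax(.data$intensity - background, 0)) %>%
    tidyr::pivot_wider(id_cols = c("replicate", "time"),
                       names_from = "band", values_from = "signal") %>%
    mutate(
      across(c("mono", "di", "tri"),
             ~ if (normalize_to_unmodified)
                 ifelse(.data$unmodified > 0, .x / .data$unmodified, .x)
               else .x),
      total = .data$mono + .data$di + .data$tri,
      detected = .data$total > 0
    )
  ratios <- per_rep %>%
    tidyr::pivot_longer(c("mono", "di", "tri"),
                        names_to = "isoform", values_to = "signal") %>%
    mutate(ratio = ifelse(.data$detected, .data$signal / .data$total, 0))
  ratios %>%
    group_by(.data$time, .data$isoform) %>%
    summarise(
      below_detection = !any(.data$detected),
      std = if (sum(.data$detected) > 1) sd(.data$ratio[.data$detected]) else 0,
      ratio = mean(.data$ratio[.data$detected]),
      .groups = "drop"
    ) %>%
    mutate(
      ratio = ifelse(.data$below_detection, 0, .data$ratio),
      std = ifelse(.data$below_detection, 0, .data$std),
      isoform = factor(.data$isoform, levels = c("mono", "di", "tri"))
    ) %>%
    select("time", "isoform", "ratio", "std", "below_detection") %>%
    arrange(.data$time, .data$isoform)
}

#' Write a ratio series to CSV
#'
#' The experimental ratio-series dialect: comma-separated with a header row
#' and `#`-prefixed metadata lines, columns `time`, `isoform`, `ratio`,
#' optional `std`, `below_detection`.
#'
#' @param series Ratio series tibble.
#' @param path Output path.
#' @param metadata Named character vector written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_ratio_csv <- function(series, path, metadata = c()) {
  lines <- c(
    paste0("# prrsim ratio series"),
    if (length(metadata)) paste0("# ", names(metadata), ": ", metadata)
  )
  writeLines(lines, path)
  readr::write_csv(series, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a ratio series CSV
#'
#' @param path Path written by [write_ratio_csv()] (or following the same
#'   layout).
#' @return A ratio series tibble.
#' @export
read_ratio_csv <- function(path) {
  out <- readr::read_csv(path, comment = "#", col_types = readr::cols())
  out$isoform <- factor(out$isoform, levels = c("mono", "di", "tri"))
  out
}
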