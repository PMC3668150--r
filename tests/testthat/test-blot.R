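truth_series <- function(times, mono, di, tri, unmod = 1000) {
  tibble::tibble(
    time = rep(times, times = 4),
    channel = rep(c("mono", "di", "tri", "unmodified"), each = length(times)),
    mean = c(mono, di, tri, rep(unmod, length(times)))
  )
}

test_that("a noiseless blot is exactly proportional to the truth", {
  truth <- truth_series(c(0, 1), mono = c(10, 5), di = c(10, 2), tri = c(20, 1))
  blot <- generate_blot(truth, blot_params(noise_cv = 0, gain = 3,
                                           n_replicates = 2), seed = 1)
  got <- blot[blot$band == "mono" & blot$replicate == 1, ]
  expect_equal(got$intensity, 3 * c(10, 5))
  # replicates are identical without noise
  expect_equal(blot$intensity[blot$replicate == 1],
               blot$intensity[blot$replicate == 2])
})

test_that("noiseless quantification recovers the exact ratios", {
  truth <- truth_series(0, mono = 10, di = 10, tri = 20)
  blot <- generate_blot(truth, blot_params(noise_cv = 0), seed = 1)
  ratios <- ratios_from_blot(blot)
  expect_equal(ratios$ratio, c(0.25, 0.25, 0.50))
  expect_equal(ratios$std, rep(0, 3))
  expect_false(any(ratios$below_detection))
})

test_that("zero-signal lanes come out below detection", {
  truth <- truth_series(c(0, 1), mono = c(0, 10), di = c(0, 10), tri = c(0, 20))
  blot <- generate_blot(truth, blot_params(noise_cv = 0.1, background = 2),
                        seed = 4)
  ratios <- ratios_from_blot(blot, background = 2)
  expect_true(all(ratios$below_detection[ratios$time == 0]))
  expect_false(any(ratios$below_detection[ratios$time == 1]))
  expect_equal(ratios$ratio[ratios$time == 0], rep(0, 3))
})

test_that("noise propagates into replicate-to-replicate dispersion", {
  truth <- truth_series(0, mono = 100, di = 100, tri = 200)
  blot <- generate_blot(truth, blot_params(noise_cv = 0.2, n_replicates = 3),
                        seed = 7)
  ratios <- ratios_from_blot(blot)
  expect_true(all(ratios$std > 0))
})

test_that("loading normalisation cancels in the ratios", {
  truth <- truth_series(c(0, 1), mono = c(30, 10), di = c(20, 10), tri = c(10, 20))
  blot <- generate_blot(truth, blot_params(noise_cv = 0.3, n_replicates = 3),
                        seed = 11)
  with_norm <- ratios_from_blot(blot, normalize_to_unmodified = TRUE)
  without_norm <- ratios_from_blot(blot, normalize_to_unmodified = FALSE)
  expect_equal(with_norm$ratio, without_norm$ratio)
  expect_equal(with_norm$std, without_norm$std)
})

test_that("full chain ensemble -> UR -> blot -> NR round-trips exactly", {
  net <- build_prr_network(lesions = 1001)
  ens <- run_ensemble(net, n_runs = 3, t_end = 3600,
                      sample_times = c(0, 1800, 3600), method = "ssa",
                      base_seed = 31)
  ur <- units_representation(ens)
  direct <- normalized_representation(ur)
  blot <- generate_blot(ur, blot_params(noise_cv = 0, background = 0),
                        seed = 1)
  via_blot <- ratios_from_blot(blot)
  joined <- dplyr::inner_join(direct, via_blot, by = c("time", "isoform"),
                              suffix = c("_direct", "_blot"))
  expect_equal(joined$ratio_blot, joined$ratio_direct)
  expect_equal(joined$below_detection_blot, joined$below_detection_direct)
})

test_that("noisy replicate means converge to the truth as noise vanishes", {
  truth <- truth_series(0, mono = 500, di = 300, tri = 200)
  target <- c(0.5, 0.3, 0.2)
  devs <- vapply(c(0.4, 0.1, 0.01), function(cv) {
    blot <- generate_blot(truth, blot_params(noise_cv = cv, n_replicates = 8),
                          seed = 99)
    mean(abs(ratios_from_blot(blot)$ratio - target))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 0.005)
})

test_that("replicate-mean ratios cover the truth at the 3-sigma scale", {
  # with 3 replicates the interval mean +/- 3 sigma/sqrt(3), with sigma the
  # replicate-level dispersion of a single blot's ratio, should cover the
  # true ratio at nearly every detected time point. (The 3-replicate sample
  # sd cannot be used here: a t-interval with 2 degrees of freedom at the
  # 3-sigma multiplier only covers ~90% per cell.)
  truth <- truth_series(c(0, 1, 2), mono = c(50, 100, 20), di = c(30, 80, 10),
                        tri = c(20, 60, 5))
  target <- normalized_representation(truth)
  params <- blot_params(noise_cv = 0.2, n_replicates = 3)
  # replicate-level sigma estimated once from one many-replicate blot:
  # per-replicate ratios are band/(sum of modified bands) (loading
  # normalisation cancels)
  sigma_true <- withr::with_seed(271, {
    big <- generate_blot(truth, blot_params(noise_cv = 0.2, n_replicates = 2000))
    per_rep <- big |>
      tidyr::pivot_wider(names_from = band, values_from = intensity) |>
      dplyr::mutate(total = mono + di + tri)
    out <- tidyr::pivot_longer(per_rep, c(mono, di, tri),
                               names_to = "isoform", values_to = "band") |>
      dplyr::group_by(time, isoform) |>
      dplyr::summarise(sigma = stats::sd(band / total), .groups = "drop") |>
      dplyr::mutate(isoform = factor(isoform, levels = c("mono", "di", "tri"))) |>
      dplyr::arrange(time, isoform)
    out$sigma
  })
  reps <- 200
  covered <- withr::with_seed(314, {
    vapply(seq_len(reps), function(i) {
      est <- ratios_from_blot(generate_blot(truth, params))
      all(abs(est$ratio - target$ratio) <= 3 * sigma_true / sqrt(3))
    }, logical(1))
  })
  expect_gte(mean(covered), 0.95)
})

test_that("ratio CSV writer and reader round-trip with metadata", {
  truth <- truth_series(c(0, 1800), mono = c(10, 8), di = c(5, 4), tri = c(5, 2))
  ratios <- ratios_from_blot(generate_blot(truth, blot_params(noise_cv = 0.1),
                                           seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratio_csv(ratios, path, metadata = c(seed = "3", scenario = "synthetic"))
  expect_true(any(grepl("^# seed: 3", readLines(path))))
  back <- read_ratio_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(ratios))
})
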