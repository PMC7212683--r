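test_that("invalid configurations are rejected with descriptive messages", {
  expect_error(cohort_config(n_td = 0), "positive integers")
  expect_error(cohort_config(videos = data.frame(video_id = "v1",
                                                 duration_s = 25)),
               "\\[13, 20\\]")
  expect_error(cohort_config(frame_rate_hz = -1), "positive")
  expect_error(cohort_config(dropout_rate = 1.4), "\\[0, 1\\]")
  bad <- default_calibration_targets()
  bad$avg_au6_sd[1] <- 0
  expect_error(cohort_config(calibration_targets = bad), "positive")
  expect_error(cohort_config(scale_effects = list(withdrawal_auc6_cor = -1.2)),
               "\\(-1, 1\\)")
})

test_that("identical config and seed reproduce the cohort byte-for-byte", {
  cfg <- small_config(seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- generate_cohort(small_config(seed = 100))
  expect_false(identical(a$traces$evidence, c2$traces$evidence))
})

test_that("zero amplitude and zero noise yield identically zero features", {
  cfg <- small_config(
    seed = 4, calibration_targets = NULL,
    burst_amplitude = list(td = c(mean = 0, sd = 0),
                           over = c(mean = 0, sd = 0),
                           under = c(mean = 0, sd = 0)),
    baseline_noise_sd = 0)
  ch <- generate_cohort(cfg)
  expect_true(all(ch$traces$evidence == 0))
  f <- extract_features(ch$traces)
  expect_true(all(f$avg_au12 == 0 & f$avg_au6 == 0 &
                  f$auc_au12 == 0 & f$auc_au6 == 0))
})

test_that("trace structure honours the recording model", {
  cfg <- small_config(seed = 8)
  ch <- generate_cohort(cfg)
  expect_true(all(ch$participants$age_years >= 6))
  expect_true(all(is.na(ch$participants$iq[ch$participants$group == "TD"])))
  one <- ch$traces[ch$traces$participant_id == "P001" &
                   ch$traces$video_id == "v1" & ch$traces$au == "AU12", ]
  expect_equal(diff(one$time_s), rep(1 / 24, nrow(one) - 1))
  expect_true(all(is.finite(ch$traces$evidence[ch$traces$face_detected])))
  # every participant x 3 videos x 2 AUs present
  expect_equal(nrow(unique(ch$traces[c("participant_id", "video_id", "au")])),
               nrow(ch$participants) * 3 * 2)
})

test_that("frames without a detected face carry no information downstream", {
  ch <- generate_cohort(small_config(seed = 23))
  f1 <- extract_features(ch$traces)
  perturbed <- ch$traces
  idx <- !perturbed$face_detected
  expect_gt(sum(idx), 0)
  perturbed$evidence[idx] <- perturbed$evidence[idx] * 50 + 1000
  f2 <- extract_features(perturbed)
  expect_equal(f1, f2)
})

test_that("group feature moments are calibrated to their targets", {
  # moment consistency at a large cohort: means within 2% (relative to the
  # feature scale) and SDs within 2% of the target SD
  cfg <- cohort_config(n_td = 2000, n_asd_over = 2000, n_asd_under = 2000,
                       seed = 12)
  ch <- generate_traces(generate_participants(cfg), cfg)
  f <- extract_features(ch$traces)
  m <- merge(f, ch$participants, by = "participant_id")
  tg <- default_calibration_targets()
  for (cell in c("td", "over", "under")) {
    s <- if (cell == "td") m[m$group == "TD", ] else
      m[m$true_subgroup == cell, ]
    t_row <- tg[tg$group == cell, ]
    for (au in c("au12", "au6")) {
      mu <- t_row[[paste0("avg_", au, "_mean")]]
      sdv <- t_row[[paste0("avg_", au, "_sd")]]
      vals <- s[[paste0("avg_", au)]]
      expect_lt(abs(mean(vals) - mu), 0.02 * max(abs(mu), sdv))
      expect_lt(abs(sd(vals) - sdv), 0.02 * sdv)
    }
  }
  # Table 1 means at the study sizes, within 3 standard errors
  cfg2 <- cohort_config(seed = 3)
  ch2 <- generate_traces(generate_participants(cfg2), cfg2)
  f2 <- merge(extract_features(ch2$traces), ch2$participants,
              by = "participant_id")
  td <- f2[f2$group == "TD", ]
  expect_lt(abs(mean(td$avg_au12) - 0.64), 3 * 0.63 / sqrt(41))
  ov <- f2[f2$true_subgroup == "over", ]
  expect_lt(abs(mean(ov$avg_au12) - 1.08), 3 * 0.78 / sqrt(35))
  un <- f2[f2$true_subgroup == "under", ]
  expect_lt(abs(mean(un$avg_au12) - 0.09), 3 * 0.57 / sqrt(89))
})

test_that("a deterministic single burst reproduces its closed-form features", {
  # one raised-cosine burst, no noise, no dropout: the per-video average is
  # amplitude * duration / (2 * video duration) sampled on the frame grid,
  # and the AUC matches a dense Riemann oracle
  cfg <- cohort_config(n_td = 1, n_asd_over = 1, n_asd_under = 1,
                       videos = data.frame(video_id = "v1", duration_s = 16),
                       baseline_noise_sd = 0, dropout_rate = 0,
                       event_rate = c(td = 1e-9, over = 1e-9, under = 1e-9),
                       duchenne_fraction = c(td = 1, over = 1, under = 1),
                       calibration_targets = NULL,
                       burst_amplitude = list(td = c(mean = 2, sd = 0),
                                              over = c(mean = 2, sd = 0),
                                              under = c(mean = 2, sd = 0)),
                       seed = 5)
  # event_rate ~ 0 forces the generator's guaranteed single burst path
  ch <- generate_traces(generate_participants(cfg), cfg)
  tr <- ch$traces[ch$traces$participant_id == "P001" &
                  ch$traces$au == "AU12", ]
  tr <- tr[order(tr$frame_index), ]
  peak <- max(tr$evidence)
  expect_gt(peak, 0)
  # recover burst support from the signal, then check the integral
  on <- which(tr$evidence > 1e-12)
  dur <- (length(on) - 1) / 24
  area_expected <- peak * dur / 2  # raised cosine: area = A * T / 2
  expect_equal(auc_abs_evidence(tr$evidence, tr$time_s), area_expected,
               tolerance = 0.03)
  expect_equal(mean(tr$evidence), area_expected / max(tr$time_s),
               tolerance = 0.03)
})

test_that("caregiver scales honour ranges, missingness and planted effects", {
  cfg <- small_config(seed = 14)
  ch <- generate_cohort(cfg)
  reg <- scale_registry()
  for (k in seq_len(nrow(reg))) {
    v <- ch$participants[[reg$scale[k]]]
    asd <- ch$participants$group == "ASD"
    expect_true(all(is.na(v[!asd])))
    expect_true(all(v[asd] >= reg$min[k] & v[asd] <= reg$max[k]))
  }
  # null configuration: subgroup differences centred on zero across seeds
  null_cfg <- function(seed)
    cohort_config(n_asd_over = 30, n_asd_under = 30, seed = seed,
                  scale_effects = list(impulsivity_shift = 0,
                                       withdrawal_auc6_cor = 0))
  diffs <- vapply(1:40, function(s) {
    cfg <- null_cfg(s)
    p <- generate_scales(generate_participants(cfg), cfg)
    a <- p$abi_sr_impulsivity[p$true_subgroup == "over"]
    b <- p$abi_sr_impulsivity[p$true_subgroup == "under"]
    (mean(a) - mean(b)) / sd(c(a, b))
  }, 0)
  # each null diff ~ N(0, sqrt(1/30 + 1/30)); 3 SE bound on the mean of 40
  expect_lt(abs(mean(diffs)), 3 * sqrt(1 / 30 + 1 / 30) / sqrt(40))
})

test_that("planted impulsivity shift yields a stable positive rank contrast", {
  hits <- vapply(1:100, function(s) {
    cfg <- cohort_config(seed = s)
    p <- generate_scales(generate_participants(cfg), cfg)
    asd <- p[p$group == "ASD", ]
    res <- group_difference(asd$abi_sr_impulsivity, asd$true_subgroup,
                            ref = "under")
    res$r > 0
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("the planted withdrawal-AUC correlation is recovered downstream", {
  # large under-subgroup: partial Spearman should sit within Fisher-z
  # sampling error of the planted value (Gaussian-copula Spearman of
  # rho = -0.3 is about -0.287)
  cfg <- cohort_config(n_td = 4, n_asd_over = 4, n_asd_under = 600, seed = 77)
  ch <- generate_cohort(cfg)
  f <- extract_features(ch$traces)
  m <- merge(f, ch$participants, by = "participant_id")
  un <- m[m$true_subgroup == "under", ]
  res <- partial_spearman(un$abc_lethargy_social_withdrawal, un$auc_au6,
                          data.frame(age = un$age_years, sex = un$sex,
                                     iq = un$iq))
  expect_lt(abs(res$r - (-0.3)), 3 / sqrt(nrow(un) - 3))
  expect_lt(res$p, 0.001)
})

test_that("trace and participant tables round-trip through CSV at full precision", {
  ch <- generate_cohort(small_config(seed = 41))
  td <- withr::local_tempdir()
  write_traces(ch$traces, file.path(td, "tr.csv"))
  tr2 <- read_traces(file.path(td, "tr.csv"))
  expect_equal(ch$traces, tr2)
  write_participants(ch$participants, file.path(td, "pp.csv"))
  pp2 <- read_participants(file.path(td, "pp.csv"))
  expect_equal(ch$participants$latent_avg_au12, pp2$latent_avg_au12)
  cfgf <- file.path(td, "cfg.json")
  write_cohort_config(small_config(seed = 41), cfgf)
  cfg2 <- read_cohort_config(cfgf)
  expect_identical(generate_participants(cfg2),
                   generate_participants(small_config(seed = 41)))
})
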