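test_that("evidence transform is the log10 posterior odds", {
  expect_equal(evidence_from_probability(0.5), 0)
  expect_equal(evidence_from_probability(0.9), log10(9))
  p <- seq(0.01, 0.99, by = 0.01)
  expect_equal(probability_from_evidence(evidence_from_probability(p)), p,
               tolerance = 1e-12)
  # antisymmetry about 0.5
  expect_equal(evidence_from_probability(0.8),
               -evidence_from_probability(0.2))
  expect_error(evidence_from_probability(1.2), "\\[0, 1\\]")
  expect_warning(e <- evidence_from_probability(c(0, 1)), "clipped")
  expect_true(all(is.finite(e)))
})

test_that("average evidence uses detected frames only", {
  expect_equal(average_evidence(rep(0.5, 100)), 0.5)
  expect_equal(average_evidence(c(0, 1, 2, 3)), 1.5)
  set.seed(21)
  ev <- rnorm(500)
  mask <- runif(500) > 0.3
  expect_equal(average_evidence(ev, mask), mean(ev[mask]))
  expect_true(is.na(average_evidence(ev, rep(FALSE, 500))))
})

test_that("absolute-evidence AUC matches closed forms and a Riemann oracle", {
  n13 <- 13 * 24
  tr <- make_trace(rep(1, n13))
  expect_equal(auc_abs_evidence(tr$evidence, tr$time_s), (n13 - 1) / 24)
  expect_equal(auc_abs_evidence(rep(0, 100), (0:99) / 24), 0)
  # triangular pulse: peak 2, base 4 s, area 4
  fps <- 24
  tt <- (0:(20 * fps - 1)) / fps
  tri <- function(t) pmax(0, 2 * (1 - abs(t - 8) / 2))
  got <- auc_abs_evidence(tri(tt), tt)
  expect_equal(got, 4, tolerance = 1e-3)
  expect_equal(got, riemann_abs(tri, max(tt)), tolerance = 1e-3)
  # raised-cosine pulse against the dense-grid oracle
  rc <- function(t) ifelse(t >= 3 & t <= 6.5,
                           1.7 * 0.5 * (1 - cos(2 * pi * (t - 3) / 3.5)), 0)
  expect_equal(auc_abs_evidence(rc(tt), tt), riemann_abs(rc, max(tt)),
               tolerance = 1e-3)
})

test_that("AUC integrates piecewise over valid runs; gaps add no area", {
  ev <- rep(1, 48)
  t <- (0:47) / 24
  mask <- rep(TRUE, 48); mask[20:28] <- FALSE
  # two runs: frames 1..19 and 29..48 -> (19-1)/24 + (48-29)/24
  expect_equal(auc_abs_evidence(ev, t, mask), 18 / 24 + 19 / 24)
  expect_true(is.na(auc_abs_evidence(ev, t, rep(c(TRUE, FALSE), 24))))
  # AUC of |x| dominates |integral of x| (triangle inequality)
  set.seed(5)
  for (i in 1:20) {
    e <- rnorm(100)
    tt <- (0:99) / 24
    signed <- sum(0.5 * (e[-1] + e[-100]) * diff(tt))
    expect_gte(auc_abs_evidence(e, tt) + 1e-12, abs(signed))
  }
})

test_that("cross-video aggregation averages valid videos only", {
  pv <- data.frame(
    participant_id = rep("P1", 3), video_id = c("v1", "v2", "v3"),
    avg_au12 = c(1, 2, 3), avg_au6 = c(1, 2, 3),
    auc_au12 = c(1, 2, 3), auc_au6 = c(1, 2, 3))
  agg <- aggregate_features(pv)
  expect_equal(agg$avg_au12, 2)
  expect_equal(agg$n_valid_videos, 3)
  pv$avg_au12[2] <- NA  # video 2 invalid
  agg <- aggregate_features(pv)
  expect_equal(agg$avg_au12, 2)  # mean of 1, 3
  expect_equal(agg$n_valid_videos, 2)
  pv[c("avg_au12", "avg_au6", "auc_au12", "auc_au6")] <- NA
  expect_error(aggregate_features(pv), "no participant")
})

test_that("vectorised extraction equals the per-trace reference, trace by trace", {
  ch <- generate_cohort(small_config(seed = 31))
  pv <- per_video_features(ch$traces)
  sp <- split(ch$traces, ch$traces[c("participant_id", "video_id", "au")],
              drop = TRUE)
  for (nm in sample(names(sp), 20)) {
    tr <- sp[[nm]]
    tr <- tr[order(tr$frame_index), ]
    row <- pv[pv$participant_id == tr$participant_id[1] &
              pv$video_id == tr$video_id[1], ]
    col <- if (tr$au[1] == "AU12") c("avg_au12", "auc_au12")
           else c("avg_au6", "auc_au6")
    expect_equal(row[[col[1]]],
                 average_evidence(tr$evidence, tr$face_detected))
    expect_equal(row[[col[2]]],
                 auc_abs_evidence(tr$evidence, tr$time_s, tr$face_detected))
  }
})

test_that("frame-count bookkeeping matches the recording arithmetic", {
  fps <- 24
  cfg13 <- cohort_config(n_td = 1, n_asd_over = 1, n_asd_under = 1,
                         videos = data.frame(video_id = c("a", "b", "c"),
                                             duration_s = c(13, 13, 13)),
                         seed = 2)
  ch <- generate_cohort(cfg13)
  per_au <- table(ch$traces$participant_id, ch$traces$au)
  expect_true(all(per_au == 3 * 13 * fps))  # 936 frames per participant-AU
  cfg20 <- cohort_config(n_td = 1, n_asd_over = 1, n_asd_under = 1,
                         videos = data.frame(video_id = c("a", "b", "c"),
                                             duration_s = c(20, 20, 20)),
                         seed = 2)
  ch20 <- generate_cohort(cfg20)
  expect_true(all(table(ch20$traces$participant_id, ch20$traces$au) ==
                  3 * 20 * fps))  # 1440
})

test_that("average evidence is frame-rate invariant for a smooth waveform", {
  f <- function(t) 0.8 * 0.5 * (1 - cos(2 * pi * pmax(0, pmin(t - 2, 3)) / 3)) +
    0.2 * sin(t / 3)
  t24 <- (0:(16 * 24 - 1)) / 24
  t240 <- (0:(16 * 240 - 1)) / 240
  a24 <- average_evidence(f(t24))
  a240 <- average_evidence(f(t240))
  expect_equal(a24, a240, tolerance = 0.01)
})

test_that("permuting participants permutes features identically", {
  ch <- generate_cohort(small_config(seed = 13))
  f1 <- extract_features(ch$traces)
  shuffled <- ch$traces[sample(nrow(ch$traces)), ]
  f2 <- extract_features(shuffled)
  f2 <- f2[match(f1$participant_id, f2$participant_id), ]
  rownames(f2) <- NULL
  expect_equal(f1, f2)
})

test_that("feature normalisation gives exact z-scores and rejects degeneracy", {
  ch <- generate_cohort(small_config(seed = 17))
  f <- extract_features(ch$traces)
  z <- normalize_features(f, c("avg_au12", "avg_au6"))
  expect_equal(colMeans(z), c(avg_au12 = 0, avg_au6 = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(avg_au12 = 1, avg_au6 = 1), tolerance = 1e-12)
  # two-pass oracle
  expect_equal(z[, 1], (f$avg_au12 - mean(f$avg_au12)) / sd(f$avg_au12),
               ignore_attr = TRUE)
  dup <- f[rep(1, 5), ]
  expect_error(normalize_features(dup), "zero-variance")
})
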