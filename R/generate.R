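#' Generate participant records for a synthetic cohort
#'
#' Draws group membership, demographics and the latent per-participant
#' responsiveness targets that the trace generator will realise. Latent
#' average-evidence targets are moment-calibrated: within each group the
#' sample mean, SD and correlation of the targets equal the configured
#' calibration moments exactly (for cells with at least 4 members), so the
#' cohort reproduces the intended group feature moments up to within-
#' participant noise.
#'
#' @param config a [cohort_config()].
#' @return data frame with one row per participant: `participant_id`,
#'   `group` (`TD`/`ASD`), `true_subgroup` (`over`/`under`/`none`; generator
#'   ground truth, hidden from inference), `age_years`, `sex`, `iq`, and the
#'   latent targets `latent_avg_au12`, `latent_avg_au6`.
#' @export
generate_participants <- function(config) {
  validate_cohort_config(config)
  with_seed(derive_seed(config$seed, "generate"), {
    cells <- data.frame(
      cell = c("td", "over", "under"),
      group = c("TD", "ASD", "ASD"),
      subgroup = c("none", "over", "under"),
      n = c(config$n_td, config$n_asd_over, config$n_asd_under)
    )
    out <- vector("list", nrow(cells))
    offset <- 0L
    for (i in seq_len(nrow(cells))) {
      cc <- cells[i, ]
      dem <- config$demographics[config$demographics$group == cc$cell, ]
      n <- cc$n
      age <- rshift_gamma(n, dem$age_mean, dem$age_sd, min = 6)
      sex <- ifelse(stats::runif(n) < dem$male_fraction, "male", "female")
      iq <- if (is.na(dem$iq_mean)) rep(NA_real_, n) else
        stats::rnorm(n, dem$iq_mean, dem$iq_sd)
      lat <- draw_latent_targets(n, cc$cell, config)
      out[[i]] <- data.frame(
        participant_id = sprintf("P%03d", offset + seq_len(n)),
        group = cc$group,
        true_subgroup = cc$subgroup,
        age_years = age,
        sex = sex,
        iq = iq,
        latent_avg_au12 = lat[, 1],
        latent_avg_au6 = lat[, 2],
        stringsAsFactors = FALSE
      )
      offset <- offset + n
    }
    do.call(rbind, out)
  })
}

# age >= 6, right-skewed: 6 + gamma matched to the target mean/SD
rshift_gamma <- function(n, mean, sd, min = 6) {
  m <- mean - min
  if (m <= 0) return(rep(min, n))
  shape <- (m / sd)^2
  min + stats::rgamma(n, shape = shape, scale = sd^2 / m)
}

# latent (avg_au12, avg_au6) targets; exact sample moments when n >= 4
draw_latent_targets <- function(n, cell, config) {
  ct <- config$calibration_targets
  if (is.null(ct)) return(matrix(NA_real_, n, 2))  # amplitude-driven path
  tg <- ct[ct$group == cell, ]
  mu <- c(tg$avg_au12_mean, tg$avg_au6_mean)
  sdv <- c(tg$avg_au12_sd, tg$avg_au6_sd)
  C <- matrix(c(1, tg$cor, tg$cor, 1), 2, 2) * tcrossprod(sdv)
  z <- matrix(stats::rnorm(n * 2), n, 2)
  if (n >= 4) {
    z <- scale(z)
    z <- z %*% solve(chol(stats::cov(z)))  # exact identity sample covariance
    z <- z %*% chol(C)
  } else {
    z <- z %*% chol(C)
  }
  sweep(z, 2, mu, "+")
}

#' Generate frame-level AU-evidence traces for a cohort
#'
#' Synthesises per-frame evidence series for AU12 and AU6 for every
#' participant and video. Each series is zero-mean baseline noise plus
#' smooth raised-cosine smile bursts; Duchenne bursts raise both AUs with
#' correlated amplitudes, non-Duchenne bursts raise AU12 only. Face-tracking
#' dropout is inserted in contiguous blocks. When the config carries
#' calibration targets, the per-participant burst scale is solved so the
#' signal-only average evidence over detected frames equals the
#' participant's latent target.
#'
#' @param participants output of [generate_participants()].
#' @param config the same [cohort_config()].
#' @return list with `traces` (long data frame: `participant_id`,
#'   `video_id`, `au`, `frame_index`, `time_s`, `evidence`,
#'   `face_detected`) and `participants` (input augmented with the realised
#'   latent energies `latent_auc_au12`, `latent_auc_au6`).
#' @export
generate_traces <- function(participants, config) {
  validate_cohort_config(config)
  fps <- config$frame_rate_hz
  vids <- config$videos
  n_fr <- as.integer(round(vids$duration_s * fps))
  times <- lapply(n_fr, function(k) (seq_len(k) - 1) / fps)
  calibrated <- !is.null(config$calibration_targets)

  with_seed(derive_seed(config$seed, "traces"), {
    nv <- length(n_fr)
    np <- nrow(participants)
    # column accumulators, one slot per participant x video (both AUs stacked)
    acc_pid <- acc_vid <- acc_au <- vector("list", np * nv)
    acc_fi <- acc_t <- acc_e <- acc_fd <- vector("list", np * nv)
    auc12 <- auc6 <- numeric(nrow(participants))
    lat12 <- lat6 <- numeric(nrow(participants))
    for (i in seq_len(nrow(participants))) {
      p <- participants[i, ]
      cell <- if (p$group == "TD") "td" else p$true_subgroup
      plan <- draw_burst_plan(cell, vids$duration_s, config)
      masks <- lapply(n_fr, function(k) draw_dropout_mask(k, config, fps))
      s12 <- s6 <- vector("list", length(n_fr))
      for (v in seq_along(n_fr)) {
        s12[[v]] <- burst_signal(times[[v]], plan[[v]], au = "AU12")
        s6[[v]] <- burst_signal(times[[v]], plan[[v]], au = "AU6")
      }
      if (calibrated) {
        c12 <- solve_amplitude(p$latent_avg_au12, s12, masks)
        c6 <- solve_amplitude(p$latent_avg_au6, s6, masks)
      } else {
        amp <- config$burst_amplitude[[cell]]
        a <- stats::rnorm(1, amp[["mean"]], amp[["sd"]])
        c12 <- c6 <- a
      }
      lat12[i] <- mean(vapply(seq_along(s12), function(v) {
        m <- masks[[v]]
        if (!any(m)) return(NA_real_)
        mean(c12 * s12[[v]][m])
      }, 0), na.rm = TRUE)
      lat6[i] <- mean(vapply(seq_along(s6), function(v) {
        m <- masks[[v]]
        if (!any(m)) return(NA_real_)
        mean(c6 * s6[[v]][m])
      }, 0), na.rm = TRUE)
      auc12[i] <- mean(vapply(seq_along(s12), function(v)
        trapz(times[[v]], abs(c12 * s12[[v]])), 0))
      auc6[i] <- mean(vapply(seq_along(s6), function(v)
        trapz(times[[v]], abs(c6 * s6[[v]])), 0))
      for (v in seq_along(n_fr)) {
        k <- n_fr[v]
        e12 <- c12 * s12[[v]] + stats::rnorm(k, 0, config$baseline_noise_sd)
        e6 <- c6 * s6[[v]] + stats::rnorm(k, 0, config$baseline_noise_sd)
        slot <- (i - 1L) * nv + v
        acc_pid[[slot]] <- rep(p$participant_id, 2L * k)
        acc_vid[[slot]] <- rep(vids$video_id[v], 2L * k)
        acc_au[[slot]] <- rep(c("AU12", "AU6"), each = k)
        acc_fi[[slot]] <- rep(seq_len(k) - 1L, 2L)
        acc_t[[slot]] <- rep(times[[v]], 2L)
        acc_e[[slot]] <- c(e12, e6)
        acc_fd[[slot]] <- rep(masks[[v]], 2L)
      }
    }
    participants$latent_auc_au12 <- auc12
    participants$latent_auc_au6 <- auc6
    # realised (mask-aware) signal-only averages, kept as generator truth
    participants$latent_avg_au12_realised <- lat12
    participants$latent_avg_au6_realised <- lat6
    traces <- data.frame(
      participant_id = unlist(acc_pid, use.names = FALSE),
      video_id = unlist(acc_vid, use.names = FALSE),
      au = unlist(acc_au, use.names = FALSE),
      frame_index = unlist(acc_fi, use.names = FALSE),
      time_s = unlist(acc_t, use.names = FALSE),
      evidence = unlist(acc_e, use.names = FALSE),
      face_detected = unlist(acc_fd, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    list(traces = traces, participants = participants)
  })
}

# burst plan for one participant across all videos; guarantees at least one
# burst overall and at least one Duchenne burst so calibration is solvable
draw_burst_plan <- function(cell, durations, config) {
  rate <- config$event_rate[[cell]]
  dfrac <- config$duchenne_fraction[[cell]]
  rho <- config$au_coupling
  mu_b <- config$smile_duration_s[["mean"]]
  sd_b <- config$smile_duration_s[["sd"]]
  plan <- vector("list", length(durations))
  for (v in seq_along(durations)) {
    k <- stats::rpois(1, rate)
    plan[[v]] <- draw_bursts(k, durations[v], mu_b, sd_b, dfrac, rho)
  }
  total <- sum(vapply(plan, nrow, 0L))
  if (total == 0L) {
    v <- sample.int(length(durations), 1)
    plan[[v]] <- draw_bursts(1L, durations[v], mu_b, sd_b, dfrac, rho)
  }
  if (!any(unlist(lapply(plan, function(b) b$duchenne)))) {
    nb <- vapply(plan, nrow, 0L)
    cand <- rep(which(nb > 0), nb[nb > 0])
    v <- cand[sample.int(length(cand), 1)]
    j <- sample.int(nrow(plan[[v]]), 1)
    plan[[v]]$duchenne[j] <- TRUE
  }
  plan
}

draw_bursts <- function(k, duration, mu_b, sd_b, dfrac, rho) {
  if (k == 0L) {
    return(data.frame(start = numeric(0), dur = numeric(0),
                      duchenne = logical(0), rel12 = numeric(0),
                      rel6 = numeric(0)))
  }
  dur <- vapply(seq_len(k), function(j) {
    hi <- min(6, duration)
    repeat {
      d <- stats::rnorm(1, mu_b, sd_b)
      if (d >= 1 && d <= hi) return(d)
    }
  }, 0)
  start <- stats::runif(k, 0, duration - dur)
  duch <- stats::runif(k) < dfrac
  z12 <- stats::rnorm(k)
  z6 <- rho * z12 + sqrt(1 - rho^2) * stats::rnorm(k)
  data.frame(start = start, dur = dur, duchenne = duch,
             rel12 = exp(0.25 * z12), rel6 = exp(0.25 * z6))
}

# raised-cosine pulse: 0.5 * (1 - cos(2*pi*tau/dur)) on [start, start+dur]
burst_signal <- function(t, bursts, au = c("AU12", "AU6")) {
  au <- match.arg(au)
  s <- numeric(length(t))
  if (nrow(bursts) == 0) return(s)
  for (j in seq_len(nrow(bursts))) {
    b <- bursts[j, ]
    if (au == "AU6" && !b$duchenne) next
    rel <- if (au == "AU12") b$rel12 else b$rel6
    inside <- t >= b$start & t <= b$start + b$dur
    tau <- t[inside] - b$start
    s[inside] <- s[inside] + rel * 0.5 * (1 - cos(2 * pi * tau / b$dur))
  }
  s
}

# contiguous dropout blocks; expected masked fraction ~= dropout_rate
draw_dropout_mask <- function(n_frames, config, fps) {
  detected <- rep(TRUE, n_frames)
  if (config$dropout_rate <= 0) return(detected)
  block <- max(1, round(config$dropout_block_s * fps))
  n_blocks <- stats::rpois(1, config$dropout_rate * n_frames / block)
  if (n_blocks == 0) return(detected)
  for (b in seq_len(n_blocks)) {
    len <- stats::rgeom(1, 1 / block) + 1L
    st <- sample.int(n_frames, 1)
    detected[st:min(n_frames, st + len - 1L)] <- FALSE
  }
  detected
}

# scale so that the cross-video mean of per-video signal averages over
# detected frames equals the latent target
solve_amplitude <- function(target, signals, masks) {
  svals <- vapply(seq_along(signals), function(v) {
    m <- masks[[v]]
    if (!any(m)) return(NA_real_)
    mean(signals[[v]][m])
  }, 0)
  s_bar <- mean(svals, na.rm = TRUE)
  if (!is.finite(s_bar) || abs(s_bar) < 1e-12) return(0)
  target / s_bar
}

trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum(0.5 * (y[-1] + y[-n]) * diff(t))
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: draws participant records, synthesises the
#' frame-level evidence traces, and attaches caregiver scale scores.
#'
#' @param config a [cohort_config()].
#' @return list with `traces` and `participants` (including scales).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_td = 4, n_asd_over = 4,
#'                                         n_asd_under = 4, seed = 3))
#' head(cohort$traces)
generate_cohort <- function(config) {
  participants <- generate_participants(config)
  gen <- generate_traces(participants, config)
  gen$participants <- generate_scales(gen$participants, config)
  gen
}

#' Attach caregiver-reported scale scores to participant records
#'
#' Draws the eight caregiver scales (see [scale_registry()]) for ASD
#' participants on instrument-plausible integer ranges. Two associations can
#' be planted via `config$scale_effects`: a shift of ABI self-regulation
#' impulsivity in the over-responsive subgroup (SD units), and a rank
#' correlation between ABC lethargy/social-withdrawal and the latent AU6 AUC
#' within the under-responsive subgroup. All other scales are independent
#' noise. TD participants receive `NA` for these ASD instruments.
#'
#' @param participants participant records carrying `true_subgroup` and
#'   (for the planted correlation) `latent_auc_au6`.
#' @param config a [cohort_config()].
#' @return `participants` with one integer column per scale.
#' @export
generate_scales <- function(participants, config) {
  validate_cohort_config(config)
  reg <- scale_registry()
  eff <- config$scale_effects
  shift <- eff$impulsivity_shift %||% 0
  rho <- eff$withdrawal_auc6_cor %||% 0
  if (abs(rho) >= 1) stop("planted correlation must lie in (-1, 1)")
  asd <- participants$group == "ASD"
  n_asd <- sum(asd)
  with_seed(derive_seed(config$seed, "scales"), {
    for (k in seq_len(nrow(reg))) {
      sc <- reg[k, ]
      z <- stats::rnorm(n_asd)
      if (sc$scale == "abi_sr_impulsivity") {
        z <- z + shift * (participants$true_subgroup[asd] == "over")
      }
      if (sc$scale == "abc_lethargy_social_withdrawal" && rho != 0) {
        under <- participants$true_subgroup[asd] == "under"
        if (sum(under) >= 3 && !is.null(participants$latent_auc_au6)) {
          a <- participants$latent_auc_au6[asd][under]
          za <- as.numeric(scale(a))
          z[under] <- rho * za + sqrt(1 - rho^2) * z[under]
        }
      }
      mid <- (sc$min + sc$max) / 2
      width <- (sc$max - sc$min) / 6
      score <- pmin(sc$max, pmax(sc$min, round(mid + z * width)))
      col <- rep(NA_integer_, nrow(participants))
      col[asd] <- as.integer(score)
      participants[[sc$scale]] <- col
    }
    participants
  })
}
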