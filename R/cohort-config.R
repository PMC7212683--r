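#' Configuration of a synthetic facial-responsiveness cohort
#'
#' Builds the full generative specification for a synthetic cohort of
#' typically-developing (TD) participants and two latent autism-spectrum
#' (ASD) responsiveness subgroups ("over-responsive", "under-responsive"),
#' watching three short amusing video clips while an automated
#' facial-expression system reports per-frame log10 posterior-odds
#' ("evidence") for the smile action units AU12 (lip-corner puller) and AU6
#' (cheek raiser).
#'
#' The defaults encode the study conditions the downstream analysis assumes:
#' group sizes 41/35/89, three videos of 13-20 s at 24 frames/s, smile
#' bursts lasting about 3-4 s, and per-group moments of the average-evidence
#' features used for calibration. Evidence is baseline-relative log-odds and
#' may be negative; the area-under-curve features take absolute values
#' downstream.
#'
#' @param n_td,n_asd_over,n_asd_under group sizes (positive integers).
#' @param videos data frame with columns `video_id` and `duration_s`;
#'   durations must lie in `[13, 20]` seconds.
#' @param frame_rate_hz sampling rate of the evidence series (frames/s).
#' @param smile_duration_s named vector `c(mean=, sd=)` of the smile-burst
#'   duration in seconds (truncated to `[1, 6]` s at generation time).
#' @param event_rate named vector of expected bursts per video for
#'   `td`, `over` and `under` participants.
#' @param duchenne_fraction named vector (same names) of the probability
#'   that a burst is a Duchenne smile (activates AU6 jointly with AU12);
#'   non-Duchenne bursts raise AU12 only.
#' @param burst_amplitude list with elements `td`, `over`, `under`, each
#'   `c(mean=, sd=)`: per-participant peak-evidence scale used when
#'   `calibration_targets` is `NULL`.
#' @param baseline_noise_sd SD of the zero-mean frame-level evidence noise.
#' @param dropout_rate expected fraction of frames with
#'   `face_detected = FALSE`; dropout occurs in contiguous blocks.
#' @param dropout_block_s mean length (seconds) of a dropout block.
#' @param au_coupling correlation of AU12/AU6 relative burst amplitudes
#'   within a Duchenne burst.
#' @param calibration_targets data frame with one row per group
#'   (`td`, `over`, `under`) and columns `avg_au12_mean`, `avg_au12_sd`,
#'   `avg_au6_mean`, `avg_au6_sd`, `cor`: target moments of the two
#'   average-evidence features. When supplied, per-participant burst
#'   amplitudes are solved so the cohort feature moments match these targets
#'   exactly in the latent (noise-free) signal; set to `NULL` to draw
#'   amplitudes from `burst_amplitude` instead.
#' @param demographics data frame with one row per group and columns
#'   `age_mean`, `age_sd`, `male_fraction`, `iq_mean`, `iq_sd` (IQ is `NA`
#'   for TD, which never receives the IQ instrument).
#' @param scale_effects list of planted caregiver-scale associations:
#'   `impulsivity_shift` (shift of ABI self-regulation impulsivity in the
#'   over-responsive subgroup, in SD units) and `withdrawal_auc6_cor`
#'   (correlation between ABC lethargy/social-withdrawal and the latent AU6
#'   AUC within the under-responsive subgroup, must lie in (-1, 1)).
#' @param seed integer seed; identical config + seed reproduces the cohort
#'   byte-for-byte.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_td = 5, n_asd_over = 4, n_asd_under = 6, seed = 7)
#' str(cfg$videos)
cohort_config <- function(n_td = 41,
                          n_asd_over = 35,
                          n_asd_under = 89,
                          videos = data.frame(
                            video_id = c("v1", "v2", "v3"),
                            duration_s = c(13, 17, 20)
                          ),
                          frame_rate_hz = 24,
                          smile_duration_s = c(mean = 3.5, sd = 0.5),
                          event_rate = c(td = 2, over = 3, under = 1.5),
                          duchenne_fraction = c(td = 0.6, over = 0.8, under = 0.4),
                          burst_amplitude = list(
                            td = c(mean = 2, sd = 0.8),
                            over = c(mean = 3, sd = 1),
                            under = c(mean = 0.5, sd = 0.3)
                          ),
                          baseline_noise_sd = 0.3,
                          dropout_rate = 0.05,
                          dropout_block_s = 0.5,
                          au_coupling = 0.8,
                          calibration_targets = default_calibration_targets(),
                          demographics = default_demographics(),
                          scale_effects = list(
                            impulsivity_shift = 0.5,
                            withdrawal_auc6_cor = -0.3
                          ),
                          seed = 1) {
  cfg <- list(
    n_td = n_td, n_asd_over = n_asd_over, n_asd_under = n_asd_under,
    videos = videos, frame_rate_hz = frame_rate_hz,
    smile_duration_s = smile_duration_s, event_rate = event_rate,
    duchenne_fraction = duchenne_fraction, burst_amplitude = burst_amplitude,
    baseline_noise_sd = baseline_noise_sd, dropout_rate = dropout_rate,
    dropout_block_s = dropout_block_s, au_coupling = au_coupling,
    calibration_targets = calibration_targets, demographics = demographics,
    scale_effects = scale_effects, seed = seed
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Default calibration moments of the average-evidence features
#'
#' Per-group means/SDs of average AU12 and average AU6 evidence, and the
#' latent correlation between the two, used to calibrate burst amplitudes.
#'
#' @return data frame with rows `td`, `over`, `under`.
#' @export
default_calibration_targets <- function() {
  data.frame(
    group = c("td", "over", "under"),
    avg_au12_mean = c(0.64, 1.08, 0.09),
    avg_au12_sd = c(0.63, 0.78, 0.57),
    avg_au6_mean = c(0.34, 1.02, 0.038),
    avg_au6_sd = c(0.55, 0.63, 0.15),
    cor = c(0.5, 0.5, 0.5)
  )
}

#' Default demographic moments per group
#'
#' Age, sex and IQ moments for the TD group and the two ASD responsiveness
#' subgroups. Ages are drawn from a 6-year-shifted gamma (study inclusion
#' requires age >= 6 and empirical age distributions are right-skewed); IQ
#' is never measured for TD participants.
#'
#' @return data frame with rows `td`, `over`, `under`.
#' @export
default_demographics <- function() {
  data.frame(
    group = c("td", "over", "under"),
    age_mean = c(16.27, 12.03, 16.12),
    age_sd = c(13.18, 4.82, 8.94),
    male_fraction = c(27 / 41, 26 / 35, 67 / 89),
    iq_mean = c(NA, 105.43, 96.82),
    iq_sd = c(NA, 14.98, 20.25)
  )
}

validate_cohort_config <- function(cfg) {
  stopifnot(is.list(cfg))
  cnt <- c(cfg$n_td, cfg$n_asd_over, cfg$n_asd_under)
  if (any(!is.finite(cnt)) || any(cnt <= 0) || any(cnt != round(cnt)))
    stop("group sizes must be positive integers")
  v <- cfg$videos
  if (!is.data.frame(v) || !all(c("video_id", "duration_s") %in% names(v)))
    stop("videos must be a data frame with columns video_id and duration_s")
  if (any(v$duration_s < 13 | v$duration_s > 20))
    stop("video durations must lie in [13, 20] seconds")
  if (anyDuplicated(v$video_id)) stop("video_id values must be unique")
  if (!is.finite(cfg$frame_rate_hz) || cfg$frame_rate_hz <= 0)
    stop("frame_rate_hz must be positive")
  if (cfg$smile_duration_s[["mean"]] <= 0 || cfg$smile_duration_s[["sd"]] < 0)
    stop("smile_duration_s must have positive mean and non-negative sd")
  for (nm in c("td", "over", "under")) {
    if (!nm %in% names(cfg$event_rate) || cfg$event_rate[[nm]] < 0)
      stop("event_rate must supply a non-negative rate for group ", nm)
    dfrac <- cfg$duchenne_fraction[[nm]]
    if (is.null(dfrac) || dfrac < 0 || dfrac > 1)
      stop("duchenne_fraction must lie in [0, 1] for group ", nm)
  }
  if (cfg$baseline_noise_sd < 0) stop("baseline_noise_sd must be >= 0")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate > 1)
    stop("dropout_rate must lie in [0, 1]")
  if (cfg$dropout_block_s <= 0) stop("dropout_block_s must be positive")
  if (abs(cfg$au_coupling) > 1) stop("au_coupling must lie in [-1, 1]")
  ct <- cfg$calibration_targets
  if (!is.null(ct)) {
    need <- c("group", "avg_au12_mean", "avg_au12_sd", "avg_au6_mean",
              "avg_au6_sd", "cor")
    if (!is.data.frame(ct) || !all(need %in% names(ct)))
      stop("calibration_targets must have columns ", paste(need, collapse = ", "))
    if (!all(c("td", "over", "under") %in% ct$group))
      stop("calibration_targets must cover groups td, over, under")
    if (any(ct$avg_au12_sd <= 0) || any(ct$avg_au6_sd <= 0))
      stop("calibration target SDs must be positive")
    if (any(abs(ct$cor) >= 1)) stop("calibration target correlation must lie in (-1, 1)")
  }
  se <- cfg$scale_effects
  if (!is.null(se$withdrawal_auc6_cor) && abs(se$withdrawal_auc6_cor) >= 1)
    stop("planted correlation withdrawal_auc6_cor must lie in (-1, 1)")
  if (!is.null(se$impulsivity_shift) && !is.finite(se$impulsivity_shift))
    stop("impulsivity_shift must be finite")
  if (!is.finite(cfg$seed)) stop("seed must be a finite integer")
  invisible(cfg)
}

#' Registry of caregiver-reported scales emulated by the generator
#'
#' Integer score ranges for the eight caregiver scales carried by each ASD
#' participant record. Scores are generated on these instrument-plausible
#' integer ranges and treated as ordinal downstream.
#'
#' @return data frame with columns `scale`, `min`, `max`.
#' @export
scale_registry <- function() {
  data.frame(
    scale = c("abc_irritability", "abc_lethargy_social_withdrawal",
              "abc_hyperactivity_noncompliance", "abi_rrb_hypersensitivity",
              "abi_self_regulation", "abi_sr_impulsivity",
              "rbsr_ritualistic_behavior", "srs2_social_communication"),
    min = c(0, 0, 0, 0, 0, 0, 0, 0),
    max = c(45, 48, 48, 24, 32, 24, 18, 66)
  )
}
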