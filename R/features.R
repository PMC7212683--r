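#' Convert an action-unit posterior probability to evidence (log10 odds)
#'
#' Automated facial-expression systems report per-frame evidence as the
#' base-10 logarithm of the posterior odds that an action unit is active,
#' `log10(p / (1 - p))`. Probabilities of exactly 0 or 1 are clipped to
#' `[eps, 1 - eps]` with a warning so the transform stays finite.
#'
#' @param p posterior probability (vector allowed), in `[0, 1]`.
#' @param eps clipping bound for degenerate probabilities.
#' @return evidence values; strictly increasing in `p`, 0 at `p = 0.5`,
#'   antisymmetric about 0.5.
#' @seealso [probability_from_evidence()]
#' @export
#' @examples
#' evidence_from_probability(c(0.5, 0.9))
evidence_from_probability <- function(p, eps = 1e-6) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probabilities must lie in [0, 1]")
  if (any(p == 0 | p == 1)) {
    warning("probabilities of exactly 0 or 1 clipped to [eps, 1 - eps]")
    p <- pmin(1 - eps, pmax(eps, p))
  }
  log10(p / (1 - p))
}

#' Inverse of [evidence_from_probability()]
#' @param e evidence values (log10 posterior odds).
#' @return probabilities in (0, 1).
#' @export
probability_from_evidence <- function(e) {
  o <- 10^e
  o / (1 + o)
}

#' Average evidence over detected frames of one trace
#'
#' Arithmetic mean of the evidence series restricted to frames where the
#' face was detected; frames without a detected face carry no information.
#'
#' @param evidence numeric evidence series for one participant/video/AU.
#' @param face_detected logical validity mask, same length.
#' @return the mean, or `NA` when no frame is valid.
#' @export
average_evidence <- function(evidence, face_detected = rep(TRUE, length(evidence))) {
  stopifnot(length(evidence) == length(face_detected))
  if (!any(face_detected)) return(NA_real_)
  mean(evidence[face_detected])
}

#' Area under the absolute evidence curve of one trace
#'
#' Trapezoidal integral of `|evidence|` against time in seconds, computed
#' piecewise over maximal runs of consecutive detected frames; gaps
#' contribute no area. This captures the strength ("energy") of the signal
#' regardless of its sign.
#'
#' @param evidence numeric evidence series.
#' @param time_s per-frame timestamps (strictly increasing).
#' @param face_detected logical validity mask.
#' @return area in evidence-seconds (>= 0), or `NA` when no two consecutive
#'   frames are valid.
#' @export
auc_abs_evidence <- function(evidence, time_s,
                             face_detected = rep(TRUE, length(evidence))) {
  n <- length(evidence)
  stopifnot(length(time_s) == n, length(face_detected) == n)
  if (n < 2) return(NA_real_)
  ok <- face_detected[-n] & face_detected[-1]
  if (!any(ok)) return(NA_real_)
  a <- abs(evidence)
  sum((0.5 * (a[-n] + a[-1]) * diff(time_s))[ok])
}

#' Extract per-video AU features from a long trace table
#'
#' Computes, for every participant x video x AU, the average evidence over
#' detected frames and the area under the absolute evidence curve
#' (trapezoid over maximal valid runs). Fully vectorised single pass over
#' the long table.
#'
#' @param traces long data frame as produced by [generate_traces()] (columns
#'   `participant_id`, `video_id`, `au`, `frame_index`, `time_s`,
#'   `evidence`, `face_detected`).
#' @return data frame with one row per participant x video and columns
#'   `avg_au12`, `avg_au6`, `auc_au12`, `auc_au6` (`NA` where a video/AU had
#'   no usable frames).
#' @export
per_video_features <- function(traces) {
  need <- c("participant_id", "video_id", "au", "frame_index", "time_s",
            "evidence", "face_detected")
  miss <- setdiff(need, names(traces))
  if (length(miss)) stop("traces missing columns: ", paste(miss, collapse = ", "))
  o <- order(traces$participant_id, traces$video_id, traces$au,
             traces$frame_index, method = "radix")
  tr <- traces[o, ]
  key <- paste(tr$participant_id, tr$video_id, tr$au, sep = "\r")
  f <- factor(key, levels = unique(key))
  valid <- tr$face_detected
  # averages over detected frames
  n_valid <- as.vector(rowsum(as.numeric(valid), f))
  sum_valid <- as.vector(rowsum(ifelse(valid, tr$evidence, 0), f))
  avg <- ifelse(n_valid > 0, sum_valid / n_valid, NA_real_)
  # trapezoid over consecutive valid same-trace frame pairs
  n <- nrow(tr)
  same <- key[-n] == key[-1]
  ok <- same & valid[-n] & valid[-1] &
    (tr$frame_index[-1] == tr$frame_index[-n] + 1L)
  a <- abs(tr$evidence)
  contrib <- ifelse(ok, 0.5 * (a[-n] + a[-1]) * (tr$time_s[-1] - tr$time_s[-n]), 0)
  auc <- as.vector(rowsum(c(contrib, 0), f))
  has_pair <- as.vector(rowsum(c(as.numeric(ok), 0), f)) > 0
  auc[!has_pair] <- NA_real_
  lv <- strsplit(levels(f), "\r", fixed = TRUE)
  out <- data.frame(
    participant_id = vapply(lv, `[`, "", 1),
    video_id = vapply(lv, `[`, "", 2),
    au = vapply(lv, `[`, "", 3),
    avg = avg, auc = auc, stringsAsFactors = FALSE
  )
  wide <- stats::reshape(out, idvar = c("participant_id", "video_id"),
                         timevar = "au", direction = "wide", sep = "_")
  names(wide) <- sub("^avg_AU12$", "avg_au12", names(wide))
  names(wide) <- sub("^avg_AU6$", "avg_au6", names(wide))
  names(wide) <- sub("^auc_AU12$", "auc_au12", names(wide))
  names(wide) <- sub("^auc_AU6$", "auc_au6", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Aggregate per-video features to one feature vector per participant
#'
#' A video is valid for a participant when all four per-video features are
#' available; each final feature is the unweighted mean over the
#' participant's valid videos. Participants with no valid video are dropped
#' with a message.
#'
#' @param per_video output of [per_video_features()].
#' @return data frame with columns `participant_id`, `avg_au12`, `avg_au6`,
#'   `auc_au12`, `auc_au6`, `n_valid_videos`.
#' @export
aggregate_features <- function(per_video) {
  cols <- c("avg_au12", "avg_au6", "auc_au12", "auc_au6")
  miss <- setdiff(c("participant_id", cols), names(per_video))
  if (length(miss)) stop("per_video missing columns: ", paste(miss, collapse = ", "))
  valid <- stats::complete.cases(per_video[cols])
  pv <- per_video[valid, ]
  if (!nrow(pv)) stop("no participant has a valid video")
  f <- factor(pv$participant_id, levels = unique(pv$participant_id))
  nv <- as.vector(table(f))
  agg <- rowsum(as.matrix(pv[cols]), f) / nv
  dropped <- setdiff(unique(per_video$participant_id), levels(f))
  if (length(dropped))
    message("excluding ", length(dropped),
            " participant(s) with no valid video: ",
            paste(dropped, collapse = ", "))
  data.frame(participant_id = levels(f), agg,
             n_valid_videos = nv, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Extract the final per-participant feature set from traces
#'
#' Convenience wrapper chaining [per_video_features()] and
#' [aggregate_features()].
#'
#' @inheritParams per_video_features
#' @return see [aggregate_features()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_td = 3, n_asd_over = 3,
#'                                         n_asd_under = 3, seed = 2))
#' extract_features(cohort$traces)
extract_features <- function(traces) {
  aggregate_features(per_video_features(traces))
}

#' Column-wise z-score normalisation of a feature matrix
#'
#' Standardises the selected feature columns to mean 0 and SD 1 over the
#' rows supplied (e.g. the ASD rows only, when preparing the clustering
#' input). The centring and scaling constants are attached as attributes so
#' fitted components can be mapped back to the original scale.
#'
#' @param features data frame of feature vectors.
#' @param columns feature columns to standardise.
#' @return numeric matrix of z-scores with attributes `center` and `scale`.
#' @export
normalize_features <- function(features,
                               columns = c("avg_au12", "avg_au6")) {
  miss <- setdiff(columns, names(features))
  if (length(miss)) stop("unknown feature columns: ", paste(miss, collapse = ", "))
  x <- as.matrix(features[columns])
  if (nrow(x) < 2) stop("need at least 2 rows to normalise")
  if (any(!is.finite(x))) stop("features must be finite")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance feature column(s): ",
         paste(columns[sds == 0], collapse = ", "))
  z <- scale(x)
  out <- z[, , drop = FALSE]
  attr(out, "center") <- attr(z, "scaled:center")
  attr(out, "scale") <- attr(z, "scaled:scale")
  rownames(out) <- features$participant_id
  out
}
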