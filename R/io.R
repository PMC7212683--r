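# All numeric output is written with 17 significant digits so repeated runs
# are byte-identical and round-trip exactly.

write_table17 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- num17(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read frame-level evidence traces as long-format CSV
#'
#' Dialect: header `participant_id,video_id,au,frame_index,time_s,evidence,
#' face_detected`, numerics at 17 significant digits, booleans as
#' `TRUE`/`FALSE`.
#'
#' @param traces long trace data frame.
#' @param path CSV path.
#' @return the path (write) or the data frame (read).
#' @export
write_traces <- function(traces, path) write_table17(traces, path)

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  utils::read.csv(path, colClasses = c(
    participant_id = "character", video_id = "character", au = "character",
    frame_index = "integer", time_s = "numeric", evidence = "numeric",
    face_detected = "logical"))
}

#' Write / read participant records (metadata + scales) as CSV
#' @param participants participant data frame.
#' @param path CSV path.
#' @export
write_participants <- function(participants, path) write_table17(participants, path)

#' @rdname write_participants
#' @export
read_participants <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the per-participant feature table as CSV
#' @param features feature data frame from [extract_features()].
#' @param path CSV path.
#' @export
write_features <- function(features, path) write_table17(features, path)

#' @rdname write_features
#' @export
read_features <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Write a BIC model-selection grid as CSV
#'
#' Rows are component counts, columns the 14 family codes; infeasible fits
#' are blank.
#'
#' @param selection an `au_model_selection` from [model_select()].
#' @param path CSV path.
#' @export
write_bic_grid <- function(selection, path) {
  write_table17(selection$grid, path)
}

#' Write a fitted mixture as JSON
#'
#' Stores weights, means, the volume/shape/orientation covariance factors,
#' log-likelihood, parameter count, BIC and per-participant hard labels.
#'
#' @param fit an `au_mixture`.
#' @param participant_ids ids aligned with the fitted rows.
#' @param path JSON path.
#' @export
write_fit_json <- function(fit, participant_ids, path) {
  obj <- list(
    family = fit$family, G = fit$G, dims = fit$dims,
    weights = fit$pi,
    means = t(fit$mean),
    volume = fit$volume,
    shape = t(fit$shape),
    orientation = lapply(fit$orientation, identity),
    loglik = fit$loglik, n_params = fit$n_params, bic = fit$bic,
    converged = fit$converged, n_iter = fit$n_iter,
    labels = stats::setNames(as.list(fit$labels), participant_ids)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write / read a cohort configuration as JSON
#' @param config a [cohort_config()].
#' @param path JSON path.
#' @export
write_cohort_config <- function(config, path) {
  jsonlite::write_json(cohort_config_as_list(config), path,
                       auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

# plain nested list (named vectors as objects) for JSON serialisation
cohort_config_as_list <- function(config) {
  cfg <- unclass(config)
  cfg$smile_duration_s <- as.list(cfg$smile_duration_s)
  cfg$event_rate <- as.list(cfg$event_rate)
  cfg$duchenne_fraction <- as.list(cfg$duchenne_fraction)
  cfg$burst_amplitude <- lapply(cfg$burst_amplitude, as.list)
  cfg
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$videos <- as.data.frame(raw$videos)
  raw$calibration_targets <- if (!is.null(raw$calibration_targets))
    as.data.frame(raw$calibration_targets)
  raw$demographics <- as.data.frame(raw$demographics)
  raw$smile_duration_s <- unlist(raw$smile_duration_s)
  raw$event_rate <- unlist(raw$event_rate)
  raw$duchenne_fraction <- unlist(raw$duchenne_fraction)
  raw$burst_amplitude <- lapply(raw$burst_amplitude, unlist)
  raw$scale_effects <- lapply(raw$scale_effects, unlist)
  class(raw) <- "cohort_config"
  validate_cohort_config(raw)
  raw
}
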