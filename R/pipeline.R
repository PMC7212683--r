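#' Configuration of a full analysis pipeline run
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort (or the
#'   expected structure of externally supplied data).
#' @param G_range component counts to try in model selection.
#' @param families covariance families to try.
#' @param n_restarts EM restarts per model-selection cell.
#' @param scales caregiver scales to analyse (must exist in the registry).
#' @param out_dir output directory.
#' @param seed master seed; fans out deterministically to every stochastic
#'   stage via [derive_seed()] and overrides `cohort$seed`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), G_range = 1:9,
                            families = mixture_families(), n_restarts = 10,
                            scales = scale_registry()$scale,
                            out_dir = "aumix-run", seed = 1) {
  bad <- setdiff(scales, scale_registry()$scale)
  if (length(bad)) stop("unknown scale(s): ", paste(bad, collapse = ", "))
  stopifnot(all(G_range >= 1), all(families %in% mixture_families()))
  cohort$seed <- seed
  cfg <- list(cohort = cohort, G_range = G_range, families = families,
              n_restarts = n_restarts, scales = scales, out_dir = out_dir,
              seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate -> extract -> cluster -> analyse -> report. Writes
#' six artifact files into `config$out_dir` (`traces.csv`,
#' `participants.csv`, `features.csv`, `bic_grid.csv`, `mixture_fit.json`,
#' `report.json`) plus `manifest.json` and a `tables/` directory of report
#' CSVs. Reruns with the same config and seed are byte-identical.
#' Externally supplied data can bypass the generator via `traces` /
#' `participants`.
#'
#' @param config a [pipeline_config()].
#' @param traces optional long trace table in the generator's dialect
#'   (bypasses cohort generation).
#' @param participants optional participant table (required with `traces`).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the report bundle, the selected fit, the
#'   subgroup labels, features and artifact paths.
#' @export
run_pipeline <- function(config, traces = NULL, participants = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[aumix] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  if (is.null(traces)) {
    say("generating synthetic cohort (seed ", config$seed, ")")
    cohort <- stage("generate", generate_cohort(config$cohort))
    traces <- cohort$traces
    participants <- cohort$participants
  } else {
    if (is.null(participants)) stop("participants must accompany traces")
    say("using externally supplied traces/participants")
    errs <- validate_trace_tables(traces, participants,
                                  frame_rate_hz = config$cohort$frame_rate_hz)
    if (nrow(errs)) stop("input validation failed: ",
                         paste(errs$message, collapse = "; "))
  }
  p_traces <- file.path(out, "traces.csv")
  p_part <- file.path(out, "participants.csv")
  stage("generate", {
    write_traces(traces, p_traces)
    write_participants(participants, p_part)
  })

  say("extracting features")
  features <- stage("features", extract_features(traces))
  p_feat <- file.path(out, "features.csv")
  write_features(features, p_feat)

  say("clustering ASD participants (", length(config$G_range), " x ",
      length(config$families), " grid)")
  sel <- stage("cluster", {
    asd_ids <- participants$participant_id[participants$group == "ASD"]
    asd_feat <- features[features$participant_id %in% asd_ids, ]
    z <- normalize_features(asd_feat, c("avg_au12", "avg_au6"))
    list(sel = model_select(z, G_range = config$G_range,
                            families = config$families,
                            n_restarts = config$n_restarts,
                            seed = derive_seed(config$seed, "cluster")),
         asd_feat = asd_feat)
  })
  p_grid <- file.path(out, "bic_grid.csv")
  p_fit <- file.path(out, "mixture_fit.json")
  write_bic_grid(sel$sel, p_grid)
  write_fit_json(sel$sel$best, sel$asd_feat$participant_id, p_fit)
  say("selected ", sel$sel$best$family, " with G = ", sel$sel$best$G,
      " (BIC ", round(sel$sel$best$bic, 2), ")")

  subgroup <- NULL
  lab <- label_subgroups(sel$sel$best, sel$asd_feat)
  if (!is.null(lab))
    subgroup <- stats::setNames(lab$subgroup, sel$asd_feat$participant_id)

  say("running group contrasts and partial correlations")
  report <- stage("analyze", build_report(features, participants, subgroup))
  p_report <- file.path(out, "report.json")
  stage("report", {
    jsonlite::write_json(unclass(report), p_report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "columns",
                         na = "null")
    write_report_tables(report, file.path(out, "tables"))
  })

  config_plain <- unclass(config)
  config_plain$out_dir <- NULL  # manifests are location-independent
  config_plain$cohort <- cohort_config_as_list(config_plain$cohort)
  manifest <- list(
    package = "aumix",
    version = as.character(utils::packageVersion("aumix")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = fnv1a(jsonlite::toJSON(config_plain, auto_unbox = TRUE,
                                         digits = NA, dataframe = "columns")),
    config = config_plain,
    artifacts = c("traces.csv", "participants.csv", "features.csv",
                  "bic_grid.csv", "mixture_fit.json", "report.json")
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  say("done; artifacts in ", out)
  invisible(list(report = report, fit = sel$sel$best, selection = sel$sel,
                 subgroup = subgroup, features = features,
                 participants = participants,
                 paths = c(p_traces, p_part, p_feat, p_grid, p_fit, p_report)))
}

#' Validate externally supplied trace / participant tables
#'
#' Checks the trace CSV dialect: required columns, strictly increasing and
#' evenly spaced timestamps per participant x video x AU, finite evidence on
#' detected frames, and participant-id cross-referencing between the two
#' tables. Returns a machine-readable error table, empty on success.
#'
#' @param trace_csv path to a trace CSV (or a data frame).
#' @param participant_csv path to a participant CSV (or a data frame).
#' @return data frame with columns `code` and `message` (zero rows = valid).
#' @export
validate_inputs <- function(trace_csv, participant_csv) {
  tr <- if (is.character(trace_csv)) {
    if (!file.exists(trace_csv)) stop("cannot read trace file: ", trace_csv)
    read_traces(trace_csv)
  } else trace_csv
  pp <- if (is.character(participant_csv)) {
    if (!file.exists(participant_csv))
      stop("cannot read participant file: ", participant_csv)
    read_participants(participant_csv)
  } else participant_csv
  validate_trace_tables(tr, pp)
}

validate_trace_tables <- function(tr, pp, frame_rate_hz = NULL) {
  errs <- list()
  add <- function(code, message)
    errs[[length(errs) + 1]] <<- data.frame(code = code, message = message,
                                            stringsAsFactors = FALSE)
  need <- c("participant_id", "video_id", "au", "frame_index", "time_s",
            "evidence", "face_detected")
  miss <- setdiff(need, names(tr))
  if (length(miss)) {
    add("schema", paste("trace table missing columns:",
                        paste(miss, collapse = ", ")))
    return(do.call(rbind, errs))
  }
  if (!"participant_id" %in% names(pp))
    add("schema", "participant table missing column participant_id")
  key <- paste(tr$participant_id, tr$video_id, tr$au, sep = "/")
  sp <- split(seq_len(nrow(tr)), key)
  rates <- numeric(0)
  for (nm in names(sp)) {
    t <- tr$time_s[sp[[nm]]]
    dt <- diff(t)
    if (length(dt) && any(dt <= 0))
      add("non-monotone timestamps",
          paste0("non-monotone timestamps in ", nm))
    else if (length(dt) &&
             max(abs(dt - stats::median(dt))) > 1e-6 * stats::median(dt))
      add("irregular spacing", paste0("uneven frame spacing in ", nm))
    else if (length(dt)) rates <- c(rates, 1 / stats::median(dt))
    ev <- tr$evidence[sp[[nm]]][tr$face_detected[sp[[nm]]]]
    if (any(!is.finite(ev)))
      add("non-finite evidence",
          paste0("non-finite evidence on detected frames in ", nm))
  }
  if (length(rates) && diff(range(rates)) > 1e-6 * stats::median(rates))
    add("frame-rate mismatch", "frame rate differs across traces")
  if (!is.null(frame_rate_hz) && length(rates) &&
      abs(stats::median(rates) - frame_rate_hz) > 1e-6 * frame_rate_hz)
    add("frame-rate mismatch",
        paste0("frame rate ", signif(stats::median(rates), 6),
               " does not match configured ", frame_rate_hz))
  if ("participant_id" %in% names(pp)) {
    only_tr <- setdiff(unique(tr$participant_id), pp$participant_id)
    only_pp <- setdiff(pp$participant_id, unique(tr$participant_id))
    if (length(only_tr))
      add("cross-reference", paste("participants in traces but not metadata:",
                                   paste(only_tr, collapse = ", ")))
    if (length(only_pp))
      add("cross-reference", paste("participants in metadata but no traces:",
                                   paste(only_pp, collapse = ", ")))
  }
  if (!length(errs))
    return(data.frame(code = character(0), message = character(0)))
  do.call(rbind, errs)
}
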