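feature_cols <- function() c("avg_au12", "avg_au6", "auc_au12", "auc_au6")

#' Assemble the full analysis report bundle
#'
#' Builds the four table families of the analysis: (a) descriptive
#' statistics by cohort (TD, all ASD, and the two clustered ASD subgroups),
#' (b) rank-based covariate-adjusted contrasts of the four AU features
#' between each ASD group/subgroup and TD, (c) over- vs under-responsive
#' subgroup comparisons on caregiver scales, features and demographics, and
#' (d) partial Spearman correlation grids (scales x features) in the entire
#' ASD group and within each subgroup, adjusted for age, sex and IQ.
#'
#' @param features output of [extract_features()].
#' @param participants participant records (with scales).
#' @param subgroup named character vector (`participant_id` -> `"over"` /
#'   `"under"`) from the clustering stage, or `NULL` to skip subgroup
#'   tables.
#' @return list of class `au_report` with elements `descriptives`,
#'   `contrasts`, `subgroup_comparisons`, `partial_correlations`.
#' @export
build_report <- function(features, participants, subgroup = NULL) {
  if (is.null(features) || is.null(participants))
    stop("missing stage output: features and participants are required")
  dat <- merge(participants, features, by = "participant_id")
  dat$cluster_subgroup <- if (!is.null(subgroup))
    unname(subgroup[dat$participant_id]) else NA_character_
  scales <- intersect(scale_registry()$scale, names(dat))

  cohorts <- list(
    TD = dat$group == "TD",
    ASD = dat$group == "ASD",
    `ASD over-responsive` = dat$group == "ASD" &
      !is.na(dat$cluster_subgroup) & dat$cluster_subgroup == "over",
    `ASD under-responsive` = dat$group == "ASD" &
      !is.na(dat$cluster_subgroup) & dat$cluster_subgroup == "under"
  )
  desc <- do.call(rbind, lapply(names(cohorts), function(nm) {
    s <- dat[cohorts[[nm]], ]
    mean_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    sd_na <- function(v) if (sum(!is.na(v)) < 2) NA_real_ else stats::sd(v, na.rm = TRUE)
    row <- data.frame(cohort = nm, n = nrow(s),
                      male_n = sum(s$sex == "male"),
                      age_mean = mean_na(s$age_years), age_sd = sd_na(s$age_years),
                      iq_mean = mean_na(s$iq), iq_sd = sd_na(s$iq))
    for (fc in feature_cols()) {
      row[[paste0(fc, "_mean")]] <- mean(s[[fc]])
      row[[paste0(fc, "_sd")]] <- stats::sd(s[[fc]])
    }
    row
  }))

  age_sex <- function(s) data.frame(age = s$age_years, sex = s$sex)
  age_sex_iq <- function(s) data.frame(age = s$age_years, sex = s$sex, iq = s$iq)
  contrast_block <- function(sel, label, covfun, grp_col) {
    s <- dat[sel, ]
    do.call(rbind, lapply(feature_cols(), function(fc)
      group_difference(s[[fc]], s[[grp_col]], covfun(s), ref = "TD",
                       comparison = label, feature_name = fc)))
  }
  contrasts <- NULL
  sub_tbl <- NULL
  pc <- list()

  contrasts <- rbind(
    contrast_block(rep(TRUE, nrow(dat)), "ASD vs TD", age_sex, "group"),
    if (!is.null(subgroup)) {
      tmp <- dat
      tmp$cmp_group <- ifelse(tmp$group == "TD", "TD", tmp$cluster_subgroup)
      rbind(
        {
          s <- tmp[tmp$cmp_group %in% c("over", "TD"), ]
          do.call(rbind, lapply(feature_cols(), function(fc)
            group_difference(s[[fc]], s$cmp_group, age_sex(s), ref = "TD",
                             comparison = "ASD over-responsive vs TD",
                             feature_name = fc)))
        },
        {
          s <- tmp[tmp$cmp_group %in% c("under", "TD"), ]
          do.call(rbind, lapply(feature_cols(), function(fc)
            group_difference(s[[fc]], s$cmp_group, age_sex(s), ref = "TD",
                             comparison = "ASD under-responsive vs TD",
                             feature_name = fc)))
        }
      )
    }
  )

  if (!is.null(subgroup)) {
    s <- dat[dat$group == "ASD" & !is.na(dat$cluster_subgroup), ]
    over_vs_under <- function(y, nm, covs)
      group_difference(y, s$cluster_subgroup, covs, ref = "under",
                       comparison = "over vs under", feature_name = nm)
    sub_tbl <- rbind(
      do.call(rbind, lapply(scales, function(sc)
        over_vs_under(s[[sc]], sc, age_sex_iq(s)))),
      do.call(rbind, lapply(feature_cols(), function(fc)
        over_vs_under(s[[fc]], fc, age_sex_iq(s)))),
      over_vs_under(s$age_years, "age", NULL),
      over_vs_under(as.numeric(s$sex == "male"), "sex", NULL),
      over_vs_under(s$iq, "iq", NULL)
    )
    pc_sets <- list(
      ASD = s,
      `ASD over-responsive` = s[s$cluster_subgroup == "over", ],
      `ASD under-responsive` = s[s$cluster_subgroup == "under", ]
    )
  } else {
    pc_sets <- list(ASD = dat[dat$group == "ASD", ])
  }
  pc <- lapply(pc_sets, function(s) {
    do.call(rbind, lapply(scales, function(sc) {
      do.call(rbind, lapply(feature_cols(), function(fc) {
        res <- tryCatch(
          partial_spearman(s[[sc]], s[[fc]], age_sex_iq(s),
                           x_name = sc, y_name = fc),
          error = function(e) data.frame(
            scale = sc, feature = fc, r = NA_real_, p = NA_real_,
            ci_low = NA_real_, ci_high = NA_real_, n = NA_integer_,
            n_dropped = NA_integer_, covariates = "age+sex+iq",
            stringsAsFactors = FALSE)
        )
        res
      }))
    }))
  })

  out <- list(descriptives = desc, contrasts = contrasts,
              subgroup_comparisons = sub_tbl, partial_correlations = pc)
  class(out) <- "au_report"
  out
}

#' Render a report bundle as annotated text
#'
#' Human-readable rendering with the usual asterisk convention: `*` marks
#' `p < .05` (no multiple-comparison correction is applied).
#'
#' @param bundle an `au_report` from [build_report()].
#' @return character vector of lines (also printed invisibly).
#' @export
render_report <- function(bundle) {
  star <- function(p) ifelse(!is.na(p) & p < 0.05, "*", "")
  fmt_eff <- function(tb) sprintf(
    "  %-38s %-12s r = %6.3f (p = %.3g)%s [%.2f, %.2f] n = %d",
    tb$comparison %||% tb$scale, tb$feature_or_scale %||% tb$feature,
    tb$r, tb$p, star(tb$p), tb$ci_low, tb$ci_high, tb$n)
  lines <- c("Cohort descriptives:",
             utils::capture.output(print(bundle$descriptives, digits = 3)))
  lines <- c(lines, "", "Group contrasts (rank-based, covariate-adjusted):")
  for (i in seq_len(nrow(bundle$contrasts)))
    lines <- c(lines, fmt_eff(bundle$contrasts[i, ]))
  if (!is.null(bundle$subgroup_comparisons)) {
    lines <- c(lines, "", "Over- vs under-responsive comparisons:")
    for (i in seq_len(nrow(bundle$subgroup_comparisons)))
      lines <- c(lines, fmt_eff(bundle$subgroup_comparisons[i, ]))
  }
  for (nm in names(bundle$partial_correlations)) {
    tb <- bundle$partial_correlations[[nm]]
    lines <- c(lines, "", paste0("Partial Spearman correlations (", nm, "):"))
    for (i in seq_len(nrow(tb))) {
      row <- tb[i, ]
      lines <- c(lines, sprintf("  %-34s x %-10s r = %6.3f (p = %.3g)%s",
                                row$scale, row$feature, row$r, row$p,
                                star(row$p)))
    }
  }
  invisible(lines)
}

#' @export
print.au_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Write the report tables as CSV files
#'
#' @param bundle an `au_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report_tables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(tb, nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_table17(tb, p)
    paths <<- c(paths, p)
  }
  wr(bundle$descriptives, "descriptives")
  wr(bundle$contrasts, "contrasts")
  if (!is.null(bundle$subgroup_comparisons))
    wr(bundle$subgroup_comparisons, "subgroup_comparisons")
  for (nm in names(bundle$partial_correlations))
    wr(bundle$partial_correlations[[nm]],
       paste0("partial_correlations_", gsub("[^a-z0-9]+", "_", tolower(nm))))
  invisible(paths)
}
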