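#' Rank-transform a numeric vector
#'
#' Average ranks for ties; missing values stay missing. Analyses in this
#' package are performed on ranks so that results are not driven by
#' outliers.
#'
#' @param values numeric vector, possibly with `NA`.
#' @return numeric vector of ranks (same length), `NA` preserved.
#' @export
#' @examples
#' rank_transform(c(1, 1, 2))  # 1.5 1.5 3
rank_transform <- function(values) {
  if (sum(!is.na(values)) < 2) stop("need at least 2 non-missing values")
  rank(values, na.last = "keep", ties.method = "average")
}

# build the numeric covariate design: numeric covariates are ranked,
# two-level character/factor covariates enter as 0/1 indicators
covariate_design <- function(covariates) {
  if (is.null(covariates) || NCOL(covariates) == 0)
    return(NULL)
  covariates <- as.data.frame(covariates)
  cols <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.numeric(v)) rank_transform(v)
    else {
      lv <- sort(unique(stats::na.omit(as.character(v))))
      if (length(lv) > 2)
        stop("categorical covariate ", nm, " has more than 2 levels")
      as.numeric(as.character(v) == lv[length(lv)])
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- names(covariates)
  m
}

fisher_ci <- function(r, n, n_covariates, level = 0.95) {
  se <- 1 / sqrt(n - 3 - n_covariates)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  z <- atanh(min(1 - 1e-12, max(-1 + 1e-12, r)))
  tanh(z + c(-1, 1) * zq * se)
}

#' Rank-based covariate-adjusted group contrast
#'
#' Ordinary least squares of the rank-transformed feature on a group
#' indicator plus covariates (numeric covariates ranked, sex as an
#' indicator). The group coefficient's t statistic is converted to an
#' effect size `r = t / sqrt(t^2 + df)`; the two-sided p-value comes from
#' the t distribution and the 95% CI from the Fisher z transform with
#' `SE = 1 / sqrt(n - 3 - #covariates)`. Rows with any missing value are
#' dropped casewise (and counted).
#'
#' @param feature numeric outcome values.
#' @param group group labels (two levels).
#' @param covariates data frame of covariates (may be `NULL`).
#' @param ref the reference level of `group`; the reported effect is
#'   positive when the other level has larger values.
#' @param comparison label stored in the result.
#' @param feature_name label stored in the result.
#' @return one-row data frame (an effect result): `comparison`,
#'   `feature_or_scale`, `r`, `p`, `ci_low`, `ci_high`, `n`, `n_dropped`,
#'   `covariates`.
#' @export
#' @examples
#' set.seed(1)
#' g <- rep(c("A", "B"), each = 30)
#' y <- rnorm(60) + (g == "B")
#' group_difference(y, g, ref = "A")
group_difference <- function(feature, group, covariates = NULL, ref = NULL,
                             comparison = NULL, feature_name = "feature") {
  group <- as.character(group)
  lv <- sort(unique(stats::na.omit(group)))
  if (length(lv) != 2) stop("group must have exactly 2 levels, got: ",
                            paste(lv, collapse = ", "))
  if (is.null(ref)) ref <- lv[1]
  if (!ref %in% lv) stop("ref level ", ref, " not present")
  trt <- setdiff(lv, ref)
  if (is.null(comparison)) comparison <- paste(trt, "vs", ref)
  cm <- covariate_design(covariates)
  df_all <- data.frame(.y = feature, .g = as.numeric(group == trt))
  if (!is.null(cm)) df_all <- cbind(df_all, as.data.frame(cm))
  keep <- stats::complete.cases(df_all)
  n_dropped <- sum(!keep)
  dat <- df_all[keep, , drop = FALSE]
  n <- nrow(dat)
  if (length(unique(dat$.g)) < 2) stop("a group is empty after casewise deletion")
  dat$.y <- rank_transform(dat$.y)
  # re-rank numeric covariates within the retained rows
  if (!is.null(cm)) {
    for (nm in colnames(cm)) {
      v <- dat[[nm]]
      if (length(unique(v)) > 2) dat[[nm]] <- rank_transform(v)
    }
  }
  fit <- stats::lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design; collinear column(s): ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  tval <- sm[".g", "t value"]
  dfree <- fit$df.residual
  r <- tval / sqrt(tval^2 + dfree)
  p <- 2 * stats::pt(-abs(tval), dfree)
  q <- if (is.null(cm)) 0 else ncol(cm)
  ci <- fisher_ci(r, n, q)
  data.frame(comparison = comparison, feature_or_scale = feature_name,
             r = r, p = p, ci_low = ci[1], ci_high = ci[2],
             n = n, n_dropped = n_dropped,
             covariates = paste(colnames(cm), collapse = "+"),
             stringsAsFactors = FALSE)
}

#' Partial Spearman correlation with covariates
#'
#' Rank-transforms `x`, `y` and the numeric covariates, residualises the
#' ranked `x` and `y` on the covariates (with intercept) by least squares,
#' and reports the Pearson correlation of the residuals. With no covariates
#' this reduces exactly to the ordinary Spearman correlation. The p-value
#' uses a t statistic with `df = n - 2 - #covariates`; the CI uses the
#' Fisher z transform.
#'
#' @param x,y numeric vectors.
#' @param covariates data frame of covariates (may be `NULL`).
#' @param x_name,y_name labels stored in the result.
#' @return one-row data frame: `scale`, `feature`, `r`, `p`, `ci_low`,
#'   `ci_high`, `n`, `n_dropped`, `covariates`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- x + rnorm(50)
#' partial_spearman(x, y)$r
#' cor(x, y, method = "spearman")  # identical with no covariates
partial_spearman <- function(x, y, covariates = NULL,
                             x_name = "x", y_name = "y") {
  cm <- covariate_design(covariates)
  df_all <- data.frame(.x = x, .y = y)
  if (!is.null(cm)) df_all <- cbind(df_all, as.data.frame(cm))
  keep <- stats::complete.cases(df_all)
  n_dropped <- sum(!keep)
  dat <- df_all[keep, , drop = FALSE]
  n <- nrow(dat)
  q <- if (is.null(cm)) 0 else ncol(cm)
  if (n < q + 3 || n - 2 - q < 1)
    stop("insufficient non-missing observations (n = ", n, ")")
  rx <- rank_transform(dat$.x)
  ry <- rank_transform(dat$.y)
  if (q > 0) {
    Z <- as.matrix(dat[, colnames(cm), drop = FALSE])
    for (j in seq_len(ncol(Z)))
      if (length(unique(Z[, j])) > 2) Z[, j] <- rank_transform(Z[, j])
    Z <- cbind(1, Z)
    rx <- stats::lsfit(Z, rx, intercept = FALSE)$residuals
    ry <- stats::lsfit(Z, ry, intercept = FALSE)$residuals
  }
  r <- stats::cor(rx, ry)
  dfree <- n - 2 - q
  tval <- r * sqrt(dfree / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), dfree)
  ci <- fisher_ci(r, n, q)
  data.frame(scale = x_name, feature = y_name, r = r, p = p,
             ci_low = ci[1], ci_high = ci[2], n = n, n_dropped = n_dropped,
             covariates = paste(colnames(cm), collapse = "+"),
             stringsAsFactors = FALSE)
}
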