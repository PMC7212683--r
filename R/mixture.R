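#' The fourteen eigendecomposed covariance parameterisations
#'
#' Finite Gaussian mixtures are fitted with component covariances factored
#' as `Sigma_k = lambda_k * D_k %*% A_k %*% t(D_k)`, where the scalar
#' `lambda_k` controls the volume of the density ellipsoid, the diagonal
#' matrix `A_k` (with `det(A_k) = 1`) its shape, and the orthogonal matrix
#' `D_k` its orientation. Each three-letter code states whether volume,
#' shape and orientation are Equal across components, Variable, or (for
#' shape/orientation) the Identity: e.g. `"EII"` is spherical with equal
#' volume, `"VVI"` diagonal with variable volume and shape, `"VVV"` fully
#' unconstrained.
#'
#' @return character vector of the 14 family codes.
#' @export
mixture_families <- function() {
  c("EII", "VII", "EEI", "VEI", "EVI", "VVI", "EEE", "EVE", "VEE", "VVE",
    "EEV", "VEV", "EVV", "VVV")
}

#' Count free parameters of a mixture specification
#'
#' Number of independently estimated parameters: `G - 1` mixing weights,
#' `G * d` component means, plus the family-specific covariance count
#' (volume contributes 1 or `G`, shape `d - 1` or `G * (d - 1)`,
#' orientation `d * (d - 1) / 2` or `G` times that).
#'
#' @param family one of [mixture_families()].
#' @param G number of components (>= 1).
#' @param dims data dimensionality.
#' @return integer parameter count.
#' @export
#' @examples
#' count_free_parameters("VVV", 2, 2)  # 11
count_free_parameters <- function(family, G, dims) {
  if (!family %in% mixture_families()) stop("unknown family code: ", family)
  if (G < 1 || G != round(G)) stop("G must be a positive integer")
  d <- dims
  orient <- d * (d - 1) / 2
  cov_params <- switch(family,
    EII = 1,
    VII = G,
    EEI = d,
    VEI = G + (d - 1),
    EVI = 1 + G * (d - 1),
    VVI = G * d,
    EEE = d * (d + 1) / 2,
    EVE = 1 + G * (d - 1) + orient,
    VEE = G + (d - 1) + orient,
    VVE = G + G * (d - 1) + orient,
    EEV = 1 + (d - 1) + G * orient,
    VEV = G + (d - 1) + G * orient,
    EVV = 1 + G * (d - 1) + G * orient,
    VVV = G * d * (d + 1) / 2
  )
  as.integer((G - 1) + G * d + cov_params)
}

#' Bayesian information criterion (larger is better)
#'
#' `BIC = 2 * loglik - n_params * log(n)`; with this sign convention the
#' best model is the one with the largest value.
#'
#' @param loglik maximised log-likelihood.
#' @param n_params number of free parameters.
#' @param n number of observations.
#' @return the BIC value.
#' @export
bic <- function(loglik, n_params, n) {
  if (n <= 0) stop("n must be positive")
  2 * loglik - n_params * log(n)
}

#' Fit a constrained-covariance Gaussian mixture by EM
#'
#' Expectation-maximisation for a `G`-component Gaussian mixture whose
#' covariances obey one of the fourteen eigendecomposition families. The
#' E-step computes responsibilities from the current component densities;
#' the M-step maximises the complete-data likelihood under the family's
#' volume/shape/orientation constraints (closed form for most families;
#' inner fixed-point iterations for the coupled families `VEI`, `VEV`,
#' `VEE`, `EVE`, `VVE`, with the common-orientation update performed by
#' cyclic Givens-rotation sweeps with a closed-form optimal angle).
#' Responsibilities are initialised by k-means++-style seeding; the best of
#' `n_restarts` runs by final log-likelihood is returned.
#'
#' @param x numeric matrix (n x d) of observations, standardised upstream.
#' @param family covariance family code, see [mixture_families()].
#' @param G number of components.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @param n_restarts number of random initialisations.
#' @param reg_floor eigenvalue floor, as a fraction of the mean marginal
#'   variance; applied (and flagged) when a covariance collapses.
#' @param seed integer seed for the initialisations (`NULL`: current RNG).
#' @param init_z optional n x G responsibility matrix used as an additional
#'   (first) initialisation, e.g. to warm-start from a nested family's fit.
#' @param engine `"cpp"` (default) for the compiled core, `"r"` for the pure
#'   R reference implementation; both give the same results and are
#'   cross-checked in the test suite.
#' @return an object of class `au_mixture`: mixing weights `pi`, means
#'   (d x G), covariance list `Sigma` and its volume/shape/orientation
#'   factors, `loglik` and the per-iteration `loglik_trace`, `n_params`,
#'   `bic`, responsibilities `z`, hard `labels`, `converged`, `n_iter`, and
#'   a `regularized` flag.
#' @export
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(100), ncol = 2), matrix(rnorm(100, 4), ncol = 2))
#' fit <- em_fit(x, "VVV", 2, n_restarts = 3, seed = 1)
#' fit$pi
em_fit <- function(x, family, G, tol = 1e-8, max_iter = 500, n_restarts = 10,
                   reg_floor = 1e-6, seed = NULL, init_z = NULL,
                   engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!family %in% mixture_families()) stop("unknown family code: ", family)
  n <- nrow(x); d <- ncol(x)
  if (any(!is.finite(x))) stop("data must be finite")
  if (G < 1 || G != round(G)) stop("G must be a positive integer")
  if (n <= G * d) stop("too few observations (n = ", n, ") for G = ", G,
                       " components in ", d, " dimensions")
  if (family %in% c("EVE", "VVE") && d > 2 && G > 1) {
    # Givens sweeps handle general d, but only d = 2 is exercised/validated
    # by this package; larger d is permitted yet may converge slowly.
  }
  floor_val <- reg_floor * mean(apply(x, 2, stats::var))
  if (!is.finite(floor_val) || floor_val <= 0) floor_val <- reg_floor

  if (G == 1) {
    z <- matrix(1, n, 1)
    fit <- em_run(x, z, family, G, tol, max_iter = 1, floor_val, engine)
    fit$converged <- TRUE  # single-component M-step is the exact MLE
    return(finish_fit(fit, x, family, G, n, d))
  }

  inits <- list()
  if (!is.null(init_z)) {
    init_z <- as.matrix(init_z)
    stopifnot(nrow(init_z) == n, ncol(init_z) == G)
    inits <- list(init_z)
  }
  rs <- with_seed(seed, lapply(seq_len(n_restarts), function(r)
    kmeanspp_responsibilities(x, G)))
  inits <- c(inits, rs)

  best <- NULL
  failures <- 0L
  for (z0 in inits) {
    fit <- tryCatch(em_run(x, z0, family, G, tol, max_iter, floor_val, engine),
                    error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1L; next }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("all ", length(inits), " initialisations failed for family ",
         family, ", G = ", G)
  finish_fit(best, x, family, G, n, d)
}

# one EM run from an initial responsibility matrix; dispatches to the
# compiled core or the pure R reference implementation
em_run <- function(x, z, family, G, tol, max_iter, floor_val,
                   engine = "cpp") {
  if (engine == "cpp") {
    fam_idx <- match(family, mixture_families()) - 1L
    res <- .em_core_cpp(x, z, fam_idx, tol, max_iter, floor_val, 1e-7)
    res$pi <- as.vector(res$pi)
    res$mu <- matrix(res$mu, ncol = G)
    res$loglik_trace <- as.vector(res$loglik_trace)
    return(res)
  }
  em_run_r(x, z, family, G, tol, max_iter, floor_val)
}

em_run_r <- function(x, z, family, G, tol, max_iter, floor_val) {
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  regularized <- FALSE
  params <- NULL
  for (it in seq_len(max_iter)) {
    params <- mstep(x, z, family, floor_val)
    regularized <- regularized || params$regularized
    es <- estep(x, params$pi, params$mu, params$Sigma)
    z <- es$z
    ll <- es$loglik
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (1 + abs(ll))) { converged <- TRUE; break }
    ll_prev <- ll
  }
  list(pi = params$pi, mu = params$mu, Sigma = params$Sigma,
       z = z, loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       converged = converged, n_iter = length(ll_trace),
       regularized = regularized)
}

finish_fit <- function(fit, x, family, G, n, d) {
  dec <- decompose_sigmas(fit$Sigma)
  npar <- count_free_parameters(family, G, d)
  out <- list(
    family = family, G = G, dims = d,
    pi = fit$pi, mean = fit$mu, Sigma = fit$Sigma,
    volume = dec$volume, shape = dec$shape, orientation = dec$orientation,
    loglik = fit$loglik, loglik_trace = fit$loglik_trace,
    n_params = npar, bic = bic(fit$loglik, npar, n),
    z = fit$z, converged = fit$converged, n_iter = fit$n_iter,
    regularized = fit$regularized, n = n
  )
  class(out) <- "au_mixture"
  out$labels <- assign_clusters(out, quiet = TRUE)
  out
}

#' @export
print.au_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture (%s, G = %d, d = %d)\n", x$family, x$G, x$dims))
  cat(sprintf("  loglik %.4f | params %d | BIC %.4f | %s in %d iter%s\n",
              x$loglik, x$n_params, x$bic,
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              if (x$regularized) " | covariance floor applied" else ""))
  cat("  weights:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

# volume / unit-determinant shape / orientation factors of each covariance
decompose_sigmas <- function(Sigma) {
  vols <- vapply(Sigma, function(S) det(S)^(1 / nrow(S)), 0)
  shapes <- lapply(seq_along(Sigma), function(k) {
    e <- eigen(Sigma[[k]], symmetric = TRUE)
    e$values / vols[k]
  })
  orients <- lapply(Sigma, function(S) eigen(S, symmetric = TRUE)$vectors)
  list(volume = vols, shape = do.call(cbind, shapes), orientation = orients)
}

# log N(x; mu, Sigma) for all rows of x
ldmvnorm <- function(x, mu, Sigma) {
  R <- chol(Sigma)
  xc <- sweep(x, 2, mu)
  y <- backsolve(R, t(xc), transpose = TRUE)
  -0.5 * ncol(x) * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(y^2)
}

estep <- function(x, pi_k, mu, Sigma) {
  n <- nrow(x); G <- length(pi_k)
  lp <- matrix(0, n, G)
  for (k in seq_len(G))
    lp[, k] <- ldmvnorm(x, mu[, k], Sigma[[k]]) + log(pi_k[k])
  m <- lp[cbind(seq_len(n), max.col(lp, ties.method = "first"))]
  lse <- m + log(rowSums(exp(lp - m)))
  list(z = exp(lp - lse), loglik = sum(lse))
}

mstep <- function(x, z, family, floor_val, inner_tol = 1e-7) {
  n <- nrow(x); d <- ncol(x); G <- ncol(z)
  nk <- colSums(z)
  if (any(nk < 1e-8)) stop("component collapsed (empty responsibility mass)")
  pi_k <- nk / n
  mu <- matrix(0, d, G)
  W <- vector("list", G)  # weighted scatter per component
  for (k in seq_len(G)) {
    mu[, k] <- colSums(z[, k] * x) / nk[k]
    xc <- sweep(x, 2, mu[, k]) * sqrt(z[, k])
    W[[k]] <- crossprod(xc)
  }
  Sigma <- sigma_mstep(family, W, nk, n, d, G, inner_tol)
  regularized <- FALSE
  for (k in seq_len(G)) {
    e <- eigen(Sigma[[k]], symmetric = TRUE)
    if (any(e$values < floor_val)) {
      regularized <- TRUE
      v <- pmax(e$values, floor_val)
      Sigma[[k]] <- e$vectors %*% (v * t(e$vectors))
    }
  }
  list(pi = pi_k, mu = mu, Sigma = Sigma, regularized = regularized)
}

# family-constrained covariance updates (see the methods vignette for the
# closed forms and the fixed-point schemes of the coupled families)
sigma_mstep <- function(family, W, nk, n, d, G, inner_tol) {
  Wsum <- Reduce(`+`, W)
  rep_list <- function(S) lapply(seq_len(G), function(k) S)
  gdet <- function(v) prod(v)^(1 / d)
  switch(family,
    EII = {
      lam <- sum(vapply(W, function(w) sum(diag(w)), 0)) / (n * d)
      rep_list(diag(lam, d))
    },
    VII = lapply(seq_len(G), function(k)
      diag(sum(diag(W[[k]])) / (nk[k] * d), d)),
    EEI = rep_list(diag(diag(Wsum) / n, d)),
    VEI = {
      a <- diag(Wsum); a <- a / gdet(a)
      lam <- rep(1, G)
      for (i in 1:100) {
        lam <- vapply(seq_len(G), function(k)
          sum(diag(W[[k]]) / a) / (nk[k] * d), 0)
        b <- Reduce(`+`, lapply(seq_len(G), function(k) diag(W[[k]]) / lam[k]))
        a_new <- b / gdet(b)
        if (max(abs(a_new - a)) < inner_tol * max(abs(a))) { a <- a_new; break }
        a <- a_new
      }
      lapply(seq_len(G), function(k) diag(lam[k] * a, d))
    },
    EVI = {
      dets <- vapply(W, function(w) gdet(diag(w)), 0)
      lam <- sum(dets) / n
      lapply(seq_len(G), function(k) diag(lam * diag(W[[k]]) / dets[k], d))
    },
    VVI = lapply(seq_len(G), function(k) diag(diag(W[[k]]) / nk[k], d)),
    EEE = rep_list(Wsum / n),
    VVV = lapply(seq_len(G), function(k) W[[k]] / nk[k]),
    EEV = {
      eg <- lapply(W, function(w) eigen(w, symmetric = TRUE))
      om <- Reduce(`+`, lapply(eg, `[[`, "values"))
      shape <- om / gdet(om)
      lam <- gdet(om) / n
      lapply(seq_len(G), function(k) {
        L <- eg[[k]]$vectors
        L %*% (lam * shape * t(L))
      })
    },
    VEV = {
      eg <- lapply(W, function(w) eigen(w, symmetric = TRUE))
      omk <- lapply(eg, `[[`, "values")
      a <- Reduce(`+`, omk); a <- a / gdet(a)
      for (i in 1:100) {
        lam <- vapply(seq_len(G), function(k) sum(omk[[k]] / a) / (nk[k] * d), 0)
        b <- Reduce(`+`, lapply(seq_len(G), function(k) omk[[k]] / lam[k]))
        a_new <- b / gdet(b)
        if (max(abs(a_new - a)) < inner_tol * max(abs(a))) { a <- a_new; break }
        a <- a_new
      }
      lapply(seq_len(G), function(k) {
        L <- eg[[k]]$vectors
        L %*% (lam[k] * a * t(L))
      })
    },
    EVV = {
      dets <- vapply(W, function(w) max(det(w), .Machine$double.xmin)^(1 / d), 0)
      lam <- sum(dets) / n
      lapply(seq_len(G), function(k) lam * W[[k]] / dets[k])
    },
    VEE = {
      C <- Wsum / n
      C <- C / det(C)^(1 / d)
      lam <- rep(1, G)
      for (i in 1:100) {
        lam <- vapply(seq_len(G), function(k)
          sum(diag(solve(C, W[[k]]))) / (nk[k] * d), 0)
        Wt <- Reduce(`+`, lapply(seq_len(G), function(k) W[[k]] / lam[k]))
        C_new <- Wt / det(Wt)^(1 / d)
        if (max(abs(C_new - C)) < inner_tol * max(abs(C))) { C <- C_new; break }
        C <- C_new
      }
      lapply(seq_len(G), function(k) lam[k] * C)
    },
    EVE = common_orientation_mstep(W, nk, n, d, G, equal_volume = TRUE, inner_tol),
    VVE = common_orientation_mstep(W, nk, n, d, G, equal_volume = FALSE, inner_tol),
    stop("unknown family code: ", family)
  )
}

# EVE / VVE: alternate shape(+volume) updates with a common-orientation
# update by cyclic Givens sweeps (closed-form optimal angle per plane)
common_orientation_mstep <- function(W, nk, n, d, G, equal_volume, inner_tol) {
  Wsum <- Reduce(`+`, W)
  D <- eigen(Wsum, symmetric = TRUE)$vectors
  obj_prev <- Inf
  A <- matrix(1, d, G); lam <- rep(1, G)
  for (i in 1:100) {
    Sk <- lapply(W, function(w) crossprod(D, w %*% D))
    diags <- lapply(Sk, diag)
    if (equal_volume) {
      dets <- vapply(diags, function(v) prod(v)^(1 / d), 0)
      lam_c <- sum(dets) / n
      lam <- rep(lam_c, G)
      A <- vapply(seq_len(G), function(k) diags[[k]] / dets[k], numeric(d))
    } else {
      full <- vapply(seq_len(G), function(k) diags[[k]] / nk[k], numeric(d))
      lam <- apply(full, 2, function(v) prod(v)^(1 / d))
      A <- sweep(full, 2, lam, "/")
    }
    A <- matrix(A, nrow = d)
    M <- sweep(1 / A, 2, lam, "/")  # inverse eigenvalue weights per component
    D <- givens_orientation(D, W, M)
    obj <- orientation_objective(W, nk, D, A, lam)
    if (is.finite(obj_prev) && abs(obj_prev - obj) < inner_tol * (1 + abs(obj)))
      break
    obj_prev <- obj
  }
  lapply(seq_len(G), function(k) D %*% (lam[k] * A[, k] * t(D)))
}

orientation_objective <- function(W, nk, D, A, lam) {
  G <- length(W); d <- nrow(D)
  s <- 0
  for (k in seq_len(G)) {
    Sig_inv <- D %*% ((1 / (lam[k] * A[, k])) * t(D))
    s <- s + sum(Sig_inv * W[[k]]) + nk[k] * (d * log(lam[k]) + sum(log(A[, k])))
  }
  s
}

# minimise sum_k tr(D M_k D' W_k) over orthogonal D by Givens sweeps;
# M is d x G of inverse eigenvalues. For each coordinate plane the optimal
# rotation angle is closed-form: minimise P cos(2t) + Q sin(2t).
givens_orientation <- function(D, W, M, max_sweeps = 50, tol = 1e-10) {
  d <- nrow(D); G <- length(W)
  for (sweep_i in seq_len(max_sweeps)) {
    max_theta <- 0
    for (i in seq_len(d - 1)) for (j in (i + 1):d) {
      P <- 0; Q <- 0
      for (k in seq_len(G)) {
        S <- crossprod(D, W[[k]] %*% D)
        w <- M[i, k] - M[j, k]
        P <- P + w * (S[i, i] - S[j, j]) / 2
        Q <- Q + w * S[i, j]
      }
      theta <- 0.5 * atan2(-Q, -P)
      if (abs(theta) > tol) {
        cs <- cos(theta); sn <- sin(theta)
        Dij <- D[, c(i, j)]
        D[, i] <- Dij %*% c(cs, sn)
        D[, j] <- Dij %*% c(-sn, cs)
      }
      max_theta <- max(max_theta, abs(theta))
    }
    if (max_theta < tol) break
  }
  D
}

# k-means++-style seeding: spread centres, then one-hot nearest-centre
# responsibilities
kmeanspp_responsibilities <- function(x, G) {
  n <- nrow(x)
  centers <- matrix(0, G, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (k in seq_len(G - 1) + 1) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1, prob = p)
    centers[k, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[k, ])^2))
  }
  dist2 <- vapply(seq_len(G), function(k)
    rowSums(sweep(x, 2, centers[k, ])^2), numeric(n))
  lab <- max.col(-dist2, ties.method = "first")
  z <- matrix(0, n, G)
  z[cbind(seq_len(n), lab)] <- 1
  # guard: every component needs some mass
  for (k in seq_len(G)) if (sum(z[, k]) == 0) z[sample.int(n, 1), k] <- 1
  z / rowSums(z)
}

#' Mixture density of a fitted model
#'
#' @param fit an `au_mixture` object.
#' @param x matrix of points at which to evaluate the density.
#' @return numeric vector of density values.
#' @export
mixture_density <- function(fit, x) {
  x <- as.matrix(x)
  dens <- numeric(nrow(x))
  for (k in seq_len(fit$G))
    dens <- dens + fit$pi[k] * exp(ldmvnorm(x, fit$mean[, k], fit$Sigma[[k]]))
  dens
}

#' Hard cluster assignment from responsibilities
#'
#' Each observation is assigned to the component with the highest posterior
#' probability; exact ties are broken towards the lowest component index and
#' reported with a message.
#'
#' @param fit an `au_mixture` object (or a responsibility matrix).
#' @param quiet suppress the tie message.
#' @return integer vector of component indices.
#' @export
assign_clusters <- function(fit, quiet = FALSE) {
  z <- if (is.matrix(fit)) fit else fit$z
  lab <- max.col(z, ties.method = "first")
  mx <- z[cbind(seq_len(nrow(z)), lab)]
  ties <- rowSums(z == mx) > 1
  if (any(ties) && !quiet)
    message(sum(ties), " tied assignment(s) broken towards the lowest ",
            "component index")
  lab
}

#' Label a two-component fit as over-/under-responsive
#'
#' For a `G = 2` mixture fitted on (average AU12, average AU6), the
#' component whose members have the larger mean of `avg_au12 + avg_au6` is
#' labelled "over"; the other "under". Ties are broken by `avg_au12` (and
#' reported). For `G != 2` the labelling is skipped with a notice and `NULL`
#' is returned, so a pipeline can still report the raw clustering.
#'
#' @param fit an `au_mixture` object fitted to the ASD rows.
#' @param features data frame with `avg_au12` and `avg_au6`, rows aligned
#'   with the observations `fit` was fitted on.
#' @return list with `component_labels` (named character vector, one entry
#'   per component) and `subgroup` (per-observation labels), or `NULL`.
#' @export
label_subgroups <- function(fit, features) {
  if (fit$G != 2) {
    message("subgroup labelling skipped: fit has G = ", fit$G,
            " components (expected 2)")
    return(NULL)
  }
  stopifnot(nrow(features) == nrow(fit$z))
  lab <- fit$labels
  sums <- tapply(features$avg_au12 + features$avg_au6, lab, mean)
  au12 <- tapply(features$avg_au12, lab, mean)
  comp <- as.integer(names(sums))
  if (length(comp) < 2) stop("a component has no assigned member")
  over <- if (sums[1] > sums[2]) comp[1]
          else if (sums[2] > sums[1]) comp[2]
          else {
            message("equal component feature sums; tie broken by avg_au12")
            comp[which.max(au12)]
          }
  component_labels <- ifelse(comp == over, "over", "under")
  names(component_labels) <- comp
  list(component_labels = component_labels,
       subgroup = unname(component_labels[as.character(lab)]))
}

#' Fit all families over a range of component counts and select by BIC
#'
#' Fits every (family, G) combination, collects the BIC values in a grid
#' (rows = G, columns = family; `NA` where a fit was infeasible), and
#' returns the maximum-BIC fit.
#'
#' @inheritParams em_fit
#' @param G_range integer vector of component counts to try.
#' @param families family codes to try.
#' @param verbose print progress per cell.
#' @return list of class `au_model_selection`: `best` (an `au_mixture`),
#'   `grid` (data frame of BIC values), `failed` (character vector of failed
#'   cells).
#' @export
model_select <- function(x, G_range = 1:9, families = mixture_families(),
                         tol = 1e-8, max_iter = 500, n_restarts = 10,
                         reg_floor = 1e-6, seed = NULL, verbose = FALSE,
                         engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  x <- as.matrix(x)
  grid <- matrix(NA_real_, length(G_range), length(families),
                 dimnames = list(G_range, families))
  best <- NULL
  failed <- character(0)
  for (gi in seq_along(G_range)) {
    for (fi in seq_along(families)) {
      G <- G_range[gi]; fam <- families[fi]
      cell_seed <- if (is.null(seed)) NULL else
        (seed + 131 * gi + fi) %% 2147483647
      fit <- tryCatch(
        em_fit(x, fam, G, tol = tol, max_iter = max_iter,
               n_restarts = n_restarts, reg_floor = reg_floor,
               seed = cell_seed, engine = engine),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        failed <- c(failed, paste0(fam, ":G", G))
        next
      }
      grid[gi, fi] <- fit$bic
      if (verbose)
        message(sprintf("%s G=%d  BIC %.3f", fam, G, fit$bic))
      if (is.null(best) || fit$bic > best$bic) best <- fit
    }
  }
  if (is.null(best))
    stop("every (family, G) fit failed: ", paste(failed, collapse = ", "))
  out <- list(best = best,
              grid = data.frame(G = G_range, grid, check.names = FALSE),
              failed = failed)
  class(out) <- "au_model_selection"
  out
}

#' @export
print.au_model_selection <- function(x, ...) {
  cat(sprintf("BIC model selection over %d cells (%d failed)\n",
              prod(dim(x$grid) - c(0, 1)), length(x$failed)))
  cat(sprintf("best: %s with G = %d, BIC = %.2f\n",
              x$best$family, x$best$G, x$best$bic))
  invisible(x)
}
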