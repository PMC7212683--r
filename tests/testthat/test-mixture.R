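test_that("free-parameter counts match enumeration and the mclust oracle", {
  expect_equal(count_free_parameters("VVV", 1, 2), 5)
  expect_equal(count_free_parameters("EII", 2, 2), 6)
  expect_equal(count_free_parameters("VVV", 2, 2), 11)
  for (fam in mixture_families()) for (G in 1:4) for (d in 2:3) {
    expect_equal(count_free_parameters(fam, G, d),
                 mclust::nMclustParams(fam, d = d, G = G),
                 info = paste(fam, G, d))
  }
  expect_error(count_free_parameters("XYZ", 2, 2), "unknown family")
})

test_that("BIC uses the larger-is-better convention", {
  expect_equal(bic(0, 0, 10), 0)
  expect_equal(bic(-100, 5, 100), -200 - 5 * log(100))
  expect_lt(bic(-100, 6, 100), bic(-100, 5, 100))
  expect_error(bic(0, 0, 0), "positive")
})

test_that("a single-component VVV fit is the closed-form Gaussian MLE", {
  set.seed(3)
  x <- rmvn2(200, c(1, -2), matrix(c(2, .7, .7, 1), 2))
  fit <- em_fit(x, "VVV", 1)
  expect_equal(as.vector(fit$mean), colMeans(x), tolerance = 1e-10)
  expect_equal(fit$Sigma[[1]], cov(x) * (nrow(x) - 1) / nrow(x),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$pi, 1)
  # loglik agrees with a direct evaluation of the Gaussian density
  S <- cov(x) * 199 / 200
  ll <- sum(apply(x, 1, function(r)
    -log(2 * pi) - 0.5 * log(det(S)) -
      0.5 * t(r - colMeans(x)) %*% solve(S, r - colMeans(x))))
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
})

test_that("compiled and reference engines agree on shared initialisations", {
  set.seed(11)
  x <- rbind(rmvn2(90, c(0, 0), matrix(c(1, .4, .4, 1.5), 2)),
             rmvn2(60, c(3, 2.5), matrix(c(.7, -.2, -.2, .5), 2)))
  z0 <- matrix(runif(150 * 2), 150, 2)
  z0 <- z0 / rowSums(z0)
  for (fam in mixture_families()) {
    a <- em_fit(x, fam, 2, n_restarts = 0, init_z = z0, tol = 1e-10)
    b <- em_fit(x, fam, 2, n_restarts = 0, init_z = z0, tol = 1e-10,
                engine = "r")
    expect_equal(a$loglik, b$loglik, tolerance = 1e-8, info = fam)
    expect_equal(a$pi, b$pi, tolerance = 1e-6, info = fam)
  }
})

test_that("converged loglik matches the mclust oracle on shared inits", {
  suppressMessages(library(mclust))  # me() dispatches helpers by name
  set.seed(42)
  x <- rbind(rmvn2(120, c(0, 0), matrix(c(1, .5, .5, 2), 2)),
             rmvn2(80, c(4, 3), matrix(c(.6, -.3, -.3, .8), 2)))
  z0 <- mclust::unmap(sample(1:2, 200, TRUE))
  closed <- setdiff(mixture_families(), c("VEE", "VVE"))
  for (fam in closed) {
    mine <- em_fit(x, fam, 2, n_restarts = 0, init_z = z0, tol = 1e-10)
    mc <- mclust::me(data = x, modelName = fam, z = z0,
                     control = mclust::emControl(tol = c(1e-10, 1e-10)))
    expect_equal(mine$loglik, mc$loglik, tolerance = 1e-4, info = fam)
  }
  # coupled-orientation families: never worse than the oracle's optimum
  for (fam in c("VEE", "VVE")) {
    mine <- em_fit(x, fam, 2, n_restarts = 5, init_z = z0, seed = 1,
                   tol = 1e-10)
    mc <- mclust::me(data = x, modelName = fam, z = z0,
                     control = mclust::emControl(tol = c(1e-10, 1e-10)))
    expect_gte(mine$loglik, mc$loglik - 1e-4)
  }
})

test_that("the EM log-likelihood trajectory is non-decreasing for every family", {
  set.seed(19)
  x <- rbind(rmvn2(70, c(0, 0), rot2(25) %*% diag(c(2, .3)) %*% t(rot2(25))),
             rmvn2(50, c(1.5, 1), rot2(100) %*% diag(c(1, .2)) %*% t(rot2(100))),
             rmvn2(40, c(-1, 2), diag(c(.5, .5))))
  for (fam in mixture_families()) {
    fit <- em_fit(x, fam, 3, n_restarts = 4, seed = 2)
    dl <- diff(fit$loglik_trace)
    expect_gte(min(dl), -1e-7 * (1 + abs(fit$loglik)))
  }
})

test_that("nested families never beat their generalisations", {
  set.seed(29)
  x <- rbind(rmvn2(100, c(0, 0), matrix(c(1.2, .5, .5, .8), 2)),
             rmvn2(100, c(2.5, 2), matrix(c(.5, -.25, -.25, 1.3), 2)))
  fit_chain <- function(chain) {
    ll <- -Inf
    prev <- NULL
    for (fam in chain) {
      fit <- em_fit(x, fam, 2, n_restarts = 6, seed = 5,
                    init_z = if (is.null(prev)) NULL else prev$z)
      expect_gte(fit$loglik, ll - 1e-6)
      ll <- fit$loglik
      prev <- fit
    }
  }
  fit_chain(c("EII", "EEI", "EEE", "VEE", "VVV"))
  fit_chain(c("EII", "VII", "VVI", "VVV"))
  fit_chain(c("EEI", "EVI", "EVE", "EVV", "VVV"))
  fit_chain(c("EEE", "EEV", "VEV", "VVV"))
})

test_that("well-separated planted components are recovered", {
  set.seed(31)
  # ~6 pooled SDs between means
  x <- rbind(rmvn2(220, c(0, 0), diag(c(1, 1))),
             rmvn2(180, c(6, 0), matrix(c(1, .3, .3, 1), 2)))
  truth <- rep(1:2, c(220, 180))
  fit <- em_fit(x, "VVV", 2, n_restarts = 5, seed = 3)
  ord <- order(fit$mean[1, ])
  expect_lt(max(abs(fit$mean[, ord] - cbind(c(0, 0), c(6, 0)))), 0.2)
  expect_gt(adjusted_rand(truth, fit$labels), 0.99)
})

test_that("degenerate data is floored and flagged rather than crashing", {
  x <- matrix(1, 60, 2)
  fit <- em_fit(x, "VVV", 2, n_restarts = 2, seed = 1)
  expect_true(fit$regularized)
  expect_true(all(is.finite(fit$loglik)))
})

test_that("mixture parameters are recovered within Monte Carlo error", {
  set.seed(47)
  pi_t <- c(0.4, 0.6)
  mu_t <- cbind(c(0, 0), c(3, 2))
  S1 <- rot2(30) %*% diag(c(2, .4)) %*% t(rot2(30))
  S2 <- rot2(115) %*% diag(c(1, .25)) %*% t(rot2(115))
  n <- 1000
  n1 <- rbinom(1, n, pi_t[1])
  x <- rbind(rmvn2(n1, mu_t[, 1], S1), rmvn2(n - n1, mu_t[, 2], S2))
  fit <- em_fit(x, "VVV", 2, n_restarts = 5, seed = 9)
  ord <- order(fit$mean[1, ])
  nk <- n * pi_t
  expect_lt(abs(fit$pi[ord][1] - 0.4), 3 * sqrt(0.4 * 0.6 / n))
  for (k in 1:2) {
    Sk <- if (k == 1) S1 else S2
    for (j in 1:2)
      expect_lt(abs(fit$mean[j, ord[k]] - mu_t[j, k]),
                3 * sqrt(Sk[j, j] / nk[k]))
    expect_lt(abs(fit$Sigma[[ord[k]]][1, 1] - Sk[1, 1]),
              3 * Sk[1, 1] * sqrt(2 / nk[k]))
    expect_lt(abs(fit$Sigma[[ord[k]]][1, 2] - Sk[1, 2]),
              3 * sqrt((Sk[1, 1] * Sk[2, 2] + Sk[1, 2]^2) / nk[k]))
  }
})

test_that("fitted covariance factors satisfy the decomposition constraints", {
  set.seed(53)
  x <- rbind(rmvn2(80, c(0, 0), matrix(c(1, .3, .3, .7), 2)),
             rmvn2(80, c(2, 2), matrix(c(.6, -.2, -.2, 1.1), 2)))
  for (fam in c("VVI", "EVE", "VVE", "VEV", "VVV")) {
    fit <- em_fit(x, fam, 2, n_restarts = 4, seed = 4)
    expect_equal(sum(fit$pi), 1, tolerance = 1e-12)
    expect_equal(rowSums(fit$z), rep(1, nrow(x)), tolerance = 1e-10)
    for (k in 1:2) {
      expect_equal(prod(fit$shape[, k]), 1, tolerance = 1e-8)  # det(A) = 1
      D <- fit$orientation[[k]]
      expect_equal(crossprod(D), diag(2), tolerance = 1e-8, ignore_attr = TRUE)
      S <- fit$volume[k] * D %*% diag(fit$shape[, k]) %*% t(D)
      expect_equal(S, fit$Sigma[[k]], tolerance = 1e-8)
      expect_true(all(eigen(fit$Sigma[[k]], symmetric = TRUE)$values > 0))
    }
  }
})

test_that("the fitted mixture density integrates to one", {
  set.seed(59)
  x <- rbind(rmvn2(100, c(0, 0), diag(2)),
             rmvn2(100, c(3, 1), matrix(c(.8, .3, .3, .6), 2)))
  fit <- em_fit(x, "VVV", 2, n_restarts = 4, seed = 6)
  gx <- seq(-7, 10, length.out = 400)
  gy <- seq(-7, 8, length.out = 400)
  dens <- mixture_density(fit, as.matrix(expand.grid(gx, gy)))
  integral <- sum(dens) * diff(gx[1:2]) * diff(gy[1:2])
  expect_equal(integral, 1, tolerance = 0.01)
})

test_that("cluster assignment is the responsibility argmax with logged ties", {
  z <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.5, 0.5))
  expect_message(lab <- assign_clusters(z), "tied")
  expect_equal(lab, c(1L, 2L, 1L))
  set.seed(61)
  zr <- matrix(runif(300), 100, 3)
  zr <- zr / rowSums(zr)
  expect_equal(assign_clusters(zr, quiet = TRUE),
               apply(zr, 1, which.max))
})

test_that("subgroup labelling follows the larger joint AU mean and is
           invariant to component order", {
  feats <- data.frame(avg_au12 = c(rep(1.0, 10), rep(0.1, 20)),
                      avg_au6 = c(rep(1.0, 10), rep(0.05, 20)))
  fake_fit <- function(lab) {
    z <- mclust::unmap(lab)
    structure(list(G = 2, z = z, labels = lab), class = "au_mixture")
  }
  lab1 <- c(rep(1L, 10), rep(2L, 20))
  out1 <- label_subgroups(fake_fit(lab1), feats)
  expect_equal(unname(out1$component_labels["1"]), "over")
  expect_equal(out1$subgroup, c(rep("over", 10), rep("under", 20)))
  # swap component indices: subgroup labels must be unchanged
  out2 <- label_subgroups(fake_fit(3L - lab1), feats)
  expect_equal(out2$subgroup, out1$subgroup)
  # G != 2 is skipped with a notice
  g3 <- structure(list(G = 3), class = "au_mixture")
  expect_message(res <- label_subgroups(g3, feats), "skipped")
  expect_null(res)
})

test_that("model selection fills the full grid and returns the BIC maximum", {
  set.seed(67)
  x <- rbind(rmvn2(150, c(0, 0), diag(2)),
             rmvn2(100, c(4, 3), matrix(c(.6, -.3, -.3, .8), 2)))
  sel <- model_select(x, G_range = 1:3, n_restarts = 3, seed = 8)
  expect_equal(dim(sel$grid), c(3, 15))  # G column + 14 families
  expect_equal(names(sel$grid)[-1], mixture_families())
  filled <- !is.na(as.matrix(sel$grid[, -1]))
  expect_equal(max(sel$grid[, -1], na.rm = TRUE), sel$best$bic)
  expect_equal(sel$best$G, 2)
  # grid shape for the full default range is 9 x 14 = 126 cells
  expect_equal(length(1:9) * length(mixture_families()), 126)
})
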