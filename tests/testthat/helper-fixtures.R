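# shared fixtures, built in code

small_config <- function(seed = 7, ...) {
  cohort_config(n_td = 6, n_asd_over = 5, n_asd_under = 8, seed = seed, ...)
}

# a single-trace data frame at a given frame rate
make_trace <- function(evidence, fps = 24,
                       face_detected = rep(TRUE, length(evidence)),
                       participant_id = "P001", video_id = "v1", au = "AU12") {
  n <- length(evidence)
  data.frame(participant_id = participant_id, video_id = video_id, au = au,
             frame_index = seq_len(n) - 1L, time_s = (seq_len(n) - 1) / fps,
             evidence = evidence, face_detected = face_detected,
             stringsAsFactors = FALSE)
}

# fine-grid Riemann sum of |f| on [0, t_end] -- independent integration oracle
riemann_abs <- function(f, t_end, n_grid = 2e5) {
  tt <- seq(0, t_end, length.out = n_grid)
  sum(abs(f(tt))) * (t_end / (n_grid - 1))
}

# draw from a 2-d Gaussian without extra dependencies
rmvn2 <- function(n, mu, Sigma) {
  z <- matrix(stats::rnorm(2 * n), n, 2) %*% chol(Sigma)
  sweep(z, 2, mu, "+")
}

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
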