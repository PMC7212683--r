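#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded package functions never disturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream as-is.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible per-stage seed from a master seed
#'
#' A single pipeline seed fans out to one seed per stage so each stage can be
#' rerun in isolation and still match a full pipeline run. The rule is a
#' fixed affine map modulo a Mersenne prime, keeping results inside the
#' 32-bit integer range R requires.
#'
#' @param seed master integer seed.
#' @param stage stage name (character) or index (integer).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "generate")
derive_seed <- function(seed, stage) {
  stages <- c("generate", "traces", "scales", "features", "cluster",
              "analyze", "report")
  idx <- if (is.character(stage)) match(stage, stages) else as.integer(stage)
  if (is.na(idx)) stop("unknown pipeline stage: ", stage)
  m <- 2147483647  # 2^31 - 1
  s <- (as.numeric(seed) %% m) * 48271 %% m
  as.integer((s + idx * 1000003) %% (m - 1) + 1)
}

#' FNV-1a hash of a character string (hex)
#' @keywords internal
#' @noRd
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.numeric(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Format numerics at full precision for deterministic text output
#' @keywords internal
#' @noRd
num17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
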