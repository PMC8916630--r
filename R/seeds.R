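#' Derive a named child seed from a master seed
#'
#' Simulation runs draw from several independent sources of randomness
#' (exposure generation, per-sigma measurement-error sets, per-scenario
#' cohort outcomes). Each source gets its own stream, derived
#' deterministically from the master seed and a stream name, so that adding
#' scenarios or changing one sigma never perturbs the draws of another.
#'
#' @param master integer master seed.
#' @param name character stream name, e.g. `"cohort:8.5,1.05,1"`.
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @examples
#' child_seed(1, "exposure")
#' @export
child_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name),
            length(name) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps everything inside R's integer range
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% m
  as.integer((((abs(master) %% m) * 48271) %% m + h) %% m)
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
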