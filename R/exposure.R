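#' Packaged pool of candidate city-mean PM2.5 values
#'
#' Returns the 229 synthetic candidate annual-mean PM2.5 city values
#' (micrograms per cubic metre) shipped with the package. The pool is a
#' deterministic lognormal quantile grid calibrated so that a 100-city
#' quartile-stratified sample places 7, 8.5 and 9.5 ug/m3 near the 15th,
#' 40th and 55th percentiles of the sampled set - the anchors the threshold
#' experiment is designed around. See `data-raw/make_fixtures.R` for the
#' construction.
#'
#' @return Numeric vector of 229 positive city means, ug/m3.
#' @export
city_base_pool <- function() {
  df <- utils::read.csv(system.file("extdata", "city_base_pool_synthetic.csv",
                                    package = "crthresh", mustWork = TRUE))
  df$true_pm
}

#' Generate "true" city-mean exposures by stratified sampling
#'
#' Draws `n_cities` true city-mean PM2.5 values from a candidate pool:
#' the pool is split into quartiles, `n_cities / 4` means are sampled
#' without replacement from each quartile, and each sampled mean is
#' perturbed by an independent Uniform(-jitter, jitter) draw. True
#' exposures are constant over follow-up years.
#'
#' @param n_cities number of cities (divisible by 4).
#' @param base_pool numeric vector of candidate city means, ug/m3.
#' @param jitter half-width of the uniform perturbation, ug/m3.
#' @param seed integer seed; identical seeds give identical sets.
#' @return A data.frame of class `city_exposure` with columns `city`
#'   (integer id) and `true_pm` (ug/m3, all positive).
#' @examples
#' ex <- generate_true_exposures(100, seed = 1)
#' quantile(ex$true_pm)
#' @export
generate_true_exposures <- function(n_cities = 100, base_pool = city_base_pool(),
                                    jitter = 1, seed) {
  if (n_cities %% 4 != 0) stop("n_cities must be divisible by 4")
  if (length(base_pool) < n_cities)
    stop("base pool (", length(base_pool), ") smaller than n_cities")
  per_q <- n_cities / 4
  qs <- stats::quantile(base_pool, c(0.25, 0.5, 0.75), type = 7)
  grp <- findInterval(base_pool, qs, left.open = TRUE) + 1L # 1..4
  if (any(tabulate(grp, 4L) < per_q))
    stop("a quartile of the base pool has fewer than ", per_q, " candidates")
  pm <- with_seed(seed, {
    picked <- unlist(lapply(1:4, function(g) {
      cand <- base_pool[grp == g]
      cand[sample.int(length(cand), per_q)]
    }))
    picked + if (jitter > 0) stats::runif(n_cities, -jitter, jitter) else 0
  })
  if (any(pm <= 0))
    stop("jitter produced a non-positive city mean; use a larger pool floor")
  structure(data.frame(city = seq_len(n_cities), true_pm = pm),
            class = c("city_exposure", "data.frame"), seed = seed)
}

# Truncated normal draws via inverse CDF: exactly n uniforms are consumed
# per call, so seed streams stay aligned regardless of sigma or bound
# (rejection sampling would not guarantee that).
rtruncnorm_bounded <- function(n, sd, bound) {
  stopifnot(sd > 0, bound > 0)
  p <- stats::pnorm(c(-bound, bound), sd = sd)
  stats::qnorm(p[1] + stats::runif(n) * (p[2] - p[1]), sd = sd)
}

#' Draw replicated classical measurement-error sets
#'
#' Generates `n_sets` independent replicates of per-city measurement error
#' from a mean-zero normal with standard deviation `sigma`, truncated to
#' `[-bound, bound]` (the bound is an absolute cap in ug/m3, the same for
#' every sigma). One draw per city per replicate; within a replicate the
#' error is constant over follow-up years, matching time-constant true
#' exposures. Error sets are meant to be drawn once per sigma and reused
#' across all scenarios of a run (common random numbers), so differences
#' between scenarios are never due to different error draws.
#'
#' @param n_cities number of cities.
#' @param sigma error standard deviation, ug/m3 (> 0).
#' @param n_sets number of replicates.
#' @param bound truncation bound, ug/m3 (default 4).
#' @param seed integer seed.
#' @return An object of class `exposure_errors`: a list with `errors`
#'   (n_sets x n_cities matrix, all entries within the bound), `sigma`,
#'   `bound` and `seed`.
#' @examples
#' es <- draw_error_sets(100, sigma = 1, n_sets = 100, seed = 7)
#' max(abs(es$errors))
#' @export
draw_error_sets <- function(n_cities, sigma, n_sets = 100, bound = 4, seed) {
  if (!(sigma > 0)) stop("sigma must be positive")
  if (!(bound > 0)) stop("bound must be positive")
  if (n_sets < 1) stop("n_sets must be at least 1")
  e <- with_seed(seed,
                 rtruncnorm_bounded(n_sets * n_cities, sd = sigma, bound = bound))
  structure(list(errors = matrix(e, nrow = n_sets, ncol = n_cities),
                 sigma = sigma, bound = bound, seed = seed),
            class = "exposure_errors")
}

#' @export
print.exposure_errors <- function(x, ...) {
  cat("Measurement-error sets: ", nrow(x$errors), " replicates x ",
      ncol(x$errors), " cities, sigma = ", x$sigma, " ug/m3, bound = +/-",
      x$bound, " ug/m3\n", sep = "")
  invisible(x)
}

#' Observed exposure under classical error
#'
#' The observed city-mean PM2.5 is the true mean plus the error draw; no
#' clamping is applied (observed values at or below zero are legitimate
#' inputs to the hinge transform downstream).
#'
#' @param true_pm true city mean(s), ug/m3.
#' @param error error draw(s), ug/m3.
#' @return `true_pm + error`, ug/m3.
#' @export
observe <- function(true_pm, error) true_pm + error
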