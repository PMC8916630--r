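#' Configuration for the factorial measurement-error experiment
#'
#' Collects every dial of the simulation study. The defaults reproduce the
#' full study grid: true thresholds 7 / 8.5 / 9.5 ug/m3, true hazard ratios
#' 1.0025 / 1.005 / 1.01 / 1.02 / 1.05 per ug/m3, error SDs 1 / 2 / 4 ug/m3
#' (45 scenario combinations, 15 distinct concentration-response
#' functions), 100 error replicates per SD, and a cohort of 100 cities x
#' 20,000 males enrolled at age 60 and followed 20 years (2 million
#' individuals). The `"desk"` preset keeps the grid but shrinks each city
#' to 2,000 persons and uses 25 replicates, for quick pipeline checks.
#'
#' @param thresholds true thresholds, ug/m3.
#' @param hrs true hazard ratios per ug/m3.
#' @param sigmas measurement-error SDs, ug/m3.
#' @param replicates error replicates per sigma.
#' @param n_cities number of cities (divisible by 4).
#' @param persons_per_city individuals enrolled per city.
#' @param years follow-up length, years.
#' @param start_age enrolment age; the cohort birth year is
#'   `first_year - start_age`.
#' @param first_year first calendar year of follow-up.
#' @param error_bound truncation bound of the error distribution, ug/m3.
#' @param jitter half-width of the uniform perturbation applied when
#'   sampling true city means from the base pool, ug/m3.
#' @param seed master seed; all streams are derived from it by
#'   [child_seed()].
#' @param scale `"full"` or `"desk"`; the preset overrides
#'   `persons_per_city` and `replicates` unless those are given explicitly.
#' @param share_cohort_across_sigma if TRUE, scenarios differing only in
#'   sigma reuse one cohort realisation (variance-reduction alternative);
#'   default FALSE simulates one cohort per (T, h, sigma) combination.
#' @param fit_splines if TRUE, [run_scenario()] also fits the
#'   relative-risk spline diagnostic for every replicate.
#' @return An object of class `experiment_config`.
#' @examples
#' experiment_config(scale = "desk", seed = 1)
#' @export
experiment_config <- function(thresholds = c(7, 8.5, 9.5),
                              hrs = c(1.0025, 1.005, 1.01, 1.02, 1.05),
                              sigmas = c(1, 2, 4),
                              replicates = NULL,
                              n_cities = 100,
                              persons_per_city = NULL,
                              years = 20,
                              start_age = 60,
                              first_year = 2000,
                              error_bound = 4,
                              jitter = 1,
                              seed = 1,
                              scale = c("full", "desk"),
                              share_cohort_across_sigma = FALSE,
                              fit_splines = FALSE) {
  scale <- match.arg(scale)
  if (is.null(persons_per_city))
    persons_per_city <- if (scale == "full") 20000L else 2000L
  if (is.null(replicates))
    replicates <- if (scale == "full") 100L else 25L
  if (n_cities %% 4 != 0) stop("n_cities must be divisible by 4")
  stopifnot(persons_per_city >= 1, replicates >= 1,
            years >= 1, error_bound > 0, all(sigmas > 0), all(hrs >= 1),
            all(thresholds >= 0))
  structure(list(thresholds = thresholds, hrs = hrs, sigmas = sigmas,
                 replicates = as.integer(replicates),
                 n_cities = as.integer(n_cities),
                 persons_per_city = as.integer(persons_per_city),
                 years = as.integer(years), start_age = start_age,
                 first_year = first_year, error_bound = error_bound,
                 jitter = jitter, seed = as.integer(seed), scale = scale,
                 share_cohort_across_sigma = share_cohort_across_sigma,
                 fit_splines = fit_splines),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Experiment config (", x$scale, " scale): ", sep = "")
  cat(length(x$thresholds) * length(x$hrs) * length(x$sigmas),
      "scenario combinations,", x$replicates, "replicates each\n")
  cat("  cohort:", x$n_cities, "cities x", x$persons_per_city, "persons x",
      x$years, "years; master seed", x$seed, "\n")
  invisible(x)
}

# degenerate-hinge stub: the model collapses to the null, LL at beta = 0
null_collapsed_fit <- function(outcome, covariate, ties) {
  structure(list(beta = NA_real_, se = NA_real_, hr = NA_real_,
                 ci = c(NA_real_, NA_real_),
                 loglik = cox_partial_loglik(0, outcome, covariate, ties),
                 converged = TRUE, iter = 0L,
                 n_deaths = total_deaths(outcome),
                 n_individuals = total_individuals(outcome), ties = ties),
            class = "cox_fit")
}

fit_or_collapse <- function(outcome, covariate, ties = "breslow") {
  if (length(unique(covariate)) < 2L)
    null_collapsed_fit(outcome, covariate, ties)
  else cox_fit(outcome, covariate, ties = ties)
}

#' Run one scenario of the measurement-error experiment
#'
#' Simulates one cohort under the scenario's true concentration-response,
#' then, for each measurement-error replicate: forms observed exposures,
#' fits the no-threshold and true-threshold Cox models and compares them
#' ([compare_threshold_models()]), grid-searches the best-fitting threshold
#' ([scan_thresholds()]), checks hazard-ratio coverage of the best fit
#' ([hr_coverage_check()]), and optionally fits the relative-risk spline.
#'
#' @param scenario a [cr_scenario()].
#' @param cities `city_exposure` data.frame of true exposures.
#' @param schedule `mortality_schedule` of baseline probabilities.
#' @param errors an `exposure_errors` object whose sigma matches the
#'   scenario.
#' @param config an [experiment_config()].
#' @return A list with `scenario`, `replicates` (a per-replicate
#'   data.frame), `detect` (counts per criterion), `best_freq` (named
#'   vector over scan candidates), `coverage_failures`, `n_deaths`,
#'   `splines` (list of `rr_spline` or NULL) and `convergence_failures`.
#' @export
run_scenario <- function(scenario, cities, schedule, errors, config) {
  stopifnot(inherits(errors, "exposure_errors"))
  if (!isTRUE(all.equal(errors$sigma, scenario$sigma)))
    stop("error sets were drawn for sigma ", errors$sigma,
         ", scenario has sigma ", scenario$sigma)
  R <- config$replicates
  if (nrow(errors$errors) < R)
    stop("error sets hold ", nrow(errors$errors), " replicates; config asks ",
         R)
  cohort_name <- if (config$share_cohort_across_sigma)
    paste0("cohort:", scenario$threshold, ",", scenario$hr)
  else paste0("cohort:", scenario_label(scenario))
  outcome <- simulate_cohort(cities, schedule, scenario,
                             config$persons_per_city,
                             seed = child_seed(config$seed, cohort_name))
  candidates <- seq(scenario$threshold - 4, scenario$threshold + 4, by = 1)
  reps <- data.frame(replicate = seq_len(R), stat = NA_real_,
                     detect_aic = NA, detect_bic_deaths = NA,
                     detect_bic_individuals = NA, thr_hr = NA_real_,
                     best_threshold = NA_real_,
                     best_beta = NA_real_, best_hr = NA_real_,
                     best_ci_low = NA_real_, best_ci_high = NA_real_,
                     coverage_fail = NA_integer_, converged = NA)
  splines <- if (config$fit_splines) vector("list", R) else NULL
  for (r in seq_len(R)) {
    obs <- observe(cities$true_pm, errors$errors[r, ])
    fit_null <- fit_or_collapse(outcome, obs)
    fit_thr <- fit_or_collapse(outcome, effective_pm(obs, scenario$threshold))
    cmp <- compare_threshold_models(fit_thr, fit_null)
    scan <- scan_thresholds(outcome, obs, scenario$threshold)
    best <- scan$best_fit
    reps$stat[r] <- cmp$stat
    reps$detect_aic[r] <- cmp$preferred[["aic"]]
    reps$detect_bic_deaths[r] <- cmp$preferred[["bic_deaths"]]
    reps$detect_bic_individuals[r] <- cmp$preferred[["bic_individuals"]]
    reps$thr_hr[r] <- fit_thr$hr
    reps$best_threshold[r] <- scan$best
    if (!is.null(best)) {
      reps$best_beta[r] <- best$beta
      reps$best_hr[r] <- best$hr
      reps$best_ci_low[r] <- best$ci[1]
      reps$best_ci_high[r] <- best$ci[2]
      reps$coverage_fail[r] <- hr_coverage_check(best, scenario$hr)
      reps$converged[r] <- fit_null$converged && fit_thr$converged &&
        best$converged
    } else {
      reps$converged[r] <- fit_null$converged && fit_thr$converged
    }
    if (config$fit_splines)
      splines[[r]] <- fit_spline(city_relative_risk(outcome, obs))
  }
  best_freq <- table(factor(reps$best_threshold, levels = candidates))
  list(scenario = scenario,
       replicates = reps,
       detect = c(aic = sum(reps$detect_aic),
                  bic_deaths = sum(reps$detect_bic_deaths),
                  bic_individuals = sum(reps$detect_bic_individuals)),
       best_freq = best_freq,
       coverage_failures = sum(reps$coverage_fail, na.rm = TRUE),
       n_deaths = total_deaths(outcome),
       splines = splines,
       convergence_failures = sum(!reps$converged))
}

#' Run the full factorial experiment
#'
#' Generates true exposures once (stream `"exposure"`), draws one set of
#' error replicates per sigma (streams `"errors:<sigma>"`) reused by every
#' scenario with that sigma - the common-random-numbers structure that
#' makes detection differences across scenarios attributable to the
#' scenario, not the error draws - and runs [run_scenario()] for every
#' (threshold, hazard ratio, sigma) combination.
#'
#' @param config an [experiment_config()].
#' @param schedule optional `mortality_schedule`; defaults to the packaged
#'   life table interpolated at birth year `first_year - start_age`.
#' @param cities optional `city_exposure` set; defaults to a fresh
#'   stratified sample from the packaged base pool.
#' @param progress if TRUE, print one line per scenario.
#' @return An object of class `experiment_result`: list with `config`,
#'   `cities`, `scenarios` (named list of [run_scenario()] blocks, names
#'   `"T,h,sigma"`).
#' @examples
#' \donttest{
#' cfg <- experiment_config(scale = "desk", seed = 1,
#'                          thresholds = 8.5, hrs = c(1.02, 1.05))
#' res <- run_grid(cfg)
#' build_tables(res)$detection
#' }
#' @export
run_grid <- function(config, schedule = NULL, cities = NULL,
                     progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(schedule)) {
    lt <- default_life_table()
    schedule <- interpolate_schedule(lt, config$first_year - config$start_age,
                                     config$start_age, config$years)
  }
  if (is.null(cities))
    cities <- generate_true_exposures(config$n_cities, jitter = config$jitter,
                                      seed = child_seed(config$seed,
                                                        "exposure"))
  error_sets <- lapply(config$sigmas, function(s)
    draw_error_sets(config$n_cities, s, config$replicates,
                    bound = config$error_bound,
                    seed = child_seed(config$seed, paste0("errors:", s))))
  names(error_sets) <- as.character(config$sigmas)
  grid <- expand.grid(threshold = config$thresholds, hr = config$hrs,
                      sigma = config$sigmas, KEEP.OUT.ATTRS = FALSE)
  scenarios <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sc <- cr_scenario(grid$threshold[i], grid$hr[i], grid$sigma[i])
    if (progress)
      cat(sprintf("[%2d/%2d] T=%g h=%g sigma=%g ...\n", i, nrow(grid),
                  sc$threshold, sc$hr, sc$sigma))
    scenarios[[i]] <- run_scenario(sc, cities, schedule,
                                   error_sets[[as.character(sc$sigma)]],
                                   config)
    names(scenarios)[i] <- scenario_label(sc)
    if (progress)
      cat(sprintf("        detect(BICn)=%d/%d best@true=%d conv.fail=%d\n",
                  scenarios[[i]]$detect[["bic_individuals"]],
                  config$replicates,
                  scenarios[[i]]$best_freq[[as.character(sc$threshold)]],
                  scenarios[[i]]$convergence_failures))
  }
  structure(list(config = config, cities = cities, scenarios = scenarios),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment result:", length(x$scenarios), "scenarios x",
      x$config$replicates, "replicates\n")
  invisible(x)
}

#' Summary tables of an experiment
#'
#' Collapses an [run_grid()] result into the study's reporting tables:
#' detection counts per criterion (threshold model preferred over the
#' no-threshold model), best-fitting-threshold frequency matrices (one row
#' per hazard ratio x sigma, columns over the scan grid; each row sums to
#' the replicate count), hazard-ratio coverage-failure counts, and the
#' per-replicate best-fit hazard-ratio estimates (tick-plot data).
#'
#' @param result an `experiment_result`.
#' @return A list with `detection` (long data.frame: threshold, hr, sigma,
#'   detect_aic, detect_bic_deaths, detect_bic_individuals, n_deaths),
#'   `best_freq` (named list per true threshold of wide data.frames),
#'   `coverage` (long data.frame of coverage-failure counts) and
#'   `hr_estimates` (long per-replicate data.frame).
#' @export
build_tables <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  blocks <- result$scenarios
  meta <- do.call(rbind, lapply(blocks, function(b)
    data.frame(threshold = b$scenario$threshold, hr = b$scenario$hr,
               sigma = b$scenario$sigma)))
  detection <- cbind(meta, do.call(rbind, lapply(blocks, function(b)
    data.frame(detect_aic = b$detect[["aic"]],
               detect_bic_deaths = b$detect[["bic_deaths"]],
               detect_bic_individuals = b$detect[["bic_individuals"]],
               n_deaths = b$n_deaths))))
  rownames(detection) <- NULL
  best_freq <- lapply(split(seq_along(blocks), meta$threshold), function(ix) {
    wide <- do.call(rbind, lapply(ix, function(i)
      as.integer(blocks[[i]]$best_freq)))
    colnames(wide) <- names(blocks[[ix[1]]]$best_freq)
    cbind(meta[ix, c("hr", "sigma")], as.data.frame(wide), row.names = NULL)
  })
  coverage <- cbind(meta, coverage_failures = vapply(
    blocks, function(b) b$coverage_failures, numeric(1)))
  rownames(coverage) <- NULL
  hr_estimates <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    r <- blocks[[i]]$replicates
    data.frame(threshold = meta$threshold[i], hr = meta$hr[i],
               sigma = meta$sigma[i], replicate = r$replicate,
               best_threshold = r$best_threshold, best_hr = r$best_hr,
               best_ci_low = r$best_ci_low, best_ci_high = r$best_ci_high,
               stat = r$stat)
  }))
  list(detection = detection, best_freq = best_freq, coverage = coverage,
       hr_estimates = hr_estimates)
}

#' Write experiment tables to CSV
#'
#' @param result an `experiment_result`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tb <- build_tables(result)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(tb$detection, "detection_counts.csv")
  for (tt in names(tb$best_freq))
    wr(tb$best_freq[[tt]], paste0("best_threshold_freq_T", tt, ".csv"))
  wr(tb$coverage, "coverage_failures.csv")
  wr(tb$hr_estimates, "hr_estimates.csv")
  cfg <- result$config
  manifest <- list(package = "crthresh",
                   version = as.character(utils::packageVersion("crthresh")),
                   config = unclass(cfg))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    p <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
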