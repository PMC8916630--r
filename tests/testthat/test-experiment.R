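small_cfg <- function(...) {
  defaults <- list(thresholds = 8.5, hrs = c(1.02, 1.05), sigmas = 1,
                   n_cities = 40, persons_per_city = 400, years = 10,
                   replicates = 3, seed = 5)
  over <- list(...)
  do.call(experiment_config, modifyList(defaults, over))
}

small_inputs <- function(cfg) {
  list(cities = generate_true_exposures(cfg$n_cities,
                                        seed = child_seed(cfg$seed, "exposure")),
       schedule = gompertz_schedule(n_years = cfg$years),
       errors = draw_error_sets(cfg$n_cities, 1, cfg$replicates,
                                seed = child_seed(cfg$seed, "errors:1")))
}

test_that("the default configuration spans the full factorial study grid", {
  cfg <- experiment_config(seed = 1)
  expect_equal(length(cfg$thresholds) * length(cfg$hrs) * length(cfg$sigmas),
               45)
  expect_equal(length(cfg$thresholds) * length(cfg$hrs), 15)
  expect_equal(cfg$n_cities * cfg$persons_per_city, 2e6)
  expect_equal(cfg$replicates, 100L)
  desk <- experiment_config(scale = "desk", seed = 1)
  expect_equal(desk$persons_per_city, 2000L)
  expect_equal(desk$replicates, 25L)
  expect_error(experiment_config(n_cities = 30), "divisible by 4")
})

test_that("one scenario yields one row per replicate with coherent aggregates", {
  cfg <- small_cfg()
  inp <- small_inputs(cfg)
  block <- run_scenario(cr_scenario(8.5, 1.05, 1), inp$cities, inp$schedule,
                        inp$errors, cfg)
  expect_equal(nrow(block$replicates), 3)
  expect_equal(sum(block$best_freq), 3)
  expect_equal(names(block$best_freq),
               as.character(seq(4.5, 12.5, by = 1)))
  expect_true(all(block$detect <= 3))
  expect_equal(unname(block$detect["aic"]), sum(block$replicates$detect_aic))
  expect_true(block$coverage_failures <= 3)

  one <- small_cfg(replicates = 1)
  errs1 <- draw_error_sets(one$n_cities, 1, 1,
                           seed = child_seed(one$seed, "errors:1"))
  b1 <- run_scenario(cr_scenario(8.5, 1.05, 1), inp$cities, inp$schedule,
                     errs1, one)
  expect_equal(nrow(b1$replicates), 1)

  # sigma mismatch between scenario and error sets is an integrity error
  expect_error(run_scenario(cr_scenario(8.5, 1.05, 2), inp$cities,
                            inp$schedule, inp$errors, cfg), "sigma")
})

test_that("identical configuration and seed reproduce the experiment exactly", {
  cfg <- small_cfg()
  r1 <- run_grid(cfg)
  r2 <- run_grid(cfg)
  expect_identical(build_tables(r1), build_tables(r2))
  expect_identical(r1$cities, r2$cities)
})

test_that("summary tables have the study schema and row sums equal the replicate count", {
  cfg <- small_cfg()
  res <- run_grid(cfg)
  tb <- build_tables(res)
  expect_named(tb, c("detection", "best_freq", "coverage", "hr_estimates"))
  expect_equal(nrow(tb$detection), 2)
  expect_named(tb$detection, c("threshold", "hr", "sigma", "detect_aic",
                               "detect_bic_deaths", "detect_bic_individuals",
                               "n_deaths"))
  freq <- tb$best_freq[["8.5"]]
  cand_cols <- setdiff(names(freq), c("hr", "sigma"))
  expect_equal(unname(rowSums(freq[cand_cols])),
               rep(cfg$replicates, nrow(freq)))
  expect_equal(nrow(tb$hr_estimates), 2 * cfg$replicates)
  expect_true(all(tb$coverage$coverage_failures <= cfg$replicates))
})

test_that("desk and full presets emit the same file schema", {
  cfg <- small_cfg()
  res <- run_grid(cfg)
  dir <- tempfile("tables")
  paths <- write_tables(res, dir)
  expect_true(all(file.exists(file.path(dir, c("detection_counts.csv",
                                               "best_threshold_freq_T8.5.csv",
                                               "coverage_failures.csv",
                                               "hr_estimates.csv")))))
  got <- read.csv(file.path(dir, "detection_counts.csv"))
  expect_named(got, names(build_tables(res)$detection))
})

test_that("seed streams are stable: adding a sigma never perturbs existing scenarios", {
  cfg1 <- small_cfg()
  cfg2 <- small_cfg(sigmas = c(1, 2))
  t1 <- build_tables(run_grid(cfg1))$detection
  t2 <- build_tables(run_grid(cfg2))$detection
  shared <- t2[t2$sigma == 1, ]
  rownames(shared) <- NULL
  expect_identical(t1, shared)
})

test_that("sharing the cohort across sigmas reuses one realisation per C-R", {
  cfg <- experiment_config(thresholds = 8.5, hrs = 1.05, sigmas = c(1, 2),
                           n_cities = 40, persons_per_city = 400, years = 10,
                           replicates = 2, seed = 5,
                           share_cohort_across_sigma = TRUE)
  tb <- build_tables(run_grid(cfg))$detection
  expect_equal(tb$n_deaths[1], tb$n_deaths[2])
  cfg$share_cohort_across_sigma <- FALSE
  tb2 <- build_tables(run_grid(cfg))$detection
  expect_false(tb2$n_deaths[1] == tb2$n_deaths[2])
})

test_that("spline diagnostics are attached per replicate when requested", {
  cfg <- small_cfg(fit_splines = TRUE)
  inp <- small_inputs(cfg)
  block <- run_scenario(cr_scenario(8.5, 1.05, 1), inp$cities, inp$schedule,
                        inp$errors, cfg)
  expect_length(block$splines, 3)
  expect_s3_class(block$splines[[1]], "rr_spline")
})
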