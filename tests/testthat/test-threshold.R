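fake_fit <- function(ll, deaths = 500, n = 1e4, converged = TRUE) {
  structure(list(loglik = ll, converged = converged, n_deaths = deaths,
                 n_individuals = n, ci = c(NA, NA)),
            class = "cox_fit")
}

test_that("model comparison applies the AIC and BIC penalties for one parameter", {
  cmp <- compare_threshold_models(fake_fit(-100), fake_fit(-107.5),
                                  n_deaths = 1000, n_individuals = 2e6)
  expect_equal(cmp$stat, 15)
  expect_equal(unname(cmp$penalty["aic"]), 2)
  expect_equal(unname(cmp$penalty["bic_deaths"]), log(1000))
  expect_equal(unname(cmp$penalty["bic_individuals"]), log(2e6))
  expect_equal(unname(cmp$penalty["bic_individuals"]), 14.5087, tolerance = 1e-4)
  expect_true(all(cmp$preferred))      # 15 beats all three penalties
  expect_true(cmp$detected)

  tie <- compare_threshold_models(fake_fit(-100), fake_fit(-100))
  expect_equal(tie$stat, 0)
  expect_false(any(tie$preferred))     # identical LL: null preferred everywhere

  # statistic depends on the LL difference only
  shifted <- compare_threshold_models(fake_fit(-100 + 321), fake_fit(-107.5 + 321),
                                      n_deaths = 1000, n_individuals = 2e6)
  expect_equal(shifted$stat, cmp$stat)

  # decision monotonicity when ln(n_ind) >= ln(n_deaths) >= 2
  mid <- compare_threshold_models(fake_fit(-100), fake_fit(-104),
                                  n_deaths = 1000, n_individuals = 2e6)
  expect_true(mid$preferred[["aic"]])
  expect_true(mid$preferred[["bic_deaths"]])
  expect_false(mid$preferred[["bic_individuals"]])

  expect_error(compare_threshold_models(fake_fit(-1, deaths = 10),
                                        fake_fit(-2, deaths = 20)),
               "different data")
  expect_warning(compare_threshold_models(fake_fit(-1, converged = FALSE),
                                          fake_fit(-2)), "converge")
})

test_that("coverage failure is a one-sided upper-limit check", {
  ci_fit <- function(lo, hi) structure(list(ci = c(lo, hi), converged = TRUE),
                                       class = "cox_fit")
  expect_equal(hr_coverage_check(ci_fit(1.010, 1.030), 1.05), 1L)
  expect_equal(hr_coverage_check(ci_fit(1.010, 1.060), 1.05), 0L)
  expect_equal(hr_coverage_check(ci_fit(1.010, 1.050), 1.05), 0L) # strict
  expect_equal(hr_coverage_check(ci_fit(1.010, 1.030), 1.0), 0L)  # one-sided
})

test_that("the scan covers true threshold +/- 4 and breaks ties toward the smaller candidate", {
  cities <- generate_true_exposures(40, city_base_pool(), seed = 31)
  sched <- gompertz_schedule(n_years = 10)
  out <- simulate_cohort(cities, sched, cr_scenario(8.5, 1.08, 0), 2000,
                         seed = 32)
  sc <- scan_thresholds(out, cities$true_pm, 8.5)
  expect_equal(sc$table$candidate, seq(4.5, 12.5, by = 1))
  expect_equal(sc$best, sc$table$candidate[which.max(sc$table$loglik)])
  expect_equal(sc$best_fit$loglik, max(sc$table$loglik))
  # error-free scan at a strong hazard ratio finds the true threshold
  expect_equal(sc$best, 8.5)
})

test_that("degenerate candidates fall back to the null log-likelihood exactly", {
  cities <- generate_true_exposures(20, city_base_pool(), seed = 41)
  sched <- gompertz_schedule(n_years = 5)
  out <- simulate_cohort(cities, sched, cr_scenario(0, 1, 1), 1000, seed = 42)
  big_T <- max(cities$true_pm) + 5
  sc <- scan_thresholds(out, cities$true_pm, big_T, halfwidth = 2, step = 1)
  degenerate <- sc$table$candidate > max(cities$true_pm)
  expect_true(any(degenerate))
  ll0 <- cox_partial_loglik(0, out, rep(0, 20))
  expect_equal(sc$table$loglik[degenerate],
               rep(ll0, sum(degenerate)))
})

test_that("a no-effect cohort leads the comparison to prefer the null model", {
  cities <- generate_true_exposures(100, seed = 51)
  lt <- default_life_table()
  sched <- interpolate_schedule(lt, 1940, 60, 20)
  out <- simulate_cohort(cities, sched, cr_scenario(0, 1, 1), 2000, seed = 52)
  errs <- draw_error_sets(100, 1, 5, seed = 53)
  prefer <- vapply(1:5, function(r) {
    obs <- observe(cities$true_pm, errs$errors[r, ])
    cmp <- compare_threshold_models(cox_fit(out, effective_pm(obs, 8.5)),
                                    cox_fit(out, obs))
    cmp$detected
  }, logical(1))
  expect_false(any(prefer))
})
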