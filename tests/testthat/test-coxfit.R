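test_that("partial log-likelihood matches hand expansions", {
  w <- worked_instance()
  x <- c(0, 1)
  # beta = 0: exponentials collapse to counts
  expect_equal(cox_partial_loglik(0, w, x), -3 * log(20))
  for (b in c(-1, 0.3, log(2), 2))
    expect_equal(cox_partial_loglik(b, w, x),
                 2 * b - 3 * log(10 + 10 * exp(b)))
  # multi-year instance against direct evaluation of the Breslow formula
  inst <- list(at_risk = rbind(c(20, 30), c(15, 25)),
               deaths = rbind(c(2, 3), c(1, 4)))
  x2 <- c(1.5, 4)
  b <- 0.2
  direct <- b * (2 * 1.5 + 3 * 4 + 1 * 1.5 + 4 * 4) -
    5 * log(20 * exp(1.5 * b) + 30 * exp(4 * b)) -
    5 * log(15 * exp(1.5 * b) + 25 * exp(4 * b))
  expect_equal(cox_partial_loglik(b, inst, x2), direct)
})

test_that("partial likelihood is location invariant and Efron reduces to Breslow without ties", {
  inst <- random_instance()
  for (b in c(-0.5, 0.1, 1)) {
    base <- cox_partial_loglik(b, inst$outcome, inst$x)
    expect_equal(cox_partial_loglik(b, inst$outcome, inst$x + 3.7), base)
    expect_equal(cox_partial_loglik(b, inst$outcome, inst$x - 12), base)
  }
  # one death per event time: the Efron correction vanishes
  single <- list(at_risk = rbind(c(10, 8), c(9, 8), c(9, 7)),
                 deaths = rbind(c(1, 0), c(0, 1), c(1, 0)))
  for (b in c(-0.3, 0.4))
    expect_equal(cox_partial_loglik(b, single, c(0, 2), ties = "efron"),
                 cox_partial_loglik(b, single, c(0, 2), ties = "breslow"))
})

test_that("the worked instance has the closed-form maximiser log 2", {
  fit <- cox_fit(worked_instance(), c(0, 1))
  expect_true(fit$converged)
  expect_equal(fit$beta, log(2), tolerance = 1e-8)
  expect_equal(fit$hr, 2, tolerance = 1e-7)
  expect_equal(fit$loglik, 2 * log(2) - 3 * log(30))
})

test_that("rescaling the covariate rescales the slope and leaves the optimum LL unchanged", {
  set.seed(21)
  inst <- random_instance()
  f1 <- cox_fit(inst$outcome, inst$x)
  f2 <- cox_fit(inst$outcome, inst$x * 2)
  expect_equal(f2$beta, f1$beta / 2, tolerance = 1e-7)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-9)
  f3 <- cox_fit(inst$outcome, inst$x + 5)
  expect_equal(f3$beta, f1$beta, tolerance = 1e-7)
  expect_equal(f3$loglik, f1$loglik, tolerance = 1e-9)
})

test_that("Newton maximiser agrees with brute-force maximisation on random instances", {
  set.seed(99)
  for (k in 1:25) {
    inst <- random_instance()
    fit <- cox_fit(inst$outcome, inst$x, tol = 1e-12)
    expect_true(fit$converged)
    brute <- optimize(function(b) cox_partial_loglik(b, inst$outcome, inst$x),
                      c(-6, 6), maximum = TRUE, tol = 1e-10)
    expect_lt(abs(fit$beta - brute$maximum), 1e-6)
    expect_gte(fit$loglik + 1e-10, brute$objective)
    # concavity safeguard: the optimum beats beta = 0 and nearby points
    expect_gte(fit$loglik,
               cox_partial_loglik(0, inst$outcome, inst$x) - 1e-10)
    expect_gte(fit$loglik + 1e-8,
               cox_partial_loglik(fit$beta + 0.01, inst$outcome, inst$x))
  }
})

test_that("fits agree with survival::coxph on disaggregated records", {
  skip_if_not_installed("survival")
  set.seed(314)
  for (k in 1:20) {
    inst <- random_instance()
    df <- disaggregate(inst$outcome, inst$x)
    for (ties in c("breslow", "efron")) {
      fit <- cox_fit(inst$outcome, inst$x, ties = ties, tol = 1e-12)
      ref <- suppressWarnings(
        survival::coxph(survival::Surv(time, status) ~ x, data = df,
                        ties = ties,
                        control = survival::coxph.control(eps = 1e-12,
                                                          iter.max = 50)))
      expect_lt(abs(fit$beta - unname(coef(ref))), 1e-4)
      expect_lt(abs(fit$se - sqrt(unname(vcov(ref)[1, 1]))), 1e-4)
      expect_lt(abs(fit$loglik - ref$loglik[2]), 1e-6)
    }
  }
})

test_that("degenerate inputs are rejected with clear errors", {
  w <- worked_instance()
  expect_error(cox_fit(w, c(1, 1)), "degenerate")
  no_deaths <- make_outcome(rbind(c(10, 10)), rbind(c(0, 0)))
  expect_error(cox_fit(no_deaths, c(0, 1)), "no deaths")
  expect_error(cox_fit(w, c(0, 1, 2)), "one value per city")
  empty_risk <- list(at_risk = rbind(c(5, 5), c(0, 0)),
                     deaths = rbind(c(5, 5), c(0, 1)))
  expect_error(cox_partial_loglik(0, empty_risk, c(0, 1)), "empty risk set")
})

test_that("methods expose coefficients, CI, and log-likelihood coherently", {
  fit <- cox_fit(worked_instance(), c(0, 1))
  expect_equal(unname(coef(fit)), fit$beta)
  expect_equal(unname(vcov(fit)[1, 1]), fit$se ^ 2)
  ci <- confint(fit)
  expect_equal(exp(ci[1, ]), fit$ci, ignore_attr = TRUE)
  expect_true(fit$ci[1] <= fit$hr && fit$hr <= fit$ci[2])
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_output(print(fit), "Cox PH fit")
  expect_output(print(summary(fit)), "partial logLik")
})

test_that("the true log hazard is recovered with nominal coverage under the generating model", {
  lt <- default_life_table()
  sched <- interpolate_schedule(lt, 1940, 60, 20)
  cities <- generate_true_exposures(100, seed = 8)
  hinge <- effective_pm(cities$true_pm, 8.5)
  covered <- vapply(1:30, function(s) {
    out <- simulate_cohort(cities, sched, cr_scenario(8.5, 1.05, 0), 20000,
                           seed = 1000 + s)
    fit <- cox_fit(out, hinge)
    ci <- log(fit$ci)
    ci[1] <= log(1.05) && log(1.05) <= ci[2]
  }, logical(1))
  expect_gte(sum(covered), 27) # >= 90 percent of replicate seeds
})
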