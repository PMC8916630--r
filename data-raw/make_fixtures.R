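# Build the plain-text fixtures shipped under inst/extdata/.
# Both are deterministic (no RNG) so re-running reproduces them byte-for-byte.
#
#  * life_table_synthetic.csv - males-only cohort life table, birth years
#    1930/1940/1950, ages 60-80. Annual q follows a Gompertz law doubling
#    every 8.3 years from q0 at age 60, with a mild secular improvement
#    across birth cohorts (x0.93 per decade); the 1940 cohort has exactly
#    q0 = 0.011, the gompertz_schedule() defaults.
#
#  * city_base_pool_synthetic.csv - 229 candidate city-mean PM2.5 values,
#    the quantile grid of a lognormal(meanlog 2.2135, sdlog 0.2606). The
#    parameters are the least-squares fit of a lognormal quantile function
#    through the percentile anchors (15%, 7), (40%, 8.5), (55%, 9.5) ug/m3,
#    so a quartile-stratified 100-city sample from the pool places the
#    thresholds 7 / 8.5 / 9.5 near the 15th / 40th / 55th percentiles.

out <- file.path("inst", "extdata")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ages <- 60:80
birth_years <- c(1930, 1940, 1950)
q0 <- 0.011 * 0.93 ^ ((birth_years - 1940) / 10)
lt <- expand.grid(age = ages, birth_year = birth_years)
lt$sex <- "M"
lt$q <- round(pmin(1, q0[match(lt$birth_year, birth_years)] *
                        2 ^ ((lt$age - 60) / 8.3)), 6)
lt <- lt[order(lt$birth_year, lt$age), c("birth_year", "sex", "age", "q")]
write.csv(lt, file.path(out, "life_table_synthetic.csv"), row.names = FALSE,
          quote = FALSE)

# lognormal anchor fit: regress log(anchor) on qnorm(percentile)
p <- c(0.15, 0.40, 0.55)
x <- c(7, 8.5, 9.5)
fit <- lm(log(x) ~ qnorm(p))
meanlog <- round(unname(coef(fit)[1]), 4)
sdlog <- round(unname(coef(fit)[2]), 4)
pool <- data.frame(candidate = 1:229,
                   true_pm = round(qlnorm((1:229) / 230, meanlog, sdlog), 4))
write.csv(pool, file.path(out, "city_base_pool_synthetic.csv"),
          row.names = FALSE, quote = FALSE)
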