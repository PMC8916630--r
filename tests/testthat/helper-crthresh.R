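# shared fixture builders (everything built in code; no binary files)

# minimal aggregated outcome from explicit count matrices
make_outcome <- function(at_risk, deaths, persons = at_risk[1, ]) {
  structure(list(at_risk = at_risk, deaths = deaths,
                 persons_per_city = persons[1],
                 n_years = nrow(at_risk), seed = NA),
            class = "cohort_outcome")
}

# the hand-expanded single-event-time instance:
# two cities, x = (0, 1), n = (10, 10), d = (1, 2)
# LL(beta) = 2 beta - 3 log(10 + 10 e^beta), maximised at beta = log 2
worked_instance <- function() {
  make_outcome(at_risk = matrix(c(10, 10), nrow = 1),
               deaths = matrix(c(1, 2), nrow = 1))
}

# random small aggregated instance with guaranteed non-degenerate covariate
random_instance <- function(max_cities = 5, max_years = 3) {
  J <- sample(2:max_cities, 1)
  Tn <- sample(1:max_years, 1)
  n0 <- sample(5:30, J, replace = TRUE)
  at_risk <- deaths <- matrix(0L, Tn, J)
  alive <- n0
  for (t in seq_len(Tn)) {
    at_risk[t, ] <- alive
    d <- rbinom(J, alive, 0.25)
    deaths[t, ] <- d
    alive <- alive - d
  }
  if (sum(deaths) == 0) deaths[1, 1] <- 1L
  x <- round(runif(J, 0, 10), 2)
  if (length(unique(x)) < 2) x[1] <- x[1] + 1
  list(outcome = make_outcome(at_risk, deaths), x = x)
}

# disaggregate an outcome into per-individual (time, status) records for
# survival::coxph; survivors of the last year are censored there
disaggregate <- function(outcome, x) {
  J <- ncol(outcome$deaths)
  Tn <- outcome$n_years
  rows <- list()
  for (j in seq_len(J)) {
    for (t in seq_len(Tn)) {
      d <- outcome$deaths[t, j]
      if (d > 0) rows[[length(rows) + 1L]] <-
          data.frame(time = t, status = 1, x = x[j], n = d)
    }
    surv <- outcome$at_risk[Tn, j] - outcome$deaths[Tn, j]
    if (surv > 0) rows[[length(rows) + 1L]] <-
        data.frame(time = Tn, status = 0, x = x[j], n = surv)
  }
  df <- do.call(rbind, rows)
  df[rep(seq_len(nrow(df)), df$n), c("time", "status", "x")]
}

# write a valid life-table CSV and return its path
write_life_table_csv <- function(dir = tempdir(), q_fun = NULL) {
  path <- tempfile("lt", tmpdir = dir, fileext = ".csv")
  grid <- expand.grid(age = 60:80, birth_year = c(1930, 1940, 1950))
  grid$sex <- "M"
  if (is.null(q_fun))
    q_fun <- function(by, age) 0.01 * (1 + (by - 1930) / 100) *
      2 ^ ((age - 60) / 8)
  grid$q <- q_fun(grid$birth_year, grid$age)
  write.csv(grid[, c("birth_year", "sex", "age", "q")], path,
            row.names = FALSE)
  path
}
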