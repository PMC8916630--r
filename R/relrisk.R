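#' City crude death rates and relative risks
#'
#' Computes, per city, the crude death rate over follow-up (total deaths
#' divided by total person-years, with individuals contributing a full
#' person-year in their death year, consistent with the simulator's annual
#' resolution) and the relative risk against the city with the lowest
#' *observed* PM2.5. Because the reference is chosen on observed exposure,
#' it can change from one measurement-error replicate to the next.
#'
#' @param outcome a `cohort_outcome`.
#' @param observed_pm numeric vector of observed city-mean PM2.5, ug/m3.
#' @return A data.frame of class `rr_table` with columns `city`,
#'   `observed_pm`, `rate` (deaths per person-year) and `rr` (reference
#'   city = 1); attribute `reference` holds the reference city index.
#' @examples
#' cities <- generate_true_exposures(100, seed = 1)
#' out <- simulate_cohort(cities, gompertz_schedule(),
#'                        cr_scenario(8.5, 1.05, 1), 2000, seed = 2)
#' rr <- city_relative_risk(out, cities$true_pm)
#' head(rr)
#' @export
city_relative_risk <- function(outcome, observed_pm) {
  J <- ncol(outcome$deaths)
  if (length(observed_pm) != J)
    stop("observed_pm must have one value per city")
  d <- colSums(outcome$deaths)
  py <- colSums(outcome$at_risk)
  rate <- d / py
  ref <- which.min(observed_pm)
  if (rate[ref] <= 0)
    stop("reference city (lowest observed PM) has no deaths; ",
         "relative risks undefined")
  structure(data.frame(city = seq_len(J), observed_pm = observed_pm,
                       rate = rate, rr = rate / rate[ref]),
            class = c("rr_table", "data.frame"), reference = ref)
}

#' Natural cubic spline fit to city relative risks
#'
#' Least-squares fit of relative risk on a natural cubic spline basis of
#' observed PM2.5 with `df` basis columns plus intercept. Interior knots sit
#' at the 25th/50th/75th percentiles of the observed exposures and boundary
#' knots at the observed extremes, so the curve is linear beyond the data
#' range (the defining natural-spline constraint).
#'
#' @param rr an `rr_table` from [city_relative_risk()].
#' @param df spline degrees of freedom (basis columns); default 4.
#' @param grid_n number of points of the uniform exposure grid on which the
#'   fitted curve is returned.
#' @return An object of class `rr_spline`: list with `knots`,
#'   `boundary_knots`, `coefficients` (intercept + df basis coefficients),
#'   `grid` (PM2.5 values) and `fitted` (fitted relative risk on the grid).
#' @examples
#' cities <- generate_true_exposures(100, seed = 1)
#' out <- simulate_cohort(cities, gompertz_schedule(),
#'                        cr_scenario(8.5, 1.05, 1), 2000, seed = 2)
#' sp <- fit_spline(city_relative_risk(out, cities$true_pm))
#' plot(sp)
#' @export
fit_spline <- function(rr, df = 4, grid_n = 100) {
  stopifnot(inherits(rr, "rr_table"), df >= 2)
  x <- rr$observed_pm
  if (length(unique(x)) < df + 1)
    stop("need at least df + 1 distinct exposure values")
  bknots <- range(x)
  probs <- seq_len(df - 1) / df # df - 1 interior knots -> df basis columns
  knots <- stats::quantile(x, probs, names = FALSE)
  basis <- splines::ns(x, knots = knots, Boundary.knots = bknots)
  if (ncol(basis) != df) stop("spline basis has wrong dimension")
  X <- cbind(1, basis)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient spline basis; exposures too clustered")
  fit <- stats::lm.fit(X, rr$rr)
  grid <- seq(bknots[1], bknots[2], length.out = grid_n)
  gb <- cbind(1, splines::ns(grid, knots = knots, Boundary.knots = bknots))
  structure(list(knots = knots, boundary_knots = bknots,
                 coefficients = fit$coefficients, df = df, grid = grid,
                 fitted = as.vector(gb %*% fit$coefficients)),
            class = "rr_spline")
}

#' Evaluate a fitted relative-risk spline
#'
#' @param object an `rr_spline`.
#' @param newdata PM2.5 values at which to evaluate (extrapolation beyond
#'   the boundary knots is linear).
#' @param ... unused.
#' @return Fitted relative risks.
#' @export
predict.rr_spline <- function(object, newdata, ...) {
  b <- cbind(1, splines::ns(newdata, knots = object$knots,
                            Boundary.knots = object$boundary_knots))
  as.vector(b %*% object$coefficients)
}

#' @export
print.rr_spline <- function(x, ...) {
  cat("Natural cubic spline RR fit: df =", x$df, "\n")
  cat("  interior knots:", paste(format(x$knots, digits = 4), collapse = ", "),
      "ug/m3; boundary:", paste(format(x$boundary_knots, digits = 4),
                                collapse = " - "), "\n")
  invisible(x)
}

#' @export
plot.rr_spline <- function(x, ...,
                           xlab = expression(PM[2.5] ~ (mu * g / m^3)),
                           ylab = "Relative risk") {
  graphics::plot(x$grid, x$fitted, type = "l", xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
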