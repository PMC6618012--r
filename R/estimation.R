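# Parameter estimation with the forward reaction-diffusion model: the
# fluorescence calibration factor s (OLS), day respiration Rd and Vcmax
# (one-dimensional least squares through the solver), and held-out
# validation. Fits drive the model ci_driven with the measured Ci by
# default, which avoids compounding stomatal-model error.

# Forward AN predictions for a set of records at fixed parameters.
# Maintains a warm-start field per record across repeated calls (the cache
# environment is supplied by the optimizer loop).
predict_an_records <- function(records, ctx, vcmax, rd, tp, s_cal,
                               kmc = 26.7, kmo = 16.4, sco = 2.6,
                               scenario, control, limitation = "dynamic",
                               cache = NULL) {
  n <- nrow(records)
  an <- numeric(n)
  for (i in seq_len(n)) {
    j <- electron_transport(s_cal, records$Iinc[i], records$Phi2[i])
    kin <- kinetic_params(vcmax = vcmax, j = j, rd = rd, tp = tp,
                          s_cal = s_cal, kmc = kmc, kmo = kmo, sco = sco)
    bc <- boundary_condition("ci_driven", ci = records$Ci[i],
                             o = records$O[i])
    init <- if (!is.null(cache)) cache$fields[[i]] else NULL
    sol <- solve_steady_state(ctx, kin, boundary = bc, scenario = scenario,
                              limitation = limitation, control = control,
                              init = init)
    if (!is.null(cache)) cache$fields[[i]] <- sol$internals$c
    an[i] <- sol$an
  }
  an
}

new_mesodiff_fit <- function(parameter, estimate, se, rss, records, resid,
                             fitted, scenario, regime, subset, at_bound) {
  structure(
    list(parameter = parameter, estimate = estimate, se = se, rss = rss,
         n_obs = nrow(records), n_params = 1L, residuals = resid,
         fitted = fitted, records = records, scenario = scenario,
         regime = regime, subset = subset, at_bound = at_bound),
    class = "mesodiff_fit"
  )
}

#' @export
print.mesodiff_fit <- function(x, ...) {
  cat(sprintf("<mesodiff_fit> %s = %.4f (SE %.4f), scenario '%s', regime %s\n",
              x$parameter, x$estimate, x$se, x$scenario, x$regime))
  cat(sprintf("  RSS = %.5g on %d records (%s)%s\n", x$rss, x$n_obs,
              x$subset, if (x$at_bound) " [estimate at bound]" else ""))
  invisible(x)
}

#' @export
tidy.mesodiff_fit <- function(x, ...) {
  tibble::tibble(term = x$parameter, estimate = x$estimate,
                 std.error = x$se, scenario = x$scenario, regime = x$regime)
}

#' @export
glance.mesodiff_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, n_obs = x$n_obs, n_params = x$n_params,
    sigma = sqrt(x$rss / max(x$n_obs - x$n_params, 1)),
    AIC = aic_ls(x$rss, x$n_obs, x$n_params),
    at_bound = x$at_bound
  )
}

# Scalar bounded least squares; returns estimate, rss and a
# Gaussian-linearization SE (residual variance times inverse curvature of
# the half-RSS). Brent search (derivative-free) on each bracket between
# consecutive start values, so a shallow or locally flat objective cannot
# trap a gradient step; the best bracket wins.
scalar_lsq <- function(objective, bounds, starts, n_obs, h = 0.02) {
  starts <- sort(unique(pmin(pmax(starts, bounds[1]), bounds[2])))
  brackets <- cbind(c(bounds[1], starts), c(starts, bounds[2]))
  brackets <- brackets[brackets[, 2] - brackets[, 1] > 1e-10, , drop = FALSE]
  fits <- lapply(seq_len(nrow(brackets)), function(i) {
    stats::optimize(objective, interval = brackets[i, ],
                    tol = 1e-6 * diff(bounds))
  })
  best <- fits[[which.min(vapply(fits, function(f) f$objective, 0))]]
  est <- best$minimum
  rss <- best$objective
  # polish once on a shrunken bracket around the winner
  lo <- max(bounds[1], est - 0.05 * diff(bounds))
  hi <- min(bounds[2], est + 0.05 * diff(bounds))
  pol <- stats::optimize(objective, interval = c(lo, hi),
                         tol = 1e-7 * diff(bounds))
  if (pol$objective < rss) {
    est <- pol$minimum
    rss <- pol$objective
  }
  at_bound <- min(est - bounds[1], bounds[2] - est) < 1e-4 * diff(bounds)
  x0 <- min(max(est, bounds[1] + h), bounds[2] - h)
  d2 <- (objective(x0 + h) - 2 * objective(x0) + objective(x0 - h)) / h^2
  sigma2 <- rss / max(n_obs - 1, 1)
  se <- if (is.finite(d2) && d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_
  list(estimate = est, rss = rss, se = se, at_bound = at_bound)
}

#' Calibrate the fluorescence-to-electron-transport factor s
#'
#' Ordinary least-squares slope of AN on `Iinc * Phi2 / 4` over the
#' low-irradiance records of a nonphotorespiratory light-response curve.
#' The slope is the calibration factor `s_cal` used in
#' `J = s_cal * Iinc * Phi2`; the negated intercept is the Yin-method Rd
#' estimate for the same data.
#'
#' @param data A gas-exchange tibble; rows are filtered to
#'   `curve_type == "AI"`, `regime == "NPR"` (when those columns are
#'   present) and `Iinc <= iinc_max`.
#' @param iinc_max Upper irradiance bound for the regression window
#'   (umol m-2 s-1).
#' @return An object of class `calibration_fit` with `s_cal`, `se`,
#'   `intercept`, `rd_yin` and the underlying `lm` fit.
#' @export
fit_calibration_s <- function(data, iinc_max = 150) {
  d <- data
  if ("curve_type" %in% names(d)) d <- d[d$curve_type == "AI", ]
  if ("regime" %in% names(d)) d <- d[d$regime == "NPR", ]
  d <- d[!is.na(d$Iinc) & d$Iinc <= iinc_max & !is.na(d$AN), ]
  if (!"Phi2" %in% names(d) || all(is.na(d$Phi2))) {
    stop("calibration requires Phi2 measurements", call. = FALSE)
  }
  d <- d[!is.na(d$Phi2), ]
  if (nrow(d) < 3) stop("need at least 3 records to calibrate s", call. = FALSE)
  x <- d$Iinc * d$Phi2 / 4
  if (stats::var(x) < 1e-12) {
    stop("zero variance in Iinc * Phi2 / 4; cannot calibrate s", call. = FALSE)
  }
  fit <- stats::lm(d$AN ~ x)
  cf <- summary(fit)$coefficients
  structure(
    list(s_cal = unname(cf[2, 1]), se = unname(cf[2, 2]),
         intercept = unname(cf[1, 1]), intercept_se = unname(cf[1, 2]),
         rd_yin = -unname(cf[1, 1]), n_obs = nrow(d),
         r_squared = summary(fit)$r.squared, lm = fit),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> s = %.4f (SE %.4f), intercept = %.3f, n = %d\n",
              x$s_cal, x$se, x$intercept, x$n_obs))
  invisible(x)
}

#' @export
tidy.calibration_fit <- function(x, ...) {
  tibble::tibble(term = c("s_cal", "intercept"),
                 estimate = c(x$s_cal, x$intercept),
                 std.error = c(x$se, x$intercept_se))
}

#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n_obs = x$n_obs)
}

# Common front-end for the 1D solver fits: filter, context, objective.
prepare_fit_records <- function(data, curve_type, regime, filter_expr) {
  d <- data
  if ("curve_type" %in% names(d)) d <- d[d$curve_type == curve_type, ]
  if ("regime" %in% names(d)) d <- d[d$regime == regime, ]
  d <- d[stats::complete.cases(d[, c("Iinc", "Ci", "O", "AN", "Phi2")]), ]
  d[filter_expr(d), ]
}

#' Estimate day respiration with the reaction-diffusion model
#'
#' One-dimensional least squares over Rd: for each low-irradiance record
#' (`Iinc <= iinc_max`), the forward model is driven `ci_driven` with the
#' measured Ci and the record's electron transport rate
#' `J = s_cal * Iinc * Phi2`, and Rd is chosen to minimize the sum of
#' squared residuals between measured and simulated AN. Fits are run per
#' release scenario and per O2 regime. The standard error comes from
#' Gaussian linearization (residual variance times the inverse curvature of
#' the objective).
#'
#' @param data A gas-exchange tibble (light-response records).
#' @param scenario Release scenario, `"inner"`, `"gaps"` or `"outer"`.
#' @param regime `"PR"` (O = 21 kPa) or `"NPR"` (O = 2 kPa).
#' @param vcmax,tp Fixed FvCB parameters during the Rd fit.
#' @param s_cal Calibration factor from [fit_calibration_s()].
#' @param anatomy,transport Model configuration.
#' @param control A [solver_control()]; `nx`, `ny` set the fitting mesh.
#' @param iinc_max Irradiance cutoff for usable records (umol m-2 s-1).
#' @param bounds Search interval for Rd (umol m-2 s-1).
#' @param starts Multistart initial values.
#' @param kmc,kmo,sco Rubisco constants.
#' @return A `mesodiff_fit` object (see [tidy.mesodiff_fit()]).
#' @export
fit_rd <- function(data, scenario, regime = c("PR", "NPR"),
                   vcmax = 120, tp = NULL, s_cal,
                   anatomy = fixture_anatomy("ho_default"),
                   transport = transport_params(),
                   control = solver_control(), iinc_max = 150,
                   bounds = c(0, 10), starts = c(0.5, 1.5, 3.0),
                   kmc = 26.7, kmo = 16.4, sco = 2.6) {
  regime <- match.arg(regime)
  d <- prepare_fit_records(data, "AI", regime,
                           function(x) x$Iinc <= iinc_max)
  if (nrow(d) < 3) {
    stop("fewer than 3 usable light-response records at Iinc <= ",
         iinc_max, call. = FALSE)
  }
  geom <- build_unit_cell(anatomy, scenario)
  ctx <- build_solver_context(generate_mesh(geom, c(control$nx, control$ny)),
                              transport)
  cache <- new.env(parent = emptyenv())
  cache$fields <- vector("list", nrow(d))
  objective <- function(rd) {
    pred <- predict_an_records(d, ctx, vcmax = vcmax, rd = rd, tp = tp,
                               s_cal = s_cal, kmc = kmc, kmo = kmo,
                               sco = sco, scenario = scenario,
                               control = control, cache = cache)
    sum((d$AN - pred)^2)
  }
  sol <- scalar_lsq(objective, bounds, starts, nrow(d))
  if (sol$at_bound) warning("Rd estimate is at the search bound")
  pred <- predict_an_records(d, ctx, vcmax = vcmax, rd = sol$estimate,
                             tp = tp, s_cal = s_cal, kmc = kmc, kmo = kmo,
                             sco = sco, scenario = scenario,
                             control = control, cache = cache)
  new_mesodiff_fit("rd", sol$estimate, sol$se, sol$rss, d, d$AN - pred,
                   pred, scenario, regime,
                   sprintf("AI curve, Iinc <= %g", iinc_max), sol$at_bound)
}

#' Estimate Vcmax with the reaction-diffusion model
#'
#' One-dimensional least squares over Vcmax on the low-CO2 part of the
#' photorespiratory CO2-response curve (`Ca < ca_max`, where carboxylation
#' is Rubisco-limited), with Rd fixed from [fit_rd()].
#'
#' @inheritParams fit_rd
#' @param rd Fixed day respiration (from [fit_rd()]).
#' @param ca_max Ambient CO2 cutoff (Pa).
#' @param bounds Search interval for Vcmax.
#' @param starts Multistart initial values.
#' @return A `mesodiff_fit` object.
#' @export
fit_vcmax <- function(data, scenario, rd, tp = NULL, s_cal,
                      anatomy = fixture_anatomy("ho_default"),
                      transport = transport_params(),
                      control = solver_control(), ca_max = 30,
                      bounds = c(5, 500), starts = c(60, 120, 240),
                      kmc = 26.7, kmo = 16.4, sco = 2.6) {
  d <- prepare_fit_records(data, "ACa", "PR", function(x) x$Ca < ca_max)
  if (nrow(d) < 3) {
    stop("fewer than 3 usable CO2-response records at Ca < ", ca_max,
         call. = FALSE)
  }
  geom <- build_unit_cell(anatomy, scenario)
  ctx <- build_solver_context(generate_mesh(geom, c(control$nx, control$ny)),
                              transport)
  cache <- new.env(parent = emptyenv())
  cache$fields <- vector("list", nrow(d))
  objective <- function(vcmax) {
    pred <- predict_an_records(d, ctx, vcmax = vcmax, rd = rd, tp = tp,
                               s_cal = s_cal, kmc = kmc, kmo = kmo,
                               sco = sco, scenario = scenario,
                               control = control, cache = cache)
    sum((d$AN - pred)^2)
  }
  sol <- scalar_lsq(objective, bounds, starts, nrow(d), h = 0.5)
  if (sol$at_bound) warning("Vcmax estimate is at the search bound")
  pred <- predict_an_records(d, ctx, vcmax = sol$estimate, rd = rd, tp = tp,
                             s_cal = s_cal, kmc = kmc, kmo = kmo, sco = sco,
                             scenario = scenario, control = control,
                             cache = cache)
  new_mesodiff_fit("vcmax", sol$estimate, sol$se, sol$rss, d, d$AN - pred,
                   pred, scenario, "PR",
                   sprintf("ACa curve, O = 21 kPa, Ca < %g Pa", ca_max),
                   sol$at_bound)
}

#' Validate fitted parameters on held-out records
#'
#' Predicts AN for records not used in any fit (driven ci_driven with the
#' measured Ci) and summarizes the prediction error.
#'
#' @param data Held-out gas-exchange records (any mix of curve types and
#'   regimes).
#' @param scenario Release scenario.
#' @param vcmax,tp,s_cal Fitted parameters.
#' @param rd_pr,rd_npr Fitted day respiration per regime; `rd_npr` defaults
#'   to `rd_pr`.
#' @param anatomy,transport,control Model configuration.
#' @param kmc,kmo,sco Rubisco constants.
#' @return A tibble with per-record `AN_pred`, `residual`, and attributes
#'   `rmse` and `bias` (also returned by [glance.mesodiff_validation()]),
#'   wrapped in class `mesodiff_validation`.
#' @export
validate_model <- function(data, scenario, vcmax, rd_pr, rd_npr = rd_pr,
                           tp = NULL, s_cal,
                           anatomy = fixture_anatomy("ho_default"),
                           transport = transport_params(),
                           control = solver_control(),
                           kmc = 26.7, kmo = 16.4, sco = 2.6) {
  d <- data[stats::complete.cases(data[, c("Iinc", "Ci", "O", "AN", "Phi2")]), ]
  if (nrow(d) == 0) stop("held-out set is empty", call. = FALSE)
  geom <- build_unit_cell(anatomy, scenario)
  ctx <- build_solver_context(generate_mesh(geom, c(control$nx, control$ny)),
                              transport)
  regime <- if ("regime" %in% names(d)) d$regime else
    ifelse(d$O > 10, "PR", "NPR")
  pred <- numeric(nrow(d))
  for (r in unique(regime)) {
    rows <- which(regime == r)
    rd <- if (r == "PR") rd_pr else rd_npr
    pred[rows] <- predict_an_records(d[rows, ], ctx, vcmax = vcmax, rd = rd,
                                     tp = tp, s_cal = s_cal, kmc = kmc,
                                     kmo = kmo, sco = sco,
                                     scenario = scenario, control = control)
  }
  out <- d
  out$AN_pred <- pred
  out$residual <- out$AN - pred
  out <- tibble::as_tibble(out)
  attr(out, "rmse") <- sqrt(mean(out$residual^2))
  attr(out, "bias") <- mean(out$residual)
  class(out) <- c("mesodiff_validation", class(out))
  out
}

#' @export
glance.mesodiff_validation <- function(x, ...) {
  tibble::tibble(rmse = attr(x, "rmse"), bias = attr(x, "bias"),
                 n_obs = nrow(x))
}
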