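# Comparator estimators of day respiration (Kok, Yin, Laisk), simulations
# of the Laisk measurement conditions with the reaction-diffusion model,
# gm/freass response sweeps, and AIC-based ranking of the release scenarios.

#' Kok-method estimate of day respiration
#'
#' OLS regression of AN on Iinc over a low-irradiance window (above the
#' Kok-effect breakpoint); Rd is the negated intercept. The method assumes
#' both Phi2 and Cc constant over the window, so it underestimates Rd when
#' Phi2 declines with irradiance.
#'
#' @param data A light-response gas-exchange tibble.
#' @param window Irradiance window `c(min, max)` (umol m-2 s-1).
#' @return A one-row tibble: `method`, `rd`, `se`, `slope`, `slope_se`,
#'   `n_obs`.
#' @export
kok_method <- function(data, window = c(50, 150)) {
  d <- data
  if ("curve_type" %in% names(d)) d <- d[d$curve_type == "AI", ]
  d <- d[!is.na(d$Iinc) & !is.na(d$AN) &
           d$Iinc >= window[1] & d$Iinc <= window[2], ]
  if (nrow(d) < 3) {
    stop("fewer than 3 records in the irradiance window [",
         window[1], ", ", window[2], "]", call. = FALSE)
  }
  fit <- stats::lm(AN ~ Iinc, data = d)
  cf <- summary(fit)$coefficients
  tibble::tibble(method = "kok", rd = -unname(cf[1, 1]),
                 se = unname(cf[1, 2]), slope = unname(cf[2, 1]),
                 slope_se = unname(cf[2, 2]), n_obs = nrow(d))
}

#' Yin-method estimate of day respiration
#'
#' OLS regression of AN on `Iinc * Phi2 / 4` over a low-irradiance window;
#' Rd is the negated intercept. Unlike the Kok method this accounts for the
#' decline of Phi2 with irradiance, but it still assumes Cc constant, so it
#' underestimates Rd under photorespiratory conditions where Cc falls with
#' irradiance and part of the (photo)respired CO2 is reassimilated.
#'
#' @inheritParams kok_method
#' @return A one-row tibble: `method`, `rd`, `se`, `slope` (the calibration
#'   factor s), `slope_se`, `n_obs`.
#' @export
yin_method <- function(data, window = c(50, 150)) {
  d <- data
  if ("curve_type" %in% names(d)) d <- d[d$curve_type == "AI", ]
  if (!"Phi2" %in% names(d) || all(is.na(d$Phi2))) {
    stop("the Yin method requires Phi2 measurements", call. = FALSE)
  }
  d <- d[!is.na(d$Iinc) & !is.na(d$AN) & !is.na(d$Phi2) &
           d$Iinc >= window[1] & d$Iinc <= window[2], ]
  if (nrow(d) < 3) {
    stop("fewer than 3 records in the irradiance window [",
         window[1], ", ", window[2], "]", call. = FALSE)
  }
  x <- d$Iinc * d$Phi2 / 4
  fit <- stats::lm(d$AN ~ x)
  cf <- summary(fit)$coefficients
  tibble::tibble(method = "yin", rd = -unname(cf[1, 1]),
                 se = unname(cf[1, 2]), slope = unname(cf[2, 1]),
                 slope_se = unname(cf[2, 2]), n_obs = nrow(d))
}

#' Laisk-method estimate of day respiration
#'
#' Fits a line to the low-Ci part of each AN-Ci curve (one curve per
#' irradiance), computes all pairwise line intersections for diagnostics,
#' and estimates the common intersection by least squares over the line
#' family `AN_j = a_j (Ci - Ci_star) + A_star` with shared `(Ci_star,
#' A_star)` and free slopes. Rd is `-A_star`; `Ci_star` is often read as
#' the apparent CO2 compensation point.
#'
#' @param data AN-Ci records for several irradiances; curves are identified
#'   by the `Iinc` column.
#' @param ci_max Low-Ci window (Pa): only records with `Ci <= ci_max` enter
#'   the line fits.
#' @return An object of class `laisk_fit`: per-curve `lines`, `pairwise`
#'   intersections, `ci_star`, `a_star`, `rd_laisk = -a_star`, standard
#'   errors, and the family RSS.
#' @export
laisk_method <- function(data, ci_max = 10) {
  d <- data[!is.na(data$Ci) & !is.na(data$AN) & data$Ci <= ci_max, ]
  counts <- table(d$Iinc)
  keep <- names(counts)[counts >= 3]
  d <- d[d$Iinc %in% as.numeric(keep), ]
  curves <- sort(unique(d$Iinc), decreasing = TRUE)
  if (length(curves) < 2) {
    stop("need at least 2 curves with >= 3 records at Ci <= ", ci_max,
         call. = FALSE)
  }
  lines <- purrr::map_dfr(curves, function(ii) {
    di <- d[d$Iinc == ii, ]
    fit <- stats::lm(AN ~ Ci, data = di)
    cf <- stats::coef(fit)
    tibble::tibble(Iinc = ii, intercept = unname(cf[1]),
                   slope = unname(cf[2]), n_obs = nrow(di))
  })
  if (max(lines$slope) - min(lines$slope) < 1e-6) {
    stop("AN-Ci lines are parallel; no intersection", call. = FALSE)
  }
  pairs <- utils::combn(seq_len(nrow(lines)), 2)
  pairwise <- dplyr::bind_rows(apply(pairs, 2, function(pp) {
    l1 <- lines[pp[1], ]; l2 <- lines[pp[2], ]
    ci_x <- (l2$intercept - l1$intercept) / (l1$slope - l2$slope)
    tibble::tibble(Iinc_1 = l1$Iinc, Iinc_2 = l2$Iinc, ci = ci_x,
                   an = l1$slope * ci_x + l1$intercept)
  }))
  # common intersection: profile out the slopes given (ci_star, a_star)
  rss_fun <- function(p) {
    ci_star <- p[1]; a_star <- p[2]
    sum(vapply(curves, function(ii) {
      di <- d[d$Iinc == ii, ]
      xx <- di$Ci - ci_star
      yy <- di$AN - a_star
      a_j <- sum(xx * yy) / sum(xx^2)
      sum((yy - a_j * xx)^2)
    }, 0))
  }
  init <- c(mean(pairwise$ci), mean(pairwise$an))
  opt <- stats::optim(init, rss_fun, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  n_tot <- nrow(d)
  n_par <- 2 + length(curves)
  sigma2 <- opt$value / max(n_tot - n_par, 1)
  h <- 1e-3
  hess <- matrix(0, 2, 2)
  e <- diag(2) * h
  for (a in 1:2) for (b in 1:2) {
    hess[a, b] <- (rss_fun(opt$par + e[a, ] + e[b, ]) -
                     rss_fun(opt$par + e[a, ] - e[b, ]) -
                     rss_fun(opt$par - e[a, ] + e[b, ]) +
                     rss_fun(opt$par - e[a, ] - e[b, ])) / (4 * h^2)
  }
  ses <- tryCatch(sqrt(diag(2 * sigma2 * solve(hess))),
                  error = function(e) c(NA_real_, NA_real_))
  structure(
    list(lines = lines, pairwise = pairwise,
         ci_star = opt$par[1], a_star = opt$par[2],
         rd_laisk = -opt$par[2], ci_star_se = ses[1], a_star_se = ses[2],
         rss = opt$value, n_obs = n_tot, ci_max = ci_max),
    class = "laisk_fit"
  )
}

#' @export
print.laisk_fit <- function(x, ...) {
  cat(sprintf("<laisk_fit> %d curves, Ci <= %g Pa\n", nrow(x$lines), x$ci_max))
  cat(sprintf("  common intersection: Ci* = %.3f Pa, A* = %.3f (Rd = %.3f)\n",
              x$ci_star, x$a_star, x$rd_laisk))
  cat(sprintf("  pairwise Ci spread %.4f Pa, family RSS %.4g\n",
              max(x$pairwise$ci) - min(x$pairwise$ci), x$rss))
  invisible(x)
}

#' @export
tidy.laisk_fit <- function(x, ...) {
  tibble::tibble(term = c("ci_star", "a_star", "rd_laisk"),
                 estimate = c(x$ci_star, x$a_star, x$rd_laisk),
                 std.error = c(x$ci_star_se, x$a_star_se, x$a_star_se))
}

#' @export
glance.laisk_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_obs = x$n_obs, n_curves = nrow(x$lines),
                 ci_spread = max(x$pairwise$ci) - min(x$pairwise$ci))
}

#' Simulate AN-Ci curve families under the Laisk measurement conditions
#'
#' Runs the reaction-diffusion model ci_driven, electron-transport limited
#' (as the Laisk method assumes), at a family of electron transport rates
#' corresponding to low irradiances, and applies [laisk_method()] to the
#' simulated curves. This reveals whether the curves share a common
#' intersection at `AN = -Rd` under each release scenario: they do for
#' release in the inner cytosol or the cytosol gaps but not for release in
#' the outer cytosol.
#'
#' @param scenario Release scenario.
#' @param rd Day respiration input (umol m-2 s-1).
#' @param j_values Electron transport rates (umol m-2 s-1); defaults to the
#'   rates at Iinc = 150, 100, 50, 25 umol m-2 s-1.
#' @param iinc_labels Irradiance labels matching `j_values`.
#' @param o O2 partial pressure (kPa).
#' @param ci_grid Ci grid (Pa) for the simulated curves; should lie in the
#'   low-Ci window.
#' @param vcmax,sco,kmc,kmo Kinetic constants (`vcmax` is inactive under
#'   the electron-transport limitation but required by the parameter set).
#' @param anatomy,transport,control Model configuration.
#' @return An object of class `laisk_sim`: the simulated `curves` tibble
#'   and the [laisk_method()] fit.
#' @export
simulate_laisk_family <- function(scenario, rd = 1.5,
                                  j_values = c(52.0, 36.3, 19.3, 9.1),
                                  iinc_labels = c(150, 100, 50, 25),
                                  o = 21, ci_grid = seq(0.8, 9.2, by = 1.2),
                                  vcmax = 1000, sco = 2.6, kmc = 26.7,
                                  kmo = 16.4,
                                  anatomy = fixture_anatomy("ho_default"),
                                  transport = transport_params(),
                                  control = solver_control()) {
  stopifnot(length(j_values) == length(iinc_labels))
  geom <- build_unit_cell(anatomy, scenario)
  ctx <- build_solver_context(generate_mesh(geom, c(control$nx, control$ny)),
                              transport)
  curves <- purrr::map_dfr(seq_along(j_values), function(m) {
    warm <- NULL
    purrr::map_dfr(ci_grid, function(ci) {
      kin <- kinetic_params(vcmax = vcmax, j = j_values[m], rd = rd,
                            kmc = kmc, kmo = kmo, sco = sco)
      bc <- boundary_condition("ci_driven", ci = ci, o = o)
      sol <- solve_steady_state(ctx, kin, boundary = bc, scenario = scenario,
                                limitation = "electron_transport",
                                control = control, init = warm)
      warm <<- sol$internals$c
      tibble::tibble(Iinc = iinc_labels[m], J = j_values[m], Ci = ci,
                     AN = sol$an, Cc = sol$cc)
    })
  })
  fit <- laisk_method(curves, ci_max = max(ci_grid) + 1e-9)
  structure(list(curves = curves, fit = fit, rd_input = rd,
                 gamma_star = gamma_star(o, sco), scenario = scenario),
            class = "laisk_sim")
}

#' @export
print.laisk_sim <- function(x, ...) {
  cat(sprintf("<laisk_sim> scenario '%s', Rd input %.3f, Gamma* %.3f Pa\n",
              x$scenario, x$rd_input, x$gamma_star))
  print(x$fit)
  invisible(x)
}

#' Sweep gm and freass over ambient CO2 or irradiance
#'
#' Runs the stomata-coupled forward model over a grid of ambient CO2
#' pressures (at saturating light) or irradiances (at ambient CO2) and
#' records the apparent mesophyll conductance and the reassimilated
#' fraction at each point. Phi2 and gs come from the truth's sub-models.
#'
#' @param truth A [synth_truth()] object providing the physiological
#'   parameters and sub-models.
#' @param scenario Release scenario; defaults to the truth's.
#' @param sweep `"Ca"` or `"Iinc"`.
#' @param values Sweep grid; defaults to the standard design grids.
#' @param o O2 partial pressure (kPa): 21 for the photorespiratory regime,
#'   2 for the nonphotorespiratory one.
#' @param iinc_fixed Irradiance during a Ca sweep (umol m-2 s-1).
#' @param ca_fixed Ambient CO2 during an Iinc sweep (Pa).
#' @param control A [solver_control()].
#' @return A tibble with one row per grid point: `scenario`, `sweep`,
#'   `value`, `Iinc`, `Ca`, `O`, `an`, `ci`, `cc`, `gm`, `freass`.
#' @export
response_sweep <- function(truth, scenario = truth$scenario,
                           sweep = c("Ca", "Iinc"), values = NULL, o = 21,
                           iinc_fixed = 1500, ca_fixed = 40,
                           control = solver_control()) {
  stopifnot(inherits(truth, "synth_truth"))
  sweep <- match.arg(sweep)
  if (is.null(values)) {
    values <- if (sweep == "Ca") CA_GRID else IINC_GRID
  }
  geom <- build_unit_cell(truth$anatomy, scenario)
  ctx <- build_solver_context(generate_mesh(geom, c(control$nx, control$ny)),
                              truth$transport)
  rd <- if (o > 10) truth$rd_pr else truth$rd_npr
  warm <- NULL
  purrr::map_dfr(values, function(v) {
    iinc <- if (sweep == "Ca") iinc_fixed else v
    ca <- if (sweep == "Ca") v else ca_fixed
    phi2 <- phi2_submodel(truth, iinc)
    j <- electron_transport(truth$s_cal, iinc, phi2)
    kin <- kinetic_params(vcmax = truth$vcmax, j = j, rd = rd,
                          kmc = truth$kmc, kmo = truth$kmo, sco = truth$sco)
    bc <- boundary_condition("ca_driven", ca = ca,
                             gs = gs_submodel(truth, iinc), o = o)
    sol <- solve_steady_state(ctx, kin, boundary = bc, scenario = scenario,
                              control = control, tracer = TRUE, init = warm)
    warm <<- sol$internals$c
    tibble::tibble(scenario = scenario, sweep = sweep, value = v,
                   Iinc = iinc, Ca = ca, O = o, an = sol$an, ci = sol$ci,
                   cc = sol$cc, gm = sol$gm, freass = sol$freass)
  })
}

#' Least-squares AIC
#'
#' `AIC = n ln(RSS/n) + 2K`, where `K = k_params + 1` counts the fitted
#' parameters plus the residual variance.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of observations.
#' @param k_params Number of fitted model parameters (K is `k_params + 1`).
#' @return The AIC value.
#' @export
#' @examples
#' aic_ls(5, 20, 2)  # 20 * log(0.25) + 6
aic_ls <- function(rss, n, k_params) {
  k <- k_params + 1
  if (any(rss <= 0)) stop("`rss` must be positive (degenerate fit)",
                          call. = FALSE)
  if (any(n <= k) || any(k < 2)) {
    stop("need n > K >= 2 (K = k_params + 1)", call. = FALSE)
  }
  n * log(rss / n) + 2 * k
}

#' Scenario support from AIC differences
#'
#' Computes `delta AIC = AIC - min(AIC)` across candidate scenarios and
#' flags substantial support with the inclusive rule `delta AIC <= 2`.
#'
#' @param table A data frame with a `scenario` column and either an `aic`
#'   column or the triple `rss`, `n`, `k_params` from which AIC is computed
#'   via [aic_ls()].
#' @param threshold Support threshold on delta AIC (inclusive).
#' @return The input tibble with `aic`, `delta_aic` and logical `support`
#'   columns, sorted by `delta_aic`.
#' @export
delta_aic <- function(table, threshold = 2) {
  tb <- tibble::as_tibble(table)
  if (nrow(tb) < 2) stop("need at least 2 scenarios to compare", call. = FALSE)
  if (!"aic" %in% names(tb)) {
    if (!all(c("rss", "n", "k_params") %in% names(tb))) {
      stop("table must contain `aic` or (`rss`, `n`, `k_params`)",
           call. = FALSE)
    }
    tb$aic <- mapply(aic_ls, tb$rss, tb$n, tb$k_params)
  }
  tb$delta_aic <- tb$aic - min(tb$aic)
  tb$support <- tb$delta_aic <= threshold
  dplyr::arrange(tb, .data$delta_aic)
}
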