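test_that("Kok method recovers an exact line and applies its window", {
  d <- tibble::tibble(curve_type = "AI", Iinc = c(25, 50, 100, 150),
                      AN = 0.05 * c(25, 50, 100, 150) - 1.0, Phi2 = 0.75)
  est <- suppressWarnings(kok_method(d))
  expect_equal(est$rd, 1.0, tolerance = 1e-10)
  expect_equal(est$n_obs, 3L)  # the Iinc = 25 record is below the window
  expect_error(kok_method(d, window = c(500, 900)), "fewer than 3")
})

test_that("Yin method recovers a known intercept and requires Phi2", {
  iinc <- c(50, 75, 100, 125, 150)
  phi2 <- 0.8 / (1 + iinc / 1000)
  d <- tibble::tibble(curve_type = "AI", Iinc = iinc, Phi2 = phi2,
                      AN = 0.5 * iinc * phi2 / 4 - 1.2)
  est <- suppressWarnings(yin_method(d))
  expect_equal(est$rd, 1.2, tolerance = 1e-10)
  expect_equal(est$slope, 0.5, tolerance = 1e-10)
  expect_error(yin_method(dplyr::select(d, -Phi2)), "Phi2")
})

test_that("method bias ordering holds on photorespiratory synthetic data", {
  dat <- base_synth()
  tr <- quick_truth()
  pr <- dat[dat$regime == "PR", ]
  npr <- dat[dat$regime == "NPR", ]
  kok <- suppressWarnings(kok_method(pr))
  yin <- suppressWarnings(yin_method(pr))
  # declining Phi2 biases Kok low; reassimilation biases both low under PR
  expect_lt(kok$rd, yin$rd)
  expect_lt(yin$rd, tr$rd_pr)
  # under nonphotorespiratory conditions Yin is close to truth
  yin_npr <- suppressWarnings(yin_method(npr))
  expect_lt(abs(yin_npr$rd - tr$rd_npr), 0.05)
  # Yin underestimation under PR is positive, same order as low-light freass
  underest <- (tr$rd_pr - yin$rd) / tr$rd_pr
  expect_gt(underest, 0)
  expect_lt(underest, 0.5)
})

test_that("Laisk line family fits recover constructed intersections", {
  # three lines through (Ci* = 2.1, A* = -1.3)
  slopes <- c(0.6, 0.4, 0.25)
  ci <- seq(1, 8, by = 1)
  d <- dplyr::bind_rows(lapply(seq_along(slopes), function(i) {
    tibble::tibble(Iinc = c(150, 100, 50)[i], Ci = ci,
                   AN = slopes[i] * (ci - 2.1) - 1.3)
  }))
  fit <- laisk_method(d, ci_max = 10)
  expect_equal(fit$ci_star, 2.1, tolerance = 1e-4)
  expect_equal(fit$a_star, -1.3, tolerance = 1e-4)
  expect_equal(fit$rd_laisk, 1.3, tolerance = 1e-4)
  expect_equal(nrow(fit$pairwise), choose(3, 2))
  expect_lt(max(fit$pairwise$ci) - min(fit$pairwise$ci), 1e-6)
  # pairwise algebra: A = 0.5 Ci - 2 and A = 0.3 Ci - 1 cross at (5, 0.5)
  d2 <- dplyr::bind_rows(
    tibble::tibble(Iinc = 150, Ci = c(1, 4, 8), AN = 0.5 * c(1, 4, 8) - 2),
    tibble::tibble(Iinc = 50, Ci = c(1, 4, 8), AN = 0.3 * c(1, 4, 8) - 1))
  f2 <- laisk_method(d2, ci_max = 10)
  expect_equal(f2$pairwise$ci, 5.0, tolerance = 1e-8)
  expect_equal(f2$pairwise$an, 0.5, tolerance = 1e-8)
  # parallel lines have no intersection
  d3 <- dplyr::bind_rows(
    tibble::tibble(Iinc = 150, Ci = c(1, 4, 8), AN = 0.5 * c(1, 4, 8) - 2),
    tibble::tibble(Iinc = 50, Ci = c(1, 4, 8), AN = 0.5 * c(1, 4, 8) - 1))
  expect_error(laisk_method(d3, ci_max = 10), "parallel")
  # non-concurrent lines: positive family RSS and unequal pairwise points
  d4 <- dplyr::bind_rows(d2,
    tibble::tibble(Iinc = 25, Ci = c(1, 4, 8), AN = 0.2 * c(1, 4, 8) - 1.5))
  f4 <- laisk_method(d4, ci_max = 10)
  expect_gt(f4$rss, 1e-6)
  expect_gt(max(f4$pairwise$ci) - min(f4$pairwise$ci), 1e-3)
})

test_that("Laisk simulations separate release scenarios qualitatively", {
  ctrl <- quick_ctrl()
  sims <- lapply(c("inner", "gaps", "outer"), function(sc) {
    simulate_laisk_family(sc, rd = 1.5, control = ctrl,
                          ci_grid = seq(1, 9, by = 2))
  })
  names(sims) <- c("inner", "gaps", "outer")
  spread <- vapply(sims, function(s) {
    max(s$fit$pairwise$ci) - min(s$fit$pairwise$ci)
  }, 0)
  a_star_err <- vapply(sims, function(s) abs(s$fit$a_star + 1.5), 0)
  # release behind or between the chloroplasts concurs far more tightly,
  # and lands far closer to AN = -Rd, than release outside them
  expect_lt(spread[["inner"]], 0.5 * spread[["outer"]])
  expect_lt(a_star_err[["inner"]], 0.5 * a_star_err[["outer"]])
  expect_lt(a_star_err[["gaps"]], a_star_err[["outer"]])
  # outer release: every pairwise intersection sits above -Rd, and the
  # adjacent-irradiance intersections move to higher Ci at higher light
  pw <- sims[["outer"]]$fit$pairwise
  expect_true(all(pw$an > -1.5))
  adj <- pw[abs(match(pw$Iinc_1, c(150, 100, 50, 25)) -
                  match(pw$Iinc_2, c(150, 100, 50, 25))) == 1, ]
  adj <- adj[order(pmin(adj$Iinc_1, adj$Iinc_2)), ]
  expect_true(all(diff(adj$ci) > 0))
  # the intersections do not coincide with Ci = Gamma* in any scenario
  for (s in sims) expect_gt(abs(s$fit$ci_star - s$gamma_star), 0.05)
})

test_that("gm responds to Ca with the scenario-dependent shape", {
  tr <- quick_truth()
  ctrl <- quick_ctrl()
  ca <- c(10, 20, 40, 70, 100)
  sw <- lapply(c("inner", "gaps", "outer"), function(sc) {
    response_sweep(tr, scenario = sc, sweep = "Ca", values = ca, o = 21,
                   control = ctrl)
  })
  names(sw) <- c("inner", "gaps", "outer")
  # release behind the chloroplasts: gm falls with Ca; outside: it rises
  expect_true(all(diff(sw$inner$gm) < 0))
  expect_true(all(diff(sw$outer$gm) > 0))
  expect_gt(sw$gaps$gm[length(ca)], sw$gaps$gm[1])
  # pointwise scenario ordering
  expect_true(all(sw$inner$gm > sw$gaps$gm))
  expect_true(all(sw$gaps$gm > sw$outer$gm))
  # freass is a proper fraction, decreasing in Ca for a saturating sink
  for (s in sw) {
    expect_true(all(s$freass >= 0 & s$freass <= 1))
    expect_true(all(diff(s$freass) < 0))
  }
})

test_that("freass saturates with irradiance", {
  tr <- quick_truth()
  sw <- response_sweep(tr, scenario = "inner", sweep = "Iinc",
                       values = c(50, 150, 350, 700, 1200), o = 21,
                       control = quick_ctrl())
  expect_true(all(diff(sw$freass) > 0))
  # saturation: increments shrink
  expect_lt(diff(sw$freass)[4], diff(sw$freass)[1])
})

test_that("least-squares AIC and the inclusive support rule are exact", {
  expect_equal(aic_ls(5, 20, 2), 20 * log(5 / 20) + 2 * 3)
  expect_error(aic_ls(0, 20, 2), "positive")
  expect_error(aic_ls(5, 3, 3), "n > K")
  # adding a parameter at unchanged RSS costs exactly 2
  expect_equal(aic_ls(5, 20, 3) - aic_ls(5, 20, 2), 2)
  tb <- tibble::tibble(scenario = c("inner", "gaps", "outer"),
                       aic = c(-21.7, -20.0, -10.0))
  out <- delta_aic(tb)
  expect_equal(out$delta_aic, c(0, 1.7, 11.7))
  expect_equal(out$support, c(TRUE, TRUE, FALSE))
  # the threshold is inclusive
  tb2 <- tibble::tibble(scenario = c("a", "b"), aic = c(0, 2))
  expect_true(all(delta_aic(tb2)$support))
  # computed route from (rss, n, k_params)
  tb3 <- tibble::tibble(scenario = c("a", "b"), rss = c(5, 5), n = 20,
                        k_params = c(2, 2))
  expect_equal(delta_aic(tb3)$delta_aic, c(0, 0))
})

test_that("plot constructors return ggplot objects", {
  ctx <- quick_ctx("inner")
  kin <- kinetic_params(vcmax = 120, j = 200, rd = 1.5)
  sol <- solve_steady_state(ctx, kin,
                            boundary = boundary_condition("ci_driven",
                                                          ci = 25, o = 21))
  expect_s3_class(autoplot(sol), "ggplot")
  sim <- simulate_laisk_family("inner", rd = 1.5, control = quick_ctrl(),
                               ci_grid = seq(1, 9, by = 2))
  expect_s3_class(autoplot(sim), "ggplot")
  tr <- quick_truth()
  sw <- response_sweep(tr, sweep = "Ca", values = c(20, 40), o = 21,
                       control = quick_ctrl())
  expect_s3_class(plot_response_sweep(sw, "gm"), "ggplot")
})
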