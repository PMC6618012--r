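test_that("calibration recovers a noiseless line and flags degenerate input", {
  d <- tibble::tibble(
    curve_type = "AI", regime = "NPR",
    Iinc = c(30, 60, 90, 120, 150), Phi2 = 0.75,
    AN = 0.85 * c(30, 60, 90, 120, 150) * 0.75 / 4 - 1.2
  )
  fit <- suppressWarnings(fit_calibration_s(d))  # lm warns on an exact fit
  expect_equal(fit$s_cal, 0.85, tolerance = 1e-10)
  expect_equal(fit$intercept, -1.2, tolerance = 1e-10)
  expect_equal(fit$rd_yin, 1.2, tolerance = 1e-10)
  # duplicated regressor values only -> no slope
  d2 <- d
  d2$Iinc <- 100
  expect_error(fit_calibration_s(d2), "zero variance")
  d3 <- d
  d3$Phi2 <- NA_real_
  expect_error(fit_calibration_s(d3), "Phi2")
})

test_that("calibration slope is unbiased under noise", {
  set.seed(42)
  iinc <- seq(20, 150, length.out = 11)
  phi2 <- 0.8 / (1 + iinc / 1000)
  x <- iinc * phi2 / 4
  d <- tibble::tibble(curve_type = "AI", regime = "NPR", Iinc = iinc,
                      Phi2 = phi2, AN = 0.85 * x - 1.2 + rnorm(11, 0, 0.1))
  fit <- fit_calibration_s(d)
  expect_lt(abs(fit$s_cal - 0.85), 3 * fit$se)
})

test_that("Rd is recovered from noiseless synthetic data per regime", {
  tr <- quick_truth()
  dat <- base_synth()
  f_pr <- fit_rd(dat, "inner", "PR", vcmax = tr$vcmax, tp = tr$tp,
                 s_cal = tr$s_cal, control = quick_ctrl())
  expect_equal(f_pr$estimate, tr$rd_pr, tolerance = 1e-3)
  expect_lt(f_pr$rss, 1e-6)
  f_npr <- fit_rd(dat, "inner", "NPR", vcmax = tr$vcmax, tp = tr$tp,
                  s_cal = tr$s_cal, control = quick_ctrl())
  expect_equal(f_npr$estimate, tr$rd_npr, tolerance = 1e-3)
  # regimes never share records and the built-in PR > NPR ordering survives
  expect_gt(f_pr$estimate, f_npr$estimate)
  expect_equal(f_pr$n_obs, 6L)
  expect_equal(f_npr$n_obs, 6L)
  # records above the irradiance cutoff are excluded from the objective
  expect_true(all(f_pr$records$Iinc <= 150))
  # broom-style accessors
  td <- tidy(f_pr)
  expect_identical(td$term, "rd")
  gl <- glance(f_pr)
  expect_true(all(c("rss", "AIC") %in% names(gl)))
})

test_that("the Rd objective is unimodal with its minimum at the estimate", {
  tr <- quick_truth()
  dat <- base_synth()
  fit <- fit_rd(dat, "inner", "PR", vcmax = tr$vcmax, tp = tr$tp,
                s_cal = tr$s_cal, control = quick_ctrl())
  d <- fit$records
  ctx <- quick_ctx("inner")
  rss_at <- function(rd) {
    pred <- mesodiff:::predict_an_records(d, ctx, vcmax = tr$vcmax, rd = rd,
                                          tp = tr$tp, s_cal = tr$s_cal,
                                          scenario = "inner",
                                          control = quick_ctrl())
    sum((d$AN - pred)^2)
  }
  grid <- seq(0.25, 4, by = 0.75)
  vals <- vapply(grid, rss_at, 0)
  expect_true(all(vals >= fit$rss - 1e-9))
  expect_lte(fit$rss, rss_at(tr$rd_pr) + 1e-9)
})

test_that("Vcmax is recovered noiselessly and uses only the low-Ca subset", {
  tr <- quick_truth()
  dat <- base_synth()
  fit <- fit_vcmax(dat, "inner", rd = tr$rd_pr, tp = tr$tp,
                   s_cal = tr$s_cal, control = quick_ctrl())
  expect_equal(fit$estimate, tr$vcmax, tolerance = tr$vcmax * 5e-3)
  expect_true(all(fit$records$Ca < 30))
  expect_error(fit_vcmax(dat[dat$Ca >= 40, ], "inner", rd = tr$rd_pr,
                         tp = tr$tp, s_cal = tr$s_cal,
                         control = quick_ctrl()),
               "fewer than 3")
})

test_that("mismatched scenario inflates the Vcmax uncertainty", {
  tr <- quick_truth()  # generated with release in the inner cytosol
  dat <- base_synth()
  f_in <- fit_vcmax(dat, "inner", rd = tr$rd_pr, tp = tr$tp,
                    s_cal = tr$s_cal, control = quick_ctrl())
  f_out <- fit_vcmax(dat, "outer", rd = tr$rd_pr, tp = tr$tp,
                     s_cal = tr$s_cal, control = quick_ctrl())
  expect_gt(f_out$se, f_in$se)
  expect_gt(f_out$rss, f_in$rss)
})

test_that("validation reproduces fit RSS on the fitting set and caps TPU", {
  tr <- quick_truth()
  dat <- base_synth()
  fit <- fit_rd(dat, "inner", "PR", vcmax = tr$vcmax, tp = tr$tp,
                s_cal = tr$s_cal, control = quick_ctrl())
  # degenerate call: held-out = fitting set
  v <- validate_model(fit$records, "inner", vcmax = tr$vcmax,
                      rd_pr = fit$estimate, tp = tr$tp, s_cal = tr$s_cal,
                      control = quick_ctrl())
  expect_equal(attr(v, "rmse"), sqrt(fit$rss / fit$n_obs), tolerance = 1e-4)
  # noiseless matched-scenario predictions on genuinely held-out records
  held <- dat[dat$curve_type == "ACa" & dat$regime == "NPR", ]
  v2 <- validate_model(held, "inner", vcmax = tr$vcmax, rd_pr = tr$rd_pr,
                       rd_npr = tr$rd_npr, tp = tr$tp, s_cal = tr$s_cal,
                       control = quick_ctrl())
  expect_lt(attr(v2, "rmse"), 1e-3)
  expect_true(all(is.finite(v2$AN_pred)))
  # the NPR high-Ca plateau is TPU-capped
  expect_true(all(v2$AN_pred <= 3 * tr$tp - tr$rd_npr + 1e-9))
  expect_error(validate_model(dat[0, ], "inner", vcmax = 120, rd_pr = 1.5,
                              s_cal = 0.5), "empty")
})

test_that("noisy replicates recover Rd with small bias", {
  tr <- quick_truth()
  dat <- base_synth()
  est <- vapply(1:12, function(r) {
    noisy <- with_noise(dat, sd_an = 0.2, seed = 100 + r)
    fit_rd(noisy, "inner", "PR", vcmax = tr$vcmax, tp = tr$tp,
           s_cal = tr$s_cal, control = quick_ctrl())$estimate
  }, 0)
  expect_lt(abs(mean(est) - tr$rd_pr), 0.05 * tr$rd_pr + 2 * sd(est) / sqrt(12))
})
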