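chi90 <- stats::qchisq(0.9, 1)

test_that("profile scans preserve the optimum at the fitted prediction", {
  fx <- fx_linear()
  tgt <- prediction_target("y", 5)
  z_hat <- predict(fx$model, fx$fit$theta_hat, tgt)
  pc <- ppl_scan(fx$model, fx$data, tgt, fx$fit, alpha = 0.9)
  vc <- vpl_scan(fx$model, fx$data, validation_setup(tgt, 0.3), fx$fit,
                 alpha = 0.9)
  for (cv in list(pc, vc)) {
    expect_gte(min(cv$neg2PL), fx$fit$neg2LL_star - 1e-7)
    expect_equal(min(cv$neg2PL), fx$fit$neg2LL_star, tolerance = 1e-7)
    expect_equal(cv$grid[which.min(cv$neg2PL)], z_hat, tolerance = 1e-6)
  }
})

test_that("linear-Gaussian profiles have the analytic curvatures", {
  fx <- fx_linear()
  t0 <- 5
  SD <- 0.3
  ora <- linear_oracle(fx$times, fx$sigma, fx$theta_true, alpha = 0.9, sd = SD)
  se <- ora$se(t0)
  tgt <- prediction_target("y", t0)
  z_hat <- predict(fx$model, fx$fit$theta_hat, tgt)

  pc <- ppl_scan(fx$model, fx$data, tgt, fx$fit, alpha = 0.9)
  expect_lt(max(abs(pc$neg2PL - (fx$fit$neg2LL_star +
                                   (pc$grid - z_hat)^2 / se^2))), 1e-5)

  vc <- vpl_scan(fx$model, fx$data, validation_setup(tgt, SD), fx$fit,
                 alpha = 0.9)
  expect_lt(max(abs(vc$neg2PL - (fx$fit$neg2LL_star +
                                   (vc$grid - z_hat)^2 / (se^2 + SD^2)))),
            1e-5)

  # rescaling the validation curve recovers the prediction curvature 1/se^2
  rs <- rescale_vpl_to_ppl(vc)
  expect_equal(rs$kind, "prediction")
  expect_lt(max(abs(rs$neg2PL - (fx$fit$neg2LL_star +
                                   (rs$grid - z_hat)^2 / se^2))), 1e-4)
  # at the optimum the correction vanishes: PPL = VPL
  expect_equal(min(rs$neg2PL), min(vc$neg2PL), tolerance = 1e-8)
})

test_that("rescaling demands a validation curve with recorded responses", {
  cv <- make_quadratic_curve()
  expect_error(rescale_vpl_to_ppl(cv, 0.1), "validation",
               class = "pplik_config_error")
  bare <- profile_curve(1:5, c(4, 1, 0, 1, 4), neg2LL_star = 0,
                        kind = "validation")
  expect_error(rescale_vpl_to_ppl(bare, 0.1), "z'",
               class = "pplik_config_error")
})

test_that("interval construction inverts a quadratic profile analytically", {
  cv <- make_quadratic_curve(center = 2, curv_se = 0.1)
  ci <- interval_from_curve(cv, 2.706)
  expect_equal(ci$lower, 2 - 0.1 * sqrt(2.706), tolerance = 1e-3)
  expect_equal(ci$upper, 2 + 0.1 * sqrt(2.706), tolerance = 1e-3)
  expect_false(ci$unbounded_lower || ci$unbounded_upper)
  # threshold zero collapses onto the optimum
  ci0 <- interval_from_curve(cv, 0)
  expect_equal(ci0$lower, 2, tolerance = 1e-6)
  expect_equal(ci0$upper, 2, tolerance = 1e-6)
})

test_that("a flat tail below the threshold is reported as unbounded", {
  g <- seq(0, 4, by = 0.1)
  v <- ifelse(g < 1, 5 + (g - 1)^2 * 100, 5 + 0.2 * (g - 1) / 3)
  cv <- profile_curve(g, v, neg2LL_star = 5, kind = "prediction",
                      sides = list(left = list(reason = "crossed",
                                               crossed = TRUE),
                                   right = list(reason = "max_steps",
                                                crossed = FALSE)))
  ci <- interval_from_curve(cv, 2.706)
  expect_true(ci$unbounded_upper)
  expect_identical(ci$upper, Inf)
  expect_false(ci$unbounded_lower)
  # curves whose minimum misses their own optimum are a contract violation
  bad <- profile_curve(g, v + 10, neg2LL_star = 5, kind = "prediction")
  expect_error(interval_from_curve(bad, 2.706), "threshold",
               class = "pplik_config_error")
})

test_that("the asymptotic threshold is the chi-square quantile and is monotone", {
  expect_equal(profile_threshold(0.9), stats::qchisq(0.9, 1),
               tolerance = 1e-12)
  alphas <- c(0.5, 0.8, 0.9, 0.95, 0.99, 0.999)
  expect_true(all(diff(vapply(alphas, profile_threshold, numeric(1))) > 0))
  expect_error(profile_threshold(1.2), class = "pplik_config_error")
  fx <- fx_linear()
  expect_error(profile_threshold(0.9, "montecarlo", fx$model, fx$data,
                                 fx$fit, prediction_target("y", 5),
                                 n_reps = 99),
               "at least 100", class = "pplik_config_error")
})

test_that("prediction intervals nest inside validation intervals", {
  fx <- fx_abc_full()
  thr <- profile_threshold(0.9)
  for (spec in list(c("A", 10), c("C", 50))) {
    tgt <- prediction_target(spec[1], as.numeric(spec[2]))
    z_hat <- predict(fx$model, fx$fit$theta_hat, tgt)
    pci <- interval_from_curve(ppl_scan(fx$model, fx$data, tgt, fx$fit,
                                        alpha = 0.9), thr, 0.9)
    vci <- interval_from_curve(vpl_scan(fx$model, fx$data,
                                        validation_setup(tgt, 0.1), fx$fit,
                                        alpha = 0.9), thr, 0.9)
    expect_lte(vci$lower, pci$lower)
    expect_gte(vci$upper, pci$upper)
    expect_true(pci$lower <= z_hat && z_hat <= pci$upper)
    expect_true(vci$lower <= z_hat && z_hat <= vci$upper)
  }
})

test_that("shrinking the validation error collapses the VCI onto the PCI", {
  fx <- fx_linear()
  t0 <- 5
  ora <- linear_oracle(fx$times, fx$sigma, fx$theta_true, alpha = 0.9)
  se <- ora$se(t0)
  tgt <- prediction_target("y", t0)
  thr <- profile_threshold(0.9)
  vci <- interval_from_curve(vpl_scan(fx$model, fx$data,
                                      validation_setup(tgt, se / 10), fx$fit,
                                      alpha = 0.9), thr, 0.9)
  pci <- interval_from_curve(ppl_scan(fx$model, fx$data, tgt, fx$fit,
                                      alpha = 0.9), thr, 0.9)
  half_v <- (vci$upper - vci$lower) / 2
  half_p <- (pci$upper - pci$lower) / 2
  expect_equal(half_v, half_p * sqrt(1 + 0.01), tolerance = 1e-3)
})
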