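test_that("-2 log-likelihood equals the standardized residual sum of squares", {
  m <- abc_model()
  des <- abc_design("full")
  # perfect fit on noise-free data
  d0 <- simulate_dataset(m, abc_theta_true, des, noise_spec(sigma = 0, seed = 1))
  d0$sigma <- 0.1
  expect_lt(neg2_loglik(m, abc_theta_true, d0), 1e-10)
  # one point exactly one sigma off contributes exactly 1
  d1 <- d0[5, , drop = FALSE]
  d1$value <- d1$value + d1$sigma
  expect_equal(neg2_loglik(m, abc_theta_true, d1), 1, tolerance = 1e-7)
  # noisy data at a perturbed theta: brute-force oracle sum
  d <- simulate_dataset(m, abc_theta_true, des, noise_spec(seed = 21))
  theta_p <- abc_theta_true * c(1.2, 0.8, 1.1)
  expect_equal(neg2_loglik(m, theta_p, d), abc_neg2ll_oracle(theta_p, d),
               tolerance = 1e-6)
})

test_that("multi-start fitting recovers the truth from noise-free data", {
  m <- abc_model()
  d <- simulate_dataset(m, abc_theta_true, abc_design("full"),
                        noise_spec(sigma = 0, seed = 1))
  d$sigma <- 0.1
  f <- fit_model(m, d, n_starts = 10, seed = 4)
  expect_lt(max(abs(f$theta_hat - abc_theta_true) / abc_theta_true), 1e-4)
  expect_lt(f$neg2LL_star, 1e-8)
  expect_gte(f$converged_fraction, 0.5)
})

test_that("the fitted optimum matches closed-form weighted least squares and is a fixed point", {
  fx <- fx_linear()
  ora <- linear_oracle(fx$times, fx$sigma, fx$theta_true)
  th_wls <- ora$theta_hat(fx$data$value)
  expect_equal(unname(fx$fit$theta_hat[["theta1"]]), th_wls,
               tolerance = 1e-6)
  # refitting from the optimum does not move it
  f2 <- fit_model(fx$model, fx$data, n_starts = 1, seed = 9,
                  start = fx$fit$theta_hat)
  expect_lt(abs(f2$neg2LL_star - fx$fit$neg2LL_star), 1e-8)
})

test_that("fitting is deterministic given the seed", {
  m <- abc_model()
  d <- simulate_dataset(m, abc_theta_true, abc_design("full"),
                        noise_spec(seed = 33))
  f1 <- fit_model(m, d, n_starts = 5, seed = 17)
  f2 <- fit_model(m, d, n_starts = 5, seed = 17)
  expect_identical(f1$theta_hat, f2$theta_hat)
})

test_that("the parameter profile is exactly quadratic for the linear model", {
  fx <- fx_linear()
  ora <- linear_oracle(fx$times, fx$sigma, fx$theta_true, alpha = 0.9)
  out <- profile_parameter(fx$model, fx$data, fx$fit, "theta1", alpha = 0.9)
  th_hat <- fx$fit$theta_hat[["theta1"]]
  # curvature equals the analytic Fisher information sum(t^2)/sigma^2
  expected <- fx$fit$neg2LL_star + (out$curve$grid - th_hat)^2 * ora$St2 /
    fx$sigma^2
  expect_lt(max(abs(out$curve$neg2PL - expected)) /
              max(1, max(expected)), 1e-6)
  # profile value at the optimum is the global optimum
  expect_equal(min(out$curve$neg2PL), fx$fit$neg2LL_star, tolerance = 1e-8)
  # CI endpoints: theta_hat +/- sqrt(q) sigma / sqrt(sum t^2)
  half <- sqrt(stats::qchisq(0.9, 1)) * ora$theta_se
  expect_equal(out$ci$lower, th_hat - half, tolerance = 1e-4 * half)
  expect_equal(out$ci$upper, th_hat + half, tolerance = 1e-4 * half)
  expect_true(out$ci$lower <= th_hat && th_hat <= out$ci$upper)
})

test_that("a practically non-identifiable parameter yields an unbounded profile side", {
  fx <- fx_abc_short()
  out <- profile_parameter(fx$model, fx$data, fx$fit, "theta3", alpha = 0.9)
  # the concentration dimension is unconstrained upward by transient data
  expect_false(out$curve$right_crossed)
  expect_true(out$ci$unbounded_upper)
  expect_gte(min(out$curve$neg2PL), fx$fit$neg2LL_star - 1e-6)
})
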