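test_that("band interpolation is exact at its knots and spans the fit", {
  fx <- fx_abc_full()
  b <- pci_band(fx$model, fx$data, fx$fit, "C", times = c(10, 30, 50, 70),
                alpha = 0.9)
  at_knots <- interpolate_band(b, b$time)
  expect_equal(at_knots$lower, b$lower, tolerance = 1e-10)
  expect_equal(at_knots$upper, b$upper, tolerance = 1e-10)
  # the band never excludes the maximum-likelihood trajectory
  expect_true(all(b$lower <= b$estimate & b$estimate <= b$upper))
  # interpolation between knots stays within the knot bound range
  mid <- interpolate_band(b, c(20, 40, 60))
  expect_true(all(is.finite(mid$lower) & is.finite(mid$upper)))
  expect_true(all(mid$lower <= mid$upper))
})

test_that("interpolation segments break at unbounded knots", {
  b <- make_band("A", times = c(0, 10, 20, 30),
                 lower = c(0, 1, 1, 1), upper = c(0, 2, 3, 4),
                 unb_r = c(FALSE, FALSE, TRUE, FALSE))
  out <- interpolate_band(b, c(5, 15, 25))
  expect_true(is.finite(out$lower[1]))
  # upper side: knots 20 is unbounded, so 15 and 25 fall in broken segments
  expect_true(is.na(out$upper[2]))
  expect_true(is.na(out$upper[3]))
})

test_that("observability classification flags unbounded times and sides", {
  ok <- make_band("C", 0:3, lower = rep(0, 4), upper = rep(1, 4))
  expect_equal(classify_observability(ok)$status, "observable")

  bad <- make_band("A", 0:3, lower = rep(0, 4), upper = c(0, 1, 1, 1),
                   unb_r = c(FALSE, TRUE, TRUE, TRUE))
  cls <- classify_observability(bad)
  expect_equal(cls$status, "non_observable")
  # the bounded width-zero point at t = 0 is not an offender
  expect_equal(cls$detail$time, 1:3)
  expect_true(all(cls$detail$side == "upper"))
})

test_that("design ranking orders by width with unbounded entries first and stable ties", {
  b1 <- make_band("s1", c(0, 10), lower = c(0, 0), upper = c(1, 5))
  b2 <- make_band("s2", c(0, 10), lower = c(0, 0), upper = c(1, 2),
                  unb_r = c(FALSE, TRUE))
  b3 <- make_band("s3", c(0, 10), lower = c(0, 0), upper = c(1, 5))
  rk <- design_ranking(list(b1, b2, b3))
  expect_identical(rk$width[1], Inf)
  expect_equal(rk$state[1], "s2")
  expect_equal(rk$width[2:3], c(5, 5))
  # deterministic tie-break by (state, time)
  expect_equal(rk$state[2:3], c("s1", "s3"))
  expect_equal(rk[rk$width == 1, "state"], c("s1", "s2", "s3"))
  rk2 <- design_ranking(list(b3, b2, b1))
  expect_identical(rk, rk2)
})

test_that("linear-Gaussian interval coverage sits at the nominal level", {
  fx <- fx_linear()
  tgt <- prediction_target("y", 5)
  cov <- coverage_study(fx$model, c(theta1 = fx$theta_true), fx$design, tgt,
                        alpha = 0.9, n_reps = 60, seed = 5)
  expect_true(cov$valid)
  # exact binomial acceptance band for p = 0.9, n = 60 (alpha_test = 1%)
  lo <- stats::qbinom(0.005, 60, 0.9) / 60
  hi <- stats::qbinom(0.995, 60, 0.9) / 60
  expect_gte(cov$coverage, lo)
  expect_lte(cov$coverage, hi)
  # nested levels on the same replicate stream
  cov99 <- coverage_study(fx$model, c(theta1 = fx$theta_true), fx$design,
                          tgt, alpha = 0.99, n_reps = 60, seed = 5)
  expect_gte(cov99$coverage, cov$coverage)
})

test_that("validation-mode coverage holds for a noisy future measurement", {
  fx <- fx_linear()
  tgt <- prediction_target("y", 5)
  cov <- coverage_study(fx$model, c(theta1 = fx$theta_true), fx$design, tgt,
                        alpha = 0.9, n_reps = 50, seed = 6,
                        mode = "validation", sd = 0.5)
  lo <- stats::qbinom(0.005, 50, 0.9) / 50
  expect_gte(cov$coverage, lo)
  expect_lte(cov$coverage, 1)
})
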