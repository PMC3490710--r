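test_that("simulated datasets are reproducible and correctly sized", {
  m <- abc_model()
  des <- abc_design("full")
  d1 <- simulate_dataset(m, abc_theta_true, des, noise_spec(seed = 7))
  d2 <- simulate_dataset(m, abc_theta_true, des, noise_spec(seed = 7))
  d3 <- simulate_dataset(m, abc_theta_true, des, noise_spec(seed = 8))
  expect_identical(d1, d2)
  expect_false(isTRUE(all.equal(d1$value, d3$value)))
  expect_equal(nrow(d1), 11L)
  expect_true(all(d1$sigma == 0.1))
  expect_equal(d1$observable, rep("C", 11))
})

test_that("zero noise reproduces the observation map exactly", {
  m <- abc_model()
  des <- abc_design("full")
  d <- simulate_dataset(m, abc_theta_true, des, noise_spec(sigma = 0, seed = 1))
  cf <- abc_closed_form(abc_theta_true, des$times)
  expect_equal(d$value, unname(cf[, "C"]), tolerance = 1e-7)
})

test_that("standardized residuals at the truth behave like white noise", {
  m <- abc_model()
  des <- experimental_design(seq(0, 100, by = 1), "C")
  d <- simulate_dataset(m, abc_theta_true, des, noise_spec(seed = 13))
  cf <- abc_closed_form(abc_theta_true, d$time)
  r <- (d$value - cf[, "C"]) / d$sigma
  n <- length(r)
  expect_lt(abs(mean(r)), 4 / sqrt(n))
  expect_lt(abs(stats::var(r) - 1), 4 / sqrt(n))
})

test_that("datasets and trajectories survive CSV round trips", {
  m <- abc_model()
  d <- simulate_dataset(m, abc_theta_true, abc_design("full"),
                        noise_spec(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(d, path)
  d2 <- read_dataset_csv(path)
  expect_equal(d2$value, d$value, tolerance = 1e-12)
  expect_equal(d2$observable, d$observable)
  expect_equal(names(d2), c("time", "observable", "value", "sigma"))

  traj <- integrate_model(m, abc_theta_true, c(0, 10, 20))
  tpath <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, tpath)
  got <- utils::read.csv(tpath)
  expect_equal(names(got), c("time", "A", "B", "C"))
  expect_equal(got$A, unname(traj$states[, "A"]), tolerance = 1e-12)
})
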