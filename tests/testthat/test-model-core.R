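test_that("numerical integration of the chain agrees with the closed form", {
  m <- abc_model()
  times <- seq(0, 100, by = 5)
  set.seed(101)
  for (i in 1:5) {
    theta <- abc_theta_true * exp(runif(3, -0.7, 0.7))
    traj <- integrate_model(m, theta, times)
    cf <- abc_closed_form(theta, times)
    expect_lt(max(abs(traj$states - cf)), 1e-6)
    # mass conservation A + B + C = A(0)
    expect_lt(max(abs(rowSums(traj$states) - theta[[3]])), 1e-8)
  }
})

test_that("trajectory starts at the initial condition and refining the grid does not change it", {
  m <- abc_model()
  theta <- abc_theta_true
  coarse <- integrate_model(m, theta, seq(0, 100, by = 10))
  fine <- integrate_model(m, theta, seq(0, 100, by = 5))
  expect_equal(unname(coarse$states[1, ]), c(1, 0, 0))
  shared <- match(coarse$times, fine$times)
  expect_lt(max(abs(coarse$states - fine$states[shared, ])), 1e-6)
  # prediction is a single response, invariant to how it is reached
  z <- predict(m, theta, prediction_target("A", 10))
  expect_equal(z, exp(-0.5), tolerance = 1e-7)
})

test_that("observation map supports identity, sums and ratios of states", {
  m <- abc_model()
  traj <- integrate_model(m, abc_theta_true, seq(0, 100, by = 10))
  obs <- observe(m, traj, abc_theta_true)
  expect_equal(unname(obs[, "C"]), unname(traj$states[, "C"]))

  mk <- mapk_model()
  trk <- integrate_model(mk, mk$parameters, seq(0, 1000, by = 200))
  ok <- observe(mk, trk, mk$parameters)
  expect_equal(unname(ok[, "Mek_active"]),
               unname(trk$states[, "Mek_p"] + trk$states[, "Mek_pp"]))

  # a prediction can be any expression, e.g. a concentration ratio
  z <- predict(m, abc_theta_true, prediction_target("B / A", 10))
  cf <- abc_closed_form(abc_theta_true, 10)
  expect_equal(z, unname(cf[1, "B"] / cf[1, "A"]), tolerance = 1e-7)
})

test_that("piecewise-constant inputs enter the dynamics", {
  m <- ode_model("pulse", states = "x", parameters = c(k = 1),
                 rhs = c(x = "k * u"), observables = c(y = "x"),
                 initial_values = list(x = 0), noise_sd = c(y = 0.1),
                 inputs = list(default = list(
                   u = data.frame(time = c(0, 5), value = c(1, 0)))))
  traj <- integrate_model(m, c(k = 1), c(2, 5, 10))
  expect_equal(unname(traj$states[, "x"]), c(2, 5, 5), tolerance = 1e-6)
})

test_that("model declaration is validated", {
  expect_error(ode_model("bad", states = "A", parameters = c(k = 1),
                         rhs = c(A = "-k * Q"), observables = c(y = "A"),
                         initial_values = list(A = 1)),
               "unknown symbol", class = "pplik_config_error")
  expect_error(ode_model("bad", states = c("A", "B"), parameters = c(k = 1),
                         rhs = c(A = "-k * A"), observables = c(y = "A"),
                         initial_values = list(A = 1, B = 0)),
               "one expression per state", class = "pplik_config_error")
  expect_error(ode_model("bad", states = "A", parameters = c(k = -1),
                         rhs = c(A = "-k * A"), observables = c(y = "A"),
                         initial_values = list(A = 1)),
               "positive", class = "pplik_config_error")
  m <- abc_model()
  traj <- integrate_model(m, abc_theta_true, c(0, 10))
  expect_error(observe(m, traj, abc_theta_true, "nope"),
               "unknown observable", class = "pplik_config_error")
  expect_error(experimental_design(c(0, 10, 10), "C"),
               class = "pplik_config_error")
})

test_that("integration failure is an explicit condition carrying theta", {
  m <- ode_model("blowup", states = "x", parameters = c(k = 1),
                 rhs = c(x = "k * x^2"), observables = c(y = "x"),
                 initial_values = list(x = 1), noise_sd = c(y = 0.1))
  err <- tryCatch(integrate_model(m, c(k = 5), c(0, 10)),
                  pplik_integration_error = function(e) e)
  expect_s3_class(err, "pplik_integration_error")
  expect_equal(err$theta[["k"]], 5)
})

test_that("a model survives a YAML round trip", {
  mk <- mapk_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ode_model(mk, path)
  mk2 <- read_ode_model(path)
  expect_equal(mk2$states, mk$states)
  expect_equal(mk2$parameters, mk$parameters)
  t1 <- integrate_model(mk, mk$parameters, c(0, 300, 600))
  t2 <- integrate_model(mk2, mk2$parameters, c(0, 300, 600))
  expect_equal(t1$states, t2$states, tolerance = 1e-10)
})
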