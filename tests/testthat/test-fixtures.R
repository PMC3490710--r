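test_that("chain model defaults, designs and closed form match the stated setup", {
  m <- abc_model()
  expect_equal(unname(m$parameters), c(0.05, 0.1, 1))
  expect_equal(abc_design("full")$times, seq(0, 100, by = 10))
  expect_equal(abc_design("short")$times, seq(0, 20, by = 2))

  cf <- abc_closed_form(c(0.05, 0.1, 1), 10)
  expect_equal(unname(cf[1, ]), c(0.60653, 0.23865, 0.15482),
               tolerance = 1e-4)
  expect_equal(unname(abc_closed_form(c(0.05, 0.1, 1), 0)[1, ]), c(1, 0, 0))
  tt <- seq(0, 200, by = 7)
  expect_lt(max(abs(rowSums(abc_closed_form(c(0.05, 0.1, 1), tt)) - 1)),
            1e-12)
  expect_error(abc_closed_form(c(0.1, 0.1, 1), 5), "degenerate",
               class = "pplik_config_error")
  # the chain absorbs into C at steady state
  traj <- integrate_model(m, abc_theta_true, c(0, 500))
  expect_lt(max(abs(traj$states[2, c("A", "B")])), 1e-6)
  expect_equal(unname(traj$states[2, "C"]), 1, tolerance = 1e-6)
})

test_that("MAPK fixture has the stated dimensions and conservation laws", {
  mk <- mapk_model()
  expect_length(mk$states, 8L)
  expect_length(mk$parameters, 14L)
  dat <- simulate_dataset(mk, mk$parameters, mapk_design(),
                          noise_spec(seed = 1))
  expect_equal(nrow(dat), 33L)
  expect_true(all(dat$sigma == 10))
  traj <- integrate_model(mk, mk$parameters, seq(0, 1000, by = 50))
  erk_tot <- rowSums(traj$states[, c("Erk", "Erk_p", "Erk_pp")])
  expect_lt(diff(range(erk_tot)), 1e-5)
  mek_tot <- rowSums(traj$states[, c("Mek", "Mek_p", "Mek_pp")])
  expect_lt(diff(range(mek_tot)), 1e-5)
})

test_that("MAPK trajectories stay bounded and non-negative over the parameter box", {
  mk <- mapk_model()
  set.seed(77)
  total <- 100 + 300 + 300
  for (i in 1:25) {
    theta <- mk$parameters * exp(runif(14, -log(10), log(10)))
    traj <- tryCatch(integrate_model(mk, theta, seq(0, 1000, by = 100)),
                     pplik_integration_error = function(e) NULL)
    # occasional stiff failures are signalled, never silent
    if (is.null(traj)) next
    expect_gte(min(traj$states), -1e-6)
    expect_lte(max(traj$states), total)
  }
})

test_that("the linear oracle evaluates its closed forms", {
  ora <- linear_oracle(1:10, sigma = 1, theta_true = 1, alpha = 0.9,
                       sd = 0)
  expect_equal(ora$pci_half(5), sqrt(2.70554) * 5 / sqrt(385),
               tolerance = 1e-5)
  expect_equal(ora$pci_half(0), 0)
  # sd = 0 collapses validation onto prediction
  expect_equal(ora$vci_half(5), ora$pci_half(5))
})
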