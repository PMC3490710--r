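# Shared fixtures, built once per test run and cached.  Everything is
# generated in code from seeded noise; no files are read.

.fx_cache <- new.env(parent = emptyenv())

fx_get <- function(key, make) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- make()
  .fx_cache[[key]]
}

abc_theta_true <- c(theta1 = 0.05, theta2 = 0.1, theta3 = 1)

fx_abc_full <- function() fx_get("abc_full", function() {
  m <- abc_model()
  d <- simulate_dataset(m, abc_theta_true, abc_design("full"),
                        noise_spec(seed = 42))
  f <- fit_model(m, d, n_starts = 12, seed = 1)
  list(model = m, data = d, fit = f)
})

fx_abc_short <- function() fx_get("abc_short", function() {
  m <- abc_model()
  d <- simulate_dataset(m, abc_theta_true, abc_design("short"),
                        noise_spec(seed = 42))
  f <- fit_model(m, d, n_starts = 20, seed = 1)
  list(model = m, data = d, fit = f)
})

# linear-Gaussian reference problem: y = theta t + eps, known sigma
fx_linear <- function() fx_get("linear", function() {
  times <- 1:10
  sigma <- 1
  theta_true <- 0.5
  m <- linear_model(theta1 = theta_true, sigma = sigma)
  des <- experimental_design(times, "y")
  d <- simulate_dataset(m, c(theta1 = theta_true), des, noise_spec(seed = 11))
  f <- fit_model(m, d, n_starts = 3, seed = 1)
  list(model = m, data = d, fit = f, design = des,
       times = times, sigma = sigma, theta_true = theta_true)
})

# brute-force -2LL oracle for the chain model: standardized squared
# residuals summed over the analytic trajectory, independent of the
# package's objective code
abc_neg2ll_oracle <- function(theta, data) {
  cf <- abc_closed_form(theta, data$time)
  F <- cf[cbind(seq_len(nrow(data)), match(data$observable, colnames(cf)))]
  sum(((data$value - F) / data$sigma)^2)
}

# synthetic confidence band with controllable flags, for classification and
# ranking tests
make_band <- function(state, times, lower, upper, unb_l = FALSE,
                      unb_r = FALSE, alpha = 0.9) {
  b <- data.frame(time = times, estimate = (lower + upper) / 2,
                  lower = lower, upper = upper,
                  unbounded_lower = rep_len(unb_l, length(times)),
                  unbounded_upper = rep_len(unb_r, length(times)),
                  quality = "ok")
  attr(b, "state") <- state
  attr(b, "alpha") <- alpha
  attr(b, "mode") <- "prediction"
  attr(b, "interpolation") <- "monoH.FC"
  class(b) <- c("confidence_band", "data.frame")
  b
}

# quadratic -2 profile curve with analytic threshold crossings
make_quadratic_curve <- function(center = 2, curv_se = 0.1, f0 = 5,
                                 halfspan = 0.6, n = 41) {
  g <- seq(center - halfspan, center + halfspan, length.out = n)
  profile_curve(g, f0 + (g - center)^2 / curv_se^2, neg2LL_star = f0,
                kind = "prediction",
                sides = list(left = list(reason = "crossed", crossed = TRUE),
                             right = list(reason = "crossed", crossed = TRUE)))
}
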