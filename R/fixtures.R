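#' Two-step reaction chain model A -> B -> C
#'
#' Small mass-action chain used throughout for illustration and testing:
#' A converts to B with rate `theta1` and B to C with rate `theta2`; the
#' initial amount of A is the third free parameter `theta3`, while B and C
#' start at zero.  Only C is observed, with Gaussian noise of standard
#' deviation 0.1 (roughly 10% signal-to-noise, typical of cell-biology
#' measurements).  Defaults: theta1 = 0.05, theta2 = 0.1, theta3 = 1.
#'
#' @return An [ode_model()].
#' @export
abc_model <- function() {
  ode_model(
    name = "abc_chain",
    states = c("A", "B", "C"),
    parameters = c(theta1 = 0.05, theta2 = 0.1, theta3 = 1),
    rhs = c(A = "-theta1 * A",
            B = "theta1 * A - theta2 * B",
            C = "theta2 * B"),
    observables = c(C = "C"),
    initial_values = list(A = "theta3", B = 0, C = 0),
    noise_sd = c(C = 0.1)
  )
}

#' Measurement designs for the chain model
#'
#' The `"full"` design observes C at t = 0, 10, ..., 100 and covers the
#' saturation of C; all three states are then practically observable.  The
#' `"short"` design observes C at t = 0, 2, ..., 20, sampling only the
#' transient rise of C: the total amount (the concentration dimension of
#' the parameters) is then practically non-identifiable and A and B become
#' non-observable.
#'
#' @param which `"full"` or `"short"`.
#' @return An [experimental_design()].
#' @export
abc_design <- function(which = c("full", "short")) {
  which <- match.arg(which)
  times <- if (which == "full") seq(0, 100, by = 10) else seq(0, 20, by = 2)
  experimental_design(times, observables = "C")
}

#' Closed-form solution of the chain model
#'
#' Analytic trajectory of the linear chain, used as an integration oracle:
#' A = theta3 exp(-theta1 t),
#' B = theta3 theta1 / (theta2 - theta1) (exp(-theta1 t) - exp(-theta2 t)),
#' C = theta3 - A - B.
#'
#' @param theta Parameter vector `(theta1, theta2, theta3)`.
#' @param t Time point(s).
#' @return Matrix with columns `A`, `B`, `C` (one row per time).  Refuses
#'   the degenerate case theta1 == theta2.
#' @export
abc_closed_form <- function(theta, t) {
  theta <- stats::setNames(as.numeric(theta), NULL)
  if (length(theta) != 3L) stop_config("theta must have length 3")
  if (theta[1] == theta[2])
    stop_config("degenerate case theta1 == theta2 is not supported")
  A <- theta[3] * exp(-theta[1] * t)
  B <- theta[3] * theta[1] / (theta[2] - theta[1]) *
    (exp(-theta[1] * t) - exp(-theta[2] * t))
  cbind(A = A, B = B, C = theta[3] - A - B)
}

#' MAP kinase cascade model with negative feedback
#'
#' Eight-state Michaelis-Menten model of the Raf -> Mek -> Erk cascade:
#' Raf is activated to Raf* (inhibited by doubly phosphorylated Erk** --
#' the negative feedback), Raf* drives the two phosphorylation steps
#' Mek -> Mek* -> Mek**, and Mek** drives Erk -> Erk* -> Erk**;
#' phosphatases reverse every step.  As is conventional for this cascade,
#' the parameters of the two consecutive phosphorylation steps of Mek and
#' of Erk are identical (likewise the dephosphorylation steps), and the
#' initial concentrations are known (Raf 100 nM, Mek 300 nM, Erk 300 nM,
#' all unphosphorylated), leaving 14 free parameters.  Default rate values
#' follow the published parameterization of this cascade (maximal rates in
#' nM/s, Michaelis and inhibition constants in nM); they are synthetic
#' stand-ins for test purposes and can be overridden via the returned
#' model's `parameters`.
#'
#' Measured are the phosphorylated forms, as with phospho-specific
#' antibodies: Raf*, Mek* + Mek**, Erk* + Erk**, each with sigma = 10 nM.
#'
#' @return An [ode_model()].
#' @export
mapk_model <- function() {
  ode_model(
    name = "mapk_cascade",
    states = c("Raf", "Raf_p", "Mek", "Mek_p", "Mek_pp",
               "Erk", "Erk_p", "Erk_pp"),
    parameters = c(
      V1 = 2.5, Ki = 9, n_fb = 1, K1 = 10,   # Raf activation + feedback
      V2 = 0.25, K2 = 8,                     # Raf* dephosphorylation
      k3 = 0.025, K3 = 15,                   # Mek (de)phosphorylation by Raf*
      V5 = 0.75, K5 = 15,
      k7 = 0.025, K7 = 15,                   # Erk (de)phosphorylation by Mek**
      V9 = 0.5, K9 = 15
    ),
    rates = list(
      v1 = "V1 * Raf / ((1 + (Erk_pp / Ki)^n_fb) * (K1 + Raf))",
      v2 = "V2 * Raf_p / (K2 + Raf_p)",
      v3 = "k3 * Raf_p * Mek / (K3 + Mek)",
      v4 = "k3 * Raf_p * Mek_p / (K3 + Mek_p)",
      v5 = "V5 * Mek_pp / (K5 + Mek_pp)",
      v6 = "V5 * Mek_p / (K5 + Mek_p)",
      v7 = "k7 * Mek_pp * Erk / (K7 + Erk)",
      v8 = "k7 * Mek_pp * Erk_p / (K7 + Erk_p)",
      v9 = "V9 * Erk_pp / (K9 + Erk_pp)",
      v10 = "V9 * Erk_p / (K9 + Erk_p)"
    ),
    rhs = c(
      Raf = "v2 - v1",
      Raf_p = "v1 - v2",
      Mek = "v6 - v3",
      Mek_p = "v3 + v5 - v4 - v6",
      Mek_pp = "v4 - v5",
      Erk = "v10 - v7",
      Erk_p = "v7 + v9 - v8 - v10",
      Erk_pp = "v8 - v9"
    ),
    observables = c(Raf_active = "Raf_p",
                    Mek_active = "Mek_p + Mek_pp",
                    Erk_active = "Erk_p + Erk_pp"),
    initial_values = list(Raf = 100, Raf_p = 0, Mek = 300, Mek_p = 0,
                          Mek_pp = 0, Erk = 300, Erk_p = 0, Erk_pp = 0),
    noise_sd = c(Raf_active = 10, Mek_active = 10, Erk_active = 10)
  )
}

#' Default measurement design for the MAP kinase model
#'
#' All three phospho-observables at t = 0, 100, ..., 1000 seconds
#' (3 x 11 = 33 data points).
#'
#' @return An [experimental_design()].
#' @export
mapk_design <- function() {
  experimental_design(seq(0, 1000, by = 100),
                      observables = c("Raf_active", "Mek_active",
                                      "Erk_active"))
}

#' Linear growth model y = theta1 * t
#'
#' One-state model with constant production (`dx/dt = theta1`, x(0) = 0),
#' so the observed response depends linearly on the single parameter.  For
#' linear-Gaussian problems the chi-square threshold is exact, making this
#' the analytic reference case for estimator, profile and coverage
#' behavior; see [linear_oracle()] for the closed forms.
#'
#' @param theta1 Default production rate.
#' @param sigma Measurement noise SD.
#' @return An [ode_model()].
#' @export
linear_model <- function(theta1 = 0.1, sigma = 1) {
  ode_model(
    name = "linear_growth",
    states = "x",
    parameters = c(theta1 = theta1),
    rhs = c(x = "theta1"),
    observables = c(y = "x"),
    initial_values = list(x = 0),
    noise_sd = c(y = sigma)
  )
}

#' Closed forms for the linear-Gaussian reference problem
#'
#' For data y_i = theta t_i + eps_i with known sigma, the weighted
#' least-squares estimator is theta_hat = sum(t_i y_i) / sum(t_i^2) with
#' standard error sigma / sqrt(sum t_i^2).  A prediction z = theta t0 has
#' standard error se = sigma |t0| / sqrt(sum t_i^2); the profile-based
#' prediction interval has half-width sqrt(qchisq(alpha, 1)) se and the
#' validation interval for a future measurement with error SD has
#' half-width sqrt(qchisq(alpha, 1)) sqrt(se^2 + SD^2).
#'
#' @param times Measurement times (sum of squares must be positive).
#' @param sigma Measurement noise SD.
#' @param theta_true True parameter (used by `z_true`).
#' @param alpha Confidence level.
#' @param sd Validation measurement error (0 allowed: then VCI = PCI).
#' @return List of closed-form quantities and functions: `St2`,
#'   `theta_se`, `theta_hat(y)`, `z_true(t0)`, `se(t0)`, `pci_half(t0)`,
#'   `vci_half(t0)`.
#' @export
linear_oracle <- function(times, sigma, theta_true, alpha = 0.9, sd = 0) {
  St2 <- sum(times^2)
  if (St2 <= 0) stop_config("sum(times^2) must be > 0")
  q <- stats::qchisq(alpha, 1)
  se <- function(t0) sigma * abs(t0) / sqrt(St2)
  list(
    St2 = St2,
    theta_se = sigma / sqrt(St2),
    theta_hat = function(y) sum(times * y) / St2,
    z_true = function(t0) theta_true * t0,
    se = se,
    pci_half = function(t0) sqrt(q) * se(t0),
    vci_half = function(t0) sqrt(q) * sqrt(se(t0)^2 + sd^2)
  )
}
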