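## Independent oracles and shared fixtures.  Everything here is deliberately
## naive (dense summation, plain bisection) and shares no code path with the
## package internals it checks.

## dense brute-force expectation: exact loop over all n, Simpson rule on a
## fine log-spaced metabolic-rate grid.  Only viable for small communities.
brute_expectation <- function(weight_fn, lambda, state, params, beta,
                              eps_max = NULL, eps_points = 4001) {
  lambda <- as.numeric(lambda)
  U <- round(state$N)
  if (is.null(eps_max)) eps_max <- 50 / (abs(lambda[2]) + 1e-12)
  ## Simpson on a log grid: substitute eps = e^u so d eps = eps du
  u <- seq(0, log(eps_max), length.out = eps_points)
  eps <- exp(u)
  du <- u[2] - u[1]
  sw <- c(1, rep(c(4, 2), length.out = eps_points - 2), 1) * du / 3
  num <- 0; den <- 0
  n <- seq_len(U)
  for (i in seq_along(eps)) {
    lw <- -lambda[1] * n - lambda[2] * n * eps[i] -
      lambda[3] * f_rate(n, eps[i], state, params) -
      lambda[4] * h_rate(n, eps[i], state, params, beta) -
      lambda[5] * q_rate(n, eps[i], state, params)
    b <- exp(lw) * eps[i] * sw[i]          # jacobian eps from the log grid
    num <- num + sum(weight_fn(n, eps[i]) * b)
    den <- den + sum(b)
  }
  num / den
}

## plain bisection on the finite-sum abundance relation
oracle_beta_exact <- function(S, N) {
  g <- function(b) { n <- 1:N; w <- exp(-b * n); (S / N) * sum(w) - sum(w / n) }
  lo <- 1e-8; hi <- 1
  for (i in 1:200) { mid <- sqrt(lo * hi); if (g(mid) > 0) lo <- mid else hi <- mid }
  lo
}

## plain bisection on beta * ln(1/beta) = ratio
oracle_beta_approx <- function(ratio) {
  g <- function(b) b * log(1 / b) - ratio
  lo <- 1e-12; hi <- exp(-1)
  for (i in 1:200) { mid <- sqrt(lo * hi); if (g(mid) < 0) lo <- mid else hi <- mid }
  lo
}

## a small synthetic community for brute-force comparisons
small_state <- function() community_state(S = 12, N = 360, E = 4200)

small_params <- function() {
  transition_params(b0 = 0.3, d0 = 0.25, m0 = 5, w0 = 1.1, w10 = 0.35,
                    Ec = 5500, mu = 0.05)
}

## reference configuration used throughout
bci_sol <- function() static_solution(bci_state())

## printed perturbation table for the reference forest (four columns):
## endpoint states, endpoint derivatives and fitted multipliers
published_perturbations <- function() {
  list(
    m0_0 = list(disturb = "m0=0",
                state = c(S = 314.2, N = 217962, E = 2.0380e7),
                derivs = c(dS_dt = -0.242, dN_dt = -418, dE_dt = -4349),
                lambda = c(0.00037020, 1.4717e-5, 0.074392, -1.5435e-5,
                           -0.0049918)),
    d0_25 = list(disturb = "d0=0.25",
                 state = c(S = 319.6, N = 144430, E = 1.7331e7),
                 derivs = c(dS_dt = -0.009, dN_dt = -1052, dE_dt = -112262),
                 lambda = c(0.0023398, 9.6690e-6, 0.16739, -0.00019515,
                            -0.015078)),
    w0_95 = list(disturb = "w0=0.95",
                 state = c(S = 320.8, N = 262537, E = 1.8280e7),
                 derivs = c(dS_dt = 0.0246, dN_dt = 2350, dE_dt = -48162),
                 lambda = c(-0.0073972, 0.000054585, 0.58409, 0.00050473,
                            -0.27931)),
    comb = list(disturb = c("mu=0.024", "m0=200", "d0=0.235", "w0=0.99"),
                state = c(S = 314.9, N = 166984, E = 1.7822e7),
                derivs = c(dS_dt = -0.196, dN_dt = -758, dE_dt = -88709),
                lambda = c(0.0014027, 0.000012665, 0.16072, -0.00010897,
                           -0.0091964)))
}

expect_rel <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * abs(expected)),
              label = sprintf("%.8g vs %.8g (rel tol %g)", actual[1],
                              expected[1], tol))
}
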