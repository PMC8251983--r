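## The truncated first-iteration procedure: freeze the static structure
## function at t = 0, perturb the rate parameters, run the state variables
## forward under the frozen-multiplier derivative equations, then refit all
## five Lagrange multipliers to the endpoint constraints.

#' Frozen-multiplier context
#'
#' Captures everything that stays fixed during a frozen-multiplier run: the
#' static solution at the pre-perturbation state and the five frozen
#' per-species expectation constants
#' `E[n], E[n eps], E[n/eps^(1/3)], E[n eps^(2/3)], E[delta(n,1)/eps^(1/3)]`
#' over the frozen two-multiplier structure function, together with the
#' perturbed rate parameters.  The state dependence of the derivative
#' equations then enters only through the explicit prefactors of the
#' transition functions (and, by default, through the state-derived `beta`
#' inside the growth-loss coefficient of `h` — the multipliers are frozen,
#' but `beta(S, N)` is a state quantity that updates with the state
#' variables).
#'
#' @param state0 Pre-perturbation [community_state()] (the steady state).
#' @param params Perturbed [transition_params()] (in force from t = 0).
#' @param constants `"closed_form"` (default) evaluates the frozen averages
#'   with the closed-form Beta-function brackets the steady-state calibration
#'   is built on; `"quadrature"` computes them by exact summation/quadrature
#'   over the frozen structure function.
#' @param update_beta Should the `ln^(2/3)(1/beta)` factor inside `h` track
#'   the evolving state (default `TRUE`)?  `FALSE` freezes it at the static
#'   value, for sensitivity analysis.
#' @param quad [quad_config()] (used by the quadrature constants).
#' @return An object of class `frozen_context`.
#' @export
frozen_context <- function(state0, params, constants = c("closed_form",
                                                         "quadrature"),
                           update_beta = TRUE, quad = quad_config()) {
  constants <- match.arg(constants)
  state0 <- as_community_state(state0)
  sol <- static_solution(state0)
  S0 <- state0$S; N0 <- state0$N; E0 <- state0$E
  if (constants == "closed_form") {
    br <- si_brackets(S0, N0, E0, sol$log_inv_beta)
    k <- list(n = N0 / S0, ne = E0 / S0,
              f1 = br$bracket_N / S0,
              h1 = br$bracket_E / S0,
              xd = br$ext_kernel / S0)
  } else {
    lam <- static_lagrange(sol)
    ws <- list(weight_abundance(), weight_energy(),
               dyn_weight(v = function(e) e^(-1 / 3)),
               dyn_weight(v = function(e) e^(2 / 3)),
               dyn_weight(d = function(e) e^(-1 / 3)))
    pass <- engine_pass(lam, state0, params, sol$beta, weights = ws,
                        quad = quad)
    k <- list(n = pass$values[1], ne = pass$values[2], f1 = pass$values[3],
              h1 = pass$values[4], xd = pass$values[5])
  }
  structure(list(state0 = state0, sol = sol, params = params,
                 constants = constants, k = k, update_beta = update_beta),
            class = "frozen_context")
}

#' Frozen-multiplier state-variable derivatives
#'
#' The derivative equations of the truncated first iteration:
#' `dN/dt = S E[f]`, `dE/dt = S E[h]`, `dS/dt = E[q]`, with the expectations
#' taken over the frozen static structure function and the transition
#' functions evaluated at the current state and the perturbed parameters.
#'
#' @param state Current [community_state()].
#' @param ctx A [frozen_context()].
#' @return A `derivative_vector` (`dN_dt`, `dE_dt`, `dS_dt`).
#' @export
frozen_derivatives <- function(state, ctx) {
  state <- as_community_state(state)
  par <- ctx$params
  S <- state$S; N <- state$N; E <- state$E
  ratio <- E / par$Ec
  k <- ctx$k
  bcur <- if (ctx$update_beta) solve_beta_approx(S, N) else ctx$sol$beta
  imm <- par$m0 * S * k$n / N
  dN <- (par$b0 - par$d0 * ratio) * S * k$f1 + imm
  dE <- (par$w0 - par$d0 * ratio) * S * k$h1 -
    w1_effective(par, bcur) * S * k$ne + imm
  dS <- par$m0 * exp(-par$mu * S - EULER_GAMMA) +
    par$sigma1 * par$K * S / (par$K + S) +
    par$sigma2 * par$b0 * S * k$f1 -
    par$d0 * ratio * S * k$xd
  structure(c(dN_dt = dN, dE_dt = dE, dS_dt = dS),
            class = "derivative_vector")
}

#' Frozen-multiplier trajectory
#'
#' Integrates [frozen_derivatives()] from the pre-perturbation state over a
#' horizon `T` (default 25 years).  The default integrator is explicit Euler
#' with a one-year step — the convention of the iteration scheme (`dt = 1`
#' with integer step index); 4th-order Runge-Kutta is available and the two
#' agree closely (the dynamics are slow on the yearly scale).
#'
#' @param ctx A [frozen_context()].
#' @param T Horizon in years.
#' @param dt Step (years).
#' @param method `"euler"` (default) or `"rk4"`.
#' @return A `dyna_trajectory` with attribute `endpoint`: a list with the
#'   endpoint `state` and `derivs` (the constraints for the MaxEnt refit).
#' @examples
#' \donttest{
#' ctx <- frozen_context(bci_state(), modifyList(bci_params(), list(m0 = 0)))
#' tr <- frozen_trajectory(ctx)
#' attr(tr, "endpoint")$state
#' }
#' @export
frozen_trajectory <- function(ctx, T = 25, dt = 1,
                              method = c("euler", "rk4")) {
  method <- match.arg(method)
  if (T <= 0 || dt <= 0) stop("T and dt must be positive", call. = FALSE)
  x <- c(ctx$state0$S, ctx$state0$N, ctx$state0$E)
  times <- seq(0, T, by = dt)
  if (times[length(times)] < T) times <- c(times, T)
  rows <- matrix(NA_real_, length(times), 7)
  rhs <- function(x) {
    d <- frozen_derivatives(community_state(x[1], x[2], x[3]), ctx)
    c(d[["dS_dt"]], d[["dN_dt"]], d[["dE_dt"]])
  }
  for (i in seq_along(times)) {
    d <- rhs(x)
    rows[i, ] <- c(times[i], x, d)
    if (i == length(times)) break
    h <- times[i + 1] - times[i]
    if (method == "euler") {
      x <- x + h * d
    } else {
      k1 <- d
      k2 <- rhs(x + h / 2 * k1)
      k3 <- rhs(x + h / 2 * k2)
      k4 <- rhs(x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (any(!is.finite(x)) || any(x <= 0))
      stop("frozen trajectory blow-up: state left (0, Inf)", call. = FALSE)
  }
  res <- data.frame(t = rows[, 1], S = rows[, 2], N = rows[, 3], E = rows[, 4],
                    dS_dt = rows[, 5], dN_dt = rows[, 6], dE_dt = rows[, 7])
  res$beta <- vapply(seq_len(nrow(res)),
                     function(i) solve_beta_approx(res$S[i], res$N[i]),
                     numeric(1))
  class(res) <- c("dyna_trajectory", "data.frame")
  endstate <- community_state(rows[nrow(rows), 2], rows[nrow(rows), 3],
                              rows[nrow(rows), 4])
  attr(res, "endpoint") <- list(
    state = endstate,
    derivs = structure(c(dN_dt = rows[nrow(rows), 6],
                         dE_dt = rows[nrow(rows), 7],
                         dS_dt = rows[nrow(rows), 5]),
                       class = "derivative_vector"))
  res
}

#' Perturbed structure function from endpoint constraints
#'
#' Takes the endpoint state and derivatives of a frozen-multiplier run as the
#' five constraints and solves the MaxEnt problem for the five-multiplier
#' structure function (delegating to [fit_lambdas()]), with the transition
#' functions evaluated at the endpoint state and the perturbed parameters.
#' `beta` inside `h` is solved from the endpoint `(S, N)` by default,
#' consistently with the transition functions being functions of the current
#' state.
#'
#' @param state_T Endpoint [community_state()].
#' @param derivs_T Endpoint `derivative_vector` (or list with `dN_dt`,
#'   `dE_dt`, `dS_dt`).
#' @param ctx The [frozen_context()] of the run.
#' @param beta `"endpoint"` (default), `"frozen"`, or a number.
#' @param quad,control Passed to [fit_lambdas()].
#' @return A [lagrange_vector()] (attributes: residuals, achieved,
#'   iterations, plus `beta` and `state` used).
#' @export
perturbed_structure <- function(state_T, derivs_T, ctx,
                                beta = c("endpoint", "frozen"),
                                quad = quad_config(), control = list()) {
  state_T <- as_community_state(state_T)
  b <- if (is.numeric(beta)) beta
  else switch(match.arg(beta),
              endpoint = solve_beta_approx(state_T$S, state_T$N),
              frozen = ctx$sol$beta)
  targets <- constraint_vector(state_T, derivs = as.list(derivs_T))
  lam <- fit_lambdas(targets, state_T, ctx$params, b,
                     init = static_lagrange(ctx$sol), quad = quad,
                     control = control)
  attr(lam, "beta") <- b
  attr(lam, "state") <- state_T
  lam
}

#' First-iteration perturbation analysis
#'
#' Convenience wrapper running the whole truncated procedure for a
#' disturbance: freeze the static structure function at the reference state,
#' apply the parameter changes, integrate to `T = 25`, refit the five
#' multipliers to the endpoint constraints, and (optionally) derive the
#' perturbed abundance and metabolic-rate distributions with their static
#' overlays.
#'
#' @param state0 Pre-perturbation state (default [bci_state()]).
#' @param params Undisturbed parameters (default [bci_params()]).
#' @param disturbances Parameter changes applied at t = 0 (strings or
#'   [disturbance()]s).
#' @param T Horizon (years), default 25.
#' @param metrics Also compute [perturbed_metrics()]? (slower).
#' @param ... Passed to [frozen_context()].
#' @return List with `trajectory`, `state`, `derivs`, `lambda`, and
#'   optionally `metrics`.
#' @export
first_iteration <- function(state0 = bci_state(), params = bci_params(),
                            disturbances = NULL, T = 25, metrics = FALSE,
                            ...) {
  pert <- params_at_time(params, as_disturbance_list(disturbances), t = 0)
  ctx <- frozen_context(state0, pert, ...)
  tr <- frozen_trajectory(ctx, T = T)
  ep <- attr(tr, "endpoint")
  lam <- perturbed_structure(ep$state, ep$derivs, ctx)
  out <- list(trajectory = tr, state = ep$state, derivs = ep$derivs,
              lambda = lam, context = ctx)
  if (metrics) out$metrics <- perturbed_metrics(lam, ep$state, ctx)
  out
}

#' Perturbed macroecological metrics
#'
#' Marginals of the perturbed five-multiplier structure function — the
#' species abundance distribution and the metabolic rate distribution over
#' individuals — together with the matching static (log-series /
#' two-multiplier) curves for overlay, and the rank transforms at the
#' endpoint `S` (abundance ranks) and `N` (metabolism ranks).
#'
#' @param lambda A [lagrange_vector()] from [perturbed_structure()].
#' @param state_T Endpoint state.
#' @param ctx The [frozen_context()].
#' @param quad A [quad_config()].
#' @param n_max Largest abundance tabulated explicitly in the SAD.
#' @return A list: `sad` (n, phi_perturbed, phi_static), `mrdi`
#'   (epsilon, psi_perturbed, psi_static), `rank_abundance`,
#'   `rank_metabolism` (each with perturbed and static columns).
#' @export
perturbed_metrics <- function(lambda, state_T, ctx, quad = quad_config(),
                              n_max = 4096) {
  state_T <- as_community_state(state_T)
  b <- attr(lambda, "beta")
  if (is.null(b)) b <- solve_beta_approx(state_T$S, state_T$N)
  pert <- marginals(lambda, state_T, ctx$params, b, quad = quad,
                    n_max = n_max)
  stat <- marginals(static_lagrange(ctx$sol), state_T, ctx$params,
                    ctx$sol$beta, quad = quad, n_max = n_max)
  list(
    sad = data.frame(n = pert$sad$n, phi_perturbed = pert$sad$phi,
                     phi_static = stat$sad$phi),
    mrdi = data.frame(epsilon = pert$mrdi$epsilon,
                      psi_perturbed = pert$mrdi$psi,
                      psi_static = approx(stat$mrdi$epsilon, stat$mrdi$psi,
                                          xout = pert$mrdi$epsilon,
                                          rule = 2)$y),
    rank_abundance = data.frame(rank = pert$rank_abundance$rank,
                                n_perturbed = pert$rank_abundance$n,
                                n_static = stat$rank_abundance$n),
    rank_metabolism = data.frame(rank = pert$rank_metabolism$rank,
                                 eps_perturbed = pert$rank_metabolism$epsilon,
                                 eps_static = stat$rank_metabolism$epsilon))
}
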