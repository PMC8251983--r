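## The general iteration engine: alternate state updates, transition-function
## updates, derivative updates (with the previous step's multipliers) and
## five-constraint MaxEnt refits, for arbitrarily many steps.

#' Initialise an iteration record
#'
#' Step 0 of the iteration: the pre-perturbation static structure function
#' (multipliers `(lambda1_s, lambda2_s, 0, 0, 0)`), with derivatives obtained
#' by averaging the (possibly already perturbed) transition functions over
#' it.
#'
#' @param state0 Initial [community_state()].
#' @param params [transition_params()] in force at step 0 (perturbed values
#'   if a disturbance is imposed at t = 0).
#' @param quad A [quad_config()].
#' @return An `iteration_record`: list with `i`, `state`, `lambda`, `beta`,
#'   `derivs`, `residuals`.
#' @export
dyna_init <- function(state0, params, quad = quad_config()) {
  state0 <- as_community_state(state0)
  sol <- static_solution(state0)
  lam <- static_lagrange(sol)
  ach <- achieved_constraints(lam, state0, params, sol$beta, quad)
  structure(list(i = 0L, state = state0, lambda = lam, beta = sol$beta,
                 derivs = structure(c(dN_dt = state0$S * ach[["dn_per_s"]],
                                      dE_dt = state0$S * ach[["de_per_s"]],
                                      dS_dt = ach[["ds"]]),
                                    class = "derivative_vector"),
                 residuals = NULL),
            class = "iteration_record")
}

#' One step of the general iteration
#'
#' Implements the literal update ordering of the iteration scheme:
#' 1. state update `X_{i+1} = X_i + (dX_i/dt) dt` (explicit Euler);
#' 2. transition functions updated by substituting `X_{i+1}` (and the step's
#'    parameters `c_{i+1}`, including the state-derived `beta`);
#' 3. derivatives at `i+1` from averages over the structure function whose
#'    multipliers are still those of step `i`;
#' 4. a five-constraint MaxEnt refit at the new constraints, warm-started at
#'    the step-`i` multipliers.
#'
#' With `refit_first = TRUE` the refit instead precedes the derivative
#' update within the step (the alternative reading of the update order).
#'
#' @param rec An `iteration_record`.
#' @param params [transition_params()] for the new step.
#' @param dt Step length (years).
#' @param quad A [quad_config()].
#' @param refit Fit the multipliers at the new constraints (default `TRUE`;
#'   `FALSE` leaves the old multipliers in place, i.e. the frozen scheme).
#' @param refit_first See above.
#' @param on_nonconvergence `"abort"` (default) raises the fit error;
#'   `"carry"` keeps the previous multipliers for the step and records the
#'   failure in the `refit_ok` field.  The mixed constraint vector the
#'   literal update ordering produces (new-state ratios with
#'   previous-multiplier derivative averages) can leave the feasible moment
#'   region as the state drifts, in which case no multiplier vector attains
#'   it; `"carry"` lets long runs continue across such steps.
#' @param control Passed to [fit_lambdas()].
#' @return The next `iteration_record`.
#' @export
dyna_step <- function(rec, params, dt = 1, quad = quad_config(),
                      refit = TRUE, refit_first = FALSE,
                      on_nonconvergence = c("abort", "carry"),
                      control = list()) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  d <- rec$derivs
  x1 <- community_state(rec$state$S + d[["dS_dt"]] * dt,
                        rec$state$N + d[["dN_dt"]] * dt,
                        rec$state$E + d[["dE_dt"]] * dt)
  beta1 <- solve_beta_approx(x1$S, x1$N)

  derivs_at <- function(lam) {
    ach <- achieved_constraints(lam, x1, params, beta1, quad)
    structure(c(dN_dt = x1$S * ach[["dn_per_s"]],
                dE_dt = x1$S * ach[["de_per_s"]],
                dS_dt = ach[["ds"]]), class = "derivative_vector")
  }

  do_fit <- function(targets) {
    res <- try(fit_lambdas(targets, x1, params, beta1, init = rec$lambda,
                           quad = quad, control = control), silent = TRUE)
    if (inherits(res, "try-error")) {
      if (on_nonconvergence == "abort")
        stop(attr(res, "condition")$message, call. = FALSE)
      return(NULL)
    }
    res
  }
  refit_ok <- NA
  if (refit && refit_first) {
    d_prev <- derivs_at(rec$lambda)
    lam1 <- do_fit(constraint_vector(x1, derivs = as.list(d_prev)))
    refit_ok <- !is.null(lam1)
    if (is.null(lam1)) lam1 <- rec$lambda
    d1 <- derivs_at(lam1)
  } else {
    d1 <- derivs_at(rec$lambda)
    if (refit) {
      lam1 <- do_fit(constraint_vector(x1, derivs = as.list(d1)))
      refit_ok <- !is.null(lam1)
      if (is.null(lam1)) lam1 <- rec$lambda
    } else lam1 <- rec$lambda
  }
  structure(list(i = rec$i + 1L, state = x1, lambda = lam1, beta = beta1,
                 derivs = d1, refit_ok = refit_ok,
                 residuals = attr(lam1, "residuals")),
            class = "iteration_record")
}

#' Run the general iteration
#'
#' Iterates [dyna_step()] from the static pre-perturbation solution, with a
#' disturbance schedule applied by step time, until `n_steps` steps have run
#' or every relative state derivative has fallen below the equilibrium
#' tolerance.
#'
#' @param state0 Initial state.
#' @param params Undisturbed parameters.
#' @param disturbances Disturbance schedule (applied at step times).
#' @param n_steps Maximum number of steps.
#' @param dt Step length (years).
#' @param equilibrium_tol Relative-derivative threshold for early stopping
#'   (`NULL` to disable).
#' @param quad,control,refit,refit_first,on_nonconvergence Passed to
#'   [dyna_step()].
#' @return List of `iteration_record`s (including the initial one), of class
#'   `dyna_run`.  On a mid-run failure the records up to the failure are
#'   returned with attribute `error`.
#' @export
dyna_run <- function(state0, params, disturbances = NULL, n_steps = 25,
                     dt = 1, equilibrium_tol = 1e-7, quad = quad_config(),
                     refit = TRUE, refit_first = FALSE,
                     on_nonconvergence = c("abort", "carry"),
                     control = list()) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  sched <- as_disturbance_list(disturbances)
  rec <- dyna_init(state0, params_at_time(params, sched, 0), quad)
  records <- list(rec)
  err <- NULL
  for (i in seq_len(n_steps)) {
    pstep <- params_at_time(params, sched, i * dt)
    nxt <- try(dyna_step(rec, pstep, dt = dt, quad = quad, refit = refit,
                         refit_first = refit_first,
                         on_nonconvergence = on_nonconvergence,
                         control = control),
               silent = TRUE)
    if (inherits(nxt, "try-error")) {
      err <- attr(nxt, "condition")$message
      break
    }
    rec <- nxt
    records[[length(records) + 1]] <- rec
    if (!is.null(equilibrium_tol)) {
      d <- rec$derivs
      rel <- c(abs(d[["dS_dt"]]) / max(rec$state$S, 1),
               abs(d[["dN_dt"]]) / rec$state$N,
               abs(d[["dE_dt"]]) / rec$state$E)
      if (max(rel) < equilibrium_tol) break
    }
  }
  class(records) <- "dyna_run"
  attr(records, "dt") <- dt
  if (!is.null(err)) attr(records, "error") <- err
  records
}

#' @export
as.data.frame.dyna_run <- function(x, ...) {
  dt <- attr(x, "dt")
  out <- do.call(rbind, lapply(x, function(r) {
    data.frame(i = r$i, t = r$i * dt, S = r$state$S, N = r$state$N,
               E = r$state$E, dS_dt = r$derivs[["dS_dt"]],
               dN_dt = r$derivs[["dN_dt"]], dE_dt = r$derivs[["dE_dt"]],
               beta = r$beta, lambda1 = r$lambda[1], lambda2 = r$lambda[2],
               lambda3 = r$lambda[3], lambda4 = r$lambda[4],
               lambda5 = r$lambda[5],
               refit_ok = if (is.null(r$refit_ok)) NA else r$refit_ok)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.dyna_run <- function(x, ...) {
  cat(sprintf("general iteration run: %d records (dt = %g yr)\n",
              length(x), attr(x, "dt")))
  if (!is.null(attr(x, "error")))
    cat("  stopped early:", attr(x, "error"), "\n")
  print(utils::tail(as.data.frame(x)[, 1:9], 3))
  invisible(x)
}
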