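## Expectations over the (possibly five-multiplier) structure function
##
##   R(n, eps) = exp(-l1 n - l2 n eps - l3 f - l4 h - l5 q) / Z
##
## on the support n in 1..N (discrete), eps in [1, Inf) (continuous).  Because
## f and h are linear in n and q is (constant + linear in n + a delta at
## n = 1), the exponent collapses to  -A(eps) * n - l5 qd(eps) delta_{n,1}
## (plus a constant), and all n-sums of 1, n and n^2 against exp(-A n) have
## closed geometric forms over the full finite support.  The eps axis is then
## a one-dimensional quadrature.  This makes partition sums, constraint
## expectations and marginals exact in n and cheap enough for Newton fits.

## ---- stable geometric sums -------------------------------------------------

## G0 = sum_{n=1}^{U} x^n, G1 = sum n x^n, G2 = sum n^2 x^n, with x = exp(-A).
## Stable for A down to ~1e-12 via expm1; valid for moderately negative A too
## (finite sums), which the engine permits only below the exponent cap.
geom_sums <- function(A, U, order = 2) {
  x <- exp(-A)
  em1 <- -expm1(-A)            # 1 - x
  emU <- -expm1(-A * U)        # 1 - x^U
  xU <- exp(-A * U)
  G0 <- x * emU / em1
  out <- list(G0 = G0)
  if (order >= 1) {
    ## G1 = x (1 - (U+1) x^U + U x^{U+1}) / (1-x)^2
    num1 <- 1 - (U + 1) * xU + U * xU * x
    out$G1 <- x * num1 / em1^2
  }
  if (order >= 2) {
    ## G2 = x (1 + x - (U+1)^2 x^U + (2U^2+2U-1) x^{U+1} - U^2 x^{U+2}) / (1-x)^3
    num2 <- 1 + x - (U + 1)^2 * xU + (2 * U^2 + 2 * U - 1) * xU * x -
      U^2 * xU * x^2
    out$G2 <- x * num2 / em1^3
  }
  out
}

## ---- weights ---------------------------------------------------------------

#' Structure-function weights
#'
#' The expectation engine integrates weights of the form
#' `w(n, eps) = u(eps) + v(eps) * n + d(eps) * delta(n, 1)`, which covers every
#' quantity the theory needs (`n`, `n*eps`, the transition functions, biomass
#' kernels, ...).  `dyn_weight()` builds such a weight from its component
#' functions; `weight_abundance()`, `weight_energy()` and
#' `weight_transition()` are the canned constraint weights.
#'
#' @param u,v,d Functions of `eps` (or `NULL` for zero): the n-constant,
#'   n-linear and delta(n=1) components.
#' @return An object of class `dyn_weight`.
#' @export
dyn_weight <- function(u = NULL, v = NULL, d = NULL) {
  structure(list(u = u, v = v, d = d), class = "dyn_weight")
}

#' @rdname dyn_weight
#' @export
weight_abundance <- function() dyn_weight(v = function(eps) rep(1, length(eps)))

#' @rdname dyn_weight
#' @export
weight_energy <- function() dyn_weight(v = function(eps) eps)

#' @rdname dyn_weight
#' @param which One of `"f"`, `"h"`, `"q"`.
#' @param state,params,beta Evaluation context for the transition functions.
#' @export
weight_transition <- function(which = c("f", "h", "q"), state, params, beta) {
  which <- match.arg(which)
  switch(which,
         f = dyn_weight(v = function(eps)
           transition_coefs(eps, state, params, beta)$cf),
         h = dyn_weight(v = function(eps)
           transition_coefs(eps, state, params, beta)$ch),
         q = dyn_weight(
           u = function(eps) {
             co <- transition_coefs(eps, state, params, beta)
             rep(co$q0, length(eps))
           },
           v = function(eps) transition_coefs(eps, state, params, beta)$cq,
           d = function(eps) transition_coefs(eps, state, params, beta)$qd))
}

## evaluate a dyn_weight's components at eps nodes
eval_weight <- function(w, eps) {
  zero <- numeric(length(eps))
  list(u = if (is.null(w$u)) zero else w$u(eps),
       v = if (is.null(w$v)) zero else w$v(eps),
       d = if (is.null(w$d)) zero else w$d(eps))
}

## ---- Lagrange vectors ------------------------------------------------------

#' Lagrange multiplier vectors
#'
#' A five-component multiplier vector for the dynamic structure function:
#' `lambda1` and `lambda2` are conjugate to `N/S` and `E/S` as in the static
#' theory; `lambda3`, `lambda4`, `lambda5` are conjugate to the derivative
#' constraints `(1/S) dN/dt`, `(1/S) dE/dt` and `dS/dt`.  Setting the last
#' three to zero recovers the static solution.
#'
#' @param lambda1,lambda2,lambda3,lambda4,lambda5 Multiplier values (finite;
#'   `lambda3..5` may be negative).
#' @return A named numeric vector of class `lagrange`.
#' @export
lagrange_vector <- function(lambda1, lambda2, lambda3 = 0, lambda4 = 0,
                            lambda5 = 0) {
  lv <- c(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
          lambda4 = lambda4, lambda5 = lambda5)
  if (!all(is.finite(lv))) stop("multipliers must be finite", call. = FALSE)
  structure(lv, class = "lagrange")
}

#' @rdname lagrange_vector
#' @param sol A [static_solution()]; returns its two-multiplier vector with
#'   `lambda3..5 = 0`.
#' @export
static_lagrange <- function(sol) {
  lagrange_vector(sol$lambda1, sol$lambda2)
}

as_lagrange <- function(x) {
  if (inherits(x, "lagrange")) return(x)
  x <- as.numeric(x)
  if (length(x) == 2) x <- c(x, 0, 0, 0)
  if (length(x) != 5) stop("a Lagrange vector has 5 components", call. = FALSE)
  lagrange_vector(x[1], x[2], x[3], x[4], x[5])
}

#' Log-weight of the structure function
#'
#' The (unnormalised) log weight
#' `-l1 n - l2 n eps - l3 f(n,eps) - l4 h(n,eps) - l5 q(n,eps)` at a point of
#' the microstate space.  An error is raised if the magnitude exceeds the
#' configured exponent cap, which signals a non-normalisable multiplier set.
#'
#' @param n,eps Microstate coordinates (`n >= 1` integer, `eps >= 1`).
#' @param lambda A [lagrange_vector()] (or length-5 numeric).
#' @param state,params,beta Evaluation context for the transition functions.
#' @param quad A [quad_config()].
#' @return The log weight (vectorised over `n`, `eps`).
#' @export
log_weight <- function(n, eps, lambda, state, params, beta,
                       quad = quad_config()) {
  if (any(n < 1) || any(n != round(n)))
    stop("n must be integer >= 1", call. = FALSE)
  if (any(eps < 1)) stop("eps must be >= 1", call. = FALSE)
  l <- as_lagrange(lambda)
  co <- transition_coefs(eps, state, params, beta)
  A <- l[1] + l[2] * eps + l[3] * co$cf + l[4] * co$ch + l[5] * co$cq
  lw <- -A * n - l[5] * (co$q0 + co$qd * (n == 1))
  if (any(abs(lw) > quad$exponent_cap))
    stop("log-weight exceeds exponent cap: non-normalisable multiplier set",
         call. = FALSE)
  lw
}

## ---- the engine ------------------------------------------------------------

## One pass over the eps axis: returns Z_tilde (normalisation without the
## constant exp(-l5 q0) factor), the integrals of each requested weight, and
## optionally the per-node data needed by the marginals.
engine_pass <- function(lambda, state, params, beta, weights = list(),
                        quad = quad_config(), moments = FALSE,
                        keep_nodes = FALSE, n_panels = NULL) {
  l <- as_lagrange(lambda)
  U <- max(1, round(state$N))
  panel <- quad_panels(quad)
  ## a fixed panel count makes the integral smooth in lambda (used for
  ## finite-difference Jacobians); otherwise the walk stops adaptively
  npanels_total <- if (is.null(n_panels)) {
    quad$max_octaves * quad$panels_per_octave
  } else n_panels

  ## divergence screen: the large-eps behaviour of A is dominated by the
  ## n*eps multiplier and the linear term of ch
  a_lin <- unname(l[2] - l[4] * w1_effective(params, beta))
  if (a_lin <= 0)
    stop("divergent structure function: weight does not decay in eps",
         call. = FALSE)

  nw <- length(weights)
  Zt <- 0
  Zt_abs <- 0
  vals <- numeric(nw)
  vals_abs <- numeric(nw)   # absolute accumulations: tail criterion must not
                            # be fooled by cancelling integrands
  m2 <- numeric(nw * (nw + 1) / 2)   # upper-triangle cross moments
  nodes_eps <- list(); nodes_w <- list(); nodes_A <- list(); nodes_dfac <- list()
  done_tail <- FALSE

  for (j in seq_len(npanels_total)) {
    p <- panel(j)
    eps <- p$x
    co <- transition_coefs(eps, state, params, beta)
    A <- l[1] + l[2] * eps + l[3] * co$cf + l[4] * co$ch + l[5] * co$cq
    if (any(!is.finite(A)))
      stop("non-finite exponent in structure function", call. = FALSE)
    if (any(A <= 0))
      stop("divergent structure function: non-decaying weight at finite eps",
           call. = FALSE)
    g <- geom_sums(A, U, order = if (moments) 2 else 1)
    dexp <- -l[5] * co$qd
    if (any(abs(dexp) > quad$exponent_cap))
      stop("log-weight exceeds exponent cap: non-normalisable multiplier set",
           call. = FALSE)
    dfac <- expm1(dexp)                 # exp(-l5 qd) - 1
    e1 <- exp(-A)                       # n = 1 Boltzmann factor
    zint <- g$G0 + e1 * dfac
    Zt_j <- sum(p$w * zint)
    Zt <- Zt + Zt_j
    Zt_abs <- Zt_abs + abs(Zt_j)

    ok <- abs(Zt_j) <= quad$tail_rel * max(Zt_abs, 1e-300)
    wev <- lapply(weights, eval_weight, eps = eps)
    for (k in seq_len(nw)) {
      we <- wev[[k]]
      wint <- we$u * g$G0 + we$v * g$G1 +
        e1 * (dfac * (we$u + we$v) + (1 + dfac) * we$d)
      v_j <- sum(p$w * wint)
      vals[k] <- vals[k] + v_j
      vals_abs[k] <- vals_abs[k] + abs(v_j)
      if (abs(v_j) > quad$tail_rel * max(vals_abs[k], 1e-300)) ok <- FALSE
    }
    if (moments) {
      ## cross moments E[w_j w_k]: products of affine-in-n weights are
      ## quadratic in n (plus delta corrections at n = 1), so they too have
      ## exact n-sums.  These supply the analytic Hessian (weight covariance)
      ## of the MaxEnt dual.
      idx <- 0
      for (k in seq_len(nw)) for (kk in k:nw) {
        idx <- idx + 1
        wk <- wev[[k]]; wl <- wev[[kk]]
        w1k <- wk$u + wk$v + wk$d     # value at n = 1
        w1l <- wl$u + wl$v + wl$d
        xint <- wk$u * wl$u * g$G0 + (wk$u * wl$v + wl$u * wk$v) * g$G1 +
          wk$v * wl$v * g$G2 +
          e1 * ((1 + dfac) * w1k * w1l - (wk$u + wk$v) * (wl$u + wl$v))
        m2[idx] <- m2[idx] + sum(p$w * xint)
      }
    }
    if (keep_nodes) {
      nodes_eps[[j]] <- eps; nodes_w[[j]] <- p$w
      nodes_A[[j]] <- A; nodes_dfac[[j]] <- dfac
    }
    if (is.null(n_panels) && ok) { done_tail <- TRUE; break }
  }
  if (is.null(n_panels) && !done_tail)
    stop("quadrature failed to reach the exponential tail within max_octaves",
         call. = FALSE)
  n_panels_used <- j
  if (Zt <= 0 || !is.finite(Zt))
    stop("partition sum is not positive and finite", call. = FALSE)

  out <- list(Z_tilde = Zt, values = vals / Zt, q0_const = {
    co1 <- transition_coefs(1, state, params, beta); co1$q0
  }, lambda = l, U = U, n_panels = n_panels_used)
  if (moments) {
    ## unpack upper triangle into the symmetric E[w_j w_k] matrix
    M <- matrix(0, nw, nw)
    idx <- 0
    for (k in seq_len(nw)) for (kk in k:nw) {
      idx <- idx + 1
      M[k, kk] <- M[kk, k] <- m2[idx] / Zt
    }
    out$cross_moments <- M
    out$second_moments <- diag(M)
  }
  if (keep_nodes) {
    out$nodes <- list(eps = unlist(nodes_eps), w = unlist(nodes_w),
                      A = unlist(nodes_A), dfac = unlist(nodes_dfac))
  }
  out
}

#' Partition sum of the structure function
#'
#' The normalisation `Z` of the structure function for a given multiplier
#' vector, summing `n` exactly over `1..N` and integrating `eps` over
#' `[1, Inf)` with adaptive tail truncation.  For the static two-multiplier
#' case this approaches `ln(1/beta)/lambda2`.
#'
#' @inheritParams log_weight
#' @return `Z > 0`.
#' @export
partition_sum <- function(lambda, state, params, beta, quad = quad_config()) {
  l <- as_lagrange(lambda)
  pass <- engine_pass(l, state, params, beta, quad = quad)
  ## reinstate the constant factor from the n-independent part of q
  exp(-l[5] * pass$q0_const) * pass$Z_tilde
}

#' Expectation of a weight over the structure function
#'
#' Computes `E[w] = sum_{n,eps} w(n, eps) R(n, eps)` with `R` normalised by the
#' partition sum.  `weight` is either a [dyn_weight()] (exact in `n`, the
#' production path) or a plain `function(n, eps)`, in which case a dense
#' term-by-term summation over all `n` is used (available for small `N` only;
#' intended for validation).
#'
#' @param weight A [dyn_weight()] or a `function(n, eps)`.
#' @inheritParams log_weight
#' @return The expectation (a number).
#' @examples
#' st <- bci_state(); sol <- static_solution(st)
#' expectation(weight_abundance(), static_lagrange(sol), st, bci_params(),
#'             sol$beta)  # ~ N/S
#' @export
expectation <- function(weight, lambda, state, params, beta,
                        quad = quad_config()) {
  if (inherits(weight, "dyn_weight")) {
    pass <- engine_pass(lambda, state, params, beta, weights = list(weight),
                        quad = quad)
    return(pass$values[1])
  }
  if (!is.function(weight))
    stop("weight must be a dyn_weight or a function(n, eps)", call. = FALSE)
  dense_expectation(weight, lambda, state, params, beta, quad)
}

## term-by-term path for arbitrary weight functions (validation only)
dense_expectation <- function(fn, lambda, state, params, beta, quad) {
  U <- max(1, round(state$N))
  if (U > 20000)
    stop("dense expectation path supports N <= 20000; supply a dyn_weight",
         call. = FALSE)
  l <- as_lagrange(lambda)
  pass <- engine_pass(l, state, params, beta, quad = quad, keep_nodes = TRUE)
  nd <- pass$nodes
  num <- 0; den <- 0
  n <- seq_len(U)
  for (i in seq_along(nd$eps)) {
    boltz <- exp(-nd$A[i] * n)
    boltz[1] <- boltz[1] * (1 + nd$dfac[i])
    num <- num + nd$w[i] * sum(fn(n, nd$eps[i]) * boltz)
    den <- den + nd$w[i] * sum(boltz)
  }
  num / den
}

## ---- constraints and the MaxEnt fit ---------------------------------------

#' Constraint vector for the dynamic MaxEnt problem
#'
#' The five constraint targets of the dynamic structure function: per-species
#' abundance `N/S`, per-species metabolic rate `E/S`, the per-species
#' derivatives `(1/S) dN/dt` and `(1/S) dE/dt`, and `dS/dt`.
#'
#' @param state A [community_state()].
#' @param dN_dt,dE_dt,dS_dt Time derivatives of the state variables (per
#'   year); a `derivs` list with these names may be given instead.
#' @param derivs Optional named list/vector with `dN_dt`, `dE_dt`, `dS_dt`.
#' @return Named numeric of class `constraint_vector`:
#'   `n_per_s`, `e_per_s`, `dn_per_s`, `de_per_s`, `ds`.
#' @export
constraint_vector <- function(state, dN_dt = 0, dE_dt = 0, dS_dt = 0,
                              derivs = NULL) {
  state <- as_community_state(state)
  if (!is.null(derivs)) {
    dN_dt <- derivs[["dN_dt"]]; dE_dt <- derivs[["dE_dt"]]
    dS_dt <- derivs[["dS_dt"]]
  }
  structure(c(n_per_s = state$N / state$S, e_per_s = state$E / state$S,
              dn_per_s = dN_dt / state$S, de_per_s = dE_dt / state$S,
              ds = dS_dt),
            class = "constraint_vector")
}

## the five achieved constraint expectations at a multiplier vector
constraint_weights <- function(state, params, beta) {
  list(weight_abundance(), weight_energy(),
       weight_transition("f", state, params, beta),
       weight_transition("h", state, params, beta),
       weight_transition("q", state, params, beta))
}

achieved_constraints <- function(lambda, state, params, beta,
                                 quad = quad_config(), moments = FALSE,
                                 n_panels = NULL) {
  ws <- constraint_weights(state, params, beta)
  pass <- engine_pass(lambda, state, params, beta, weights = ws, quad = quad,
                      moments = moments, n_panels = n_panels)
  out <- setNames(pass$values,
                  c("n_per_s", "e_per_s", "dn_per_s", "de_per_s", "ds"))
  if (moments) {
    attr(out, "second_moments") <- pass$second_moments
    attr(out, "cross_moments") <- pass$cross_moments
    attr(out, "log_Z") <- log(pass$Z_tilde) - lambda[5] * pass$q0_const
  }
  attr(out, "n_panels") <- pass$n_panels
  out
}

#' Scaled constraint residuals
#'
#' Residual `k` is `(achieved_k - target_k) / scale_k` with
#' `scale_k = max(|target_k|, floor_k)`; the floors keep near-zero derivative
#' targets from demanding absolute accuracy below what the state-variable
#' constraints themselves define.
#'
#' @param lambda A [lagrange_vector()].
#' @param targets A [constraint_vector()].
#' @inheritParams log_weight
#' @return Named numeric vector of five scaled residuals.
#' @export
constraint_residuals <- function(lambda, targets, state, params, beta,
                                 quad = quad_config()) {
  ach <- achieved_constraints(lambda, state, params, beta, quad)
  (ach - as.numeric(targets)) / residual_scales(targets)
}

residual_scales <- function(targets) {
  t <- as.numeric(targets)
  floors <- c(1, 1, 1e-6 * max(1, abs(t[1])), 1e-6 * max(1, abs(t[2])), 1e-6)
  pmax(abs(t), floors)
}

#' Fit the Lagrange multipliers to constraint targets
#'
#' Solves the five-constraint MaxEnt problem: finds the multiplier vector
#' whose structure function reproduces the targets
#' (`E[n] = N/S`, `E[n eps] = E/S`, `E[f] = (1/S)dN/dt`,
#' `E[h] = (1/S)dE/dt`, `E[q] = dS/dt`).  Damped Newton iteration with a
#' forward-difference Jacobian in per-multiplier scaled coordinates
#' (the five constraints span many orders of magnitude, so both residuals and
#' multipliers are rescaled to O(1) before solving); initialised by default at
#' the pre-perturbation static solution `(lambda1_s, lambda2_s, 0, 0, 0)`.
#' If plain Newton stalls, a homotopy on the derivative targets is attempted.
#' Entirely deterministic.
#'
#' @param targets A [constraint_vector()].
#' @param state,params,beta Context: the state supplying the support and the
#'   transition functions' arguments, the perturbed rate parameters, and the
#'   beta used inside `h`.
#' @param init Initial multiplier vector (default: static solution of
#'   `state`).
#' @param quad A [quad_config()].
#' @param control List: `tol` (max scaled residual, default 1e-8), `maxit`,
#'   `fd_rel` (relative finite-difference step), `verbose`.
#' @return A [lagrange_vector()] with attributes `residuals` (scaled),
#'   `iterations` and `achieved`.
#' @export
fit_lambdas <- function(targets, state, params, beta, init = NULL,
                        quad = quad_config(), control = list()) {
  ctrl <- modifyList(list(tol = 1e-8, maxit = 60, fd_rel = 1e-6,
                          verbose = FALSE), control)
  if (is.null(init)) {
    sol <- static_solution(state)
    init <- static_lagrange(sol)
  }
  init <- as_lagrange(init)

  res <- newton_lambda(as.numeric(targets), state, params, beta, init, quad,
                       ctrl)
  if (!res$converged) {
    ## homotopy fallback: walk the whole target vector from the values the
    ## initial multipliers already achieve to the requested targets, with an
    ## adaptive step, warm-starting each leg at the previous solution
    lam <- init
    t_full <- as.numeric(targets)
    t_start <- as.numeric(achieved_constraints(init, state, params, beta, quad))
    frac <- 0; dfrac <- 0.1; legs <- 0
    while (frac < 1 && legs < 300) {
      legs <- legs + 1
      f_try <- min(1, frac + dfrac)
      t_frac <- (1 - f_try) * t_start + f_try * t_full
      leg <- newton_lambda(t_frac, state, params, beta, lam, quad, ctrl)
      if (leg$converged) {
        frac <- f_try
        lam <- leg$lambda
        res <- leg
        dfrac <- min(dfrac * 2, 0.2)
      } else {
        dfrac <- dfrac / 2
        if (dfrac < 1e-4) break
      }
    }
    if (frac < 1) res$converged <- FALSE
    else {
      ## re-verify against the exact requested targets
      res <- newton_lambda(t_full, state, params, beta, lam, quad, ctrl)
    }
  }
  if (!res$converged)
    stop(sprintf(paste0("MaxEnt fit did not converge: max scaled residual ",
                        "%.3g after %d iterations"),
                 max(abs(res$residuals)), res$iterations), call. = FALSE)
  out <- as_lagrange(res$lambda)
  attr(out, "residuals") <- res$residuals
  attr(out, "iterations") <- res$iterations
  attr(out, "achieved") <- res$achieved
  out
}

## Damped Newton minimisation of the MaxEnt dual.
##
## The structure function is an exponential family in the multipliers, so the
## constraint equations E[w_k] = t_k are the stationarity conditions of the
## strictly convex dual objective
##     G(lambda) = log Z(lambda) + sum_k lambda_k t_k,
## whose gradient is t - E[w] and whose Hessian is the covariance matrix of
## the constraint weights -- both available analytically from the engine's
## exact moment sums.  Damped Newton with an Armijo backtracking line search
## on G is then globally convergent; a diagonal ridge guards the (severely
## ill-conditioned) covariance solve.
newton_lambda <- function(targets, state, params, beta, init, quad, ctrl) {
  scales_r <- residual_scales(targets)
  eval_pt <- function(lam) {
    ach <- achieved_constraints(lam, state, params, beta, quad, moments = TRUE)
    out <- list(ach = ach,
                r = (as.numeric(ach) - targets) / scales_r,
                G = attr(ach, "log_Z") + sum(lam * targets),
                H = attr(ach, "cross_moments") -
                  tcrossprod(as.numeric(ach)))
    if (!all(is.finite(out$r)) || !is.finite(out$G) || !all(is.finite(out$H)))
      stop("non-finite constraint moments", call. = FALSE)
    out
  }
  lam <- as.numeric(init)
  cur <- try(eval_pt(lam), silent = TRUE)
  if (inherits(cur, "try-error"))
    stop("initial multiplier vector is not normalisable", call. = FALSE)

  ## The weight covariance is severely ill-conditioned: the transition
  ## functions are nearly collinear with the state-variable weights and the
  ## five constraints span ~10 orders of magnitude.  Whiten the constraint
  ## basis once, by the covariance at the initial point, so that subsequent
  ## Hessians are near-identity and the Newton solve resolves directions that
  ## are invisible in raw coordinates.  (Newton steps are invariant under this
  ## linear change of basis in exact arithmetic; the gain is purely numerical.)
  dsc0 <- 1 / sqrt(pmax(diag(cur$H), 1e-300))
  e0 <- eigen(cur$H * tcrossprod(dsc0), symmetric = TRUE)
  ev0 <- pmax(e0$values, max(e0$values) * 1e-13)
  Twhiten <- diag(1 / sqrt(ev0)) %*% t(e0$vectors) %*% diag(dsc0)

  iters <- 0
  for (it in seq_len(ctrl$maxit)) {
    iters <- it
    if (max(abs(cur$r)) < ctrl$tol) break
    grad <- targets - as.numeric(cur$ach)
    Hp <- Twhiten %*% cur$H %*% t(Twhiten)
    gp <- as.numeric(Twhiten %*% grad)
    if (!all(is.finite(Hp)) || !all(is.finite(gp))) break
    ee <- try(eigen(Hp, symmetric = TRUE), silent = TRUE)
    if (inherits(ee, "try-error")) break
    evals <- pmax(ee$values, max(ee$values) * 1e-14)
    step <- -as.numeric(crossprod(Twhiten,
      ee$vectors %*% (crossprod(ee$vectors, gp) / evals)))
    slope <- sum(grad * step)           # directional derivative of G
    if (!is.finite(slope) || slope >= 0) break
    alpha <- 1
    accepted <- FALSE
    for (ls in 1:40) {
      trial <- try(eval_pt(lam + alpha * step), silent = TRUE)
      if (!inherits(trial, "try-error") && is.finite(trial$G) &&
          (trial$G <= cur$G + 1e-4 * alpha * slope + 1e-10 ||
           ## near the optimum the dual is flat to machine precision while
           ## residuals are still resolvable: fall back to residual descent
           sum(trial$r^2) < 0.999 * sum(cur$r^2))) {
        lam <- lam + alpha * step
        cur <- trial
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (ctrl$verbose)
      message(sprintf("  fit it %d: max|r| = %.3e (alpha = %.3g, G = %.10g)",
                      it, max(abs(cur$r)), alpha, cur$G))
    if (!accepted) break
  }
  list(lambda = lam, residuals = cur$r, achieved = cur$ach,
       converged = max(abs(cur$r)) < ctrl$tol, iterations = iters)
}
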