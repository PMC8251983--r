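#' Solve for the abundance-distribution parameter beta
#'
#' The static structure function assigns species abundance `n` the weight
#' `exp(-beta * n) / n` with `beta = lambda1 + lambda2`.  `solve_beta_exact()`
#' finds `beta` from the finite-sum relation
#' `(S/N) * sum_{n=1}^{N} exp(-beta n) = sum_{n=1}^{N} exp(-beta n) / n`,
#' while `solve_beta_approx()` uses the small-beta approximation
#' `beta * ln(1/beta) = S/N`, valid when `S << N`.  The approximate form is
#' what the rest of the package uses by default; the exact solver is provided
#' for validation.
#'
#' Both solvers are deterministic: a bracketing scan on `log(beta)` followed by
#' bisection and a Newton polish.
#'
#' @param S Species richness (1 <= S < N).
#' @param N Total abundance.
#' @return The root `beta` (dimensionless, > 0; the approximate solver returns
#'   the small root, < 1/e).
#' @examples
#' solve_beta_approx(320, 230000)
#' solve_beta_exact(64, 1024)
#' @export
solve_beta_exact <- function(S, N) {
  if (S >= N) stop("solve_beta_exact requires S < N", call. = FALSE)
  if (S < 1) stop("solve_beta_exact requires S >= 1", call. = FALSE)
  N <- round(N)
  n <- seq_len(N)
  g <- function(beta) {
    w <- exp(-beta * n)
    (S / N) * sum(w) - sum(w / n)
  }
  ## g(0+) = S - H_N; a root needs S > H_N (rare species-rich corner cases
  ## such as S=1, N=2 leave g < 0 everywhere).
  logb <- seq(log(1e-12), log(20), length.out = 400)
  gv <- vapply(exp(logb), g, numeric(1))
  sgn <- sign(gv)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(flip) == 0)
    stop("no root for beta: the abundance relation is infeasible for this S/N",
         call. = FALSE)
  lo <- exp(logb[flip[1]]); hi <- exp(logb[flip[1] + 1])
  r <- uniroot(g, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  ## Newton polish on the residual
  for (i in 1:8) {
    w <- exp(-r * n)
    res <- (S / N) * sum(w) - sum(w / n)
    dres <- -(S / N) * sum(n * w) + sum(w)
    if (dres == 0) break
    step <- res / dres
    if (!is.finite(step)) break
    r2 <- r - step
    if (r2 <= 0) break
    r <- r2
    if (abs(step) < 1e-15 * r) break
  }
  r
}

#' @rdname solve_beta_exact
#' @export
solve_beta_approx <- function(S, N) {
  ratio <- S / N
  if (ratio <= 0) stop("S/N must be positive", call. = FALSE)
  ## beta * ln(1/beta) attains its maximum 1/e at beta = 1/e
  if (ratio >= exp(-1))
    stop("S/N >= 1/e: no root of beta*ln(1/beta) = S/N exists", call. = FALSE)
  g <- function(b) b * log(1 / b) - ratio
  ## the small root lies in (0, 1/e); bisect on log(beta)
  lo <- 1e-300; hi <- exp(-1) * (1 - 1e-12)
  if (g(lo) > 0) lo <- ratio * 1e-8   # extremely small ratios: tighten bracket
  r <- uniroot(g, c(lo, hi), tol = .Machine$double.eps^0.5)$root
  ## Newton polish: g'(b) = ln(1/b) - 1
  for (i in 1:30) {
    step <- g(r) / (log(1 / r) - 1)
    r2 <- r - step
    if (r2 <= 0 || r2 >= exp(-1)) break
    r <- r2
    if (abs(step) < 1e-16 * r) break
  }
  r
}

#' Static MaxEnt solution for the structure function
#'
#' Computes the Lagrange multipliers of the static structure function
#' `R(n, eps) = exp(-lambda1 n - lambda2 n eps) / Z` from the state variables
#' alone, in the standard approximation regime `S << N << E`:
#' `lambda2 = S / (E - N)`, `beta = lambda1 + lambda2` from the abundance
#' relation, and `Z = ln(1/beta) / lambda2`.
#'
#' @param state A [community_state()].
#' @param beta_method `"approx"` (default; the small-beta relation) or
#'   `"exact"` (finite-sum relation), or a numeric value of beta supplied
#'   directly.
#' @return An object of class `static_solution` with fields `beta`, `lambda1`,
#'   `lambda2`, `Z` and `log_inv_beta`.
#' @examples
#' static_solution(bci_state())
#' @export
static_solution <- function(state, beta_method = c("approx", "exact")) {
  state <- as_community_state(state)
  if (state$E <= state$N)
    stop("static solution requires E > N", call. = FALSE)
  beta <- if (is.numeric(beta_method)) {
    beta_method
  } else {
    beta_method <- match.arg(beta_method)
    switch(beta_method,
           approx = solve_beta_approx(state$S, state$N),
           exact  = solve_beta_exact(state$S, state$N))
  }
  lambda2 <- state$S / (state$E - state$N)
  lambda1 <- beta - lambda2
  log_inv_beta <- log(1 / beta)
  structure(list(beta = beta, lambda1 = lambda1, lambda2 = lambda2,
                 Z = log_inv_beta / lambda2, log_inv_beta = log_inv_beta,
                 state = state),
            class = "static_solution")
}

#' @export
print.static_solution <- function(x, ...) {
  cat(sprintf(paste0("static MaxEnt solution:\n  beta    = %.8g\n",
                     "  lambda1 = %.8g\n  lambda2 = %.8g\n  Z       = %.8g\n",
                     "  ln(1/beta) = %.8g\n"),
              x$beta, x$lambda1, x$lambda2, x$Z, x$log_inv_beta))
  invisible(x)
}

## Sum_{n=1}^{N} exp(-beta n)/n, the log-series normaliser on finite support.
logseries_norm <- function(beta, N) {
  N <- round(N)
  if (beta * N > 45) {
    ## tail beyond N is below double precision: use the closed infinite sum
    -log1p(-exp(-beta))
  } else if (N <= 5e6) {
    n <- seq_len(N)
    sum(exp(-beta * n) / n)
  } else {
    ## large support with non-negligible tail: chunked summation
    acc <- 0
    lo <- 1
    while (lo <= N) {
      hi <- min(lo + 1e6 - 1, N)
      n <- lo:hi
      acc <- acc + sum(exp(-beta * n) / n)
      lo <- hi + 1
    }
    acc
  }
}

#' Static species abundance distribution (log-series)
#'
#' Probability that a randomly chosen species has abundance `n` under the
#' static structure function: `phi(n) = exp(-beta n) / (n ln(1/beta))`,
#' renormalised over the finite support `n = 1..N` so that the distribution
#' sums exactly to one.
#'
#' @param n Integer abundance(s), `>= 1`.
#' @param sol A [static_solution()].
#' @param renormalise Renormalise over the finite support (default `TRUE`);
#'   `FALSE` returns the infinite-support form as printed.
#' @return Probability mass at `n` (vectorised).
#' @export
sad_logseries <- function(n, sol, renormalise = TRUE) {
  if (any(n < 1)) stop("abundance n must be >= 1", call. = FALSE)
  if (any(n != round(n))) stop("abundance n must be integer", call. = FALSE)
  beta <- sol$beta
  raw <- exp(-beta * n) / n
  if (renormalise) raw / logseries_norm(beta, sol$state$N)
  else raw / sol$log_inv_beta
}

## Normalisation of the metabolic rate density over [1, upper), where the
## upper limit is taken far into the exponential tail.
mrdi_norm <- function(sol) {
  ## psi(eps) = (beta/lambda2) e^{-g}/(1-e^{-g})^2 with g = lambda1+lambda2*eps.
  ## Closed form: int_1^Inf e^{-g}/(1-e^{-g})^2 deps = 1/(lambda2 (e^{beta}-1)),
  ## since gamma(1) = lambda1 + lambda2 = beta.
  (sol$beta / sol$lambda2) / (sol$lambda2 * expm1(sol$beta))
}

#' Static metabolic rate distribution over individuals
#'
#' Density of the metabolic rate `eps` of a randomly chosen individual under
#' the static structure function:
#' `psi(eps) = (beta/lambda2) e^{-gamma(eps)} / (1 - e^{-gamma(eps)})^2` with
#' `gamma(eps) = lambda1 + lambda2 * eps`, renormalised over the continuous
#' support `eps in [1, Inf)`.
#'
#' @param eps Metabolic rate(s), `>= 1` (units of the smallest individual).
#' @param sol A [static_solution()].
#' @param renormalise Renormalise over the support (default `TRUE`).
#' @return Density at `eps` (vectorised).
#' @export
mrdi <- function(eps, sol, renormalise = TRUE) {
  if (any(eps < 1)) stop("metabolic rate eps must be >= 1", call. = FALSE)
  g <- sol$lambda1 + sol$lambda2 * eps
  raw <- (sol$beta / sol$lambda2) * exp(-g) / expm1(-g)^2
  if (renormalise) raw / mrdi_norm(sol) else raw
}

#' Mean metabolic rate of individuals in a species of abundance n
#'
#' Under the static structure function the metabolic rate of an individual in
#' a species of abundance `n` is exponential with rate `lambda2 * n` on
#' `[1, Inf)`, so the conditional mean is `1 + 1/(lambda2 * n)`: more abundant
#' species have smaller-bodied individuals (energy equivalence).
#'
#' @param n Abundance(s), `>= 1`.
#' @param sol A [static_solution()].
#' @return Conditional mean metabolic rate (strictly decreasing in `n`).
#' @export
mean_metabolism_given_n <- function(n, sol) {
  if (any(n < 1)) stop("abundance n must be >= 1", call. = FALSE)
  1 + 1 / (sol$lambda2 * n)
}
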