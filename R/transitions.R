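## Mechanistic transition functions.
##
## f governs dn/dt for a species of abundance n whose individuals have
## metabolic rate eps; h governs the rate of change of the summed metabolic
## rate of such a species; q governs dS/dt contributions.  All three depend on
## the current macrostate X = (S, N, E) and the rate constants c; h further
## depends on beta through the growth-loss scaling factor.
##
## f and h are homogeneous of degree 1 in n, so they decompose as
## f = cf(eps) * n and h = ch(eps) * n; q decomposes as
## q = q0 + cq(eps) * n + qd(eps) * delta_{n,1}.  The expectation engine
## exploits this decomposition; the per-(n, eps) evaluators below are the
## user-facing forms.

## Effective growth-loss rate w1 applied to n*eps inside h.
w1_effective <- function(params, beta) {
  lf <- log(1 / beta)^(2 / 3)
  switch(params$w10_log_factor,
         divide   = params$w10 / lf,
         multiply = params$w10 * lf)
}

## epsilon-dependent coefficients of the n-linear parts (vectorised over eps)
transition_coefs <- function(eps, state, params, beta) {
  ratio <- state$E / params$Ec
  cf <- (params$b0 - params$d0 * ratio) * eps^(-1 / 3) + params$m0 / state$N
  ch <- (params$w0 - params$d0 * ratio) * eps^(2 / 3) -
    w1_effective(params, beta) * eps + params$m0 / state$N
  cq <- params$sigma2 * params$b0 * state$S * eps^(-1 / 3)
  qd <- -state$S * params$d0 * ratio * eps^(-1 / 3)
  q0 <- params$m0 * exp(-params$mu * state$S - EULER_GAMMA) +
    params$sigma1 * params$K * state$S / (params$K + state$S)
  list(cf = cf, ch = ch, cq = cq, qd = qd, q0 = q0)
}

#' Mechanistic transition functions
#'
#' Per-species rates of change used to drive the dynamics:
#'
#' * `f_rate(n, eps)`: abundance change,
#'   `(b0 - d0 E/Ec) n / eps^(1/3) + m0 n / N`.  Birth and death scale as
#'   `n/eps^(1/3)` (metabolic scaling); `E/Ec` is a community-level zero-sum
#'   constraint; immigrants land in a species with probability `n/N`.
#' * `h_rate(n, eps)`: change of the summed metabolic rate of a species,
#'   `w0 n eps^(2/3) - w1eff n eps - d0 n eps^(2/3) E/Ec + m0 n / N`, where
#'   `w1eff` applies the `ln^(2/3)(1/beta)` scaling to `w10` (see
#'   [transition_params()] for the `w10_log_factor` convention); immigrants
#'   arrive with metabolic rate 1.
#' * `q_rate(n, eps)`: species-richness change,
#'   `m0 exp(-mu S - gamma_E) + sigma1 K S/(K + S) + sigma2 b0 n S/eps^(1/3)
#'    - S delta(n,1) d0 (E/Ec)/eps^(1/3)`,
#'   combining immigration-driven diversification (`gamma_E` is the
#'   Euler-Mascheroni constant, about 0.5772), saturating and per-birth
#'   speciation, and extinction when the last remaining individual of a
#'   species dies.
#'
#' `f` and `h` are linear in `n` and vanish at `n = 0`; `q` requires integer
#' `n` because of the Kronecker delta in the extinction term.
#'
#' @param n Species abundance (>= 0 for `f`, `h`; integer >= 1 for `q`).
#' @param eps Metabolic rate of the species' individuals (>= 1).
#' @param state A [community_state()].
#' @param params A [transition_params()].
#' @param beta Abundance-distribution parameter in (0, 1), used by `h`.
#' @return Rate of change (per year), vectorised over `n` and `eps`.
#' @examples
#' f_rate(1, 1, bci_state(), bci_params())
#' q_rate(2, 1, bci_state(), bci_params())
#' @export
f_rate <- function(n, eps, state, params) {
  check_micro_args(n, eps, state)
  co <- transition_coefs(eps, state, params, beta = 0.5)  # beta unused by f
  co$cf * n
}

#' @rdname f_rate
#' @export
h_rate <- function(n, eps, state, params, beta) {
  check_micro_args(n, eps, state)
  if (beta <= 0 || beta >= 1) stop("beta must lie in (0, 1)", call. = FALSE)
  co <- transition_coefs(eps, state, params, beta)
  co$ch * n
}

#' @rdname f_rate
#' @export
q_rate <- function(n, eps, state, params) {
  check_micro_args(n, eps, state)
  if (any(n != round(n)) || any(n < 1))
    stop("q_rate requires integer n >= 1 (Kronecker delta at n = 1)",
         call. = FALSE)
  co <- transition_coefs(eps, state, params, beta = 0.5)  # beta unused by q
  co$q0 + co$cq * n + co$qd * (n == 1)
}

check_micro_args <- function(n, eps, state) {
  if (any(eps < 1)) stop("metabolic rate eps must be >= 1", call. = FALSE)
  if (any(n < 0)) stop("abundance n must be >= 0", call. = FALSE)
  if (state$N <= 0) stop("state must have N > 0", call. = FALSE)
  invisible(TRUE)
}
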