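## Steady-state scaling laws: species-area relationships under different
## diversification mechanisms, community biomass, and the
## productivity-biomass-diversity-abundance relation.

## Coefficients of the biomass-metabolism relation and its inverse, as
## displayed (4.17 encodes the closed-form approximations; the inverse
## prefactor follows algebraically).
BIOMASS_COEF <- 4.17

#' Coefficient of the productivity relation
#'
#' The multiplicative constant of `P = c B^(3/4) S^(1/4) ln^(3/4)(1/beta)`,
#' obtained by algebraically inverting the community biomass-metabolism
#' relation: `c = 4.17^(-3/4)`, which is 0.343 to three decimals.
#'
#' @return The coefficient (a number).
#' @export
pbd_coefficient <- function() BIOMASS_COEF^(-3 / 4)

#' Community biomass and productivity scaling
#'
#' `biomass()` evaluates the steady-state closed form
#' `B = m1 * 4.17 * E^(4/3) / (S^(1/3) ln(1/beta))`, with individual mass
#' related to metabolism by `m = m1 eps^(4/3)` and `m1 = 1` in the package's
#' units.  `biomass_expectation()` computes the same quantity by direct
#' averaging `S * E[n eps^(4/3)]` over the static structure function (the
#' validation route).  `productivity_relation()` is the inverse law
#' `P = 0.343 B^(3/4) S^(1/4) ln^(3/4)(1/beta)` with `P` identified with the
#' total metabolic rate `E`.
#'
#' @param state A [community_state()].
#' @param sol Optional [static_solution()] (computed from `state` if absent).
#' @param m1 Mass of the smallest individual (units prefactor).
#' @return A number (`B` in units of `m1`, or `P` in units of `E`).
#' @examples
#' st <- bci_state()
#' B <- biomass(st)
#' productivity_relation(B, st$S, static_solution(st)$beta)  # ~ st$E
#' @export
biomass <- function(state, sol = NULL, m1 = 1) {
  state <- as_community_state(state)
  if (is.null(sol)) sol <- static_solution(state)
  m1 * BIOMASS_COEF * state$E^(4 / 3) / (state$S^(1 / 3) * sol$log_inv_beta)
}

#' @rdname biomass
#' @param quad A [quad_config()].
#' @export
biomass_expectation <- function(state, sol = NULL, m1 = 1,
                                quad = quad_config()) {
  state <- as_community_state(state)
  if (is.null(sol)) sol <- static_solution(state)
  w <- dyn_weight(v = function(eps) eps^(4 / 3))
  m1 * state$S * expectation(w, static_lagrange(sol), state, null_params(),
                             sol$beta, quad)
}

#' @rdname biomass
#' @param B Total biomass (units of `m1`).
#' @param S Species richness.
#' @param beta Abundance-distribution parameter in (0, 1).
#' @export
productivity_relation <- function(B, S, beta) {
  if (any(beta <= 0) || any(beta >= 1))
    stop("beta must lie in (0, 1)", call. = FALSE)
  0.343 * B^(3 / 4) * S^(1 / 4) * log(1 / beta)^(3 / 4)
}

## parameter set with no dynamics, for purely static expectations
null_params <- function() {
  transition_params(b0 = 0, d0 = 0, m0 = 0, w0 = 0, w10 = 0, Ec = 1, mu = 0)
}

#' Species-area relationships by steady-state upscaling
#'
#' In a nested design the carrying capacity `Ec`, the community metabolism
#' `E` and the abundance `N` scale linearly with censused area; area is
#' represented by dimensionless scale factors (powers of two) relative to an
#' anchor community.  At each scale the steady-state richness is solved from
#' the diversification-extinction balance, self-consistently with
#' `beta(S, N)`.
#'
#' `sar_immigration()` uses the immigration-only balance (immigration from
#' the metacommunity against extinction); `m0` scales with area by default.
#' `sar_speciation()` uses the speciation relations: `"saturating"`
#' (richness-saturating speciation, `S >> K`, quarter-power scaling),
#' `"linear"` (`S << K`, linear-in-area scaling), `"per_birth"`
#' (speciation proportional to births, linear scaling), or
#' `"log_speciation"` — the variant with logarithmic dependence of
#' speciation on richness, `S ln^(3/4)(S) ~ A^(1/4) ln^(3/4)(1/beta)`,
#' calibrated at the anchor scale.
#'
#' @param params [transition_params()] at the anchor scale.
#' @param anchor Anchor [community_state()] (near steady state).
#' @param octaves Number of doublings spanned (default 7).
#' @param m0_scales Does the immigration rate scale with area (default
#'   `TRUE`)?
#' @return A `data.frame` with columns `scale` (log2 factor), `area_factor`
#'   and `S`.
#' @examples
#' \donttest{sar_immigration(bci_params(), bci_state(), octaves = 4)}
#' @export
sar_immigration <- function(params, anchor = bci_state(), octaves = 7,
                            m0_scales = TRUE) {
  anchor <- as_community_state(anchor)
  ks <- seq(-floor(octaves / 2), octaves - floor(octaves / 2))
  S <- vapply(ks, function(k) {
    a <- 2^k
    p <- params
    p$Ec <- params$Ec * a
    if (m0_scales) p$m0 <- params$m0 * a
    steady_S_given(p, E = anchor$E * a, N = anchor$N * a)
  }, numeric(1))
  data.frame(scale = ks, area_factor = 2^ks, S = S)
}

#' @rdname sar_immigration
#' @param relation Which speciation-driven relation to use (see Details).
#' @export
sar_speciation <- function(params, anchor = bci_state(), octaves = 7,
                           relation = c("saturating", "linear", "per_birth",
                                        "log_speciation")) {
  relation <- match.arg(relation)
  anchor <- as_community_state(anchor)
  ks <- seq(-floor(octaves / 2), octaves - floor(octaves / 2))
  ratio <- anchor$E / params$Ec      # E/Ec is scale-free in nested designs

  s_of <- function(a) {
    E <- anchor$E * a; N <- anchor$N * a
    g <- function(S) {
      L <- log(1 / solve_beta_approx(S, N))
      rhs <- switch(relation,
        saturating = (0.35 * params$sigma1 * L /
                        (params$d0 * ratio))^(3 / 4) * E^(1 / 4),
        linear = (0.35 * params$sigma1 * L / (params$d0 * ratio))^3 * E,
        per_birth = (0.9 * params$sigma2 * params$b0 /
                       (params$d0 * ratio))^(3 / 4) * L * E,
        log_speciation = NA)  # handled below
      S - rhs
    }
    if (relation == "log_speciation") {
      L_a <- log(1 / solve_beta_approx(anchor$S, anchor$N))
      C <- anchor$S * log(anchor$S)^(3 / 4) / L_a^(3 / 4)
      g <- function(S) {
        L <- log(1 / solve_beta_approx(S, N))
        S * log(max(S, 1.0001))^(3 / 4) - C * a^(1 / 4) * L^(3 / 4)
      }
    }
    uniroot(g, lower = 1.001, upper = N * exp(-1) * 0.999, tol = 1e-9)$root
  }
  S <- vapply(2^ks, s_of, numeric(1))
  data.frame(scale = ks, area_factor = 2^ks, S = S)
}
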