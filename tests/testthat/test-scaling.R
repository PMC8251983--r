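test_that("immigration-only species-area curve is monotone and log-concave", {
  sar <- sar_immigration(bci_params(), bci_state(), octaves = 7)
  expect_true(all(diff(sar$S) > 0))
  ## concave in log-log coordinates: decreasing local slope
  slopes <- diff(log(sar$S)) / diff(log(sar$area_factor))
  expect_true(all(diff(slopes) < 0))
  ## the anchor richness is recovered at scale factor one
  expect_rel(sar$S[sar$scale == 0], 320, 0.02)
})

test_that("scale-independent immigration gives quarter-power richness scaling", {
  ## asymptotic regime: S << 1/mu and ln(1/beta) so large that its slow area
  ## dependence contributes negligibly to the local slope; the immigration
  ## rate is set so the anchor balances at S = 20
  N0 <- 1e26; E0 <- 90 * N0
  L <- log(1 / solve_beta_approx(20, N0))
  ext <- 0.2 * 1.02 * gamma(2 / 3) * 20^(4 / 3) * E0^(2 / 3) / (E0 * L)
  m0 <- ext * exp(0.5772156649 + 1e-6 * 20)
  par <- transition_params(b0 = 0.2, d0 = 0.2, m0 = m0, w0 = 1,
                           w10 = 0.4096, Ec = E0 / 1.02, mu = 1e-6)
  anchor <- community_state(20, N0, E0)
  sar <- sar_immigration(par, anchor, octaves = 4, m0_scales = FALSE)
  expect_rel(sar$S[sar$scale == 0], 20, 1e-6)
  slope <- diff(log(sar$S)) / diff(log(sar$area_factor))
  expect_true(all(abs(slope - 0.25) < 0.05 * 0.25))
})

test_that("speciation-driven scaling follows the printed power laws", {
  par_s <- transition_params(b0 = 0.2, d0 = 0.2, m0 = 0, w0 = 1, w10 = 0.4096,
                             Ec = 2e7, mu = 0.0219, sigma1 = 0.005, K = 1)
  sat <- sar_speciation(par_s, bci_state(), octaves = 6,
                        relation = "saturating")
  ## quadrupling area multiplies S by ~sqrt(2), up to slow log corrections
  r <- sat$S[sat$scale == 2] / sat$S[sat$scale == 0]
  expect_gt(r, sqrt(2) * 0.95)
  expect_lt(r, sqrt(2) * 1.25)
  par_b <- transition_params(b0 = 0.2, d0 = 0.2, m0 = 0, w0 = 1, w10 = 0.4096,
                             Ec = 2e7, mu = 0.0219, sigma2 = 1e-5)
  pb <- sar_speciation(par_b, bci_state(), octaves = 6,
                       relation = "per_birth")
  ## S/E constant up to the ln(1/beta) factor
  L <- vapply(seq_len(nrow(pb)), function(i)
    log(1 / solve_beta_approx(pb$S[i], 230000 * pb$area_factor[i])),
    numeric(1))
  ratio <- pb$S / (pb$area_factor * L)
  expect_lt(diff(range(ratio)) / mean(ratio), 0.01)
  ## the log-speciation variant grows sublinearly but without saturating
  ls <- sar_speciation(par_s, bci_state(), octaves = 6,
                       relation = "log_speciation")
  expect_true(all(diff(ls$S) > 0))
  slopes <- diff(log(ls$S)) / diff(log(ls$area_factor))
  expect_true(all(slopes < 1) && all(slopes > 0))
})

test_that("closed-form biomass agrees with the direct expectation", {
  ## the closed form carries the small-beta approximations, so its accuracy
  ## against the exact average degrades as S/N grows: ~4% at the
  ## forest-like end of the decade, ~12% at the sparse end
  ratios <- vapply(10^seq(-3, -2, length.out = 10), function(sn) {
    N <- 2e5
    st <- community_state(S = sn * N, N = N, E = 90 * N)
    biomass_expectation(st) / biomass(st)
  }, numeric(1))
  expect_true(all(abs(ratios[10^seq(-3, -2, length.out = 10) <= 1.5e-3] - 1)
                  < 0.05))
  expect_true(all(abs(ratios - 1) < 0.12))
  ## the degradation is monotone in S/N (a beta-approximation effect)
  expect_true(all(diff(ratios) < 0))
  ## and the reference community sits inside the 5% band
  expect_rel(biomass_expectation(bci_state()), biomass(bci_state()), 0.05)
})

test_that("biomass and productivity relations scale and invert correctly", {
  st <- bci_state()
  sol <- static_solution(st)
  B <- biomass(st)
  ## E -> 8E at fixed S and beta multiplies B by 16
  st8 <- community_state(st$S, st$N, 8 * st$E)
  expect_rel(biomass(st8, sol), 16 * B, 1e-10)
  expect_rel(biomass(st, sol, m1 = 3), 3 * B, 1e-12)
  ## inverting the biomass relation yields the productivity coefficient
  expect_equal(round(pbd_coefficient(), 3), 0.343)
  ## round trip through the printed rounded coefficients
  expect_rel(productivity_relation(B, st$S, sol$beta), st$E, 0.005)
  ## homogeneity of degree 3/4 in biomass
  expect_rel(productivity_relation(8 * B, st$S, sol$beta),
             8^(3 / 4) * productivity_relation(B, st$S, sol$beta), 1e-12)
  expect_error(productivity_relation(B, st$S, 1.2), "beta")
  ## with P and abundance fixed, biomass falls with richness
  P <- productivity_relation(B, st$S, sol$beta)
  B_of_S <- function(S) (P / (0.343 * S^(1 / 4) *
                                sol$log_inv_beta^(3 / 4)))^(4 / 3)
  expect_lt(B_of_S(640), B_of_S(320))
})
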