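test_that("reference configuration sits near a steady state of the closed forms", {
  d <- closed_form_derivatives(bci_state(), bci_params())
  expect_lt(abs(d[["dN_dt"]]), 1e-3 * 230000)
  expect_lt(abs(d[["dS_dt"]]), 0.05)
  expect_lt(abs(d[["dE_dt"]]), 1e-3 * 2.04e7)
  ## without immigration only the extinction loss remains in dS/dt
  par0 <- bci_params(); par0$m0 <- 0
  expect_lt(closed_form_derivatives(bci_state(), par0)[["dS_dt"]], 0)
})

test_that("closed forms approximate the expectation-engine averages", {
  par <- bci_params()
  states <- list(bci_state(),
                 community_state(320 * 1.2, 230000 * 1.2, 2.04e7 * 1.2),
                 community_state(320 * 0.8, 230000 * 0.8, 2.04e7 * 0.8))
  for (st in states) {
    sol <- static_solution(st)
    lam <- static_lagrange(sol)
    ach <- dynamete:::achieved_constraints(lam, st, par, sol$beta)
    cf <- closed_form_derivatives(st, par, beta = sol$beta)
    ## compare the gain and loss components, which set the scale of each
    ## equation (the net derivatives are near-cancelling differences)
    gross_N <- abs(par$b0 * st$S * ach[["n_per_s"]])      # order of dN terms
    expect_lt(abs(cf[["dN_dt"]] - st$S * ach[["dn_per_s"]]) / gross_N, 0.15)
    gross_E <- abs(par$w0 * st$E)
    expect_lt(abs(cf[["dE_dt"]] - st$S * ach[["de_per_s"]]) / gross_E, 0.15)
    gross_S <- par$m0 * exp(-par$mu * st$S - 0.5772156649) + 1e-3
    expect_lt(abs(cf[["dS_dt"]] - ach[["ds"]]) / gross_S, 0.15)
  }
})

test_that("steady state solves the coupled system self-consistently", {
  par <- bci_params()
  ss <- steady_state(par, mode = "immigration_only")
  d <- closed_form_derivatives(ss, par)
  expect_lt(abs(d[["dN_dt"]]) / ss$N, 1e-6)
  expect_lt(abs(d[["dE_dt"]]) / ss$E, 1e-6)
  expect_lt(abs(d[["dS_dt"]]) / ss$S, 1e-6)
  ## near the published reference values
  expect_rel(ss$S, 320, 0.02)
  expect_rel(ss$E, 2.04e7, 0.02)
  ## the m0 -> 0 limit of the abundance balance: E -> Ec b0/d0 exactly
  par0 <- par; par0$m0 <- 1e-9
  expect_rel(steady_E_given(par0, 320, 230000), par$Ec * par$b0 / par$d0,
             1e-6)
  expect_error(steady_state(transition_params(b0 = 0.2, d0 = 0.2, m0 = 1,
                                              w0 = 1, w10 = 0.4, Ec = 2e7,
                                              mu = 0.02, sigma1 = 0.1)),
               "sigma")
})

test_that("conditional solvers reproduce the reference state variables", {
  par <- bci_params()
  expect_rel(steady_E_given(par, S = 320, N = 230000), 2.04e7, 0.02)
  expect_rel(steady_S_given(par, E = 2.04e7, N = 230000), 320, 0.02)
})

test_that("trajectories stay near the fixed point and converge in step size", {
  par <- bci_params()
  tr <- integrate_trajectory(bci_state(), par, T = 100, dt = 0.1)
  expect_lt(max(abs(tr$S / 320 - 1)), 0.01)
  expect_lt(max(abs(tr$N / 230000 - 1)), 0.01)
  expect_lt(max(abs(tr$E / 2.04e7 - 1)), 0.01)
  ## halving the step changes the endpoint by far less than 0.1%
  tr2 <- integrate_trajectory(bci_state(), par, T = 20, dt = 0.2)
  tr3 <- integrate_trajectory(bci_state(), par, T = 20, dt = 0.1)
  endd <- abs(unlist(tr2[nrow(tr2), c("S", "N", "E")]) /
                unlist(tr3[nrow(tr3), c("S", "N", "E")]) - 1)
  expect_lt(max(endd), 1e-3)
})

test_that("a death-rate increase drives damped oscillation of abundance", {
  tr <- integrate_trajectory(bci_state(), bci_params(),
                             disturbances = "d0=0.25@0", T = 100, dt = 0.1)
  ## initial large decline in N ...
  i_min <- which.min(tr$N)
  expect_lt(tr$N[i_min], 0.8 * 230000)
  expect_gt(tr$t[i_min], 0)
  expect_lt(tr$t[i_min], 100)
  ## ... followed by a partial, damped recovery
  expect_gt(max(tr$N[tr$t > tr$t[i_min]]), tr$N[i_min] * 1.02)
  expect_lt(max(tr$N[tr$t > tr$t[i_min]]), 230000)
})

test_that("immigration shutdown hits richness much harder than energy", {
  tr <- integrate_trajectory(bci_state(), bci_params(),
                             disturbances = "m0=0", T = 50, dt = 0.1)
  at50 <- tr[nrow(tr), ]
  expect_lt(abs(at50$E / 2.04e7 - 1), abs(at50$S / 320 - 1))
  ## near-linear early decline of S
  expect_lt(at50$S, 320)
})

test_that("recovery from depletion shows the signature overshoot pattern", {
  tr <- recovery_experiment(bci_params(), depletion_fraction = 0.8, T = 400,
                            dt = 0.2)
  ss <- attr(tr, "steady")
  ## S rises monotonically toward the steady state
  expect_true(all(diff(tr$S) > -1e-9))
  expect_gt(tr$S[nrow(tr)], 0.9 * ss$S)
  ## N overshoots, then declines back toward steady state
  expect_gt(max(tr$N), ss$N)
  expect_lt(tr$N[nrow(tr)], max(tr$N))
  ## E overshoots much more weakly than N (relative amplitudes)
  overN <- max(tr$N) / ss$N - 1
  overE <- max(tr$E) / ss$E - 1
  expect_lt(overE, overN)
})

test_that("disturbance schedules parse and reject malformed tokens", {
  d <- parse_disturbance("d0=0.25@3")
  expect_equal(d$param, "d0"); expect_equal(d$value, 0.25)
  expect_equal(d$t_on, 3)
  expect_error(parse_disturbance("d0~0.25"), "cannot parse")
  expect_error(parse_disturbance("zz=1"), "unknown transition parameter")
  expect_error(parse_disturbance("d0=abc"), "bad value")
})
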