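test_that("zero perturbation leaves the frozen trajectory at its start", {
  ctx <- frozen_context(bci_state(), bci_params())
  d0 <- frozen_derivatives(bci_state(), ctx)
  expect_lt(abs(d0[["dN_dt"]]), 1e-3 * 230000)
  expect_lt(abs(d0[["dE_dt"]]), 1e-3 * 2.04e7)
  expect_lt(abs(d0[["dS_dt"]]), 0.05)
  tr <- frozen_trajectory(ctx)
  ep <- attr(tr, "endpoint")$state
  expect_lt(abs(ep$S / 320 - 1), 0.005)
  expect_lt(abs(ep$N / 230000 - 1), 0.005)
  expect_lt(abs(ep$E / 2.04e7 - 1), 0.005)
})

test_that("frozen derivatives are smooth in the state", {
  ctx <- frozen_context(bci_state(), modifyList(bci_params(), list(d0 = 0.25)))
  base <- frozen_derivatives(bci_state(), ctx)
  for (h in c(1e-3, 1e-4)) {
    up <- frozen_derivatives(community_state(320, 230000 * (1 + h),
                                             2.04e7 * (1 + h)), ctx)
    expect_lt(max(abs(up - base) / (abs(base) + 1)), h * 50)
  }
})

test_that("immigration shutdown removes the diversification gain only", {
  par0 <- modifyList(bci_params(), list(m0 = 0))
  ctx <- frozen_context(bci_state(), par0)
  d <- frozen_derivatives(bci_state(), ctx)
  expect_rel(d[["dS_dt"]], -0.25, 0.05)
})

test_that("the frozen 25-year run reproduces the published endpoint states", {
  for (cl in published_perturbations()) {
    fi <- first_iteration(disturbances = cl$disturb)
    expect_rel(fi$state$S, cl$state[["S"]], 0.02)
    expect_rel(fi$state$N, cl$state[["N"]], 0.02)
    expect_rel(fi$state$E, cl$state[["E"]], 0.02)
  }
})

test_that("integrator choice barely moves the frozen endpoints", {
  ctx <- frozen_context(bci_state(), modifyList(bci_params(), list(d0 = 0.25)))
  e1 <- attr(frozen_trajectory(ctx, method = "euler"), "endpoint")$state
  e2 <- attr(frozen_trajectory(ctx, method = "rk4", dt = 0.1),
             "endpoint")$state
  expect_rel(e1$N, e2$N, 0.02)
  expect_rel(e1$E, e2$E, 0.01)
})

test_that("perturbed structure functions reproduce their own constraints", {
  fi <- first_iteration(disturbances = "w0=0.95")
  expect_lt(max(abs(attr(fi$lambda, "residuals"))), 1e-8)
  ## achieved constraints re-evaluated independently at the fit
  r <- constraint_residuals(fi$lambda,
                            constraint_vector(fi$state,
                                              derivs = as.list(fi$derivs)),
                            fi$state, fi$context$params,
                            attr(fi$lambda, "beta"))
  expect_lt(max(abs(r)), 1e-7)
})

test_that("zero perturbation keeps the fitted multipliers static", {
  par <- bci_params()
  ss <- steady_state(par, engine = "expectation", init = bci_state())
  ctx <- frozen_context(ss, par, constants = "quadrature")
  tr <- frozen_trajectory(ctx)
  ep <- attr(tr, "endpoint")
  lam <- perturbed_structure(ep$state, ep$derivs, ctx)
  expect_lt(max(abs(as.numeric(lam)[3:5])), 1e-3)
  m <- perturbed_metrics(lam, ep$state, ctx)
  ## rank curves match the static overlay to well under 1% of their range
  ra <- m$rank_abundance
  expect_lt(max(abs(log(ra$n_perturbed + 1) - log(ra$n_static + 1))),
            0.01 * diff(range(log(ra$n_static + 1))))
})

test_that("death-rate increase reshapes the metabolic distribution as published", {
  fi <- first_iteration(disturbances = "d0=0.25", metrics = TRUE)
  mr <- fi$metrics$mrdi
  ## more of the very smallest individuals
  expect_gt(mr$psi_perturbed[1], mr$psi_static[1])
  ## fewer individuals with low (2-100) metabolic rate
  sel <- mr$epsilon >= 2 & mr$epsilon <= 100
  dx <- diff(mr$epsilon)
  trap <- function(y) sum(((y[-1] + y[-length(y)]) / 2 * dx)[sel[-1]])
  expect_lt(trap(mr$psi_perturbed), trap(mr$psi_static))
})

test_that("growth and death perturbations shift the SAD in opposite directions", {
  fi_d <- first_iteration(disturbances = "d0=0.25", metrics = TRUE)
  fi_w <- first_iteration(disturbances = "w0=0.95", metrics = TRUE)
  dev_d <- fi_d$metrics$sad$phi_perturbed[1] - fi_d$metrics$sad$phi_static[1]
  dev_w <- fi_w$metrics$sad$phi_perturbed[1] - fi_w$metrics$sad$phi_static[1]
  expect_true(sign(dev_d) * sign(dev_w) < 0)
})
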