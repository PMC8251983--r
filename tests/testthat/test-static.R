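test_that("exact beta solver matches an independent bisection oracle", {
  expect_rel(solve_beta_exact(64, 1024), 0.01466974771, 1e-6)
  ## residual contract of the finite-sum relation
  b <- solve_beta_exact(64, 1024)
  n <- 1:1024
  w <- exp(-b * n)
  expect_lt(abs((64 / 1024) * sum(w) - sum(w / n)) / sum(w / n), 1e-10)
})

test_that("infeasible abundance relations raise errors", {
  expect_error(solve_beta_exact(1, 2), "infeasible")
  expect_error(solve_beta_exact(10, 10), "S < N")
  expect_error(solve_beta_approx(1, 2), "1/e")
  expect_error(solve_beta_approx(exp(-1) * (1 + 1e-6), 1), "1/e")
})

test_that("approximate beta solver hits the small root precisely", {
  b <- solve_beta_approx(320, 230000)
  expect_rel(b, 0.000159076673, 1e-8)      # frozen bisection oracle
  expect_lt(abs(b * log(1 / b) - 320 / 230000) / (320 / 230000), 1e-12)
  expect_lt(b, exp(-1))
})

test_that("beta is monotone in S/N and the two solvers agree when S << N", {
  ratios <- 10^seq(-6, -2, length.out = 20)
  betas <- vapply(ratios, function(r) solve_beta_approx(r * 1e6, 1e6),
                  numeric(1))
  expect_true(all(diff(betas) > 0))
  for (sn in list(c(64, 65536), c(320, 230000), c(150, 40000))) {
    expect_rel(solve_beta_approx(sn[1], sn[2]),
               solve_beta_exact(sn[1], sn[2]), 0.02)
  }
})

test_that("static solution reproduces the defining identities", {
  sol <- bci_sol()
  expect_equal(sol$lambda2, 320 / (2.04e7 - 230000))
  expect_rel(sol$lambda2, 1.5865146e-05, 1e-6)
  expect_rel(sol$lambda1, 0.00014321153, 1e-6)
  expect_identical(sol$lambda1 + sol$lambda2, sol$beta)
  expect_equal(sol$Z, sol$log_inv_beta / sol$lambda2)
  expect_error(static_solution(community_state(10, 100, 100)), "E > N")
})

test_that("log-series SAD has the printed form and normalises on its support", {
  sol <- bci_sol()
  expect_rel(sad_logseries(1, sol, renormalise = FALSE), 0.11431817, 1e-5)
  expect_equal(sad_logseries(2, sol) / sad_logseries(1, sol),
               exp(-sol$beta) / 2, tolerance = 1e-12)
  n <- seq_len(230000)
  p <- sad_logseries(n, sol)
  expect_true(all(p >= 0))
  expect_true(all(diff(p) < 0))
  expect_lt(abs(sum(p) - 1), 1e-6)
  expect_error(sad_logseries(0, sol), ">= 1")
})

test_that("metabolic rate density is decreasing, positive and normalised", {
  sol <- bci_sol()
  ## gamma(eps = 1) is exactly beta
  expect_equal(sol$lambda1 + sol$lambda2 * 1, sol$beta)
  eps <- exp(seq(0, log(5e6), length.out = 3001))
  psi <- mrdi(eps, sol)
  expect_true(all(psi >= 0))
  expect_true(all(diff(psi) < 0))
  ## Simpson on the log grid
  du <- diff(log(eps))[1]
  sw <- c(1, rep(c(4, 2), length.out = length(eps) - 2), 1) * du / 3
  expect_lt(abs(sum(psi * eps * sw) - 1), 1e-4)
  expect_error(mrdi(0.5, sol), ">= 1")
})

test_that("mean metabolism declines with abundance (energy equivalence)", {
  sol <- bci_sol()
  n <- c(1, 2, 5, 10, 100, 1000)
  eb <- mean_metabolism_given_n(n, sol)
  expect_true(all(diff(eb) < 0))
  expect_equal(mean_metabolism_given_n(2 * n, sol) <
                 mean_metabolism_given_n(n, sol), rep(TRUE, length(n)))
  ## brute-force conditional mean over a fine grid at n = 1
  eps <- seq(1, 60 / sol$lambda2, length.out = 2e5)
  w <- exp(-sol$lambda2 * 1 * eps)
  expect_rel(sum(eps * w) / sum(w), mean_metabolism_given_n(1, sol), 1e-3)
  ## within 10% of 1/lambda2 at the reference configuration
  expect_rel(mean_metabolism_given_n(1, sol), 1 / sol$lambda2, 0.1)
})

test_that("state-variable constraints are recovered under the static solution", {
  st <- bci_state()
  sol <- static_solution(st)
  lam <- static_lagrange(sol)
  en <- expectation(weight_abundance(), lam, st, bci_params(), sol$beta)
  ene <- expectation(weight_energy(), lam, st, bci_params(), sol$beta)
  expect_rel(st$S * en, st$N, 0.005)
  expect_rel(st$S * ene, st$E, 0.005)
})
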