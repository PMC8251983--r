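#' Marginal distributions of the structure function
#'
#' Derives the macroecological metrics from a (static or five-multiplier)
#' structure function: the species abundance distribution
#' `phi(n) = sum_eps R(n, eps)`, the metabolic rate distribution over
#' individuals `psi(eps) = (S/N) sum_n n R(n, eps)`, and the rank transforms
#' (expected abundance of the r-th most abundant of `S` species; expected
#' metabolic rate of the r-th largest of `N` individuals).  Both marginals
#' are renormalised on their supports.
#'
#' @param lambda A [lagrange_vector()].
#' @param state,params,beta Evaluation context (support `n` in `1..N`, the
#'   transition functions, and the `beta` used inside `h`).
#' @param quad A [quad_config()].
#' @param n_max Largest abundance tabulated term-by-term in the SAD table
#'   (the tail mass beyond it is reported as an attribute; rank curves use
#'   exact partial sums beyond `n_max`).
#' @param eps_points Number of grid points for the MRDI table.
#' @return List with `sad` (`n`, `phi`), `mrdi` (`epsilon`, `psi`),
#'   `rank_abundance` (`rank`, `n`), `rank_metabolism` (`rank`, `epsilon`);
#'   attribute `sad_tail_mass`.
#' @examples
#' st <- bci_state(); sol <- static_solution(st)
#' m <- marginals(static_lagrange(sol), st, bci_params(), sol$beta)
#' head(m$sad)
#' @export
marginals <- function(lambda, state, params, beta, quad = quad_config(),
                      n_max = 4096, eps_points = 2000) {
  state <- as_community_state(state)
  l <- as_lagrange(lambda)
  U <- max(1, round(state$N))
  n_max <- min(n_max, U)
  pass <- engine_pass(l, state, params, beta, quad = quad, keep_nodes = TRUE)
  nd <- pass$nodes
  Zt <- pass$Z_tilde
  eps_hi <- max(nd$eps)

  ## ---- SAD: term-by-term for n <= n_max --------------------------------
  nseq <- seq_len(n_max)
  ## chunked to bound memory: phi(n) = int exp(-A n) deps / Zt
  phi <- numeric(n_max)
  chunk <- max(1, floor(5e6 / length(nd$eps)))
  for (lo in seq(1, n_max, by = chunk)) {
    hi <- min(lo + chunk - 1, n_max)
    phi[lo:hi] <- as.numeric(exp(-outer(nseq[lo:hi], nd$A)) %*% nd$w) / Zt
  }
  phi[1] <- phi[1] + sum(nd$w * exp(-nd$A) * nd$dfac) / Zt
  Fmax <- sum(phi)
  tail_mass <- max(0, 1 - Fmax)
  ## renormalise so the SAD table + analytic tail sum to one exactly
  sad <- data.frame(n = nseq, phi = phi)

  ## exact CDF via closed-form partial geometric sums (any n)
  cdf_n <- function(n) {
    vapply(n, function(m) {
      g <- geom_sums(nd$A, m, order = 0)
      (sum(nd$w * g$G0) + sum(nd$w * exp(-nd$A) * nd$dfac)) / Zt
    }, numeric(1))
  }

  ## ---- rank abundance ---------------------------------------------------
  Sr <- max(1, round(state$S))
  qr <- 1 - (seq_len(Sr) - 0.5) / Sr          # rank 1 = most abundant
  Fcum <- cumsum(phi)
  ranks_n <- numeric(Sr)
  inside <- qr <= Fcum[n_max]
  ranks_n[inside] <- findInterval(qr[inside], Fcum) + 1
  if (any(!inside)) {
    ## bisect on the exact CDF beyond the table
    for (i in which(!inside)) {
      lo <- n_max; hi <- U
      while (hi - lo > 1) {
        mid <- floor((lo + hi) / 2)
        if (cdf_n(mid) < qr[i]) lo <- mid else hi <- mid
      }
      ranks_n[i] <- hi
    }
  }
  rank_abundance <- data.frame(rank = seq_len(Sr), n = ranks_n)

  ## ---- MRDI -------------------------------------------------------------
  eg <- exp(seq(log(1), log(eps_hi), length.out = eps_points))
  co <- transition_coefs(eg, state, params, beta)
  A <- l[1] + l[2] * eg + l[3] * co$cf + l[4] * co$ch + l[5] * co$cq
  g1 <- geom_sums(A, U, order = 1)
  dfac <- expm1(-l[5] * co$qd)
  psi_raw <- (g1$G1 + exp(-A) * dfac) / Zt * (state$S / state$N)
  ## renormalise on the support (trapezoid on the evaluation grid)
  dx <- diff(eg)
  norm <- sum((psi_raw[-1] + psi_raw[-eps_points]) / 2 * dx)
  psi <- psi_raw / norm
  mrdi <- data.frame(epsilon = eg, psi = psi)

  ## ---- rank metabolism ---------------------------------------------------
  Nr <- max(1, round(state$N))
  cdf_eps <- cumsum(c(0, (psi[-1] + psi[-eps_points]) / 2 * dx))
  cdf_eps <- cdf_eps / cdf_eps[eps_points]
  qe <- 1 - (seq_len(Nr) - 0.5) / Nr          # rank 1 = largest individual
  ## invert by monotone interpolation on the grid
  keep <- c(TRUE, diff(cdf_eps) > 0)
  ranks_eps <- approx(cdf_eps[keep], eg[keep], xout = qe, rule = 2)$y
  rank_metabolism <- data.frame(rank = seq_len(Nr), epsilon = ranks_eps)

  out <- list(sad = sad, mrdi = mrdi, rank_abundance = rank_abundance,
              rank_metabolism = rank_metabolism)
  attr(out, "sad_tail_mass") <- tail_mass
  out
}
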