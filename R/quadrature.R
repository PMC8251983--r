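## Quadrature over the metabolic-rate axis.
##
## All structure-function integrands are smooth in eps and decay like a power
## law out to eps ~ 1/lambda2_eff before rolling off exponentially, so the
## axis is covered by log2-spaced panels with fixed-order Gauss-Legendre nodes
## on each panel.  The panel walk extends adaptively until every integral's
## marginal panel contribution falls below `tail_rel` of its running total.

#' Quadrature configuration
#'
#' Controls the metabolic-rate quadrature used by the expectation engine.
#' Refining the scheme (more panels per octave or more nodes per panel) must
#' not change any reported expectation by more than the stated relative
#' tolerance; this contract is exercised in the test suite.
#'
#' @param rel_tol Target relative accuracy of reported expectations.
#' @param nodes_per_panel Gauss-Legendre order per panel.
#' @param panels_per_octave Number of panels per factor of 2 in `eps`.
#' @param tail_rel Stop extending the upper tail once every integral's panel
#'   contribution is below this fraction of its running total.
#' @param max_octaves Hard cap on the number of octaves walked.
#' @param exponent_cap Absolute cap on exponents; exceeding it signals a
#'   non-normalisable multiplier set.
#' @return A list of class `quad_config`.
#' @export
quad_config <- function(rel_tol = 1e-9, nodes_per_panel = 15,
                        panels_per_octave = 2, tail_rel = 1e-12,
                        max_octaves = 64, exponent_cap = 700) {
  structure(list(rel_tol = rel_tol, nodes_per_panel = nodes_per_panel,
                 panels_per_octave = panels_per_octave, tail_rel = tail_rel,
                 max_octaves = max_octaves, exponent_cap = exponent_cap),
            class = "quad_config")
}

## Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch; cached per order.
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  if (n == 1) {
    out <- list(x = 0, w = 2)
  } else {
    k <- seq_len(n - 1)
    b <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1)] <- b
    J[cbind(k + 1, k)] <- b
    e <- eigen(J, symmetric = TRUE)
    out <- list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
  }
  .gl_cache[[key]] <- out
  out
}

## Panel nodes and weights covering [1, 2^max_octaves] in octave blocks.
## Returns a generator: panel(j) gives nodes/weights of the j-th panel.
quad_panels <- function(quad) {
  gl <- gauss_legendre(quad$nodes_per_panel)
  ppo <- quad$panels_per_octave
  function(j) {
    ## panel j (1-based) spans [2^(a), 2^(a + 1/ppo)] in eps
    a <- (j - 1) / ppo
    lo <- 2^a
    hi <- 2^(a + 1 / ppo)
    half <- (hi - lo) / 2
    list(x = lo + half * (gl$x + 1), w = gl$w * half)
  }
}
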