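## Synthetic censuses: samples from the predicted static distributions, and
## conversion of census tables to state variables.  The only stochastic code
## in the package; everything is reproducible from the seed.

#' Sample a synthetic census from a static solution
#'
#' Draws `S` species with abundances i.i.d. from the finite-support
#' log-series SAD and, for every individual, a metabolic rate from the
#' conditional distribution given its species' abundance (a unit-shifted
#' exponential with rate `lambda2 * n` — the exact conditional of the static
#' structure function).
#'
#' @param sol A [static_solution()].
#' @param S Number of species to draw.
#' @param seed Integer seed (the function restores the caller's RNG state).
#' @param n_support Upper abundance limit (defaults to the solution's `N`).
#' @return A `synthetic_census`: list with `species` (`species_id`,
#'   `abundance`) and `individuals` (`species_id`, `epsilon`).
#' @examples
#' cen <- sample_census(static_solution(bci_state()), S = 50, seed = 1)
#' census_to_state(cen)
#' @export
sample_census <- function(sol, S, seed, n_support = NULL) {
  if (S < 1) stop("S must be >= 1", call. = FALSE)
  if (is.null(n_support)) n_support <- round(sol$state$N)
  if (!is.finite(sol$beta) || sol$beta <= 0)
    stop("infeasible static solution", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  n <- seq_len(n_support)
  pmf <- exp(-sol$beta * n) / n
  cdf <- cumsum(pmf) / sum(pmf)
  ab <- findInterval(runif(S), cdf) + 1L

  ids <- rep.int(seq_len(S), ab)
  eps <- 1 + rexp(sum(ab), rate = sol$lambda2 * rep.int(ab, ab))
  structure(list(species = data.frame(species_id = seq_len(S), abundance = ab),
                 individuals = data.frame(species_id = ids, epsilon = eps)),
            class = "synthetic_census")
}

#' @export
print.synthetic_census <- function(x, ...) {
  cat(sprintf("synthetic census: %d species, %d individuals\n",
              nrow(x$species), nrow(x$individuals)))
  invisible(x)
}

#' State variables of a census
#'
#' `S` is the number of species, `N` the summed abundance and `E` the summed
#' metabolic rate of all individuals.  A census without per-individual
#' metabolic rates gets `E = N` (every individual at the units floor), with a
#' message.
#'
#' @param census A `synthetic_census` or a compatible list.
#' @return A [community_state()].
#' @export
census_to_state <- function(census) {
  sp <- census$species
  if (is.null(sp) || nrow(sp) == 0) stop("empty census", call. = FALSE)
  if (any(sp$abundance < 1)) stop("census abundances must be >= 1", call. = FALSE)
  N <- sum(sp$abundance)
  ind <- census$individuals
  if (is.null(ind)) {
    message("census has no metabolic rates; using E = N (units floor)")
    E <- N
  } else {
    if (any(ind$epsilon < 1))
      stop("metabolic rates must be >= 1 (units convention)", call. = FALSE)
    if (nrow(ind) != N)
      stop("individual table does not match the summed abundances",
           call. = FALSE)
    E <- sum(ind$epsilon)
  }
  community_state(nrow(sp), N, E)
}

#' Census CSV input and output
#'
#' Two dialects: wide — columns `species_id, abundance` (no metabolic
#' rates) — and long — columns `species_id, epsilon`, one row per individual.
#' `read_census_csv()` auto-detects the dialect from the header.
#'
#' @param path CSV file path.
#' @return A `synthetic_census` (the wide dialect yields no `individuals`).
#' @export
read_census_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  cols <- names(tab)
  if (all(c("species_id", "abundance") %in% cols)) {
    census <- list(species = tab[, c("species_id", "abundance")],
                   individuals = NULL)
  } else if (all(c("species_id", "epsilon") %in% cols)) {
    ab <- as.data.frame(table(tab$species_id), stringsAsFactors = FALSE)
    names(ab) <- c("species_id", "abundance")
    census <- list(species = ab, individuals = tab[, c("species_id", "epsilon")])
  } else {
    stop("census CSV needs columns (species_id, abundance) or (species_id, epsilon)",
         call. = FALSE)
  }
  structure(census, class = "synthetic_census")
}

#' @rdname read_census_csv
#' @param census A `synthetic_census`.
#' @param long Write the long (per-individual) dialect if rates are present?
#' @export
write_census_csv <- function(census, path, long = !is.null(census$individuals)) {
  if (long) {
    if (is.null(census$individuals))
      stop("census has no individuals table", call. = FALSE)
    write.csv(census$individuals, path, row.names = FALSE, quote = FALSE)
  } else {
    write.csv(census$species, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
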