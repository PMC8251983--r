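## JSON and CSV input/output.  Numbers are written with 17 significant
## digits so round trips are bit-stable.

#' Read and write configuration objects as JSON
#'
#' States are stored as `{"S":..., "N":..., "E":...}`; parameter files use
#' the canonical keys `b0, d0, m0, w0, w10, Ec, mu, sigma1, sigma2, K` plus
#' an optional `disturbances` list of `{param, value, t_on}` records;
#' multiplier files use `lambda1..lambda5`.
#'
#' @param x Object to write.
#' @param path File path.
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @export
write_state_json <- function(x, path) {
  x <- as_community_state(x)
  jsonlite::write_json(list(S = x$S, N = x$N, E = x$E), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_state_json
#' @export
read_state_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  community_state(j$S, j$N, j$E)
}

#' @rdname write_state_json
#' @export
write_params_json <- function(x, path) {
  keys <- c("b0", "d0", "m0", "w0", "w10", "Ec", "mu", "sigma1", "sigma2", "K")
  out <- x[keys]
  if (!identical(x$w10_log_factor, "divide"))
    out$w10_log_factor <- x$w10_log_factor
  disturb <- attr(x, "disturbances")
  if (!is.null(disturb))
    out$disturbances <- lapply(as_disturbance_list(disturb), function(d)
      list(param = d$param, value = d$value, t_on = d$t_on))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_state_json
#' @export
read_params_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- transition_params(
    b0 = j$b0, d0 = j$d0, m0 = j$m0, w0 = j$w0, w10 = j$w10, Ec = j$Ec,
    mu = j$mu,
    sigma1 = if (is.null(j$sigma1)) 0 else j$sigma1,
    sigma2 = if (is.null(j$sigma2)) 0 else j$sigma2,
    K = if (is.null(j$K)) 1 else j$K,
    w10_log_factor = if (is.null(j$w10_log_factor)) "divide"
                     else j$w10_log_factor)
  if (!is.null(j$disturbances)) {
    dl <- j$disturbances
    if (is.data.frame(dl)) dl <- split(dl, seq_len(nrow(dl)))
    attr(p, "disturbances") <- lapply(dl, function(d)
      disturbance(d$param, d$value, if (is.null(d$t_on)) 0 else d$t_on))
  }
  p
}

#' @rdname write_state_json
#' @export
write_lambda_json <- function(x, path) {
  l <- as_lagrange(x)
  jsonlite::write_json(as.list(setNames(as.numeric(l), names(l))), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_state_json
#' @export
read_lambda_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lagrange_vector(j$lambda1, j$lambda2, j$lambda3, j$lambda4, j$lambda5)
}

#' Write a table as CSV with full precision
#'
#' Comma-separated, UTF-8, header row, `.` decimal; numeric columns printed
#' with 17 significant digits for bit-stable round trips.
#'
#' @param tab A data frame.
#' @param path Output path.
#' @export
write_table_csv <- function(tab, path) {
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(col) sprintf("%.17g", col))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
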