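#' Design parameters for a Bernoulli CUSUM proficiency test
#'
#' Bundles the four quantities that define the sequential test: the acceptable
#' failure rate `p0`, the unacceptable failure rate `p1`, the type 1 error
#' `alpha` (probability of falsely declaring an operator nonproficient) and the
#' type 2 error `beta` (probability of falsely declaring an operator
#' proficient).
#'
#' @param p0 Acceptable failure rate, in (0, 1). Default 0.1.
#' @param p1 Unacceptable failure rate, in (0, 1); must exceed `p0`.
#'   Default 0.2.
#' @param alpha Type 1 error probability, in (0, 1). Default 0.1.
#' @param beta Type 2 error probability, in (0, 1). Default 0.1.
#'
#' @return An object of class `"cusum_params"`: a named list with elements
#'   `p0`, `p1`, `alpha`, `beta`.
#' @seealso [cusum_constants()] for the derived scoring constants.
#' @examples
#' cusum_params()                  # the default EBUS-TBNA design
#' cusum_params(0.05, 0.15)        # a stricter design
#' @export
cusum_params <- function(p0 = 0.1, p1 = 0.2, alpha = 0.1, beta = 0.1) {
  for (nm in c("p0", "p1", "alpha", "beta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v >= 1)
      stop(sprintf("'%s' must be a single number strictly inside (0, 1), got %s",
                   nm, deparse(v)), call. = FALSE)
  }
  if (p0 >= p1)
    stop(sprintf(
      "p0 (%g) must be strictly smaller than p1 (%g): with p0 >= p1 the ",
      p0, p1), "sequential test has no discriminating power", call. = FALSE)
  structure(list(p0 = p0, p1 = p1, alpha = alpha, beta = beta),
            class = "cusum_params")
}

#' Derive CUSUM scoring constants and decision intervals
#'
#' Computes, from the design parameters, the log-likelihood-ratio increments
#' \eqn{P = \ln(p_1/p_0)} and \eqn{Q = \ln((1-p_0)/(1-p_1))}, the per-success
#' chart decrement \eqn{s = Q/(P+Q)} (each failure adds \eqn{1-s}), the
#' log-odds bounds \eqn{a = \ln((1-\beta)/\alpha)} and
#' \eqn{b = \ln((1-\alpha)/\beta)}, and the decision intervals
#' \eqn{H_0 = b/(P+Q)} and \eqn{H_1 = a/(P+Q)}. All natural logarithms; full
#' floating-point precision is retained (printing rounds to 2 decimals).
#'
#' @param params A [cusum_params()] object (or arguments passed on to it).
#' @param ... If `params` is missing, arguments forwarded to [cusum_params()].
#'
#' @return An object of class `"cusum_constants"`: a named list with elements
#'   `P`, `Q`, `s`, `failure_increment` (`= 1 - s`), `a`, `b`, `H0`, `H1`, and
#'   the originating `params`.
#' @examples
#' k <- cusum_constants(cusum_params(p0 = 0.1, p1 = 0.2, alpha = 0.1, beta = 0.1))
#' k            # prints H0 = H1 = 2.71 for the default design
#' k$s          # 0.1452444 at full precision
#' @export
cusum_constants <- function(params = cusum_params(...), ...) {
  if (!inherits(params, "cusum_params"))
    params <- do.call(cusum_params, as.list(params))
  P <- log(params$p1 / params$p0)
  Q <- log((1 - params$p0) / (1 - params$p1))
  a <- log((1 - params$beta) / params$alpha)
  b <- log((1 - params$alpha) / params$beta)
  s <- Q / (P + Q)
  structure(list(
    P = P, Q = Q, s = s, failure_increment = 1 - s,
    a = a, b = b, H0 = b / (P + Q), H1 = a / (P + Q),
    params = params
  ), class = "cusum_constants")
}

#' @export
print.cusum_params <- function(x, ...) {
  cat("CUSUM design parameters\n")
  cat(sprintf("  acceptable failure rate    p0 = %g\n", x$p0))
  cat(sprintf("  unacceptable failure rate  p1 = %g\n", x$p1))
  cat(sprintf("  type 1 error            alpha = %g\n", x$alpha))
  cat(sprintf("  type 2 error             beta = %g\n", x$beta))
  invisible(x)
}

#' @export
print.cusum_constants <- function(x, digits = 2, ...) {
  cat("CUSUM scoring constants (rounded for display)\n")
  cat(sprintf("  P = ln(p1/p0)           = %.*f\n", digits, x$P))
  cat(sprintf("  Q = ln((1-p0)/(1-p1))   = %.*f\n", digits, x$Q))
  cat(sprintf("  s (success decrement)   = %.*f\n", digits, x$s))
  cat(sprintf("  1 - s (failure increment) = %.*f\n", digits, x$failure_increment))
  cat(sprintf("  decision intervals: H0 = %.*f, H1 = %.*f\n",
              digits, x$H0, digits, x$H1))
  invisible(x)
}

#' @export
as.list.cusum_constants <- function(x, ...) unclass(x)

# Runtime guard: the two-boundary rule assumes no single attempt can complete a
# 2H excursion (otherwise a signal could fire at attempt 1). Holds for any
# conventional design (e.g. the default: max step 0.855 < 2H = 5.42).
check_step_vs_threshold <- function(constants) {
  step_max <- max(constants$s, constants$failure_increment)
  if (step_max >= 2 * min(constants$H0, constants$H1))
    stop("a single attempt's chart step (", signif(step_max, 4),
         ") reaches the 2*H decision threshold (",
         signif(2 * min(constants$H0, constants$H1), 4),
         "); choose design parameters with more separation or smaller errors",
         call. = FALSE)
  invisible(TRUE)
}
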