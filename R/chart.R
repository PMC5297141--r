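#' Parse an outcome vector
#'
#' Outcomes are coded with failure = 1 and success = 0. Accepted inputs:
#' integer/numeric 0/1, logical (`TRUE` = failure), or character/factor with
#' tokens `"F"`/`"S"` (case-insensitive; `"failure"`/`"success"` also accepted).
#'
#' @param x Vector of outcome marks.
#' @return Integer vector of 0 (success) / 1 (failure).
#' @export
as_outcomes <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    bad <- which(!(x %in% c(0, 1)))
    if (length(bad))
      stop("unknown outcome value ", deparse(x[bad[1]]), " at position ",
           bad[1], " (expected 0/1, S/F)", call. = FALSE)
    return(as.integer(x))
  }
  if (is.character(x)) {
    u <- toupper(trimws(x))
    out <- ifelse(u %in% c("F", "FAILURE", "1"), 1L,
                  ifelse(u %in% c("S", "SUCCESS", "0"), 0L, NA_integer_))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad))
      stop("unknown outcome token ", deparse(x[bad[1]]), " at position ",
           bad[1], " (expected 0/1, S/F)", call. = FALSE)
    return(out)
  }
  stop("cannot interpret outcomes of class ", class(x)[1], call. = FALSE)
}

#' Bernoulli CUSUM trajectory
#'
#' The chart starts at \eqn{C_0 = 0} and accumulates \eqn{1 - s} for each
#' failure and \eqn{-s} for each success. There is no holding barrier at zero:
#' a consistently successful operator's chart descends without bound, which is
#' what makes the downward-excursion proficiency signal possible.
#'
#' @param outcomes Outcome vector (see [as_outcomes()]); may be empty.
#' @param constants A [cusum_constants()] object.
#' @return Numeric vector of chart values `C_0 .. C_n` (length
#'   `length(outcomes) + 1`).
#' @examples
#' k <- cusum_constants()
#' cusum_trajectory(c("S", "S", "S"), k)   # 0, -s, -2s, -3s
#' @export
cusum_trajectory <- function(outcomes, constants = cusum_constants()) {
  stopifnot(inherits(constants, "cusum_constants"))
  f <- as_outcomes(outcomes)
  c(0, cumsum(ifelse(f == 1L, constants$failure_increment, -constants$s)))
}

# Core sequential scan implementing the two-boundary excursion rule.
# State is referenced to the running extrema since the last signal (or the
# start): a proficient signal fires at the first attempt where the chart has
# descended 2*H0 below the running maximum, a nonproficient signal where it has
# ascended 2*H1 above the running minimum. Every signal resets both extrema at
# the signalling value, so a repeat signal requires a fresh 2*H excursion.
# The changepoint estimate attached to each signal is the attempt at which the
# referenced extremum was attained (0 = the start value C_0).
#
# Returns list(states, signals) where states is an integer vector per attempt
# (0 inconclusive, 1 proficient, -1 nonproficient) and signals a data.frame
# with columns attempt, state, changepoint_attempt.
signal_scan <- function(outcomes, constants) {
  check_step_vs_threshold(constants)
  s <- constants$s
  fi <- constants$failure_increment
  up <- 2 * constants$H1
  dn <- 2 * constants$H0
  n <- length(outcomes)
  states <- integer(n)
  sig_at <- integer(0); sig_st <- integer(0); sig_cp <- integer(0)
  C <- 0; mx <- 0; mn <- 0; argmx <- 0L; argmn <- 0L; st <- 0L
  for (i in seq_len(n)) {
    C <- C + if (outcomes[i] == 1L) fi else -s
    if (C > mx) { mx <- C; argmx <- i }
    if (C < mn) { mn <- C; argmn <- i }
    if (mx - C >= dn) {
      if (st != 1L) {
        sig_at <- c(sig_at, i); sig_st <- c(sig_st, 1L); sig_cp <- c(sig_cp, argmx)
      }
      st <- 1L
      mx <- C; mn <- C; argmx <- i; argmn <- i
    } else if (C - mn >= up) {
      if (st != -1L) {
        sig_at <- c(sig_at, i); sig_st <- c(sig_st, -1L); sig_cp <- c(sig_cp, argmn)
      }
      st <- -1L
      mx <- C; mn <- C; argmx <- i; argmn <- i
    }
    states[i] <- st
  }
  list(states = states,
       signals = data.frame(attempt = sig_at, state = sig_st,
                            changepoint_attempt = sig_cp))
}

state_label <- function(code) {
  c("nonproficient", "inconclusive", "proficient")[code + 2L]
}

# Collapse a per-attempt state vector into maximal same-state runs.
states_to_segments <- function(states, signals) {
  n <- length(states)
  if (n == 0L)
    return(data.frame(state = character(0), start_attempt = integer(0),
                      end_attempt = integer(0), signal_attempt = integer(0),
                      changepoint_attempt = integer(0)))
  brk <- c(0L, which(diff(states) != 0L), n)
  starts <- brk[-length(brk)] + 1L
  ends <- brk[-1L]
  seg <- data.frame(
    state = state_label(states[starts]),
    start_attempt = starts,
    end_attempt = ends,
    signal_attempt = NA_integer_,
    changepoint_attempt = NA_integer_
  )
  # the signal that opened each non-initial segment is the state-changing
  # signal at its first attempt
  if (nrow(signals)) {
    idx <- match(seg$start_attempt, signals$attempt)
    seg$signal_attempt <- signals$attempt[idx]
    seg$changepoint_attempt <- signals$changepoint_attempt[idx]
  }
  seg
}

#' Classify a CUSUM trajectory into proficiency state segments
#'
#' Applies the two-boundary rule: a proficient signal fires at the first
#' attempt where the chart has descended `2 * H0` below its running maximum
#' since the last signal (or the start); a nonproficient signal fires where the
#' chart has ascended `2 * H1` above the running minimum. A signal resets both
#' running extrema at the signalling value; the declared state persists until
#' the opposite signal. Attempts before the first signal are inconclusive.
#'
#' Each segment carries the attempt at which its opening signal fired
#' (`signal_attempt`, `NA` for the initial segment) and the changepoint
#' estimate `changepoint_attempt` — the attempt at which the running extremum
#' referenced by the signal was attained, the usual CUSUM estimate of when the
#' underlying failure rate actually shifted.
#'
#' @param values Numeric trajectory `C_0 .. C_n` as produced by
#'   [cusum_trajectory()]. Step sizes are validated against `constants`.
#' @param constants A [cusum_constants()] object.
#' @return A data.frame of segments with columns `state` (one of
#'   `"inconclusive"`, `"proficient"`, `"nonproficient"`), `start_attempt`,
#'   `end_attempt`, `signal_attempt`, `changepoint_attempt`. Segments partition
#'   `1..n`; an empty trajectory yields zero rows.
#' @export
classify_states <- function(values, constants = cusum_constants()) {
  stopifnot(inherits(constants, "cusum_constants"))
  if (!is.numeric(values) || length(values) < 1L || values[1] != 0)
    stop("'values' must be a numeric trajectory starting at C_0 = 0",
         call. = FALSE)
  steps <- diff(values)
  outcomes <- integer(length(steps))
  for (i in seq_along(steps)) {
    if (abs(steps[i] - constants$failure_increment) < 1e-8) outcomes[i] <- 1L
    else if (abs(steps[i] + constants$s) < 1e-8) outcomes[i] <- 0L
    else stop("trajectory step ", i, " (", signif(steps[i], 6),
              ") matches neither -s nor 1-s for the supplied constants",
              call. = FALSE)
  }
  sc <- signal_scan(outcomes, constants)
  states_to_segments(sc$states, sc$signals)
}

#' Fit a CUSUM proficiency chart to an outcome sequence
#'
#' The central constructor: computes the trajectory and the proficiency
#' classification in one object.
#'
#' @param outcomes Outcome vector (see [as_outcomes()]): failure = 1/`"F"`,
#'   success = 0/`"S"`.
#' @param constants A [cusum_constants()] object; defaults to the standard
#'   design (`p0 = 0.1`, `p1 = 0.2`, `alpha = beta = 0.1`).
#' @param id Optional label (e.g. operator id) carried into printing and
#'   plotting.
#'
#' @return An object of class `"cusum_chart"` with components `outcomes`
#'   (integer 0/1), `values` (trajectory, length `n + 1`), `segments` (as from
#'   [classify_states()]), `signals`, `constants`, `id`.
#' @examples
#' ch <- cusum_chart(rep("S", 40))
#' ch              # proficient from attempt 38
#' summary(ch)
#' @export
cusum_chart <- function(outcomes, constants = cusum_constants(), id = NULL) {
  stopifnot(inherits(constants, "cusum_constants"))
  f <- as_outcomes(outcomes)
  if (anyNA(f)) stop("outcomes contain missing values", call. = FALSE)
  values <- c(0, cumsum(ifelse(f == 1L, constants$failure_increment,
                               -constants$s)))
  sc <- signal_scan(f, constants)
  structure(list(
    outcomes = f,
    values = values,
    segments = states_to_segments(sc$states, sc$signals),
    signals = sc$signals,
    constants = constants,
    id = id
  ), class = "cusum_chart")
}

#' Proficiency segments of a chart
#' @param chart A [cusum_chart()] object.
#' @return The segment data.frame (see [classify_states()]).
#' @export
proficiency_segments <- function(chart) {
  stopifnot(inherits(chart, "cusum_chart"))
  chart$segments
}

#' @export
print.cusum_chart <- function(x, ...) {
  n <- length(x$outcomes)
  cat("CUSUM proficiency chart",
      if (!is.null(x$id)) paste0(" [", x$id, "]"), "\n", sep = "")
  cat(sprintf("  %d attempts, %d failures (%.1f%%), final value %.3f\n",
              n, sum(x$outcomes), if (n) 100 * mean(x$outcomes) else 0,
              x$values[n + 1L]))
  if (nrow(x$segments) == 0L) {
    cat("  (no attempts)\n")
  } else {
    fin <- x$segments[nrow(x$segments), ]
    cat(sprintf("  current state: %s (since attempt %d)\n",
                fin$state, fin$start_attempt))
  }
  invisible(x)
}

#' @export
summary.cusum_chart <- function(object, ...) {
  structure(list(chart = object), class = "summary.cusum_chart")
}

#' @export
print.summary.cusum_chart <- function(x, ...) {
  ch <- x$chart
  print(ch)
  if (nrow(ch$segments)) {
    cat("\nState segments:\n")
    print(ch$segments, row.names = FALSE)
  }
  cat(sprintf("\nDecision intervals: H0 = %.2f, H1 = %.2f (signal = 2*H excursion)\n",
              ch$constants$H0, ch$constants$H1))
  invisible(x)
}

#' @export
as.data.frame.cusum_chart <- function(x, ...) {
  n <- length(x$outcomes)
  st <- if (n) {
    seg <- x$segments
    rep(seg$state, seg$end_attempt - seg$start_attempt + 1L)
  } else character(0)
  data.frame(
    attempt = seq_len(n),
    outcome = c("S", "F")[x$outcomes + 1L],
    cusum = x$values[-1L],
    state = st
  )
}

#' Plot a CUSUM proficiency chart
#'
#' Chart value against attempt number, horizontal gridlines every `H0` units,
#' signal attempts marked.
#'
#' @param x A [cusum_chart()] object.
#' @param ... Further arguments passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.cusum_chart <- function(x, ...) {
  n <- length(x$outcomes)
  H <- x$constants$H0
  ylim <- range(x$values, -H, H)
  graphics::plot(0:n, x$values, type = "s", xlab = "sampling attempt",
                 ylab = "CUSUM value", ylim = ylim,
                 main = if (!is.null(x$id)) paste("CUSUM chart:", x$id)
                        else "CUSUM chart", ...)
  grid_at <- seq(floor(ylim[1] / H), ceiling(ylim[2] / H)) * H
  graphics::abline(h = grid_at, col = "grey70", lty = 3)
  graphics::abline(h = 0, col = "grey40")
  if (nrow(x$signals)) {
    cols <- ifelse(x$signals$state == 1L, "forestgreen", "firebrick")
    graphics::abline(v = x$signals$attempt, col = cols, lty = 2)
    graphics::points(x$signals$attempt, x$values[x$signals$attempt + 1L],
                     pch = 19, col = cols)
  }
  invisible(x)
}
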