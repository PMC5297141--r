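#' Map proficiency state segments to chronological case intervals
#'
#' Translates attempt-level state segments into case-level interval labels
#' following the study semantics: the initial inconclusive span and any
#' nonproficient span before proficiency was first attained are labelled
#' `learning`; proficient spans are `proficiency`; a nonproficient span after
#' proficiency was first attained is `worsening`. Boundaries follow the
#' convention that the case containing the signalling attempt closes the
#' preceding interval and the next case opens the new one.
#'
#' @param segments Segment data.frame as returned by [classify_states()] or
#'   [proficiency_segments()].
#' @param attempt_to_case Integer vector: the (1-based, nondecreasing)
#'   chronological case index of each attempt; must cover every attempt in
#'   `segments` (multiple nodes per case allowed).
#' @return A data.frame with columns `label` (one of `"learning"`,
#'   `"proficiency"`, `"worsening"`), `start_case`, `end_case` (inclusive),
#'   partitioning the case range chronologically. Adjacent intervals with the
#'   same label are merged; an interval emptied by two signals falling in the
#'   same case is dropped.
#' @examples
#' k <- cusum_constants()
#' ch <- cusum_chart(c(rep("S", 45), rep("F", 10), rep("S", 45)), k)
#' segment_intervals(proficiency_segments(ch), rep(1:50, each = 2))
#' @export
segment_intervals <- function(segments, attempt_to_case) {
  stopifnot(is.data.frame(segments))
  empty <- data.frame(label = character(0), start_case = integer(0),
                      end_case = integer(0))
  if (nrow(segments) == 0L) return(empty)
  n_attempts <- max(segments$end_attempt)
  if (length(attempt_to_case) < n_attempts)
    stop("attempt_to_case (length ", length(attempt_to_case),
         ") does not cover all ", n_attempts, " attempts", call. = FALSE)
  attempt_to_case <- as.integer(attempt_to_case)
  if (is.unsorted(attempt_to_case))
    stop("attempt_to_case must be nondecreasing", call. = FALSE)

  prof_seen <- FALSE
  labels <- character(nrow(segments))
  for (j in seq_len(nrow(segments))) {
    st <- segments$state[j]
    if (st == "proficient") {
      labels[j] <- "proficiency"
      prof_seen <- TRUE
    } else if (st == "inconclusive") {
      labels[j] <- "learning"
    } else {
      labels[j] <- if (prof_seen) "worsening" else "learning"
    }
  }

  # boundary j sits at the case of the signal opening segment j+1
  m <- nrow(segments)
  bnd <- if (m > 1L) attempt_to_case[segments$signal_attempt[-1L]] else integer(0)
  start_case <- c(attempt_to_case[segments$start_attempt[1L]], bnd + 1L)
  end_case <- c(bnd, attempt_to_case[n_attempts])

  out <- data.frame(label = labels, start_case = start_case,
                    end_case = end_case)
  out <- out[out$end_case >= out$start_case, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  # merge adjacent same-label intervals (e.g. inconclusive then nonproficient,
  # both labelled learning)
  keep <- c(TRUE, out$label[-1L] != out$label[-nrow(out)])
  grp <- factor(cumsum(keep), levels = unique(cumsum(keep)))
  merged <- data.frame(
    label = out$label[keep],
    start_case = as.vector(tapply(out$start_case, grp, min)),
    end_case = as.vector(tapply(out$end_case, grp, max))
  )
  rownames(merged) <- NULL
  merged$start_case <- as.integer(merged$start_case)
  merged$end_case <- as.integer(merged$end_case)
  merged
}

#' Changepoint estimates at interval transitions
#'
#' For each transition between interval labels (learning to proficiency,
#' proficiency to worsening, ...), returns the estimated attempt at which the
#' underlying failure rate shifted: the `changepoint_attempt` of the segment
#' opening the new label, i.e. the attempt where the chart attained the
#' running extremum that the signalling excursion was measured from. Signal
#' attempts themselves lag the true change by roughly `2*H / |p - s|`
#' attempts; the extremum estimate does not.
#'
#' @param segments Segment data.frame from [classify_states()] or
#'   [proficiency_segments()].
#' @return Integer vector of estimated change attempts, one per label
#'   transition (empty if the chart never changes label).
#' @export
interval_changepoints <- function(segments) {
  if (nrow(segments) < 2L) return(integer(0))
  prof_seen <- FALSE
  labels <- character(nrow(segments))
  for (j in seq_len(nrow(segments))) {
    st <- segments$state[j]
    if (st == "proficient") {
      labels[j] <- "proficiency"; prof_seen <- TRUE
    } else if (st == "inconclusive") {
      labels[j] <- "learning"
    } else {
      labels[j] <- if (prof_seen) "worsening" else "learning"
    }
  }
  idx <- which(labels[-1L] != labels[-length(labels)]) + 1L
  as.integer(segments$changepoint_attempt[idx])
}
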