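#' @section Record schema:
#' One row per sampled lymph node, columns in this order:
#' `operator_id`, `case_id`, `node_order` (1-based within case), `date_order`
#' (integer chronological rank; alternatively an ISO-8601 `date` column),
#' `outcome` (`"S"` success / `"F"` failure; 0/1 also accepted, failure = 1),
#' `attending_assist` (0/1), `cytopathologist` (0/1), `midazolam_mg`,
#' `fentanyl_ug`.
#' @name record-schema
#' @keywords internal
NULL

RECORD_COLUMNS <- c("operator_id", "case_id", "node_order", "date_order",
                    "outcome", "attending_assist", "cytopathologist",
                    "midazolam_mg", "fentanyl_ug")

#' Validate a table of sampling-attempt records
#'
#' Checks the column contract, outcome coding, uniqueness of
#' `(case_id, node_order)`, and that case-level covariates (attending,
#' cytopathologist, doses) are constant within each case. An ISO-8601 `date`
#' column is converted to an integer `date_order` if the latter is absent.
#'
#' @param records A data.frame of sampling attempts (see `record-schema`).
#' @return The validated data.frame (with `date_order` filled in if derived
#'   from `date`).
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (is.null(records$date_order) && !is.null(records$date)) {
    d <- as.Date(as.character(records$date))
    if (anyNA(d))
      stop("row ", which(is.na(d))[1],
           ": 'date' is not ISO-8601 (YYYY-MM-DD)", call. = FALSE)
    records$date_order <- as.integer(d)
  }
  need <- c("operator_id", "case_id", "node_order", "date_order", "outcome")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  # outcome tokens, with the offending row named
  oc <- tryCatch(as_outcomes(records$outcome), error = function(e) e)
  if (inherits(oc, "error")) {
    bad <- sub(".*at position (\\d+).*", "\\1", conditionMessage(oc))
    stop("row ", bad, ": ", sub(" at position \\d+", "", conditionMessage(oc)),
         call. = FALSE)
  }
  if (any(records$node_order < 1 | records$node_order != round(records$node_order)))
    stop("'node_order' must be positive integers", call. = FALSE)
  key <- paste(records$case_id, records$node_order, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (case_id, node_order) at row ",
         which(duplicated(key))[1],
         ": records cannot be totally ordered", call. = FALSE)
  for (v in intersect(c("attending_assist", "cytopathologist",
                        "midazolam_mg", "fentanyl_ug"), names(records))) {
    per_case <- tapply(records[[v]], records$case_id,
                       function(x) length(unique(x[!is.na(x)])))
    if (any(per_case > 1, na.rm = TRUE))
      stop("covariate '", v, "' varies within case ",
           names(per_case)[which(per_case > 1)[1]],
           " (case-level covariates must be constant across a case's nodes)",
           call. = FALSE)
  }
  records
}

#' Pool all operators' attempts into one institutional sequence
#'
#' Orders records chronologically by `date_order`, breaking ties by
#' `(case_id, node_order)`, and numbers the pooled attempts 1..n. A
#' chronological case index (`case_index`) is assigned by order of each case's
#' first appearance. Per-operator sequences are obtained by filtering the
#' pooled result, which preserves each operator's own chronology.
#'
#' @param records Sampling-attempt records (validated via
#'   [validate_records()]).
#' @return The records sorted chronologically, with columns `attempt`
#'   (1..n over the pooled sequence) and `case_index` (1-based chronological
#'   case rank) appended.
#' @export
pool_institutional <- function(records) {
  records <- validate_records(records)
  ord <- order(records$date_order, records$case_id, records$node_order)
  pooled <- records[ord, , drop = FALSE]
  rownames(pooled) <- NULL
  pooled$attempt <- seq_len(nrow(pooled))
  pooled$case_index <- match(pooled$case_id, unique(pooled$case_id))
  pooled
}

#' Read / write sampling-attempt records as CSV
#'
#' UTF-8 CSV with a header row; outcomes coded `"S"`/`"F"`. Columns follow the
#' documented schema order.
#'
#' @param path File path.
#' @param records A records data.frame.
#' @return `read_records` returns the validated data.frame; `write_records`
#'   returns `path` invisibly.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_records(records)
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  cols <- intersect(RECORD_COLUMNS, names(records))
  utils::write.csv(records[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}
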