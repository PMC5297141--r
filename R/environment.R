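ENV_COVARIATES <- c("attending_assist", "cytopathologist",
                    "high_midazolam", "high_fentanyl")

#' Build the learning-environment analysis frame
#'
#' Joins sampling-attempt records to chronological proficiency intervals and
#' dichotomizes the sedation/analgesia doses. The analysis outcome
#' `outcome_nonproficient` marks rows falling in a worsening interval; the raw
#' sampling outcome is kept as `outcome_failure`. Rows with a missing model
#' covariate are dropped (complete-case analysis) and the drop count is
#' reported via a message and the `n_dropped` attribute.
#'
#' @param records Sampling-attempt records (see [validate_records()]).
#' @param intervals Interval labels from [segment_intervals()] (columns
#'   `label`, `start_case`, `end_case` on the chronological case index).
#' @param midazolam_threshold High-dose midazolam cutpoint in mg, inclusive
#'   (`>=`). Default 10.
#' @param fentanyl_threshold High-dose fentanyl cutpoint in µg, inclusive.
#'   Default 300.
#' @param unit Unit of analysis: `"node"` (one row per sampling attempt, the
#'   study's default) or `"case"` (one row per case; covariates are case-level
#'   and a case's `outcome_failure` is 1 if any of its nodes failed).
#' @return A data.frame with columns `unit_id`, `case_index`, `interval`,
#'   `outcome_nonproficient`, `outcome_failure`, `attending_assist`,
#'   `cytopathologist`, `high_midazolam`, `high_fentanyl`, plus attribute
#'   `n_dropped`.
#' @export
build_analysis_frame <- function(records, intervals,
                                 midazolam_threshold = 10,
                                 fentanyl_threshold = 300,
                                 unit = c("node", "case")) {
  unit <- match.arg(unit)
  pooled <- if (!is.null(records$attempt) && !is.null(records$case_index))
    records else pool_institutional(records)
  stopifnot(is.data.frame(intervals),
            all(c("label", "start_case", "end_case") %in% names(intervals)))

  lab <- rep(NA_character_, nrow(pooled))
  for (j in seq_len(nrow(intervals))) {
    inside <- pooled$case_index >= intervals$start_case[j] &
      pooled$case_index <= intervals$end_case[j]
    lab[inside] <- intervals$label[j]
  }
  if (anyNA(lab))
    stop("case ", pooled$case_id[which(is.na(lab))[1]],
         " (chronological index ", pooled$case_index[which(is.na(lab))[1]],
         ") is not covered by the supplied intervals", call. = FALSE)

  frame <- data.frame(
    unit_id = pooled$case_id,
    case_index = pooled$case_index,
    interval = lab,
    outcome_nonproficient = as.integer(lab == "worsening"),
    outcome_failure = as_outcomes(pooled$outcome),
    attending_assist = as.integer(pooled$attending_assist),
    cytopathologist = as.integer(pooled$cytopathologist),
    high_midazolam = as.integer(pooled$midazolam_mg >= midazolam_threshold),
    high_fentanyl = as.integer(pooled$fentanyl_ug >= fentanyl_threshold)
  )

  if (unit == "case") {
    any_fail <- tapply(frame$outcome_failure, as.character(frame$unit_id), max)
    frame <- frame[!duplicated(frame$unit_id), , drop = FALSE]
    frame$outcome_failure <- as.integer(any_fail[as.character(frame$unit_id)])
    rownames(frame) <- NULL
  }

  complete <- stats::complete.cases(frame[, ENV_COVARIATES])
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message("build_analysis_frame: dropped ", n_dropped,
            " row(s) with missing model covariates")
  frame <- frame[complete, , drop = FALSE]
  rownames(frame) <- NULL
  attr(frame, "n_dropped") <- n_dropped
  frame
}

# Firth-penalized logistic regression (Jeffreys prior): Newton iteration on
# the modified score U*(b) = X'(y - p + h (1/2 - p)), h the hat diagonal from
# the Fisher information, with step-halving on the penalized log-likelihood.
# Returns finite estimates under complete or quasi-complete separation.
firth_logistic <- function(X, y, maxit = 100, tol = 1e-8) {
  p_dim <- ncol(X)
  beta <- numeric(p_dim)
  pen_ll <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- pmax(mu * (1 - mu), .Machine$double.eps)
    info <- crossprod(X * W, X)
    sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(info)$modulus
  }
  ll_old <- pen_ll(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- pmax(mu * (1 - mu), .Machine$double.eps)
    info <- crossprod(X * W, X)
    XWh <- X * sqrt(W)
    h <- rowSums((XWh %*% solve(info)) * XWh)
    U <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    delta <- solve(info, U)
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      ll_new <- pen_ll(beta_new)
      if (is.finite(ll_new) && (ll_new >= ll_old - 1e-10 || step < 1e-4)) break
      step <- step / 2
    }
    conv <- max(abs(beta_new - beta))
    beta <- beta_new
    ll_old <- ll_new
    if (conv < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  W <- pmax(mu * (1 - mu), .Machine$double.eps)
  vcov <- solve(crossprod(X * W, X))
  list(coefficients = stats::setNames(beta, colnames(X)), vcov = vcov,
       iterations = it, converged = conv < tol)
}

# Per-covariate separation diagnostics: a binary covariate perfectly
# predicting the outcome on one of its levels (zero cell in the 2x2
# cross-tabulation), or a diverging ML estimate.
separation_flags <- function(frame, covariates, y, estimates,
                             divergence_bound = 10) {
  vapply(covariates, function(v) {
    x <- frame[[v]]
    zero_cell <- length(unique(x)) == 2 &&
      any(table(factor(x, levels = sort(unique(x))),
                factor(y, levels = 0:1)) == 0)
    diverged <- is.finite(estimates[v]) && abs(estimates[v]) > divergence_bound
    as.integer(zero_cell || diverged || !is.finite(estimates[v]))
  }, integer(1))
}

#' Contrast environmental covariates across proficiency intervals
#'
#' Multivariable logistic regression of worsening-interval membership (or of
#' the raw sampling outcome) on the learning-environment covariates: assisting
#' attending present, on-site cytopathologist present, high midazolam dose,
#' high fentanyl dose. Reports odds ratios with Wald 95% confidence intervals
#' and 2-tailed Wald p-values. Within-case clustering is not adjusted for
#' (each sampled node is treated as independent); interpret accordingly.
#'
#' @param frame An analysis frame from [build_analysis_frame()] (or any
#'   data.frame with the outcome and 0/1 covariate columns).
#' @param method `"wald_ml"` (maximum likelihood via [stats::glm()]; default)
#'   or `"firth"` (Jeffreys-penalized likelihood, which yields finite
#'   estimates under separation).
#' @param response `"worsening"` (models `outcome_nonproficient`, the study's
#'   interval contrast) or `"failure"` (models the sampling outcome itself).
#' @param covariates Character vector of covariate columns; defaults to the
#'   four study covariates present in `frame`.
#' @param conf_level Confidence level for the Wald intervals. Default 0.95.
#' @return An object of class `"env_fit"`: list with `table` (one row per
#'   covariate: `term`, `estimate` (log-odds), `se`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `separation_flag`), `method`, `response`, `n_rows`,
#'   `n_dropped`, `conf_level`, `coefficients`, `vcov`.
#' @examples
#' set.seed(1)
#' fr <- data.frame(outcome_nonproficient = rbinom(200, 1, 0.3),
#'                  attending_assist = rbinom(200, 1, 0.5))
#' fit_environment(fr, covariates = "attending_assist")
#' @export
fit_environment <- function(frame, method = c("wald_ml", "firth"),
                            response = c("worsening", "failure"),
                            covariates = NULL, conf_level = 0.95) {
  method <- match.arg(method)
  response <- match.arg(response)
  ycol <- if (response == "worsening") "outcome_nonproficient" else
    "outcome_failure"
  if (is.null(frame[[ycol]]))
    stop("frame has no '", ycol, "' column", call. = FALSE)
  if (is.null(covariates))
    covariates <- intersect(ENV_COVARIATES, names(frame))
  if (length(covariates) < 1L)
    stop("no model covariates found in the frame", call. = FALSE)
  y <- frame[[ycol]]
  if (length(unique(y)) < 2L)
    stop("degenerate outcome: '", ycol, "' is constant (all ", y[1],
         ") in the supplied frame", call. = FALSE)

  X <- cbind(`(Intercept)` = 1,
             as.matrix(frame[, covariates, drop = FALSE]))
  storage.mode(X) <- "double"
  const <- covariates[apply(X[, -1, drop = FALSE], 2,
                            function(v) length(unique(v)) < 2L)]
  if (length(const))
    stop("degenerate covariate: '", const[1],
         "' is constant in the supplied frame", call. = FALSE)
  if (qr(X)$rank < ncol(X)) {
    cc <- stats::cor(X[, -1, drop = FALSE])
    diag(cc) <- 0
    pair <- which(abs(abs(cc) - 1) < 1e-12, arr.ind = TRUE)
    if (nrow(pair)) {
      idx <- sort(pair[1, ])
      stop("collinear covariates: '", covariates[idx[1]], "' and '",
           covariates[idx[2]], "'", call. = FALSE)
    }
    stop("covariate matrix is rank deficient", call. = FALSE)
  }

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (method == "wald_ml") {
    fml <- stats::reformulate(covariates, response = ycol)
    fit <- suppressWarnings(stats::glm(fml, data = frame,
                                       family = stats::binomial()))
    est <- stats::coef(fit)
    V <- suppressWarnings(stats::vcov(fit))
  } else {
    ff <- firth_logistic(X, y)
    est <- ff$coefficients
    V <- ff$vcov
  }
  se <- sqrt(diag(V))
  flags <- separation_flags(frame, covariates, y, est)
  idx <- covariates
  tab <- data.frame(
    term = covariates,
    estimate = unname(est[idx]),
    se = unname(se[idx]),
    odds_ratio = unname(exp(est[idx])),
    ci_low = unname(exp(est[idx] - z * se[idx])),
    ci_high = unname(exp(est[idx] + z * se[idx])),
    p_value = unname(2 * stats::pnorm(-abs(est[idx] / se[idx]))),
    separation_flag = unname(flags[idx])
  )
  structure(list(
    table = tab,
    coefficients = est,
    vcov = V,
    method = method,
    response = response,
    n_rows = nrow(frame),
    n_dropped = attr(frame, "n_dropped") %||% 0L,
    conf_level = conf_level
  ), class = "env_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.env_fit <- function(x, digits = 3, ...) {
  cat("Learning-environment logistic regression (", x$method, ", response: ",
      x$response, ")\n", sep = "")
  cat("  n =", x$n_rows, "rows")
  if (x$n_dropped > 0) cat(" (", x$n_dropped, " dropped for missingness)",
                           sep = "")
  cat("\n  NOTE: within-case clustering of sampled nodes is not adjusted for\n\n")
  tab <- x$table
  out <- data.frame(
    term = tab$term,
    OR = signif(tab$odds_ratio, digits),
    ci = sprintf("(%s, %s)", signif(tab$ci_low, digits),
                 signif(tab$ci_high, digits)),
    p = signif(tab$p_value, digits),
    sep = ifelse(tab$separation_flag == 1, "*", "")
  )
  names(out) <- c("term", "OR",
                  sprintf("%g%% CI", 100 * x$conf_level), "p", "")
  print(out, row.names = FALSE)
  if (any(tab$separation_flag == 1))
    cat("  * separation detected",
        if (x$method == "wald_ml") " (consider method = \"firth\")", "\n",
        sep = "")
  invisible(x)
}

#' @export
summary.env_fit <- function(object, ...) object

#' @export
coef.env_fit <- function(object, ...) object$coefficients

#' @export
vcov.env_fit <- function(object, ...) object$vcov

#' @export
confint.env_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(object$vcov))
  ci <- cbind(object$coefficients - z * se, object$coefficients + z * se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
as.data.frame.env_fit <- function(x, ...) x$table
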