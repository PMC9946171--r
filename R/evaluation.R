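# Evaluation surfaces: discrimination (Mann-Whitney AUC with DeLong
# variance and paired DeLong comparison), calibration per score value, and
# decision-curve analysis with standardized net benefit.

.orient <- function(scores, direction) {
  direction <- match.arg(direction, c("higher", "lower"))
  if (direction == "lower") -as.numeric(scores) else as.numeric(scores)
}

# midranks (average ranks for ties)
.midrank <- function(x) rank(x, ties.method = "average")

# DeLong structural components for one score vector (oriented so higher =
# higher risk). V10: one component per case; V01: one per control.
delong_components <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  if (anyNA(scores) || anyNA(y)) stop_ed("scores and outcomes must be complete")
  m <- sum(y); n <- sum(!y)
  if (m == 0 || n == 0) stop_ed("both outcome classes must be present")
  x_case <- scores[y]; x_ctrl <- scores[!y]
  tz <- .midrank(c(x_case, x_ctrl))
  tx <- .midrank(x_case)
  ty <- .midrank(x_ctrl)
  v10 <- (tz[seq_len(m)] - tx) / n
  v01 <- 1 - (tz[m + seq_len(n)] - ty) / m
  auc <- (sum(tz[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' ROC AUC with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney concordance probability (ties count 1/2)
#' after orienting the score: `direction = "higher"` when larger values
#' mean higher risk (NEWS), `"lower"` when smaller values mean higher risk
#' (ROX). The standard error comes from DeLong's structural components and
#' the 95% CI is normal-approximate, truncated to \[0, 1\].
#'
#' @param scores Numeric score per patient.
#' @param outcomes Logical event indicator (death within 24 h).
#' @param direction `"higher"` or `"lower"` (which end of the score is
#'   high-risk).
#' @return A `roc_result`: list with `auc`, `se`, `ci95`, `curve` (tibble
#'   of `fpr`, `tpr` from (0,0) to (1,1)), `n_cases`, `n_controls`.
#' @export
compute_auc <- function(scores, outcomes, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  s <- .orient(scores, direction)
  comp <- delong_components(s, outcomes)
  se <- sqrt(var(comp$v10) / comp$m + var(comp$v01) / comp$n)
  if (!is.finite(se)) se <- 0
  ci <- clamp(comp$auc + c(-1, 1) * qnorm(0.975) * se, 0, 1)
  # ROC polyline over unique thresholds, descending score
  y <- as.logical(outcomes)
  ord <- order(s, decreasing = TRUE)
  tp <- cumsum(y[ord]); fp <- cumsum(!y[ord])
  last <- !duplicated(s[ord], fromLast = TRUE)  # collapse tied thresholds
  curve <- tibble(
    fpr = c(0, fp[last] / comp$n),
    tpr = c(0, tp[last] / comp$m)
  )
  structure(
    list(auc = comp$auc, se = se, ci95 = ci, curve = curve,
         n_cases = comp$m, n_controls = comp$n, direction = direction),
    class = "roc_result"
  )
}

#' Paired DeLong comparison of two AUCs
#'
#' Compares the AUCs of two scores measured on the same patients. The
#' variance of the AUC difference uses the paired structural-component
#' covariance; the p value is two-sided normal. A score compared with
#' itself gives difference 0 and p = 1.
#'
#' @param scores_a,scores_b Numeric scores on the same patients.
#' @param outcomes Logical event indicator.
#' @param direction_a,direction_b Orientation of each score (see
#'   [compute_auc()]).
#' @return A `delong_comparison`: list with `auc_a`, `auc_b`, `difference`
#'   (a minus b), `variance`, `z`, `p`.
#' @export
delong_compare <- function(scores_a, scores_b, outcomes,
                           direction_a = "higher", direction_b = "higher") {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(outcomes)) {
    stop_ed("scores_a, scores_b and outcomes must have equal length (paired design)")
  }
  ca <- delong_components(.orient(scores_a, direction_a), outcomes)
  cb <- delong_components(.orient(scores_b, direction_b), outcomes)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ca$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ca$n
  diff <- ca$auc - cb$auc
  if (!is.finite(var_diff) || var_diff <= 0) {
    z <- if (diff == 0) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(var_diff)
  }
  p <- 2 * pnorm(-abs(z))
  structure(
    list(auc_a = ca$auc, auc_b = cb$auc, difference = diff,
         variance = max(var_diff, 0), z = z, p = p),
    class = "delong_comparison"
  )
}

#' Fit and pool a score-to-risk logistic model
#'
#' Per imputed set, fits a logistic regression of the 24-h outcome on the
#' integer score (a single linear term by default, or a natural cubic
#' spline with `form = "spline"`), then pools intercept and coefficients by
#' averaging across sets. The per-set coefficients are retained for audit.
#' By the score-equation property of maximum-likelihood logistic fits with
#' an intercept, the mean predicted risk in each fitting set equals the
#' observed event fraction.
#'
#' @param scores Output of [score_cohort()] (tibble with `.imp`,
#'   `patient_id` and score columns) or a plain numeric vector (one set).
#' @param outcomes Logical event indicator, in patient order (recycled
#'   across sets).
#' @param score Which score column to model (`"news"` or `"rox"`) when
#'   `scores` is a scored tibble.
#' @param form `"linear"` (default) or `"spline"` (natural cubic spline,
#'   3 df, knots fixed from the pooled score distribution).
#' @return An `ed_risk_model` with `intercept`, `coefficients` (pooled),
#'   `per_set` coefficient matrix, and prediction support via
#'   [predict_risk()].
#' @export
fit_risk_model <- function(scores, outcomes, score = c("news", "rox"),
                           form = c("linear", "spline")) {
  form <- match.arg(form)
  if (is.numeric(scores)) {
    score <- match.arg(score)
    sets <- list(as.numeric(scores))
  } else {
    score <- match.arg(score)
    sets <- split(as.numeric(scores[[score]]), scores$.imp)
  }
  y <- as.logical(outcomes)
  n <- length(sets[[1]])
  if (length(y) != n) stop_ed("outcomes length does not match patients per set")

  knots <- NULL
  boundary <- NULL
  if (form == "spline") {
    all_s <- unlist(sets)
    knots <- unique(stats::quantile(all_s, c(0.25, 0.5, 0.75), names = FALSE))
    boundary <- range(all_s)
  }
  basis <- function(s) {
    if (form == "linear") matrix(s, ncol = 1, dimnames = list(NULL, "score"))
    else splines::ns(s, knots = knots, Boundary.knots = boundary)
  }

  fits <- lapply(seq_along(sets), function(k) {
    s <- sets[[k]]
    if (length(unique(y)) < 2) {
      stop_ed("set %d has a single outcome class; cannot fit risk model", k)
    }
    X <- basis(s)
    fit <- suppressWarnings(glm(y ~ X, family = binomial()))
    if (!fit$converged || fit$deviance < 1e-6 ||
        any(abs(coef(fit)) > 50, na.rm = TRUE)) {
      stop_ed("logistic fit failed in set %d (possible complete separation)", k)
    }
    coef(fit)
  })
  coef_mat <- do.call(rbind, fits)
  pooled <- colMeans(coef_mat)
  structure(
    list(score = score, form = form,
         intercept = pooled[1], coefficients = pooled[-1],
         per_set = coef_mat, knots = knots, boundary = boundary,
         n = n, m = length(sets)),
    class = "ed_risk_model"
  )
}

#' Predicted 24-h mortality risk for score values
#'
#' @param model An [fit_risk_model()] object.
#' @param score_values Numeric score values.
#' @return Predicted probabilities in (0, 1).
#' @export
predict_risk <- function(model, score_values) {
  stopifnot(inherits(model, "ed_risk_model"))
  s <- as.numeric(score_values)
  X <- if (model$form == "linear") {
    matrix(s, ncol = 1)
  } else {
    splines::ns(s, knots = model$knots, Boundary.knots = model$boundary)
  }
  plogis(model$intercept + drop(X %*% model$coefficients))
}

#' Calibration of predicted against observed mortality per score value
#'
#' Groups patients by integer score value and reports, per group, the mean
#' model-predicted risk, the observed 24-h death fraction and the patient
#' count — both the calibration curve and the raw observed-mortality-by-
#' score table. Groups below `min_group_size` are dropped from the curve
#' (sparse extreme scores), but counts always total the cohort before the
#' size filter.
#'
#' @param model An [fit_risk_model()] object.
#' @param scores Numeric score per patient.
#' @param outcomes Logical event indicator.
#' @param min_group_size Smallest group to keep (default 1 = keep all).
#' @return A tibble with `score`, `n`, `predicted`, `observed`.
#' @export
calibration_curve <- function(model, scores, outcomes, min_group_size = 1L) {
  s <- as.numeric(scores)
  y <- as.logical(outcomes)
  groups <- sort(unique(s))
  tbl <- do.call(rbind, lapply(groups, function(g) {
    idx <- s == g
    tibble(score = g, n = sum(idx),
           predicted = mean(predict_risk(model, s[idx])),
           observed = mean(y[idx]))
  }))
  tbl[tbl$n >= min_group_size, , drop = FALSE]
}

#' Exchange rate (harm weight) at a threshold probability
#'
#' The odds of the threshold, `p_t / (1 - p_t)`: how many false positives
#' one missed event is worth at that threshold. At 10% the exchange rate is
#' 0.1/0.9 = 0.111.
#'
#' @param p_t Threshold probability in \[0, 1).
#' @return `p_t / (1 - p_t)`.
#' @export
exchange_rate <- function(p_t) {
  if (any(p_t >= 1 | p_t < 0)) stop_ed("threshold must lie in [0, 1)")
  p_t / (1 - p_t)
}

#' Decision curve: net benefit across threshold probabilities
#'
#' At each threshold `p_t`, patients with predicted risk >= `p_t` are
#' flagged high-risk; net benefit = TP/N - (FP/N) * p_t/(1-p_t). The curve
#' is reported alongside the treat-all reference,
#' `prevalence - (1-prevalence) * p_t/(1-p_t)`, and treat-none (always 0).
#' Standardized net benefit divides by the outcome prevalence, so 1 is the
#' maximum attainable.
#'
#' @param predicted_risks Predicted probabilities in \[0, 1\].
#' @param outcomes Logical event indicator.
#' @param thresholds Threshold probabilities in (0, 1); default 0.001 to
#'   0.10 by 0.001, covering the plausible risk range of a population with
#'   ~0.7% 24-h mortality.
#' @return A tibble with `threshold`, `net_benefit`,
#'   `standardized_net_benefit`, `treat_all`, `treat_none`; prevalence is
#'   attached as attribute `"prevalence"`.
#' @export
decision_curve <- function(predicted_risks, outcomes,
                           thresholds = seq(0.001, 0.10, by = 0.001)) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop_ed("thresholds must lie strictly inside (0, 1)")
  }
  r <- as.numeric(predicted_risks)
  if (any(r < 0 | r > 1)) stop_ed("predicted risks must lie in [0, 1]")
  y <- as.logical(outcomes)
  N <- length(y)
  prev <- mean(y)
  nb <- vapply(thresholds, function(pt) {
    pos <- r >= pt
    sum(pos & y) / N - sum(pos & !y) / N * exchange_rate(pt)
  }, numeric(1))
  out <- tibble(
    threshold = thresholds,
    net_benefit = nb,
    standardized_net_benefit = if (prev > 0) nb / prev else NA_real_,
    treat_all = prev - (1 - prev) * exchange_rate(thresholds),
    treat_none = 0
  )
  attr(out, "prevalence") <- prev
  out
}
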