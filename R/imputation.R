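# Missing-vitals handling: the study exclusion rule (>= 4 of the 5 vitals
# missing), multiple imputation by chained equations, and pooling of
# per-set estimates.

.counted_vitals <- c("sbp", "heart_rate", "spo2", "respiratory_rate", "temperature")
.impute_targets_cont <- c("sbp", "heart_rate", "respiratory_rate", "spo2",
                          "temperature", "fio2", "urea", "leukocytes")
.impute_targets_bin <- "alert"

#' Exclude records with four or more missing vitals
#'
#' Records missing at least 4 of the 5 counted vitals (systolic blood
#' pressure, heart rate, oxygen saturation, respiratory rate, temperature)
#' are considered non-randomly missing beyond repair and removed before
#' imputation. The operation is idempotent.
#'
#' @param cohort An `ed_cohort`.
#' @return A list: `cohort` (retained records), `excluded` (tibble of
#'   `patient_id` and `n_missing_vitals`), `n_input`, `n_excluded`.
#' @export
exclude_by_missingness <- function(cohort) {
  if (nrow(cohort) == 0) {
    return(list(cohort = cohort,
                excluded = tibble(patient_id = character(),
                                  n_missing_vitals = integer()),
                n_input = 0L, n_excluded = 0L))
  }
  n_missing <- rowSums(is.na(as_tibble(cohort)[.counted_vitals]))
  drop <- n_missing >= 4
  list(
    cohort = cohort[!drop, , drop = FALSE],
    excluded = tibble(patient_id = cohort$patient_id[drop],
                      n_missing_vitals = as.integer(n_missing[drop])),
    n_input = nrow(cohort),
    n_excluded = sum(drop)
  )
}

# predictive-mean-matching draw: for each missing prediction, pick one of
# the k observed donors whose (observed-model) predictions are nearest,
# and return that donor's observed value. Sorted two-pointer search keeps
# this O(n log n).
pmm_draw <- function(pred_obs, y_obs, pred_mis, k = 5L) {
  k <- min(k, length(y_obs))
  ord <- order(pred_obs)
  po <- pred_obs[ord]
  yo <- y_obs[ord]
  n_obs <- length(po)
  pos <- findInterval(pred_mis, po)
  vapply(seq_along(pred_mis), function(i) {
    lo <- max(1L, pos[i] - k)
    hi <- min(n_obs, pos[i] + k)
    idx <- lo:hi
    d <- abs(po[idx] - pred_mis[i])
    donors <- idx[order(d)][seq_len(k)]
    yo[donors[sample.int(k, 1L)]]
  }, numeric(1))
}

# Bayesian linear-model draw of coefficients (normal approximation around
# the least-squares fit with a scaled-inverse-chi-square residual variance)
.bayes_lm_draw <- function(X, y) {
  qr_x <- qr(X)
  keep <- qr_x$pivot[seq_len(qr_x$rank)]
  Xk <- X[, keep, drop = FALSE]
  fit <- lm.fit(Xk, y)
  beta <- fit$coefficients
  df <- max(length(y) - length(beta), 1L)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / rchisq(1, df)
  xtx_inv <- chol2inv(qr.R(qr(Xk)))
  beta_star <- beta + drop(MASS::mvrnorm(1, rep(0, length(beta)),
                                         sigma2 * xtx_inv))
  list(keep = keep, beta = beta, beta_star = beta_star)
}

.design_matrix <- function(tbl, exclude) {
  preds <- setdiff(c(.impute_targets_cont, .impute_targets_bin,
                     "age", "sex", "icu_admission", "died_24h"), exclude)
  cols <- lapply(preds, function(p) {
    x <- tbl[[p]]
    if (is.character(x)) as.numeric(x == "M") else as.numeric(x)
  })
  X <- cbind(1, do.call(cbind, cols))
  colnames(X) <- c("(Intercept)", preds)
  X
}

# one chained-equations sweep over the incomplete variables
.sweep_once <- function(data, miss_idx, k_donors) {
  for (v in names(miss_idx)) {
    mis <- miss_idx[[v]]
    obs <- setdiff(seq_len(nrow(data)), mis)
    X <- .design_matrix(data, exclude = v)
    if (v %in% .impute_targets_bin) {
      y <- as.numeric(data[[v]])
      fit <- tryCatch(
        suppressWarnings(glm.fit(X[obs, , drop = FALSE], y[obs],
                                 family = binomial())),
        error = function(e) NULL
      )
      if (is.null(fit) || any(!is.finite(coef(fit)))) {
        # degenerate model (e.g. separation): fall back to marginal draw
        data[[v]][mis] <- sample(data[[v]][obs], length(mis), replace = TRUE)
        next
      }
      beta <- coef(fit)
      beta[is.na(beta)] <- 0
      p <- plogis(drop(X[mis, , drop = FALSE] %*% beta))
      data[[v]][mis] <- runif(length(mis)) < p
    } else {
      draw <- .bayes_lm_draw(X[obs, , drop = FALSE], data[[v]][obs])
      pred_obs <- drop(X[obs, draw$keep, drop = FALSE] %*% draw$beta)
      pred_mis <- drop(X[mis, draw$keep, drop = FALSE] %*% draw$beta_star)
      data[[v]][mis] <- pmm_draw(pred_obs, data[[v]][obs], pred_mis, k_donors)
    }
  }
  data
}

#' Multiple imputation of missing vitals by chained equations
#'
#' Produces `m` completed copies of the cohort. Each chain initializes
#' missing cells by draws from the observed marginals, then performs
#' `iterations` sweeps; in each sweep every incomplete variable is
#' regressed on all other vitals, age, sex, the auxiliaries (urea,
#' leukocytes), ICU admission and the 24-h outcome. Continuous vitals use
#' predictive mean matching with `k_donors` donors (imputed values are
#' always observed donor values, so physiological bounds are respected);
#' the binary alertness flag uses a logistic draw. Observed cells are never
#' touched, and the whole object is deterministic given `seed` (each chain
#' runs on its own substream).
#'
#' @param cohort An `ed_cohort` that has passed [exclude_by_missingness()].
#' @param m Number of completed sets (default 20).
#' @param iterations Chained-equation sweeps per set (default 5).
#' @param seed Integer seed.
#' @param k_donors Predictive-mean-matching donor pool size (default 5).
#' @return An `ed_imputed` object: list with `sets` (m complete cohorts),
#'   `m`, `iterations`, `seed`, and `incomplete_vars`.
#' @export
mice_impute <- function(cohort, m = 20L, iterations = 5L, seed = 1L,
                        k_donors = 5L) {
  m <- as.integer(m); iterations <- as.integer(iterations)
  if (m < 1) stop_ed("m must be >= 1")
  if (m < 2) warning("m < 2: pooling across imputations is degenerate")
  if (iterations < 1) stop_ed("iterations must be >= 1")
  targets <- c(.impute_targets_cont, .impute_targets_bin)
  miss_idx <- lapply(as_tibble(cohort)[targets], function(x) which(is.na(x)))
  all_missing <- names(miss_idx)[vapply(miss_idx, length, integer(1)) == nrow(cohort) &
                                   nrow(cohort) > 0]
  if (length(all_missing) > 0) {
    stop_ed("variable(s) 100%% missing, no model can be built: %s",
            paste(all_missing, collapse = ", "))
  }
  miss_idx <- miss_idx[vapply(miss_idx, length, integer(1)) > 0]
  # impute least-missing variables first so later models see better data
  miss_idx <- miss_idx[order(vapply(miss_idx, length, integer(1)))]

  chain_seeds <- withr::with_seed(seed,
                                  sample.int(.Machine$integer.max - 1L, m))
  sets <- lapply(seq_len(m), function(ch) {
    withr::with_seed(chain_seeds[ch], {
      data <- as_tibble(cohort)
      for (v in names(miss_idx)) {
        mis <- miss_idx[[v]]
        data[[v]][mis] <- sample(data[[v]][-mis], length(mis), replace = TRUE)
      }
      sweeps <- 0L
      if (length(miss_idx) > 0) {
        for (it in seq_len(iterations)) {
          data <- .sweep_once(data, miss_idx, k_donors)
          sweeps <- sweeps + 1L
        }
      }
      attr(data, "sweeps") <- sweeps
      data
    })
  })
  structure(
    list(sets = sets, m = m, iterations = iterations, seed = seed,
         incomplete_vars = names(miss_idx)),
    class = "ed_imputed"
  )
}

#' Pool an estimate across imputed sets
#'
#' The pooled value is the arithmetic mean of the per-set values (the
#' study's stated pooling rule). Between-imputation variance is always
#' reported; when per-set (within) variances are supplied, the total
#' variance by Rubin's rules, `W + (1 + 1/m) B`, is also returned.
#'
#' @param per_set_values Numeric vector, one value per imputed set.
#' @param within Optional numeric vector of per-set sampling variances.
#' @return A `pooled_estimate`: list with `pooled`, `per_set`, `between`,
#'   and (if `within` given) `within` and `total_variance`.
#' @export
pool_estimates <- function(per_set_values, within = NULL) {
  if (length(per_set_values) == 0) stop_ed("cannot pool an empty set of values")
  m <- length(per_set_values)
  between <- if (m > 1) var(per_set_values) else 0
  out <- list(pooled = mean(per_set_values), per_set = per_set_values,
              between = between, m = m)
  if (!is.null(within)) {
    stopifnot(length(within) == m)
    out$within <- mean(within)
    out$total_variance <- out$within + (1 + 1 / m) * between
  }
  structure(out, class = "pooled_estimate")
}
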