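# End-to-end study pipeline: generate (or load) -> mask -> exclude ->
# impute -> score -> model -> evaluate, on the whole cohort and on the
# pre/post-COVID split, plus the discharged-death sensitivity analysis.

#' Configuration of a full study run
#'
#' @param generator An [generator_config()] for the synthetic cohort, or
#'   `NULL` when `cohort` supplies the data directly.
#' @param cohort Optional pre-built `ed_cohort` (e.g. from
#'   [read_cohort()]); overrides `generator`.
#' @param m,iterations Multiple-imputation settings (defaults 20 and 5).
#' @param chart_version NEWS chart version (default `"news2012"`).
#' @param thresholds Decision-curve threshold grid (default 0.001-0.10 by
#'   0.001).
#' @param split_date COVID split; presentations strictly before this date
#'   form the pre-COVID subset, the date itself and later the COVID subset
#'   (default 2020-02-01).
#' @param sensitivity_fraction Fraction of discharged patients assumed to
#'   die within 24 h in the sensitivity analysis (default 0.0004 = 0.04%).
#' @param seed_imputation,seed_sensitivity Seeds for the stochastic stages.
#' @param refit_subsets Refit the score-to-risk models within each subset
#'   (default `TRUE`); otherwise the full-cohort models are reused.
#' @param calibration_min_group Smallest score group kept in calibration
#'   output (default 20).
#' @return A `run_config` list.
#' @export
run_config <- function(generator = NULL, cohort = NULL,
                       m = 20L, iterations = 5L,
                       chart_version = "news2012",
                       thresholds = seq(0.001, 0.10, by = 0.001),
                       split_date = as.Date("2020-02-01"),
                       sensitivity_fraction = 0.0004,
                       seed_imputation = 2L, seed_sensitivity = 3L,
                       refit_subsets = TRUE,
                       calibration_min_group = 20L) {
  if (is.null(generator) && is.null(cohort)) {
    stop_ed("either a generator config or a cohort must be supplied")
  }
  if (sensitivity_fraction < 0 || sensitivity_fraction >= 1) {
    stop_ed("sensitivity_fraction must lie in [0, 1)")
  }
  split_date <- as.Date(split_date)
  if (is.na(split_date)) stop_ed("split_date is not parseable")
  structure(
    list(generator = generator, cohort = cohort, m = as.integer(m),
         iterations = as.integer(iterations), chart_version = chart_version,
         thresholds = thresholds, split_date = split_date,
         sensitivity_fraction = sensitivity_fraction,
         seed_imputation = as.integer(seed_imputation),
         seed_sensitivity = as.integer(seed_sensitivity),
         refit_subsets = isTRUE(refit_subsets),
         calibration_min_group = as.integer(calibration_min_group)),
    class = "run_config"
  )
}

#' Split a cohort at the COVID transition date
#'
#' @param cohort An `ed_cohort`.
#' @param split_date Date; records presenting strictly before it form
#'   `pre`, all others `post`. The two parts partition the cohort.
#' @return A list with elements `pre` and `post`.
#' @export
split_subsets <- function(cohort, split_date = as.Date("2020-02-01")) {
  split_date <- as.Date(split_date)
  if (is.na(split_date)) stop_ed("split_date is not parseable")
  if (anyNA(cohort$presentation_date)) {
    stop_ed("presentation_date missing for %d record(s)",
            sum(is.na(cohort$presentation_date)))
  }
  pre <- cohort$presentation_date < split_date
  list(pre = cohort[pre, , drop = FALSE], post = cohort[!pre, , drop = FALSE])
}

#' Sensitivity perturbation: assume some discharged patients died
#'
#' The primary analysis assumes no discharged patient dies within 24 h.
#' This perturbation marks exactly `round(fraction * n_discharged)`
#' discharged survivors, chosen uniformly at random, as 24-h deaths; all
#' other fields are untouched.
#'
#' @param cohort An `ed_cohort`.
#' @param fraction Fraction of discharged patients to flip (default
#'   0.0004).
#' @param seed Integer seed for the uniform draw.
#' @return The perturbed cohort.
#' @export
sensitivity_flip <- function(cohort, fraction = 0.0004, seed = 1L) {
  if (fraction < 0 || fraction >= 1) stop_ed("fraction must lie in [0, 1)")
  if (anyNA(cohort$disposition)) stop_ed("disposition missing for some records")
  discharged <- cohort$disposition == "discharged"
  n_flip <- round(fraction * sum(discharged))
  if (n_flip == 0) return(cohort)
  eligible <- which(discharged & !cohort$died_24h)
  if (length(eligible) < n_flip) {
    stop_ed("only %d discharged survivors available, %d flips requested",
            length(eligible), n_flip)
  }
  idx <- withr::with_seed(seed, sample(eligible, n_flip))
  out <- cohort
  out$died_24h[idx] <- TRUE
  out
}

# evaluate one subset: per-set scoring already done; fit models, pool AUCs
# (mean across sets, Rubin CI), paired DeLong, averaged calibration and
# decision curves
evaluate_subset <- function(sets, ids, config, chart) {
  sub_sets <- lapply(sets, function(s) s[match(ids, s$patient_id), , drop = FALSE])
  y <- sub_sets[[1]]$died_24h
  m <- length(sub_sets)
  scored <- score_cohort(
    structure(list(sets = sub_sets, m = m), class = "ed_imputed"),
    chart = chart
  )

  model_news <- fit_risk_model(scored, y, score = "news")
  model_rox <- fit_risk_model(scored, y, score = "rox")

  per_set <- lapply(seq_len(m), function(k) {
    sk <- scored[scored$.imp == k, , drop = FALSE]
    a_news <- compute_auc(sk$news, y, direction = "higher")
    a_rox <- compute_auc(sk$rox, y, direction = "lower")
    cmp <- delong_compare(sk$news, sk$rox, y,
                          direction_a = "higher", direction_b = "lower")
    risks_news <- predict_risk(model_news, sk$news)
    risks_rox <- predict_risk(model_rox, sk$rox)
    list(
      auc_news = a_news$auc, var_news = a_news$se^2,
      auc_rox = a_rox$auc, var_rox = a_rox$se^2,
      diff = cmp$difference, var_diff = cmp$variance,
      dca_news = decision_curve(risks_news, y, config$thresholds),
      dca_rox = decision_curve(risks_rox, y, config$thresholds),
      cal_news = calibration_curve(model_news, sk$news, y),
      cal_rox = calibration_curve(model_rox, sk$rox, y)
    )
  })

  pool_auc <- function(auc_key, var_key) {
    est <- pool_estimates(vapply(per_set, `[[`, numeric(1), auc_key),
                          within = vapply(per_set, `[[`, numeric(1), var_key))
    se <- sqrt(est$total_variance)
    list(auc = est$pooled, se = se,
         ci95 = clamp(est$pooled + c(-1, 1) * qnorm(0.975) * se, 0, 1),
         per_set = est$per_set)
  }
  auc_news <- pool_auc("auc_news", "var_news")
  auc_rox <- pool_auc("auc_rox", "var_rox")

  dd <- pool_estimates(vapply(per_set, `[[`, numeric(1), "diff"),
                       within = vapply(per_set, `[[`, numeric(1), "var_diff"))
  z <- if (dd$total_variance > 0) dd$pooled / sqrt(dd$total_variance) else 0
  delong <- list(difference = dd$pooled, variance = dd$total_variance,
                 z = z, p = 2 * pnorm(-abs(z)))

  avg_curves <- function(key) {
    curves <- lapply(per_set, `[[`, key)
    out <- curves[[1]]
    for (col in c("net_benefit", "standardized_net_benefit", "treat_all")) {
      out[[col]] <- rowMeans(vapply(curves, `[[`, numeric(nrow(out)), col))
    }
    out
  }
  avg_calibration <- function(key) {
    tbl <- do.call(rbind, lapply(per_set, `[[`, key))
    scores <- sort(unique(tbl$score))
    out <- do.call(rbind, lapply(scores, function(g) {
      rows <- tbl[tbl$score == g, , drop = FALSE]
      wt <- rows$n / sum(rows$n)
      tibble(score = g, n = mean(rows$n),
             predicted = sum(wt * rows$predicted),
             observed = sum(wt * rows$observed))
    }))
    out[out$n >= config$calibration_min_group, , drop = FALSE]
  }

  list(
    n = length(ids), n_deaths = sum(y), prevalence = mean(y),
    auc = list(news = auc_news, rox = auc_rox),
    delong = delong,
    models = list(
      news = list(intercept = unname(model_news$intercept),
                  slope = unname(model_news$coefficients[1])),
      rox = list(intercept = unname(model_rox$intercept),
                 slope = unname(model_rox$coefficients[1]))
    ),
    calibration = list(news = avg_calibration("cal_news"),
                       rox = avg_calibration("cal_rox")),
    decision_curves = list(news = avg_curves("dca_news"),
                           rox = avg_curves("dca_rox"))
  )
}

#' Run the full score-validation study
#'
#' Executes every stage in order: cohort generation (or intake), the
#' missingness process, the >= 4-missing-vitals exclusion, chained-equation
#' multiple imputation, NEWS/ROX scoring per imputed set, pooled logistic
#' risk models, and the three evaluation surfaces (AUC with DeLong CI and
#' paired comparison, calibration per score value, decision curves) — on
#' the full cohort, the pre/post-COVID subsets, and under the
#' discharged-death sensitivity perturbation (which is re-imputed, since
#' the outcome is an imputation predictor). Deterministic given the seeds
#' in the config.
#'
#' @param config A [run_config()].
#' @return A `study_report` list: `flow` (cohort counts), `subsets`
#'   (`all`, `pre_covid`, `post_covid`, `sensitivity`), `provenance`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  chart <- news_chart(config$chart_version)

  if (!is.null(config$cohort)) {
    masked <- config$cohort
    gen_meta <- list(source = "supplied cohort")
  } else {
    complete <- generate_cohort(config$generator)
    masked <- apply_missingness(complete, config$generator)
    gen_meta <- list(source = "synthetic",
                     seed = config$generator$seed,
                     n_requested = config$generator$n_patients)
  }

  excl <- exclude_by_missingness(masked)
  cohort <- excl$cohort
  if (nrow(cohort) == 0) stop_ed("stage exclusion: no records left to analyse")
  complete_case_fraction <-
    mean(stats::complete.cases(as_tibble(cohort)[.counted_vitals]))

  imputed <- mice_impute(cohort, m = config$m, iterations = config$iterations,
                         seed = config$seed_imputation)

  halves <- split_subsets(cohort, config$split_date)
  subset_ids <- list(
    all = cohort$patient_id,
    pre_covid = halves$pre$patient_id,
    post_covid = halves$post$patient_id
  )
  subsets <- lapply(subset_ids, function(ids) {
    if (length(ids) == 0) return(NULL)
    evaluate_subset(imputed$sets, ids, config, chart)
  })

  # sensitivity: flip discharged survivors, then re-impute because the
  # outcome feeds the imputation models
  if (config$sensitivity_fraction > 0) {
    flipped <- sensitivity_flip(cohort, config$sensitivity_fraction,
                                seed = config$seed_sensitivity)
    imputed_sens <- mice_impute(flipped, m = config$m,
                                iterations = config$iterations,
                                seed = config$seed_imputation)
    subsets$sensitivity <- evaluate_subset(imputed_sens$sets,
                                           flipped$patient_id, config, chart)
    subsets$sensitivity$n_flipped <-
      sum(flipped$died_24h) - sum(cohort$died_24h)
  } else {
    subsets$sensitivity <- subsets$all
    subsets$sensitivity$n_flipped <- 0L
  }

  structure(
    list(
      flow = list(
        n_input = excl$n_input,
        n_excluded = excl$n_excluded,
        n_included = nrow(cohort),
        complete_case_fraction = complete_case_fraction
      ),
      subsets = subsets,
      provenance = list(
        generator = gen_meta,
        m = config$m, iterations = config$iterations,
        chart_version = chart$version,
        split_date = format(config$split_date, "%Y-%m-%d"),
        sensitivity_fraction = config$sensitivity_fraction,
        seed_imputation = config$seed_imputation,
        seed_sensitivity = config$seed_sensitivity
      )
    ),
    class = "study_report"
  )
}

#' Serialize a study report to JSON
#'
#' Writes the full report (flow counts, per-subset evaluation surfaces,
#' provenance) as JSON. Identical runs produce byte-identical files.
#'
#' @param report A `study_report` from [run_study()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null")
  invisible(path)
}
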