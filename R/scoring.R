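# Risk-score computation from raw vitals. Scoring never imputes: any
# missing input yields a missing score, never a default.

#' Load a NEWS scoring chart
#'
#' The chart is shipped as a versioned YAML asset. `news2012` is the Royal
#' College of Physicians 2012 National Early Warning Score: respiratory
#' rate, SpO2, temperature, systolic blood pressure and heart rate each map
#' to 0-3 points through ordered bands, plus 2 points for supplemental
#' oxygen (FiO2 > 0.21) and 3 points for reduced consciousness (not alert).
#' Maximum total 20.
#'
#' @param version Chart version identifier (currently `"news2012"`).
#' @return A `news_chart` object.
#' @export
news_chart <- function(version = "news2012") {
  path <- system.file("extdata", paste0("news_chart_", sub("^news", "", version), ".yaml"),
                      package = "edscores")
  if (!nzchar(path)) stop_ed("unknown NEWS chart version '%s'", version)
  chart <- yaml::read_yaml(path)
  for (p in names(chart$parameters)) {
    par <- chart$parameters[[p]]
    par$upper <- as.numeric(unlist(par$upper))
    par$points <- as.integer(unlist(par$points))
    chart$parameters[[p]] <- par
    stopifnot(length(par$upper) == length(par$points),
              !is.unsorted(head(par$upper, -1)),
              all(par$points >= 0 & par$points <= 3))
  }
  structure(chart, class = "news_chart")
}

# band lookup: round to the chart's measurement grid, then find the first
# band whose inclusive upper edge is >= the value (bands partition the line)
chart_points <- function(par, x) {
  xi <- round_half_up(x / par$resolution)
  ui <- round(head(par$upper, -1) / par$resolution)
  band <- findInterval(xi, ui, left.open = TRUE) + 1L
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(xi)
  out[ok] <- as.integer(par$points[band[ok]])
  out
}

#' Compute the ROX index
#'
#' ROX = oxygen saturation (%) / FiO2 (fraction) / respiratory rate
#' (breaths/min), rounded to the nearest integer (half rounds up), e.g.
#' 95 / 0.21 / 16 gives 28. Lower values indicate higher risk. Vectorized;
#' any missing input gives `NA` (scoring never substitutes defaults).
#'
#' @param spo2 Oxygen saturation on the percent scale, in (0, 100].
#' @param fio2 Fraction of inspired oxygen in \[0.21, 1\].
#' @param respiratory_rate Breaths per minute, > 0.
#' @return Integer ROX index values (`NA` where any input is missing).
#' @export
#' @examples
#' compute_rox(95, 0.21, 16) # 28
compute_rox <- function(spo2, fio2, respiratory_rate) {
  n <- max(length(spo2), length(fio2), length(respiratory_rate))
  spo2 <- rep_len(spo2, n); fio2 <- rep_len(fio2, n)
  rr <- rep_len(respiratory_rate, n)
  ok <- !is.na(spo2) & !is.na(fio2) & !is.na(rr)
  if (any(spo2[ok] <= 0 | spo2[ok] > 100)) {
    stop_ed("spo2 must lie in (0, 100] on the percent scale")
  }
  if (any(fio2[ok] < 0.21 | fio2[ok] > 1)) {
    stop_ed("fio2 must lie in [0.21, 1] (fraction, not percent)")
  }
  if (any(rr[ok] <= 0)) stop_ed("respiratory_rate must be > 0")
  out <- rep(NA_integer_, n)
  out[ok] <- as.integer(round_half_up(spo2[ok] / fio2[ok] / rr[ok]))
  out
}

#' Compute the National Early Warning Score
#'
#' Sums the chart points for respiratory rate, SpO2, temperature, systolic
#' blood pressure and heart rate, plus the supplemental-oxygen points when
#' FiO2 exceeds room air (0.21) and the consciousness points when the
#' patient is not alert. Vectorized; any missing input gives `NA`.
#'
#' @param respiratory_rate,spo2,temperature,sbp,heart_rate Vital signs in
#'   chart units.
#' @param fio2 Fraction of inspired oxygen; values > 0.21 count as
#'   supplemental oxygen.
#' @param alert Logical; `FALSE` for patients who need voice or pain to
#'   rouse, or are unresponsive.
#' @param chart A [news_chart()] object.
#' @return Integer NEWS totals in \[0, 20\] (`NA` where any input missing).
#' @export
#' @examples
#' compute_news(respiratory_rate = 16, spo2 = 98, fio2 = 0.21,
#'              temperature = 36.8, sbp = 120, heart_rate = 70, alert = TRUE)
compute_news <- function(respiratory_rate, spo2, fio2, temperature,
                         sbp, heart_rate, alert, chart = news_chart()) {
  stopifnot(inherits(chart, "news_chart"))
  n <- max(lengths(list(respiratory_rate, spo2, fio2, temperature,
                        sbp, heart_rate, alert)))
  respiratory_rate <- rep_len(respiratory_rate, n)
  spo2 <- rep_len(spo2, n); fio2 <- rep_len(fio2, n)
  temperature <- rep_len(temperature, n); sbp <- rep_len(sbp, n)
  heart_rate <- rep_len(heart_rate, n); alert <- rep_len(alert, n)

  check_domain <- function(x, lo, hi, what) {
    if (any(!is.na(x) & (x < lo | x > hi))) {
      stop_ed("%s outside chart coverage [%g, %g]", what, lo, hi)
    }
  }
  check_domain(respiratory_rate, 0, 120, "respiratory_rate")
  check_domain(spo2, 0, 100, "spo2")
  check_domain(fio2, 0.21, 1, "fio2")
  check_domain(temperature, 20, 45, "temperature")
  check_domain(sbp, 0, 350, "sbp")
  check_domain(heart_rate, 0, 350, "heart_rate")

  total <- chart_points(chart$parameters$respiratory_rate, respiratory_rate) +
    chart_points(chart$parameters$spo2, spo2) +
    chart_points(chart$parameters$temperature, temperature) +
    chart_points(chart$parameters$sbp, sbp) +
    chart_points(chart$parameters$heart_rate, heart_rate) +
    chart$supplemental_oxygen_points * (fio2 > 0.21) +
    chart$not_alert_points * (!alert)
  as.integer(total)
}

#' Score every patient in every imputed set
#'
#' Computes NEWS and ROX per patient per completed data set. Scores differ
#' across sets only where the underlying vitals were imputed; patients with
#' fully observed scoring inputs get identical scores in every set.
#'
#' @param imputed An `ed_imputed` object from [mice_impute()], or a single
#'   `ed_cohort` (treated as one complete set; missing inputs give `NA`
#'   scores).
#' @param chart A [news_chart()] object.
#' @return A tibble with columns `.imp`, `patient_id`, `news`, `rox`.
#' @export
score_cohort <- function(imputed, chart = news_chart()) {
  sets <- if (inherits(imputed, "ed_imputed")) imputed$sets else list(imputed)
  score_one <- function(tbl, k) {
    if (inherits(imputed, "ed_imputed")) {
      needed <- c("respiratory_rate", "spo2", "fio2", "temperature",
                  "sbp", "heart_rate", "alert")
      for (v in needed) {
        if (anyNA(tbl[[v]])) {
          i <- which(is.na(tbl[[v]]))[1]
          stop_ed("imputed set %d is incomplete: patient %s missing %s",
                  k, tbl$patient_id[i], v)
        }
      }
    }
    tibble(
      .imp = k,
      patient_id = tbl$patient_id,
      news = compute_news(tbl$respiratory_rate, tbl$spo2, tbl$fio2,
                          tbl$temperature, tbl$sbp, tbl$heart_rate,
                          tbl$alert, chart = chart),
      rox = compute_rox(tbl$spo2, tbl$fio2, tbl$respiratory_rate)
    )
  }
  out <- do.call(rbind, lapply(seq_along(sets), function(k) score_one(sets[[k]], k)))
  structure(out, class = c("ed_scores", class(out)))
}
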