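# Synthetic ED cohort generator.
#
# A latent severity score z ~ N(0,1) drives 24-h death (logistic in z), all
# vitals (means interpolated between the survivor and non-survivor strata),
# oxygen therapy, alertness, ICU admission, auxiliaries and disposition.
# Default marginal targets are those of a large Dutch multicentre ED
# population: 0.7% 24-h mortality, survivor/non-survivor vital-sign means as
# published for that registry, and per-variable missingness fractions typical
# of first-recorded ED vitals (respiratory rate ~20%, FiO2 ~50%, mental
# status ~68% unrecorded).

# physiological truncation bounds applied to generated values
.vital_bounds <- list(
  sbp              = c(40, 280),
  heart_rate       = c(20, 250),
  respiratory_rate = c(4, 60),
  spo2             = c(40, 100),
  temperature      = c(30, 43),
  age              = c(18, 105),
  urea             = c(0.5, 60),
  leukocytes       = c(0.1, 100)
)

.gaussian_vitals <- c("sbp", "heart_rate", "respiratory_rate", "spo2", "temperature")
.maskable_vars <- c(.gaussian_vitals, "fio2", "alert", "urea", "leukocytes")

# supplemental-oxygen FiO2 excess over room air: 0.79 * Beta(1.2, 3.5),
# mean ~0.202, so FiO2 | supplemental averages ~0.41
.fio2_beta <- c(1.2, 3.5)
.fio2_excess_mean <- 0.79 * .fio2_beta[1] / sum(.fio2_beta)

#' Configuration for the synthetic ED cohort generator
#'
#' Collects every knob of the generator: cohort size, target 24-h mortality
#' prevalence, the strength of the latent severity effect on death
#' (log-odds per SD of severity), per-vital survivor/non-survivor stratum
#' means and SDs, per-variable missingness rates and mechanism, and seeds.
#'
#' Default stratum means and SDs reproduce a large Dutch multicentre ED
#' population (e.g. SBP 143.0 mmHg among survivors vs 133.0 among 24-h
#' deaths; respiratory rate 17.8 vs 23.3 /min; SpO2 96.7 vs 93.1%); SDs are
#' taken from the whole-population column. Default missingness rates mirror
#' the same registry's imputed-value fractions (respiratory rate 19.7%,
#' temperature 12.4%, FiO2 49.6%, alertness 68.1%).
#'
#' @param n_patients Number of ED visits to generate.
#' @param target_prevalence Marginal probability of death within 24 h
#'   (default 0.007).
#' @param severity_effect Log-odds of 24-h death per SD of latent severity
#'   (default 3). Zero gives an outcome independent of all vitals.
#' @param vital_means_alive,vital_means_dead Named vectors (sbp mmHg,
#'   heart_rate bpm, respiratory_rate /min, spo2 %, temperature deg C,
#'   fio2 fraction) of stratum means.
#' @param vital_sds Named vector of draw SDs (same units). The fio2 entry is
#'   informational: FiO2 is a room-air/supplemental mixture whose spread
#'   comes from a fixed Beta law, not a normal draw.
#' @param missingness_rates Named per-variable probabilities of being
#'   unrecorded (variables: the five vitals, fio2, alert, urea, leukocytes).
#' @param missingness_mechanism One of "MCAR", "MAR" (depends on age and
#'   disposition) or "MNAR" (probability of recording rises with severity).
#' @param discharge_fraction Baseline probability that a minimally severe
#'   survivor is discharged home (default 0.6).
#' @param date_range Length-2 Date vector; presentation dates are uniform
#'   over this window (default 2019-01-01 to 2021-12-31, spanning the
#'   COVID-19 split date).
#' @param covid_split_date Date separating the pre-COVID and COVID eras
#'   (default 2020-02-01).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#'
#' @return An object of class `ed_generator_config` (a validated list).
#' @export
#' @examples
#' cfg <- generator_config(n_patients = 1000, seed = 1)
#' cohort <- generate_cohort(cfg)
generator_config <- function(n_patients,
                             target_prevalence = 0.007,
                             severity_effect = 3,
                             vital_means_alive = c(
                               sbp = 143.0, heart_rate = 85.9,
                               respiratory_rate = 17.8, spo2 = 96.7,
                               temperature = 36.9, fio2 = 0.24
                             ),
                             vital_means_dead = c(
                               sbp = 133.0, heart_rate = 95.5,
                               respiratory_rate = 23.3, spo2 = 93.1,
                               temperature = 36.4, fio2 = 0.38
                             ),
                             vital_sds = c(
                               sbp = 21.7, heart_rate = 21.2,
                               respiratory_rate = 5.1, spo2 = 3.3,
                               temperature = 0.9, fio2 = 0.10
                             ),
                             missingness_rates = c(
                               sbp = 0.015, heart_rate = 0.033,
                               respiratory_rate = 0.197, spo2 = 0.025,
                               temperature = 0.124, fio2 = 0.496,
                               alert = 0.681, urea = 0.35, leukocytes = 0.35
                             ),
                             missingness_mechanism = c("MCAR", "MAR", "MNAR"),
                             discharge_fraction = 0.6,
                             date_range = as.Date(c("2019-01-01", "2021-12-31")),
                             covid_split_date = as.Date("2020-02-01"),
                             seed = 1L) {
  missingness_mechanism <- match.arg(missingness_mechanism)
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 0) {
    stop_ed("n_patients must be a non-negative integer")
  }
  if (!is.finite(target_prevalence) ||
      target_prevalence <= 0 || target_prevalence >= 1) {
    stop_ed("target_prevalence must lie strictly inside (0, 1)")
  }
  if (!is.finite(severity_effect)) stop_ed("severity_effect must be finite")
  vital_names <- c(.gaussian_vitals, "fio2")
  for (nm in list(vital_means_alive, vital_means_dead, vital_sds)) {
    if (!all(vital_names %in% names(nm))) {
      stop_ed("vital parameter vectors must name: %s",
              paste(vital_names, collapse = ", "))
    }
  }
  if (any(vital_sds[vital_names] <= 0)) stop_ed("all vital SDs must be > 0")
  if (!all(names(missingness_rates) %in% .maskable_vars)) {
    stop_ed("missingness_rates may only name: %s",
            paste(.maskable_vars, collapse = ", "))
  }
  if (any(missingness_rates < 0 | missingness_rates > 1)) {
    stop_ed("missingness rates must lie in [0, 1]")
  }
  if (discharge_fraction < 0 || discharge_fraction > 1) {
    stop_ed("discharge_fraction must lie in [0, 1]")
  }
  if (any(vital_means_alive[c("fio2")] < 0.21) ||
      any(vital_means_dead[c("fio2")] < 0.21)) {
    stop_ed("mean FiO2 cannot be below room air (0.21)")
  }
  date_range <- as.Date(date_range)
  if (length(date_range) != 2 || any(is.na(date_range)) ||
      date_range[1] > date_range[2]) {
    stop_ed("date_range must be two ordered parseable dates")
  }
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0 || seed > .Machine$integer.max - 2L) {
    stop_ed("seed must be an integer in [0, 2^31 - 3]")
  }
  structure(
    list(
      n_patients = n_patients,
      target_prevalence = target_prevalence,
      severity_effect = severity_effect,
      vital_means_alive = vital_means_alive[vital_names],
      vital_means_dead = vital_means_dead[vital_names],
      vital_sds = vital_sds[vital_names],
      missingness_rates = missingness_rates,
      missingness_mechanism = missingness_mechanism,
      discharge_fraction = discharge_fraction,
      date_range = date_range,
      covid_split_date = as.Date(covid_split_date),
      seed = seed
    ),
    class = "ed_generator_config"
  )
}

# E[f(p(z))] under z ~ N(0,1) with p(z) = plogis(alpha + beta z)
.severity_expect <- function(f, alpha, beta) {
  integrate(function(z) f(plogis(alpha + beta * z)) * dnorm(z),
            -Inf, Inf, rel.tol = 1e-10)$value
}

# solve the intercept alpha so the marginal death probability hits the target
solve_alpha <- function(beta, prevalence) {
  g <- function(a) .severity_expect(identity, a, beta) - prevalence
  sol <- tryCatch(
    uniroot(g, interval = c(-80, 40), tol = 1e-12, extendInt = "upX"),
    error = function(e) stop_ed("cannot solve intercept for severity_effect = %g: %s",
                                beta, conditionMessage(e))
  )
  achieved <- .severity_expect(identity, sol$root, beta)
  if (abs(achieved - prevalence) > 1e-6 * max(prevalence, 1e-6)) {
    stop_ed("intercept solve did not reach target prevalence (severity_effect pathological?)")
  }
  sol$root
}

# E[f(z) * g(p(z))] under z ~ N(0,1)
.severity_expect_z <- function(fz, gp, alpha, beta) {
  integrate(function(z) fz(z) * gp(plogis(alpha + beta * z)) * dnorm(z),
            -Inf, Inf, rel.tol = 1e-10)$value
}

# Interpolation weight w(z), linear in the latent severity z, with slope
# and offset chosen so E[w | died] = 1 and E[w | survived] = 0 exactly:
# any quantity interpolated as m_alive + (m_dead - m_alive) * w(z) then
# matches the configured stratum means in expectation. Returns the weight
# function plus the stratum moments of z needed to correct residual SDs.
.interp_params <- function(alpha, beta) {
  if (beta == 0) {
    return(list(wfun = function(z) rep(0, length(z)), slope = 0,
                z_alive = 0, z_died = 0, var_z_alive = 1))
  }
  pbar <- .severity_expect(identity, alpha, beta)
  z_died <- .severity_expect_z(identity, identity, alpha, beta) / pbar
  z_alive <- -pbar * z_died / (1 - pbar)
  slope <- 1 / (z_died - z_alive)
  ez2_alive <- .severity_expect_z(function(z) z^2, function(p) 1 - p,
                                  alpha, beta) / (1 - pbar)
  list(
    wfun = function(z) (z - z_alive) * slope,
    slope = slope, z_alive = z_alive, z_died = z_died,
    var_z_alive = ez2_alive - z_alive^2
  )
}

# per-patient latent vital mean given the interpolation weight (exported
# logic reused by tests as an oracle)
vital_mean_given_w <- function(config, vital, w) {
  a <- config$vital_means_alive[[vital]]
  d <- config$vital_means_dead[[vital]]
  a + (d - a) * w
}

# Residual draw SD per vital: the z-driven mean spread is carved out of the
# configured (survivor-stratum ~ whole-population) SD so that the marginal
# alive-stratum SD matches the configured target.
.residual_sd <- function(sd_cfg, diff, params) {
  mean_var <- (diff * params$slope)^2 * params$var_z_alive
  resid <- sd_cfg^2 - mean_var
  if (resid <= (0.2 * sd_cfg)^2) {
    stop_ed("configured SD %g is too small for the stratum separation %g", sd_cfg, diff)
  }
  sqrt(resid)
}

# Logistic-in-severity interpolation for bounded probabilities (oxygen
# therapy, alertness, ICU admission): q(z) = plogis(a + b z) with (a, b)
# solved by quadrature so that E[q | alive] and E[q | died] hit the targets
# exactly (an affine weight would clip at 0/1 and bias the strata).
.solve_prob_interp <- function(t_alive, t_died, alpha, beta, params) {
  stopifnot(t_alive > 0, t_alive < 1, t_died > 0, t_died < 1)
  pbar <- .severity_expect(identity, alpha, beta)
  if (beta == 0 || abs(t_alive - t_died) < 1e-12) {
    q <- (1 - pbar) * t_alive + pbar * t_died
    return(function(z) rep(q, length(z)))
  }
  strata <- function(a, b) {
    qa <- .severity_expect_z(function(z) plogis(a + b * z), function(p) 1 - p,
                             alpha, beta) / (1 - pbar)
    qd <- .severity_expect_z(function(z) plogis(a + b * z), identity,
                             alpha, beta) / pbar
    c(qa, qd)
  }
  obj <- function(par) {
    got <- strata(par[1], par[2])
    sum((got - c(t_alive, t_died))^2)
  }
  b0 <- (qlogis(t_died) - qlogis(t_alive)) / (params$z_died - params$z_alive)
  a0 <- qlogis(t_alive) - b0 * params$z_alive
  fit <- stats::optim(c(a0, b0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  if (fit$value > 1e-10) {
    stop_ed("cannot match stratum probabilities (%g, %g) with a logistic severity link",
            t_alive, t_died)
  }
  function(z) plogis(fit$par[1] + fit$par[2] * z)
}

.empty_cohort <- function(with_severity = TRUE) {
  tbl <- tibble(
    patient_id = character(), age = numeric(), sex = character(),
    sbp = numeric(), heart_rate = numeric(), respiratory_rate = numeric(),
    spo2 = numeric(), temperature = numeric(), fio2 = numeric(),
    alert = logical(), urea = numeric(), leukocytes = numeric(),
    icu_admission = logical(), disposition = character(),
    died_24h = logical(), presentation_date = as.Date(character())
  )
  if (with_severity) tbl$severity <- numeric()
  tbl
}

new_ed_cohort <- function(tbl, meta = list()) {
  structure(tbl, class = c("ed_cohort", class(tibble())), meta = meta)
}

#' Generate a synthetic ED cohort
#'
#' Draws `n_patients` visits from the latent-severity model described in
#' [generator_config()]. Death within 24 h occurs with probability
#' `plogis(alpha + severity_effect * z)` where the intercept `alpha` is
#' solved numerically so the marginal death rate equals
#' `target_prevalence`. Each vital is normal around a mean interpolated
#' between the survivor and non-survivor stratum targets as a monotone
#' function of severity, truncated to physiological bounds; supplemental
#' oxygen (FiO2 > 0.21), reduced alertness, ICU admission and abnormal
#' auxiliaries (urea, leukocytes) are all more likely at high severity.
#' Discharged patients never carry the 24-h death flag, matching the
#' registry's primary-analysis assumption that no discharged patient dies
#' within 24 h.
#'
#' The returned cohort is complete (no missing values); use
#' [apply_missingness()] to impose the recording process. The latent
#' severity is kept in column `severity` as simulation ground truth.
#'
#' @param config An [generator_config()] object.
#' @return An `ed_cohort` tibble with one row per visit.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ed_generator_config"))
  n <- config$n_patients
  if (n == 0) {
    return(new_ed_cohort(.empty_cohort(), meta = list(config = config)))
  }
  beta <- config$severity_effect
  alpha <- solve_alpha(beta, config$target_prevalence)
  params <- .interp_params(alpha, beta)

  resid_sds <- vapply(.gaussian_vitals, function(v) {
    .residual_sd(config$vital_sds[[v]],
                 config$vital_means_dead[[v]] - config$vital_means_alive[[v]],
                 params)
  }, numeric(1))

  # bounded severity-linked probabilities, stratum targets hit exactly
  ps_alive <- (config$vital_means_alive[["fio2"]] - 0.21) / .fio2_excess_mean
  ps_dead <- (config$vital_means_dead[["fio2"]] - 0.21) / .fio2_excess_mean
  q_supp <- .solve_prob_interp(ps_alive, ps_dead, alpha, beta, params)
  q_alert <- .solve_prob_interp(0.96, 0.30, alpha, beta, params)
  q_icu <- .solve_prob_interp(0.02, 0.50, alpha, beta, params)

  withr::with_seed(config$seed, {
    z <- rnorm(n)
    p_death <- plogis(alpha + beta * z)
    died <- runif(n) < p_death
    w <- params$wfun(z)

    draws <- list()
    for (v in .gaussian_vitals) {
      mu <- vital_mean_given_w(config, v, w)
      b <- .vital_bounds[[v]]
      draws[[v]] <- clamp(rnorm(n, mu, resid_sds[[v]]), b[1], b[2])
    }

    # FiO2: room air (0.21) unless on supplemental oxygen
    supplemental <- runif(n) < q_supp(z)
    fio2 <- rep(0.21, n)
    n_supp <- sum(supplemental)
    if (n_supp > 0) {
      fio2[supplemental] <- pmin(
        0.21 + 0.79 * rbeta(n_supp, .fio2_beta[1], .fio2_beta[2]), 1
      )
    }

    age <- clamp(rnorm(n, 61.2 + (74.1 - 61.2) * w, 18.5),
                 .vital_bounds$age[1], .vital_bounds$age[2])
    sex <- ifelse(runif(n) < clamp(0.505 + (0.538 - 0.505) * w, 0, 1), "M", "F")
    alert <- runif(n) < q_alert(z)
    icu <- runif(n) < q_icu(z)
    urea <- clamp(rnorm(n, 6.0 + (12.0 - 6.0) * w, 4.0),
                  .vital_bounds$urea[1], .vital_bounds$urea[2])
    leukocytes <- clamp(rnorm(n, 9.0 + (13.5 - 9.0) * w, 4.0),
                        .vital_bounds$leukocytes[1], .vital_bounds$leukocytes[2])

    p_discharge <- clamp(config$discharge_fraction * (1 - w), 0, 1)
    discharged <- !died & !icu & (runif(n) < p_discharge)
    disposition <- ifelse(discharged, "discharged", "admitted")

    n_days <- as.integer(config$date_range[2] - config$date_range[1]) + 1L
    presentation_date <- config$date_range[1] +
      (sample.int(n_days, n, replace = TRUE) - 1L)

    tbl <- tibble(
      patient_id = sprintf("P%07d", seq_len(n)),
      age = age, sex = sex,
      sbp = draws$sbp, heart_rate = draws$heart_rate,
      respiratory_rate = draws$respiratory_rate,
      spo2 = draws$spo2, temperature = draws$temperature, fio2 = fio2,
      alert = alert, urea = urea, leukocytes = leukocytes,
      icu_admission = icu, disposition = disposition,
      died_24h = died & !discharged,
      presentation_date = presentation_date,
      severity = z
    )
    new_ed_cohort(tbl, meta = list(config = config, alpha = alpha,
                                   interp = params[c("slope", "z_alive", "z_died",
                                                     "var_z_alive")],
                                   residual_sds = resid_sds))
  })
}

#' Impose a missing-data recording process on a complete cohort
#'
#' Marks vitals, FiO2, alertness and auxiliary labs as unrecorded (`NA`) at
#' the per-variable rates in the configuration. Under MCAR cells are masked
#' by independent coin flips; under MAR the masking probability depends on
#' observed age and disposition (younger, discharged patients have fewer
#' vitals recorded); under MNAR recording is driven by the latent severity
#' itself — nurses measure respiratory rate mainly in patients who look
#' ill, so masking probability falls with severity. Observed values are
#' never altered.
#'
#' @param cohort A complete `ed_cohort` (no prior missingness).
#' @param config The [generator_config()] that carries `missingness_rates`,
#'   `missingness_mechanism` and the seed (masking uses `seed + 1`).
#' @return The cohort with masked cells set to `NA`.
#' @export
apply_missingness <- function(cohort, config) {
  stopifnot(inherits(config, "ed_generator_config"))
  rates <- config$missingness_rates
  if (any(rates < 0 | rates > 1)) stop_ed("missingness rates must lie in [0, 1]")
  vars <- intersect(names(rates), names(cohort))
  if (any(vapply(cohort[vars], anyNA, logical(1)))) {
    stop_ed("cohort already contains missing values; apply_missingness expects a complete cohort")
  }
  n <- nrow(cohort)
  if (n == 0) return(cohort)
  mech <- config$missingness_mechanism
  if (mech == "MNAR" && is.null(cohort$severity)) {
    stop_ed("MNAR masking needs the latent severity column")
  }
  out <- cohort
  withr::with_seed(config$seed + 1L, {
    for (v in vars) {
      r <- rates[[v]]
      if (r == 0) next
      if (r == 1) { out[[v]][] <- NA; next }
      p <- switch(mech,
        MCAR = rep(r, n),
        MAR = plogis(qlogis(r) +
                       0.4 * as.numeric(scale(cohort$age)) +
                       0.8 * (as.numeric(cohort$disposition == "discharged") -
                                mean(cohort$disposition == "discharged"))),
        MNAR = plogis(qlogis(r) - 0.8 * cohort$severity)
      )
      out[[v]][runif(n) < p] <- NA
    }
  })
  out
}
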