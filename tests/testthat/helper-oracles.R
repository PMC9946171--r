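# Independent oracles and fixture builders shared across the test files.

# closed-form mean / variance of a normal draw clamped to [lo, hi]
clamp_norm_mean <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  lo * pnorm(a) + hi * (1 - pnorm(b)) +
    mu * (pnorm(b) - pnorm(a)) - sigma * (dnorm(b) - dnorm(a))
}

clamp_norm_var <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  m2 <- lo^2 * pnorm(a) + hi^2 * (1 - pnorm(b)) +
    (mu^2 + sigma^2) * (pnorm(b) - pnorm(a)) +
    sigma^2 * (a * dnorm(a) - b * dnorm(b)) +
    2 * mu * sigma * (dnorm(a) - dnorm(b))
  m2 - clamp_norm_mean(mu, sigma, lo, hi)^2
}

# exhaustive pairwise concordance probability, ties counted 1/2
brute_force_auc <- function(scores, outcomes) {
  x <- scores[as.logical(outcomes)]
  y <- scores[!as.logical(outcomes)]
  mean(outer(x, y, ">") + 0.5 * outer(x, y, "=="))
}

# hand-built minimal cohort with full control over each field
make_fixture_cohort <- function(n, seed = 1) {
  withr::with_seed(seed, {
    edscores:::new_ed_cohort(tibble::tibble(
      patient_id = sprintf("F%05d", seq_len(n)),
      age = runif(n, 20, 90),
      sex = sample(c("M", "F"), n, replace = TRUE),
      sbp = runif(n, 90, 180),
      heart_rate = runif(n, 55, 120),
      respiratory_rate = runif(n, 10, 28),
      spo2 = runif(n, 90, 100),
      temperature = runif(n, 35.5, 38.5),
      fio2 = sample(c(0.21, 0.21, 0.21, 0.4), n, replace = TRUE),
      alert = runif(n) < 0.95,
      urea = runif(n, 3, 15),
      leukocytes = runif(n, 4, 15),
      icu_admission = runif(n) < 0.03,
      disposition = sample(c("admitted", "discharged"), n, replace = TRUE),
      died_24h = logical(n),
      presentation_date = as.Date("2019-06-01") + sample.int(700, n, replace = TRUE),
      severity = rnorm(n)
    ))
  })
}

# one shared large default-config cohort, built lazily and reused so the
# expensive generation runs once per test session
shared_cohort_env <- new.env()
get_shared_cohort <- function() {
  if (is.null(shared_cohort_env$cohort)) {
    cfg <- generator_config(n_patients = 200000, seed = 424242)
    shared_cohort_env$config <- cfg
    shared_cohort_env$cohort <- generate_cohort(cfg)
  }
  list(cohort = shared_cohort_env$cohort, config = shared_cohort_env$config)
}
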