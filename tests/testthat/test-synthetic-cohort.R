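test_that("empty and invalid configurations are handled explicitly", {
  cfg <- generator_config(n_patients = 0, seed = 1)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 0)
  expect_true(all(c("patient_id", "sbp", "died_24h", "severity") %in% names(co)))

  expect_error(generator_config(n_patients = -5), "non-negative")
  expect_error(generator_config(10, target_prevalence = 0), "0, 1")
  expect_error(generator_config(10, vital_sds = c(
    sbp = -1, heart_rate = 21, respiratory_rate = 5, spo2 = 3,
    temperature = 0.9, fio2 = 0.1
  )), "SDs")
  expect_error(generator_config(10, missingness_rates = c(spo2 = 1.4)), "\\[0, 1\\]")
})

test_that("same seed and config give identical cohorts and byte-identical files", {
  cfg <- generator_config(n_patients = 2000, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))

  ma <- apply_missingness(a, cfg)
  mb <- apply_missingness(b, cfg)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ma, f1)
  write_cohort(mb, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("marginal 24-h death rate converges to the target prevalence", {
  sh <- get_shared_cohort()
  n <- nrow(sh$cohort)
  prev <- sh$config$target_prevalence
  se <- sqrt(prev * (1 - prev) / n)
  expect_lt(abs(mean(sh$cohort$died_24h) - prev), 3 * se)
})

test_that("stratum means of generated vitals match the configured targets", {
  sh <- get_shared_cohort()
  co <- sh$cohort
  cfg <- sh$config
  died <- co$died_24h
  meta <- attr(co, "meta")
  w <- (co$severity - meta$interp$z_alive) * meta$interp$slope

  for (v in c("sbp", "heart_rate", "respiratory_rate", "spo2", "temperature")) {
    bounds <- edscores:::.vital_bounds[[v]]
    sd_res <- meta$residual_sds[[v]]
    mu <- edscores:::vital_mean_given_w(cfg, v, w)
    exp_mean <- clamp_norm_mean(mu, sd_res, bounds[1], bounds[2])
    exp_var <- clamp_norm_var(mu, sd_res, bounds[1], bounds[2])
    for (stratum in list(died, !died)) {
      m_exp <- mean(exp_mean[stratum])
      # per-patient conditional expectations leave only draw noise
      se <- sqrt(mean(exp_var[stratum])) / sqrt(sum(stratum))
      expect_lt(abs(mean(co[[v]][stratum]) - m_exp), 3 * se)
      # and the model expectation itself sits close to the configured
      # target (truncation shifts it by a known, small amount)
      target <- if (isTRUE(all.equal(stratum, died))) {
        cfg$vital_means_dead[[v]]
      } else {
        cfg$vital_means_alive[[v]]
      }
      expect_lt(abs(m_exp - target), max(0.15 * cfg$vital_sds[[v]], 3 * se))
    }
  }

  # FiO2 stratum means: room-air/supplemental mixture solved to the target
  for (stratum in list(alive = !died, dead = died)) {
    target <- if (mean(died[stratum]) > 0.5) cfg$vital_means_dead[["fio2"]]
              else cfg$vital_means_alive[["fio2"]]
    se <- sd(co$fio2[stratum]) / sqrt(sum(stratum))
    expect_lt(abs(mean(co$fio2[stratum]) - target), 3 * se)
  }

  # alive-stratum SDs carry the configured totals (dead stratum is wider
  # by construction; the registry's own dead-stratum SDs are wider still)
  for (v in c("sbp", "heart_rate", "respiratory_rate", "temperature")) {
    sd_emp <- sd(co[[v]][!died])
    se_sd <- cfg$vital_sds[[v]] / sqrt(2 * sum(!died))
    expect_lt(abs(sd_emp - cfg$vital_sds[[v]]), max(4 * se_sd, 0.02 * cfg$vital_sds[[v]]))
  }
})

test_that("severity-linked covariates separate the survival strata in the right direction", {
  sh <- get_shared_cohort()
  co <- sh$cohort
  d <- co$died_24h
  expect_gt(mean(co$alert[!d]), mean(co$alert[d]))
  expect_gt(mean(co$icu_admission[d]), mean(co$icu_admission[!d]))
  expect_gt(mean(co$age[d]), mean(co$age[!d]))
  expect_gt(mean(co$urea[d]), mean(co$urea[!d]))
  expect_false(any(co$died_24h & co$disposition == "discharged"))
  expect_true(all(co$fio2 >= 0.21 & co$fio2 <= 1))
  expect_true(all(co$spo2 <= 100 & co$spo2 >= 40))
})

test_that("a zero severity effect yields chance-level discrimination", {
  cfg <- generator_config(n_patients = 50000, severity_effect = 0, seed = 7)
  co <- generate_cohort(cfg)
  sc <- score_cohort(co)
  r <- compute_auc(sc$news, co$died_24h, direction = "higher")
  expect_lt(abs(r$auc - 0.5), 3 * r$se)
})

test_that("MCAR masking hits the nominal rate and never alters observed values", {
  cfg <- generator_config(
    n_patients = 100000, seed = 21,
    missingness_rates = c(respiratory_rate = 0.197),
    missingness_mechanism = "MCAR"
  )
  full <- generate_cohort(cfg)
  masked <- apply_missingness(full, cfg)
  frac <- mean(is.na(masked$respiratory_rate))
  se <- sqrt(0.197 * (1 - 0.197) / nrow(full))
  expect_lt(abs(frac - 0.197), 3 * se)

  obs <- !is.na(masked$respiratory_rate)
  expect_identical(masked$respiratory_rate[obs], full$respiratory_rate[obs])
  expect_identical(masked$spo2, full$spo2) # untargeted variable untouched

  # zero rates are the identity
  cfg0 <- generator_config(n_patients = 5000, seed = 3,
                           missingness_rates = c(respiratory_rate = 0))
  co <- generate_cohort(cfg0)
  expect_identical(as.data.frame(apply_missingness(co, cfg0)), as.data.frame(co))

  # re-masking an already masked cohort is refused
  expect_error(apply_missingness(masked, cfg), "complete cohort")
})

test_that("MNAR recording follows severity: sicker patients are measured more", {
  cfg <- generator_config(
    n_patients = 50000, seed = 31,
    missingness_rates = c(respiratory_rate = 0.2),
    missingness_mechanism = "MNAR"
  )
  masked <- apply_missingness(generate_cohort(cfg), cfg)
  miss <- is.na(masked$respiratory_rate)
  r <- cor(as.numeric(miss), masked$severity)
  expect_lt(r, -0.05)
})

test_that("MAR masking depends on observed age and disposition", {
  cfg <- generator_config(
    n_patients = 50000, seed = 41,
    missingness_rates = c(temperature = 0.15),
    missingness_mechanism = "MAR"
  )
  masked <- apply_missingness(generate_cohort(cfg), cfg)
  miss <- is.na(masked$temperature)
  disch <- masked$disposition == "discharged"
  expect_gt(mean(miss[disch]), mean(miss[!disch]))
  expect_gt(cor(as.numeric(miss), masked$age), 0.02)
})
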