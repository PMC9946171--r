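test_that("AUC equals exhaustive pairwise concordance with ties at one half", {
  # hand-enumerable case: cases {3,5}, controls {1,2,4} -> 5/6
  y <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- compute_auc(c(3, 5, 1, 2, 4), y, direction = "higher")
  expect_equal(r$auc, 5 / 6)
  # pure ties and perfect separation
  expect_equal(compute_auc(rep(2, 5), y)$auc, 0.5)
  expect_equal(compute_auc(c(9, 8, 1, 2, 3), y)$auc, 1.0)
  # direction flip: a risk-decreasing score oriented correctly
  expect_equal(compute_auc(c(-3, -5, -1, -2, -4), y, direction = "lower")$auc, 5 / 6)

  withr::with_seed(101, {
    for (i in 1:40) {
      n <- sample(10:200, 1)
      y <- runif(n) < runif(1, 0.15, 0.6)
      if (sum(y) == 0 || sum(!y) == 0) next
      s <- round(rnorm(n) + y, sample(0:1, 1)) # rounding injects ties
      expect_equal(compute_auc(s, y)$auc, brute_force_auc(s, y), tolerance = 1e-12)
    }
  })
})

test_that("ROC curve is a monotone path from (0,0) to (1,1) containing the AUC in its CI", {
  withr::with_seed(111, {
    y <- runif(500) < 0.3
    s <- round(rnorm(500) + y * 0.8, 1)
    r <- compute_auc(s, y)
    expect_equal(unlist(r$curve[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
    expect_true(r$auc >= r$ci95[1] && r$auc <= r$ci95[2])
    # trapezoid area under the curve equals the concordance AUC
    area <- sum(diff(r$curve$fpr) * (head(r$curve$tpr, -1) + tail(r$curve$tpr, -1)) / 2)
    expect_equal(area, r$auc, tolerance = 1e-12)
  })
})

test_that("DeLong variance and paired comparison agree with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(121, {
    for (i in 1:8) {
      n <- sample(40:400, 1)
      y <- runif(n) < 0.35
      if (sum(y) < 3 || sum(!y) < 3) next
      a <- round(rnorm(n) + y * 1.1, 1)
      b <- round(rnorm(n) + y * 0.6, 1)
      r <- compute_auc(a, y)
      ra <- pROC::roc(y, a, quiet = TRUE, direction = "<")
      expect_equal(r$auc, as.numeric(ra$auc), tolerance = 1e-12)
      expect_equal(r$se^2, pROC::var(ra), tolerance = 1e-12)
      cmp <- delong_compare(a, b, y)
      ref <- pROC::roc.test(ra, pROC::roc(y, b, quiet = TRUE, direction = "<"),
                            method = "delong", paired = TRUE)
      expect_equal(cmp$p, ref$p.value, tolerance = 1e-10)
      expect_equal(cmp$difference, cmp$auc_a - cmp$auc_b)
    }
  })
})

test_that("a score compared with itself shows no difference", {
  withr::with_seed(131, {
    y <- runif(200) < 0.3
    s <- rnorm(200) + y
    cmp <- delong_compare(s, s, y)
    expect_equal(cmp$difference, 0)
    expect_equal(cmp$p, 1)
  })
})

test_that("binormal scores converge to the closed-form AUC", {
  withr::with_seed(141, {
    n <- 50000
    y <- rep(c(TRUE, FALSE), c(5000, 45000))
    s <- rnorm(n, mean = ifelse(y, 1, 0), sd = 1)
    r <- compute_auc(s, y)
    expect_lt(abs(r$auc - pnorm(1 / sqrt(2))), 3 * r$se)
  })
})

test_that("logistic risk models recover generating parameters and calibrate in the large", {
  withr::with_seed(151, {
    n <- 100000
    s <- sample(0:15, n, replace = TRUE)
    p <- plogis(-5 + 0.4 * s)
    y <- runif(n) < p
    model <- fit_risk_model(as.numeric(s), y, score = "news")
    ref <- glm(y ~ s, family = binomial())
    expect_equal(unname(model$intercept), unname(coef(ref)[1]), tolerance = 1e-8)
    expect_equal(unname(model$coefficients[1]), unname(coef(ref)[2]), tolerance = 1e-8)
    se_slope <- summary(ref)$coefficients[2, 2]
    expect_lt(abs(model$coefficients[1] - 0.4), 3 * se_slope)
    # calibration in the large: mean predicted risk == observed prevalence
    expect_equal(mean(predict_risk(model, s)), mean(y), tolerance = 1e-10)

    # null case: slope indistinguishable from zero
    y0 <- runif(50000) < 0.05
    s0 <- sample(0:15, 50000, replace = TRUE)
    m0 <- fit_risk_model(as.numeric(s0), y0)
    se0 <- summary(glm(y0 ~ s0, family = binomial()))$coefficients[2, 2]
    expect_lt(abs(m0$coefficients[1]), 3 * se0)
  })
})

test_that("single-class outcomes and separation are explicit failures", {
  expect_error(fit_risk_model(as.numeric(1:10), rep(FALSE, 10)), "single outcome class")
  y <- rep(c(FALSE, TRUE), each = 20)
  s <- c(rep(0, 20), rep(10, 20)) + rep(c(0, 0.1), 20)
  expect_error(fit_risk_model(s, y), "separation")
  expect_error(compute_auc(1:5, rep(TRUE, 5)), "both outcome classes")
})

test_that("calibration groups by integer score with faithful group statistics", {
  withr::with_seed(161, {
    n <- 40000
    s <- sample(0:12, n, replace = TRUE, prob = dbinom(0:12, 12, 0.3))
    y <- runif(n) < plogis(-6 + 0.5 * s)
    model <- fit_risk_model(as.numeric(s), y)
    cal <- calibration_curve(model, s, y)
    expect_equal(sum(cal$n), n)
    expect_true(all(cal$observed >= 0 & cal$observed <= 1))
    expect_identical(cal$score, sort(unique(as.numeric(s))))
    # well-specified model: predicted tracks observed in large groups
    big <- cal[cal$n >= 500, ]
    se_group <- sqrt(big$predicted * (1 - big$predicted) / big$n)
    expect_true(all(abs(big$predicted - big$observed) <= 3 * se_group))
    # group counts below the cutoff are dropped on request
    cal20 <- calibration_curve(model, s, y, min_group_size = 20)
    expect_true(all(cal20$n >= 20))
  })
})

test_that("net benefit reproduces direct confusion-matrix arithmetic", {
  # 100 patients, 10 events; at p_t = 0.10 all events and 20 non-events flagged
  risks <- c(rep(0.5, 10), rep(0.2, 20), rep(0.01, 70))
  y <- rep(c(TRUE, FALSE), c(10, 90))
  dc <- decision_curve(risks, y, thresholds = 0.10)
  expect_equal(dc$net_benefit, 10 / 100 - (20 / 100) * (0.1 / 0.9))
  expect_equal(dc$standardized_net_benefit, dc$net_benefit / 0.1)
  expect_equal(exchange_rate(0.10), 1 / 9)

  # everyone flagged -> net benefit equals the treat-all reference
  dc_all <- decision_curve(rep(1, 100), y, thresholds = c(0.01, 0.05))
  expect_equal(dc_all$net_benefit, dc_all$treat_all)
  # nobody flagged -> treat-none
  dc_none <- decision_curve(rep(0, 100), y, thresholds = 0.05)
  expect_equal(dc_none$net_benefit, 0)

  expect_error(decision_curve(risks, y, thresholds = 1.0), "0, 1")
  expect_error(decision_curve(risks * 3, y, thresholds = 0.1), "\\[0, 1\\]")
})

test_that("net-benefit properties hold on random cohorts", {
  withr::with_seed(171, {
    for (i in 1:25) {
      n <- sample(50:500, 1)
      r <- runif(n)^2
      y <- runif(n) < r * 0.5 + 0.05
      if (sum(y) == 0) next
      th <- sort(runif(5, 0.01, 0.9))
      dc <- decision_curve(r, y, thresholds = th)
      prev <- mean(y)
      # oracle: direct enumeration
      for (j in seq_along(th)) {
        pos <- r >= th[j]
        nb <- sum(pos & y) / n - sum(pos & !y) / n * th[j] / (1 - th[j])
        expect_equal(dc$net_benefit[j], nb, tolerance = 1e-12)
      }
      expect_true(all(dc$standardized_net_benefit <= 1 + 1e-12))
      expect_true(all(dc$net_benefit <= prev + 1e-12))
      expect_true(all(dc$treat_none == 0))
    }
  })
})
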