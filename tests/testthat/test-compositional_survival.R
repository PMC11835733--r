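test_that("log-contrast transform follows the compositional definition", {
  al <- matrix(c(0.8, 0.2), 1, 2,
               dimnames = list(NULL, c("concordant", "d1")))
  z <- log_contrast(al)
  expect_equal(unname(z[1, "lr_d1"]), log(0.25), tolerance = 1e-12)

  u <- matrix(1 / 3, 4, 3,
              dimnames = list(NULL, c("concordant", "d1", "d2")))
  expect_true(all(abs(log_contrast(u)) < 1e-12))
  expect_error(log_contrast(u, reference = "nope"), "reference")

  # scaling p_k by sqrt(e) and the rest by 1/sqrt(e) raises z_k by exactly
  # 1 and leaves the other log-ratios unchanged
  p <- c(concordant = 0.6, d1 = 0.25, d2 = 0.15)
  p2 <- p * c(1 / sqrt(exp(1)), sqrt(exp(1)), 1 / sqrt(exp(1)))
  p2 <- p2 / sum(p2)
  z1 <- log_contrast(matrix(p, 1, dimnames = list(NULL, names(p))))
  z2 <- log_contrast(matrix(p2, 1, dimnames = list(NULL, names(p))))
  expect_equal(unname(z2[1, "lr_d1"] - z1[1, "lr_d1"]), 1, tolerance = 1e-12)
  expect_equal(unname(z2[1, "lr_d2"]), unname(z1[1, "lr_d2"]), tolerance = 1e-12)

  # floor choice is immaterial for interior probabilities
  for (fl in c(1e-8, 1e-6, 1e-4)) {
    expect_equal(unname(log_contrast(al, floor = fl)[1, 1]), log(0.25),
                 tolerance = 1e-9)
  }
})

test_that("Cox fitting recovers planted hazards and rank concordance", {
  set.seed(61)
  n <- 5000
  grp <- stats::rbinom(n, 1, 0.5)
  t_ev <- stats::rexp(n, rate = 0.05 * exp(0.7 * grp))
  event <- as.integer(t_ev <= 10)
  time <- pmin(t_ev, 10)
  fit <- fit_cox(data.frame(grp = grp), time, event)
  se <- sqrt(fit$vcov["grp", "grp"])
  expect_lt(abs(fit$coefficients[["grp"]] - 0.7), 1.96 * se)

  # perfectly rank-ordered risk gives C = 1
  lp <- stats::rnorm(300)
  fitp <- suppressWarnings(
    fit_cox(data.frame(x = lp), time = exp(-lp), event = rep(1, 300)))
  expect_equal(fitp$concordance, 1, tolerance = 1e-12)

  expect_error(fit_cox(data.frame(x = 1:20), time = rep(1, 20),
                       event = rep(0, 20)), "events")
})

test_that("nested comparison equals the independent likelihood-ratio path", {
  set.seed(62)
  n <- 2000
  x1 <- stats::rnorm(n)
  x2 <- stats::rnorm(n)
  t_ev <- stats::rexp(n, rate = 0.05 * exp(0.5 * x1 + 0.3 * x2))
  event <- as.integer(t_ev <= 10)
  time <- pmin(t_ev, 10)
  base <- fit_cox(data.frame(x1 = x1), time, event)
  full <- fit_cox(data.frame(x1 = x1, x2 = x2), time, event)
  cmp <- compare_nested(base, full, n_boot = 50, seed = 1)

  # oracle: anova on the underlying survival fits
  an <- stats::anova(base$model, full$model)
  expect_equal(cmp$lrt, an[2, "Chisq"], tolerance = 1e-8)
  expect_equal(cmp$p, an[2, "Pr(>|Chi|)"], tolerance = 1e-8)
  expect_equal(cmp$df, 1)
  expect_gte(cmp$lrt, 0)
  # explained-variation bookkeeping
  expect_equal(cmp$r2_full, 1 - exp(-2 * (full$loglik - full$loglik_null) / n),
               tolerance = 1e-12)
  expect_gte(cmp$added_variance_pct, 0)
  expect_gt(cmp$delta_c, 0)

  # identical models: degenerate comparison
  same <- compare_nested(base, base, n_boot = 10, seed = 1)
  expect_equal(same$lrt, 0)
  expect_equal(same$delta_c, 0)
  expect_equal(same$added_variance_pct, 0)
  expect_error(compare_nested(full, base), "not nested")
})

test_that("lasso Cox shrinks noise and keeps planted signal", {
  set.seed(63)
  n <- 2000
  x <- matrix(stats::rnorm(n * 12), n, 12,
              dimnames = list(NULL, paste0("v", 1:12)))
  lp <- 0.8 * x[, 1] - 0.8 * x[, 2] + 0.8 * x[, 3]
  t_ev <- stats::rexp(n, rate = 0.05 * exp(lp))
  event <- as.integer(t_ev <= 10)
  time <- pmin(t_ev, 10)
  las <- lasso_cox(x, time, event, seed = 4)
  expect_true(all(las$coefficients[c("v1", "v2", "v3")] != 0))
  # coefficients of the 9 noise covariates shrink toward zero
  expect_lt(max(abs(las$coefficients[paste0("v", 4:12)])),
            min(abs(las$coefficients[c("v1", "v2", "v3")])))

  # at the top of the penalty path everything is zero
  top <- as.numeric(stats::coef(las$cv_fit$glmnet.fit,
                                s = max(las$cv_fit$lambda)))
  expect_true(all(abs(top) < 1e-8))

  # near-zero penalty approaches the unpenalized partial-likelihood fit
  unpen <- fit_cox(as.data.frame(x[, 1:3]), time, event)
  near0 <- glmnet::glmnet(x[, 1:3], survival::Surv(time, event),
                          family = "cox", lambda = c(0.05, 1e-5),
                          thresh = 1e-14)
  expect_equal(as.numeric(stats::coef(near0, s = 1e-5)),
               unname(unpen$coefficients), tolerance = 1e-3)
})

test_that("biomarker back-mapping solves the allocation equation", {
  p <- 10
  mu <- c(3, -2.5, rep(0, 8))
  means <- rbind(d_a = mu, concordant = rep(0, p))
  colnames(means) <- biomarker_names()
  mix <- make_mixture(means, list(diag(p), diag(p)), c(0.15, 0.85),
                      c("d_a", "concordant"))
  cohort <- make_mini_cohort(200, seed = 64)
  fp <- residualize(cohort)$fit_params

  for (tp in c(0.3, 0.6, 0.9)) {
    sb <- shift_biomarkers(mix, "d_a", tp, fp)
    back <- allocate(mix, matrix(sb$residual, 1,
                                 dimnames = list(NULL, colnames(means))))
    expect_equal(unname(back[1, "d_a"]), tp, tolerance = 1e-6)
  }
  # distance along the ray grows with the target probability
  t1 <- shift_biomarkers(mix, "d_a", 0.3, fp)$t
  t2 <- shift_biomarkers(mix, "d_a", 0.9, fp)$t
  expect_gt(t2, t1)
  # raw-unit mapping inverts the stored regression at the fixed covariates
  sb <- shift_biomarkers(mix, "d_a", 0.5, fp, age = 55, bmi = 30, smoking = 0)
  j <- match("fg", fp$biomarker)
  expected_fg <- fp$intercept1[j] + fp$age_coef[j] * 55 + fp$intercept2[j] +
    fp$bmi_coef[j] * 30 + fp$center[j] + sb$residual["fg"] * fp$scale[j]
  expect_equal(unname(sb$biomarkers["fg"]), unname(expected_fg),
               tolerance = 1e-10)
  # probabilities below the posterior at the concordant center are off the ray
  expect_error(shift_biomarkers(mix, "d_a", 1e-6, fp), "attainable")
})

test_that("shift hazard ratios match the linear-predictor oracle", {
  p <- 10
  mu_a <- c(3, -2.5, rep(0, 8))
  mu_b <- c(rep(0, 8), 2.5, 2.5)
  means <- rbind(d_a = mu_a, d_b = mu_b, concordant = rep(0, p))
  colnames(means) <- biomarker_names()
  mix <- make_mixture(means, rep(list(diag(p)), 3), c(0.1, 0.08, 0.82),
                      c("d_a", "d_b", "concordant"))
  fp <- residualize(make_mini_cohort(200, seed = 65))$fit_params

  beta <- c(lr_d_a = 0.4, lr_d_b = -0.2,
            stats::setNames(seq(0.05, 0.5, length.out = 10),
                            biomarker_names()))
  V <- diag(0.01, length(beta))
  dimnames(V) <- list(names(beta), names(beta))
  fake <- structure(list(coefficients = beta, vcov = V, n = 1000L),
                    class = "survival_fit")
  hr <- shift_risk(fake, mix, "d_a", fp, delta = 0.10)

  # oracle: recompute the covariate difference with plain arithmetic
  w <- c(d_a = 0.1, d_b = 0.08, concordant = 0.82)
  confs <- lapply(list(w, w + c(0.10, 0, -0.10)), function(pv) {
    z <- log(pv[c("d_a", "d_b")] / pv["concordant"])
    r <- shift_biomarkers(mix, "d_a", pv[["d_a"]], fp)$residual
    c(stats::setNames(z, c("lr_d_a", "lr_d_b")), r)
  })
  dlp <- sum(beta * (confs[[2]] - confs[[1]])[names(beta)])
  expect_equal(log(hr$estimate), dlp, tolerance = 1e-10)

  # zero coefficients force HR = 1 exactly
  fake0 <- fake
  fake0$coefficients[] <- 0
  expect_equal(shift_risk(fake0, mix, "d_a", fp)$estimate, 1)

  # HR is continuous in delta: tiny shifts give HR ~ 1
  tiny <- shift_risk(fake, mix, "d_a", fp, delta = 1e-6)
  expect_equal(tiny$estimate, 1, tolerance = 1e-3)
  expect_error(shift_risk(fake, mix, "d_a", fp, delta = 0.95), "outside")
})
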