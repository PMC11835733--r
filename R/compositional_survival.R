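# Log-contrast Cox models for profile probabilities ----------------------
#
# Allocation probabilities sum to 1, so they enter regression through the
# log-contrast representation of compositional data: for each discordant
# profile k, z_k = ln(p_k / p_concordant). A one-unit increase in z_k
# scales p_k by sqrt(e) relative to all other profiles.

#' Log-ratio transform of an allocation matrix
#'
#' Probabilities are floored at `floor` and renormalized before taking
#' `ln(p_k / p_reference)` for every discordant profile.
#'
#' @param alloc Allocation matrix with profile column names.
#' @param reference Label of the reference (concordant) column.
#' @param floor Probability floor guarding the logarithm (default 1e-6).
#' @return N x (K-1) matrix with columns `lr_<label>`.
#' @export
log_contrast <- function(alloc, reference = "concordant", floor = 1e-6) {
  if (!reference %in% colnames(alloc))
    stop(sprintf("reference profile '%s' not present", reference))
  p <- pmax(alloc, floor)
  p <- p / rowSums(p)
  others <- setdiff(colnames(alloc), reference)
  z <- log(p[, others, drop = FALSE] / p[, reference])
  colnames(z) <- paste0("lr_", others)
  z
}

#' Fit a Cox proportional hazards model
#'
#' Partial-likelihood maximization with Efron tie handling; Harrell's
#' concordance is retained along with the pieces needed for nested model
#' comparison. Rows with prevalent disease must be excluded upstream.
#'
#' @param design data.frame of covariates (may include log-ratio columns).
#' @param time Positive follow-up times (years).
#' @param event 0/1 event indicators (>= 10 events required).
#' @return A `survival_fit`: coefficients, covariance, log partial
#'   likelihoods (null and fitted), concordance, linear predictor and data
#'   handles.
#' @export
fit_cox <- function(design, time, event) {
  stopifnot(all(time > 0), all(event %in% 0:1))
  if (sum(event) < 10) stop("fewer than 10 events")
  df <- cbind(data.frame(.time = time, .event = event), design)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = df,
                         ties = "efron", x = TRUE,
                         control = survival::coxph.control(iter.max = 50))
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info)))
    warning("Cox model did not converge")
  structure(
    list(coefficients = stats::coef(fit), vcov = stats::vcov(fit),
         loglik_null = fit$loglik[1], loglik = fit$loglik[2],
         concordance = unname(fit$concordance["concordance"]),
         lp = unname(fit$linear.predictors),
         n = fit$n, nevent = fit$nevent,
         time = time, event = event, covariate_names = colnames(design),
         model = fit),
    class = "survival_fit"
  )
}

#' Compare nested Cox models
#'
#' Likelihood ratio test of the added terms (df = number of added
#' parameters); likelihood-based explained variation
#' `R2 = 1 - exp(-LR_vs_null / n)` per model, with the added variation
#' reported as a percentage of the full model's total (the null-model
#' denominator variant is also returned); and the difference in Harrell's
#' C with a paired-bootstrap standard error (linear predictors held
#' fixed).
#'
#' @param base,full `survival_fit` objects on the same rows, base
#'   covariates nested in full.
#' @param n_boot Bootstrap replicates for the delta-C covariance
#'   (default 200).
#' @param seed Seed for the bootstrap resampling.
#' @return List with `lrt`, `df`, `p`, `r2_base`, `r2_full`,
#'   `added_variance_pct`, `added_variance_pct_null_denom`, `c_base`,
#'   `c_full`, `delta_c`, `delta_c_se`, `delta_c_p`.
#' @export
compare_nested <- function(base, full, n_boot = 200L, seed = 1L) {
  if (!all(base$covariate_names %in% full$covariate_names))
    stop("models are not nested")
  if (base$n != full$n) stop("models were fitted on different rows")
  df <- length(full$coefficients) - length(base$coefficients)
  if (df < 0) stop("full model has fewer parameters than base")
  lrt <- 2 * (full$loglik - base$loglik)
  p <- if (df == 0) NA_real_ else stats::pchisq(lrt, df = df, lower.tail = FALSE)

  n <- full$n
  r2 <- function(fit) 1 - exp(-2 * (fit$loglik - fit$loglik_null) / n)
  r2b <- r2(base)
  r2f <- r2(full)
  added_full <- if (r2f > 0) 100 * (r2f - r2b) / r2f else 0
  added_null <- if (r2b > 0) 100 * (r2f - r2b) / r2b else NA_real_

  cstat <- function(lp, time, event) {
    cf <- survival::concordance(survival::Surv(time, event) ~ lp,
                                reverse = TRUE)
    unname(cf$concordance)
  }
  dc <- full$concordance - base$concordance
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (sum(full$event[idx]) < 2) return(NA_real_)
    cstat(full$lp[idx], full$time[idx], full$event[idx]) -
      cstat(base$lp[idx], base$time[idx], base$event[idx])
  }, numeric(1))
  dc_se <- stats::sd(boot, na.rm = TRUE)
  dc_p <- if (dc_se > 0) 2 * stats::pnorm(-abs(dc / dc_se)) else NA_real_

  list(lrt = lrt, df = df, p = p,
       r2_base = r2b, r2_full = r2f,
       added_variance_pct = added_full,
       added_variance_pct_null_denom = added_null,
       c_base = base$concordance, c_full = full$concordance,
       delta_c = dc, delta_c_se = dc_se, delta_c_p = dc_p)
}

#' Lasso-penalized Cox regression
#'
#' Penalized partial likelihood over a penalty path; the penalty is chosen
#' at the minimum cross-validated deviance with seeded fold assignment.
#'
#' @param design data.frame or matrix of covariates.
#' @param time,event Survival outcome.
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Seed for fold assignment.
#' @return List with `coefficients` (at the selected penalty), `lambda`,
#'   and the `cv_fit` object.
#' @export
lasso_cox <- function(design, time, event, n_folds = 10L, seed = 1L) {
  x <- as.matrix(design)
  if (sum(event) < n_folds) stop("fewer events than folds")
  y <- survival::Surv(time, event)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(n_folds), nrow(x)))
  cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(beta) <- rownames(stats::coef(cv, s = "lambda.min"))
  if (all(beta == 0))
    warning("all coefficients shrunk to zero at the selected penalty")
  list(coefficients = beta, lambda = cv$lambda.min, cv_fit = cv)
}

# posterior probability of `target` at residual r under the mixture
.posterior_at <- function(mixture, r, target) {
  allocate(mixture, matrix(r, nrow = 1,
                           dimnames = list(NULL, colnames(mixture$means))))[1, target]
}

#' Biomarker values realizing a target profile probability
#'
#' Moves along the ray from the concordant center (residual 0) toward the
#' target component's mean until the posterior probability of the target
#' profile equals `target_prob` (monotone root finding, tolerance 1e-8),
#' then maps the residual vector back to raw biomarker units at fixed
#' covariates through the stored residualization parameters.
#'
#' @param mixture Fitted `mixture_model`.
#' @param target Discordant profile label.
#' @param target_prob Desired allocation probability in (0, 1).
#' @param fit_params `fit_params` from [residualize()].
#' @param age,bmi,smoking Fixed covariates (defaults: 55 years,
#'   30 kg/m^2, non-smoker).
#' @return List with `biomarkers` (named raw-scale vector), `residual`
#'   (z-scale vector) and `t` (position along the ray).
#' @export
shift_biomarkers <- function(mixture, target, target_prob, fit_params,
                             age = 55, bmi = 30, smoking = 0) {
  stopifnot(target %in% mixture$labels, target != mixture$concordant)
  if (target_prob <= 0 || target_prob >= 1)
    stop("target_prob must be in (0, 1)")
  mu <- mixture$means[target, ]
  post <- function(t) .posterior_at(mixture, t * mu, target)
  # the posterior rises toward the component mean, then can fall again
  # as the flatter concordant tail takes over; root-find on the rising
  # branch only
  t_max <- 3
  grid <- seq(0, t_max, length.out = 201)
  pg <- vapply(grid, post, numeric(1))
  peak <- which.max(pg)
  if (target_prob < pg[1] || target_prob > pg[peak]) {
    stop(sprintf(
      "target_prob %.4f not attainable on the segment; attainable range [%.6f, %.6f]",
      target_prob, pg[1], pg[peak]))
  }
  f <- function(t) post(t) - target_prob
  t_star <- stats::uniroot(f, c(0, grid[peak]), tol = 1e-10)$root
  r <- t_star * mu
  raw <- unresidualize(fit_params, r[fit_params$biomarker], age, bmi, smoking)
  names(raw) <- fit_params$biomarker
  list(biomarkers = raw, residual = r, t = t_star)
}

#' Hazard ratio of a probability shift toward a discordant profile
#'
#' Compares two covariate configurations: the baseline profile
#' probabilities (by default the population mixture weights) versus the
#' same probabilities with `delta` mass moved from the concordant to the
#' target profile, other discordant profiles held fixed. Both the
#' discordant log-ratio terms and the biomarker terms change consistently:
#' each configuration's biomarker values come from [shift_biomarkers()] at
#' its target-profile probability. The hazard ratio is
#' `exp(beta' (x_shift - x_base))` over the model terms that change, with
#' a delta-method confidence interval from the coefficient covariance.
#'
#' @param full `survival_fit` containing the log-ratio and biomarker
#'   terms.
#' @param mixture Fitted `mixture_model`.
#' @param target Discordant profile label.
#' @param fit_params Residualization parameters for biomarker back-mapping.
#' @param baseline_probs Baseline probability vector (default: mixture
#'   weights).
#' @param delta Probability mass shifted (default 0.10).
#' @param floor Probability floor for the log-ratios.
#' @param biomarker_scale `"residual"` if the Cox model used standardized
#'   residuals as biomarker covariates (default), `"raw"` if raw units.
#' @inheritParams shift_biomarkers
#' @return One-row data.frame with the HR and 95% CI.
#' @export
shift_risk <- function(full, mixture, target, fit_params,
                       baseline_probs = NULL, delta = 0.10, floor = 1e-6,
                       biomarker_scale = c("residual", "raw"),
                       age = 55, bmi = 30, smoking = 0) {
  biomarker_scale <- match.arg(biomarker_scale)
  labs <- mixture$labels
  conc <- mixture$concordant
  if (is.null(baseline_probs)) {
    baseline_probs <- stats::setNames(mixture$weights, labs)
  }
  p0 <- baseline_probs[labs]
  p1 <- p0
  p1[conc] <- p1[conc] - delta
  p1[target] <- p1[target] + delta
  if (any(p1 <= 0) || any(p1 >= 1))
    stop("delta pushes a probability outside (0, 1)")

  covvec <- function(pv) {
    pm <- matrix(pv, nrow = 1, dimnames = list(NULL, labs))
    z <- log_contrast(pm, reference = conc, floor = floor)[1, ]
    sb <- shift_biomarkers(mixture, target, pv[target], fit_params,
                           age = age, bmi = bmi, smoking = smoking)
    bio <- if (biomarker_scale == "residual") sb$residual else sb$biomarkers
    c(z, bio)
  }
  dx <- covvec(p1) - covvec(p0)
  beta <- full$coefficients
  d <- stats::setNames(numeric(length(beta)), names(beta))
  shared <- intersect(names(beta), names(dx))
  d[shared] <- dx[shared]
  est <- sum(beta * d)
  se <- sqrt(drop(t(d) %*% full$vcov %*% d))
  out <- .profile_estimate(target, est, se,
                           2 * stats::pnorm(-abs(est / ifelse(se > 0, se, Inf))),
                           full$n, transform = exp)
  out$se <- se
  out
}
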