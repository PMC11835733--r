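# Probability-weighted profile estimates ---------------------------------
#
# All estimators weight individuals by their profile allocation
# probability, so an individual contributes fractionally to every profile.
# Under one-hot allocations each estimator reduces exactly to its
# unweighted subgroup counterpart.

#' Weighted summary of a variable within a profile
#'
#' Weighted mean and SD by direct moment formulas (frequency-weight
#' denominator `sum(w) - 1`, so one-hot weights reproduce the subgroup
#' `sd()` exactly); weighted median and quartiles by cumulative-weight
#' interpolation at plotting positions `(cum_w - w/2) / sum(w)` (with
#' equal unit weights this coincides with `quantile(type = 5)`).
#'
#' @param values Numeric vector.
#' @param probs Allocation probabilities (same length, >= 0, not all 0).
#' @return List with `mean`, `sd`, `median`, `iqr`, `q25`, `q75`,
#'   `effective_n` (sum of weights).
#' @export
weighted_summary <- function(values, probs) {
  stopifnot(length(values) == length(probs), all(probs >= 0))
  if (sum(probs) == 0) stop("all weights are zero")
  m <- sum(values * probs) / sum(probs)
  v <- sum(probs * (values - m)^2) / max(sum(probs) - 1, .Machine$double.eps)
  q <- weighted_quantile(values, probs, c(0.25, 0.5, 0.75))
  list(mean = m, sd = sqrt(v), median = q[2], iqr = q[3] - q[1],
       q25 = q[1], q75 = q[3], effective_n = sum(probs))
}

#' Weighted quantiles by cumulative-weight interpolation
#'
#' @param values Numeric vector.
#' @param probs Non-negative weights.
#' @param p Quantile levels.
#' @return Numeric vector of quantiles.
#' @export
weighted_quantile <- function(values, probs, p) {
  o <- order(values)
  x <- values[o]
  w <- probs[o]
  pos <- (cumsum(w) - w / 2) / sum(w)
  vapply(p, function(pp) {
    if (pp <= pos[1]) return(x[1])
    if (pp >= pos[length(pos)]) return(x[length(x)])
    stats::approx(pos, x, xout = pp, ties = "ordered")$y
  }, numeric(1))
}

.profile_estimate <- function(label, estimate, se, p, eff_n,
                              transform = identity) {
  data.frame(
    profile = label, estimate = transform(estimate), se = se,
    ci_low = transform(estimate - 1.96 * se),
    ci_high = transform(estimate + 1.96 * se),
    p = p, effective_n = eff_n, stringsAsFactors = FALSE
  )
}

#' Profile-specific BMI-biomarker slope
#'
#' Weighted least squares of the biomarker on BMI with age and smoking
#' adjustment, using the profile allocation probabilities as regression
#' weights. Standard errors are heteroscedasticity-robust (HC0 sandwich),
#' since the weights are estimated quantities rather than sampling
#' weights.
#'
#' @param biomarker,bmi,age,smoking Per-individual vectors.
#' @param probs Allocation probabilities for the profile.
#' @param label Profile label carried into the result.
#' @return One-row data.frame (estimate is the BMI slope).
#' @export
weighted_slope <- function(biomarker, bmi, age, smoking, probs,
                           label = "profile") {
  df <- data.frame(y = biomarker, bmi = bmi, age = age, smoking = smoking,
                   w = probs)
  df <- df[df$w > 0, , drop = FALSE]  # zero-weight rows distort robust SEs
  fit <- stats::lm(y ~ bmi + age + smoking, data = df, weights = w)
  if (any(!is.finite(stats::coef(fit))))
    stop("collinear design in weighted_slope()")
  vc <- sandwich::vcovHC(fit, type = "HC0")
  b <- stats::coef(fit)[["bmi"]]
  se <- sqrt(vc["bmi", "bmi"])
  .profile_estimate(label, b, se, 2 * stats::pnorm(-abs(b / se)), sum(probs))
}

#' Probability-weighted prevalence or incidence rate
#'
#' Prevalence is `sum(case * p) / sum(p)`; with follow-up times the
#' incidence rate is `sum(event * p) / sum(fu * p)` (events per
#' person-year). Confidence intervals come from the weighted binomial /
#' Poisson likelihood with the Kish effective sample size.
#'
#' @param events 0/1 vector.
#' @param probs Allocation probabilities.
#' @param followup Optional positive follow-up times (years); when given,
#'   an incidence rate is returned instead of a prevalence.
#' @param label Profile label.
#' @return One-row data.frame.
#' @export
weighted_prevalence_incidence <- function(events, probs, followup = NULL,
                                          label = "profile") {
  stopifnot(all(events %in% 0:1), all(probs >= 0))
  if (is.null(followup)) {
    denom <- sum(probs)
    if (denom == 0) stop("zero total weight")
    prev <- sum(events * probs) / denom
    n_eff <- sum(probs)^2 / sum(probs^2)
    se <- sqrt(max(prev * (1 - prev), .Machine$double.eps) / n_eff)
    .profile_estimate(label, prev, se, NA_real_, sum(probs))
  } else {
    stopifnot(all(followup > 0))
    denom <- sum(followup * probs)
    if (denom == 0) stop("zero weighted person-time")
    rate <- sum(events * probs) / denom
    # weighted Poisson: var(log rate) ~ sum(event * p^2) / (sum(event * p))^2
    ev_w <- sum(events * probs)
    se_log <- if (ev_w > 0) sqrt(sum(events * probs^2)) / ev_w else NA_real_
    out <- .profile_estimate(label, log(rate), se_log, NA_real_, sum(probs),
                             transform = exp)
    out$se <- se_log
    out
  }
}

#' Odds or rate ratio of a discordant profile versus the concordant
#'
#' Probability-weighted binomial (odds ratio) or Poisson (rate ratio, with
#' log person-time offset) regression: each individual enters twice, once
#' with its exposure-profile probability and once with its
#' reference-profile probability. Standard errors are cluster-robust by
#' individual (each individual's two weighted copies are dependent).
#' Quasi families are used so fractional weights are accepted.
#'
#' @param outcome 0/1 vector.
#' @param probs_exposure,probs_reference Allocation probabilities of the
#'   two profiles.
#' @param family `"binomial"` (OR) or `"poisson"` (RR).
#' @param followup Person-time offset (required for `"poisson"`).
#' @param label Profile label.
#' @return One-row data.frame; `estimate` and CI on the ratio scale.
#' @export
profile_ratio <- function(outcome, probs_exposure, probs_reference,
                          family = c("binomial", "poisson"),
                          followup = NULL, label = "profile") {
  family <- match.arg(family)
  stopifnot(all(outcome %in% 0:1))
  n <- length(outcome)
  df <- data.frame(
    y = rep(outcome, 2),
    group = rep(c(1, 0), each = n),
    id = rep(seq_len(n), 2),
    w = c(probs_exposure, probs_reference)
  )
  if (family == "poisson") {
    if (is.null(followup)) stop("poisson family requires follow-up times")
    df$off <- rep(log(followup), 2)
  }
  df <- df[df$w > 0, , drop = FALSE]
  fit <- if (family == "poisson") {
    stats::glm(y ~ group + offset(off), family = stats::quasipoisson(),
               data = df, weights = w)
  } else {
    stats::glm(y ~ group, family = stats::quasibinomial(), data = df,
               weights = w)
  }
  b <- stats::coef(fit)[["group"]]
  if (!is.finite(b) || abs(b) > 10) {
    # separation fallback: continuity-corrected weighted 2x2 table
    a <- sum(probs_exposure * outcome) + 0.5
    bb <- sum(probs_exposure * (1 - outcome)) + 0.5
    cc <- sum(probs_reference * outcome) + 0.5
    d <- sum(probs_reference * (1 - outcome)) + 0.5
    b <- log((a * d) / (bb * cc))
    se <- sqrt(1 / a + 1 / bb + 1 / cc + 1 / d)
    warning("separation detected; continuity-corrected estimate returned")
  } else {
    vc <- sandwich::vcovCL(fit, cluster = df$id, type = "HC0")
    se <- sqrt(vc["group", "group"])
  }
  out <- .profile_estimate(label, b, se, 2 * stats::pnorm(-abs(b / se)),
                           sum(probs_exposure), transform = exp)
  out$se <- se
  out
}

#' Ratios for every discordant profile with FDR adjustment
#'
#' Runs [profile_ratio()] for each discordant profile against the
#' concordant reference and appends Benjamini-Hochberg adjusted p-values
#' and a 5% FDR significance flag.
#'
#' @param outcome 0/1 vector.
#' @param alloc Allocation matrix (columns named by profile).
#' @param concordant Label of the reference column.
#' @inheritParams profile_ratio
#' @return data.frame, one row per discordant profile.
#' @export
profile_ratios <- function(outcome, alloc, concordant = "concordant",
                           family = "binomial", followup = NULL) {
  if (!concordant %in% colnames(alloc)) stop("reference profile not found")
  labs <- setdiff(colnames(alloc), concordant)
  res <- do.call(rbind, lapply(labs, function(lab) {
    profile_ratio(outcome, alloc[, lab], alloc[, concordant],
                  family = family, followup = followup, label = lab)
  }))
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  res$fdr_flag <- res$p_fdr < 0.05
  res
}

#' Pool per-cohort estimates by meta-analysis
#'
#' Fixed-effects inverse-variance pooling, or random-effects with a
#' DerSimonian-Laird between-cohort variance.
#'
#' @param estimates Log-scale per-cohort estimates.
#' @param se Their standard errors.
#' @param method `"random"` (default, the more conservative choice) or
#'   `"fixed"`.
#' @return List with `estimate`, `se`, `ci_low`, `ci_high`, `tau2`,
#'   `method`.
#' @export
meta_analyze <- function(estimates, se, method = c("random", "fixed")) {
  method <- match.arg(method)
  fit <- metafor::rma(yi = estimates, sei = se,
                      method = if (method == "random") "DL" else "FE")
  list(estimate = as.numeric(fit$beta), se = fit$se,
       ci_low = fit$ci.lb, ci_high = fit$ci.ub,
       tau2 = if (method == "random") fit$tau2 else 0,
       method = method)
}
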