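# BMI-biomarker discordance ----------------------------------------------

#' Remove gross biomarker outliers
#'
#' Values beyond `sd_threshold` standard deviations from the stratum mean
#' are treated as erroneous measurements; the whole row is dropped
#' (complete-case analysis).
#'
#' @param cohort Cohort data.frame with the ten biomarker columns.
#' @param sd_threshold Threshold in SD units (default 5).
#' @return List with `cohort` (filtered) and `log` (per-column flag counts
#'   plus rows removed).
#' @export
remove_outliers <- function(cohort, sd_threshold = 5) {
  cols <- biomarker_names()
  stopifnot(all(cols %in% names(cohort)))
  flags <- vapply(cols, function(cl) {
    x <- cohort[[cl]]
    abs(x - mean(x)) > sd_threshold * stats::sd(x)
  }, logical(nrow(cohort)))
  if (nrow(cohort) == 1L) flags <- matrix(flags, nrow = 1L,
                                          dimnames = list(NULL, cols))
  drop_row <- rowSums(flags) > 0
  if (all(drop_row)) stop("outlier removal would drop every individual")
  list(
    cohort = cohort[!drop_row, , drop = FALSE],
    log = list(per_column = colSums(flags), rows_removed = sum(drop_row),
               sd_threshold = sd_threshold)
  )
}

#' Residualize biomarkers against BMI with age/smoking adjustment
#'
#' Per biomarker, a two-stage least-squares fit: (1) the biomarker is
#' regressed on age and smoking status and the residual taken; (2) that
#' adjusted biomarker is regressed on BMI. The stage-2 residuals — the
#' departures from the BMI-based expectation — are centered and scaled to
#' unit standard deviation. All fitted coefficients and the scaling
#' constants are stored so the transformation can be re-applied
#' out-of-sample and inverted for biomarker back-mapping.
#'
#' When smoking status is constant in the stratum the smoking term is
#' dropped with a warning (its coefficient is recorded as 0).
#'
#' @param cohort QC'd cohort data.frame (complete cases).
#' @return A `residual_matrix`: list with `values` (N x 10 matrix of
#'   z-scores), `fit_params` (per-biomarker coefficients and scaling) and
#'   `stratum`.
#' @export
residualize <- function(cohort) {
  cols <- biomarker_names()
  stopifnot(all(c(cols, "age", "smoking", "bmi") %in% names(cohort)))
  if (anyNA(cohort[c(cols, "age", "smoking", "bmi")]))
    stop("missing values present; residualize() expects complete cases")
  smoking_const <- stats::var(cohort$smoking) == 0
  if (smoking_const)
    warning("smoking status is constant in this stratum; term dropped")

  n <- nrow(cohort)
  values <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  fp <- data.frame(
    biomarker = cols, intercept1 = NA_real_, age_coef = NA_real_,
    smoking_coef = NA_real_, intercept2 = NA_real_, bmi_coef = NA_real_,
    center = NA_real_, scale = NA_real_, stringsAsFactors = FALSE
  )
  for (j in seq_along(cols)) {
    y <- cohort[[cols[j]]]
    if (smoking_const) {
      f1 <- stats::lm(y ~ age, data = cohort)
      c1 <- c(stats::coef(f1), smoking = 0)
    } else {
      f1 <- stats::lm(y ~ age + smoking, data = cohort)
      c1 <- stats::coef(f1)
    }
    r1 <- stats::residuals(f1)
    f2 <- stats::lm(r1 ~ bmi, data = cohort)
    r2 <- stats::residuals(f2)
    ctr <- mean(r2)
    scl <- stats::sd(r2)
    if (scl == 0) stop(sprintf("biomarker '%s' has zero residual variance", cols[j]))
    values[, j] <- (r2 - ctr) / scl
    fp$intercept1[j] <- c1[["(Intercept)"]]
    fp$age_coef[j] <- c1[["age"]]
    fp$smoking_coef[j] <- if (smoking_const) 0 else c1[["smoking"]]
    fp$intercept2[j] <- stats::coef(f2)[["(Intercept)"]]
    fp$bmi_coef[j] <- stats::coef(f2)[["bmi"]]
    fp$center[j] <- ctr
    fp$scale[j] <- scl
  }
  structure(
    list(values = values, fit_params = fp,
         stratum = if ("sex" %in% names(cohort)) unique(cohort$sex) else NA),
    class = "residual_matrix"
  )
}

#' Apply stored residualization parameters to a cohort
#'
#' Reproduces the standardized deviations from raw data using the
#' coefficients stored by [residualize()]; on the fitting cohort the result
#' is bit-identical to the original values.
#'
#' @param fit_params `fit_params` data.frame from a `residual_matrix`.
#' @param cohort Cohort data.frame.
#' @return N x 10 matrix of standardized deviations.
#' @export
apply_residualize <- function(fit_params, cohort) {
  cols <- fit_params$biomarker
  values <- matrix(NA_real_, nrow(cohort), length(cols),
                   dimnames = list(NULL, cols))
  for (j in seq_along(cols)) {
    expected <- fit_params$intercept1[j] +
      fit_params$age_coef[j] * cohort$age +
      fit_params$smoking_coef[j] * cohort$smoking +
      fit_params$intercept2[j] +
      fit_params$bmi_coef[j] * cohort$bmi
    values[, j] <- (cohort[[cols[j]]] - expected - fit_params$center[j]) /
      fit_params$scale[j]
  }
  values
}

#' Invert residualization for one biomarker
#'
#' Maps a standardized deviation back to the raw biomarker scale at given
#' covariate values.
#'
#' @keywords internal
unresidualize <- function(fit_params, z, age, bmi, smoking) {
  fit_params$intercept1 + fit_params$age_coef * age +
    fit_params$smoking_coef * smoking + fit_params$intercept2 +
    fit_params$bmi_coef * bmi + fit_params$center + z * fit_params$scale
}

#' Multivariate discordance scores
#'
#' Squared Mahalanobis distance of each residual vector to the
#' multivariate normal centered at the BMI-based expectation (the origin in
#' residual space), using the stratum residual covariance. Under
#' multivariate normality the squared distance is chi-square distributed
#' with df equal to the number of biomarkers, giving an upper-tail p-value
#' per individual.
#'
#' @param residuals A `residual_matrix` or plain matrix of standardized
#'   deviations.
#' @return data.frame with `d2` and `pvalue`.
#' @export
mahalanobis_discordance <- function(residuals) {
  x <- if (inherits(residuals, "residual_matrix")) residuals$values else residuals
  S <- stats::cov(x)
  ok <- tryCatch({chol(S); TRUE}, error = function(e) FALSE)
  if (!ok) stop("residual covariance is singular")
  d2 <- stats::mahalanobis(x, center = rep(0, ncol(x)), cov = S)
  data.frame(d2 = d2,
             pvalue = stats::pchisq(d2, df = ncol(x), lower.tail = FALSE))
}

#' Test for excess multivariate discordance
#'
#' Compares the observed fraction of individuals flagged at level `alpha`
#' (Mahalanobis p-value below `alpha`) with the fraction expected under
#' multivariate normality, using an exact binomial test.
#'
#' @param scores Output of [mahalanobis_discordance()] (or a vector of
#'   p-values).
#' @param alpha Flagging level (default 0.05).
#' @return List with `observed`, `expected`, `n_flagged`, `n`, `p_binomial`.
#' @export
excess_discordance_test <- function(scores, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  p <- if (is.data.frame(scores)) scores$pvalue else scores
  if (length(p) < 1L) stop("no scores supplied")
  k <- sum(p < alpha)
  bt <- stats::binom.test(k, length(p), p = alpha)
  list(observed = k / length(p), expected = alpha, n_flagged = k,
       n = length(p), p_binomial = bt$p.value)
}

#' @export
print.residual_matrix <- function(x, ...) {
  cat(sprintf("residual_matrix: %d individuals x %d biomarkers (stratum: %s)\n",
              nrow(x$values), ncol(x$values), x$stratum))
  invisible(x)
}
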